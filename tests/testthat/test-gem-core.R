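test_that("a well-formed model validates cleanly and defects are itemized", {
  fx <- make_toy_gem(toy_gem_config(2, 1))
  expect_equal(nrow(validate_gem(fx$model)), 0L)

  bad <- fx$model
  bad$reactions[["R1_1"]]$lb <- 5
  bad$reactions[["R1_1"]]$ub <- 1
  v <- validate_gem(bad)
  expect_equal(v$rule, "bounds_ordered")
  expect_equal(v$entity, "R1_1")

  bad2 <- fx$model
  bad2$reactions[["R1_1"]]$gpr <- parse_gpr("ghost_gene")
  v2 <- validate_gem(bad2)
  expect_equal(v2$rule, "gene_exists")
  expect_match(v2$message, "ghost_gene")

  bad3 <- fx$model
  bad3$metabolites$mass[1] <- -2
  expect_equal(validate_gem(bad3)$rule, "mass_positive")
})

test_that("disabled_reactions implements knockout boolean semantics", {
  fx <- make_toy_gem(toy_gem_config(
    3, 1, features = list("1" = "isoenzyme", "2" = "complex")))
  m <- fx$model
  expect_equal(disabled_reactions(m, character()), character())
  # one member of an OR pair disables nothing
  expect_equal(disabled_reactions(m, "g1_1a"), character())
  expect_equal(disabled_reactions(m, c("g1_1a", "g1_1b")), "R1_1")
  # one member of an AND complex kills the reaction
  expect_equal(disabled_reactions(m, "g2_1a"), "R2_1")
  # single-gene reaction
  expect_equal(disabled_reactions(m, "g3_1"), "R3_1")
  # all genes: exactly the gene-controlled reactions
  all_ctrl <- names(Filter(function(r) r$gpr$kind != "empty", m$reactions))
  expect_setequal(disabled_reactions(m, m$genes), all_ctrl)
  # unknown genes are an error, not an empty result
  expect_error(disabled_reactions(m, "nope"), "unknown gene.*nope")
})

test_that("knockout monotonicity: larger deletions disable supersets", {
  fx <- trap_fixture()
  m <- fx$model
  set.seed(7)
  for (i in 1:25) {
    h <- sample(m$genes, sample(2:length(m$genes), 1))
    g <- sample(h, sample(seq_along(h), 1))
    expect_true(all(disabled_reactions(m, g) %in% disabled_reactions(m, h)))
  }
})

test_that("exchange lookup distinguishes present, absent, and ambiguous", {
  fx <- make_toy_gem(toy_gem_config(2, 1, features = list("2" = "no_exchange")))
  m <- fx$model
  expect_equal(find_exchange(m, "P1"), "EX_P1")        # by name
  expect_equal(find_exchange(m, "P1[e]"), "EX_P1")     # by metabolite id
  expect_equal(find_exchange(m, "EX_P1"), "EX_P1")     # by reaction id
  expect_true(is.na(find_exchange(m, "P2")))           # present, no exchange
  expect_true(is.na(find_exchange(m, "nothing_here"))) # absent entirely

  dup <- add_reaction(m, reaction("EX_P1_dup", c("P1[e]" = -1)))
  expect_error(find_exchange(dup, "P1"), "EX_P1.*EX_P1_dup")
})

test_that("formula masses parse standard formulas and flag unknowns", {
  expect_equal(formula_mass("C6H12O6"), 6 * 12.011 + 12 * 1.008 + 6 * 15.999)
  expect_equal(formula_mass("H2O"), 2 * 1.008 + 15.999)
  expect_equal(formula_mass("Fe"), 55.845)
  expect_error(formula_mass("C6Xx2"), "unknown element 'Xx'")
  expect_equal(formula_mass("Qq2", extra = c(Qq = 10)), 20)
  # metabolite override wins over formula
  m <- gem(metabolites = data.frame(id = "chitin[c]", name = "chitin",
                                    compartment = "c",
                                    formula = NA_character_, mass = 203.19),
           reactions = list(reaction("r1", c("chitin[c]" = -1))),
           objective = "r1")
  expect_equal(metabolite_mass(m, "chitin[c]"), 203.19)
})
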