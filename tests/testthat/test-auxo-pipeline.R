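test_that("rescue specs parse into DNF conjuncts", {
  expect_equal(parse_rescue_spec("homoserine | methionine + threonine"),
               list("homoserine", c("methionine", "threonine")))
  expect_equal(parse_rescue_spec("adenine"), list("adenine"))
  expect_error(parse_rescue_spec("a | "), "empty conjunct")
})

test_that("two-step simulation reproduces every planted classification", {
  fx <- trap_fixture()
  m <- fx$model
  pol <- default_policy(m)
  recs <- fx$truth$records
  for (i in seq_len(nrow(recs))) {
    r <- simulate_rescue(m, recs[i, ], pol)
    expect_equal(r$classification, recs$expected_pre[i],
                 label = sprintf("record %d (%s)", i, recs$knockout_genes[i]))
  }
  # trichotomy: growths are consistent with the labels
  r1 <- simulate_rescue(m, recs[1, ], pol)   # bypass trap
  expect_true(is_viable(r1$ko_growth, pol))
  r2 <- simulate_rescue(m, recs[2, ], pol)   # no-exchange trap
  expect_false(is_viable(r2$ko_growth, pol))
  expect_true(all(r2$conjunct_growths <= r2$ko_growth + 1e-9))
})

test_that("repair edits flip each trap to CORRECT and touch nothing else", {
  fx <- trap_fixture()
  m <- fx$model
  recs <- fx$truth$records
  classify_all <- function(model) {
    pol <- default_policy(model)
    vapply(seq_len(nrow(recs)), function(i)
      simulate_rescue(model, recs[i, ], pol)$classification, "")
  }
  pre <- classify_all(m)
  for (trap in names(fx$truth$repairs)) {
    m_fixed <- apply_edits(m, fx$truth$repairs[[trap]])$model
    post <- classify_all(m_fixed)
    i <- grep(trap, recs$rescue_spec, fixed = TRUE)
    expect_equal(post[i], "CORRECT", label = trap)
    expect_equal(post[-i], pre[-i], label = paste(trap, "(others untouched)"))
  }
  # all repairs together: everything CORRECT
  m_all <- apply_edits(m, do.call(c, unname(fx$truth$repairs)))$model
  expect_equal(classify_all(m_all), recs$expected_post)
})

test_that("medium supplements are honoured in both steps", {
  fx <- trap_fixture()
  m <- fx$model
  pol <- default_policy(m)
  rec <- fx$truth$records[3, ]  # cofactor-dependent precursor
  expect_equal(simulate_rescue(m, rec, pol)$classification, "CORRECT")
  # without the supplement, the rescue fails: the knockout also starves the
  # cofactor, which the single supplied compound cannot replace
  rec_nosupp <- rec
  rec_nosupp$medium_supplements <- ""
  expect_equal(simulate_rescue(m, rec_nosupp, pol)$classification, "TYPE_II")
  # a supplement the model cannot exchange is a hard error
  rec_bad <- rec
  rec_bad$medium_supplements <- "unicorn_extract"
  expect_error(simulate_rescue(m, rec_bad, pol), "no exchange")
})

test_that("unknown compounds and unknown genes yield unresolvable records", {
  fx <- make_toy_gem(toy_gem_config(2, 1))
  m <- fx$model
  pol <- default_policy(m)
  r <- simulate_rescue(m, data.frame(knockout_genes = "g1_1",
                                     rescue_spec = "ambrosia",
                                     medium_supplements = ""), pol)
  expect_equal(r$classification, "unresolvable")
  r2 <- simulate_rescue(m, data.frame(knockout_genes = "not_a_gene",
                                      rescue_spec = "P1",
                                      medium_supplements = ""), pol)
  expect_equal(r2$classification, "unresolvable")
  # resolvable-but-unexchangeable is TYPE_II, not unresolvable
  fx2 <- make_toy_gem(toy_gem_config(2, 1,
                                     features = list("2" = "no_exchange")))
  r3 <- simulate_rescue(fx2$model,
                        data.frame(knockout_genes = "g2_1",
                                   rescue_spec = "P2",
                                   medium_supplements = ""),
                        default_policy(fx2$model))
  expect_equal(r3$classification, "TYPE_II")
})

test_that("dataset evaluation counts and accuracy behave", {
  fx <- trap_fixture()
  m <- fx$model
  pol <- default_policy(m)
  ds <- make_synthetic_dataset(fx$truth, noise = 0.2)
  run <- run_dataset(m, ds, pol)
  expect_equal(run$summary$n, nrow(ds))
  expect_equal(run$results$classification, ds$expected_pre)
  expect_equal(run$summary$correct, sum(ds$expected_pre == "CORRECT"))
  expect_equal(run$summary$essential_in_silico,
               sum(ds$expected_pre %in% c("CORRECT", "TYPE_II")))
  expect_equal(accuracy(run),
               run$summary$correct / (run$summary$n - run$summary$unresolvable))
  expect_gte(accuracy(run), 0)
  expect_lte(accuracy(run), 1)
  # noiseless dataset on the repaired model scores 100%
  m_fixed <- apply_edits(m, do.call(c, unname(fx$truth$repairs)))$model
  clean <- make_synthetic_dataset(fx$truth, noise = 0)
  expect_equal(accuracy(run_dataset(m_fixed, clean, default_policy(m_fixed))), 1)
  # empty dataset: zero counts, accuracy refuses
  empty <- clean[0, ]
  run0 <- run_dataset(m, empty, pol)
  expect_equal(run0$summary$n, 0)
  expect_error(accuracy(run0), "empty dataset")
})

test_that("dataset TSV round-trips losslessly", {
  fx <- trap_fixture()
  ds <- make_synthetic_dataset(fx$truth, noise = 0.2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_auxo_dataset(ds, path)
  back <- read_auxo_dataset(path)
  cols <- c("knockout_genes", "rescue_spec", "medium_supplements",
            "strain_background", "reference")
  df1 <- as.data.frame(ds)[, cols]
  rownames(df1) <- NULL
  expect_identical(as.data.frame(back)[, cols], df1)
})

test_that("essential genes match the planted truth exactly", {
  fx <- trap_fixture()
  pol <- default_policy(fx$model)
  expect_setequal(essential_genes(fx$model, pol), fx$truth$essential_genes)
  # isoenzyme pair members are individually dispensable
  expect_false(any(c("g5_1a", "g5_1b") %in% essential_genes(fx$model, pol)))
})

test_that("systematic screen equals the graph-reachability oracle", {
  for (cfg in list(toy_gem_config(3, 2),
                   toy_gem_config(4, c(1, 2, 3, 2),
                                  features = list("1" = "bypass",
                                                  "2" = "no_exchange",
                                                  "4" = "complex")))) {
    fx <- make_toy_gem(cfg)
    sc <- systematic_screen(fx$model, default_policy(fx$model))
    bf <- rescue_bruteforce(fx$model)
    got <- sc$pairs[, c("gene", "exchange")]
    rownames(got) <- NULL
    expect_identical(got, bf)
  }
})

test_that("screen results replay: each pair is inviable then rescued", {
  fx <- trap_fixture()
  m <- fx$model
  pol <- default_policy(m)
  sc <- systematic_screen(m, pol)
  expect_gt(nrow(sc$pairs), 0)
  for (i in seq_len(nrow(sc$pairs))) {
    ko <- apply_knockout(m, sc$pairs$gene[i])
    expect_false(is_viable(solve_fba(ko), pol))
    expect_true(is_viable(
      solve_fba(open_uptake(ko, sc$pairs$exchange[i], -1000)), pol))
  }
  # genes with viable knockouts never appear
  expect_false("g1_1" %in% sc$pairs$gene)  # bypass keeps it viable
})

test_that("screen honours the compound filter", {
  fx <- make_toy_gem(toy_gem_config(2, 1))
  sc <- systematic_screen(fx$model, default_policy(fx$model),
                          compound_filter = function(met) met == "P1[e]")
  expect_true(all(sc$pairs$compound == "P1[e]"))
})

test_that("substrate usage scores alternative sources against the default", {
  fx <- make_toy_gem(toy_gem_config(2, 1))
  m <- fx$model
  # wire in an alternative carbon source feeding the same pool
  m <- add_reaction(m, reaction("T_alt", c("alt[e]" = -1, "substrate[c]" = 1)),
                    new_metabolites = data.frame(id = "alt[e]", name = "alt",
                                                 compartment = "e"))
  m <- add_reaction(m, reaction("EX_alt", c("alt[e]" = -1), lb = 0))
  pol <- default_policy(m)
  tab <- substrate_usage(m, "C", c("alt", "P1", "unobtainium"), pol,
                         sources = list(C = "substrate"))
  expect_equal(tab$status, c("viable", "inviable", "unresolvable"))
  # the default source trivially replaces itself
  self <- substrate_usage(m, "C", "substrate", pol,
                          sources = list(C = "substrate"))
  expect_equal(self$status, "viable")
})

test_that("model comparison localizes the effect of a single repair", {
  fx <- trap_fixture()
  m <- fx$model
  m_fixed <- apply_edits(m, fx$truth$repairs[["P1"]])$model  # bypass block
  ds <- fx$truth$records
  cmp <- compare_models(m, m_fixed, ds)
  changed <- cmp$per_record[cmp$per_record$changed, ]
  expect_equal(nrow(changed), 1)
  expect_equal(changed$rescue_spec, "P1")
  expect_equal(changed$class_a, "TYPE_I")
  expect_equal(changed$class_b, "CORRECT")
  expect_equal(cmp$summary_b$correct, cmp$summary_a$correct + 1)
  # a model against itself has zero deltas
  cmp0 <- compare_models(m, m, ds)
  expect_false(any(cmp0$per_record$changed))
})
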