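test_that("equation parser handles coefficients, arrows, and glucan names", {
  eq <- parse_equation("l-glutamate[m] + oxaloacetate[m] => 2-oxoglutarate[m] + l-aspartate[m]")
  expect_false(eq$reversible)
  expect_equal(eq$stoich[["l-glutamate[m]"]], -1)
  expect_equal(eq$stoich[["l-aspartate[m]"]], 1)

  eq2 <- parse_equation("0.74851 (1->3)-beta-D-glucan[ce] + 2 H+[c] => carbohydrate[c]")
  expect_equal(eq2$stoich[["(1->3)-beta-D-glucan[ce]"]], -0.74851)
  expect_equal(eq2$stoich[["H+[c]"]], -2)

  eq3 <- parse_equation("heme a[e] =>")
  expect_equal(eq3$stoich, c("heme a[e]" = -1))

  expect_true(parse_equation("a[c] <=> b[c]")$reversible)
  expect_equal(parse_equation("1e-06 x[c] => y[c]")$stoich[["x[c]"]], -1e-06)
  expect_error(parse_equation("a[c] b[c]"), "no reaction arrow")
})

test_that("blocking stops flux; reverse-blocking spares the forward direction", {
  fx <- make_toy_gem(toy_gem_config(2, 1))
  m <- fx$model
  blocked <- block_reaction(m, "R1_1", "both")
  expect_equal(blocked$reactions[["R1_1"]]$ub, 0)
  expect_lt(solve_fba(blocked)$objective, solve_fba(m)$objective)

  rev <- block_reaction(m, "T_P1", "reverse")   # reversible transporter
  expect_equal(rev$reactions[["T_P1"]]$lb, 0)
  expect_equal(rev$reactions[["T_P1"]]$ub, 1000)
  # on an irreversible reaction it is a no-op
  noop <- block_reaction(m, "R1_1", "reverse")
  expect_identical(noop, m)
  # blocking a zero-flux reaction leaves the optimum unchanged
  expect_equal(solve_fba(block_reaction(m, "EX_P1"))$objective,
               solve_fba(m)$objective, tolerance = 1e-9)
})

test_that("set_gpr replaces rules, rejects unknown genes, round-trips", {
  fx <- make_toy_gem(toy_gem_config(1, 1))
  m <- fx$model
  expect_error(set_gpr(m, "R1_1", "stranger"), "unregistered gene")
  m2 <- set_gpr(register_genes(m, "stranger"), "R1_1", "g1_1 or stranger")
  expect_identical(gpr_render(m2$reactions[["R1_1"]]$gpr), "g1_1 or stranger")
  expect_error(set_gpr(m, "R1_1", "a and (b"), "unbalanced")
  expect_error(set_gpr(m, "ghost", "g1_1"), "unknown reaction")
})

test_that("add_reaction/add_exchange demand atomic metabolite payloads", {
  fx <- make_toy_gem(toy_gem_config(1, 1))
  m <- fx$model
  expect_error(add_reaction(m, reaction("r_new", c("mystery[c]" = -1))),
               "unknown metabolite")
  m2 <- add_reaction(m, reaction("r_new", c("mystery[c]" = -1)),
                     new_metabolites = data.frame(id = "mystery[c]",
                                                  name = "mystery",
                                                  compartment = "c"))
  expect_true("r_new" %in% names(m2$reactions))
  expect_error(add_reaction(m2, reaction("r_new", c("mystery[c]" = -1))),
               "already exists")
  m3 <- add_exchange(m2, "mystery[c]")
  r <- m3$reactions[["EX_mystery[c]"]]
  expect_equal(r$stoich, c("mystery[c]" = -1))
  expect_equal(r$lb, 0)  # closed for uptake until a rescue opens it
})

test_that("rescaling conserves mass exactly on the worked two-species case", {
  m <- rescale_fixture()
  m2 <- rescale_pseudoreaction(m, "r_pool", "C[c]", -1, mode = "raw")
  st <- m2$reactions[["r_pool"]]$stoich
  # f = 200 / (200 + 50) = 0.8
  expect_equal(st[["A[c]"]], -0.8)
  expect_equal(st[["B[c]"]], -0.8)
  expect_equal(st[["C[c]"]], -0.8)
  expect_equal(total_reactant_mass(m2, "r_pool"), 200)
  # the equivalent final-mode call reproduces the same stoichiometry
  m3 <- rescale_pseudoreaction(m, "r_pool", "C[c]", -0.8, mode = "final")
  expect_equal(m3$reactions[["r_pool"]]$stoich, st, tolerance = 1e-12)
})

test_that("rescaling conserves mass and ratios on randomized specs", {
  set.seed(404)
  for (i in 1:40) {
    k <- sample(2:6, 1)
    ids <- sprintf("S%d[c]", seq_len(k))
    masses <- stats::runif(k + 1, 10, 500)
    coefs <- -stats::runif(k, 0.05, 2)
    mets <- data.frame(id = c(ids, "new[c]", "pool[c]"),
                       name = c(ids, "new", "pool"), compartment = "c",
                       formula = NA_character_,
                       mass = c(masses, NA))
    m <- gem(metabolites = mets,
             reactions = list(
               reaction("r_pool", stats::setNames(c(coefs, 1),
                                                  c(ids, "pool[c]"))),
               reaction("r_drain", c("pool[c]" = -1))),
             objective = "r_drain")
    mode <- sample(c("raw", "final"), 1)
    newc <- if (mode == "raw") -stats::runif(1, 0.05, 1) else {
      # keep the final-mode mass strictly below the pool mass
      m0 <- total_reactant_mass(m, "r_pool")
      -stats::runif(1, 0.01, 0.9) * m0 / masses[k + 1]
    }
    m2 <- rescale_pseudoreaction(m, "r_pool", "new[c]", newc, mode = mode)
    expect_equal(total_reactant_mass(m2, "r_pool"),
                 total_reactant_mass(m, "r_pool"), tolerance = 1e-9)
    st0 <- m$reactions[["r_pool"]]$stoich[ids]
    st1 <- m2$reactions[["r_pool"]]$stoich[ids]
    ratio <- st1 / st0
    expect_lt(max(ratio) - min(ratio), 1e-9)  # uniform scaling
  }
})

test_that("rescaling edge cases: zero coefficient, missing mass, presence", {
  m <- rescale_fixture()
  expect_identical(rescale_pseudoreaction(m, "r_pool", "C[c]", 0), m)
  m_nomass <- m
  m_nomass$metabolites$mass[1] <- NA
  expect_error(rescale_pseudoreaction(m_nomass, "r_pool", "C[c]", -1),
               "no mass available for reactant 'A\\[c\\]'")
  m2 <- rescale_pseudoreaction(m, "r_pool", "C[c]", -1)
  expect_error(rescale_pseudoreaction(m2, "r_pool", "C[c]", -1),
               "already present")
})

test_that("pseudo_append adds tiny cofactor terms without touching the rest", {
  m <- rescale_fixture()
  m2 <- pseudo_append(m, "r_pool", "C[c]", -1e-06)
  st <- m2$reactions[["r_pool"]]$stoich
  expect_equal(st[["C[c]"]], -1e-06)
  expect_equal(st[c("A[c]", "B[c]")],
               m$reactions[["r_pool"]]$stoich[c("A[c]", "B[c]")])
  expect_error(pseudo_append(m2, "r_pool", "C[c]", -1e-06), "already present")
  expect_error(pseudo_append(m, "r_pool", "C[c]", 0), "degenerate")
})

test_that("apply_edits is ordered, logged, all-or-nothing, and replayable", {
  fx <- trap_fixture()
  m <- fx$model
  edits <- do.call(c, unname(fx$truth$repairs))
  res <- apply_edits(m, edits)
  expect_equal(nrow(res$log), length(edits))
  expect_false(identical(res$model, m))
  # empty edit list: identity
  expect_identical(apply_edits(m, list())$model, m)
  # failure midway reports the edit and leaves no partial result
  bad <- c(edits, list(curation_edit("block_reaction", "ghost")))
  expect_error(apply_edits(m, bad),
               sprintf("edit %d.*ghost.*model unchanged", length(bad)))
  # serialize + reload + reapply gives the identical curated model
  for (ext in c(".yaml", ".json")) {
    path <- withr::local_tempfile(fileext = ext)
    write_edits(edits, path)
    expect_identical(apply_edits(m, read_edits(path))$model, res$model,
                     label = ext)
  }
  # unknown kinds are rejected at load
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(list(kind = "explode", target = "r1")), path)
  expect_error(read_edits(path), "unknown curation edit kind")
})
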