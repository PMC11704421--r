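test_that("the encoded curation set matches its published summary counts", {
  edits <- yeast9_curation_set()
  counts <- curation_set_counts(edits)
  expect_equal(counts$gpr_edits, 12)
  expect_equal(counts$blocked, 8)
  expect_equal(counts$added_synthesis, 2)
  expect_equal(counts$added_exchange, 1)
  expect_equal(counts$pseudo_adjustments, 2)
  # the reverse-only block targets the cystathionine synthase reaction
  kinds <- vapply(edits, `[[`, "", "kind")
  expect_equal(vapply(edits[kinds == "block_reverse"], `[[`, "", "target"),
               "r_0815")
  # every edit carries gene-compound provenance
  expect_true(all(vapply(edits, function(e)
    length(e$provenance$pairs) > 0, logical(1))))
})

test_that("the curation set applies cleanly to the synthetic skeleton", {
  sk <- synthetic_yeast9_skeleton()
  expect_equal(nrow(validate_gem(sk)), 0L)
  res <- apply_edits(sk, yeast9_curation_set())
  cur <- res$model
  expect_equal(nrow(validate_gem(cur)), 0L)

  # blocks landed
  for (rid in c("r_0217", "r_0312", "r_4703", "r_0559", "r_1026",
                "r_2070", "r_2071")) {
    expect_equal(cur$reactions[[rid]]$ub, 0, label = rid)
  }
  expect_equal(cur$reactions[["r_0815"]]$lb, 0)   # reverse blocked
  expect_equal(cur$reactions[["r_0815"]]$ub, 1000) # forward kept

  # GPR rewrites landed verbatim
  expect_identical(gpr_render(cur$reactions[["r_0080"]]$gpr),
                   "(YGL125W and YPL023C) or YGL125W")
  expect_identical(gpr_render(cur$reactions[["r_0250"]]$gpr),
                   "YJL130C or (YJR109C and YOR303W)")
  expect_identical(gpr_render(cur$reactions[["r_0477"]]$gpr), "YKL104C")
  expect_identical(gpr_render(cur$reactions[["r_0172"]]$gpr),
                   "YMR169C or YMR170C")
  for (rid in sprintf("r_%d", 2488:2495)) {
    expect_identical(gpr_render(cur$reactions[[rid]]$gpr), "YGR157W",
                     label = rid)
  }

  # additions landed; heme a exchange resolvable post-curation only
  expect_true(is.na(find_exchange(sk, "heme a")))
  expect_equal(find_exchange(cur, "heme a"), "r_temp1")
  expect_equal(cur$reactions[["r_temp1"]]$lb, 0)
  expect_true(all(c("r_temp2", "r_temp3") %in% names(cur$reactions)))
  expect_identical(gpr_render(cur$reactions[["r_temp3"]]$gpr), "YGR144W")
  expect_equal(
    cur$reactions[["r_temp3"]]$stoich[["H2O[c]"]], 3)

  # pseudoreaction coefficients readable from the curated stoichiometry
  expect_equal(cur$reactions[["r_4048"]]$stoich[["chitin[c]"]], -0.02361)
  expect_equal(cur$reactions[["r_4598"]]$stoich[["glutathione[c]"]], -1e-06)

  # chitin entered mass-conservatively: pool mass unchanged, ratios kept
  expect_equal(total_reactant_mass(cur, "r_4048"),
               total_reactant_mass(sk, "r_4048"), tolerance = 1e-9)
  orig <- sk$reactions[["r_4048"]]$stoich
  orig <- orig[orig < 0]
  newc <- cur$reactions[["r_4048"]]$stoich[names(orig)]
  ratio <- newc / orig
  expect_lt(max(ratio) - min(ratio), 1e-9)
  expect_lt(ratio[[1]], 1)  # originals scaled down to make room

  # MET13/MET12 semantics hold on the curated rule
  expect_equal(disabled_reactions(cur, "YPL023C"), character())
  expect_true("r_0080" %in% disabled_reactions(cur, "YGL125W"))
})

test_that("applying the curation set twice fails on the duplicate exchange", {
  sk <- synthetic_yeast9_skeleton()
  once <- apply_edits(sk, yeast9_curation_set())$model
  expect_error(apply_edits(once, yeast9_curation_set()),
               "r_temp1.*model unchanged")
})

test_that("curated skeleton survives an SBML round trip with edits intact", {
  cur <- apply_edits(synthetic_yeast9_skeleton(), yeast9_curation_set())$model
  path <- withr::local_tempfile(fileext = ".xml")
  write_gem_sbml(cur, path)
  back <- read_gem_sbml(path)
  r <- back$reactions[["r_4048"]]
  chit <- names(r$stoich)[grepl("chitin", names(r$stoich))]
  expect_equal(unname(r$stoich[chit]), -0.02361, tolerance = 1e-12)
  expect_identical(
    gpr_render(back$reactions[["r_0080"]]$gpr),
    "(YGL125W and YPL023C) or YGL125W")
})
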