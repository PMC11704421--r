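test_that("toy fixture optimum matches its closed-form construction", {
  # biomass drains one unit of each precursor plus one ATP (two ATP per
  # substrate), so the optimum is uptake / (n_precursors + 0.5)
  for (n in 1:4) {
    fx <- make_toy_gem(toy_gem_config(n, 2))
    expect_equal(solve_fba(fx$model)$objective, 10 / (n + 0.5),
                 tolerance = 1e-8)
    expect_equal(fx$truth$wt_growth, 10 / (n + 0.5))
  }
})

test_that("solver optimum matches vertex enumeration on random tiny LPs", {
  set.seed(202)
  for (i in 1:40) {
    lp <- random_tiny_lp()
    mine <- lp_solve(lp$obj, lp$S, lp$lb, lp$ub)
    oracle <- lp_vertex_max(lp$obj, lp$S, lp$lb, lp$ub)
    if (oracle$feasible) {
      expect_equal(mine$status, "optimal")
      expect_equal(mine$objective, oracle$objective, tolerance = 1e-6)
    } else {
      expect_equal(mine$status, "infeasible")
    }
  }
})

test_that("optimal solutions satisfy mass balance and bounds", {
  fx <- trap_fixture()
  S <- stoich_matrix(fx$model)
  sol <- solve_fba(fx$model)
  expect_lt(max(abs(S %*% sol$fluxes)), 1e-6)
  lb <- vapply(fx$model$reactions, `[[`, 0, "lb")
  ub <- vapply(fx$model$reactions, `[[`, 0, "ub")
  expect_true(all(sol$fluxes >= lb - 1e-9 & sol$fluxes <= ub + 1e-9))
})

test_that("forced flux through an unproducible metabolite is infeasible", {
  m <- gem(metabolites = data.frame(id = "a[c]", name = "a",
                                    compartment = "c"),
           reactions = list(reaction("r1", c("a[c]" = -1), lb = 1),
                            reaction("r_obj", c("a[c]" = -1), lb = 0)),
           objective = "r_obj")
  sol <- solve_fba(m)
  expect_equal(sol$status, "infeasible")
  expect_equal(growth_rate(sol), 0)
  expect_false(is_viable(sol, viability_policy(1, 0.01)))
})

test_that("knockouts only constrain: growth never increases, and nests", {
  fx <- trap_fixture()
  m <- fx$model
  wt <- solve_fba(m)$objective
  set.seed(303)
  for (i in 1:15) {
    h <- sample(m$genes, sample(seq_along(m$genes), 1))
    g <- sample(h, sample(seq_along(h), 1))
    gh <- growth_rate(solve_fba(apply_knockout(m, h)))
    gg <- growth_rate(solve_fba(apply_knockout(m, g)))
    expect_lte(gh, wt + 1e-6)
    expect_lte(gh, gg + 1e-6)
  }
})

test_that("knockout of an isoenzyme member or reaction-less gene is neutral", {
  fx <- make_toy_gem(toy_gem_config(2, 1, features = list("1" = "isoenzyme")))
  m <- fx$model
  wt <- solve_fba(m)$objective
  expect_equal(growth_rate(solve_fba(apply_knockout(m, "g1_1a"))), wt,
               tolerance = 1e-9)
  m2 <- register_genes(m, "idle_gene")
  expect_equal(growth_rate(solve_fba(apply_knockout(m2, "idle_gene"))), wt,
               tolerance = 1e-9)
})

test_that("opening an uptake never decreases the optimum and is idempotent", {
  fx <- trap_fixture()
  m <- fx$model
  base <- solve_fba(m)$objective
  for (ex in exchange_reactions(m)) {
    opened <- open_uptake(m, ex, -1000)
    g1 <- solve_fba(opened)$objective
    expect_gte(g1, base - 1e-6)
    expect_equal(solve_fba(open_uptake(opened, ex, -1000))$objective, g1,
                 tolerance = 1e-9)
  }
  expect_error(open_uptake(m, "R_biomass"), "not an exchange")
  expect_error(open_uptake(m, "ghost_rxn"), "unknown reaction")
})

test_that("viability threshold: at-threshold is viable, below is not", {
  pol <- viability_policy(reference_growth = 0.0859, fraction = 0.01)
  expect_true(is_viable(0.0859, pol))
  expect_true(is_viable(0.0859 * 0.01, pol))          # exact tie: viable
  expect_false(is_viable(0.0859 * 0.01 - 1e-12, pol))
  expect_false(is_viable(0, pol))
  expect_error(viability_policy(1, 0))
  expect_error(viability_policy(1, 1))
})

test_that("wild-type growth caches and refuses a non-growing model", {
  fx <- make_toy_gem(toy_gem_config(2, 1))
  expect_equal(wild_type_growth(fx$model), solve_fba(fx$model)$objective)
  dead <- block_reaction(fx$model, "R_biomass")
  expect_error(wild_type_growth(dead), "cannot grow")
})
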