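# Random-instance generators shared across test files.

# Random GPR string over genes G1..Gk, built directly as text so the string
# (not the package's parse tree) is the source of truth.
random_gpr_string <- function(n_genes, depth = 3) {
  genes <- paste0("G", seq_len(n_genes))
  build <- function(d) {
    if (d == 0 || stats::runif(1) < 0.35) {
      return(sample(genes, 1))
    }
    op <- sample(c(" and ", " or "), 1)
    k <- sample(2:3, 1)
    args <- vapply(seq_len(k), function(i) build(d - 1), "")
    paste0("(", paste(args, collapse = op), ")")
  }
  build(depth)
}

# Random tiny stoichiometric LP with finite bounds, for oracle comparisons.
random_tiny_lp <- function() {
  m <- sample(2:6, 1)
  n <- sample((m + 1):8, 1)
  list(
    S = matrix(sample(-2:2, m * n, TRUE), m, n),
    lb = ifelse(stats::runif(n) < 0.3, -10, 0),
    ub = stats::runif(n, 1, 10),
    obj = {o <- numeric(n); o[sample(n, 1)] <- 1; o}
  )
}

# The standard trap-laden fixture used by several files.
trap_fixture <- function() {
  make_toy_gem(toy_gem_config(
    5, 2,
    features = list("1" = "bypass", "2" = "no_exchange",
                    "3" = "medium_conditional", "4" = "conjunctive",
                    "5" = "isoenzyme")))
}

# Worked two-species pseudoreaction rescale fixture: A and B at mass 100,
# coefficient -1 each; adding C (mass 50, raw coefficient -1) must give
# f = 200/250 = 0.8.
rescale_fixture <- function() {
  gem(
    metabolites = data.frame(
      id = c("A[c]", "B[c]", "C[c]", "pool[c]"),
      name = c("A", "B", "C", "pool"),
      compartment = "c", formula = NA_character_,
      mass = c(100, 100, 50, NA)),
    reactions = list(
      reaction("r_pool", c("A[c]" = -1, "B[c]" = -1, "pool[c]" = 1)),
      reaction("r_drain", c("pool[c]" = -1))),
    objective = "r_drain")
}

total_reactant_mass <- function(model, rxn_id, masses = NULL) {
  st <- model$reactions[[rxn_id]]$stoich
  re <- st[st < 0]
  sum(abs(re) * vapply(names(re), function(met) {
    if (!is.null(masses) && met %in% names(masses)) masses[[met]]
    else metabolite_mass(model, met)
  }, 0))
}
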