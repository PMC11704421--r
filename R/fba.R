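#' Flux balance analysis
#'
#' Solves the steady-state LP: maximize the flux of an objective reaction
#' subject to mass balance `S v = 0` and the model's flux bounds. Only the
#' objective value is contract-stable -- large models have alternative optima,
#' so individual fluxes of one optimal vector are not unique.
#'
#' @param model a validated `gem`.
#' @param objective reaction id to maximize; defaults to the model's biomass
#'   objective.
#' @return An object of class `flux_solution`: `status`
#'   (`"optimal"`/`"infeasible"`), `objective` (growth rate, 1/h, when
#'   optimal), and `fluxes` (named vector, mmol/gDW/h).
#' @export
solve_fba <- function(model, objective = model$objective) {
  r <- model$reactions[[objective]]
  if (is.null(r)) stop(sprintf("unknown objective reaction '%s'", objective),
                       call. = FALSE)
  S <- stoich_matrix(model)
  lb <- vapply(model$reactions, `[[`, 0, "lb")
  ub <- vapply(model$reactions, `[[`, 0, "ub")
  obj <- as.numeric(colnames(S) == objective)
  sol <- lp_solve(obj, S, lb, ub)
  if (sol$status == "optimal") {
    structure(list(status = "optimal", objective = sol$objective,
                   fluxes = stats::setNames(sol$v, colnames(S))),
              class = "flux_solution")
  } else if (sol$status == "infeasible") {
    structure(list(status = "infeasible", objective = NA_real_,
                   fluxes = NULL), class = "flux_solution")
  } else {
    stop(sprintf("LP solver failure (status: %s)", sol$status), call. = FALSE)
  }
}

#' @export
print.flux_solution <- function(x, ...) {
  cat(sprintf("<flux_solution> status: %s; objective: %s\n", x$status,
              if (is.na(x$objective)) "-" else format(x$objective)))
  invisible(x)
}

#' Growth rate of a solution (infeasible counts as zero)
#'
#' A knockout that makes the LP infeasible cannot grow; for viability
#' purposes its growth rate is 0.
#'
#' @param sol a `flux_solution` or a bare growth rate.
#' @return Growth rate, 1/h.
#' @export
growth_rate <- function(sol) {
  if (inherits(sol, "flux_solution")) {
    if (sol$status != "optimal") return(0)
    return(sol$objective)
  }
  as.numeric(sol)
}

.wt_cache <- new.env(parent = emptyenv())

#' Wild-type growth rate under the model's default medium
#'
#' FBA on the unmodified model; the value is cached per model fingerprint.
#' This is the reference the viability threshold is taken from.
#'
#' @param model a `gem`.
#' @return Growth rate, 1/h.
#' @export
wild_type_growth <- function(model) {
  key <- rlang::hash(model)
  if (!is.null(.wt_cache[[key]])) return(.wt_cache[[key]])
  sol <- solve_fba(model)
  if (sol$status != "optimal" || sol$objective <= 1e-9) {
    stop("model cannot grow on its default medium", call. = FALSE)
  }
  .wt_cache[[key]] <- sol$objective
  sol$objective
}

#' Apply a gene knockout to a model
#'
#' Every reaction whose GPR loses support under the deletion gets its bounds
#' fixed to zero; the input model is untouched.
#'
#' @param model a `gem`.
#' @param genes character vector of deleted gene ids (must exist).
#' @return The constrained model copy.
#' @export
apply_knockout <- function(model, genes) {
  for (rid in disabled_reactions(model, genes)) {
    model$reactions[[rid]]$lb <- 0
    model$reactions[[rid]]$ub <- 0
  }
  model
}

#' Open an exchange reaction for uptake
#'
#' Sets the exchange's lower bound (upper bound untouched). The default
#' -1000 mmol/gDW/h is the conventional "unconstrained" uptake used to test
#' whether a supplemented compound rescues growth.
#'
#' @param model a `gem`.
#' @param rxn_id exchange reaction id.
#' @param lb new lower bound.
#' @return The modified model copy.
#' @export
open_uptake <- function(model, rxn_id, lb = -1000) {
  r <- gem_get_reaction(model, rxn_id)
  if (!is_exchange(r)) {
    stop(sprintf("'%s' is not an exchange reaction", rxn_id), call. = FALSE)
  }
  model$reactions[[rxn_id]]$lb <- lb
  model
}

#' Viability policy
#'
#' Growth is called viable iff it reaches `fraction` of the wild-type
#' reference optimum. Ties at the threshold resolve to viable (the >=
#' convention): only predictions strictly below the threshold are inviable.
#'
#' @param reference_growth wild-type optimum, 1/h.
#' @param fraction threshold multiplier, default 0.01 (1%).
#' @return An object of class `viability_policy`.
#' @export
viability_policy <- function(reference_growth, fraction = 0.01) {
  stopifnot(reference_growth >= 0, fraction > 0, fraction < 1)
  structure(list(reference_growth = reference_growth, fraction = fraction),
            class = "viability_policy")
}

#' Viability policy derived from a model's own wild-type optimum
#'
#' @param model a `gem`.
#' @param fraction threshold multiplier.
#' @return A `viability_policy`.
#' @export
default_policy <- function(model, fraction = 0.01) {
  viability_policy(wild_type_growth(model), fraction)
}

#' Is a predicted growth rate viable?
#'
#' @param growth growth rate (1/h) or a `flux_solution` (infeasible maps to
#'   growth 0).
#' @param policy a `viability_policy`.
#' @return `TRUE` iff growth >= fraction x reference.
#' @export
is_viable <- function(growth, policy) {
  stopifnot(inherits(policy, "viability_policy"))
  growth_rate(growth) >= policy$fraction * policy$reference_growth
}
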