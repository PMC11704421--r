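#' Verification oracles
#'
#' Exhaustive reference implementations used to check the production code
#' paths on small instances. They deliberately share nothing with the code
#' they verify: the GPR oracle evaluates the rule string through R's own
#' parser, the LP oracle enumerates polytope vertices, and the rescue oracle
#' reasons about metabolite producibility on the network graph without
#' solving any LP.
#'
#' @name oracles
NULL

#' Truth-table evaluation of a GPR string via R's parser
#'
#' Substitutes TRUE/FALSE for gene tokens in the raw rule string and
#' evaluates the result with `eval(parse(...))` -- R's `&&`/`||` and
#' parenthesis handling stand in for the package's own expression tree.
#' Gene ids must be syntactically simple (alphanumeric/underscore) so that
#' word-boundary substitution is unambiguous.
#'
#' @param text GPR string.
#' @param genes gene ids appearing in `text`.
#' @param deleted subset of `genes` treated as deleted (false).
#' @return Logical: does the rule hold under the deletion?
#' @export
gpr_truthtable_eval <- function(text, genes, deleted = character()) {
  if (!nzchar(trimws(text))) return(TRUE)
  expr <- text
  expr <- gsub("\\band\\b", "&&", expr, ignore.case = TRUE)
  expr <- gsub("\\bor\\b", "||", expr, ignore.case = TRUE)
  for (g in genes) {
    expr <- gsub(paste0("\\b", g, "\\b"),
                 if (g %in% deleted) "FALSE" else "TRUE", expr)
  }
  isTRUE(eval(parse(text = expr)))
}

#' Full truth table of a GPR string
#'
#' @param text GPR string.
#' @param genes gene ids appearing in `text`.
#' @return data.frame with one logical column per gene (TRUE = present) and
#'   a `value` column.
#' @export
gpr_truthtable <- function(text, genes) {
  k <- length(genes)
  states <- expand.grid(rep(list(c(TRUE, FALSE)), k))
  names(states) <- genes
  states$value <- vapply(seq_len(nrow(states)), function(i) {
    deleted <- genes[!unlist(states[i, seq_len(k)])]
    gpr_truthtable_eval(text, genes, deleted)
  }, logical(1))
  states
}

#' LP maximum by vertex enumeration
#'
#' Enumerates the basic solutions of `{S v = 0, lb <= v <= ub}` (all choices
#' of n - rank(S) variables pinned at a bound) and returns the best feasible
#' objective. Exponential: guarded to at most 10 variables.
#'
#' @param obj objective coefficients.
#' @param S equality-constraint matrix.
#' @param lb,ub finite bounds.
#' @param tol feasibility tolerance.
#' @return List with `feasible` and `objective` (`-Inf` when infeasible).
#' @export
lp_vertex_max <- function(obj, S, lb, ub, tol = 1e-8) {
  S <- as.matrix(S)
  n <- ncol(S)
  if (n > 10) stop("vertex enumeration guarded to <= 10 variables",
                   call. = FALSE)
  r <- qr(S)$rank
  nb <- n - r
  best <- -Inf
  feas <- FALSE
  consider <- function(v) {
    if (max(abs(S %*% v)) > tol) return()
    if (all(v >= lb - tol & v <= ub + tol)) {
      feas <<- TRUE
      best <<- max(best, sum(obj * v))
    }
  }
  if (nb == 0) {
    v <- tryCatch(qr.solve(S, rep(0, nrow(S))), error = function(e) NULL)
    if (!is.null(v)) consider(v)
  } else {
    combs <- utils::combn(n, nb)
    grid <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), nb)))
    for (ci in seq_len(ncol(combs))) {
      N <- combs[, ci]
      B <- setdiff(seq_len(n), N)
      SB <- S[, B, drop = FALSE]
      if (length(B) && qr(SB)$rank < length(B)) next
      for (gi in seq_len(nrow(grid))) {
        vN <- ifelse(grid[gi, ], ub[N], lb[N])
        vB <- if (length(B)) {
          tryCatch(qr.solve(SB, -S[, N, drop = FALSE] %*% vN),
                   error = function(e) NULL)
        } else numeric()
        if (is.null(vB)) next
        v <- numeric(n)
        v[N] <- vN
        v[B] <- vB
        consider(v)
      }
    }
  }
  list(feasible = feas, objective = best)
}

#' Metabolites producible by graph closure
#'
#' Iterates to a fixpoint: a reaction direction can fire when its bound
#' allows it and every metabolite it consumes in that direction is already
#' producible; whatever it produces becomes producible. Exchanges with
#' negative lower bounds seed the closure (their reverse direction consumes
#' nothing). This qualitative semantics coincides with "positive biomass
#' flux is feasible" on the acyclic unit-coefficient networks the toy
#' generator emits; it is not a general FBA substitute.
#'
#' @param model a `gem`.
#' @param disabled reaction ids excluded from the closure.
#' @return Character vector of producible metabolite ids.
#' @export
producible_metabolites <- function(model, disabled = character()) {
  have <- character()
  active <- model$reactions[setdiff(gem_reaction_ids(model), disabled)]
  repeat {
    grew <- FALSE
    for (r in active) {
      if (r$ub > 0) {
        ins <- names(r$stoich)[r$stoich < 0]
        if (all(ins %in% have)) {
          outs <- names(r$stoich)[r$stoich > 0]
          new <- setdiff(outs, have)
          if (length(new)) { have <- c(have, new); grew <- TRUE }
        }
      }
      if (r$lb < 0) {
        ins <- names(r$stoich)[r$stoich > 0]
        if (all(ins %in% have)) {
          outs <- names(r$stoich)[r$stoich < 0]
          new <- setdiff(outs, have)
          if (length(new)) { have <- c(have, new); grew <- TRUE }
        }
      }
    }
    if (!grew) break
  }
  have
}

reachability_viable <- function(model, deleted = character(),
                                open = character()) {
  for (ex in open) model$reactions[[ex]]$lb <- -1000
  disabled <- disabled_reactions(model, deleted)
  have <- producible_metabolites(model, disabled)
  biomass <- model$reactions[[model$objective]]
  needs <- names(biomass$stoich)[biomass$stoich < 0]
  all(needs %in% have)
}

#' Brute-force rescue enumeration by graph reachability
#'
#' The independent reference for the systematic screen: for every gene whose
#' knockout makes biomass unreachable, try every exchange reaction one at a
#' time and record the ones whose opening restores reachability. No linear
#' programming is involved, so agreement with the LP-driven screen checks
#' both the loop logic and the viability calls. Valid on toy-generator
#' models (see [producible_metabolites()] for the semantics).
#'
#' @param model a `gem`.
#' @param genes genes to test (default all).
#' @return data.frame with `gene` and `exchange` for every rescuing pair.
#' @export
rescue_bruteforce <- function(model, genes = model$genes) {
  exchanges <- exchange_reactions(model)
  out <- list()
  for (g in genes) {
    if (!length(disabled_reactions(model, g))) next
    if (reachability_viable(model, deleted = g)) next
    for (ex in exchanges) {
      if (reachability_viable(model, deleted = g, open = ex)) {
        out[[length(out) + 1L]] <- data.frame(gene = g, exchange = ex)
      }
    }
  }
  do.call(rbind, out) %||% data.frame(gene = character(),
                                      exchange = character())
}
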