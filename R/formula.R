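#' Element masses for formula-derived molar masses
#'
#' Monoisotopic precision is not needed for biomass bookkeeping; standard
#' atomic weights (g/mol, equivalently g/mmol per mmol-scale coefficient
#' bookkeeping) are used. The table is user-extensible: supply extra elements
#' via the `extra` argument of [formula_mass()].
#'
#' @return Named numeric vector of atomic masses.
#' @export
element_masses <- function() {
  c(C = 12.011, H = 1.008, N = 14.007, O = 15.999, P = 30.974, S = 32.06,
    Fe = 55.845, Zn = 65.38, Mg = 24.305, Na = 22.990, K = 39.098,
    Ca = 40.078, Cl = 35.45)
}

#' Molar mass from an elemental formula
#'
#' Parses formulas like `"C6H12O6"` (element symbol = uppercase letter plus
#' optional lowercase letters, optional integer count). Charged pseudo-element
#' suffixes are not supported; polymeric pseudo-metabolites without formulas
#' need an explicit per-metabolite mass override instead.
#'
#' @param formula elemental formula string.
#' @param extra named numeric vector of additional element masses, taking
#'   precedence over the built-in table.
#' @return Mass in g/mmol-scale units.
#' @export
formula_mass <- function(formula, extra = NULL) {
  masses <- element_masses()
  if (!is.null(extra)) masses[names(extra)] <- extra
  if (is.na(formula) || !nzchar(formula)) {
    stop("empty formula has no mass", call. = FALSE)
  }
  m <- gregexpr("([A-Z][a-z]*)([0-9]*)", formula)[[1]]
  toks <- regmatches(formula, gregexpr("([A-Z][a-z]*)([0-9]*)", formula))[[1]]
  if (!length(toks) || sum(nchar(toks)) != nchar(formula)) {
    stop(sprintf("cannot parse formula '%s'", formula), call. = FALSE)
  }
  total <- 0
  for (tk in toks) {
    el <- sub("[0-9]*$", "", tk)
    cnt <- sub("^[A-Za-z]*", "", tk)
    cnt <- if (nzchar(cnt)) as.numeric(cnt) else 1
    if (!el %in% names(masses)) {
      stop(sprintf("unknown element '%s' in formula '%s'", el, formula),
           call. = FALSE)
    }
    total <- total + masses[[el]] * cnt
  }
  total
}

#' Molar mass of a model metabolite
#'
#' An explicit `mass` override on the metabolite wins; otherwise the mass is
#' derived from the elemental formula. Returns `NA` when neither is
#' available.
#'
#' @param model a `gem`.
#' @param met_id metabolite id.
#' @return Mass, or `NA_real_`.
#' @export
metabolite_mass <- function(model, met_id) {
  i <- match(met_id, model$metabolites$id)
  if (is.na(i)) stop(sprintf("unknown metabolite '%s'", met_id), call. = FALSE)
  if (!is.na(model$metabolites$mass[i])) return(model$metabolites$mass[i])
  f <- model$metabolites$formula[i]
  if (!is.na(f) && nzchar(f)) {
    return(tryCatch(formula_mass(f), error = function(e) NA_real_))
  }
  NA_real_
}
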