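#' Construct a genome-scale metabolic model (GEM)
#'
#' The container holds metabolites, reactions, genes, and the identifier of
#' the biomass (objective) reaction. Metabolite ids follow the bracket
#' convention `name[compartment]` common in consensus yeast models (e.g.
#' `"l-aspartate[m]"`); the compartment is additionally kept as a separate
#' field for lookups.
#'
#' @param metabolites data.frame with columns `id`, `name`, `compartment`,
#'   and optionally `formula` (elemental formula, `NA` allowed) and `mass`
#'   (explicit g/mmol override for species without a usable formula, e.g.
#'   polymeric pseudo-metabolites).
#' @param reactions list of reactions created with [reaction()].
#' @param genes character vector of gene ids.
#' @param objective id of the biomass reaction.
#' @return An object of class `gem`.
#' @export
gem <- function(metabolites, reactions, genes = character(), objective) {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  if (!"formula" %in% names(metabolites)) metabolites$formula <- NA_character_
  if (!"mass" %in% names(metabolites)) metabolites$mass <- NA_real_
  if (!"name" %in% names(metabolites)) metabolites$name <- metabolites$id
  names(reactions) <- vapply(reactions, `[[`, "", "id")
  m <- structure(list(
    metabolites = metabolites,
    reactions = reactions,
    genes = genes,
    objective = objective
  ), class = "gem")
  m
}

#' Construct a reaction
#'
#' @param id reaction identifier.
#' @param stoich named numeric vector mapping metabolite id to signed
#'   coefficient (negative = consumed, positive = produced).
#' @param lb,ub flux bounds in mmol/gDW/h (biomass in 1/h).
#' @param gpr GPR string or `gpr` object; default empty (not gene-controlled).
#' @param name display name.
#' @param notes free-text provenance.
#' @return A list of class `gem_reaction`.
#' @export
reaction <- function(id, stoich, lb = 0, ub = 1000, gpr = "", name = id,
                     notes = "") {
  if (!inherits(gpr, "gpr")) gpr <- parse_gpr(gpr)
  structure(list(id = id, name = name, stoich = stoich, lb = lb, ub = ub,
                 gpr = gpr, notes = notes),
            class = "gem_reaction")
}

#' Is a reaction an exchange reaction?
#'
#' Exchange (boundary) reactions touch exactly one metabolite and are written
#' in the export convention `met ->` (coefficient -1); negative flux denotes
#' uptake from the environment.
#'
#' @param rxn a `gem_reaction`.
#' @return `TRUE` for single-metabolite reactions.
#' @export
is_exchange <- function(rxn) length(rxn$stoich) == 1L

#' @export
print.gem <- function(x, ...) {
  cat(sprintf("<gem> %d metabolites, %d reactions, %d genes; objective: %s\n",
              nrow(x$metabolites), length(x$reactions), length(x$genes),
              x$objective))
  invisible(x)
}

gem_reaction_ids <- function(model) names(model$reactions)

gem_get_reaction <- function(model, rxn_id) {
  r <- model$reactions[[rxn_id]]
  if (is.null(r)) stop(sprintf("unknown reaction '%s'", rxn_id), call. = FALSE)
  r
}

#' Stoichiometric matrix of a model
#'
#' @param model a `gem`.
#' @return A dense metabolite-by-reaction matrix with dimnames.
#' @export
stoich_matrix <- function(model) {
  mets <- model$metabolites$id
  rxns <- gem_reaction_ids(model)
  S <- matrix(0, length(mets), length(rxns), dimnames = list(mets, rxns))
  for (j in seq_along(rxns)) {
    st <- model$reactions[[j]]$stoich
    S[names(st), j] <- st
  }
  S
}

#' Validate GEM structural invariants
#'
#' Violations are data, not exceptions: each row names the offending entity
#' and the rule it breaks. An empty result means the model is well-formed.
#'
#' @param model a `gem`.
#' @return data.frame with columns `entity`, `rule`, `message`.
#' @export
validate_gem <- function(model) {
  v <- list()
  bad <- function(entity, rule, message) {
    v[[length(v) + 1L]] <<- data.frame(entity = entity, rule = rule,
                                       message = message)
  }
  met_ids <- model$metabolites$id
  dup <- met_ids[duplicated(met_ids)]
  for (d in unique(dup)) bad(d, "unique_metabolite_id", "duplicate metabolite id")
  rxn_ids <- gem_reaction_ids(model)
  dupr <- rxn_ids[duplicated(rxn_ids)]
  for (d in unique(dupr)) bad(d, "unique_reaction_id", "duplicate reaction id")
  if (!model$objective %in% rxn_ids) {
    bad(model$objective, "objective_present",
        "objective reaction not found in model")
  }
  for (r in model$reactions) {
    if (length(r$stoich) == 0L) {
      bad(r$id, "stoich_nonempty", "reaction has empty stoichiometry")
    }
    if (!all(is.finite(r$stoich))) {
      bad(r$id, "stoich_finite", "non-finite stoichiometric coefficient")
    }
    if (r$lb > r$ub) {
      bad(r$id, "bounds_ordered", sprintf("lb (%g) > ub (%g)", r$lb, r$ub))
    }
    missing_mets <- setdiff(names(r$stoich), met_ids)
    for (mm in missing_mets) {
      bad(r$id, "metabolite_exists",
          sprintf("references unknown metabolite '%s'", mm))
    }
    missing_genes <- setdiff(gpr_genes(r$gpr), model$genes)
    for (mg in missing_genes) {
      bad(r$id, "gene_exists", sprintf("GPR cites unknown gene '%s'", mg))
    }
  }
  for (i in seq_len(nrow(model$metabolites))) {
    mass <- model$metabolites$mass[i]
    if (!is.na(mass)) {
      if (mass <= 0) {
        bad(model$metabolites$id[i], "mass_positive", "mass override <= 0")
      } else if (!is.na(model$metabolites$formula[i]) &&
                 nzchar(model$metabolites$formula[i])) {
        fm <- tryCatch(formula_mass(model$metabolites$formula[i]),
                       error = function(e) NA_real_)
        if (!is.na(fm) && abs(fm - mass) > 1e-6) {
          bad(model$metabolites$id[i], "mass_consistent",
              sprintf("mass %g disagrees with formula mass %g", mass, fm))
        }
      }
    }
  }
  if (length(v)) do.call(rbind, v) else
    data.frame(entity = character(), rule = character(), message = character())
}

#' Reactions disabled by a gene deletion
#'
#' A reaction is disabled when its non-empty GPR evaluates false with the
#' deleted genes set to false. A gene that appears in no GPR is valid input
#' and disables nothing.
#'
#' @param model a `gem`.
#' @param deleted character vector of gene ids; all must exist in the model.
#' @return Character vector of disabled reaction ids.
#' @export
disabled_reactions <- function(model, deleted) {
  unknown <- setdiff(deleted, model$genes)
  if (length(unknown)) {
    stop(sprintf("unknown gene id(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  if (!length(deleted)) return(character())
  out <- character()
  for (r in model$reactions) {
    if (r$gpr$kind != "empty" && !eval_gpr(r$gpr, deleted)) {
      out <- c(out, r$id)
    }
  }
  out
}

#' Find the exchange reaction for a compound
#'
#' The query is matched against metabolite ids (exact, case-sensitive) and
#' then against display names (case-insensitive) of metabolites in the
#' extracellular compartment. Returns `NA` when the compound has no exchange
#' reaction in the model -- the caller decides what that means (the heme-like
#' curation cases hinge on it).
#'
#' @param model a `gem`.
#' @param query metabolite id, display name, or exchange reaction id.
#' @param extracellular compartment id treated as extracellular for
#'   name-based lookup.
#' @return The exchange reaction id, or `NA_character_` when none exists.
#'   Two exchanges matching one query is an error listing the candidates.
#' @export
find_exchange <- function(model, query, extracellular = "e") {
  # direct exchange-reaction id
  r <- model$reactions[[query]]
  if (!is.null(r) && is_exchange(r)) return(r$id)
  mets <- model$metabolites
  hit <- mets$id == query
  if (!any(hit)) {
    hit <- tolower(mets$name) == tolower(query) &
      mets$compartment == extracellular
  }
  if (!any(hit)) {
    # fall back to any-compartment name match so intracellular-only species
    # (no extracellular form) are still recognized as present-but-unexchanged
    hit <- tolower(mets$name) == tolower(query)
  }
  if (!any(hit)) return(NA_character_)
  targets <- mets$id[hit]
  cand <- character()
  for (r in model$reactions) {
    if (is_exchange(r) && names(r$stoich) %in% targets) cand <- c(cand, r$id)
  }
  if (length(cand) > 1L) {
    stop(sprintf("ambiguous exchange for '%s': candidates %s", query,
                 paste(cand, collapse = ", ")), call. = FALSE)
  }
  if (length(cand) == 0L) return(NA_character_)
  cand
}

#' All exchange reaction ids of a model
#'
#' @param model a `gem`.
#' @return Character vector, in model order.
#' @export
exchange_reactions <- function(model) {
  ids <- gem_reaction_ids(model)
  ids[vapply(model$reactions, is_exchange, logical(1))]
}

#' Register additional genes on a model
#'
#' GPR rewrites may introduce genes absent from the model; they must be
#' registered before [set_gpr()] will accept them.
#'
#' @param model a `gem`.
#' @param genes character vector of new gene ids.
#' @return The updated model.
#' @export
register_genes <- function(model, genes) {
  model$genes <- union(model$genes, genes)
  model
}
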