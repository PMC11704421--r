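#' Parse a reaction equation string
#'
#' Accepts the display form used in curation tables, e.g.
#' `"l-glutamate[m] + oxaloacetate[m] => 2-oxoglutarate[m] + l-aspartate[m]"`.
#' Arrows: `=>` and `->` (irreversible), `<=>` (reversible). Terms are
#' optional numeric coefficient followed by a bracketed metabolite id. A
#' one-sided equation (`"heme a[e] =>"`) is the exchange/export form.
#'
#' @param text equation string.
#' @return List with `stoich` (named signed coefficients) and `reversible`.
#' @export
parse_equation <- function(text) {
  # arrows must be free-standing tokens: metabolite names may contain "->"
  # (e.g. "(1->3)-beta-D-glucan")
  arrow_re <- "(^|[[:space:]])(<=>|=>|->)([[:space:]]|$)"
  m <- regexec(arrow_re, text)[[1]]
  if (m[1] == -1) {
    stop(sprintf("no reaction arrow in equation '%s'", text), call. = FALSE)
  }
  arrow <- regmatches(text, regexec(arrow_re, text))[[1]][3]
  sides <- strsplit(text, arrow_re)[[1]]
  lhs <- if (length(sides) >= 1) sides[1] else ""
  rhs <- if (length(sides) >= 2) sides[2] else ""
  parse_side <- function(s, sign) {
    s <- trimws(s)
    if (!nzchar(s)) return(numeric())
    terms <- trimws(strsplit(s, "\\s\\+\\s")[[1]])
    out <- numeric()
    for (tm in terms) {
      m <- regmatches(tm, regexec("^([0-9.eE+-]+\\s+)?(.+)$", tm))[[1]]
      coef <- if (!is.na(m[2]) && nzchar(trimws(m[2]))) as.numeric(trimws(m[2])) else 1
      met <- trimws(m[3])
      out[met] <- (if (met %in% names(out)) out[[met]] else 0) + sign * coef
    }
    out
  }
  lhs_st <- parse_side(lhs, -1)
  rhs_st <- parse_side(rhs, +1)
  st <- lhs_st
  for (k in names(rhs_st)) st[k] <- (if (k %in% names(st)) st[[k]] else 0) + rhs_st[[k]]
  st <- st[st != 0]
  list(stoich = st, reversible = arrow == "<=>")
}

#' Curation edits
#'
#' A closed vocabulary of replayable model edits, each tagged with
#' provenance (the gene-compound pair that motivated it, the error type it
#' fixes, and citation text). Kinds: `block_reaction`, `block_reverse`,
#' `set_gpr`, `add_reaction`, `add_exchange`, `pseudo_add_rescale`,
#' `pseudo_append`. Unknown kinds are rejected at construction and at load.
#'
#' @param kind edit kind (one of the vocabulary above).
#' @param target reaction id the edit applies to (for additions, the new id).
#' @param payload kind-specific payload list.
#' @param provenance list with elements such as `pairs` (gene-compound
#'   pairs), `error_type` (`"type_I"`/`"type_II"`), `citation`, `ambiguous`.
#' @return An object of class `curation_edit`.
#' @export
curation_edit <- function(kind, target, payload = list(), provenance = list()) {
  kinds <- c("block_reaction", "block_reverse", "set_gpr", "add_reaction",
             "add_exchange", "pseudo_add_rescale", "pseudo_append")
  if (!kind %in% kinds) {
    stop(sprintf("unknown curation edit kind '%s'", kind), call. = FALSE)
  }
  structure(list(kind = kind, target = target, payload = payload,
                 provenance = provenance), class = "curation_edit")
}

#' @export
print.curation_edit <- function(x, ...) {
  cat(sprintf("<curation_edit> %s %s\n", x$kind, x$target))
  invisible(x)
}

#' Block a reaction
#'
#' `direction = "both"` fixes both bounds to zero; `"reverse"` forbids only
#' the reverse direction (`lb <- max(lb, 0)`), leaving forward flux intact --
#' a no-op on an already irreversible reaction.
#'
#' @param model a `gem`.
#' @param rxn_id reaction id.
#' @param direction `"both"` or `"reverse"`.
#' @return The modified model copy.
#' @export
block_reaction <- function(model, rxn_id, direction = c("both", "reverse")) {
  direction <- match.arg(direction)
  r <- gem_get_reaction(model, rxn_id)
  if (direction == "both") {
    model$reactions[[rxn_id]]$lb <- 0
    model$reactions[[rxn_id]]$ub <- 0
  } else {
    model$reactions[[rxn_id]]$lb <- max(r$lb, 0)
  }
  model
}

#' Replace a reaction's GPR
#'
#' All genes in the new rule must already exist in the model; register novel
#' genes first with [register_genes()].
#'
#' @param model a `gem`.
#' @param rxn_id reaction id.
#' @param gpr_text new GPR string.
#' @return The modified model copy.
#' @export
set_gpr <- function(model, rxn_id, gpr_text) {
  gem_get_reaction(model, rxn_id)
  expr <- parse_gpr(gpr_text)
  unknown <- setdiff(gpr_genes(expr), model$genes)
  if (length(unknown)) {
    stop(sprintf("GPR for '%s' cites unregistered gene(s): %s", rxn_id,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  model$reactions[[rxn_id]]$gpr <- expr
  model
}

#' Add a reaction to a model
#'
#' Unknown metabolites must be supplied through `new_metabolites` and are
#' added atomically with the reaction; otherwise the addition errors.
#' Duplicate reaction ids error -- curation sets are deliberately
#' non-idempotent, so applying one twice fails loudly rather than silently
#' double-editing.
#'
#' @param model a `gem`.
#' @param rxn a `gem_reaction` (see [reaction()]).
#' @param new_metabolites optional data.frame of metabolites to add
#'   (columns as in [gem()]).
#' @return The extended model copy.
#' @export
add_reaction <- function(model, rxn, new_metabolites = NULL) {
  if (rxn$id %in% gem_reaction_ids(model)) {
    stop(sprintf("reaction id '%s' already exists", rxn$id), call. = FALSE)
  }
  if (!is.null(new_metabolites)) {
    new_metabolites <- as.data.frame(new_metabolites, stringsAsFactors = FALSE)
    if (!"formula" %in% names(new_metabolites)) new_metabolites$formula <- NA_character_
    if (!"mass" %in% names(new_metabolites)) new_metabolites$mass <- NA_real_
    if (!"name" %in% names(new_metabolites)) new_metabolites$name <- new_metabolites$id
    fresh <- !new_metabolites$id %in% model$metabolites$id
    model$metabolites <- rbind(model$metabolites,
                               new_metabolites[fresh, names(model$metabolites)])
  }
  unknown <- setdiff(names(rxn$stoich), model$metabolites$id)
  if (length(unknown)) {
    stop(sprintf("reaction '%s' references unknown metabolite(s): %s",
                 rxn$id, paste(unknown, collapse = ", ")), call. = FALSE)
  }
  unknown_g <- setdiff(gpr_genes(rxn$gpr), model$genes)
  if (length(unknown_g)) {
    stop(sprintf("reaction '%s' GPR cites unregistered gene(s): %s",
                 rxn$id, paste(unknown_g, collapse = ", ")), call. = FALSE)
  }
  model$reactions[[rxn$id]] <- rxn
  model
}

#' Add an exchange reaction for a metabolite
#'
#' Created in the export convention (`met ->`, coefficient -1) and closed for
#' uptake by default (`lb = 0`); rescue simulations open it later.
#'
#' @param model a `gem`.
#' @param met_id metabolite id (must exist, or be supplied via
#'   `new_metabolites`).
#' @param rxn_id id for the new exchange; default `EX_<met_id>`.
#' @param lb,ub bounds.
#' @param new_metabolites optional metabolites to add atomically.
#' @return The extended model copy.
#' @export
add_exchange <- function(model, met_id, rxn_id = paste0("EX_", met_id),
                         lb = 0, ub = 1000, new_metabolites = NULL) {
  rx <- reaction(id = rxn_id, stoich = stats::setNames(-1, met_id),
                 lb = lb, ub = ub, name = paste("exchange:", met_id))
  add_reaction(model, rx, new_metabolites = new_metabolites)
}

#' Mass-balanced rescaling of a biomass pseudoreaction
#'
#' Incorporates a new species into a pooled pseudoreaction (e.g. adding
#' chitin to the carbohydrate pool) while conserving the pool's total
#' reactant mass. Each reactant coefficient is first converted to mass units
#' (`|coeff| * molar mass`); with initial total mass `M0` and new-species
#' mass `m_new`, all reactant masses are scaled by `f = M0 / (M0 + m_new)`
#' and converted back to coefficients, so the total reactant mass after the
#' edit equals `M0` exactly.
#'
#' Two coefficient modes are supported, because curation tables sometimes
#' print the *final* coefficient rather than the raw one:
#' * `mode = "raw"`: `new_coefficient` is the pre-scaling coefficient; the
#'   new species is scaled by `f` along with everything else.
#' * `mode = "final"`: `new_coefficient` is the post-edit coefficient; the
#'   original reactants are scaled by `f = (M0 - m_new) / M0`.
#' Both conserve total reactant mass and preserve the pairwise coefficient
#' ratios of the pre-existing reactants (uniform scaling).
#'
#' @param model a `gem`.
#' @param rxn_id pseudoreaction id.
#' @param new_species metabolite id of the species to incorporate.
#' @param new_coefficient its (negative, reactant-side) coefficient.
#' @param masses named numeric vector of per-unit masses overriding or
#'   augmenting formula-derived masses; every reactant must end up with a
#'   mass.
#' @param mode `"raw"` or `"final"` (see above).
#' @return The modified model copy.
#' @export
rescale_pseudoreaction <- function(model, rxn_id, new_species,
                                   new_coefficient, masses = NULL,
                                   mode = c("raw", "final")) {
  mode <- match.arg(mode)
  r <- gem_get_reaction(model, rxn_id)
  if (!new_species %in% model$metabolites$id) {
    stop(sprintf("unknown metabolite '%s'", new_species), call. = FALSE)
  }
  if (new_species %in% names(r$stoich)) {
    stop(sprintf("species '%s' already present in '%s'", new_species, rxn_id),
         call. = FALSE)
  }
  if (new_coefficient == 0) return(model)
  if (new_coefficient > 0) {
    stop("new species must enter on the reactant side (negative coefficient)",
         call. = FALSE)
  }
  mass_of <- function(met) {
    if (!is.null(masses) && met %in% names(masses)) return(masses[[met]])
    m <- metabolite_mass(model, met)
    if (is.na(m)) {
      stop(sprintf("no mass available for reactant '%s' (supply an override)",
                   met), call. = FALSE)
    }
    m
  }
  reactants <- r$stoich[r$stoich < 0]
  rmass <- vapply(names(reactants), mass_of, 0)
  if (any(rmass <= 0)) stop("all species masses must be positive", call. = FALSE)
  m0 <- sum(abs(reactants) * rmass)
  m_new <- abs(new_coefficient) * mass_of(new_species)
  if (mode == "raw") {
    f <- m0 / (m0 + m_new)
    new_coef_final <- new_coefficient * f
  } else {
    if (m_new >= m0) {
      stop("final-mode coefficient implies non-positive residual mass",
           call. = FALSE)
    }
    f <- (m0 - m_new) / m0
    new_coef_final <- new_coefficient
  }
  st <- r$stoich
  st[names(reactants)] <- reactants * f
  st[new_species] <- new_coef_final
  model$reactions[[rxn_id]]$stoich <- st
  model
}

#' Append a species to a pseudoreaction without rescaling
#'
#' For cofactor-style additions with tiny coefficients, where the mass
#' perturbation is negligible and the curation source appends rather than
#' rebalances.
#'
#' @param model a `gem`.
#' @param rxn_id pseudoreaction id.
#' @param met_id species to append (must exist, must not already be in the
#'   reaction).
#' @param coefficient signed coefficient; zero is rejected.
#' @return The modified model copy.
#' @export
pseudo_append <- function(model, rxn_id, met_id, coefficient) {
  r <- gem_get_reaction(model, rxn_id)
  if (!met_id %in% model$metabolites$id) {
    stop(sprintf("unknown metabolite '%s'", met_id), call. = FALSE)
  }
  if (met_id %in% names(r$stoich)) {
    stop(sprintf("species '%s' already present in '%s'", met_id, rxn_id),
         call. = FALSE)
  }
  if (coefficient == 0) {
    stop("coefficient 0 is degenerate; refusing to append", call. = FALSE)
  }
  st <- r$stoich
  st[met_id] <- coefficient
  model$reactions[[rxn_id]]$stoich <- st
  model
}

apply_one_edit <- function(model, edit) {
  p <- edit$payload
  switch(edit$kind,
    block_reaction = block_reaction(model, edit$target, "both"),
    block_reverse = block_reaction(model, edit$target, "reverse"),
    set_gpr = {
      if (!is.null(p$new_genes)) model <- register_genes(model, unlist(p$new_genes))
      set_gpr(model, edit$target, p$gpr)
    },
    add_reaction = {
      if (!is.null(p$new_genes)) model <- register_genes(model, unlist(p$new_genes))
      eq <- parse_equation(p$equation)
      lb <- p$lb %||% if (eq$reversible) -1000 else 0
      ub <- p$ub %||% 1000
      nm <- edit_new_metabolites(p)
      add_reaction(model,
                   reaction(id = edit$target, stoich = eq$stoich, lb = lb,
                            ub = ub, gpr = p$gpr %||% "",
                            name = p$name %||% edit$target,
                            notes = p$notes %||% ""),
                   new_metabolites = nm)
    },
    add_exchange = {
      nm <- edit_new_metabolites(p)
      add_exchange(model, p$metabolite, rxn_id = edit$target,
                   lb = p$lb %||% 0, ub = p$ub %||% 1000,
                   new_metabolites = nm)
    },
    pseudo_add_rescale = rescale_pseudoreaction(
      model, edit$target, p$new_species, p$coefficient,
      masses = if (!is.null(p$masses)) unlist(p$masses) else NULL,
      mode = p$mode %||% "raw"),
    pseudo_append = pseudo_append(model, edit$target, p$species, p$coefficient)
  )
}

edit_new_metabolites <- function(p) {
  if (is.null(p$new_metabolites)) return(NULL)
  do.call(rbind, lapply(p$new_metabolites, function(m) {
    data.frame(id = m$id, name = m$name %||% m$id,
               compartment = m$compartment %||% "",
               formula = m$formula %||% NA_character_,
               mass = m$mass %||% NA_real_)
  }))
}

#' Apply a list of curation edits
#'
#' Edits are applied in list order on a working copy; any failure aborts the
#' whole application with a report naming the offending edit, leaving the
#' input model untouched (all-or-nothing semantics). The returned log records
#' each edit's before/after state of the targeted reaction.
#'
#' @param model a `gem`.
#' @param edits list of `curation_edit` objects.
#' @return List with `model` (the curated copy) and `log` (data.frame with
#'   one row per edit: `kind`, `target`, `before`, `after`).
#' @export
apply_edits <- function(model, edits) {
  out <- model
  log <- vector("list", length(edits))
  for (i in seq_along(edits)) {
    e <- edits[[i]]
    if (!inherits(e, "curation_edit")) {
      stop(sprintf("edit %d is not a curation_edit", i), call. = FALSE)
    }
    before <- describe_reaction(out, e$target)
    out <- tryCatch(apply_one_edit(out, e), error = function(err) {
      stop(sprintf("curation aborted at edit %d (%s %s): %s; model unchanged",
                   i, e$kind, e$target, conditionMessage(err)), call. = FALSE)
    })
    log[[i]] <- data.frame(kind = e$kind, target = e$target,
                           before = before,
                           after = describe_reaction(out, e$target))
  }
  list(model = out, log = do.call(rbind, log) %||%
         data.frame(kind = character(), target = character(),
                    before = character(), after = character()))
}

describe_reaction <- function(model, rxn_id) {
  r <- model$reactions[[rxn_id]]
  if (is.null(r)) return("(absent)")
  sprintf("[%g,%g] gpr='%s' stoich={%s}", r$lb, r$ub, gpr_render(r$gpr),
          paste(sprintf("%s:%.6g", names(r$stoich), r$stoich), collapse = ", "))
}

#' Serialize / load curation edits (YAML or JSON)
#'
#' Files are a list of records with `kind`, `target`, `payload`,
#' `provenance`; unknown kinds are rejected at load.
#'
#' @param edits list of `curation_edit`.
#' @param path file path (`.yaml`/`.yml` or `.json`).
#' @return `read_edits()` returns a list of `curation_edit`.
#' @export
write_edits <- function(edits, path) {
  recs <- lapply(edits, function(e) {
    list(kind = e$kind, target = e$target, payload = e$payload,
         provenance = e$provenance)
  })
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(recs, path)
  } else {
    jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_edits
#' @export
read_edits <- function(path) {
  recs <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  }
  lapply(recs, function(r) {
    curation_edit(r$kind, r$target, r$payload %||% list(),
                  r$provenance %||% list())
  })
}
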