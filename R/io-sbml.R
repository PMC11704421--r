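#' SBML Level 3 + fbc model I/O
#'
#' Covers the fbc-package subset that constraint-based models actually use:
#' species (with chemical formulas), reactions with reactant/product
#' stoichiometry, flux bounds as shared parameters referenced through
#' `fbc:lowerFluxBound` / `fbc:upperFluxBound`, nested
#' `fbc:geneProductAssociation` trees, the gene-product list, and the active
#' maximization objective. Other SBML packages are ignored on read and never
#' written.
#'
#' Identifier handling: SBML SIds forbid the bracket/dash characters used in
#' display-style metabolite ids, so the writer sanitizes ids deterministically
#' (non-alphanumerics become `_`, prefixed to avoid leading digits) and
#' preserves the display name and compartment verbatim; the reader keeps the
#' file's ids as-is. Gene products carry the original gene id in `fbc:label`,
#' which the reader restores.
#'
#' @param model a `gem`.
#' @param path file path.
#' @return `read_gem_sbml()` returns a validated `gem`.
#' @name sbml_io
NULL

SBML_CORE_NS <- "http://www.sbml.org/sbml/level3/version1/core"
SBML_FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

sbml_sid <- function(x, prefix) {
  s <- gsub("[^A-Za-z0-9_]", "_", x)
  ifelse(grepl("^[A-Za-z_]", s) & !duplicated(s), s, paste0(prefix, s))
}

#' @rdname sbml_io
#' @export
write_gem_sbml <- function(model, path) {
  met_sid <- sbml_sid(model$metabolites$id, "M_")
  if (anyDuplicated(met_sid)) {
    met_sid <- make.unique(met_sid, sep = "_")
  }
  names(met_sid) <- model$metabolites$id
  gene_sid <- paste0("G_", gsub("[^A-Za-z0-9_]", "_", model$genes))
  names(gene_sid) <- model$genes

  doc <- xml2::xml_new_root(
    "sbml", xmlns = SBML_CORE_NS, "xmlns:fbc" = SBML_FBC_NS,
    level = "3", version = "1", "fbc:required" = "false"
  )
  mod <- xml2::xml_add_child(doc, "model", id = "model", "fbc:strict" = "true")

  comps <- unique(model$metabolites$compartment)
  lc <- xml2::xml_add_child(mod, "listOfCompartments")
  for (cp in comps) {
    xml2::xml_add_child(lc, "compartment", id = sbml_sid(cp, "c_"),
                        constant = "true")
  }

  ls <- xml2::xml_add_child(mod, "listOfSpecies")
  for (i in seq_len(nrow(model$metabolites))) {
    m <- model$metabolites[i, ]
    sp <- xml2::xml_add_child(ls, "species", id = met_sid[[m$id]],
                              name = m$name,
                              compartment = sbml_sid(m$compartment, "c_"),
                              hasOnlySubstanceUnits = "false",
                              boundaryCondition = "false", constant = "false")
    if (!is.na(m$formula) && nzchar(m$formula)) {
      xml2::xml_set_attr(sp, "fbc:chemicalFormula", m$formula)
    }
  }

  # shared bound parameters, one per distinct value
  bounds <- sort(unique(c(vapply(model$reactions, `[[`, 0, "lb"),
                          vapply(model$reactions, `[[`, 0, "ub"))))
  bid <- sprintf("bnd_%d", seq_along(bounds))
  names(bid) <- vapply(bounds, format, "", digits = 17)
  lp <- xml2::xml_add_child(mod, "listOfParameters")
  for (i in seq_along(bounds)) {
    xml2::xml_add_child(lp, "parameter", id = bid[[i]],
                        value = format(bounds[i], digits = 17),
                        constant = "true")
  }

  lr <- xml2::xml_add_child(mod, "listOfReactions")
  for (r in model$reactions) {
    rn <- xml2::xml_add_child(
      lr, "reaction", id = sbml_sid(r$id, "R_"), name = r$name,
      reversible = if (r$lb < 0) "true" else "false", fast = "false",
      "fbc:lowerFluxBound" = bid[[format(r$lb, digits = 17)]],
      "fbc:upperFluxBound" = bid[[format(r$ub, digits = 17)]]
    )
    reac <- r$stoich[r$stoich < 0]
    prod <- r$stoich[r$stoich > 0]
    if (length(reac)) {
      lre <- xml2::xml_add_child(rn, "listOfReactants")
      for (k in seq_along(reac)) {
        xml2::xml_add_child(lre, "speciesReference",
                            species = met_sid[[names(reac)[k]]],
                            stoichiometry = format(-reac[[k]], digits = 17),
                            constant = "true")
      }
    }
    if (length(prod)) {
      lpr <- xml2::xml_add_child(rn, "listOfProducts")
      for (k in seq_along(prod)) {
        xml2::xml_add_child(lpr, "speciesReference",
                            species = met_sid[[names(prod)[k]]],
                            stoichiometry = format(prod[[k]], digits = 17),
                            constant = "true")
      }
    }
    if (r$gpr$kind != "empty") {
      ga <- xml2::xml_add_child(rn, "fbc:geneProductAssociation")
      sbml_write_gpr(ga, r$gpr, gene_sid)
    }
  }

  lo <- xml2::xml_add_child(mod, "fbc:listOfObjectives",
                            "fbc:activeObjective" = "obj")
  ob <- xml2::xml_add_child(lo, "fbc:objective", "fbc:id" = "obj",
                            "fbc:type" = "maximize")
  lfo <- xml2::xml_add_child(ob, "fbc:listOfFluxObjectives")
  xml2::xml_add_child(lfo, "fbc:fluxObjective",
                      "fbc:reaction" = sbml_sid(model$objective, "R_"),
                      "fbc:coefficient" = "1")

  if (length(model$genes)) {
    lg <- xml2::xml_add_child(mod, "fbc:listOfGeneProducts")
    for (g in model$genes) {
      xml2::xml_add_child(lg, "fbc:geneProduct", "fbc:id" = gene_sid[[g]],
                          "fbc:label" = g)
    }
  }

  xml2::write_xml(doc, path)
  invisible(path)
}

sbml_write_gpr <- function(parent, expr, gene_sid) {
  switch(expr$kind,
    gene = xml2::xml_add_child(parent, "fbc:geneProductRef",
                               "fbc:geneProduct" = gene_sid[[expr$gene]]),
    and = {
      nd <- xml2::xml_add_child(parent, "fbc:and")
      for (a in expr$args) sbml_write_gpr(nd, a, gene_sid)
    },
    or = {
      nd <- xml2::xml_add_child(parent, "fbc:or")
      for (a in expr$args) sbml_write_gpr(nd, a, gene_sid)
    }
  )
  invisible(parent)
}

#' @rdname sbml_io
#' @export
read_gem_sbml <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  doc <- xml2::read_xml(path)
  ns <- c(s = SBML_CORE_NS, fbc = SBML_FBC_NS)
  errs <- character()

  sp_nodes <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  mets <- do.call(rbind, lapply(sp_nodes, function(nd) {
    data.frame(
      id = xml2::xml_attr(nd, "id"),
      name = xml2::xml_attr(nd, "name") %|na|% xml2::xml_attr(nd, "id"),
      compartment = xml2::xml_attr(nd, "compartment") %|na|% "",
      formula = xml2::xml_attr(nd, "chemicalFormula"),
      mass = NA_real_
    )
  }))

  params <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns)
  pval <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                          xml2::xml_attr(params, "id"))

  gp_nodes <- xml2::xml_find_all(doc, ".//fbc:listOfGeneProducts/fbc:geneProduct", ns)
  glabel <- stats::setNames(
    xml2::xml_attr(gp_nodes, "label") %|na|% xml2::xml_attr(gp_nodes, "id"),
    xml2::xml_attr(gp_nodes, "id"))

  rx_nodes <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  rxns <- list()
  for (nd in rx_nodes) {
    rid <- xml2::xml_attr(nd, "id")
    lbref <- xml2::xml_attr(nd, "lowerFluxBound")
    ubref <- xml2::xml_attr(nd, "upperFluxBound")
    if (is.na(lbref) || is.na(ubref)) {
      errs <- c(errs, sprintf("reaction '%s': no flux bounds (fbc bound references missing)", rid))
      next
    }
    if (!lbref %in% names(pval) || !ubref %in% names(pval)) {
      errs <- c(errs, sprintf("reaction '%s': bound parameter not defined", rid))
      next
    }
    st <- numeric()
    for (sr in xml2::xml_find_all(nd, "./s:listOfReactants/s:speciesReference", ns)) {
      sp <- xml2::xml_attr(sr, "species")
      st[sp] <- (st[sp] %|na0|% 0) - as.numeric(xml2::xml_attr(sr, "stoichiometry"))
    }
    for (sr in xml2::xml_find_all(nd, "./s:listOfProducts/s:speciesReference", ns)) {
      sp <- xml2::xml_attr(sr, "species")
      st[sp] <- (st[sp] %|na0|% 0) + as.numeric(xml2::xml_attr(sr, "stoichiometry"))
    }
    ga <- xml2::xml_find_first(nd, "./fbc:geneProductAssociation", ns)
    gpr <- if (inherits(ga, "xml_missing")) gpr_empty() else {
      kids <- xml2::xml_find_all(ga, "./*")
      if (length(kids) != 1L) gpr_empty() else sbml_read_gpr(kids[[1]], glabel, ns)
    }
    rxns[[rid]] <- reaction(id = rid, stoich = st, lb = pval[[lbref]],
                            ub = pval[[ubref]], gpr = gpr,
                            name = xml2::xml_attr(nd, "name") %|na|% rid)
  }

  fo <- xml2::xml_find_first(
    doc, ".//fbc:listOfObjectives/fbc:objective/fbc:listOfFluxObjectives/fbc:fluxObjective", ns)
  if (inherits(fo, "xml_missing")) {
    errs <- c(errs, "missing objective reaction (no fbc objective found)")
    objective <- NA_character_
  } else {
    objective <- xml2::xml_attr(fo, "reaction")
  }

  if (length(errs)) {
    stop(paste(c("invalid SBML model:", errs), collapse = "\n  "), call. = FALSE)
  }
  model <- gem(metabolites = mets, reactions = rxns,
               genes = unname(glabel), objective = objective)
  viol <- validate_gem(model)
  if (nrow(viol)) {
    stop(paste(c("model fails validation:",
                 sprintf("%s [%s]: %s", viol$entity, viol$rule, viol$message)),
               collapse = "\n  "), call. = FALSE)
  }
  model
}

sbml_read_gpr <- function(node, glabel, ns) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    gid <- xml2::xml_attr(node, "geneProduct")
    return(gpr_gene(glabel[[gid]] %||% gid))
  }
  kids <- lapply(xml2::xml_find_all(node, "./*"),
                 sbml_read_gpr, glabel = glabel, ns = ns)
  gpr_node(if (nm == "and") "and" else "or", kids)
}

`%|na|%` <- function(a, b) ifelse(is.na(a), b, a)
`%|na0|%` <- function(a, b) if (length(a) == 0 || is.na(a)) b else a
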