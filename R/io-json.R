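#' Read / write models in the native JSON dialect
#'
#' The dialect is a direct serialization of the [gem()] container: metabolite
#' records (`id`, `name`, `compartment`, `formula`, `mass`), reaction records
#' (`id`, `name`, `stoich` as an id-to-coefficient map, `lb`, `ub`, `gpr`
#' string, `notes`), the gene list, and the objective reaction id. Numbers
#' are written at full precision so save/load round-trips models
#' bit-equivalently; it is the preferred format for fixtures and tests.
#'
#' @param model a `gem`.
#' @param path file path.
#' @return `read_gem_json()` returns a `gem`; `write_gem_json()` returns
#'   `path` invisibly.
#' @export
write_gem_json <- function(model, path) {
  doc <- list(
    format = "auxofba-gem-1",
    metabolites = lapply(seq_len(nrow(model$metabolites)), function(i) {
      m <- model$metabolites[i, ]
      out <- list(id = m$id, name = m$name, compartment = m$compartment)
      if (!is.na(m$formula)) out$formula <- m$formula
      if (!is.na(m$mass)) out$mass <- m$mass
      out
    }),
    reactions = lapply(model$reactions, function(r) {
      list(id = r$id, name = r$name, stoich = as.list(r$stoich),
           lb = r$lb, ub = r$ub, gpr = gpr_render(r$gpr), notes = r$notes)
    }),
    genes = as.list(model$genes),
    objective = model$objective
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_gem_json
#' @export
read_gem_json <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  errs <- character()
  for (f in c("metabolites", "reactions", "objective")) {
    if (is.null(doc[[f]])) errs <- c(errs, sprintf("missing field '%s'", f))
  }
  if (length(errs)) {
    stop(paste(c("invalid model JSON:", errs), collapse = "\n  "), call. = FALSE)
  }
  mets <- do.call(rbind, lapply(doc$metabolites, function(m) {
    data.frame(id = m$id, name = m$name %||% m$id,
               compartment = m$compartment %||% "",
               formula = m$formula %||% NA_character_,
               mass = as.numeric(m$mass %||% NA_real_))
  }))
  rxns <- lapply(doc$reactions, function(r) {
    st <- vapply(r$stoich, as.numeric, 0)
    reaction(id = r$id, stoich = st, lb = as.numeric(r$lb),
             ub = as.numeric(r$ub),
             gpr = r$gpr %||% "", name = r$name %||% r$id,
             notes = r$notes %||% "")
  })
  model <- gem(metabolites = mets, reactions = rxns,
               genes = unlist(doc$genes) %||% character(),
               objective = doc$objective)
  viol <- validate_gem(model)
  if (nrow(viol)) {
    stop(paste(c("model fails validation:",
                 sprintf("%s [%s]: %s", viol$entity, viol$rule, viol$message)),
               collapse = "\n  "), call. = FALSE)
  }
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load / save a model, dispatching on format
#'
#' @param path file path.
#' @param format `"json"` (native dialect) or `"sbml"` (Level 3 + fbc);
#'   guessed from the file extension when omitted.
#' @param model a `gem`.
#' @return `load_model()` returns a validated `gem`.
#' @export
load_model <- function(path, format = c("auto", "json", "sbml")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE))
      "sbml" else "json"
  }
  switch(format, json = read_gem_json(path), sbml = read_gem_sbml(path))
}

#' @rdname load_model
#' @export
save_model <- function(model, path, format = c("auto", "json", "sbml")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE))
      "sbml" else "json"
  }
  switch(format, json = write_gem_json(model, path),
         sbml = write_gem_sbml(model, path))
  invisible(path)
}
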