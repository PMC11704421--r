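#' Auxotrophy datasets
#'
#' An auxotrophy record pairs a knockout gene set with a rescue
#' specification: the knockout is experimentally inviable, and supplying the
#' specified compound(s) restores growth. The TSV grammar supports the
#' realities of curated literature data: multi-gene knockouts
#' (`;`-separated), disjunctive-normal-form rescues (conjuncts separated by
#' `|`, members of a conjunct by `+` -- e.g.
#' `homoserine | methionine + threonine` means homoserine alone OR
#' methionine and threonine together), and medium supplements that must be
#' present throughout both simulation steps (the adenine/thiamine style of
#' condition-dependent auxotrophy).
#'
#' Columns: `knockout_genes`, `rescue_spec`, `medium_supplements` (optional),
#' `strain_background` (optional), `reference` (optional).
#'
#' @param path TSV file path.
#' @return A data.frame of class `auxo_dataset` with the columns above.
#' @export
read_auxo_dataset <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  required <- c("knockout_genes", "rescue_spec")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("dataset missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  for (opt in c("medium_supplements", "strain_background", "reference")) {
    if (!opt %in% names(df)) df[[opt]] <- ""
  }
  bad <- !nzchar(trimws(df$rescue_spec))
  if (any(bad)) {
    stop(sprintf("empty rescue_spec in row(s): %s",
                 paste(which(bad), collapse = ", ")), call. = FALSE)
  }
  class(df) <- c("auxo_dataset", "data.frame")
  df
}

#' @rdname read_auxo_dataset
#' @param records an `auxo_dataset` (or compatible data.frame).
#' @export
write_auxo_dataset <- function(records, path) {
  cols <- c("knockout_genes", "rescue_spec", "medium_supplements",
            "strain_background", "reference")
  for (cl in cols) if (!cl %in% names(records)) records[[cl]] <- ""
  utils::write.table(records[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

split_list <- function(x, sep) {
  if (is.na(x) || !nzchar(trimws(x))) return(character())
  trimws(strsplit(x, sep, fixed = TRUE)[[1]])
}

#' Parse a rescue specification into its DNF conjuncts
#'
#' @param spec rescue string, e.g. `"homoserine | methionine + threonine"`.
#' @return List of character vectors, one per conjunct.
#' @export
parse_rescue_spec <- function(spec) {
  conjuncts <- split_list(spec, "|")
  if (!length(conjuncts)) stop("empty rescue specification", call. = FALSE)
  out <- lapply(conjuncts, split_list, sep = "+")
  if (any(!lengths(out))) stop("empty conjunct in rescue specification",
                               call. = FALSE)
  out
}

#' Resolve a compound to its exchange reaction
#'
#' Three outcomes, and the distinction matters for classification:
#' `"ok"` (exchange found), `"no_exchange"` (the compound exists in the
#' model but has no exchange reaction -- supplementation cannot be
#' simulated, so a rescue through it fails), and `"unknown"` (the compound
#' matches nothing in the model -- the record is unresolvable and is
#' excluded rather than scored).
#'
#' @param model a `gem`.
#' @param compound id or name (see [find_exchange()]).
#' @return List with `status` and `exchange` (id or `NA`).
#' @export
resolve_compound <- function(model, compound) {
  ex <- tryCatch(find_exchange(model, compound),
                 error = function(e) stop(e))
  if (!is.na(ex)) return(list(status = "ok", exchange = ex))
  known <- compound %in% model$metabolites$id ||
    tolower(compound) %in% tolower(model$metabolites$name)
  list(status = if (known) "no_exchange" else "unknown",
       exchange = NA_character_)
}
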