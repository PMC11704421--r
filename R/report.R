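#' Flux-difference report for a gene knockout
#'
#' Solves FBA before and after the knockout and ranks reactions by absolute
#' flux change. This is the inspection aid behind block-reaction curation:
#' when a knockout unexpectedly keeps growing, the reactions whose flux
#' jumps are the compensatory pathways to scrutinize. Caveat (also attached
#' to the result): alternative optima make individual fluxes non-unique, so
#' the ranking is a lead generator, not evidence by itself.
#'
#' @param model a `gem`.
#' @param genes gene ids to knock out.
#' @param tol fluxes with `|delta|` below this are dropped.
#' @return data.frame `reaction`, `flux_before`, `flux_after`, `abs_diff`,
#'   sorted by decreasing `abs_diff`; attribute `caveat` documents the
#'   non-uniqueness.
#' @export
flux_diff_report <- function(model, genes, tol = 1e-9) {
  before <- solve_fba(model)
  after <- solve_fba(apply_knockout(model, genes))
  ids <- gem_reaction_ids(model)
  fb <- if (before$status == "optimal") before$fluxes else
    stats::setNames(numeric(length(ids)), ids)
  fa <- if (after$status == "optimal") after$fluxes else
    stats::setNames(numeric(length(ids)), ids)
  df <- data.frame(reaction = ids, flux_before = fb[ids],
                   flux_after = fa[ids],
                   abs_diff = abs(fa[ids] - fb[ids]), row.names = NULL)
  df <- df[df$abs_diff > tol, ]
  df <- df[order(-df$abs_diff, df$reaction), ]
  rownames(df) <- NULL
  attr(df, "caveat") <-
    "individual fluxes are one optimal vector; alternative optima exist"
  df
}

#' Machine-readable run summary
#'
#' Every CLI run writes one of these next to its results: the effective
#' configuration, fingerprints of the inputs, and the headline counts.
#' Two runs with identical inputs produce identical summaries (no
#' timestamps).
#'
#' @param config named list of effective settings.
#' @param models named list of `gem`s to fingerprint.
#' @param counts named list of result counts.
#' @param path output JSON path, or `NULL` to return the object only.
#' @return The summary list, invisibly when written.
#' @export
run_summary <- function(config, models = list(), counts = list(),
                        path = NULL) {
  summary <- list(
    config = config,
    model_fingerprints = lapply(models, rlang::hash),
    counts = counts
  )
  if (!is.null(path)) {
    jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    return(invisible(summary))
  }
  summary
}
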