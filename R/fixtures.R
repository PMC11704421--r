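#' Configuration for the toy-GEM generator
#'
#' The generator builds a minimal but fully functional metabolic network:
#' one substrate exchange (finite uptake, 10 mmol/gDW/h), an energy side
#' reaction, and per biomass precursor a linear gene-labelled synthesis
#' pathway. Per-precursor feature flags plant the structures behind the
#' misprediction taxonomy:
#'
#' * `isoenzyme` -- the first pathway step is catalysed by either of two
#'   genes (OR rule); neither is individually essential.
#' * `complex` -- the first step needs both subunits (AND rule); each is
#'   essential.
#' * `bypass` -- a gene-free compensatory reaction also makes the precursor,
#'   so the pathway knockout stays viable: a planted type-I trap, repaired
#'   by blocking the bypass.
#' * `no_exchange` -- the precursor has no exchange reaction, so its rescue
#'   cannot be simulated: a planted type-II trap, repaired by adding the
#'   extracellular species, a transporter, and an exchange.
#' * `medium_conditional` -- a vitamin-like cofactor branches off the first
#'   pathway intermediate and is also consumed by biomass; knocking out step
#'   one starves both products, so the rescue only works with the cofactor
#'   supplied in the medium throughout (requires pathway length >= 2).
#' * `conjunctive` -- the precursor splits into two biomass components, so
#'   rescue needs both compounds together (a conjunctive rescue, invisible
#'   to the single-compound screen).
#'
#' Topology is fully deterministic given the flags; the seed is carried into
#' the planted truth and only drives downstream dataset randomization.
#'
#' @param n_precursors number of biomass precursors (>= 1).
#' @param pathway_lengths steps per precursor pathway (recycled to length
#'   `n_precursors`).
#' @param features named list: `features[[i]]` is a character vector of
#'   flags for precursor `i`.
#' @param seed integer seed recorded in the truth object.
#' @return A `toy_gem_config` list.
#' @export
toy_gem_config <- function(n_precursors = 3, pathway_lengths = 2,
                           features = list(), seed = 1L) {
  stopifnot(n_precursors >= 1)
  pathway_lengths <- rep_len(pathway_lengths, n_precursors)
  feats <- vector("list", n_precursors)
  for (i in seq_len(n_precursors)) {
    f <- if (!is.null(names(features))) {
      features[[as.character(i)]] %||% character()
    } else if (i <= length(features)) {
      features[[i]] %||% character()
    } else character()
    if (all(c("isoenzyme", "complex") %in% f)) {
      stop(sprintf("precursor %d: isoenzyme and complex are contradictory", i),
           call. = FALSE)
    }
    trapf <- c("bypass", "no_exchange", "medium_conditional", "conjunctive")
    if (sum(trapf %in% f) > 1) {
      stop(sprintf("precursor %d: at most one trap flag is supported", i),
           call. = FALSE)
    }
    if (any(trapf %in% f) && any(c("isoenzyme", "complex") %in% f)) {
      stop(sprintf(
        "precursor %d: gene-rule flags cannot be combined with a trap flag", i),
        call. = FALSE)
    }
    if ("medium_conditional" %in% f && pathway_lengths[i] < 2) {
      stop(sprintf("precursor %d: medium_conditional needs pathway length >= 2", i),
           call. = FALSE)
    }
    feats[[i]] <- f
  }
  structure(list(n_precursors = n_precursors,
                 pathway_lengths = pathway_lengths,
                 features = feats, seed = as.integer(seed)),
            class = "toy_gem_config")
}

#' Generate a toy GEM with planted ground truth
#'
#' @param config a [toy_gem_config()].
#' @return List with `model` (a validated `gem`) and `truth`, a
#'   `planted_truth` list carrying: `essential_genes`; `rescue_pairs`
#'   (gene/compound pairs the systematic screen must find); `records`
#'   (an auxotrophy dataset with `expected_pre` / `expected_post`
#'   classifications before and after repair); `repairs` (per-trap curation
#'   edit lists); and the closed-form `wt_growth`.
#' @export
make_toy_gem <- function(config = toy_gem_config()) {
  stopifnot(inherits(config, "toy_gem_config"))
  n <- config$n_precursors
  mets <- list()
  rxns <- list()
  genes <- character()
  addm <- function(id, name = sub("\\[.*\\]$", "", id)) {
    comp <- sub("^.*\\[(.*)\\]$", "\\1", id)
    mets[[length(mets) + 1L]] <<- data.frame(
      id = id, name = name, compartment = comp,
      formula = NA_character_, mass = NA_real_)
    id
  }
  addr <- function(id, stoich, lb = 0, ub = 1000, gpr = "", name = id) {
    rxns[[length(rxns) + 1L]] <<- reaction(id, stoich, lb, ub, gpr, name)
    id
  }

  addm("substrate[e]")
  addm("substrate[c]")
  addm("atp[c]")
  addr("EX_substrate", c("substrate[e]" = -1), lb = -10)
  addr("T_substrate", c("substrate[e]" = -1, "substrate[c]" = 1))
  addr("R_energy", c("substrate[c]" = -1, "atp[c]" = 2))

  biomass_in <- c("atp[c]" = -1)
  essential <- character()
  pairs <- list()
  records <- list()
  repairs <- list()
  substrate_cost <- 0.5  # atp: 1 per biomass at 2 atp per substrate

  for (i in seq_len(n)) {
    f <- config$features[[i]]
    L <- config$pathway_lengths[i]
    P <- sprintf("P%d[c]", i)
    step_met <- function(k) if (k == L) P else sprintf("I%d_%d[c]", i, k)
    gene_of <- function(k) sprintf("g%d_%d", i, k)
    for (k in seq_len(L)) addm(step_met(k))

    for (k in seq_len(L)) {
      from <- if (k == 1) "substrate[c]" else step_met(k - 1)
      gk <- gene_of(k)
      if (k == 1 && "isoenzyme" %in% f) {
        gpr <- sprintf("%sa or %sb", gk, gk)
        genes <- c(genes, paste0(gk, "a"), paste0(gk, "b"))
      } else if (k == 1 && "complex" %in% f) {
        gpr <- sprintf("%sa and %sb", gk, gk)
        genes <- c(genes, paste0(gk, "a"), paste0(gk, "b"))
      } else {
        gpr <- gk
        genes <- c(genes, gk)
      }
      addr(sprintf("R%d_%d", i, k),
           stats::setNames(c(-1, 1), c(from, step_met(k))), gpr = gpr)
    }

    # which pathway genes are essential (before any repair)
    step_genes <- function(k) {
      if (k == 1 && "complex" %in% f) paste0(gene_of(1), c("a", "b"))
      else if (k == 1 && "isoenzyme" %in% f) character()  # OR: not individually
      else gene_of(k)
    }
    path_essential <- unlist(lapply(seq_len(L), step_genes))

    has_exchange <- !"no_exchange" %in% f && !"conjunctive" %in% f
    if (has_exchange) {
      Pe <- addm(sprintf("P%d[e]", i))
      addr(sprintf("T_P%d", i), stats::setNames(c(-1, 1), c(Pe, P)),
           lb = -1000)
      addr(sprintf("EX_P%d", i), stats::setNames(-1, Pe), lb = 0)
    }

    if ("bypass" %in% f) {
      addr(sprintf("R_bypass%d", i),
           stats::setNames(c(-1, 1), c("substrate[c]", P)),
           name = sprintf("compensatory bypass to P%d", i))
      repairs[[sprintf("P%d", i)]] <- list(
        curation_edit("block_reaction", sprintf("R_bypass%d", i),
                      provenance = list(pairs = sprintf("g%d_1-P%d", i, i),
                                        error_type = "type_I")))
      records[[length(records) + 1L]] <- data.frame(
        knockout_genes = gene_of(1), rescue_spec = sprintf("P%d", i),
        medium_supplements = "", strain_background = "toy",
        reference = "planted", expected_pre = "TYPE_I",
        expected_post = "CORRECT")
      # pathway genes are shadowed by the bypass: not essential pre-repair
    } else if ("no_exchange" %in% f) {
      repairs[[sprintf("P%d", i)]] <- list(
        curation_edit("add_exchange", sprintf("EX_P%d", i),
          payload = list(metabolite = sprintf("P%d[e]", i),
                         new_metabolites = list(list(
                           id = sprintf("P%d[e]", i), name = sprintf("P%d", i),
                           compartment = "e")))),
        curation_edit("add_reaction", sprintf("T_P%d", i),
          payload = list(equation = sprintf("P%d[e] <=> P%d[c]", i, i))))
      records[[length(records) + 1L]] <- data.frame(
        knockout_genes = gene_of(1), rescue_spec = sprintf("P%d", i),
        medium_supplements = "", strain_background = "toy",
        reference = "planted", expected_pre = "TYPE_II",
        expected_post = "CORRECT")
      essential <- c(essential, path_essential)
    } else if ("medium_conditional" %in% f) {
      v <- addm(sprintf("v%d[c]", i))
      ve <- addm(sprintf("v%d[e]", i))
      addr(sprintf("R_v%d", i),
           stats::setNames(c(-1, 1), c(step_met(1), v)))
      addr(sprintf("T_v%d", i), stats::setNames(c(-1, 1), c(ve, v)),
           lb = -1000)
      addr(sprintf("EX_v%d", i), stats::setNames(-1, ve), lb = 0)
      biomass_in[v] <- -1
      substrate_cost <- substrate_cost + 1
      records[[length(records) + 1L]] <- data.frame(
        knockout_genes = gene_of(1), rescue_spec = sprintf("P%d", i),
        medium_supplements = sprintf("v%d", i), strain_background = "toy",
        reference = "planted", expected_pre = "CORRECT",
        expected_post = "CORRECT")
      essential <- c(essential, path_essential)
      # single-compound rescue exists only for steps >= 2 (cofactor intact)
      for (g in setdiff(path_essential, step_genes(1))) {
        pairs[[length(pairs) + 1L]] <- data.frame(
          gene = g, compound = sprintf("P%d", i))
      }
    } else if ("conjunctive" %in% f) {
      for (s in c("a", "b")) {
        Cc <- addm(sprintf("C%d%s[c]", i, s))
        Ce <- addm(sprintf("C%d%s[e]", i, s))
        addr(sprintf("R_split%d%s", i, s),
             stats::setNames(c(-1, 1), c(P, Cc)))
        addr(sprintf("T_C%d%s", i, s),
             stats::setNames(c(-1, 1), c(Ce, Cc)), lb = -1000)
        addr(sprintf("EX_C%d%s", i, s), stats::setNames(-1, Ce), lb = 0)
        biomass_in[Cc] <- -1
      }
      substrate_cost <- substrate_cost + 2
      records[[length(records) + 1L]] <- data.frame(
        knockout_genes = gene_of(1),
        rescue_spec = sprintf("C%da | C%da + C%db", i, i, i),
        medium_supplements = "", strain_background = "toy",
        reference = "planted", expected_pre = "CORRECT",
        expected_post = "CORRECT")
      essential <- c(essential, path_essential)
    } else {
      ko <- if ("isoenzyme" %in% f) {
        paste0(gene_of(1), c("a", "b"), collapse = ";")
      } else gene_of(1)
      records[[length(records) + 1L]] <- data.frame(
        knockout_genes = ko, rescue_spec = sprintf("P%d", i),
        medium_supplements = "", strain_background = "toy",
        reference = "planted", expected_pre = "CORRECT",
        expected_post = "CORRECT")
      essential <- c(essential, path_essential)
      for (g in path_essential) {
        pairs[[length(pairs) + 1L]] <- data.frame(
          gene = g, compound = sprintf("P%d", i))
      }
    }

    if (!"conjunctive" %in% f) {
      biomass_in[P] <- -1
      substrate_cost <- substrate_cost + if ("conjunctive" %in% f) 2 else 1
    }
  }

  addr("R_biomass", biomass_in, name = "biomass drain")
  model <- gem(metabolites = do.call(rbind, mets), reactions = rxns,
               genes = unique(genes), objective = "R_biomass")
  viol <- validate_gem(model)
  if (nrow(viol)) stop("internal: toy model fails validation", call. = FALSE)

  recs <- do.call(rbind, records)
  class(recs) <- c("auxo_dataset", "data.frame")
  truth <- structure(list(
    essential_genes = sort(unique(essential)),
    rescue_pairs = do.call(rbind, pairs) %||%
      data.frame(gene = character(), compound = character()),
    records = recs,
    repairs = repairs,
    wt_growth = 10 / substrate_cost,
    seed = config$seed,
    config = config
  ), class = "planted_truth")
  list(model = model, truth = truth)
}

#' Generate a synthetic auxotrophy dataset from planted truth
#'
#' Emits the truth's designed records plus `round(noise * n)` deliberately
#' mismatched records (an essential gene paired with a compound that cannot
#' rescue it), with ground-truth expected classifications alongside.
#'
#' @param truth a `planted_truth`.
#' @param noise fraction in `[0, 1)` of additional wrong records.
#' @param seed integer seed for the noise draw (defaults to the truth's
#'   seed).
#' @return An `auxo_dataset` with extra columns `expected_pre` and
#'   `expected_post` (the ground-truth labels; drop them before feeding a
#'   plain evaluation).
#' @export
make_synthetic_dataset <- function(truth, noise = 0, seed = truth$seed) {
  stopifnot(inherits(truth, "planted_truth"), noise >= 0, noise < 1)
  recs <- truth$records
  n_noise <- round(noise * nrow(recs))
  if (n_noise > 0) {
    if (nrow(truth$rescue_pairs) == 0) {
      stop("cannot generate noise records: no planted rescue pairs",
           call. = FALSE)
    }
    compounds <- unique(c(truth$rescue_pairs$compound, "not_in_any_model"))
    rng <- local({set.seed(seed); list(
      gi = sample.int(nrow(truth$rescue_pairs), n_noise, replace = TRUE),
      ci = sample.int(length(compounds), n_noise, replace = TRUE))})
    for (j in seq_len(n_noise)) {
      pair <- truth$rescue_pairs[rng$gi[j], ]
      wrong <- setdiff(compounds, pair$compound)
      compound <- wrong[((rng$ci[j] - 1) %% length(wrong)) + 1]
      expected <- if (compound == "not_in_any_model") "unresolvable" else "TYPE_II"
      recs <- rbind(recs, data.frame(
        knockout_genes = pair$gene, rescue_spec = compound,
        medium_supplements = "", strain_background = "toy",
        reference = "noise", expected_pre = expected,
        expected_post = expected))
    }
  }
  class(recs) <- c("auxo_dataset", "data.frame")
  recs
}
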