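#' End-to-end pipeline run configuration
#'
#' Either a CSV input (`input`) or a simulation config (`simulation`) must
#' be supplied. All seeds and thresholds are recorded in the output
#' manifest so a run can be reproduced exactly.
#'
#' @param input path to an abundance CSV (see [read_abundance()]), or NULL.
#' @param simulation a [sim_config()], or NULL.
#' @param control control-group label.
#' @param selection a [selection_config()].
#' @param n_components,sam_permutations,n_trees model settings.
#' @param pathway_library path to a pathway library JSON, or NULL to skip
#'   the pathway stage.
#' @param pathway_permutations Global Test permutations.
#' @param seed global seed for the stochastic stages.
#' @param out_dir output directory (created if needed).
#' @return list of class `"run_config"`.
#' @export
run_config <- function(input = NULL, simulation = NULL, control = "control",
                       selection = selection_config(), n_components = 5,
                       sam_permutations = 1000, n_trees = 500,
                       pathway_library = NULL, pathway_permutations = 2000,
                       seed = 1, out_dir = "consensusmet-out") {
  if (is.null(input) && is.null(simulation))
    stop("validation error: provide `input` or `simulation`")
  if (!is.null(input) && !file.exists(input))
    stop("validation error: input file not found: ", input)
  if (!is.null(pathway_library) && !file.exists(pathway_library))
    stop("validation error: pathway library not found: ", pathway_library)
  structure(list(input = input, simulation = simulation, control = control,
                 selection = selection, n_components = n_components,
                 sam_permutations = sam_permutations, n_trees = n_trees,
                 pathway_library = pathway_library,
                 pathway_permutations = pathway_permutations,
                 seed = seed, out_dir = out_dir),
            class = "run_config")
}

#' Run the full pipeline and write the artifact bundle
#'
#' Stages: load or simulate the panel; preprocess and fit the four models
#' plus consensus via [consensus_fit()]; optional pathway analysis of the
#' consensus set in unfiltered / FDR-only / full-filter modes; write all
#' result tables as CSV plus a JSON provenance manifest. Identical configs
#' give byte-identical tables.
#'
#' @param config a [run_config()].
#' @return (invisibly) list: `fit` (the [consensus_fit()]), `pathways`
#'   (or NULL), `truth` (for simulated input), `files` (named vector of
#'   written paths), `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  wr <- function(df, name) {
    path <- file.path(config$out_dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    files[[name]] <<- path
    path
  }

  truth <- NULL
  if (!is.null(config$simulation)) {
    sim <- simulate_panel(config$simulation)
    tab <- sim$table
    truth <- sim$truth
    write_abundance(tab, file.path(config$out_dir, "abundance.csv"))
    files[["abundance.csv"]] <- file.path(config$out_dir, "abundance.csv")
    write_truth(truth, file.path(config$out_dir, "truth.json"))
    files[["truth.json"]] <- file.path(config$out_dir, "truth.json")
  } else {
    tab <- read_abundance(config$input, control = config$control)
  }
  if (!config$control %in% tab$group)
    stop("validation error: control label '", config$control,
         "' absent from the panel")

  fit <- consensus_fit(tab, control = config$control,
                       config = config$selection,
                       n_components = config$n_components,
                       sam_permutations = config$sam_permutations,
                       n_trees = config$n_trees, seed = config$seed)

  wr(fit$table, "feature_stats.csv")
  wr(fit$table[fit$table$consensus,
               c("metabolite", "fold_change", "univariate_fdr", "vip_comp1",
                 "mda", "sam_q")], "consensus_table.csv")
  wr(volcano_classify(fit$univariate, fit$panel$fold_change,
                      q_threshold = fit$config$fdr_max)[
       , c("metabolite", "log2_fc", "neg_log10_q", "class")], "volcano.csv")
  wr(sam_plot_data(fit$sam), "sam_plot.csv")
  sc <- fit$plsda$scores
  wr(data.frame(sample = rownames(sc), group = fit$plsda$group,
                sc[, seq_len(min(2, ncol(sc))), drop = FALSE]),
     "plsda_scores.csv")
  pc <- pca_scores(fit$panel$pareto)
  wr(data.frame(sample = rownames(pc$scores), group = fit$panel$pareto$group,
                pc$scores), "pca_scores.csv")
  wr(data.frame(metabolite = names(fit$forest$mda), mda = fit$forest$mda,
                row.names = NULL), "mda_ranking.csv")
  wr(fit$overlap$lattice, "overlap_lattice.csv")

  pathways <- NULL
  if (!is.null(config$pathway_library)) {
    lib <- read_pathway_library(config$pathway_library)
    # map measured metabolite names onto the library's canonical compound
    # IDs; unmatched metabolites keep their names and simply fall outside
    # every pathway
    pwx <- fit$panel$pareto
    mp <- map_metabolites(colnames(pwx$values), lib)
    cn <- colnames(pwx$values)
    cn[match(names(mp$matched), cn)] <- unname(mp$matched)
    colnames(pwx$values) <- make.unique(cn)
    disc <- fit$selected
    hit <- disc %in% names(mp$matched)
    disc[hit] <- unname(mp$matched[disc[hit]])
    pw <- pathway_analyze(pwx, disc, lib, mode = "none",
                          n_permutations = config$pathway_permutations,
                          seed = config$seed)
    full <- pw[pw$fdr_q < 0.05 & pw$impact > 0.25 & pw$percent_affected > 20,
               , drop = FALSE]
    fdr_only <- pw[pw$fdr_q < 0.05, , drop = FALSE]
    wr(as.data.frame(pw), "pathways_unfiltered.csv")
    wr(as.data.frame(fdr_only), "pathways_fdr.csv")
    wr(as.data.frame(full), "pathways_full.csv")
    pathways <- list(unfiltered = pw, fdr = fdr_only, full = full)
  }

  manifest <- list(
    package = "consensusmet",
    version = as.character(utils::packageVersion("consensusmet")),
    seed = config$seed,
    control = config$control,
    thresholds = unclass(config$selection),
    n_components = config$n_components,
    sam_permutations = config$sam_permutations,
    sam_delta = fit$sam$delta,
    n_trees = config$n_trees,
    retention_pct = fit$panel$retention_pct,
    per_method = as.list(fit$overlap$per_method),
    n_consensus = length(fit$selected),
    simulation = if (!is.null(config$simulation))
      unclass(config$simulation[setdiff(names(config$simulation),
                                        "pathway_library")]),
    input = config$input,
    files = as.list(basename(unlist(files))))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  files[["manifest.json"]] <- file.path(config$out_dir, "manifest.json")

  invisible(list(fit = fit, pathways = pathways, truth = truth,
                 files = files, manifest = manifest))
}
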