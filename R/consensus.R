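#' Selection thresholds for the four feature-selection models
#'
#' All comparisons are strict, matching the convention of reporting
#' discriminant features at FDR < 0.05, VIP > 1.0 and MDA > 0.
#'
#' @param fdr_max univariate BH q-value bound (default 0.05).
#' @param sam_fdr_max SAM FDR target used to choose delta when `sam_delta`
#'   is `"auto-for-fdr"` (default 0.05).
#' @param sam_delta numeric delta, or `"auto-for-fdr"` to pick the smallest
#'   delta attaining `sam_fdr_max`.
#' @param vip_min VIP cutoff (default 1.0).
#' @param mda_min MDA cutoff (default 0).
#' @param fc_gate optional fold-change gate (e.g. 2 to require a two-fold
#'   change in either direction); `NULL` disables it.
#' @return list of class `"selection_config"`.
#' @export
selection_config <- function(fdr_max = 0.05, sam_fdr_max = 0.05,
                             sam_delta = "auto-for-fdr", vip_min = 1.0,
                             mda_min = 0, fc_gate = NULL) {
  stopifnot(fdr_max > 0, fdr_max < 1, sam_fdr_max > 0, sam_fdr_max < 1,
            is.finite(vip_min), is.finite(mda_min))
  structure(list(fdr_max = fdr_max, sam_fdr_max = sam_fdr_max,
                 sam_delta = sam_delta, vip_min = vip_min, mda_min = mda_min,
                 fc_gate = fc_gate),
            class = "selection_config")
}

#' Four-way consensus of discriminant-metabolite calls
#'
#' Combines the univariate, SAM, PLS-DA VIP and random-forest results into
#' one per-metabolite statistics table and flags the consensus: metabolites
#' selected by all four models under their own calling rules. All four
#' results must cover exactly the same metabolite universe.
#'
#' @param univariate a [t_test_all()] result.
#' @param sam a [sam_fit()] result (delta-band calls are used; the per-
#'   metabolite q is reported alongside).
#' @param plsda a [plsda_fit()] result (cumulative VIP over all fitted
#'   components is gated; component-1 VIP is reported).
#' @param forest a [forest_fit()] result.
#' @param config a [selection_config()].
#' @param fold_change named fold-change vector on the un-logged scale.
#' @return data.frame of class `"feature_stats_table"`, input metabolite
#'   order, with per-method statistics, per-method membership flags and the
#'   `consensus` flag (the AND of the four).
#' @export
build_consensus <- function(univariate, sam, plsda, forest, config,
                            fold_change = NULL) {
  stopifnot(inherits(config, "selection_config"))
  ids <- univariate$metabolite
  universes <- list(sam = names(sam$d), plsda = rownames(plsda$weights),
                    forest = names(forest$mda))
  for (nm in names(universes)) {
    if (!setequal(ids, universes[[nm]])) {
      diff <- c(setdiff(ids, universes[[nm]]), setdiff(universes[[nm]], ids))
      stop("metabolite universe mismatch (univariate vs ", nm, "): ",
           paste(utils::head(diff, 10), collapse = ", "))
    }
  }
  vip_all <- vip_scores(plsda)
  vip1 <- plsda$vip_by_component[, 1L]
  fc <- if (is.null(fold_change)) rep(NA_real_, length(ids)) else
    unname(fold_change[ids])

  in_t <- univariate$fdr_q < config$fdr_max
  in_sam <- unname(sam$called[ids])
  in_vip <- unname(vip_all[ids] > config$vip_min)
  in_rf <- unname(forest$mda[ids] > config$mda_min)
  if (!is.null(config$fc_gate)) {
    gate <- fc > config$fc_gate | fc < 1 / config$fc_gate
    in_t <- in_t & gate
  }
  out <- data.frame(metabolite = ids,
                    fold_change = fc,
                    univariate_fdr = univariate$fdr_q,
                    vip_comp1 = unname(vip1[ids]),
                    vip_cumulative = unname(vip_all[ids]),
                    mda = unname(forest$mda[ids]),
                    sam_q = unname(sam$q_value[ids]),
                    in_univariate = in_t, in_sam = in_sam, in_plsda = in_vip,
                    in_forest = in_rf,
                    consensus = in_t & in_sam & in_vip & in_rf,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("feature_stats_table", "data.frame")
  out
}

#' Per-method totals and the full four-set overlap lattice
#'
#' @param stats_table a [build_consensus()] table.
#' @return list: `per_method` (named counts), `consensus` (count), and
#'   `lattice`, a data.frame with one row per membership pattern of the
#'   four methods and the number of metabolites showing it.
#' @export
method_overlap_report <- function(stats_table) {
  stopifnot(inherits(stats_table, "feature_stats_table"))
  flags <- stats_table[, c("in_univariate", "in_sam", "in_plsda", "in_forest")]
  per_method <- colSums(flags)
  names(per_method) <- c("univariate", "sam", "plsda", "forest")
  pat <- do.call(paste0, lapply(flags, function(f) as.integer(f)))
  grid <- expand.grid(in_univariate = c(FALSE, TRUE), in_sam = c(FALSE, TRUE),
                      in_plsda = c(FALSE, TRUE), in_forest = c(FALSE, TRUE))
  key <- do.call(paste0, lapply(grid, as.integer))
  lattice <- cbind(grid, count = as.integer(table(factor(pat, levels = key))))
  list(per_method = per_method, consensus = sum(stats_table$consensus),
       lattice = lattice)
}

#' Apply the consensus thresholds to a pre-computed statistics table
#'
#' For tables that already carry the per-metabolite statistics (for example
#' published reference tables): keeps rows passing all requested strict
#' gates. Gates set to `NULL` are skipped.
#'
#' @param table data.frame with columns among `univariate_fdr`, `sam_q`
#'   (or `sam_fdr`), `vip_comp1`, `mda`.
#' @param fdr_max,sam_fdr_max,vip_min,mda_min thresholds; `NULL` disables
#'   the corresponding gate.
#' @return the subset of rows passing every active gate.
#' @export
filter_stats_table <- function(table, fdr_max = 0.05, sam_fdr_max = 0.05,
                               vip_min = 1.0, mda_min = 0) {
  keep <- rep(TRUE, nrow(table))
  if (!is.null(fdr_max)) keep <- keep & table$univariate_fdr < fdr_max
  if (!is.null(sam_fdr_max)) {
    samcol <- if ("sam_q" %in% names(table)) table$sam_q else table$sam_fdr
    keep <- keep & samcol < sam_fdr_max
  }
  if (!is.null(vip_min)) keep <- keep & table$vip_comp1 > vip_min
  if (!is.null(mda_min)) keep <- keep & table$mda > mda_min
  table[keep, , drop = FALSE]
}
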