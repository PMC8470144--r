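#' Fit the four-model consensus feature selection on a two-group panel
#'
#' The package's central fitter. From a raw abundance table it runs the
#' whole preprocessing chain (completeness filter, control-mean
#' normalization, fold change, log10 transform, Pareto scaling) and the four
#' independent feature-selection models:
#'
#' 1. FDR-adjusted pooled-variance t-tests (on the log matrix),
#' 2. SAM with permutation-estimated FDR and delta-band calling (log matrix),
#' 3. NIPALS PLS-DA with VIP scores (Pareto-scaled matrix),
#' 4. a 500-tree random forest with raw out-of-bag permutation importance
#'    (Pareto-scaled matrix),
#'
#' then intersects the four discriminant lists into the consensus set.
#'
#' @param x an [abundance_table()], or a samples x metabolites numeric
#'   matrix (then `group` is required).
#' @param group group labels when `x` is a matrix.
#' @param control control-group label.
#' @param config a [selection_config()] of thresholds.
#' @param n_components PLS-DA components (default 5).
#' @param sam_permutations SAM permutation budget (default 1000; two groups
#'   of six enumerate all 462 balanced splits).
#' @param n_trees random-forest trees (default 500).
#' @param cellcount_factors optional per-sample scaling nuisance divided out
#'   first.
#' @param test_on run the univariate and SAM models on the `"log"` matrix
#'   (default) or on the `"pareto"`-scaled one.
#' @param seed seed for the stochastic stages (SAM label sampling if any,
#'   forest bootstrap).
#' @return object of class `"consensus_fit"`: `table` (the
#'   [build_consensus()] statistics table), `selected` (consensus metabolite
#'   IDs), the per-model fits (`univariate`, `sam`, `plsda`, `forest`), the
#'   `panel` preprocessing bundle, `overlap` report, `config` and `call`.
#' @export
consensus_fit <- function(x, group = NULL, control = "control",
                          config = selection_config(), n_components = 5,
                          sam_permutations = 1000, n_trees = 500,
                          cellcount_factors = NULL,
                          test_on = c("log", "pareto"), seed = 1) {
  cl <- match.call()
  test_on <- match.arg(test_on)
  if (!inherits(x, "abundance_table")) {
    if (is.null(group)) stop("`group` is required when `x` is a matrix")
    x <- abundance_table(as.matrix(x), group, control = control)
  }
  panel <- preprocess_panel(x, cellcount_factors = cellcount_factors)
  uni_mat <- if (test_on == "log") panel$log else panel$pareto

  uni <- t_test_all(uni_mat, fold_change = panel$fold_change)
  sam <- if (is.numeric(config$sam_delta)) {
    sam_fit(uni_mat, n_permutations = sam_permutations,
            delta = config$sam_delta, seed = seed)
  } else {
    sam_fit(uni_mat, n_permutations = sam_permutations,
            target_fdr = config$sam_fdr_max, seed = seed)
  }
  pls <- plsda_fit(panel$pareto, n_components = n_components)
  rf <- forest_fit(panel$pareto, n_trees = n_trees, seed = seed)

  tab <- build_consensus(uni, sam, pls, rf, config,
                         fold_change = panel$fold_change)
  structure(list(table = tab, selected = tab$metabolite[tab$consensus],
                 univariate = uni, sam = sam, plsda = pls, forest = rf,
                 panel = panel, overlap = method_overlap_report(tab),
                 config = config, seed = seed, call = cl),
            class = "consensus_fit")
}

#' @export
print.consensus_fit <- function(x, ...) {
  pm <- x$overlap$per_method
  cat("Four-model consensus feature selection\n")
  cat(sprintf("  retained metabolites: %d (%.1f%% of input)\n",
              ncol(x$panel$filtered$values), x$panel$retention_pct))
  cat(sprintf("  discriminant: t-test %d | SAM %d (delta=%.2f) | VIP>%.1f %d | MDA>%g %d\n",
              pm["univariate"], pm["sam"], x$sam$delta, x$config$vip_min,
              pm["plsda"], x$config$mda_min, pm["forest"]))
  cat("  consensus (all four):", length(x$selected), "metabolites\n")
  invisible(x)
}

#' @export
summary.consensus_fit <- function(object, ...) {
  out <- list(retention_pct = object$panel$retention_pct,
              per_method = object$overlap$per_method,
              n_consensus = length(object$selected),
              selected = object$selected,
              sam_delta = object$sam$delta,
              sam_fdr_at_delta = object$sam$fdr_at_delta,
              plsda_explained_y = object$plsda$explained_y_variance,
              forest_oob_error = object$forest$oob_error)
  class(out) <- "summary.consensus_fit"
  out
}

#' @export
print.summary.consensus_fit <- function(x, ...) {
  cat(sprintf("retention: %.1f%%\n", x$retention_pct))
  cat("per-method discriminant counts:\n")
  print(x$per_method)
  cat(sprintf("SAM delta %.2f (est. FDR %.4g); forest OOB error %.3f\n",
              x$sam_delta, x$sam_fdr_at_delta, x$forest_oob_error))
  cat("consensus:", x$n_consensus, "metabolites\n")
  if (x$n_consensus) print(utils::head(x$selected, 20))
  invisible(x)
}

#' @export
coef.consensus_fit <- function(object, ...) {
  stats::setNames(log2(object$table$fold_change), object$table$metabolite)
}

#' Diagnostic plots for a consensus fit
#'
#' @param x a [consensus_fit()].
#' @param type `"volcano"` (log2 FC vs -log10 q), `"sam"` (observed vs
#'   expected d), `"scores"` (PLS-DA components 1-2) or `"mda"` (top forest
#'   importances).
#' @param ... passed to the underlying plot call.
#' @return `x`, invisibly; draws on the active device.
#' @export
plot.consensus_fit <- function(x, type = c("volcano", "sam", "scores", "mda"),
                               ...) {
  type <- match.arg(type)
  if (type == "volcano") {
    v <- volcano_classify(x$univariate, x$panel$fold_change,
                          q_threshold = x$config$fdr_max)
    graphics::plot(v$log2_fc, v$neg_log10_q,
                   col = ifelse(v$significant, 2, 1),
                   xlab = "log2 fold change", ylab = "-log10 FDR q", ...)
    graphics::abline(h = -log10(x$config$fdr_max), lty = 2)
  } else if (type == "sam") {
    sp <- sam_plot_data(x$sam)
    graphics::plot(sp$d_expected, sp$d_observed,
                   col = ifelse(sp$called, 2, 1),
                   xlab = "expected d", ylab = "observed d", ...)
    graphics::abline(0, 1)
    graphics::abline(x$sam$delta, 1, lty = 2)
    graphics::abline(-x$sam$delta, 1, lty = 2)
  } else if (type == "scores") {
    sc <- x$plsda$scores
    k <- min(2L, ncol(sc))
    graphics::plot(sc[, 1L], if (k > 1) sc[, 2L] else rep(0, nrow(sc)),
                   col = ifelse(x$plsda$group == x$plsda$control, 1, 2),
                   xlab = "component 1", ylab = "component 2", ...)
  } else {
    mda <- sort(x$forest$mda, decreasing = TRUE)
    top <- utils::head(mda, 25)
    graphics::barplot(rev(top), horiz = TRUE, las = 1,
                      xlab = "mean decrease accuracy", ...)
  }
  invisible(x)
}
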