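#' Random-forest classification with out-of-bag permutation importance
#'
#' Fits a Breiman random forest (bootstrap-resampled CART trees, sqrt(p)
#' candidate features per split, grown to purity) on the processed matrix
#' and returns the raw mean decrease in out-of-bag accuracy (MDA) per
#' metabolite: the average over trees of the drop in OOB accuracy when the
#' feature is permuted within the tree's OOB set, unscaled by its standard
#' error. Deterministic for a fixed seed.
#'
#' @param x a `"processed_matrix"` (conventionally Pareto-scaled).
#' @param n_trees number of trees (default 500; >= 50 enforced).
#' @param seed RNG seed for the bootstrap/feature subsampling.
#' @return object of class `"forest_fit"`: `mda` (named per-metabolite raw
#'   MDA), `oob_error`, `n_trees`, `seed`, and the underlying
#'   [randomForest::randomForest] object as `model`.
#' @export
forest_fit <- function(x, n_trees = 500, seed = 1) {
  stopifnot(inherits(x, "processed_matrix"))
  if (n_trees < 50) stop("use at least 50 trees")
  grp <- factor(x$group, levels = c(x$control,
                                    setdiff(unique(x$group), x$control)))
  if (nlevels(grp) != 2) stop("need exactly two groups")
  set.seed(seed)
  rf <- randomForest::randomForest(x$values, grp, ntree = n_trees,
                                   importance = TRUE)
  mda <- randomForest::importance(rf, type = 1, scale = FALSE)[, 1L]
  oob <- mean(rf$predicted != grp)
  structure(list(mda = mda, oob_error = oob, n_trees = n_trees, seed = seed,
                 model = rf),
            class = "forest_fit")
}

#' @export
print.forest_fit <- function(x, ...) {
  cat("random forest:", x$n_trees, "trees, OOB error",
      sprintf("%.3f", x$oob_error), "\n")
  cat("  metabolites with MDA > 0:", sum(x$mda > 0), "of", length(x$mda), "\n")
  invisible(x)
}

#' Select discriminant metabolites by MDA
#'
#' Strict inequality: a metabolite is kept only when its raw mean decrease
#' accuracy exceeds the threshold; MDA exactly 0 (no predictive importance)
#' is excluded.
#'
#' @param fit a [forest_fit()] result (or any named MDA vector).
#' @param threshold default 0.
#' @return character vector of selected metabolite identifiers.
#' @export
select_by_mda <- function(fit, threshold = 0) {
  mda <- if (inherits(fit, "forest_fit")) fit$mda else fit
  names(mda)[mda > threshold]
}
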