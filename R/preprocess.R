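#' Drop metabolites with any missing reading
#'
#' The pipeline's stringent completeness filter: a metabolite is retained
#' only if it was measured in every sample of the panel. No imputation is
#' attempted.
#'
#' @param x an [abundance_table()].
#' @return a list with `table` (the filtered [abundance_table()]),
#'   `retention_fraction` (kept / total) and `retention_pct` (the same as a
#'   percentage rounded to 1 decimal place).
#' @export
filter_complete <- function(x) {
  stopifnot(inherits(x, "abundance_table"))
  total <- ncol(x$values)
  if (total == 0L) stop("empty abundance table")
  keep <- colSums(is.na(x$values)) == 0L
  if (!any(keep))
    stop("all ", total, " metabolites have at least one missing value; ",
         "nothing retained")
  out <- abundance_table(x$values[, keep, drop = FALSE], x$group, x$control)
  frac <- sum(keep) / total
  list(table = out, retention_fraction = frac,
       retention_pct = round(100 * frac, 1))
}

#' Normalize each metabolite to its control-group mean
#'
#' Divides every metabolite column by the mean abundance of that metabolite
#' in the control group, so control means become exactly 1 and treated
#' values are expressed relative to control. Run after [filter_complete()];
#' the table must be complete.
#'
#' @param x a complete [abundance_table()].
#' @return an [abundance_table()] on the control-relative scale.
#' @export
normalize_to_control <- function(x) {
  stopifnot(inherits(x, "abundance_table"))
  if (anyNA(x$values))
    stop("table has missing values; run filter_complete() first")
  idx <- group_indices(x)
  ctrl_mean <- colMeans(x$values[idx$control, , drop = FALSE])
  bad <- ctrl_mean == 0
  if (any(bad))
    stop("control-group mean is zero for: ",
         paste(colnames(x$values)[bad], collapse = ", "))
  abundance_table(sweep(x$values, 2L, ctrl_mean, "/"), x$group, x$control)
}

#' Log-transform abundances
#'
#' @param x a complete [abundance_table()] with strictly positive values.
#' @param base logarithm base; default 10 (the usual convention for
#'   metabolomics preprocessing).
#' @return an [abundance_table()] of log abundances. Values may be negative
#'   after this step; downstream functions no longer assume non-negativity.
#' @export
log_transform <- function(x, base = 10) {
  stopifnot(inherits(x, "abundance_table"))
  if (anyNA(x$values)) stop("table has missing values; filter first")
  if (any(x$values <= 0))
    stop("log transform requires strictly positive values")
  out <- x
  out$values <- log(x$values, base = base)
  out
}

#' Pareto-scale a matrix of (log) abundances
#'
#' Per metabolite: centre on the mean and divide by the square root of the
#' sample standard deviation (n-1 denominator) -- the usual compromise
#' between unit-variance and no scaling for LC-MS data. Constant columns are
#' centred but left unscaled, with a warning.
#'
#' @param x an [abundance_table()] (typically log-transformed).
#' @return a `"processed_matrix"`: list with `values` (complete samples x
#'   metabolites matrix, column means 0), `group`, `control` and a
#'   `provenance` record of the applied steps.
#' @export
pareto_scale <- function(x) {
  stopifnot(inherits(x, "abundance_table"))
  if (anyNA(x$values)) stop("table has missing values; filter first")
  v <- x$values
  mu <- colMeans(v)
  sdv <- apply(v, 2L, stats::sd)
  cen <- sweep(v, 2L, mu, "-")
  const <- sdv == 0
  if (any(const))
    warning(sum(const), " constant metabolite column(s) centred but not scaled")
  scl <- ifelse(const, 1, sqrt(sdv))
  processed_matrix(sweep(cen, 2L, scl, "/"), x$group, x$control,
                   steps = c("pareto"))
}

processed_matrix <- function(values, group, control, steps = character()) {
  structure(list(values = values, group = group, control = control,
                 provenance = list(steps = steps)),
            class = "processed_matrix")
}

#' @export
print.processed_matrix <- function(x, ...) {
  cat("processed_matrix:", nrow(x$values), "samples x", ncol(x$values),
      "metabolites; steps:", paste(x$provenance$steps, collapse = " -> "), "\n")
  invisible(x)
}

#' Per-metabolite fold change, treated over control
#'
#' Computed on the un-logged scale (usually after [normalize_to_control()]):
#' `FC_j = mean(treated_j) / mean(control_j)`. Values below 1 denote
#' down-regulation.
#'
#' @param x a complete [abundance_table()].
#' @return named numeric vector of fold changes, one per metabolite.
#' @export
fold_change <- function(x) {
  stopifnot(inherits(x, "abundance_table"))
  if (anyNA(x$values)) stop("table has missing values; filter first")
  idx <- group_indices(x)
  mc <- colMeans(x$values[idx$control, , drop = FALSE])
  if (any(mc == 0))
    stop("control mean is zero for: ",
         paste(colnames(x$values)[mc == 0], collapse = ", "))
  colMeans(x$values[idx$treated, , drop = FALSE]) / mc
}

#' Run the full preprocessing chain
#'
#' Optional cell-count division, completeness filter, control-mean
#' normalization, fold change on the normalized scale, log transform, and
#' Pareto scaling. Univariate tests are run on the log matrix and the
#' multivariate models on the Pareto-scaled matrix, mirroring common
#' metabolomics practice.
#'
#' @param x an [abundance_table()] of raw relative abundances.
#' @param cellcount_factors optional positive per-sample scaling nuisance to
#'   divide out before anything else (see [normalize_cellcount()]).
#' @param log_base base for the log step (default 10).
#' @return a list of class `"processed_panel"` with elements `filtered`
#'   (complete [abundance_table()]), `retention_fraction`, `retention_pct`,
#'   `normalized`, `fold_change`, `log` and `pareto` (both
#'   `"processed_matrix"` objects) and `provenance`.
#' @export
preprocess_panel <- function(x, cellcount_factors = NULL, log_base = 10) {
  if (!is.null(cellcount_factors))
    x <- normalize_cellcount(x, cellcount_factors)
  flt <- filter_complete(x)
  norm <- normalize_to_control(flt$table)
  fc <- fold_change(norm)
  lg <- log_transform(norm, base = log_base)
  logm <- processed_matrix(lg$values, lg$group, lg$control,
                           steps = c("filter", "control-normalize",
                                     sprintf("log%g", log_base)))
  par <- pareto_scale(lg)
  par$provenance$steps <- c(logm$provenance$steps, "pareto")
  structure(list(filtered = flt$table,
                 retention_fraction = flt$retention_fraction,
                 retention_pct = flt$retention_pct,
                 normalized = norm, fold_change = fc,
                 log = logm, pareto = par,
                 provenance = list(log_base = log_base,
                                   retention_fraction = flt$retention_fraction)),
            class = "processed_panel")
}
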