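#' Configuration for the synthetic two-group panel generator
#'
#' Describes a steady-state LC-MS/MS style panel: log-normal baseline
#' abundances spanning several orders of magnitude, a fraction of
#' metabolites carrying a true group effect (fold change with random
#' direction), abundance-dependent or completely-random missingness, and a
#' per-sample multiplicative cell-count nuisance.
#'
#' Defaults describe the study design the pipeline targets: 296 metabolites,
#' six replicates per group, within-group biological variation of 0.2 on the
#' natural-log scale, and a per-cell dropout rate of 0.04 under the
#' abundance-biased masking default, which at 12 samples leaves roughly
#' 78-83% of metabolites fully observed.
#'
#' @param n_metabolites number of metabolites in the panel.
#' @param n_per_group replicates per group (>= 2).
#' @param baseline_log_mean_range interval (natural-log scale) from which
#'   per-metabolite baseline means are drawn uniformly.
#' @param baseline_log_sd within-group biological SD on the natural-log scale.
#' @param frac_differential fraction of metabolites with a planted effect.
#' @param effect_fc_range interval of true fold changes (> 0); each planted
#'   metabolite draws a magnitude in this range and an up/down direction
#'   with probability 1/2 each.
#' @param missing_rate overall fraction of cells masked as missing.
#' @param missing_mode `"low-abundance-biased"` (default; mask probability a
#'   logistic function of log abundance, calibrated so the overall rate is
#'   `missing_rate`) or `"random"`.
#' @param cellcount_cv coefficient of variation of the per-sample
#'   multiplicative cell-count factor (0 disables it).
#' @param pathway_library optional [read_pathway_library()] object; when
#'   given, metabolites are named by the library's compound IDs (recycled as
#'   needed) and planted effects are concentrated inside its pathways.
#' @param seed integer seed; the generator is fully deterministic given the
#'   config.
#' @return a list of class `"sim_config"`.
#' @export
sim_config <- function(n_metabolites = 296, n_per_group = 6,
                       baseline_log_mean_range = c(log(1e3), log(1e7)),
                       baseline_log_sd = 0.2,
                       frac_differential = 0.1,
                       effect_fc_range = c(1.25, 4),
                       missing_rate = 0.04,
                       missing_mode = c("low-abundance-biased", "random"),
                       cellcount_cv = 0.1,
                       pathway_library = NULL,
                       seed = 1L) {
  missing_mode <- match.arg(missing_mode)
  if (n_metabolites < 1 || n_per_group < 2)
    stop("need n_metabolites >= 1 and n_per_group >= 2")
  if (frac_differential < 0 || frac_differential > 1)
    stop("frac_differential must lie in [0, 1]")
  if (missing_rate < 0 || missing_rate > 1)
    stop("missing_rate must lie in [0, 1]")
  if (any(effect_fc_range <= 0)) stop("effect_fc_range bounds must be > 0")
  if (baseline_log_sd <= 0) stop("baseline_log_sd must be positive")
  if (cellcount_cv < 0) stop("cellcount_cv must be non-negative")
  structure(list(n_metabolites = as.integer(n_metabolites),
                 n_per_group = as.integer(n_per_group),
                 baseline_log_mean_range = sort(baseline_log_mean_range),
                 baseline_log_sd = baseline_log_sd,
                 frac_differential = frac_differential,
                 effect_fc_range = sort(effect_fc_range),
                 missing_rate = missing_rate,
                 missing_mode = missing_mode,
                 cellcount_cv = cellcount_cv,
                 pathway_library = pathway_library,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate a synthetic two-group metabolomics panel with known truth
#'
#' Abundances are `exp(N(mu_j, sigma^2)) * effect * cellcount_factor`; for
#' treated samples of a planted metabolite the effect is its true fold
#' change. Missing entries are masked to `NA` according to the configured
#' mode. Identical configs (including seed) give bitwise-identical output.
#'
#' @param config a [sim_config()].
#' @return list with `table` (an [abundance_table()], groups `"control"` and
#'   `"treated"`) and `truth` (list: `differential_ids`, `fc_by_id`,
#'   `missing_mask`, `cellcount_factors`, `baseline_log_mean`).
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)

  m <- config$n_metabolites
  n <- 2L * config$n_per_group
  group <- rep(c("control", "treated"), each = config$n_per_group)

  ids <- sprintf("M%04d", seq_len(m))
  lib <- config$pathway_library
  if (!is.null(lib)) {
    comp <- unique(unlist(lapply(lib$pathways, function(p) p$compounds)))
    ids[seq_len(min(m, length(comp)))] <- comp[seq_len(min(m, length(comp)))]
  }

  mu <- stats::runif(m, config$baseline_log_mean_range[1],
                     config$baseline_log_mean_range[2])
  logx <- matrix(stats::rnorm(n * m, mean = rep(mu, each = n),
                              sd = config$baseline_log_sd), nrow = n)

  n_diff <- round(config$frac_differential * m)
  if (n_diff > 0) {
    if (!is.null(lib)) {
      pooled <- intersect(unlist(lapply(lib$pathways, function(p) p$compounds)), ids)
      cand <- if (length(pooled) >= n_diff) pooled else ids
      diff_idx <- sort(match(sample(cand, n_diff), ids))
    } else {
      diff_idx <- sort(sample.int(m, n_diff))
    }
    magnitude <- stats::runif(n_diff, config$effect_fc_range[1],
                              config$effect_fc_range[2])
    up <- sample(c(TRUE, FALSE), n_diff, replace = TRUE)
    fc <- ifelse(up, magnitude, 1 / magnitude)
    treated_rows <- which(group == "treated")
    logx[treated_rows, diff_idx] <-
      logx[treated_rows, diff_idx] + rep(log(fc), each = length(treated_rows))
  } else {
    diff_idx <- integer()
    fc <- numeric()
  }

  cc <- if (config$cellcount_cv > 0) {
    sdl <- sqrt(log(1 + config$cellcount_cv^2))
    stats::rlnorm(n, meanlog = -sdl^2 / 2, sdlog = sdl)
  } else rep(1, n)
  x <- exp(logx) * cc  # row-wise recycling: cc has length n = nrow

  mask <- matrix(FALSE, n, m)
  if (config$missing_rate > 0) {
    if (config$missing_mode == "random") {
      mask <- matrix(stats::runif(n * m) < config$missing_rate, n, m)
    } else {
      lx <- log(x)
      slope <- 1.5  # logistic steepness on the natural-log abundance scale
      target <- config$missing_rate
      f <- function(a) mean(stats::plogis(a - slope * lx)) - target
      a <- stats::uniroot(f, lower = slope * min(lx) - 50,
                          upper = slope * max(lx) + 50)$root
      mask <- matrix(stats::runif(n * m) < stats::plogis(a - slope * lx), n, m)
    }
  }
  xm <- x
  xm[mask] <- NA_real_

  dimnames(xm) <- list(sprintf("%s_%d", group,
                               stats::ave(seq_len(n), group, FUN = seq_along)),
                       ids)
  dimnames(mask) <- dimnames(xm)
  tab <- abundance_table(xm, group, control = "control")
  truth <- list(differential_ids = ids[diff_idx],
                fc_by_id = stats::setNames(fc, ids[diff_idx]),
                missing_mask = mask,
                cellcount_factors = stats::setNames(cc, rownames(xm)),
                baseline_log_mean = stats::setNames(mu, ids))
  list(table = tab, truth = truth)
}

#' Divide out per-sample cell-count factors
#'
#' Replicate-plate cell counts act as a per-sample multiplicative nuisance;
#' this divides each sample's readings by its factor. Missing entries stay
#' missing.
#'
#' @param x an [abundance_table()].
#' @param factors positive numeric vector, one per sample (matched by name
#'   when named).
#' @return the normalized [abundance_table()].
#' @export
normalize_cellcount <- function(x, factors) {
  stopifnot(inherits(x, "abundance_table"))
  if (!is.null(names(factors)))
    factors <- factors[rownames(x$values)]
  if (length(factors) != nrow(x$values) || anyNA(factors))
    stop("need one factor per sample")
  if (any(factors <= 0)) stop("cell-count factors must be positive")
  out <- x
  out$values <- x$values / factors
  out
}

#' Write simulation ground truth as JSON
#'
#' @param truth the `truth` element of [simulate_panel()] output.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(
    list(differential_ids = truth$differential_ids,
         fc_by_id = as.list(truth$fc_by_id),
         cellcount_factors = as.list(truth$cellcount_factors),
         missing_mask = truth$missing_mask),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
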