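#' SAM moderated test statistics
#'
#' The significance-analysis-of-microarrays statistic adapted to metabolite
#' panels: `d_i = (mean_treated - mean_control) / (s_i + s0)`, where `s_i`
#' is the pooled standard error of the group-mean difference,
#' `sqrt((1/n1 + 1/n2) * pooled variance)`, and `s0` is a fudge factor that
#' stabilises the denominator for low-variance features. With `s0 = 0` the
#' statistic is exactly the pooled-variance t statistic.
#'
#' @param x a `"processed_matrix"` (conventionally the log matrix).
#' @param s0 non-negative fudge factor, or `"auto"` to select the percentile
#'   of the `s_i` distribution (searched over 0%, 5%, ..., 100%) that
#'   minimises the coefficient of variation of the median absolute deviation
#'   of `d` across `s`-quantile windows.
#' @return named list: `d` (named per-metabolite statistic), `s` (standard
#'   errors), `numerator` (mean differences), `s0` (the value used).
#' @export
sam_statistics <- function(x, s0 = "auto") {
  stopifnot(inherits(x, "processed_matrix"))
  v <- x$values
  is_ctrl <- x$group == x$control
  n1 <- sum(is_ctrl); n2 <- sum(!is_ctrl)
  if (n1 < 2 || n2 < 2) stop("both groups need >= 2 samples")
  if (all(apply(v, 2L, stats::sd) == 0)) stop("all metabolites constant")
  m1 <- colMeans(v[is_ctrl, , drop = FALSE])
  m2 <- colMeans(v[!is_ctrl, , drop = FALSE])
  sp2 <- ((n1 - 1) * apply(v[is_ctrl, , drop = FALSE], 2L, stats::var) +
          (n2 - 1) * apply(v[!is_ctrl, , drop = FALSE], 2L, stats::var)) /
         (n1 + n2 - 2)
  s <- sqrt((1 / n1 + 1 / n2) * sp2)
  num <- m2 - m1
  if (identical(s0, "auto")) s0 <- .sam_s0_auto(num, s)
  if (!is.numeric(s0) || s0 < 0) stop("s0 must be non-negative or \"auto\"")
  list(d = num / (s + s0), s = s, numerator = num, s0 = s0)
}

# Tusher/Chu-style fudge-factor search: candidate s0 values are percentiles
# of s; pick the one minimising the CV of mad(d) across s-quantile windows.
.sam_s0_auto <- function(num, s) {
  cands <- unique(c(0, stats::quantile(s, seq(0, 1, by = 0.05), names = FALSE)))
  nwin <- min(100L, max(2L, floor(length(s) / 5)))
  win <- cut(rank(s, ties.method = "first"), breaks = nwin, labels = FALSE)
  cv <- vapply(cands, function(s0c) {
    dd <- num / (s + s0c)
    mads <- tapply(dd, win, stats::mad)
    mu <- mean(mads)
    if (mu == 0) Inf else stats::sd(mads) / mu
  }, numeric(1))
  cands[which.min(cv)]
}

# All (or a sample of) balanced group-label reassignments, as a B x n
# 0/1 matrix marking which samples play "control". For equal group sizes
# split/complement pairs are collapsed by pinning sample 1 to control
# (choose(11,5) = 462 distinguishable splits for 6 vs 6).
.sam_assignments <- function(group, control, n_permutations, seed) {
  n <- length(group)
  n1 <- sum(group == control)
  total <- if (n1 * 2L == n) choose(n - 1, n1 - 1) else choose(n, n1)
  if (total <= n_permutations) {
    sets <- if (n1 * 2L == n) {
      cbind(1L, t(utils::combn(2:n, n1 - 1L)))
    } else t(utils::combn(n, n1))
  } else {
    set.seed(seed)
    seen <- new.env(hash = TRUE)
    sets <- matrix(0L, n_permutations, n1)
    b <- 0L
    while (b < n_permutations) {
      cand <- sort(sample.int(n, n1))
      if (n1 * 2L == n && !(1L %in% cand)) cand <- sort(setdiff(seq_len(n), cand))
      key <- paste(cand, collapse = ",")
      if (is.null(seen[[key]])) {
        seen[[key]] <- TRUE
        b <- b + 1L
        sets[b, ] <- cand
      }
    }
  }
  A <- matrix(0, nrow(sets), n)
  A[cbind(rep(seq_len(nrow(sets)), ncol(sets)), as.vector(sets))] <- 1
  A
}

#' Permutation null for SAM
#'
#' Recomputes the SAM statistic under permuted group labels, keeping the
#' same `s0`. All distinct balanced label assignments are enumerated when
#' their number does not exceed `n_permutations` (462 for two groups of
#' six); otherwise that many distinct assignments are sampled without
#' replacement.
#'
#' @param x a `"processed_matrix"`.
#' @param s0 numeric fudge factor (use the observed fit's value).
#' @param n_permutations permutation budget (warning below 50).
#' @param seed RNG seed used only when sampling is needed.
#' @return list: `d_perm` (B x metabolites matrix of permuted statistics),
#'   `d_expected` (mean of the i-th order statistic across permutations),
#'   `n_permutations` (B actually used), `enumerated` (logical).
#' @export
sam_permute <- function(x, s0, n_permutations = 1000, seed = 1) {
  stopifnot(inherits(x, "processed_matrix"), is.numeric(s0))
  if (n_permutations < 50)
    warning("fewer than 50 permutations gives a coarse FDR estimate")
  v <- x$values
  n <- nrow(v)
  n1 <- sum(x$group == x$control)
  n2 <- n - n1
  A <- .sam_assignments(x$group, x$control, n_permutations, seed)
  S1 <- A %*% v
  Q1 <- A %*% v^2
  St <- matrix(colSums(v), nrow(A), ncol(v), byrow = TRUE)
  Qt <- matrix(colSums(v^2), nrow(A), ncol(v), byrow = TRUE)
  S2 <- St - S1; Q2 <- Qt - Q1
  var1 <- pmax(0, (Q1 - S1^2 / n1) / (n1 - 1))
  var2 <- pmax(0, (Q2 - S2^2 / n2) / (n2 - 1))
  sp <- sqrt((1 / n1 + 1 / n2) * ((n1 - 1) * var1 + (n2 - 1) * var2) / (n - 2))
  d_perm <- (S2 / n2 - S1 / n1) / (sp + s0)
  sorted <- t(apply(d_perm, 1L, sort))
  list(d_perm = d_perm, d_expected = colMeans(sorted),
       n_permutations = nrow(A), enumerated = nrow(A) <= n_permutations &&
         !anyNA(A))
}

# Delta-band cut rule on rank-aligned observed vs expected order statistics.
# Returns the two cutoffs; delta <= 0 is the degenerate zero-width band
# where every metabolite lies beyond it.
.sam_cutoffs <- function(d_sorted, d_expected, delta) {
  if (delta <= 0) return(c(cutlow = -Inf, cutup = -Inf))
  diffs <- d_sorted - d_expected
  up <- which(d_sorted > 0 & diffs > delta)
  cutup <- if (length(up)) d_sorted[up[1L]] else Inf
  lo <- which(d_sorted < 0 & diffs < -delta)
  cutlow <- if (length(lo)) d_sorted[lo[length(lo)]] else -Inf
  c(cutlow = cutlow, cutup = cutup)
}

# Vectorised form of .sam_cutoffs over a whole delta grid: for the upper
# side, cutup(delta) = min{ d_(i) : d_(i) > 0, d_(i) - dbar_(i) > delta },
# computed with a cumulative minimum over candidates ordered by decreasing
# band exceedance; symmetrically for the lower side.
.sam_cut_vec <- function(d_sorted, d_expected, deltas) {
  diffs <- d_sorted - d_expected
  pos <- which(d_sorted > 0)
  if (length(pos)) {
    o <- order(diffs[pos], decreasing = TRUE)
    cmin <- cummin(d_sorted[pos][o])
    k <- length(pos) - findInterval(deltas, sort(diffs[pos]))
    cutup <- ifelse(k > 0, cmin[pmax(k, 1L)], Inf)
  } else cutup <- rep(Inf, length(deltas))
  neg <- which(d_sorted < 0)
  if (length(neg)) {
    o <- order(-diffs[neg], decreasing = TRUE)
    cmax <- cummax(d_sorted[neg][o])
    k <- length(neg) - findInterval(deltas, sort(-diffs[neg]))
    cutlow <- ifelse(k > 0, cmax[pmax(k, 1L)], -Inf)
  } else cutlow <- rep(-Inf, length(deltas))
  zero <- deltas <= 0
  cutup[zero] <- -Inf
  cutlow[zero] <- -Inf
  list(cutup = cutup, cutlow = cutlow)
}

# FDR table over a delta grid. For each delta: the observed cut thresholds,
# the number called, and two mean false-call estimates across permutations
# -- exceedances of the observed thresholds (the classic estimator) and
# exceedances of thresholds recomputed within each permutation by the same
# cut rule (self-calibrating under exchangeability). The working FDR is the
# more conservative of the two, pi0-scaled; `fdr_mono` is its suffix
# maximum, which makes the delta search monotone.
.sam_delta_table <- function(d, d_expected, d_perm, pi0, delta_step = 0.01) {
  ord <- order(d)
  d_sorted <- d[ord]
  diffs <- abs(d_sorted - d_expected)
  deltas <- seq(0, max(diffs) + delta_step, by = delta_step)
  cuts <- .sam_cut_vec(d_sorted, d_expected, deltas)
  cutlow <- cuts$cutlow; cutup <- cuts$cutup
  m <- length(d)
  n_called <- (m - findInterval(cutup, d_sorted, left.open = TRUE)) +
    findInterval(cutlow, d_sorted)
  B <- nrow(d_perm)
  counts_obs <- counts_self <- matrix(0, B, length(deltas))
  for (b in seq_len(B)) {
    row <- sort(d_perm[b, ])
    counts_obs[b, ] <- (m - findInterval(cutup, row, left.open = TRUE)) +
      findInterval(cutlow, row)
    pc <- .sam_cut_vec(row, d_expected, deltas)
    counts_self[b, ] <- (m - findInterval(pc$cutup, row, left.open = TRUE)) +
      findInterval(pc$cutlow, row)
  }
  false_obs <- colMeans(counts_obs)
  false_self <- colMeans(counts_self)
  fdr <- ifelse(n_called == 0, 0,
                pmin(1, pi0 * pmax(false_obs, false_self) / pmax(n_called, 1)))
  data.frame(delta = deltas, cutlow = cutlow, cutup = cutup,
             n_called = n_called, false_obs = false_obs,
             false_self = false_self, fdr = fdr,
             fdr_mono = rev(cummax(rev(fdr))))
}

#' Fit SAM on a two-group panel
#'
#' Computes the moderated d statistic, its permutation null, the
#' pi0-corrected FDR estimate as a function of the delta band width, per-
#' metabolite q-values (the smallest estimated FDR at which the metabolite
#' is called), and the call set at a chosen delta. When `delta` is `NULL`
#' the smallest delta (grid step `delta_step`) whose estimated FDR does not
#' exceed `target_fdr` is used.
#'
#' The FDR at each delta is pi0 times the mean across permutations of the
#' number of permuted statistics beyond the thresholds, divided by the
#' number called; the count uses the more conservative of two schemes --
#' exceedances of the observed thresholds, and exceedances of thresholds
#' recomputed within each permutation by the same cut rule (which is
#' self-calibrating under label exchangeability). The delta search walks
#' the suffix maximum of that curve, so the target-to-delta mapping is
#' monotone and cannot latch onto granular zero-count dips at the extreme
#' tail. pi0, the fraction of truly unchanged metabolites, is estimated by
#' the quartile rule `min(1, 2 * #\{d in [q25, q75] of permuted d\} / m)`.
#'
#' @inheritParams sam_permute
#' @param delta half-width of the exclusion band on the observed-vs-expected
#'   quantile plot; `NULL` to choose automatically for `target_fdr`.
#' @param target_fdr FDR target used when `delta` is `NULL`.
#' @param delta_step grid step for the delta search.
#' @return object of class `"sam_fit"`: `d`, `d_expected` (rank-aligned),
#'   `order` (rank -> metabolite index), `s0`, `pi0`, `delta`,
#'   `fdr_at_delta`, `called` (named logical), `q_value` (named),
#'   `delta_table`, `n_permutations`, `cutoffs`.
#' @export
sam_fit <- function(x, s0 = "auto", n_permutations = 1000, delta = NULL,
                    target_fdr = 0.05, delta_step = 0.01, seed = 1) {
  stats_ <- sam_statistics(x, s0 = s0)
  d <- stats_$d
  perm <- sam_permute(x, s0 = stats_$s0, n_permutations = n_permutations,
                      seed = seed)
  qs <- stats::quantile(perm$d_perm, c(0.25, 0.75), names = FALSE)
  pi0 <- min(1, 2 * sum(d >= qs[1] & d <= qs[2]) / length(d))
  tab <- .sam_delta_table(d, perm$d_expected, perm$d_perm, pi0,
                          delta_step = delta_step)
  if (is.null(delta)) {
    ok <- which(tab$fdr_mono <= target_fdr)
    if (!length(ok))
      stop("no delta on the grid attains FDR <= ", target_fdr,
           "; best achievable is ", signif(min(tab$fdr_mono), 3))
    delta <- tab$delta[ok[1L]]
  }
  g <- max(which(tab$delta <= delta + 1e-12))
  called <- d >= tab$cutup[g] | d <= tab$cutlow[g]
  # q-values: call sets are nested in delta, so metabolite i is called on a
  # prefix of the grid; q_i is the (monotone) FDR at the end of that prefix,
  # the smallest estimated FDR at which i is still called.
  q <- rep(1, length(d))
  for (i in seq_along(d)) {
    idx <- which(d[i] >= tab$cutup | d[i] <= tab$cutlow)
    if (length(idx)) q[i] <- tab$fdr_mono[max(idx)]
  }
  names(q) <- names(d)
  structure(list(d = d, d_expected = perm$d_expected, order = order(d),
                 s0 = stats_$s0, pi0 = pi0, delta = delta,
                 fdr_at_delta = tab$fdr_mono[g], called = called, q_value = q,
                 delta_table = tab, n_permutations = perm$n_permutations,
                 enumerated = perm$enumerated,
                 cutoffs = c(cutlow = tab$cutlow[g], cutup = tab$cutup[g])),
            class = "sam_fit")
}

#' @export
print.sam_fit <- function(x, ...) {
  cat("SAM fit:", length(x$d), "metabolites,", x$n_permutations,
      if (isTRUE(x$enumerated)) "enumerated" else "sampled", "permutations\n")
  cat(sprintf("  s0 = %.4g, pi0 = %.3f, delta = %.2f, est. FDR = %.4g\n",
              x$s0, x$pi0, x$delta, x$fdr_at_delta))
  cat("  called:", sum(x$called), "metabolites\n")
  invisible(x)
}

#' Smallest delta attaining a target FDR
#'
#' Walks the fitted delta grid (step as fitted, default 0.01) and returns
#' the smallest delta whose estimated FDR is at or below `target_fdr`,
#' together with the FDR achieved there.
#'
#' @param fit a [sam_fit()] object.
#' @param target_fdr the FDR bound.
#' @return list: `delta`, `fdr`, `n_called`.
#' @export
delta_for_fdr <- function(fit, target_fdr) {
  stopifnot(inherits(fit, "sam_fit"))
  tab <- fit$delta_table
  ok <- which(tab$fdr_mono <= target_fdr)
  if (!length(ok))
    stop("target FDR ", target_fdr, " unattainable; best achievable is ",
         signif(min(tab$fdr_mono), 3))
  g <- ok[1L]
  list(delta = tab$delta[g], fdr = tab$fdr_mono[g], n_called = tab$n_called[g])
}

#' Observed vs expected SAM order statistics
#'
#' Data behind the classic SAM quantile plot: per metabolite rank, the
#' observed and permutation-expected d with the delta band of the fit.
#'
#' @param fit a [sam_fit()] object.
#' @return data.frame: `metabolite`, `d_observed`, `d_expected`, `called`.
#' @export
sam_plot_data <- function(fit) {
  stopifnot(inherits(fit, "sam_fit"))
  ord <- fit$order
  data.frame(metabolite = names(fit$d)[ord],
             d_observed = unname(fit$d[ord]),
             d_expected = fit$d_expected,
             called = unname(fit$called[ord]),
             stringsAsFactors = FALSE)
}
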