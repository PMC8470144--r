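#' FDR-adjusted two-sample t-tests for every metabolite
#'
#' Pooled-variance (Student) two-sided t-test per metabolite, treated minus
#' control, with Benjamini-Hochberg adjustment across all retained
#' metabolites. Welch's unequal-variance form is available via `var_equal =
#' FALSE`. Constant metabolites (zero pooled variance) get t = 0, p = 1 with
#' a warning.
#'
#' @param x a `"processed_matrix"` (conventionally the log matrix from
#'   [preprocess_panel()]).
#' @param var_equal pool the group variances (default TRUE).
#' @param fold_change optional named fold-change vector (un-logged scale) to
#'   carry into the result for volcano output.
#' @return data.frame of class `"univariate_result"`: `metabolite`,
#'   `t_statistic`, `df`, `p_value`, `fdr_q`, and `log2_fc` when fold
#'   changes were supplied.
#' @export
t_test_all <- function(x, var_equal = TRUE, fold_change = NULL) {
  stopifnot(inherits(x, "processed_matrix"))
  idx <- list(control = which(x$group == x$control),
              treated = which(x$group != x$control))
  n1 <- length(idx$control); n2 <- length(idx$treated)
  if (n1 < 2 || n2 < 2) stop("both groups need >= 2 samples")
  v <- x$values
  m1 <- colMeans(v[idx$control, , drop = FALSE])
  m2 <- colMeans(v[idx$treated, , drop = FALSE])
  s1 <- apply(v[idx$control, , drop = FALSE], 2L, stats::var)
  s2 <- apply(v[idx$treated, , drop = FALSE], 2L, stats::var)
  if (var_equal) {
    sp2 <- ((n1 - 1) * s1 + (n2 - 1) * s2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, ncol(v))
  } else {
    se <- sqrt(s1 / n1 + s2 / n2)
    df <- (s1 / n1 + s2 / n2)^2 /
      ((s1 / n1)^2 / (n1 - 1) + (s2 / n2)^2 / (n2 - 1))
  }
  tstat <- (m2 - m1) / se
  const <- se == 0
  if (any(const)) {
    warning(sum(const), " constant metabolite(s): t set to 0, p to 1")
    tstat[const] <- 0
    df[const] <- n1 + n2 - 2
  }
  p <- 2 * stats::pt(abs(tstat), df = df, lower.tail = FALSE)
  p[const] <- 1
  out <- data.frame(metabolite = colnames(v), t_statistic = tstat, df = df,
                    p_value = p, fdr_q = stats::p.adjust(p, method = "BH"),
                    row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(fold_change))
    out$log2_fc <- log2(fold_change[out$metabolite])
  class(out) <- c("univariate_result", "data.frame")
  out
}

#' Volcano-style significance classification
#'
#' Two modes: `require_fc = FALSE` (the default adopted by the pipeline)
#' calls a metabolite significant when its BH q-value is below
#' `q_threshold`; `require_fc = TRUE` additionally requires the fold change
#' to exceed `fc_threshold`-fold in either direction (FC > threshold or
#' FC < 1/threshold).
#'
#' @param result a [t_test_all()] result.
#' @param fold_change named fold-change vector (un-logged scale).
#' @param fc_threshold fold-change gate (default 2).
#' @param q_threshold FDR gate (default 0.05).
#' @param require_fc apply the fold-change gate as well?
#' @return the result data.frame with added `log2_fc`, `neg_log10_q`,
#'   `significant` and `class` (`"up"`, `"down"`, `"ns"`) columns.
#' @export
volcano_classify <- function(result, fold_change, fc_threshold = 2,
                             q_threshold = 0.05, require_fc = FALSE) {
  fc <- fold_change[result$metabolite]
  sig_q <- result$fdr_q < q_threshold
  fc_pass <- fc > fc_threshold | fc < 1 / fc_threshold
  sig <- if (require_fc) sig_q & fc_pass else sig_q
  out <- result
  out$log2_fc <- log2(fc)
  out$neg_log10_q <- -log10(result$fdr_q)
  out$significant <- sig
  out$class <- ifelse(!sig, "ns", ifelse(fc >= 1, "up", "down"))
  out
}
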