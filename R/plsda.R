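#' Fit a two-class PLS-DA model by NIPALS
#'
#' PLS1 regression of a centred class code (control = -1, treated = +1)
#' on the processed metabolite matrix, with standard deflation of X per
#' component. The fit is deterministic. When the requested number of
#' components exceeds what the data can support the model is fitted with
#' the achievable number and a warning is emitted.
#'
#' @param x a `"processed_matrix"` (conventionally the Pareto-scaled one).
#' @param n_components latent components to extract (default 5).
#' @return object of class `"plsda_fit"`: `scores` (samples x components),
#'   `weights`, `loadings` (metabolites x components), `y_loadings`,
#'   `explained_y_variance` (per-component share of the class-code sum of
#'   squares), `vip` (cumulative over all fitted components),
#'   `vip_by_component` (matrix of cumulative VIP after 1..A components),
#'   `coefficients` (for prediction), plus centring info.
#' @export
plsda_fit <- function(x, n_components = 5) {
  stopifnot(inherits(x, "processed_matrix"))
  X <- x$values
  y <- ifelse(x$group == x$control, -1, 1)
  fit <- .pls1_nipals(X, y, n_components)
  structure(c(fit, list(group = x$group, control = x$control)),
            class = "plsda_fit")
}

# Core PLS1 NIPALS on raw X (centred internally) and numeric y.
.pls1_nipals <- function(X, y, n_components, warn = TRUE) {
  n <- nrow(X); p <- ncol(X)
  max_a <- min(n - 1L, p)
  if (n_components > max_a) {
    if (warn) warning("requested ", n_components, " components; rank allows ",
                      max_a, " -- fitting ", max_a)
    n_components <- max_a
  }
  xbar <- colMeans(X)
  ybar <- mean(y)
  E <- sweep(X, 2L, xbar)
  f <- y - ybar
  ss_y <- sum(f^2)
  W <- P <- matrix(0, p, n_components)
  Tm <- matrix(0, n, n_components)
  q <- numeric(n_components)
  ssy <- numeric(n_components)
  for (a in seq_len(n_components)) {
    w <- drop(crossprod(E, f))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-300) { n_components <- a - 1L; break }
    w <- w / nw
    tt <- drop(E %*% w)
    tt2 <- sum(tt^2)
    if (tt2 < 1e-300) { n_components <- a - 1L; break }
    pp <- drop(crossprod(E, tt)) / tt2
    qq <- sum(f * tt) / tt2
    E <- E - tcrossprod(tt, pp)
    f <- f - qq * tt
    W[, a] <- w; P[, a] <- pp; Tm[, a] <- tt
    q[a] <- qq
    ssy[a] <- qq^2 * tt2
  }
  keep <- seq_len(n_components)
  W <- W[, keep, drop = FALSE]; P <- P[, keep, drop = FALSE]
  Tm <- Tm[, keep, drop = FALSE]; q <- q[keep]; ssy <- ssy[keep]
  rownames(W) <- rownames(P) <- colnames(X)
  rownames(Tm) <- rownames(X)
  # regression coefficients: B = W (P'W)^-1 q
  B <- if (n_components > 0)
    drop(W %*% solve(crossprod(P, W), q)) else rep(0, p)
  vip_cum <- .vip_matrix(W, ssy)
  list(scores = Tm, weights = W, loadings = P, y_loadings = q,
       explained_y_variance = if (ss_y > 0) ssy / ss_y else ssy * 0,
       ssy = ssy, vip = vip_cum[, ncol(vip_cum)],
       vip_by_component = vip_cum,
       coefficients = stats::setNames(B, colnames(X)),
       x_center = xbar, y_center = ybar, n_components = n_components)
}

# Cumulative VIP after 1..A components:
# VIP_j(A) = sqrt( p * sum_a SSY_a (w_aj / ||w_a||)^2 / sum_a SSY_a )
.vip_matrix <- function(W, ssy) {
  p <- nrow(W); A <- ncol(W)
  if (A == 0) return(matrix(numeric(0), p, 0))
  wn2 <- sweep(W^2, 2L, colSums(W^2), "/")
  num <- sweep(wn2, 2L, ssy, "*")
  cs <- apply(num, 1L, cumsum)  # A x p (or p-vector when A == 1)
  if (A == 1L) cs <- matrix(cs, nrow = 1L)
  out <- sqrt(p * sweep(t(cs), 2L, cumsum(ssy), "/"))
  # degenerate components with zero SSY: fall back to uniform VIP of 1
  zero <- cumsum(ssy) == 0
  out[, zero] <- 1
  dimnames(out) <- list(rownames(W), paste0("comp", seq_len(A)))
  out
}

#' @export
print.plsda_fit <- function(x, ...) {
  cat("PLS-DA fit:", nrow(x$scores), "samples,", nrow(x$weights),
      "metabolites,", x$n_components, "components\n")
  cat("  explained Y variance:",
      paste(sprintf("%.3f", x$explained_y_variance), collapse = " "), "\n")
  invisible(x)
}

#' Predict class codes / labels from a PLS-DA fit
#'
#' @param object a [plsda_fit()] model.
#' @param newdata samples x metabolites matrix on the same processed scale.
#' @param type `"response"` for the continuous class code, `"class"` for
#'   labels split at the class-code midpoint.
#' @param ... unused.
#' @return numeric vector or character labels.
#' @export
predict.plsda_fit <- function(object, newdata, type = c("response", "class"),
                              ...) {
  type <- match.arg(type)
  yhat <- drop(sweep(newdata, 2L, object$x_center) %*% object$coefficients) +
    object$y_center
  if (type == "response") return(yhat)
  treated <- setdiff(unique(object$group), object$control)
  ifelse(yhat >= 0, treated, object$control)
}

#' Variable importance in projection
#'
#' @param model a [plsda_fit()].
#' @param n_components use the cumulative VIP after this many components
#'   (default: all fitted). The mean squared VIP over metabolites is 1 by
#'   construction.
#' @return named per-metabolite VIP vector.
#' @export
vip_scores <- function(model, n_components = NULL) {
  stopifnot(inherits(model, "plsda_fit"))
  if (is.null(n_components)) n_components <- model$n_components
  if (n_components < 1 || n_components > model$n_components)
    stop("n_components out of range")
  model$vip_by_component[, n_components]
}

# Between/within separation of component-1 scores; the default permutation
# statistic.
.score_separation <- function(scores1, group, control) {
  a <- scores1[group == control]; b <- scores1[group != control]
  sw <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
    (length(a) + length(b) - 2)
  if (sw == 0) return(Inf)
  (mean(b) - mean(a))^2 / sw
}

#' Permutation test of PLS-DA class separation
#'
#' Refits the model under permuted class labels and compares the chosen
#' statistic (between/within separation of component-1 scores, or LOOCV
#' accuracy) with the observed value. `p = (1 + #permuted >= observed) /
#' (1 + n_permutations)`, so the smallest reportable p is
#' `1/(n_permutations + 1)` and p is never 0. Draws that reproduce the
#' observed labelling (or its group swap) are rejected and redrawn: they
#' carry no information about the null and the `+1` rule already accounts
#' for the observed configuration.
#'
#' @param x a `"processed_matrix"`.
#' @param n_permutations number of label permutations (default 2000).
#' @param statistic `"separation"` (default) or `"accuracy"`.
#' @param n_components components for the accuracy statistic (separation
#'   uses one).
#' @param seed RNG seed.
#' @return list: `p_value`, `observed`, `permuted` (vector).
#' @export
plsda_permutation_test <- function(x, n_permutations = 2000,
                                   statistic = c("separation", "accuracy"),
                                   n_components = 5, seed = 1) {
  stopifnot(inherits(x, "processed_matrix"))
  statistic <- match.arg(statistic)
  if (n_permutations < 100) stop("use at least 100 permutations")
  y <- ifelse(x$group == x$control, -1, 1)
  stat_fun <- if (statistic == "separation") {
    function(grp) {
      fit <- .pls1_nipals(x$values, ifelse(grp == x$control, -1, 1), 1L,
                          warn = FALSE)
      .score_separation(fit$scores[, 1L], grp, x$control)
    }
  } else {
    function(grp) {
      xx <- x; xx$group <- grp
      plsda_loocv(xx, n_components = n_components)$accuracy
    }
  }
  obs <- stat_fun(x$group)
  set.seed(seed)
  # the identity relabelling (and its group swap) carries no information
  # about the null and is already accounted for by the +1 rule; redraw it
  draw <- function() {
    repeat {
      g <- sample(x$group)
      if (!all(g == x$group) &&
          !all((g == x$control) == (x$group != x$control))) return(g)
    }
  }
  perm <- vapply(seq_len(n_permutations),
                 function(i) stat_fun(draw()), numeric(1))
  list(p_value = (1 + sum(perm >= obs)) / (1 + n_permutations),
       observed = obs, permuted = perm)
}

#' Leave-one-out cross-validation of PLS-DA
#'
#' Each sample is held out once and the model refitted on the rest; returns
#' both the predictive Q2 (1 - PRESS/TSS on the centred class code) and the
#' classification accuracy (fraction of held-out samples predicted on the
#' correct side of the class-code midpoint). Folds that would empty a group
#' are skipped with a warning.
#'
#' @param x a `"processed_matrix"`.
#' @param n_components latent components (default 5).
#' @return list: `q2`, `accuracy`, `predictions` (held-out class codes).
#' @export
plsda_loocv <- function(x, n_components = 5) {
  stopifnot(inherits(x, "processed_matrix"))
  grp <- x$group
  if (min(table(grp)) < 3) stop("need >= 3 samples per group for LOOCV")
  y <- ifelse(grp == x$control, -1, 1)
  n <- nrow(x$values)
  yhat <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (min(table(grp[-i])) < 1) { warning("fold ", i, " empties a group; skipped"); next }
    fit <- .pls1_nipals(x$values[-i, , drop = FALSE], y[-i],
                        min(n_components, n - 2L), warn = FALSE)
    yhat[i] <- drop(crossprod(x$values[i, ] - fit$x_center,
                              fit$coefficients)) + fit$y_center
  }
  ok <- !is.na(yhat)
  press <- sum((y[ok] - yhat[ok])^2)
  tss <- sum((y[ok] - mean(y[ok]))^2)
  list(q2 = 1 - press / tss,
       accuracy = mean(sign(yhat[ok]) == sign(y[ok])),
       predictions = yhat)
}

#' Unsupervised PCA scores for the processed matrix
#'
#' Convenience wrapper around [stats::prcomp()] (no extra scaling; the
#' matrix is centred) for score-plot output alongside the supervised model.
#'
#' @param x a `"processed_matrix"`.
#' @param n_components columns of scores to return.
#' @return list: `scores`, `explained_variance` (proportions).
#' @export
pca_scores <- function(x, n_components = 2) {
  stopifnot(inherits(x, "processed_matrix"))
  pc <- stats::prcomp(x$values, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       explained_variance = pc$sdev^2 / sum(pc$sdev^2))
}
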