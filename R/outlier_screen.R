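#' Fit a PCA model on mean-centered spectra
#'
#' Principal component analysis by SVD of the column-centered data matrix.
#' Centering only, no scaling: reflectance channels share a scale and
#' autoscaling would inflate low-variance channels. Loadings signs are fixed
#' so that each loading's largest-magnitude element is positive, making runs
#' reproducible.
#'
#' @param X numeric `n x p` matrix (or a [spectra_dataset()]).
#' @param k number of components to retain, `1 <= k <= min(n-1, p)`.
#' @param scale logical; autoscale columns to unit variance before the
#'   decomposition (off by default).
#' @return An object of class `pca_model`: `center`, `scale`, `loadings`
#'   (`p x k`, orthonormal), `scores` (`n x k`), `eigenvalues` (score
#'   variances, all `min(n-1, p)` of them), `k`, `explained` (variance
#'   fractions of the retained components), `n`.
#' @export
fit_pca <- function(X, k, scale = FALSE) {
  if (inherits(X, "spectra_dataset")) X <- X$X
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n < 2L) stop("PCA needs at least 2 rows")
  rmax <- min(n - 1L, p)
  if (!is.numeric(k) || length(k) != 1L || k < 1L || k > rmax)
    stop("k must be between 1 and min(n-1, p) = ", rmax)
  k <- as.integer(k)
  center <- colMeans(X)
  Xc <- sweep(X, 2L, center)
  scl <- rep(1, p)
  if (scale) {
    scl <- apply(X, 2L, stats::sd)
    if (any(scl == 0)) stop("cannot autoscale: zero-variance column(s)")
    Xc <- sweep(Xc, 2L, scl, "/")
  }
  sv <- svd(Xc, nu = rmax, nv = rmax)
  eig <- sv$d[seq_len(rmax)]^2 / (n - 1L)
  load <- sv$v
  # sign convention: largest |element| of each loading positive
  flip <- apply(load, 2L, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  load <- sweep(load, 2L, flip, "*")
  scores <- Xc %*% load
  # training Q = energy in the discarded components (rank <= min(n-1, p))
  train_q <- if (k < rmax)
    rowSums(scores[, (k + 1L):rmax, drop = FALSE]^2) else rep(0, n)
  structure(
    list(center = center, scale = scl, scaled = scale,
         loadings = load[, seq_len(k), drop = FALSE],
         scores = scores[, seq_len(k), drop = FALSE],
         train_q = train_q,
         eigenvalues = eig, k = k,
         explained = eig[seq_len(k)] / sum(eig), n = n),
    class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat("<pca_model> ", x$k, " component(s), fitted on n = ", x$n, "\n", sep = "")
  cat("  % variance:", paste(sprintf("%.2f", 100 * x$explained),
                             collapse = ", "), "\n")
  invisible(x)
}

project_pca <- function(model, X) {
  if (inherits(X, "spectra_dataset")) X <- X$X
  X <- as.matrix(X)
  if (ncol(X) != length(model$center))
    stop("X has ", ncol(X), " columns; model expects ", length(model$center))
  Xc <- sweep(X, 2L, model$center)
  if (model$scaled) Xc <- sweep(Xc, 2L, model$scale, "/")
  Xc
}

#' Hotelling T-squared statistic
#'
#' Within-model distance: `T2_i = sum_a t_ia^2 / lambda_a` over the retained
#' components, where `t` are the centered scores and `lambda` the score
#' variances. Large values mean unusual variation inside the model plane.
#'
#' @param model a fitted [fit_pca()] model.
#' @param X matrix or [spectra_dataset()] to evaluate (default: training
#'   data via stored scores).
#' @return Numeric n-vector of T-squared values.
#' @export
t2_statistic <- function(model, X = NULL) {
  stopifnot(inherits(model, "pca_model"))
  lambda <- model$eigenvalues[seq_len(model$k)]
  if (any(lambda <= 0))
    stop("zero eigenvalue among the retained components")
  scores <- if (is.null(X)) model$scores
            else project_pca(model, X) %*% model$loadings
  as.numeric(rowSums(sweep(scores^2, 2L, lambda, "/")))
}

#' Q residual statistic
#'
#' Off-model distance: squared norm of the part of each centered spectrum
#' not explained by the retained loadings. Zero for spectra lying exactly in
#' the model subspace.
#'
#' @inheritParams t2_statistic
#' @return Numeric n-vector of Q values.
#' @export
q_statistic <- function(model, X = NULL) {
  stopifnot(inherits(model, "pca_model"))
  if (is.null(X)) return(model$train_q)
  Xc <- project_pca(model, X)
  scores <- Xc %*% model$loadings
  resid <- Xc - scores %*% t(model$loadings)
  as.numeric(rowSums(resid^2))
}

#' Control limits for T-squared and Q
#'
#' The T-squared limit uses the F-distribution form
#' `k (n - 1) / (n - k) * F(1 - alpha; k, n - k)`; the Q limit uses the
#' Jackson-Mudholkar approximation on the residual (discarded) eigenvalues.
#' When the model captures the full rank the Q limit is 0.
#'
#' @param model a fitted [fit_pca()] model.
#' @param alpha significance level in (0, 1); limits are at confidence
#'   `1 - alpha`.
#' @return List with `t2_limit` and `q_limit`.
#' @export
control_limits <- function(model, alpha = 0.05) {
  stopifnot(inherits(model, "pca_model"))
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  n <- model$n; k <- model$k
  if (n <= k) stop("need n > k for the T2 limit")
  t2_limit <- k * (n - 1) / (n - k) * stats::qf(1 - alpha, k, n - k)
  resid_eig <- model$eigenvalues[-seq_len(k)]
  resid_eig <- resid_eig[resid_eig > 0]
  if (!length(resid_eig)) {
    q_limit <- 0
  } else {
    th1 <- sum(resid_eig)
    th2 <- sum(resid_eig^2)
    th3 <- sum(resid_eig^3)
    h0 <- 1 - 2 * th1 * th3 / (3 * th2^2)
    if (h0 < 1e-3) h0 <- 1e-3
    ca <- stats::qnorm(1 - alpha)
    q_limit <- th1 * (ca * sqrt(2 * th2 * h0^2) / th1 +
                      1 + th2 * h0 * (h0 - 1) / th1^2)^(1 / h0)
  }
  list(t2_limit = t2_limit, q_limit = max(q_limit, 0))
}

#' Screen replicates with T-squared and Q
#'
#' Fits nothing: evaluates a fitted PCA model on data, computes both
#' statistics and their `1 - alpha` limits, and flags exceedances.
#'
#' @param model a fitted [fit_pca()] model.
#' @param X matrix or [spectra_dataset()] to screen.
#' @param alpha significance level for the limits.
#' @return An object of class `screen_result`: `t2`, `q` (n-vectors),
#'   `t2_limit`, `q_limit`, `alpha`, and logical vectors `exceeds_t2`,
#'   `exceeds_q`.
#' @export
screen_outliers <- function(model, X, alpha = 0.05) {
  t2 <- t2_statistic(model, X)
  q <- q_statistic(model, X)
  lim <- control_limits(model, alpha)
  structure(
    list(t2 = t2, q = q,
         t2_limit = lim$t2_limit, q_limit = lim$q_limit, alpha = alpha,
         exceeds_t2 = t2 > lim$t2_limit, exceeds_q = q > lim$q_limit),
    class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat("<screen_result> n =", length(x$t2),
      sprintf("| T2 limit %.3f (%d above) | Q limit %.3g (%d above)\n",
              x$t2_limit, sum(x$exceeds_t2), x$q_limit, sum(x$exceeds_q)))
  invisible(x)
}

#' Flag outlying replicates
#'
#' Default rule `"both"` flags a replicate only when it exceeds both the
#' T-squared and the Q limit — the conservative removal criterion for
#' replicate screening; `"either"` flags on either exceedance.
#'
#' @param result a [screen_outliers()] result.
#' @param rule `"both"` or `"either"`.
#' @return Logical n-vector.
#' @export
flag_outliers <- function(result, rule = c("both", "either")) {
  stopifnot(inherits(result, "screen_result"))
  rule <- match.arg(rule)
  if (rule == "both") result$exceeds_t2 & result$exceeds_q
  else result$exceeds_t2 | result$exceeds_q
}

#' Per-wavelength T-squared and Q contributions
#'
#' Decomposes both statistics of one spectrum over wavelength channels. Q
#' contributions are the squared residual per channel and sum exactly to Q.
#' T-squared contributions use the loadings-weighted score decomposition
#' `contrib_j = sum_a (t_a / lambda_a) * P_ja * xc_j`, which sums exactly to
#' T-squared.
#'
#' @param model a fitted [fit_pca()] model.
#' @param x a single spectrum (numeric p-vector).
#' @return List with `t2` and `q` contribution p-vectors.
#' @export
pca_contributions <- function(model, x) {
  stopifnot(inherits(model, "pca_model"))
  x <- as.numeric(x)
  xc <- as.numeric(project_pca(model, matrix(x, nrow = 1L)))
  t <- as.numeric(xc %*% model$loadings)
  lambda <- model$eigenvalues[seq_len(model$k)]
  w <- as.numeric(model$loadings %*% (t / lambda))
  t2_contrib <- w * xc
  resid <- xc - as.numeric(model$loadings %*% t)
  list(t2 = t2_contrib, q = resid^2)
}
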