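#' Bilinear decomposition of a symmetric PSD matrix
#'
#' Uncentered eigendecomposition of a covariance-type matrix (the matrix is
#' a second-moment object, so it is not centered before decomposition).
#' Reports per-component variance fractions under two conventions:
#'
#' * linear, `lambda_i / sum(lambda)` — the fraction of the matrix trace;
#' * squared, `lambda_i^2 / sum(lambda^2)` — the fraction of the squared
#'   Frobenius norm, the convention used for the error-covariance column of
#'   the variance-comparison table.
#'
#' When `Sigma = E'E / dof`, the squared-convention fractions of `Sigma`
#' equal the squared-and-renormalized linear fractions of `E` — the identity
#' that links the two columns of the comparison table.
#'
#' @param M symmetric positive semi-definite matrix (or an
#'   [error_covariance()]).
#' @param k number of components to report (default: full rank).
#' @return An object of class `decomposition_result`: `values` (all
#'   eigenvalues, non-increasing, clipped at 0), `loadings` (`p x k`,
#'   sign-fixed), `frac_linear`, `frac_squared`, `cum_linear`,
#'   `cum_squared` (length k), `k`, `p`.
#' @export
decompose_matrix <- function(M, k = NULL) {
  if (inherits(M, "error_covariance")) M <- M$sigma
  M <- as.matrix(M)
  p <- ncol(M)
  if (nrow(M) != p) stop("M must be square")
  asym <- max(abs(M - t(M)))
  if (asym > 1e-8 * max(abs(M), 1))
    stop("M is not symmetric (max asymmetry ", signif(asym, 3), ")")
  if (!is.null(k) && (k < 1L || k > p)) stop("k must be in 1..", p)
  eg <- eigen((M + t(M)) / 2, symmetric = TRUE)
  values <- pmax(eg$values, 0)
  values[values < 1e-12 * max(values)] <- 0  # numerically null components
  if (is.null(k)) k <- p
  k <- as.integer(k)
  load <- eg$vectors[, seq_len(k), drop = FALSE]
  flip <- apply(load, 2L, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  load <- sweep(load, 2L, flip, "*")
  new_decomposition(values, load, k, p)
}

new_decomposition <- function(values, loadings, k, p) {
  tot_lin <- sum(values)
  tot_sq <- sum(values^2)
  fl <- if (tot_lin > 0) values[seq_len(k)] / tot_lin else rep(0, k)
  fs <- if (tot_sq > 0) values[seq_len(k)]^2 / tot_sq else rep(0, k)
  structure(
    list(values = values, loadings = loadings,
         frac_linear = fl, frac_squared = fs,
         cum_linear = cumsum(fl), cum_squared = cumsum(fs),
         k = k, p = p),
    class = "decomposition_result")
}

#' @export
print.decomposition_result <- function(x, ...) {
  cat("<decomposition_result> ", x$k, " of ", x$p, " components\n", sep = "")
  df <- data.frame(component = seq_len(x$k),
                   pct_linear = round(100 * x$frac_linear, 3),
                   pct_squared = round(100 * x$frac_squared, 3))
  print(df, row.names = FALSE)
  invisible(x)
}

#' PCA of the grand-mean residual matrix
#'
#' Eigendecomposition of the residual cross-product `Ehat' Ehat` (the
#' residual matrix is already column-centered, so no further centering is
#' applied). The linear variance fractions of this decomposition are the
#' residual-matrix column of the variance-comparison table.
#'
#' @param Ehat an [error_matrix()] with `flavor = "grand_residual"`.
#' @param k number of components to report (default: full rank).
#' @return A `decomposition_result` (see [decompose_matrix()]).
#' @export
decompose_residuals <- function(Ehat, k = NULL) {
  stopifnot(inherits(Ehat, "error_matrix"))
  if (Ehat$flavor != "grand_residual")
    stop("expected a grand_residual error matrix; got flavor '",
         Ehat$flavor, "' (use residual_matrix())")
  n <- nrow(Ehat$E); p <- ncol(Ehat$E)
  rmax <- min(n, p)
  if (is.null(k)) k <- rmax
  if (k < 1L || k > p) stop("k must be in 1..", p)
  sv <- svd(Ehat$E, nu = 0L, nv = min(k, rmax))
  values <- numeric(p)
  values[seq_len(rmax)] <- sv$d^2
  values[values < 1e-12 * max(values)] <- 0
  load <- sv$v
  if (ncol(load) < k)
    load <- cbind(load, matrix(0, p, k - ncol(load)))
  flip <- apply(load, 2L, function(v) {
    s <- sign(v[which.max(abs(v))]); if (s == 0) 1 else s
  })
  load <- sweep(load, 2L, flip, "*")
  new_decomposition(values, load, as.integer(k), p)
}

#' Variance-comparison table (residuals vs error covariance)
#'
#' Side-by-side per-component percentage of variance in the grand-mean
#' residual matrix (linear fractions of its PCA) and in the error
#' covariance matrix (squared fractions of its eigendecomposition). When
#' the two columns are similar the uncorrelated (independent) error is
#' small; consistent differences indicate a larger independent-noise
#' contribution. The scalar `gap` is the component-1 difference
#' (Sigma column minus residual column), in percentage points.
#'
#' @param Ehat an [error_matrix()] with `flavor = "grand_residual"`.
#' @param Sigma an [error_covariance()] from the same dataset partition.
#' @param k number of components in the table (default 5).
#' @return An object of class `variance_comparison`: data frame `table`
#'   with columns `component`, `pct_residuals`, `pct_sigma`, `difference`;
#'   scalar `gap`.
#' @export
variance_comparison <- function(Ehat, Sigma, k = 5L) {
  stopifnot(inherits(Ehat, "error_matrix"),
            inherits(Sigma, "error_covariance"))
  if (ncol(Ehat$E) != ncol(Sigma$sigma))
    stop("residual matrix and covariance have different channel counts")
  k <- as.integer(k)
  de <- decompose_residuals(Ehat, k = k)
  ds <- decompose_matrix(Sigma, k = k)
  tab <- data.frame(component = seq_len(k),
                    pct_residuals = 100 * de$frac_linear,
                    pct_sigma = 100 * ds$frac_squared)
  tab$difference <- tab$pct_sigma - tab$pct_residuals
  structure(list(table = tab, gap = tab$difference[1L]),
            class = "variance_comparison")
}

#' @export
print.variance_comparison <- function(x, ...) {
  tab <- x$table
  tab$pct_residuals <- sprintf("%.3f", tab$pct_residuals)
  tab$pct_sigma <- sprintf("%.3f", tab$pct_sigma)
  tab$difference <- sprintf("%+.3f", as.numeric(tab$difference))
  print(tab, row.names = FALSE)
  cat(sprintf("component-1 gap: %+.3f points\n", x$gap))
  invisible(x)
}

#' Log-eigenvalue curve
#'
#' `log10` of the eigenvalues against component number, the standard curve
#' (together with cumulative variance) for choosing how many components to
#' interpret: a sharp elbow marks the transition from structured error to
#' noise-floor components. Zero eigenvalues are truncated with a message.
#'
#' @param result a `decomposition_result`.
#' @return Data frame with columns `component` and `log10_eigenvalue`.
#' @export
log_eigenvalue_curve <- function(result) {
  stopifnot(inherits(result, "decomposition_result"))
  pos <- result$values > 0
  if (!all(pos))
    message("log-eigenvalue curve truncated at rank ", sum(pos),
            " (", sum(!pos), " zero eigenvalue(s) dropped)")
  data.frame(component = which(pos),
             log10_eigenvalue = log10(result$values[pos]))
}
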