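#' K correlation (redundancy) index
#'
#' Todeschini's K index summarizes how much total correlation a set of p
#' variables carries, from the eigenvalue distribution of their correlation
#' matrix. With eigenvalue fractions `phi_j = lambda_j / sum(lambda)`,
#'
#' \deqn{K = \frac{\sum_j |\phi_j - 1/p|}{2 (p - 1) / p}}
#'
#' K = 0 when all variables are uncorrelated (identity correlation, flat
#' eigenvalue spectrum) and K = 1 when they are perfectly correlated
#' (rank-1 correlation matrix). Zero eigenvalues stay in the sum (each
#' contributes `1/p`), which is what makes the rank constraint of an
#' error matrix with fewer replicates than channels bite (see
#' [imbedded_correlation()]).
#'
#' @param x an [error_matrix()], a [spectra_dataset()] (rows treated as the
#'   data matrix), an [error_correlation()], a correlation matrix, or a
#'   plain `n x p` data matrix (`data_matrix = TRUE` forces the data-matrix
#'   reading of a square input).
#' @param data_matrix logical; treat a plain matrix as data rows rather
#'   than as a correlation matrix. Default guesses: square with unit
#'   diagonal = correlation matrix.
#' @return An object of class `k_result`: `k`, `fractions` (eigenvalue
#'   fractions used), `n` (replicate count, `NA` if a correlation matrix
#'   was supplied), `p` (variable count), `k_min` (imbedded floor, `NA`
#'   without a replicate count).
#' @export
k_index <- function(x, data_matrix = NULL) {
  n <- NA_integer_
  if (inherits(x, "error_matrix")) {
    n <- nrow(x$E)
    R <- error_correlation(error_covariance(x))$R
  } else if (inherits(x, "spectra_dataset")) {
    n <- nrow(x$X)
    R <- error_correlation(error_covariance(residual_matrix(x)))$R
  } else if (inherits(x, "error_correlation")) {
    R <- x$R
  } else {
    M <- as.matrix(x)
    looks_cor <- nrow(M) == ncol(M) &&
      max(abs(diag(M) - 1)) < 1e-8 && max(abs(M - t(M))) < 1e-8
    if (is.null(data_matrix)) data_matrix <- !looks_cor
    if (data_matrix) {
      n <- nrow(M)
      if (n < 2L) stop("a data matrix needs at least 2 rows")
      d <- apply(M, 2L, stats::sd)
      if (all(d == 0)) stop("all columns have zero variance")
      keep <- d > 1e-12 * max(d)
      R <- stats::cor(M[, keep, drop = FALSE])
    } else {
      R <- M
    }
  }
  p <- ncol(R)
  if (p < 2L) stop("K index needs at least 2 variables")
  lambda <- eigen((R + t(R)) / 2, symmetric = TRUE, only.values = TRUE)$values
  lambda <- pmax(lambda, 0)
  phi <- lambda / sum(lambda)
  k <- sum(abs(phi - 1 / p)) / (2 * (p - 1) / p)
  k <- min(max(k, 0), 1)
  k_min <- if (is.na(n)) NA_real_ else imbedded_correlation(n, p)
  structure(list(k = k, fractions = phi, n = n, p = p, k_min = k_min),
            class = "k_result")
}

#' @export
print.k_result <- function(x, ...) {
  cat(sprintf("<k_result> K = %.4f (p = %d", x$k, x$p))
  if (!is.na(x$n)) cat(sprintf(", n = %d, imbedded floor %.4f", x$n, x$k_min))
  cat(")\n")
  invisible(x)
}

#' Imbedded (minimum) correlation
#'
#' The smallest K index an `n x p` data matrix can attain. With fewer
#' replicates than channels the correlation matrix has rank at most n, so
#' its eigenvalue spectrum cannot be flat: the least-correlated achievable
#' configuration puts equal mass `p/n` on n eigenvalues and zero on the
#' rest, whose K closes to
#'
#' \deqn{K_{min} = \frac{p - n}{p - 1} \quad (n < p),}
#'
#' and 0 for `n >= p` (full rank permits the identity). A single replicate
#' forces rank 1, hence K = 1.
#'
#' @param n replicate (row) count, >= 1.
#' @param p channel (variable) count, >= 2.
#' @return The floor K value in `[0, 1]`.
#' @examples
#' imbedded_correlation(15, 236)  # 0.9404
#' imbedded_correlation(15, 74)   # 0.8082
#' @export
imbedded_correlation <- function(n, p) {
  if (!is.numeric(n) || !is.numeric(p) || length(n) != 1L || length(p) != 1L)
    stop("n and p must be single numbers")
  n <- as.integer(n); p <- as.integer(p)
  if (n < 1L) stop("n must be >= 1")
  if (p < 2L) stop("p must be >= 2")
  if (n >= p) return(0)
  (p - n) / (p - 1)
}

#' K of an explicit eigenvalue configuration
#'
#' Evaluates the K sum directly on a correlation-matrix eigenvalue spectrum
#' (values must be non-negative and sum to p). Used to cross-check the
#' closed-form imbedded correlation against the uniform rank-n
#' configuration.
#'
#' @param lambda non-negative eigenvalues of a p x p correlation matrix.
#' @return K in `[0, 1]`.
#' @export
k_from_eigenvalues <- function(lambda) {
  lambda <- as.numeric(lambda)
  if (any(lambda < 0)) stop("eigenvalues must be non-negative")
  p <- length(lambda)
  if (p < 2L) stop("need at least 2 eigenvalues")
  phi <- lambda / sum(lambda)
  sum(abs(phi - 1 / p)) / (2 * (p - 1) / p)
}
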