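#' Replicate error matrix
#'
#' Deviations of each replicate spectrum from the mean of its replicate
#' group, the group mean being taken as the true value:
#' `e_ij = x_ij - xbar_j(group of i)`. The grouping decides which variance
#' sources remain in the error (see [replicate_grouping()]). Within each
#' group the columns of E sum to zero, so `rank(E) <= n - #groups`.
#'
#' @param dataset a [spectra_dataset()].
#' @param grouping a [replicate_grouping()]; every group needs >= 2
#'   replicates.
#' @return An object of class `error_matrix` with fields `E` (`n x p`),
#'   `grouping`, `flavor = "replicate_error"`, `n_groups`, `wavelengths`.
#' @export
error_matrix <- function(dataset, grouping) {
  stopifnot(inherits(dataset, "spectra_dataset"),
            inherits(grouping, "replicate_grouping"))
  g <- droplevels(grouping$groups)
  if (length(g) != nrow(dataset$X))
    stop("grouping has ", length(g), " labels for ", nrow(dataset$X), " rows")
  sizes <- table(g)
  if (any(sizes < 2L))
    stop("singleton group(s): ",
         paste(names(sizes)[sizes < 2L], collapse = ", "),
         " (need >= 2 replicates per group)")
  E <- dataset$X
  for (lev in levels(g)) {
    idx <- g == lev
    E[idx, ] <- sweep(E[idx, , drop = FALSE], 2L,
                      colMeans(E[idx, , drop = FALSE]))
  }
  structure(
    list(E = E, grouping = grouping, flavor = "replicate_error",
         n_groups = nlevels(g), wavelengths = dataset$wavelengths),
    class = "error_matrix")
}

#' Grand-mean residual matrix
#'
#' Each spectrum minus the mean of all spectra in the dataset. Unlike the
#' grouped error matrix, this keeps all between-group structure (sample,
#' session, background differences) in the residuals; its PCA variance
#' profile is the reference against which the error covariance
#' decomposition is compared to gauge uncorrelated error.
#'
#' @param dataset a [spectra_dataset()] with at least 2 rows.
#' @return An `error_matrix` with `flavor = "grand_residual"` and one group.
#' @export
residual_matrix <- function(dataset) {
  stopifnot(inherits(dataset, "spectra_dataset"))
  if (nrow(dataset$X) < 2L)
    stop("at least 2 spectra are needed (got ", nrow(dataset$X), ")")
  E <- sweep(dataset$X, 2L, colMeans(dataset$X))
  structure(
    list(E = E, grouping = NULL, flavor = "grand_residual",
         n_groups = 1L, wavelengths = dataset$wavelengths),
    class = "error_matrix")
}

#' @export
print.error_matrix <- function(x, ...) {
  cat("<error_matrix> ", nrow(x$E), " x ", ncol(x$E),
      " (", x$flavor, ", ", x$n_groups, " group(s))\n", sep = "")
  invisible(x)
}

#' Error covariance matrix
#'
#' The pooled error covariance `Sigma = E' E / (n - #groups)`: the p x p
#' symmetric matrix whose diagonal is the per-channel error variance and
#' whose off-diagonal entries are the error covariances between wavelength
#' channels. Dividing by `n - #groups` (one degree of freedom spent per
#' estimated group mean) makes the pooled estimate unbiased.
#'
#' @param E an [error_matrix()].
#' @return An object of class `error_covariance`: `sigma` (`p x p`),
#'   `n_effective`, `wavelengths`.
#' @export
error_covariance <- function(E) {
  stopifnot(inherits(E, "error_matrix"))
  dof <- nrow(E$E) - E$n_groups
  if (dof < 1L)
    stop("no residual degrees of freedom (n = ", nrow(E$E),
         ", groups = ", E$n_groups, ")")
  sigma <- crossprod(E$E) / dof
  sigma <- (sigma + t(sigma)) / 2
  structure(
    list(sigma = sigma, n_effective = dof, wavelengths = E$wavelengths),
    class = "error_covariance")
}

#' @export
print.error_covariance <- function(x, ...) {
  d <- diag(x$sigma)
  cat("<error_covariance> ", nrow(x$sigma), " x ", ncol(x$sigma),
      ", dof = ", x$n_effective, "\n", sep = "")
  cat(sprintf("  diagonal: %.4g to %.4g (%%R)^2\n", min(d), max(d)))
  invisible(x)
}

#' Error correlation matrix
#'
#' Scale-free view of the error structure:
#' `R_jk = Sigma_jk / sqrt(Sigma_jj Sigma_kk)`. Channels whose error
#' variance is zero (relative tolerance `1e-12` of the largest diagonal
#' entry) are excluded and their indices reported, never silently dropped.
#'
#' @param Sigma an [error_covariance()].
#' @return An object of class `error_correlation`: `R` (`q x q` over
#'   retained channels), `excluded` (integer indices of dropped channels),
#'   `wavelengths` (retained).
#' @export
error_correlation <- function(Sigma) {
  stopifnot(inherits(Sigma, "error_covariance"))
  d <- diag(Sigma$sigma)
  tol <- 1e-12 * max(d, 0)
  keep <- d > tol
  if (!any(keep))
    stop("all channels have (numerically) zero error variance")
  excluded <- which(!keep)
  if (length(excluded))
    warning(length(excluded),
            " zero-variance channel(s) excluded from the correlation matrix",
            call. = FALSE)
  S <- Sigma$sigma[keep, keep, drop = FALSE]
  R <- stats::cov2cor(S)
  R[R > 1] <- 1; R[R < -1] <- -1
  structure(
    list(R = R, excluded = excluded,
         wavelengths = Sigma$wavelengths[keep]),
    class = "error_correlation")
}

#' Diagonal of the error covariance
#'
#' The per-channel error variances, the standard curve for judging
#' heteroscedasticity along the wavelength axis (flat diagonal =
#' homoscedastic noise; diagonal tracking the mean spectrum = shot noise;
#' tracking its square = multiplicative noise).
#'
#' @param Sigma an [error_covariance()].
#' @return Named numeric p-vector of error variances.
#' @export
covariance_diagonal <- function(Sigma) {
  stopifnot(inherits(Sigma, "error_covariance"))
  d <- diag(Sigma$sigma)
  names(d) <- format_wl(Sigma$wavelengths)
  d
}
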