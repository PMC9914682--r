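#' Per-wavelength mean, standard deviation and RSD
#'
#' First-look reproducibility statistics over replicates: at each wavelength
#' channel the mean spectrum, the absolute standard deviation (n-1
#' denominator) and the relative standard deviation
#' `rsd_j = 100 * s_j / mean_j` (percent). Scalar summaries are means over
#' wavelengths.
#'
#' @param dataset a [spectra_dataset()] with at least 2 replicates.
#' @return List with `mean`, `sd`, `rsd` (p-vectors), `sd_mean`, `rsd_mean`
#'   (scalars; wavelengths where the mean is 0 are dropped from `rsd_mean`
#'   with a warning and returned as `NA` in `rsd`).
#' @export
per_wavelength_stats <- function(dataset) {
  stopifnot(inherits(dataset, "spectra_dataset"))
  X <- dataset$X
  if (nrow(X) < 2L)
    stop("at least 2 replicates are needed (got ", nrow(X), ")")
  mu <- colMeans(X)
  s <- apply(X, 2L, stats::sd)
  rsd <- rep(NA_real_, length(mu))
  ok <- mu != 0
  rsd[ok] <- 100 * s[ok] / mu[ok]
  if (any(!ok))
    warning(sum(!ok), " channel(s) with zero mean: RSD undefined there",
            call. = FALSE)
  list(mean = mu, sd = s, rsd = rsd,
       sd_mean = mean(s), rsd_mean = mean(rsd[ok]))
}

#' Root-mean-square replicate deviation
#'
#' For each replicate, the root mean square over wavelengths of its
#' deviation from the mean spectrum of the replicates:
#' `RMS_i = sqrt(mean_j (x_ij - xbar_j)^2)`. Zero iff the replicate equals
#' the mean spectrum; summarized by its mean and SD over replicates.
#'
#' @param dataset a [spectra_dataset()] with at least 2 replicates.
#' @return List with `rms` (n-vector), `rms_mean`, `rms_sd`.
#' @export
rms_statistic <- function(dataset) {
  stopifnot(inherits(dataset, "spectra_dataset"))
  X <- dataset$X
  if (nrow(X) < 2L)
    stop("at least 2 replicates are needed (got ", nrow(X), ")")
  dev <- sweep(X, 2L, colMeans(X))
  rms <- sqrt(rowMeans(dev^2))
  list(rms = rms, rms_mean = mean(rms), rms_sd = stats::sd(rms))
}

#' Per-wavelength signal-to-noise ratio
#'
#' `SNR_j = xbar_j / s_j`: ratio of the mean spectrum to the absolute
#' standard deviation at each channel. Channels with zero SD are undefined
#' (`NA`) and excluded from the scalar summaries with a warning.
#'
#' @param dataset a [spectra_dataset()] with at least 2 replicates.
#' @return List with `snr` (p-vector), `snr_mean`, `snr_sd`.
#' @export
snr_spectrum <- function(dataset) {
  st <- per_wavelength_stats(dataset)
  snr <- rep(NA_real_, length(st$mean))
  ok <- st$sd > 0
  snr[ok] <- st$mean[ok] / st$sd[ok]
  if (any(!ok))
    warning(sum(!ok), " channel(s) with zero SD: SNR undefined there",
            call. = FALSE)
  list(snr = snr, snr_mean = mean(snr[ok]), snr_sd = stats::sd(snr[ok]))
}

#' Reproducibility summary table
#'
#' One column per sample, six statistics per column: mean absolute SD, mean
#' RSD (%), RMS mean and SD over replicates, SNR mean and SD over
#' wavelengths. This is the standard per-sample reproducibility summary for
#' replicated reflectance spectra.
#'
#' @param dataset a [spectra_dataset()].
#' @param by metadata column defining the partition (default `"sample_id"`).
#' @return A data frame; rows are the six statistics, columns the partition
#'   cells.
#' @export
reproducibility_table <- function(dataset, by = "sample_id") {
  stopifnot(inherits(dataset, "spectra_dataset"))
  if (!by %in% names(dataset$meta))
    stop("unknown metadata field: ", by)
  cells <- unique(dataset$meta[[by]])
  stats_names <- c("absolute_sd_mean", "relative_sd_mean_pct",
                   "rms_mean", "rms_sd", "snr_mean", "snr_sd")
  out <- data.frame(statistic = stats_names)
  for (cell in cells) {
    idx <- dataset$meta[[by]] == cell
    sub <- structure(
      list(X = dataset$X[idx, , drop = FALSE],
           wavelengths = dataset$wavelengths,
           meta = dataset$meta[idx, , drop = FALSE]),
      class = "spectra_dataset")
    if (nrow(sub$X) < 2L)
      stop("partition cell '", cell, "' has fewer than 2 replicates")
    pw <- per_wavelength_stats(sub)
    rm_ <- rms_statistic(sub)
    sn <- suppressWarnings(snr_spectrum(sub))
    out[[as.character(cell)]] <- c(pw$sd_mean, pw$rsd_mean,
                                   rm_$rms_mean, rm_$rms_sd,
                                   sn$snr_mean, sn$snr_sd)
  }
  out
}
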