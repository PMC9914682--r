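#' Heatmap of a covariance or correlation matrix
#'
#' Wavelength-labeled heatmap. Correlation maps use a fixed [-1, 1]
#' diverging scale so they are comparable across datasets; covariance maps
#' use a data-driven scale (covariance is scale-dependent, so magnitudes
#' are only comparable within a run).
#'
#' @param M `p x p` matrix, an [error_covariance()] or
#'   [error_correlation()].
#' @param wavelengths numeric axis matching `M` (taken from the object if
#'   one is given).
#' @param kind `"covariance"` or `"correlation"`.
#' @param file output path (`.png` or `.svg`); `NULL` returns the ggplot
#'   without writing.
#' @return The ggplot object, invisibly (with the file written if
#'   requested).
#' @export
render_heatmap <- function(M, wavelengths = NULL,
                           kind = c("covariance", "correlation"),
                           file = NULL) {
  kind <- match.arg(kind)
  if (inherits(M, "error_covariance")) {
    wavelengths <- M$wavelengths; M <- M$sigma
  } else if (inherits(M, "error_correlation")) {
    wavelengths <- M$wavelengths; M <- M$R
  }
  M <- as.matrix(M)
  if (nrow(M) != ncol(M)) stop("M must be square")
  if (is.null(wavelengths)) wavelengths <- seq_len(ncol(M))
  if (length(wavelengths) != ncol(M))
    stop("wavelength axis length (", length(wavelengths),
         ") does not match matrix size (", ncol(M), ")")
  df <- expand.grid(wl_x = wavelengths, wl_y = wavelengths)
  df$value <- as.vector(M)
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = wl_x, y = wl_y,
                                         fill = value)) +
    ggplot2::geom_raster() +
    ggplot2::labs(x = "wavelength (nm)", y = "wavelength (nm)",
                  fill = if (kind == "correlation") "r" else "(%R)²") +
    ggplot2::theme_minimal()
  gg <- if (kind == "correlation")
    gg + ggplot2::scale_fill_gradient2(limits = c(-1, 1),
                                       low = "#2166AC", mid = "white",
                                       high = "#B2182B")
  else
    gg + ggplot2::scale_fill_viridis_c()
  if (!is.null(file)) ggplot2::ggsave(file, gg, width = 6, height = 5, dpi = 150)
  invisible(gg)
}

#' Overlaid covariance-diagonal curves
#'
#' Plots a labeled set of per-channel error-variance curves (one per
#' session or background mode) against wavelength — the standard view for
#' comparing error magnitude and heteroscedasticity across acquisition
#' conditions.
#'
#' @param diagonals named list of numeric p-vectors (names become the
#'   legend, e.g. `"1A"` ... `"3B"`).
#' @param wavelengths numeric axis of length p.
#' @param file optional output path (`.png`/`.svg`).
#' @return The ggplot object, invisibly.
#' @export
render_diagonals <- function(diagonals, wavelengths, file = NULL) {
  if (!is.list(diagonals) || !length(diagonals))
    stop("diagonals must be a non-empty named list of vectors")
  if (is.null(names(diagonals)) || any(!nzchar(names(diagonals))))
    stop("every diagonal needs a label")
  lens <- vapply(diagonals, length, 1L)
  if (any(lens != length(wavelengths)))
    stop("all diagonals must match the wavelength axis length")
  df <- do.call(rbind, lapply(names(diagonals), function(nm)
    data.frame(wavelength = wavelengths, variance = diagonals[[nm]],
               group = nm)))
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = wavelength, y = variance,
                                         colour = group)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "wavelength (nm)", y = "error variance (%R)²",
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(file)) ggplot2::ggsave(file, gg, width = 7, height = 4, dpi = 150)
  invisible(gg)
}

#' Run the full measurement-error characterization pipeline
#'
#' Orchestrates the analysis end-to-end on an input CSV or a simulated
#' dataset and writes a report bundle to `out_dir`:
#'
#' 1. `descriptives.csv` — per-sample reproducibility table;
#' 2. `outliers.csv` — T2/Q screening per sample (optionally removing
#'    replicates flagged by the chosen rule before error estimation);
#' 3. `sigma_<sample>.csv` / `correlation_<sample>.csv` + heatmaps;
#' 4. `diagonals_by_mode.csv`/`.png` and `diagonals_by_session.csv`/`.png`;
#' 5. `variance_comparison.csv` — residuals-vs-Sigma table per sample;
#' 6. `k_index.csv` — imbedded correlation and per-session/mode K table;
#' 7. `manifest.json` — config echo, seed, stage log, artifact list.
#'
#' Screening always precedes error estimation; removal is off by default
#' (`outlier_rule = "none"`) so both the with- and without-outlier paths
#' are available.
#'
#' @param input path to a spectra CSV (exclusive with `design`).
#' @param design a [design_spec()] to simulate instead of reading a file.
#' @param noise a [noise_model()] (simulation only).
#' @param sample_effects per-sample tweaks for the simulation (see
#'   [simulate_dataset()]).
#' @param grouping grouping mode for the error matrix: `"all"`,
#'   `"per_session"` or `"per_background_mode"`.
#' @param k components for PCA screening and the comparison table.
#' @param alpha significance level for the T2/Q limits.
#' @param outlier_rule `"none"` (report only), `"both"` or `"either"`
#'   (remove flagged replicates before error estimation).
#' @param out_dir output directory (created if missing).
#' @param seed integer seed (required when simulating).
#' @param figures write PNG figures (set `FALSE` for table-only runs).
#' @return Invisibly, the manifest as a list.
#' @export
run_pipeline <- function(input = NULL, design = NULL, noise = NULL,
                         sample_effects = NULL,
                         grouping = c("all", "per_session",
                                      "per_background_mode"),
                         k = 3L, alpha = 0.05,
                         outlier_rule = c("none", "both", "either"),
                         out_dir, seed = NULL, figures = TRUE) {
  grouping <- match.arg(grouping)
  outlier_rule <- match.arg(outlier_rule)
  if (is.null(input) == is.null(design))
    stop("give exactly one of 'input' (CSV path) or 'design' (simulation)")
  if (!is.null(design) && is.null(seed))
    stop("a seed is required when simulating")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  artifacts <- character()
  log <- character()
  stage <- function(name, fun) {
    t0 <- Sys.time()
    out <- tryCatch(fun(), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    dt <- round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 2)
    msg <- paste0("[", name, "] done in ", dt, "s")
    message(msg)
    log <<- c(log, msg)
    out
  }
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    artifacts <<- c(artifacts, name)
    path
  }

  ds <- stage("load", function() {
    if (!is.null(input)) {
      d <- read_spectra(input)
    } else {
      d <- simulate_dataset(design, noise %||% noise_model(),
                            sample_effects, seed = seed)
    }
    message("  ", nrow(d$X), " replicates x ", ncol(d$X), " channels")
    d
  })

  stage("descriptives", function() {
    emit(reproducibility_table(ds), "descriptives.csv")
  })

  samples <- unique(ds$meta$sample_id)
  screen <- stage("outlier_screen", function() {
    per_sample <- lapply(samples, function(s) {
      sub <- subset_spectra(ds, sample_id == s)
      kk <- min(k, nrow(sub$X) - 1L, ncol(sub$X))
      mod <- fit_pca(sub$X, k = kk)
      sr <- screen_outliers(mod, sub$X, alpha = alpha)
      flagged_both <- flag_outliers(sr, "both")
      flagged_either <- flag_outliers(sr, "either")
      data.frame(sub$meta[c("sample_id", "session_id", "replicate_index")],
                 t2 = sr$t2, q = sr$q,
                 t2_limit = sr$t2_limit, q_limit = sr$q_limit,
                 flag_both = flagged_both, flag_either = flagged_either)
    })
    tab <- do.call(rbind, per_sample)
    emit(tab, "outliers.csv")
    tab
  })

  if (outlier_rule != "none") {
    drop_col <- if (outlier_rule == "both") "flag_both" else "flag_either"
    flagged <- screen[screen[[drop_col]], c("sample_id", "session_id",
                                            "replicate_index")]
    if (nrow(flagged)) {
      key <- function(m) paste(m$sample_id, m$session_id, m$replicate_index)
      keep <- !(key(ds$meta) %in% key(flagged))
      message("  removing ", sum(!keep), " flagged replicate(s)")
      ds <- structure(list(X = ds$X[keep, , drop = FALSE],
                           wavelengths = ds$wavelengths,
                           meta = ds$meta[keep, , drop = FALSE]),
                      class = "spectra_dataset")
    }
  }

  ecms <- stage("error_structure", function() {
    out <- list()
    for (s in samples) {
      sub <- subset_spectra(ds, sample_id == s)
      gr <- replicate_grouping(sub, grouping)
      E <- error_matrix(sub, gr)
      Sigma <- error_covariance(E)
      R <- suppressWarnings(error_correlation(Sigma))
      wls <- format_wl(Sigma$wavelengths)
      emit(data.frame(wavelength = wls, Sigma$sigma, check.names = FALSE),
           paste0("sigma_", s, ".csv"))
      emit(data.frame(wavelength = format_wl(R$wavelengths), R$R,
                      check.names = FALSE),
           paste0("correlation_", s, ".csv"))
      if (figures) {
        f1 <- file.path(out_dir, paste0("sigma_", s, ".png"))
        render_heatmap(Sigma, kind = "covariance", file = f1)
        f2 <- file.path(out_dir, paste0("correlation_", s, ".png"))
        render_heatmap(R, kind = "correlation", file = f2)
        artifacts <<- c(artifacts, basename(f1), basename(f2))
      }
      out[[s]] <- list(dataset = sub, E = E, sigma = Sigma)
    }
    out
  })

  stage("diagonals", function() {
    for (split in c("per_background_mode", "per_session")) {
      col <- if (split == "per_session") "session_id" else "background_mode"
      curves <- list()
      for (s in samples) {
        sub <- ecms[[s]]$dataset
        for (lev in unique(sub$meta[[col]])) {
          idx <- sub$meta[[col]] == lev
          cell <- structure(list(X = sub$X[idx, , drop = FALSE],
                                 wavelengths = sub$wavelengths,
                                 meta = sub$meta[idx, , drop = FALSE]),
                            class = "spectra_dataset")
          gr <- replicate_grouping(cell, "all")
          d <- covariance_diagonal(error_covariance(error_matrix(cell, gr)))
          curves[[paste(s, lev, sep = ":")]] <- as.numeric(d)
        }
      }
      name <- if (split == "per_session") "diagonals_by_session"
              else "diagonals_by_mode"
      tab <- data.frame(wavelength = format_wl(ds$wavelengths),
                        as.data.frame(curves, check.names = FALSE),
                        check.names = FALSE)
      emit(tab, paste0(name, ".csv"))
      if (figures) {
        f <- file.path(out_dir, paste0(name, ".png"))
        render_diagonals(curves, ds$wavelengths, file = f)
        artifacts <<- c(artifacts, basename(f))
      }
    }
  })

  stage("variance_comparison", function() {
    tabs <- lapply(samples, function(s) {
      sub <- ecms[[s]]$dataset
      vc <- variance_comparison(residual_matrix(sub), ecms[[s]]$sigma,
                                k = min(k, ncol(sub$X), nrow(sub$X)))
      cbind(sample_id = s, vc$table)
    })
    emit(do.call(rbind, tabs), "variance_comparison.csv")
  })

  stage("k_index", function() {
    rows <- list(); i <- 0L
    for (s in samples) {
      sub <- ecms[[s]]$dataset
      for (sess in unique(sub$meta$session_id)) {
        idx <- sub$meta$session_id == sess
        cell <- structure(list(X = sub$X[idx, , drop = FALSE],
                               wavelengths = sub$wavelengths,
                               meta = sub$meta[idx, , drop = FALSE]),
                          class = "spectra_dataset")
        gr <- replicate_grouping(cell, "all")
        kr <- suppressWarnings(k_index(error_matrix(cell, gr)))
        i <- i + 1L
        rows[[i]] <- data.frame(
          sample_id = s, session_id = sess,
          background_mode = cell$meta$background_mode[1L],
          n = kr$n, p = kr$p,
          imbedded_correlation = round(kr$k_min, 2),
          k_index = round(kr$k, 2))
      }
    }
    emit(do.call(rbind, rows), "k_index.csv")
  })

  manifest <- list(
    package = "nirnoise",
    r_version = as.character(getRversion()),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = list(input = input,
                  simulated = !is.null(design),
                  grouping = grouping, k = k, alpha = alpha,
                  outlier_rule = outlier_rule, seed = seed),
    stages = log,
    artifacts = artifacts)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

utils::globalVariables(c("wl_x", "wl_y", "value", "wavelength", "variance",
                         "group", "sample_id"))
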