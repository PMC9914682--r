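#' Replicated-spectra dataset
#'
#' Container for a block of replicated reflectance spectra: an `n x p`
#' numeric matrix (rows = replicate spectra, columns = wavelength channels,
#' values in percent reflectance), a strictly increasing wavelength axis in
#' nm, and one row of metadata per replicate identifying the sample, the
#' analytical session, the background-timing mode, the replicate index and
#' the instrument.
#'
#' @param X numeric matrix, `n x p`, percent reflectance.
#' @param wavelengths numeric vector of length `p`, strictly increasing, nm.
#' @param meta data frame with `n` rows and columns `sample_id`,
#'   `session_id`, `background_mode` (`"A"` = background before each sample,
#'   `"B"` = background at session start), `replicate_index`,
#'   `instrument_id`.
#' @return An object of class `spectra_dataset`.
#' @examples
#' X <- matrix(rnorm(12, 50, 2), nrow = 3)
#' meta <- data.frame(sample_id = "s", session_id = "1A",
#'                    background_mode = "A", replicate_index = 1:3,
#'                    instrument_id = "demo")
#' ds <- spectra_dataset(X, c(1100, 1200, 1300, 1400), meta)
#' ds
#' @export
spectra_dataset <- function(X, wavelengths, meta) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  wavelengths <- as.numeric(wavelengths)
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)

  if (nrow(X) < 1L) stop("dataset must contain at least one spectrum")
  if (ncol(X) != length(wavelengths))
    stop("number of spectral columns (", ncol(X),
         ") does not match wavelength axis length (", length(wavelengths), ")")
  if (any(!is.finite(wavelengths)) || any(wavelengths <= 0))
    stop("wavelengths must be finite and positive (nm)")
  if (any(diff(wavelengths) <= 0))
    stop("wavelength axis must be strictly increasing")
  required <- c("sample_id", "session_id", "background_mode",
                "replicate_index", "instrument_id")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols))
    stop("metadata is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  if (nrow(meta) != nrow(X))
    stop("metadata has ", nrow(meta), " rows but the matrix has ", nrow(X))
  meta$replicate_index <- as.integer(meta$replicate_index)
  meta$background_mode <- as.character(meta$background_mode)
  bad_mode <- !meta$background_mode %in% c("A", "B")
  if (any(bad_mode))
    stop("background_mode must be 'A' or 'B'; offending rows: ",
         paste(utils::head(which(bad_mode), 5L), collapse = ", "))

  dimnames(X) <- list(NULL, format_wl(wavelengths))
  out <- structure(
    list(X = X, wavelengths = wavelengths, meta = meta),
    class = "spectra_dataset")
  rng <- range(X, na.rm = TRUE)
  if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 100))
    warning("reflectance values outside [0, 100] %R (range ",
            signif(rng[1], 4), " to ", signif(rng[2], 4),
            "); kept as-is", call. = FALSE)
  out
}

format_wl <- function(wl) {
  # stable numeric labels for CSV headers and matrix dimnames
  formatC(wl, format = "fg", digits = 10, flag = "#")
}

#' @export
print.spectra_dataset <- function(x, ...) {
  cat("<spectra_dataset> ", nrow(x$X), " replicate spectra x ",
      ncol(x$X), " channels (", min(x$wavelengths), "-",
      max(x$wavelengths), " nm)\n", sep = "")
  cat("  samples:     ", paste(unique(x$meta$sample_id), collapse = ", "), "\n")
  cat("  sessions:    ", paste(unique(x$meta$session_id), collapse = ", "), "\n")
  cat("  instruments: ", paste(unique(x$meta$instrument_id), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.spectra_dataset <- function(x) dim(x$X)

META_COLS <- c("sample_id", "session_id", "background_mode",
               "replicate_index", "instrument_id")

#' Read replicated spectra from CSV
#'
#' Expects one header row: the five metadata columns `sample_id, session_id,
#' background_mode, replicate_index, instrument_id` first, then one numeric
#' column per wavelength whose label is the wavelength in nm; one spectrum
#' per row. This is the dialect [write_spectra()] emits.
#'
#' @param path path to a CSV file.
#' @return A validated [spectra_dataset()].
#' @seealso [write_spectra()]
#' @export
read_spectra <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, check.names = FALSE,
                         stringsAsFactors = FALSE, encoding = "UTF-8")
  missing_cols <- setdiff(META_COLS, names(raw))
  if (length(missing_cols))
    stop("CSV is missing metadata column(s): ",
         paste(missing_cols, collapse = ", "))
  wl_labels <- setdiff(names(raw), META_COLS)
  if (!length(wl_labels)) stop("CSV contains no wavelength columns")
  wl <- suppressWarnings(as.numeric(wl_labels))
  if (any(is.na(wl)))
    stop("non-numeric wavelength header label(s): ",
         paste(utils::head(wl_labels[is.na(wl)], 5L), collapse = ", "))
  if (any(diff(wl) <= 0))
    stop("wavelength header must be strictly increasing (nm)")
  Xraw <- raw[, wl_labels, drop = FALSE]
  for (j in seq_along(Xraw)) {
    v <- Xraw[[j]]
    if (!is.numeric(v)) {
      conv <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(conv) & !is.na(v) & nzchar(trimws(v)))
      if (length(bad))
        stop("non-numeric value at row ", bad[1L],
             ", wavelength column '", wl_labels[j], "'")
      Xraw[[j]] <- conv
    }
  }
  spectra_dataset(as.matrix(Xraw), wl, raw[, META_COLS, drop = FALSE])
}

#' Write a spectra dataset to CSV
#'
#' Writes the dialect [read_spectra()] accepts: metadata columns first, then
#' one column per wavelength labeled with its nm value. Metadata round-trips
#' exactly; reflectance values round-trip to double-precision text
#' representation (15 significant digits).
#'
#' @param dataset a [spectra_dataset()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(dataset, path) {
  stopifnot(inherits(dataset, "spectra_dataset"))
  df <- cbind(dataset$meta[, META_COLS, drop = FALSE],
              as.data.frame(dataset$X, check.names = FALSE))
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("could not write '", path, "': ", conditionMessage(ok))
  invisible(path)
}

#' Subset a spectra dataset by metadata
#'
#' Keeps replicate rows whose metadata satisfy a predicate expression;
#' surviving rows keep their order and the wavelength axis is untouched.
#'
#' @param dataset a [spectra_dataset()].
#' @param predicate an expression over the metadata columns, e.g.
#'   `sample_id == "lump"` or `session_id %in% c("1A", "2A")`.
#' @return A [spectra_dataset()] (possibly with zero rows, with a warning).
#' @export
subset_spectra <- function(dataset, predicate) {
  stopifnot(inherits(dataset, "spectra_dataset"))
  expr <- substitute(predicate)
  vars <- all.vars(expr)
  caller <- parent.frame()
  unknown <- Filter(function(v) !v %in% names(dataset$meta) &&
                      !exists(v, envir = caller),
                    vars)
  if (length(unknown))
    stop("predicate references unknown metadata field(s): ",
         paste(unknown, collapse = ", "))
  keep <- eval(expr, dataset$meta, caller)
  if (!is.logical(keep) || length(keep) != nrow(dataset$meta))
    stop("predicate must evaluate to one logical per replicate")
  keep <- which(keep %in% TRUE)
  if (!length(keep)) {
    warning("predicate matched no replicates; returning empty dataset",
            call. = FALSE)
    out <- structure(
      list(X = dataset$X[0, , drop = FALSE],
           wavelengths = dataset$wavelengths,
           meta = dataset$meta[0, , drop = FALSE]),
      class = "spectra_dataset")
    return(out)
  }
  structure(
    list(X = dataset$X[keep, , drop = FALSE],
         wavelengths = dataset$wavelengths,
         meta = dataset$meta[keep, , drop = FALSE]),
    class = "spectra_dataset")
}

#' Validate a spectra dataset
#'
#' Checks the dataset invariants and reports violations instead of erroring:
#' duplicated (sample, session, replicate) triples, missing values,
#' background mode varying within a session, and (optionally) replicate
#' groups too small to estimate an error matrix.
#'
#' @param dataset a [spectra_dataset()].
#' @param grouping optional [replicate_grouping()]; when given, groups with
#'   fewer than 2 replicates are reported as degenerate.
#' @return A data frame with columns `check` and `detail`; zero rows iff the
#'   dataset is valid.
#' @export
validate_spectra <- function(dataset, grouping = NULL) {
  stopifnot(inherits(dataset, "spectra_dataset"))
  issues <- list()
  add <- function(check, detail)
    issues[[length(issues) + 1L]] <<- data.frame(check = check, detail = detail)

  key <- do.call(paste, c(dataset$meta[c("sample_id", "session_id",
                                         "replicate_index")], sep = "\r"))
  dup <- unique(key[duplicated(key)])
  for (d in dup)
    add("duplicate_replicate",
        paste0("(sample_id, session_id, replicate_index) = (",
               gsub("\r", ", ", d), ") occurs more than once"))

  nmiss <- sum(!is.finite(dataset$X))
  if (nmiss > 0)
    add("missing_values", paste0(nmiss, " non-finite reflectance value(s)"))

  modes <- tapply(dataset$meta$background_mode, dataset$meta$session_id,
                  function(m) length(unique(m)))
  for (s in names(modes)[modes > 1L])
    add("mixed_background_mode",
        paste0("session '", s, "' mixes background modes"))

  if (!is.null(grouping)) {
    sizes <- table(grouping$groups)
    for (g in names(sizes)[sizes < 2L])
      add("degenerate_group",
          paste0("group '", g, "' has ", sizes[[g]],
                 " replicate(s); at least 2 needed for an error matrix"))
  }
  if (!length(issues))
    return(data.frame(check = character(), detail = character()))
  do.call(rbind, issues)
}

#' Assign replicates to error-estimation groups
#'
#' The error matrix subtracts each replicate's group mean; the grouping
#' decides which variance sources stay in the error. Grouping by session
#' removes session and background effects; grouping by background mode pools
#' the sessions run under one background-timing condition; `all` pools
#' everything (one group per sample).
#'
#' Groups never span samples: the group label is always the sample crossed
#' with the requested stratum.
#'
#' @param dataset a [spectra_dataset()].
#' @param mode one of `"all"`, `"per_session"`, `"per_background_mode"`,
#'   `"custom"`.
#' @param groups for `mode = "custom"`, a vector of group labels, one per
#'   replicate row.
#' @return An object of class `replicate_grouping`: list with `mode` and
#'   `groups` (factor of length `n`).
#' @export
replicate_grouping <- function(dataset,
                               mode = c("all", "per_session",
                                        "per_background_mode", "custom"),
                               groups = NULL) {
  stopifnot(inherits(dataset, "spectra_dataset"))
  mode <- match.arg(mode)
  m <- dataset$meta
  g <- switch(mode,
    all = m$sample_id,
    per_session = paste(m$sample_id, m$session_id, sep = "/"),
    per_background_mode = paste(m$sample_id, m$background_mode, sep = "/"),
    custom = {
      if (is.null(groups) || length(groups) != nrow(m))
        stop("custom grouping needs one group label per replicate")
      as.character(groups)
    })
  structure(list(mode = mode, groups = factor(g)),
            class = "replicate_grouping")
}
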