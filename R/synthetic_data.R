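#' Instrument profile for the synthetic generator
#'
#' Describes a miniaturized NIR spectrometer as a wavelength grid plus a
#' smooth base reflectance spectrum (baseline + Gaussian bands). Two
#' presets ship with the package: [avaspec_like()] (236 channels over
#' 972-1701 nm, fiber-probe dispersive instrument) and [neospectra_like()]
#' (74 channels over 1351-2559 nm, direct-contact FT instrument).
#'
#' @param name label.
#' @param wl_min,wl_max wavelength range, nm.
#' @param channels number of equally spaced channels p (>= 2).
#' @param bands data frame with columns `center` (nm), `width` (nm),
#'   `amplitude` (%R, >= 0); may have zero rows for a flat spectrum.
#' @param baseline baseline reflectance, %R.
#' @return An object of class `instrument_profile`.
#' @export
instrument_profile <- function(name, wl_min, wl_max, channels,
                               bands = data.frame(center = numeric(),
                                                  width = numeric(),
                                                  amplitude = numeric()),
                               baseline = 30) {
  if (wl_min >= wl_max) stop("wl_min must be below wl_max")
  if (channels < 2L) stop("need at least 2 channels")
  bands <- as.data.frame(bands)
  if (nrow(bands) && any(bands$amplitude < 0))
    stop("band amplitudes must be >= 0")
  structure(list(name = name, wl_min = wl_min, wl_max = wl_max,
                 channels = as.integer(channels), bands = bands,
                 baseline = baseline),
            class = "instrument_profile")
}

#' @rdname instrument_profile
#' @export
avaspec_like <- function() {
  instrument_profile(
    name = "avaspec_like", wl_min = 972, wl_max = 1701, channels = 236L,
    bands = data.frame(
      center = c(1050, 1300, 1650),
      width = c(70, 110, 80),
      amplitude = c(12, 25, 10)),
    baseline = 18)
}

#' @rdname instrument_profile
#' @export
neospectra_like <- function() {
  instrument_profile(
    name = "neospectra_like", wl_min = 1351, wl_max = 2559, channels = 74L,
    bands = data.frame(
      center = c(1550, 2150, 2500),
      width = c(120, 160, 90),
      amplitude = c(10, 6, 3)),
    baseline = 6)
}

#' Base (noise-free) spectrum of an instrument profile
#'
#' `mu_j = baseline + sum_bands amplitude * exp(-(wl_j - center)^2 /
#' (2 width^2))` on p equally spaced wavelengths. Absorption features are
#' encoded as negative-amplitude bands (reflectance dips); the result must
#' stay strictly positive so that shot noise (variance proportional to the
#' signal) is well defined.
#'
#' @param profile an [instrument_profile()].
#' @return Named numeric p-vector, %R; attribute `"wavelengths"` holds the
#'   axis.
#' @export
base_spectrum <- function(profile) {
  stopifnot(inherits(profile, "instrument_profile"))
  wl <- seq(profile$wl_min, profile$wl_max, length.out = profile$channels)
  mu <- rep(profile$baseline, profile$channels)
  if (nrow(profile$bands)) {
    for (b in seq_len(nrow(profile$bands))) {
      mu <- mu + profile$bands$amplitude[b] *
        exp(-(wl - profile$bands$center[b])^2 /
              (2 * profile$bands$width[b]^2))
    }
  }
  if (any(mu <= 0))
    stop("base spectrum must be strictly positive; adjust baseline/bands")
  names(mu) <- format_wl(wl)
  attr(mu, "wavelengths") <- wl
  mu
}

#' Noise model for simulated replicate spectra
#'
#' Variance components of the generative model, all Gaussian:
#' per-replicate offset (additive constant over the spectrum, sd
#' `sigma_offset` %R), per-replicate gain error (multiplies the base
#' spectrum, sd `sigma_mult`), shot-like channel noise (variance
#' proportional to the signal, coefficient `sigma_shot`), independent
#' channel noise (sd `sigma_iid` %R), a per-session offset (sd
#' `sigma_session` %R), and an extra offset for sessions whose background
#' was taken once at session start (mode B; sd `delta_background` %R).
#'
#' @param sigma_offset,sigma_mult,sigma_shot,sigma_iid,sigma_session,delta_background
#'   non-negative standard deviations / coefficients (see above).
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(sigma_offset = 0.5, sigma_mult = 0.02,
                        sigma_shot = 0.05, sigma_iid = 0.05,
                        sigma_session = 0.3, delta_background = 0.4) {
  vals <- c(sigma_offset, sigma_mult, sigma_shot, sigma_iid,
            sigma_session, delta_background)
  if (any(vals < 0)) stop("all noise parameters must be >= 0")
  structure(list(sigma_offset = sigma_offset, sigma_mult = sigma_mult,
                 sigma_shot = sigma_shot, sigma_iid = sigma_iid,
                 sigma_session = sigma_session,
                 delta_background = delta_background),
            class = "noise_model")
}

#' Replication design for the synthetic generator
#'
#' The default mirrors a two-background-mode replication study: for each
#' sample, `sessions_per_mode` sessions under background mode A (background
#' before each sample) and the same number under mode B (background at
#' session start), with `replicates` repositioning replicates per session.
#' Defaults (3 + 3 sessions x 15 replicates) give 90 rows per sample.
#'
#' @param samples character vector of sample labels.
#' @param sessions_per_mode sessions per background mode (>= 1).
#' @param replicates replicates per session (>= 1).
#' @param instrument an [instrument_profile()].
#' @return An object of class `design_spec`.
#' @export
design_spec <- function(samples = c("sugar_lump", "granulated_sugar"),
                        sessions_per_mode = 3L, replicates = 15L,
                        instrument = neospectra_like()) {
  stopifnot(inherits(instrument, "instrument_profile"))
  if (sessions_per_mode < 1L || replicates < 1L)
    stop("sessions_per_mode and replicates must be >= 1")
  structure(list(samples = as.character(samples),
                 sessions_per_mode = as.integer(sessions_per_mode),
                 replicates = as.integer(replicates),
                 instrument = instrument),
            class = "design_spec")
}

#' Simulate a replicated-spectra dataset
#'
#' Draws, for sample s and replicate i in session k,
#' \deqn{x_{ij} = \mu^{(s)}_j (1 + m_i) + o_i + u_k + b_k +
#'   \sigma_{shot} \sqrt{\mu^{(s)}_j}\, \eta_{ij} + \epsilon_{ij}}
#' with `m_i ~ N(0, sigma_mult^2)`, `o_i ~ N(0, sigma_offset^2)` per
#' replicate, `u_k ~ N(0, sigma_session^2)` drawn once per session,
#' `b_k ~ N(0, delta_background^2)` drawn once per mode-B session (0 for
#' mode A), and `eta`, `epsilon` iid standard normal scaled by
#' `sigma_shot sqrt(mu_j)` and `sigma_iid`. Deterministic for a fixed
#' seed. Sessions are labeled `1A..3A, 1B..3B`; session effects are shared
#' across samples measured in the same session.
#'
#' @param design a [design_spec()].
#' @param noise a [noise_model()].
#' @param sample_effects optional named list (one entry per sample) of
#'   `list(gain =, offset =)` tweaks applied to the base spectrum, so the
#'   samples differ in level/amplitude as physical samples would.
#' @param seed integer seed (mandatory: simulations must be reproducible).
#' @return A [spectra_dataset()] with full metadata.
#' @examples
#' ds <- simulate_dataset(design_spec(samples = "sugar_lump"),
#'                        noise_model(), seed = 1)
#' dim(ds)  # 90 x 74
#' @export
simulate_dataset <- function(design, noise, sample_effects = NULL,
                             seed) {
  stopifnot(inherits(design, "design_spec"), inherits(noise, "noise_model"))
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(as.integer(seed))

  mu0 <- base_spectrum(design$instrument)
  wl <- attr(mu0, "wavelengths")
  p <- length(mu0)
  S <- design$sessions_per_mode
  sessions <- data.frame(
    session_id = c(paste0(seq_len(S), "A"), paste0(seq_len(S), "B")),
    background_mode = rep(c("A", "B"), each = S))
  sessions$u <- stats::rnorm(nrow(sessions), 0, noise$sigma_session)
  sessions$b <- ifelse(sessions$background_mode == "B",
                       stats::rnorm(nrow(sessions), 0, noise$delta_background),
                       0)

  rows <- list(); metas <- list(); idx <- 0L
  for (s in design$samples) {
    eff <- sample_effects[[s]]
    mu <- as.numeric(mu0)
    if (!is.null(eff)) {
      if (!is.null(eff$gain)) mu <- mu * eff$gain
      if (!is.null(eff$offset)) mu <- mu + eff$offset
    }
    if (any(mu <= 0)) stop("sample effect drives base spectrum below 0")
    for (k in seq_len(nrow(sessions))) {
      nr <- design$replicates
      m <- stats::rnorm(nr, 0, noise$sigma_mult)
      o <- stats::rnorm(nr, 0, noise$sigma_offset)
      eta <- matrix(stats::rnorm(nr * p), nr, p)
      eps <- matrix(stats::rnorm(nr * p), nr, p)
      Xk <- outer(1 + m, mu) + o + sessions$u[k] + sessions$b[k] +
        sweep(eta, 2L, noise$sigma_shot * sqrt(mu), "*") +
        noise$sigma_iid * eps
      idx <- idx + 1L
      rows[[idx]] <- Xk
      metas[[idx]] <- data.frame(
        sample_id = s,
        session_id = sessions$session_id[k],
        background_mode = sessions$background_mode[k],
        replicate_index = seq_len(nr),
        instrument_id = design$instrument$name)
    }
  }
  suppressWarnings(
    spectra_dataset(do.call(rbind, rows), wl, do.call(rbind, metas)))
}

#' Theoretical error covariance of the noise model
#'
#' Closed-form covariance of the replicate error implied by
#' [simulate_dataset()]'s generative model, for a given grouping of
#' replicates:
#' \deqn{\Sigma = \sigma_{off}^2 J + \sigma_{mult}^2 \mu\mu' +
#'   \sigma_{shot}^2 \,\mathrm{diag}(\mu) + \sigma_{iid}^2 I \;(+\;
#'   \mathrm{between\mbox{-}session\ terms})}
#' with `J` the all-ones matrix. Grouping by session removes the session
#' and background offsets; groupings that pool across sessions keep them,
#' adding `(sigma_session^2 + w_B * delta_background^2) * J`, where `w_B`
#' is the fraction of pooled replicates measured under mode B (1 for a
#' pure mode-B pool, 0 for mode A). The between-session term is the
#' many-sessions idealization: with a small number of pooled sessions the
#' estimated session contribution is deflated by the estimation of the
#' pooled mean.
#'
#' @param noise a [noise_model()].
#' @param mu base spectrum p-vector (from [base_spectrum()], possibly with
#'   sample effects applied).
#' @param grouping `"per_session"`, `"per_background_mode"`, or `"all"`.
#' @param mode for `grouping = "per_background_mode"`: which mode the pool
#'   is, `"A"` or `"B"`.
#' @param prop_b for `grouping = "all"`: fraction of replicates under mode
#'   B (default 0.5, the balanced design).
#' @return An [error_covariance()] with `n_effective = NA` (population
#'   quantity).
#' @export
theoretical_ecm <- function(noise, mu,
                            grouping = c("per_session",
                                         "per_background_mode", "all"),
                            mode = NULL, prop_b = 0.5) {
  stopifnot(inherits(noise, "noise_model"))
  grouping <- match.arg(grouping)
  wl <- attr(mu, "wavelengths")
  mu <- as.numeric(mu)
  p <- length(mu)
  J <- matrix(1, p, p)
  sigma <- noise$sigma_offset^2 * J +
    noise$sigma_mult^2 * tcrossprod(mu) +
    noise$sigma_shot^2 * diag(mu, p) +
    noise$sigma_iid^2 * diag(p)
  if (grouping == "per_background_mode") {
    if (is.null(mode) || !mode %in% c("A", "B"))
      stop("per_background_mode needs mode = 'A' or 'B'")
    extra <- noise$sigma_session^2 +
      if (mode == "B") noise$delta_background^2 else 0
    sigma <- sigma + extra * J
  } else if (grouping == "all") {
    sigma <- sigma +
      (noise$sigma_session^2 + prop_b * noise$delta_background^2) * J
  }
  structure(list(sigma = sigma, n_effective = NA_integer_,
                 wavelengths = if (is.null(wl)) seq_len(p) else wl),
            class = "error_covariance")
}
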