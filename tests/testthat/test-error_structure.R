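test_that("the error matrix subtracts group means", {
  # two replicates a, b in one group: errors +/- (a-b)/2
  ds <- toy_dataset(rbind(c(4, 10), c(2, 6)))
  E <- error_matrix(ds, replicate_grouping(ds, "all"))
  expect_equal(unname(E$E), rbind(c(1, 2), c(-1, -2)))
  expect_equal(E$flavor, "replicate_error")

  # zero-noise dataset: E = 0
  quiet <- simulate_dataset(design_spec(samples = "s", replicates = 3L),
                            noise_model(0, 0, 0, 0, 0, 0), seed = 1)
  Eq <- error_matrix(quiet, replicate_grouping(quiet, "per_session"))
  expect_equal(max(abs(Eq$E)), 0)

  # within each group, columns sum to zero; rank <= n - #groups
  ds6 <- sim_small(seed = 3, replicates = 5L, sessions = 1L)
  gr <- replicate_grouping(ds6, "per_session")
  E6 <- error_matrix(ds6, gr)
  for (lev in levels(gr$groups))
    expect_equal(max(abs(colSums(E6$E[gr$groups == lev, , drop = FALSE]))),
                 0, tolerance = 1e-10)
  expect_lte(qr(E6$E)$rank, nrow(E6$E) - E6$n_groups)

  # singleton groups are refused by name
  m <- toy_meta(3); m$session_id <- c("1A", "1A", "2A")
  bad <- suppressWarnings(spectra_dataset(matrix(runif(6, 1, 9), 3),
                                          c(1100, 1200), m))
  expect_error(error_matrix(bad, replicate_grouping(bad, "per_session")),
               "2A")
})

test_that("grand residuals center on the overall mean and differ from grouped errors by group offsets", {
  ds <- sim_small(seed = 4, replicates = 4L, sessions = 1L)
  Ehat <- residual_matrix(ds)
  expect_equal(Ehat$flavor, "grand_residual")
  expect_equal(max(abs(colSums(Ehat$E))), 0, tolerance = 1e-10)

  same <- toy_dataset(rbind(c(3, 4), c(3, 4)))
  expect_equal(max(abs(residual_matrix(same)$E)), 0)

  # one sample, grouping = all: E and Ehat coincide
  gr <- replicate_grouping(ds, "all")
  expect_equal(error_matrix(ds, gr)$E, Ehat$E)

  # two groups with distinct means: row differences equal the group-mean offset
  X <- rbind(matrix(5, 3, 2), matrix(9, 3, 2)) + matrix(rnorm(12), 6, 2)
  m <- toy_meta(6); m$session_id <- rep(c("1A", "2A"), each = 3)
  ds2 <- suppressWarnings(spectra_dataset(X, c(1100, 1200), m))
  Eg <- error_matrix(ds2, replicate_grouping(ds2, "per_session"))$E
  Er <- residual_matrix(ds2)$E
  offs <- Er - Eg
  grand <- colMeans(X)
  for (g in 1:2) {
    rows <- if (g == 1) 1:3 else 4:6
    expected <- colMeans(X[rows, ]) - grand
    for (r in rows) expect_equal(unname(offs[r, ]), unname(expected),
                                 tolerance = 1e-12)
  }
})

test_that("the pooled covariance matches hand computation and stays PSD", {
  ds <- toy_dataset(rbind(c(1, 1), c(-1, -1)) + 5)  # errors [1,1], [-1,-1]
  E <- error_matrix(ds, replicate_grouping(ds, "all"))
  S <- error_covariance(E)
  expect_equal(S$n_effective, 1L)
  expect_equal(unname(S$sigma), matrix(2, 2, 2))

  zero <- toy_dataset(rbind(c(4, 4), c(4, 4)))
  S0 <- error_covariance(error_matrix(zero, replicate_grouping(zero, "all")))
  expect_equal(max(abs(S0$sigma)), 0)

  set.seed(8)
  for (i in 1:5) {
    ds_r <- toy_dataset(matrix(rnorm(60, 30, 4), 10, 6))
    S_r <- error_covariance(residual_matrix(ds_r))
    ev <- eigen(S_r$sigma, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-10 * max(ev))
  }
})

test_that("offset-only noise yields a flat rank-1 covariance", {
  nm <- noise_model(sigma_offset = 0.5, sigma_mult = 0, sigma_shot = 0,
                    sigma_iid = 0, sigma_session = 0, delta_background = 0)
  ds <- simulate_dataset(design_spec(samples = "s", sessions_per_mode = 1L,
                                     replicates = 100L), nm, seed = 10)
  S <- error_covariance(error_matrix(ds, replicate_grouping(ds, "per_session")))
  expect_equal(mean(S$sigma), 0.25, tolerance = 0.2)
  expect_lt(diff(range(S$sigma)) / mean(S$sigma), 1e-8)  # all entries equal
})

test_that("correlation normalizes, excludes dead channels, and handles rank-1", {
  S <- structure(list(sigma = matrix(2, 2, 2), n_effective = 1L,
                      wavelengths = c(1100, 1200)),
                 class = "error_covariance")
  R <- error_correlation(S)
  expect_equal(unname(R$R), matrix(1, 2, 2))

  Sd <- S; Sd$sigma <- diag(c(3, 7))
  expect_equal(unname(error_correlation(Sd)$R), diag(2))

  v <- c(1, 2, 3)
  Sr <- structure(list(sigma = tcrossprod(v), n_effective = 1L,
                       wavelengths = c(1, 2, 3)), class = "error_covariance")
  expect_equal(unname(error_correlation(Sr)$R), matrix(1, 3, 3),
               tolerance = 1e-12)

  Sz <- S; Sz$sigma <- diag(c(4, 0)); Sz$wavelengths <- c(1100, 1200)
  expect_warning(Rz <- error_correlation(Sz), "zero-variance")
  expect_equal(Rz$excluded, 2L)
  expect_equal(Rz$wavelengths, 1100)
  Sall0 <- S; Sall0$sigma <- matrix(0, 2, 2)
  expect_error(error_correlation(Sall0), "zero error variance")
})

test_that("covariance diagonals track the generative noise shape", {
  base <- base_spectrum(neospectra_like())
  mu <- as.numeric(base)

  shot <- noise_model(0, 0, sigma_shot = 0.3, 0, 0, 0)
  ds_s <- simulate_dataset(design_spec(samples = "s", sessions_per_mode = 1L,
                                       replicates = 250L), shot, seed = 11)
  d_s <- covariance_diagonal(error_covariance(
    error_matrix(ds_s, replicate_grouping(ds_s, "per_session"))))
  expect_gt(cor(d_s, mu, method = "spearman"), 0.95)

  mult <- noise_model(0, sigma_mult = 0.05, 0, 0, 0, 0)
  ds_m <- simulate_dataset(design_spec(samples = "s", sessions_per_mode = 1L,
                                       replicates = 250L), mult, seed = 12)
  d_m <- covariance_diagonal(error_covariance(
    error_matrix(ds_m, replicate_grouping(ds_m, "per_session"))))
  expect_gt(cor(d_m, mu^2, method = "spearman"), 0.95)

  iid <- noise_model(0, 0, 0, sigma_iid = 0.2, 0, 0)
  ds_i <- simulate_dataset(design_spec(samples = "s", sessions_per_mode = 1L,
                                       replicates = 400L), iid, seed = 13)
  d_i <- covariance_diagonal(error_covariance(
    error_matrix(ds_i, replicate_grouping(ds_i, "per_session"))))
  expect_lt(sd(d_i) / mean(d_i), 0.25)  # near-constant diagonal
  expect_equal(mean(d_i), 0.04, tolerance = 0.15)
})

test_that("with grouping=all the covariance spectrum equals the residual PCA spectrum", {
  set.seed(14)
  ds <- toy_dataset(matrix(rnorm(80, 40, 6), 10, 8))
  Ehat <- residual_matrix(ds)
  S <- error_covariance(Ehat)
  frac_sigma <- {
    ev <- eigen(S$sigma, symmetric = TRUE, only.values = TRUE)$values
    ev <- pmax(ev, 0); ev / sum(ev)
  }
  m <- fit_pca(ds$X, k = 8)
  frac_pca <- m$eigenvalues / sum(m$eigenvalues)
  expect_equal(frac_sigma[1:8], frac_pca, tolerance = 1e-10)
})
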