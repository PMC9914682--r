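test_that("PCA recovers exact low-rank structure and a complete basis", {
  # data on one line through its mean: one component, 100% variance
  set.seed(1)
  t <- rnorm(10)
  d <- runif(4)
  X <- 5 + outer(t, d)
  m1 <- fit_pca(X, 1)
  expect_equal(m1$explained, 1, tolerance = 1e-12)

  # full-rank reconstruction reproduces the centered data
  X <- matrix(rnorm(60), 10, 6)
  mf <- fit_pca(X, 6)
  Xc <- sweep(X, 2, colMeans(X))
  expect_equal(mf$scores %*% t(mf$loadings), Xc, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(crossprod(mf$loadings), diag(6), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_true(all(diff(mf$eigenvalues) <= 1e-10))

  # sign convention: the largest-magnitude loading element is positive
  expect_true(all(apply(mf$loadings, 2,
                        function(v) v[which.max(abs(v))] > 0)))
  expect_error(fit_pca(X, 10), "min\\(n-1, p\\)")
})

test_that("PC1 separates two well-separated clusters", {
  set.seed(2)
  X <- rbind(matrix(rnorm(40, 0), 10), matrix(rnorm(40, 10), 10))
  m <- fit_pca(X, 1)
  s <- m$scores[, 1]
  expect_true(all(sign(s[1:10]) == sign(s[1])) &&
                all(sign(s[11:20]) == -sign(s[1])))
})

test_that("T2 and Q match their definitions on simple cases", {
  set.seed(3)
  X <- matrix(rnorm(50, 20, 2), 10, 5)
  m <- fit_pca(X, 1)

  # the center has T2 = 0 and contributions 0
  expect_equal(t2_statistic(m, matrix(m$center, 1)), 0, tolerance = 1e-18)
  ctr <- pca_contributions(m, m$center)
  expect_equal(ctr$t2, rep(0, 5), tolerance = 1e-18)
  expect_equal(ctr$q, rep(0, 5), tolerance = 1e-18)

  # one retained component: T2 = t^2 / lambda, Q = ||residual||^2
  x <- X[3, ]
  xc <- x - m$center
  t <- sum(xc * m$loadings[, 1])
  expect_equal(t2_statistic(m, matrix(x, 1)), t^2 / m$eigenvalues[1])
  r <- xc - t * m$loadings[, 1]
  expect_equal(q_statistic(m, matrix(x, 1)), sum(r^2))

  # a sample lying exactly in the retained subspace has Q = 0
  inplane <- m$center + 2.5 * m$loadings[, 1]
  expect_equal(q_statistic(m, matrix(inplane, 1)), 0, tolerance = 1e-18)

  # full-rank model: Q = 0 for all training samples
  mfull <- fit_pca(X, 5)
  expect_equal(q_statistic(mfull, X), rep(0, 10), tolerance = 1e-16)
  expect_equal(q_statistic(mfull), rep(0, 10), tolerance = 1e-16)
})

test_that("contributions sum exactly to their statistics and localize spikes", {
  set.seed(4)
  X <- matrix(rnorm(200, 30, 3), 20, 10)
  m <- fit_pca(X, 3)
  x <- X[7, ]
  ctr <- pca_contributions(m, x)
  expect_equal(sum(ctr$q), q_statistic(m, matrix(x, 1)), tolerance = 1e-10)
  expect_equal(sum(ctr$t2), t2_statistic(m, matrix(x, 1)), tolerance = 1e-10)

  spiked <- m$center
  spiked[4] <- spiked[4] + 50
  expect_equal(which.max(pca_contributions(m, spiked)$q), 4L)
})

test_that("control limits follow their closed forms and limiting cases", {
  set.seed(5)
  X <- matrix(rnorm(10000, 0, 1), 1000, 10)
  m1 <- fit_pca(X, 1)
  lim <- control_limits(m1, alpha = 0.05)
  expect_equal(lim$t2_limit, qchisq(0.95, 1), tolerance = 0.02)

  # alpha -> 1 drives both limits toward 0
  lax <- control_limits(m1, alpha = 0.9999)
  expect_lt(lax$t2_limit, 0.01)
  expect_lt(lax$q_limit, lim$q_limit)

  mfull <- fit_pca(matrix(rnorm(50), 10, 5), 5)
  expect_equal(control_limits(mfull)$q_limit, 0)
  expect_error(control_limits(fit_pca(matrix(rnorm(20), 4, 5), 3),
                              alpha = 2), "alpha")
})

test_that("flagging rules combine the two statistics as documented", {
  fake <- structure(list(t2 = c(10, 10, 1), q = c(10, 1, 10),
                         t2_limit = 5, q_limit = 5, alpha = 0.05,
                         exceeds_t2 = c(TRUE, TRUE, FALSE),
                         exceeds_q = c(TRUE, FALSE, TRUE)),
                    class = "screen_result")
  expect_equal(flag_outliers(fake, "both"), c(TRUE, FALSE, FALSE))
  expect_equal(flag_outliers(fake, "either"), c(TRUE, TRUE, TRUE))
})

test_that("a grossly shifted replicate is flagged on both statistics", {
  # monitoring protocol: model the reference replicates, then screen new
  # spectra; a spectrum shifted by +10 sigma on all channels departs both
  # within the model plane (T2) and away from it (Q)
  nm <- noise_model(sigma_offset = 0, sigma_mult = 0.02, sigma_shot = 0.05,
                    sigma_iid = 0.05, sigma_session = 0, delta_background = 0)
  ds <- sim_small(seed = 9, replicates = 15L, sessions = 1L, noise = nm)
  s1 <- subset_spectra(ds, session_id == "1A")
  X <- s1$X
  sigma_typ <- mean(apply(X, 2, sd))
  Xnew <- rbind(X, X[7, ] + 10 * sigma_typ)
  m <- fit_pca(X, 2)
  sr <- screen_outliers(m, Xnew, alpha = 0.05)
  flags <- flag_outliers(sr, "both")
  expect_equal(which(flags), 16L)
})

test_that("statistics are invariant to the arbitrary loading sign", {
  set.seed(6)
  X <- matrix(rnorm(120, 10, 2), 20, 6)
  m <- fit_pca(X, 2)
  m2 <- m
  m2$loadings <- -m2$loadings
  m2$scores <- -m2$scores
  expect_equal(t2_statistic(m2, X), t2_statistic(m, X))
  expect_equal(q_statistic(m2, X), q_statistic(m, X))
})
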