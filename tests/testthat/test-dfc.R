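test_that("analytic envelope recovers tone amplitude and modulation", {
  x <- tone(10, amp = 2.5)
  env <- analyticEnvelope(x)
  interior <- 300:2700
  expect_lt(max(abs(env[interior] / 2.5 - 1)), 0.02)

  t <- seq_len(500 * 6) / 500
  profile <- 1 + 0.5 * sin(2 * pi * 0.5 * t)
  am <- profile * sin(2 * pi * 10 * t)
  env_am <- analyticEnvelope(am)
  expect_gt(cor(env_am[interior], profile[interior]), 0.99)
})

test_that("envelope is invariant to carrier phase shift", {
  e1 <- analyticEnvelope(tone(10, phase = 0))
  e2 <- analyticEnvelope(tone(10, phase = pi / 2))
  interior <- 300:2700
  expect_lt(max(abs(e1[interior] - e2[interior])), 0.02)
})

test_that("constant channels are rejected", {
  expect_error(analyticEnvelope(rep(0.7, 100) * 0), "zero-variance")
})

test_that("orthogonalization removes collinear content and keeps independent content", {
  set.seed(2)
  x <- iacdfc:::band_limited_noise(4000, 500, 13, 30)
  ax <- analyticSignal(x)
  # y = 2x: nothing survives
  o <- orthogonalizePair(ax, 2 * ax)
  expect_lt(sqrt(mean(o^2)) / sqrt(mean(Mod(2 * ax)^2)), 1e-6)
  # independent y: |Y_perp_X| = |y| |sin(phase difference)|, and for
  # independent narrowband signals E[sin^2] = 1/2, so about 1/sqrt(2) of
  # the RMS survives (vs ~0 for the collinear pair above) and the
  # orthogonalized magnitude still tracks the envelope of y
  y <- iacdfc:::band_limited_noise(4000, 500, 13, 30)
  ay <- analyticSignal(y)
  env_o <- abs(orthogonalizePair(ax, ay))
  rms_ratio <- sqrt(mean(env_o^2)) / sqrt(mean(Mod(ay)^2))
  expect_gt(rms_ratio, 0.55)
  expect_lt(rms_ratio, 0.85)
  expect_gt(cor(env_o, Mod(ay)), 0.3)
})

test_that("envelope standardization has mean 0, variance 1 and is scale-free", {
  set.seed(3)
  E <- abs(matrix(rnorm(3 * 1000), 3)) + 0.1
  es <- normalizeEnvelope(E, trim = 50)
  expect_equal(ncol(es$env), 900)
  for (i in 1:3) {
    expect_lt(abs(mean(es$env[i, ])), 1e-10)
    expect_lt(abs(mean(es$env[i, ]^2) - 1), 1e-10)
  }
  es2 <- normalizeEnvelope(E * c(7, 1, 1), trim = 50)
  expect_equal(es$env, es2$env, tolerance = 1e-12)
  expect_error(normalizeEnvelope(matrix(1, 2, 100)), "zero-variance")
  expect_error(normalizeEnvelope(E, trim = 500), "trim")
})

test_that("time-averaged IAC equals the Pearson correlation of the envelopes", {
  set.seed(6)
  E <- abs(matrix(rnorm(5 * 2000), 5)) + 0.05
  es <- normalizeEnvelope(E)
  tens <- computeIac(es)
  for (p in seq_len(ncol(tens$pairs))) {
    i <- tens$pairs[1, p]; j <- tens$pairs[2, p]
    expect_lt(abs(mean(tens$values[p, ]) - cor(E[i, ], E[j, ])), 1e-10)
  }
  # a standardized envelope against itself has time-mean product exactly 1
  expect_lt(abs(mean(es$env[1, ] * es$env[1, ]) - 1), 1e-10)
})

test_that("per-sample matrices are symmetric with an excluded diagonal", {
  rec <- generateSubject(tiny_spec(seed = 8, n_channels = 5, duration = 3))
  tens <- iacFromBand(rec$data, orthogonalize = TRUE, band = "beta")
  M <- iacMatrixAt(tens, 77)
  expect_true(all(is.na(diag(M))))
  expect_identical(M, t(M))
})

test_that("leakage suppression: scaled copies decorrelate only when orthogonalized", {
  set.seed(10)
  x <- iacdfc:::band_limited_noise(6000, 500, 13, 30)
  X <- rbind(x, -3.2 * x)
  t_orth <- iacFromBand(X, orthogonalize = TRUE)
  expect_lt(abs(mean(t_orth$values)), 0.02)
  t_raw <- iacFromBand(X, orthogonalize = FALSE)
  expect_gt(mean(t_raw$values), 0.98)
})

test_that("orthogonalization reduces mixing-induced spurious IAC", {
  mean_abs_iac <- function(orth) {
    sp <- subjectSpec(n_channels = 6, duration = 6, coupling = 0,
                      mixing_strength = 0.3, noise_sd = 0, burst_rate = 0,
                      seed = 14)
    rec <- generateSubject(sp)
    beta <- bandDecompose(rec)$bands$beta
    tens <- iacFromBand(beta, orthogonalize = orth)
    mean(abs(rowMeans(tens$values)))
  }
  expect_lt(mean_abs_iac(TRUE), mean_abs_iac(FALSE))
})

test_that("time-mean IAC increases with envelope coupling", {
  mean_iac <- function(cc) {
    rec <- generateSubject(tiny_spec(seed = 19, coupling = cc, duration = 5))
    mean(iacFromBand(rec$data, orthogonalize = TRUE)$values)
  }
  v <- vapply(c(0, 0.4, 0.8), mean_iac, numeric(1))
  expect_true(all(diff(v) > 0))
})

test_that("compiled and reference aS paths agree to numerical precision", {
  rec <- generateSubject(tiny_spec(seed = 23, n_channels = 7, duration = 4,
                                   beta_only = FALSE))
  beta <- bandDecompose(preprocessRecording(rec, order = 300),
                        order = 300)$bands$beta
  for (orth in c(TRUE, FALSE)) {
    a_cpp <- asSeriesFromBand(beta, orthogonalize = orth, engine = "cpp")
    a_r <- asSeriesFromBand(beta, orthogonalize = orth, engine = "r")
    expect_lt(max(abs(a_cpp$values - a_r$values)), 1e-10)
  }
})

test_that("trim policy controls the retained sample count", {
  rec <- generateSubject(tiny_spec(seed = 4, duration = 4))
  tens <- iacFromBand(rec$data, trim = 250)
  expect_equal(ncol(tens$values), 2000L - 500L)
  s <- asSeriesFromBand(rec$data, trim = 250)
  expect_length(s$values, 1500L)
})
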