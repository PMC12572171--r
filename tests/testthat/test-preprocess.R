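test_that("FIR design matches the stated vocabulary", {
  f <- designFir(0.5, 98, order = 500, fs = 500)
  expect_length(f$coef, 501)
  # passband gain at 10 Hz within +/- 1 dB
  g10 <- 20 * log10(firResponse(f, 10))
  expect_lt(abs(g10), 1)
  # for a band whose lower edge is far from DC (beta: 13 Hz, transition
  # width ~3 Hz at order 500), DC sits in the stopband, whose floor for a
  # Hamming window is about -50 dB
  beta_f <- designFir(13, 30, order = 500, fs = 500)
  expect_lt(abs(sum(beta_f$coef)), 0.01)

  notch <- designFir(48, 52, order = 500, fs = 500, kind = "notch")
  att <- 20 * log10(firResponse(notch, 50) / firResponse(notch, 40))
  expect_lt(att, -20)
})

test_that("invalid band edges are rejected", {
  expect_error(designFir(0, 40, fs = 500), "edges")
  expect_error(designFir(10, 260, fs = 500), "edges")
  expect_error(designFir(30, 13, fs = 500), "edges")
})

test_that("zero-phase filtering preserves in-band tones and kills notched ones", {
  x10 <- tone(10)
  alpha <- designFir(8, 13, order = 500, fs = 500)
  y <- applyFir(x10, alpha)
  interior <- 1000:2000
  expect_lt(abs(sd(y[interior]) / sd(x10[interior]) - 1), 0.05)

  x50 <- tone(50)
  notch <- designFir(48, 52, order = 500, fs = 500, kind = "notch")
  y50 <- applyFir(x50, notch)
  expect_lt(sd(y50[interior]) / sd(x50[interior]), 0.10)

  expect_equal(applyFir(rep(0, 3000), alpha), rep(0, 3000))
})

test_that("zero-phase contract: no lag between tone and filtered output", {
  x <- tone(10, dur = 4)
  y <- applyFir(x, designFir(8, 13, order = 400, fs = 500))
  interior <- 500:1500
  lags <- -5:5
  cc <- vapply(lags, function(l) {
    cor(x[interior], y[interior + l])
  }, numeric(1))
  expect_equal(lags[which.max(cc)], 0)
})

test_that("fft-based zero-phase application matches signal::filtfilt", {
  set.seed(4)
  x <- rnorm(3000)
  f <- designFir(8, 13, order = 200, fs = 500)
  y1 <- applyFir(x, f)
  y2 <- signal::filtfilt(signal::Ma(f$coef), x)
  # interior samples; the two differ only in edge-padding treatment
  expect_lt(max(abs(y1[500:2500] - y2[500:2500])), 1e-8)
})

test_that("filtering preserves shape and checks the sampling rate", {
  rec <- eegRecording(matrix(rnorm(3 * 2000), 3), fs = 500)
  f <- designFir(8, 13, order = 300, fs = 500)
  out <- applyFir(rec, f)
  expect_equal(dim(out$data), dim(rec$data))
  f2 <- designFir(8, 13, order = 300, fs = 250)
  expect_error(applyFir(rec, f2), "fs")
})

test_that("segment selection slices exactly and validates bounds", {
  rec <- eegRecording(matrix(rnorm(2 * 120 * 500), 2), fs = 500)
  seg <- selectSegment(rec, start = 30, duration = 60)
  expect_equal(ncol(seg$data), 30000L)
  expect_identical(seg$data[, 1], rec$data[, 15001])
  full <- selectSegment(rec, 0, 120)
  expect_identical(full$data, rec$data)
  expect_error(selectSegment(rec, 100, 60), "beyond")
})

test_that("band decomposition yields five same-shape matrices", {
  rec <- eegRecording(matrix(rnorm(3 * 3000), 3), fs = 500)
  bs <- bandDecompose(rec)
  expect_named(bs$bands, c("delta", "theta", "alpha", "beta", "gamma"))
  for (m in bs$bands) expect_equal(dim(m), dim(rec$data))
})

test_that("a 6 Hz tone lands in the theta band only", {
  rec <- eegRecording(rbind(tone(6), tone(6)), fs = 500)
  bs <- bandDecompose(rec)
  interior <- 1500:2000
  amp <- vapply(bs$bands, function(m) sd(m[1, interior]), numeric(1))
  expect_gt(amp[["theta"]] / sd(rec$data[1, interior]), 0.9)
  expect_lt(max(amp[c("delta", "alpha", "beta", "gamma")]) /
              amp[["theta"]], 0.12)
})

test_that("band outputs approximately reconstruct broadband input", {
  set.seed(9)
  rec <- eegRecording(matrix(rnorm(2 * 5000), 2), fs = 500)
  broad <- applyFir(rec, designFir(0.5, 98, order = 500, fs = 500))
  bs <- bandDecompose(broad)
  recon <- Reduce(`+`, bs$bands)
  interior <- 1000:4000
  rel <- sqrt(mean((recon[1, interior] - broad$data[1, interior])^2)) /
    sd(broad$data[1, interior])
  # residual stems from the transition-band crossfades between adjacent bands
  expect_lt(rel, 0.25)
})

test_that("band filters pass their centre and reject their neighbour's", {
  bands <- canonicalBands(500)
  centres <- sqrt(bands$f_lo * bands$f_hi)
  for (b in seq_len(nrow(bands))) {
    f <- designFir(bands$f_lo[b], bands$f_hi[b], order = 500, fs = 500)
    own <- 20 * log10(firResponse(f, centres[b]))
    expect_gt(own, -1)
    for (nb in c(b - 1, b + 1)) {
      if (nb >= 1 && nb <= nrow(bands)) {
        other <- 20 * log10(firResponse(f, centres[nb]))
        expect_lt(other, -20)
      }
    }
  }
})
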