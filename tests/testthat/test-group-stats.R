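test_that("Mann-Whitney U matches the enumerated example and its symmetries", {
  r1 <- mannWhitneyU(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r1$U, 0)
  expect_equal(r1$p, 0.1)

  # interleaved samples: U stays near the null centre n1*n2/2 = 4.5
  r2 <- mannWhitneyU(c(1, 3, 5), c(2, 4, 6))
  expect_lte(abs(r2$U - 4.5), 1.5)

  a <- c(2.3, 5.1, 0.4, 7.7); b <- c(1.1, 6.2, 3.3)
  fwd <- mannWhitneyU(a, b)
  rev_ <- mannWhitneyU(b, a)
  expect_equal(fwd$U, length(a) * length(b) - rev_$U)
  expect_equal(fwd$p, rev_$p)

  expect_error(mannWhitneyU(numeric(0), 1:3), "nonempty")
  expect_error(mannWhitneyU(rep(1, 3), rep(1, 4)), "tied")
})

test_that("exact p equals brute-force enumeration for all n1 + n2 <= 12", {
  set.seed(20)
  for (n1 in 2:5) {
    for (n2 in n1:(12 - n1)) {
      a <- rnorm(n1)
      b <- rnorm(n2, mean = 0.8)
      got <- mannWhitneyU(a, b)
      expect_equal(got$p, brute_mwu_p(a, b), tolerance = 1e-12,
                   info = sprintf("n1=%d n2=%d", n1, n2))
      # ties as well (brute force counts pairs directly, no ranks)
      at <- round(rnorm(n1), 0)
      bt <- round(rnorm(n2), 0)
      if (length(unique(c(at, bt))) > 1) {
        expect_equal(mannWhitneyU(at, bt)$p, brute_mwu_p(at, bt),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("exact p agrees with wilcox.test for tie-free samples", {
  set.seed(21)
  for (i in 1:10) {
    a <- rnorm(sample(3:7, 1))
    b <- rnorm(sample(3:7, 1), mean = 1)
    got <- mannWhitneyU(a, b)
    ref <- wilcox.test(a, b, exact = TRUE)
    expect_equal(got$U, unname(ref$statistic))
    expect_equal(got$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("large samples switch to the tie-corrected normal approximation", {
  set.seed(22)
  a <- rnorm(15); b <- rnorm(15, 1)
  got <- mannWhitneyU(a, b)
  expect_match(got$method, "normal")
  ref <- wilcox.test(a, b, exact = FALSE, correct = FALSE)
  expect_equal(got$p, ref$p.value, tolerance = 1e-10)
})

test_that("effect size r behaves per definition", {
  expect_equal(effectSizeR(50, 10, 10), 0)
  # U = 0 at n1 = n2 = 10: |Z| from null mean 50, SD sqrt(175)
  expect_equal(effectSizeR(0, 10, 10), (50 / sqrt(10 * 10 * 21 / 12)) / sqrt(20))
  expect_equal(effectSizeR(0, 10, 10), effectSizeR(100, 10, 10))
  set.seed(23)
  pooled <- rnorm(20)
  expect_equal(effectSizeR(20, 10, 10, pooled = pooled),
               effectSizeR(80, 10, 10, pooled = pooled))
})

test_that("BH adjustment matches the textbook step-up on random p-vectors", {
  expect_equal(fdrCorrect(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdrCorrect(0.037), 0.037)
  expect_equal(fdrCorrect(rep(1, 5)), rep(1, 5))
  set.seed(24)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    expect_equal(fdrCorrect(p), bh_stepup(p), tolerance = 1e-12)
  }
  # families are corrected independently
  p <- c(0.01, 0.02, 0.03, 0.04, 0.01, 0.02)
  fam <- c(1, 1, 1, 1, 2, 2)
  expect_equal(fdrCorrect(p, fam), c(bh_stepup(p[1:4]), bh_stepup(p[5:6])))
  expect_error(fdrCorrect(c(0.5, 1.2)), "0, 1")
})

test_that("Pearson screen recovers exact and null relationships", {
  tab <- data.frame(subject_id = sprintf("S%d", 1:8), band = "beta",
                    mu = 1:8, sigma = 8:1, phi = rnorm(8), kappa = rnorm(8),
                    cpz = 1:8)
  out <- pearsonScreen(tab, "cpz")
  expect_equal(out$rho[out$cumulant == "mu"], 1)
  expect_equal(out$rho[out$cumulant == "sigma"], -1)
  expect_equal(nrow(out), 4)
  expect_error(pearsonScreen(tab[1:2, ], "cpz"), ">= 3")
})

test_that("Pearson screen holds its nominal type-I error under the null", {
  set.seed(25)
  hits <- vapply(1:1000, function(i) {
    tab <- data.frame(band = "beta", mu = rnorm(11), cpz = rnorm(11))
    pearsonScreen(tab, "cpz", metrics = "mu")$p < 0.05
  }, logical(1))
  expect_gt(mean(hits), 0.03)
  expect_lt(mean(hits), 0.07)
})

test_that("group analysis runs all band x cumulant comparisons per contrast", {
  set.seed(26)
  bands <- c("delta", "theta", "alpha", "beta", "gamma")
  make_grp <- function(g, n, shift = 0) {
    do.call(rbind, lapply(seq_len(n), function(i) {
      data.frame(subject_id = paste0(g, i), group = g, band = bands,
                 mu = rnorm(5) + shift, sigma = abs(rnorm(5)),
                 phi = rnorm(5), kappa = rnorm(5, 3),
                 cpz = if (g == "HC") NA_real_ else abs(rnorm(1, 500, 100)))
    }))
  }
  # shift of 5 SD separates the groups completely with overwhelming
  # probability, so the mu comparisons must survive FDR
  tab <- rbind(make_grp("HC", 8), make_grp("SCZ", 7, shift = 5),
               make_grp("BD", 6))
  res <- runGroupAnalysis(tab, covariate = "cpz")
  expect_equal(nrow(res$comparisons), 40)  # 2 contrasts x 5 bands x 4 metrics
  expect_setequal(unique(res$comparisons$contrast),
                  c("HC vs SCZ", "HC vs BD"))
  expect_true(all(res$comparisons$p_fdr >= 0 & res$comparisons$p_fdr <= 1))
  expect_true(all(res$comparisons$r >= 0 & res$comparisons$r <= 1))
  # strong mu shift in SCZ must survive FDR
  sig <- subset(res$comparisons, contrast == "HC vs SCZ" & cumulant == "mu")
  expect_true(all(sig$flag == "significant"))
  # covariate screen produced for the dosed groups only
  expect_setequal(names(res$screen), c("SCZ", "BD"))
  expect_equal(nrow(res$screen$SCZ), 20)
  expect_error(runGroupAnalysis(tab, contrasts = list(c("HC", "XX"))),
               "missing")
})
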