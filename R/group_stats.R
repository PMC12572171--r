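# Group-level statistics: Mann-Whitney U tests with exact small-sample
# p-values, rank-biserial-style effect size r = |Z|/sqrt(N), BH-FDR
# correction within declared families, and a Pearson screen of each metric
# against a dose covariate.

#' Mann-Whitney U test
#'
#' U is the statistic for the first sample under the rank-sum identity
#' `U = R_a - n1 (n1 + 1) / 2` with midranks for ties (so `U` counts (a, b)
#' pairs with a > b, plus half the ties; `U = 0` when every a is below every
#' b). The two-sided p-value comes from exhaustive enumeration of all
#' `choose(n1 + n2, n1)` group labelings when `n1 + n2 <= exact_limit`
#' (counting labelings at least as far from the null centre `n1 n2 / 2`),
#' and from the tie-corrected normal approximation otherwise (no continuity
#' correction).
#'
#' @param a,b Numeric samples (nonempty).
#' @param exact_limit Largest `n1 + n2` for which enumeration is used
#'   (default 20).
#' @return List: `U`, `p`, `z` (tie-corrected normal deviate), `n1`, `n2`,
#'   `method`.
#' @export
mannWhitneyU <- function(a, b, exact_limit = 20) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0L || length(b) == 0L) stop("both samples must be nonempty", call. = FALSE)
  if (anyNA(a) || anyNA(b)) stop("samples must not contain NA", call. = FALSE)
  n1 <- length(a); n2 <- length(b); n <- n1 + n2
  pooled <- c(a, b)
  r <- rank(pooled)                       # midranks
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  # tie-corrected null SD
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties)
  var_u <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  if (var_u <= 0) stop("all observations are tied: U test degenerate", call. = FALSE)
  z <- (U - mu) / sqrt(var_u)
  if (n <= exact_limit) {
    labelings <- combn(n, n1)
    rs <- colSums(matrix(r[labelings], nrow = n1))
    Us <- rs - n1 * (n1 + 1) / 2
    p <- mean(abs(Us - mu) >= abs(U - mu) - 1e-12)
    method <- "exact enumeration"
  } else {
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal approximation (tie-corrected)"
  }
  list(U = U, p = p, z = z, n1 = n1, n2 = n2, method = method)
}

#' Mann-Whitney effect size r
#'
#' `r = |Z| / sqrt(n1 + n2)`, with Z the (tie-corrected, when pooled data are
#' supplied) normal deviate of U around its null mean `n1 n2 / 2`.
#'
#' @param U Mann-Whitney statistic.
#' @param n1,n2 Sample sizes (>= 1).
#' @param pooled Optional pooled data vector for tie correction of the null
#'   SD; without it the plain SD `sqrt(n1 n2 (n1 + n2 + 1) / 12)` is used.
#' @return Effect size in \[0, 1\].
#' @export
effectSizeR <- function(U, n1, n2, pooled = NULL) {
  stopifnot_scalar(U, "U", lo = 0, hi = n1 * n2)
  n <- n1 + n2
  if (is.null(pooled)) {
    var_u <- n1 * n2 * (n + 1) / 12
  } else {
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties)
    var_u <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  }
  if (var_u <= 0) stop("zero variance: all observations tied", call. = FALSE)
  abs(U - n1 * n2 / 2) / sqrt(var_u) / sqrt(n)
}

#' Benjamini-Hochberg FDR correction within families
#'
#' Step-up adjusted p-values (with the cumulative-minimum monotonicity
#' enforcement), computed separately within each level of `family`.
#'
#' @param p Vector of p-values in \[0, 1\].
#' @param family Optional grouping vector (same length as `p`); `NULL` treats
#'   all p-values as one family.
#' @return Adjusted p-values, same order as the input.
#' @export
fdrCorrect <- function(p, family = NULL) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(family)) return(p.adjust(p, method = "BH"))
  if (length(family) != length(p)) stop("family must match p in length", call. = FALSE)
  out <- numeric(length(p))
  for (f in unique(family)) {
    idx <- which(family == f)
    out[idx] <- p.adjust(p[idx], method = "BH")
  }
  out
}

#' Pearson screen of each metric against a covariate
#'
#' One Pearson correlation (and t-distribution p-value) per band x cumulant
#' between the metric and a per-subject covariate such as a
#' chlorpromazine-equivalent dose.
#'
#' @param cumulant_table Long table from [cohortCumulants()] (columns
#'   `subject_id`, `band`, `mu`, `sigma`, `phi`, `kappa`, and the covariate).
#' @param covariate Name of the covariate column.
#' @param metrics Metric columns to screen.
#' @return Data frame: `band`, `cumulant`, `rho`, `p`, `n`.
#' @export
pearsonScreen <- function(cumulant_table, covariate,
                          metrics = c("mu", "sigma", "phi", "kappa")) {
  if (!covariate %in% names(cumulant_table)) {
    stop("covariate column '", covariate, "' not found", call. = FALSE)
  }
  rows <- list()
  for (band in unique(cumulant_table$band)) {
    sub <- cumulant_table[cumulant_table$band == band, , drop = FALSE]
    for (m in metrics) {
      ok <- complete.cases(sub[[m]], sub[[covariate]])
      x <- sub[[m]][ok]; y <- sub[[covariate]][ok]
      nn <- length(x)
      if (nn < 3L) stop("need >= 3 subjects with metric and covariate", call. = FALSE)
      if (sd(x) == 0 || sd(y) == 0) {
        stop("zero-variance metric or covariate in band ", band, call. = FALSE)
      }
      rho <- cor(x, y)
      tstat <- rho * sqrt((nn - 2) / max(1 - rho^2, .Machine$double.eps))
      pval <- 2 * pt(-abs(tstat), df = nn - 2)
      rows[[length(rows) + 1L]] <- data.frame(
        band = band, cumulant = m, rho = rho, p = min(1, pval), n = nn,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Full group analysis of a cohort cumulant table
#'
#' For each requested contrast (reference group vs comparison group), runs a
#' two-sided Mann-Whitney U test per band x cumulant, corrects within the
#' contrast's own FDR family (all band x cumulant tests of one contrast, 20
#' tests for 5 bands x 4 metrics), and attaches the effect size
#' `r = |Z|/sqrt(N)`. Optionally screens each metric against a covariate
#' within each non-reference group. Results are annotated `significant`
#' (p_fdr below `alpha`) or `tendency` (p_fdr in \[alpha, 2 alpha\)).
#'
#' @param cumulant_table Long table from [cohortCumulants()].
#' @param contrasts List of 2-vectors `c(reference, comparison)`; default:
#'   first group level vs every other group.
#' @param metrics Metric columns to test.
#' @param alpha Significance level (default 0.05).
#' @param covariate Optional covariate column name for the Pearson screen.
#' @param fdr_family `"per-contrast"` (default: one family per contrast) or
#'   `"global"` (all contrasts jointly).
#' @return List with `comparisons` (contrast, band, cumulant, U, p_raw,
#'   p_fdr, r, flag) and `screen` (per non-reference group, or `NULL`).
#' @export
runGroupAnalysis <- function(cumulant_table, contrasts = NULL,
                             metrics = c("mu", "sigma", "phi", "kappa"),
                             alpha = 0.05, covariate = NULL,
                             fdr_family = c("per-contrast", "global")) {
  fdr_family <- match.arg(fdr_family)
  groups <- unique(cumulant_table$group)
  if (length(groups) < 2L) stop("at least 2 groups are required", call. = FALSE)
  if (is.null(contrasts)) {
    contrasts <- lapply(groups[-1], function(g) c(groups[1], g))
  }
  rows <- list()
  for (ct in contrasts) {
    ref <- ct[1]; cmp <- ct[2]
    if (!all(c(ref, cmp) %in% groups)) {
      stop("contrast group missing from the table: ", ref, " vs ", cmp, call. = FALSE)
    }
    for (band in unique(cumulant_table$band)) {
      sub <- cumulant_table[cumulant_table$band == band, , drop = FALSE]
      for (m in metrics) {
        xa <- sub[[m]][sub$group == ref]
        xb <- sub[[m]][sub$group == cmp]
        tst <- mannWhitneyU(xa, xb)
        rows[[length(rows) + 1L]] <- data.frame(
          contrast = paste(ref, "vs", cmp), band = band, cumulant = m,
          n1 = tst$n1, n2 = tst$n2, U = tst$U, p_raw = tst$p,
          r = effectSizeR(tst$U, tst$n1, tst$n2, pooled = c(xa, xb)),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  comparisons <- do.call(rbind, rows)
  fam <- if (fdr_family == "per-contrast") comparisons$contrast else NULL
  comparisons$p_fdr <- fdrCorrect(comparisons$p_raw, family = fam)
  comparisons$flag <- ifelse(comparisons$p_fdr < alpha, "significant",
                             ifelse(comparisons$p_fdr < 2 * alpha, "tendency", ""))
  screen <- NULL
  if (!is.null(covariate) && covariate %in% names(cumulant_table)) {
    screen <- list()
    for (g in setdiff(groups, vapply(contrasts, `[`, "", 1))) {
      sub <- cumulant_table[cumulant_table$group == g, , drop = FALSE]
      if (sum(!is.na(sub[[covariate]])) >= 3 * length(unique(sub$band))) {
        screen[[g]] <- pearsonScreen(sub, covariate, metrics = metrics)
      }
    }
    if (length(screen) == 0L) screen <- NULL
  }
  list(comparisons = comparisons, screen = screen,
       settings = list(alpha = alpha, fdr_family = fdr_family,
                       metrics = metrics))
}
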