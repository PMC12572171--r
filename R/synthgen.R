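# Synthetic EEG cohorts with known envelope-coupling structure.
#
# Each channel's band-limited signal is carrier(t) * envelope(t): the carrier
# is band-limited Gaussian noise (randomized-phase spectrum restricted to the
# band), and the envelope is a convex mixture of a channel-private slow
# positive process and a shared slow modulator, so the fraction of envelope
# variance shared across channels is controlled directly.

#' Specification of one synthetic EEG subject
#'
#' Defaults emulate the recording setup the analysis assumes: 31 electrodes,
#' 500 Hz, 60 s of continuous clean data, with oscillatory power decreasing
#' from the slow to the fast canonical bands.
#'
#' @param n_channels Number of electrodes (default 31).
#' @param fs Sampling rate in Hz (default 500).
#' @param duration Recording length in seconds (default 60); `fs * duration`
#'   must be a whole number of samples.
#' @param amplitude Named numeric vector of per-band carrier amplitudes
#'   (arbitrary units, microvolt scale).
#' @param coupling Per-band envelope coupling `c` in \[0, 1\]: the fraction of
#'   envelope variance shared through the common modulator. A scalar is
#'   recycled across bands.
#' @param burst_rate Rate of burst events in the shared modulator
#'   (events/second, >= 0).
#' @param burst_gain Multiplicative gain applied to the modulator during a
#'   burst (>= 1; 1 disables bursts).
#' @param mixing_strength Fraction in \[0, 1\] of instantaneous cross-channel
#'   leakage (zero-lag linear mixing, emulating volume conduction).
#' @param noise_sd Standard deviation of additive white sensor noise.
#' @param seed Integer seed; generation is a pure function of it.
#' @return A `subject_spec` list.
#' @export
subjectSpec <- function(n_channels = 31, fs = 500, duration = 60,
                        amplitude = c(delta = 20, theta = 10, alpha = 15,
                                      beta = 8, gamma = 4),
                        coupling = 0.3, burst_rate = 0.2, burst_gain = 1.5,
                        mixing_strength = 0.1, noise_sd = 2, seed = 1L) {
  stopifnot_scalar(n_channels, "n_channels", lo = 2)
  stopifnot_scalar(fs, "fs", lo = 1)
  stopifnot_scalar(duration, "duration", lo = .Machine$double.eps)
  n <- fs * duration
  if (abs(n - round(n)) > 1e-9) {
    stop("fs * duration must be an integer sample count", call. = FALSE)
  }
  bands <- canonicalBands(fs)
  if (is.null(names(amplitude))) names(amplitude) <- bands$name[seq_along(amplitude)]
  if (!all(bands$name %in% names(amplitude))) {
    stop("'amplitude' must name every canonical band", call. = FALSE)
  }
  if (length(coupling) == 1L) {
    coupling <- stats::setNames(rep(coupling, nrow(bands)), bands$name)
  }
  if (!all(bands$name %in% names(coupling))) {
    stop("'coupling' must be a scalar or name every canonical band", call. = FALSE)
  }
  if (any(coupling < 0 | coupling > 1)) {
    stop("envelope coupling must lie in [0, 1]", call. = FALSE)
  }
  stopifnot_scalar(mixing_strength, "mixing_strength", lo = 0, hi = 1)
  stopifnot_scalar(burst_rate, "burst_rate", lo = 0)
  stopifnot_scalar(burst_gain, "burst_gain", lo = 1)
  stopifnot_scalar(noise_sd, "noise_sd", lo = 0)
  structure(
    list(n_channels = as.integer(n_channels), fs = fs, duration = duration,
         amplitude = amplitude[bands$name], coupling = coupling[bands$name],
         burst_rate = burst_rate, burst_gain = burst_gain,
         mixing_strength = mixing_strength, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "subject_spec"
  )
}

# Constant-modulus band-limited carrier: the phase track of band-limited
# Gaussian noise, cos(arg(analytic)), unit RMS. Its Hilbert envelope is flat,
# so the envelope of carrier(t) * E(t) is E(t) itself and the envelope
# coupling parameter c maps directly onto measurable envelope correlation.
band_carrier <- function(n, fs, f_lo, f_hi) {
  a <- analyticSignal(band_limited_noise(n, fs, f_lo, f_hi))
  x <- Re(a) / pmax(Mod(a), 1e-300)
  x / sqrt(mean(x^2))
}

# Band-limited Gaussian noise of unit variance via randomized-phase spectrum.
band_limited_noise <- function(n, fs, f_lo, f_hi) {
  freqs <- (seq_len(n) - 1) * fs / n
  half <- 2:(floor(n / 2) + 1)          # positive-frequency bins
  sel <- half[freqs[half] >= f_lo & freqs[half] <= f_hi]
  if (length(sel) < 2L) stop("band too narrow for this length/fs", call. = FALSE)
  X <- complex(real = rep(0, n), imaginary = rep(0, n))
  X[sel] <- complex(real = rnorm(length(sel)), imaginary = rnorm(length(sel)))
  # Hermitian symmetry for a real signal; bin n-k+2 mirrors bin k
  mirror <- n - sel + 2L
  keep <- mirror >= 1L & mirror <= n & mirror != sel
  X[mirror[keep]] <- Conj(X[sel[keep]])
  x <- Re(stats::fft(X, inverse = TRUE)) / n
  s <- sd(x)
  if (s == 0) stop("degenerate band-limited noise", call. = FALSE)
  x / s
}

# Slow positive process: rectified low-pass (< cutoff Hz) Gaussian noise,
# scaled to unit mean.
slow_positive_process <- function(n, fs, cutoff = 1) {
  g <- band_limited_noise(n, fs, fs / n, cutoff)
  m <- abs(g)
  m / mean(m)
}

# Multiplicative burst gain profile: Poisson event times, 250 ms raised-cosine
# bumps, peak gain `burst_gain`.
burst_gain_profile <- function(n, fs, rate, gain, width = 0.25) {
  profile <- rep(0, n)
  duration <- n / fs
  n_events <- rpois(1, rate * duration)
  if (n_events > 0 && gain > 1) {
    times <- runif(n_events, 0, duration)
    half_w <- width / 2
    for (tc in times) {
      idx <- max(1L, ceiling((tc - half_w) * fs)):min(n, floor((tc + half_w) * fs))
      if (length(idx) == 0L) next
      tau <- (idx - 1) / fs - tc
      bump <- 0.5 * (1 + cos(pi * tau / half_w))
      profile[idx] <- pmax(profile[idx], bump)
    }
  }
  1 + (gain - 1) * profile
}

# Random nonnegative row-normalized mixing matrix (symmetric base), fixed per
# cohort; diag 0 so mixing_strength alone sets the self-weight.
random_mixing_matrix <- function(n_channels) {
  A <- matrix(runif(n_channels^2), n_channels)
  A <- (A + t(A)) / 2
  diag(A) <- 0
  A / rowSums(A)
}

#' Generate one synthetic EEG recording
#'
#' Builds a channels x samples matrix as a sum over the canonical bands of
#' constant-modulus randomized-phase carriers (the phase track of
#' band-limited Gaussian noise) modulated by envelopes
#' `E_ch(t) = sqrt(1 - c) * eps_ch(t) + sqrt(c) * m(t)`, where `m` is a shared
#' slow positive modulator (with optional multiplicative bursts) and `eps_ch`
#' are channel-private positive processes. Channels are then linearly mixed by
#' `(1 - mixing_strength) I + mixing_strength M` and white noise is added.
#' Output is a pure function of `spec$seed` (and `mixing_matrix`, if given).
#'
#' The per-band shared modulator traces (after bursts) are attached as
#' `attr(, "modulators")` so envelope-dynamics properties can be checked
#' against the generator's own ground truth.
#'
#' @param spec A [subjectSpec()].
#' @param subject_id,group,covariates Metadata attached to the recording.
#' @param mixing_matrix Optional pre-built mixing matrix (rows sum to 1); when
#'   `NULL` and `mixing_strength > 0`, one is drawn from the subject seed.
#' @return An [eegRecording()] with a `"modulators"` attribute.
#' @export
generateSubject <- function(spec, subject_id = "S1", group = NA_character_,
                            covariates = NULL, mixing_matrix = NULL) {
  stopifnot(inherits(spec, "subject_spec"))
  n <- as.integer(round(spec$fs * spec$duration))
  bands <- canonicalBands(spec$fs)
  with_seed(spec$seed, {
    if (is.null(mixing_matrix) && spec$mixing_strength > 0) {
      mixing_matrix <- random_mixing_matrix(spec$n_channels)
    }
    X <- matrix(0, spec$n_channels, n)
    modulators <- vector("list", nrow(bands))
    names(modulators) <- bands$name
    for (b in seq_len(nrow(bands))) {
      band <- bands$name[b]
      cc <- spec$coupling[[band]]
      m <- slow_positive_process(n, spec$fs)
      m <- m * burst_gain_profile(n, spec$fs, spec$burst_rate, spec$burst_gain)
      modulators[[band]] <- m
      for (ch in seq_len(spec$n_channels)) {
        eps <- slow_positive_process(n, spec$fs)
        env <- sqrt(1 - cc) * eps + sqrt(cc) * m
        carrier <- band_carrier(n, spec$fs, bands$f_lo[b], bands$f_hi[b])
        X[ch, ] <- X[ch, ] + spec$amplitude[[band]] * env * carrier
      }
    }
    if (spec$mixing_strength > 0) {
      W <- (1 - spec$mixing_strength) * diag(spec$n_channels) +
        spec$mixing_strength * mixing_matrix
      X <- W %*% X
    }
    if (spec$noise_sd > 0) {
      X <- X + matrix(rnorm(length(X), sd = spec$noise_sd), nrow(X))
    }
    rec <- eegRecording(X, fs = spec$fs, subject_id = subject_id,
                        group = group, covariates = covariates)
    attr(rec, "modulators") <- modulators
    attr(rec, "seed") <- spec$seed
    rec
  })
}

#' Specification of a synthetic cohort
#'
#' @param groups Named list: one entry per group, each a list with `n`
#'   (subjects, >= 1) and `spec` (a [subjectSpec()]); names are the group
#'   labels and must be unique.
#' @param covariate_fn Optional `function(label, index)` returning a named
#'   numeric vector of covariates for one subject (drawn under the cohort
#'   seed, independently of the dynamics).
#' @param seed Cohort seed; subject seeds are derived from it
#'   deterministically.
#' @return A `cohort_spec` list.
#' @export
cohortSpec <- function(groups, covariate_fn = NULL, seed = 1L) {
  if (is.null(names(groups)) || anyDuplicated(names(groups)) || any(names(groups) == "")) {
    stop("group labels must be unique non-empty names", call. = FALSE)
  }
  for (g in groups) {
    if (!is.list(g) || is.null(g$n) || is.null(g$spec) ||
        !inherits(g$spec, "subject_spec") || g$n < 1) {
      stop("each group needs n >= 1 and a subjectSpec()", call. = FALSE)
    }
  }
  structure(list(groups = groups, covariate_fn = covariate_fn,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# Deterministic subject-seed derivation, kept inside 32-bit integer range.
derive_seed <- function(cohort_seed, k) {
  as.integer((as.double(cohort_seed) * 1000003 + k * 7919) %% 2147483647)
}

#' Generate a synthetic cohort
#'
#' One recording per subject; a single mixing matrix is drawn per cohort (per
#' channel count) so leakage structure is shared, and subject seeds derive
#' deterministically from the cohort seed. The returned list carries a
#' `"manifest"` attribute (subject_id, group, seed, covariates).
#'
#' @param cspec A [cohortSpec()].
#' @return List of [eegRecording()] objects with a `"manifest"` attribute.
#' @export
generateCohort <- function(cspec) {
  stopifnot(inherits(cspec, "cohort_spec"))
  with_seed(cspec$seed, {
    nch <- unique(vapply(cspec$groups, function(g) g$spec$n_channels, integer(1)))
    mixmats <- lapply(stats::setNames(nch, nch), random_mixing_matrix)
    recs <- list()
    rows <- list()
    cov_list <- list()
    k <- 0L
    for (label in names(cspec$groups)) {
      grp <- cspec$groups[[label]]
      for (i in seq_len(grp$n)) {
        k <- k + 1L
        sid <- sprintf("%s_%02d", label, i)
        covs <- if (!is.null(cspec$covariate_fn)) cspec$covariate_fn(label, i) else NULL
        sspec <- grp$spec
        sspec$seed <- derive_seed(cspec$seed, k)
        recs[[sid]] <- generateSubject(
          sspec, subject_id = sid, group = label, covariates = covs,
          mixing_matrix = mixmats[[as.character(sspec$n_channels)]]
        )
        rows[[sid]] <- data.frame(
          subject_id = sid, group = label, seed = sspec$seed,
          stringsAsFactors = FALSE
        )
        cov_list[[sid]] <- covs
      }
    }
    # covariates may exist for only some groups: pad the others with NA so
    # the manifest rows bind into one rectangular table
    cov_names <- unique(unlist(lapply(cov_list, names)))
    for (sid in names(rows)) {
      for (cn in cov_names) {
        v <- cov_list[[sid]]
        rows[[sid]][[cn]] <- if (!is.null(v) && cn %in% names(v)) {
          unname(v[[cn]])
        } else {
          NA_real_
        }
      }
    }
    manifest <- do.call(rbind, rows)
    rownames(manifest) <- NULL
    attr(recs, "manifest") <- manifest
    recs
  })
}
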