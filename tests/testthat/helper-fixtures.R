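# Small fixture builders shared across test files.

# Tiny, fast subject spec: few channels, short duration, single-band power
# optional. Amplitudes default to beta-only so raw-signal envelopes are the
# generator's envelopes exactly.
tiny_spec <- function(seed, n_channels = 6, duration = 6, coupling = 0.3,
                      beta_only = TRUE, ...) {
  amp <- if (beta_only) {
    c(delta = 0, theta = 0, alpha = 0, beta = 8, gamma = 0)
  } else {
    c(delta = 20, theta = 10, alpha = 15, beta = 8, gamma = 4)
  }
  subjectSpec(n_channels = n_channels, duration = duration, amplitude = amp,
              coupling = coupling, mixing_strength = 0, noise_sd = 0,
              burst_rate = 0, seed = seed, ...)
}

# Mean pairwise envelope correlation of the raw generated signal.
mean_env_cor <- function(rec) {
  E <- analyticEnvelope(rec$data)
  C <- cor(t(E))
  mean(C[upper.tri(C)])
}

# Sinusoid sampled at fs for `dur` seconds.
tone <- function(freq, fs = 500, dur = 6, amp = 1, phase = 0) {
  t <- seq_len(fs * dur) / fs
  amp * sin(2 * pi * freq * t + phase)
}

# Independent textbook BH step-up oracle (kept deliberately naive).
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Brute-force two-sided Mann-Whitney p by direct pair counting over all
# labelings (independent of the package's rank-based implementation).
brute_mwu_p <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  n <- length(pooled)
  count_u <- function(x, y) {
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  }
  u_obs <- count_u(a, b)
  mu <- n1 * (n - n1) / 2
  labelings <- combn(n, n1)
  us <- apply(labelings, 2, function(idx) count_u(pooled[idx], pooled[-idx]))
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}
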