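---
title: "Dynamic amplitude-envelope connectivity with iacdfc: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic amplitude-envelope connectivity with iacdfc: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iacdfc)
```

## The scientific problem

Classic amplitude-envelope coupling (AEC) summarizes the co-fluctuation of two
electrodes' band-limited power by a *single* correlation per recording, so all
temporal structure of the coupling is lost. `iacdfc` implements the dynamic
alternative: the **instantaneous amplitude correlation (IAC)**, a per-sample
co-fluctuation index whose time average recovers classic AEC exactly, but which
additionally yields a full connectivity time course. The package covers the
complete chain:

1. zero-phase FIR preprocessing and decomposition into the canonical bands,
2. leakage correction by pairwise signal orthogonalization,
3. per-sample IAC adjacency matrices from standardized Hilbert envelopes,
4. reduction to the global **average strength** time series aS(t),
5. first- to fourth-order cumulant-based descriptors of aS,
6. non-parametric group statistics with FDR control and a Pearson dose screen,
7. a synthetic-cohort generator with controllable ground truth for all of the
   above.

## Definitions

**Envelopes.** For a band-limited channel $x_i(t)$ the analytic signal
$a_i(t)$ is obtained by zeroing negative frequencies in the FFT, and the
envelope is $E_i(t) = |a_i(t)|$.

**Standardization.** Envelopes are z-scored over the retained samples using
*population* (n-denominator) moments:
$\hat E_i(t) = (E_i(t) - \bar E_i)/\sigma_{E_i}$. This convention is what makes
the time-mean of the IAC *exactly* the Pearson correlation of the envelopes:
$$\frac{1}{T}\sum_t \hat E_i(t)\hat E_j(t) = r(E_i, E_j),$$
a property the test suite asserts to $10^{-10}$ against `cor()`.

**IAC.** The per-sample connectivity between channels $i$ and $j$ is the
Hadamard product
$$\mathrm{IAC}_{ij}(t) = \hat E_i(t)\,\hat E_j(t),$$
giving one symmetric adjacency matrix per sample (diagonal undefined, stored
as `NA`).

**Orthogonalization.** Volume conduction produces spurious zero-lag
correlation. Before computing envelopes we remove, per pair and per sample,
the component of one analytic signal that is instantaneously parallel to the
other:
$$Y_{\perp X}(t) = \Im\!\left( Y(t)\,\frac{X^*(t)}{|X(t)|} \right),$$
with a floor of $10^{-12}\times$ the median $|X|$ protecting the division.
Because orthogonalization is asymmetric, the IAC is computed in both
directions and averaged,
$\tfrac12\bigl(z(E_{i\perp j})\hat E_j + z(E_{j\perp i})\hat E_i\bigr)$,
which restores exact matrix symmetry. A channel pair that is an exact scalar
multiple (pure leakage) yields an orthogonalized envelope with zero variance;
its standardized series is defined as identically zero, so pure leakage
contributes zero connectivity rather than an error.

**Average strength.** The node strength at sample $t$ is the mean of a node's
off-diagonal row; its global mean is
$$\mathrm{aS}(t) = \binom{n}{2}^{-1} \sum_{i<j} \mathrm{IAC}_{ij}(t),$$
one scalar per retained sample.

**Cumulant descriptors.** The aS distribution over time is summarized by
population moments: mean $\mu$, standard deviation $\sigma$, skewness
$\varphi$, and kurtosis $\kappa$ in the **Pearson convention** (Gaussian
$\kappa = 3$); the excess value is stored alongside as `kappa_excess`. The
implementation is cross-checked against `e1071` type-1 moments in the tests.

**Statistics.** Group contrasts use the Mann-Whitney $U$ statistic counting
`a > b` pairs (ties count one half), with exact enumeration of all
reassignments when $n_1+n_2 \le 20$ and the tie-corrected normal approximation
(no continuity correction) otherwise; effect size
$r = |U - \mu_U|/(\sigma_U\sqrt{N})$. The band $\times$ cumulant families are
Benjamini-Hochberg corrected per contrast (optionally globally), and a Pearson
screen correlates each descriptor with a dose covariate within dosed groups.

## The synthetic generator

`generateSubject()` builds each channel, band by band, as
*carrier $\times$ envelope*:

* **Carriers** are constant-modulus randomized-phase oscillations: the phase
  track of band-limited Gaussian noise, i.e.
  $\cos(\arg(\mathrm{analytic}(\text{band noise})))$. Constant modulus puts
  *all* amplitude structure into the designed envelope, so the prescribed
  envelope correlation is recovered over the full coupling range — including
  $c \to 1$ where envelopes become identical — which stochastic-modulus
  carriers cannot achieve.
* **Envelopes** mix an independent positive process per channel with one
  shared slow (< 1 Hz) modulator per band:
  $E_{\text{ch}} = \sqrt{1-c}\,\varepsilon_{\text{ch}} + \sqrt{c}\, m$, making
  the coupling parameter $c \in [0,1]$ an interpretable dial from independent
  ($c=0$, envelope correlation $\approx 0$) to fully shared ($c=1$,
  correlation $\to 1$).
* **Bursts** are Poisson-placed 250 ms raised-cosine gain bumps with peak gain
  `burst_gain`; gains above 1 skew the aS distribution to the right
  (increasing $\varphi$), giving ground truth for the higher-order
  descriptors.
* **Mixing** applies a fixed symmetric row-normalized matrix
  $W = (1-s)I + sM$ to emulate volume conduction, the effect the
  orthogonalization stage must undo.
* Sensor noise is white Gaussian. Subject seeds are derived deterministically
  from the cohort seed so cohorts are exactly reproducible.

What the generator *does not* emulate: realistic scalp topographies or lead
fields, 1/f spectral slopes, non-stationary artifacts (blinks, muscle), or
cross-frequency coupling. It is a ground-truth harness for the estimator
chain, not a forward head model.

## Numerical choices

* **Filters**: linear-phase FIR (order 500, Hamming window) applied
  forward-backward for exact zero phase. The forward-backward pass is
  implemented by FFT convolution with the symmetric kernel
  $h \star \tilde h$ plus odd-reflection padding; it matches
  `signal::filtfilt` to $10^{-8}$ on interior samples and is much faster on
  long multichannel recordings. Canonical bands: delta 0.5–4, theta 4–8,
  alpha 8–13, beta 13–30, gamma 30–98 Hz (upper edge capped at
  $0.48 f_s$); broadband 0.5–98 Hz plus a 48–52 Hz notch.
* **Hilbert transform** via the standard FFT half-spectrum construction.
* **Edge policy**: `trim` drops a chosen number of samples at each end
  *before* envelope standardization, so filter/Hilbert edge transients never
  contaminate the moments. The default is `trim = 0`: one adjacency matrix
  per input sample.
* **Fast path**: the aS series is accumulated in C++ in $O(n^2 T)$ without
  materializing the pairs $\times$ samples tensor; the plain-R tensor path is
  kept as the reference implementation and the two agree to $10^{-10}$ in the
  tests.
* **Group labels in EDF** are carried in the recording-identification field
  (`group=...`); delimited-text I/O uses a YAML sidecar for full metadata.

## Simulation sizes in the test suite

The Monte-Carlo acceptance checks (power of the coupling contrast, direction
of the burst-gain contrast, null calibration of the FDR) run the full
per-subject chain many hundreds of times. To keep the suite within a sensible
wall-clock budget, these blocks use recordings of 4–8 s rather than the 60 s
default, 12–16 channels rather than 31, and 10–20 subjects per group; sizes were
fixed in advance from pilot runs of the *effect magnitude* (the 0.2 vs 0.5
beta-coupling contrast separates group means by $\approx 2.5$–$4$ pooled SD at
16 channels / 8 s, so 20 + 20 subjects give power well above the asserted
80%), not tuned against test outcomes. Null calibration is invariant to these sizes by construction. The
acceptance script (`scripts/acceptance.R`) uses further-reduced replicate
counts and reports rates with their `n` so the precision is explicit.

## A worked example

```{r example, eval = FALSE}
spec <- subjectSpec(n_channels = 16, duration = 10, coupling = 0.5, seed = 1)
rec  <- generateSubject(spec)
pp   <- preprocessRecording(rec)
beta <- bandDecompose(pp)$bands$beta
aS   <- asSeriesFromBand(beta, band = "beta", subject_id = rec$subject_id)
cumulants(aS)
```

Cohort-level analysis is one call: `runPipeline(pipelineConfig(...))`, or the
equivalent CLI `inst/cli/iacdfc run-all --config cfg.yaml --out results`.

## Limitations

* IAC, like all amplitude-envelope metrics, is insensitive to phase-phase
  coupling; it measures power co-fluctuation only.
* Orthogonalization removes genuinely zero-lag physiological coupling along
  with leakage; this is the standard, deliberate trade-off.
* The exact Mann-Whitney enumeration is limited to $n_1+n_2 \le 20$; beyond
  that the tie-corrected normal approximation is used.
* The generator's ground truth is stylized (see above); conclusions about
  real EEG preprocessing robustness require real data.
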