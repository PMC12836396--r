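---
title: "Models and methods in fnirsdyad"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in fnirsdyad}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fnirsdyad)
```

`fnirsdyad` implements a complete two-site fNIRS hyperscanning analysis:
optical intensities to haemoglobin concentrations, cross-montage
co-localisation, task GLMs, and residual-based inter-brain wavelet
coherence with a shuffled-dyad null. This vignette documents the models,
the tunable parameters and their defaults, the synthetic generator used to
validate every stage, and the numerical and design choices a maintainer
would want spelled out.

## The measurement model

A continuous-wave fNIRS channel records light intensity at three
wavelengths (780, 805, 830 nm). The modified Beer–Lambert law (MBLL) links
the optical-density change at wavelength $\lambda$ to chromophore
concentration changes:

$$\Delta OD_\lambda = \big(\varepsilon_{HbO_2,\lambda}\,\Delta HbO_2 +
\varepsilon_{HHb,\lambda}\,\Delta HHb\big)\, L \cdot DPF_\lambda,$$

with $L$ the source–detector separation (cm) and $DPF$ the differential
pathlength factor. `mbll_convert()` computes
$\Delta OD = -\log_{10}(I/I_0)$ with $I_0$ the whole-run temporal mean per
channel and wavelength (the baseline is not otherwise observable), and
solves the 3-equation / 2-unknown system per sample by least squares.
Three choices matter:

* **Extinction table** — instrument vendors embed their own; we package a
  standard-magnitude table in cm⁻¹ mM⁻¹ (805 nm near the isosbestic
  point). It is configurable.
* **DPF = 6.0** at all wavelengths. Because DPF is a fixed guess,
  concentrations are in arbitrary-but-consistent units; every downstream
  statistic (OLS betas, t-tests, coherence, ANOVA) is invariant to a common
  rescaling, so nothing depends on the absolute unit.
* **Baseline $I_0$ = run mean**, so recovered concentrations are relative
  to their own run mean. The round-trip identity (generator →
  `mbll_convert()`) therefore holds after removing each channel's temporal
  mean, and the tests verify it at machine precision.

## Preprocessing

* **Resampling** (`resample_series()`): Fourier-method rate conversion
  (spectrum truncation/zero-padding), output length
  $\mathrm{round}(n \cdot f_{new}/f_{old})$. The 12.34 Hz site is brought
  to the 8.13 Hz common analysis rate before filtering. The Fourier method
  is exact for band-limited signals, and everything of interest here lives
  far below the target Nyquist (4.07 Hz).
* **Band-pass** (`bandpass()`): 4th-order Butterworth, cut-offs
  0.01–0.2 Hz, applied forward and backward (`filtfilt`), i.e. zero-phase
  with the squared magnitude response. The band keeps the haemodynamic
  response and excludes drift and the ~1 Hz cardiac component.
* **Global mean removal** (`global_mean_removal()`): an SVD of the
  channels × samples matrix per chromophore, subtracting the leading
  spatial component (default 1 component). This removes the channel-common
  systemic signal; with one component it is the PCA analogue of
  subtracting a weighted global mean. The component count is configurable;
  1 is the default because the generator (and the physiological
  literature's leading-order model) has a single common systemic source.
* **Quality control** (`qc_exclude_channels()`): four rules, union =
  excluded. "Perfectly mirrored" HbO2/HHb is operationalised as
  correlation < −0.98 (no published number exists; configurable);
  saturation as intensity pinned at the recording ceiling in > 1% of
  samples; absent heartbeat as cardiac-band (0.8–1.2 Hz) spectral power
  below 0.25× the neighbouring bands; and the RMS rule flags channels
  whose raw RMS exceeds 10× the RMS of the across-channel average signal.
  Note the RMS rule only discriminates on montages large enough that one
  loud channel barely moves the average — which is the regime it was
  designed for (88–134 channels).

## Co-localisation and ROIs

Montages differ across sites, so both are projected onto a common
134-channel mask. With $d_{ij}$ the distance (mm) between input channel
$i$ and mask channel $j$:

$$K_{ij} = \exp(-\sigma\, d_{ij}^2), \qquad \sigma = 0.01\ \mathrm{mm}^{-2},$$

and each column (mask channel) is divided by its sum, making every mask
series a weighted mean of nearby input channels. Weighted means preserve
constants and relative amplitudes, and excluded channels drop out with
their rows (columns renormalised).

Two genuinely open choices are exposed as configuration:

* **Exponent form.** The smoothing constant appears in the literature both
  as a multiplier and a divisor of $d^2$. With $\sigma = 0.01$ and $d$ in
  mm, $\exp(-0.01 d^2)$ has a 10 mm decay length — localised smoothing
  with preserved spatial specificity — whereas $\exp(-d^2/0.01)$ is a
  numerical delta function. The multiplier form is the default;
  `form = "d2_over_sigma"` selects the other.
* **Distance units.** $d$ is taken in mm; if a user's geometry is in cm,
  $\sigma$ must be rescaled by 100. This is flagged in the documentation
  because the effective kernel width depends on it quadratically.

Mask channels are grouped into 14 bilateral regions defined by Brodmann
areas (angular gyrus/BA39 through frontal eye fields/BA8). Assignment is
nearest-centroid against packaged per-hemisphere MNI centroids; the
centroids are package-supplied approximations of the canonical BA
locations, versioned in `inst/extdata/roi_table_v1.csv`, not an atlas
product. ROI series are unweighted means of member channels, trading
spatial detail for signal-to-noise before coherence estimation.

## Activation GLM

The canonical HRF is a double gamma parameterised so the response peaks at
exactly the stated delays (shape $= 1 + \mathrm{delay}/\mathrm{dispersion}$):
peak 6 s, undershoot 16 s, dispersions 1 s, peak:undershoot 6:1, length
32 s, peak-normalised. Each condition's regressor is its 15 s task-block
indicator convolved with the HRF; the discrete convolution is divided by
the sampling rate so regressors approximate the continuous-time integral
and betas share a scale across sites with different native rates. An
intercept completes the design; rest is implicit.

Fitting is plain OLS on HbDiff = HbO2 − HHb per mask channel (no
prewhitening — a documented limitation, as haemodynamic noise is
autocorrelated and single-subject p-values would be optimistic; the group
inference below does not use them). The group contrast is a paired design:
per-participant (live − static) beta differences tested against zero with
a one-sample t-test, df $= n - 1$ (39 for 40 participants), with
Benjamini–Hochberg FDR across channels at $q = 0.05$.

## Inter-brain coherence

Coherence is computed between partners' angular-gyrus HHb residual series
(task effects removed by the GLM, following the psychophysiological-
interaction rationale; HHb because it is less contaminated by systemic
physiology). The continuous wavelet transform uses an analytic
complex-Gaussian (derivative-of-Gaussian) wavelet of order 3 (configurable
1–8), implemented in the frequency domain:
$\hat\psi(\omega) = \omega^n e^{-(\omega-1)^2/4}$ for $\omega > 0$, whose
modulus peaks at $\omega^\ast = (1+\sqrt{1+8n})/2$; scales are mapped from
grid periods through $\omega^\ast$ so a sinusoid of period $p$ maximises
energy at the grid period nearest $p$.

The scale grid is 4 octaves × 4 voices from a 2.5 s base period —
16 scales, periods 2.5–33.6 s (0.4 down to 0.03 Hz) — with a linear
2.5 s-increment alternative (2.5–40 s). Both constructions are provided
because published descriptions mix the two conventions; the logarithmic
grid is the default. Magnitude-squared coherence is

$$MSC(s,t) = \frac{|S(W_x W_y^*)|^2}{S(|W_x|^2)\, S(|W_y|^2)} \in [0,1],$$

with $S$ a moving average in time over **3 wavelet periods per scale** (no
cross-scale smoothing), edge-renormalised. Two properties of $S$ deserve
emphasis:

* Without smoothing the ratio is identically 1 for *any* pair of signals;
  a regression test guards that smoothing is always applied.
* The window must exceed the decorrelation time of the narrowest-band
  signal component of interest. A band-limited process of bandwidth
  $\Delta f$ stays phase-coherent for $\sim 1/\Delta f$; if the smoothing
  window is shorter, *independent* processes in the same band are
  estimated as fully coherent and no comparison can detect true coupling.
  With components of bandwidth comparable to the analysed frequency
  ($\Delta f \approx f$), a 1-period window sits below this limit while a
  3-period window sits above it — hence the 3-period default. The window
  is configurable for users whose signals are broader-band.

The estimator remains positively biased (the smoother averages few
independent segments at long periods); this bias is common to real and
shuffled dyads, which is exactly why inference is run as a comparison.
Cone-of-influence samples are included by default (an exclusion flag
exists): edge effects are also common to both dyad types.

Per dyad, MSC is computed within each condition run, averaged over time in
the run, then across the condition's repeats, giving one value per period,
condition and dyad. The null is built from **cross-site shuffled dyads**: a
seeded derangement re-pairing each participant with a non-partner from the
other laboratory, so surrogate pairs are methodologically identical to
real ones (different montages, rates, sessions) except for actual
interaction. Inference per period is (i) a paired t-test of live vs static
within real dyads and (ii) a 2×2 fixed-effects ANOVA (dyad type × face
condition) treating each dyad × condition value as one observation — with
20 + 20 dyads the interaction is F(1, 76). The between-cells layout is the
default because it is the convention this analysis follows; a
repeated-measures variant (condition stratified within dyad) is available
via `anova_2x2(..., repeated = TRUE)`. No multiplicity correction is
applied across the 16 periods by default; a BH-FDR column is optional.

## The synthetic generator

`simulate_dyad()` builds each partner's concentration field as

task (boxcar ⊛ HRF × per-channel amplitude, HHb = −1/3 × HbO2 response)
+ heartbeat (1 Hz sinusoid, random phase per channel)
+ systemic drift (smoothed random walk, identical in all channels)
+ white channel noise
+ optional coupling,

then maps concentrations to three-wavelength intensities by inverting the
MBLL, so the full preprocessing chain can be validated by round trip. The
coupling component is a unit-variance Gaussian process band-limited to
$(1 \pm 0.5) f_0$ around the coupling frequency $f_0$ (bandwidth $= f_0$,
decorrelation ≈ one period — resolvable by the 3-period smoother), added
identically to both partners and gated to the *runs* of the live
condition: spontaneous coupling in residual series is not task-locked, so
gating at the 15 s task-block level would be both physiologically odd and
would halve the injected signal's duty cycle. The amplitude for a target
true coherence $C$ follows in closed form from the band power densities:
$MSC = (S_c/(S_c+S_n))^2$ with $S_c = a^2/\Delta f$ and
$S_n = 2\sigma^2_{noise}/f_s$, solved by
`coupling_amplitude_for_msc()`.

What the generator does **not** emulate: motion artefacts, short-channel
scalp signals, spatially-correlated physiology beyond the single global
component, vascular latency differences across the cortex, or optical
cross-talk. Passing tests therefore demonstrate the *pipeline's*
correctness and calibration on a forward model matching its assumptions;
they do not certify performance on real recordings, where the QC and GMR
stages face richer artefact structure.

## Calibration suites and problem sizes

The coherence/ANOVA stage is calibrated with the lightweight residual-pair
generator (`simulate_residual_pair()`):

* **Null calibration** — 100 seeded experiments of 6 real + 6 shuffled
  dyads (one repeat per condition) with zero coupling; the empirical
  rejection rate of the interaction test at the 20 s scale must fall
  inside the binomial 95% band around $\alpha = 0.05$.
* **Power** — 100 experiments at study scale (20 real + 20 shuffled dyads,
  two repeats) with coupling injected at true coherence 0.3 at 20 s; the
  interaction must be detected in at least 80% of runs.

These sizes were chosen as the smallest designs that make the binomial
acceptance bands meaningful; the power suite runs at the full study scale
because power is a property of that scale.

## Synchronisation protocol

The handshake is deliberately minimal: clients send one ASCII line
`HELLO <site_id>`, the host waits for the expected number of clients and
broadcasts `START <epoch_s>`, then closes all connections — no in-task
messaging, so a mid-task network failure cannot disturb a running session.
Clients log six event classes (code run, connected, trigger received,
experiment start, each block start, experiment end) as tab-separated
ISO-8601 lines. `estimate_offset()` subtracts matched event times across
sites and a known ground-truth clock offset; residual lags near zero
confirm synchronised delivery. The retry policy (5 attempts, exponential
backoff) and all timeouts are configurable. Validation is loopback-only by
design: wide-area latency is a property of the deployment network, not of
the protocol logic.

## Known limitations

* OLS without prewhitening; single-channel p-values are descriptive.
* The wavelet coherence estimator is biased upward at long periods
  relative to run length; only contrasts (real vs shuffled, live vs
  static) are interpretable, not absolute MSC values.
* Nearest-centroid ROI assignment is a coarse stand-in for probabilistic
  atlas registration.
* The between-cells ANOVA ignores the within-dyad pairing of conditions;
  the repeated-measures variant is provided but not the default.
* SNIRF import/export is not implemented; the package's delimited-matrix
  + JSON sidecar format is the interchange format.
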