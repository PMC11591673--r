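---
title: "Methods: Raman band deconvolution and PLS-DA fingerprinting of zebrafish organ development"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Raman band deconvolution and PLS-DA fingerprinting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

zfRaman turns a set of Raman spectra acquired from zebrafish embryo and larva
organs — iris, forebrain, melanocytes, heart, muscle and swim bladder,
sampled every 24 h between 24 and 168 hours post-fertilisation (hpf) — into a
per-organ developmental *fingerprint*: a table of signed scalar projections
(stage × descriptor) and one non-negative *vector module* per descriptor. The
chain is

1. per-spectrum deconvolution into damped-harmonic-oscillator (DHO) bands,
2. cross-dataset grouping of fitted bands into canonical bands,
3. presence-based band retention (the ">60% of animals" rule),
4. per-organ descriptor matrices (area/width/frequency per retained band),
5. PLS-DA over stages with cross-validated component selection,
6. scalar projections and vector modules.

A synthetic generator reproduces the study design (six animals from two
clutches) so every stage of the chain can be verified against planted ground
truth without instrument data.

# The deconvolution model

Each spectrum is modelled as a smooth background plus a sum of DHO spectral
responses,

$$ I(\nu) \;=\; b(\nu) \;+\; \sum_{j} A_{0j}\,
   \frac{F_j^2\, W_j\, \nu}{(F_j^2-\nu^2)^2 + (W_j \nu)^2}, $$

where $F_j$ is the natural frequency (cm$^{-1}$), $W_j$ the damping width
$\Gamma$ (cm$^{-1}$) and $A_{0j}$ an internal scale factor. For
$W \ll F$ the profile is near-Lorentzian with FWHM $\approx W$; under strong
damping its maximum shifts below $F$. Two conventions to be aware of:

* the reported frequency is the **natural frequency** $F$, not the profile
  argmax;
* the reported width is the **damping constant** $\Gamma$, not a FWHM (the
  two nearly coincide for the narrow bands below 1800 cm$^{-1}$).

The background $b(\nu)$ is a cubic polynomial (degree configurable) in a
scaled coordinate, fitted *jointly* with all band parameters. A pre-fit
baseline — an iteratively clipped polynomial by default, optionally an
asymmetric-least-squares Whittaker smoother — seeds both peak detection and
the polynomial's starting coefficients. The polynomial is the minimal
interpretable choice for a broad fluorescence-like background; nothing in the
pipeline depends on its particular form beyond smoothness.

Band **areas** are computed by trapezoidal quadrature of each fitted
component over the fit window on a 0.5 cm$^{-1}$ grid rather than by a
closed form, so they remain correct for large $W/F$ ratios where Lorentzian
approximations drift.

## Initialisation, bounds, numerical choices

Seeds are local maxima of the Savitzky–Golay-smoothed, background-subtracted
signal whose topographic prominence exceeds `prominence_k` (default 5) times
the noise MAD (estimated from lag-1 differences). Overlapped shoulders that
produce no distinct maximum — e.g. neighbouring bands ~20 cm$^{-1}$ apart —
are additionally seeded from maxima of the negated smoothed second
derivative, accepted only where the curvature exceeds `prominence_k` times
the robust curvature scale *and* the smoothed signal itself clears the
prominence threshold; derivative seeds within 6 cm$^{-1}$ of a direct
maximum are duplicates and dropped.

The joint fit is bounded Levenberg–Marquardt least squares
(`minpack.lm::nls.lm`) with an analytic Jacobian; each band's $F$ is
box-constrained to ±12 cm$^{-1}$ around its seed (keeping components
identified), $W \in [2, 200]$, $A_0 \ge 0$. Convergence tolerances are
$10^{-8}$ relative on cost and parameters, 200 iterations, with up to 3
restarts from jittered seeds (restart RNG seeded from the configuration, so
fits are deterministic). After the first solve, components whose peak height
falls below the pruning threshold (default: twice the estimated noise sd)
are removed and the fit re-run once; components closer than 5 cm$^{-1}$ are
merged (areas summed, amplitude-weighted $F$, $W$). Optimiser failure yields
`converged = FALSE`, never an error. Degenerate inputs (zero spectrum, no
seeds) return an empty, zero-residual fit.

# Canonical bands, presence, retention

All fitted frequencies across a dataset are grouped by one-dimensional
single-linkage clustering: sort, cut at gaps larger than $\delta$ (default
10 cm$^{-1}$). The closest distinct canonical bands are 19 cm$^{-1}$ apart
(1584 vs 1603), so $\delta = 10$ separates all 24 while absorbing fit
jitter. The canonical frequency is the member median and the label its
nearest integer, which keeps descriptor names (`A1409`, `W2929`, ...) stable
across runs.

Gap clustering has one failure mode worth naming: when two close bands are
occasionally covered by a single compromise component, that component's
frequency lands in the inter-band valley and single-linkage chains the two
clusters. The pipeline therefore enables a refinement step (`refine = TRUE`
of `clusterBandFrequencies()`): clusters whose frequency span exceeds
1.5·δ are recursively split at their largest internal gap. Genuine clusters
in this data model span a few cm$^{-1}$ (bounded by the fit's ±12 cm$^{-1}$
frequency window) while bridged pairs span ≥ 19, so the threshold separates
the two regimes with a wide margin; the handful of valley strays end up
attached to one side and are absorbed by the median-based canonical
frequency. The plain unrefined rule remains the function's default.

Presence is counted per (organ, stage, band) as the fraction of *animals*
presenting the band — an animal presents a band when any of its replicate
spectra contains a member component, so replicate multiplicity never
inflates the fraction. A band is retained for an organ when at least one
stage has a fraction **strictly** greater than 0.60; a fraction of exactly
0.60 does not retain. "Time window" is interpreted as a single sampling
stage (the study's sampling unit); multi-stage windows would only loosen the
rule and are not needed for the planted designs.

# Descriptor matrices

The observation unit is (animal, stage): the PLS discriminates stages, and
replicate spectra of one animal are not independent. Replicates collapse to
the component with the largest area (strongest detection); a replicate-mean
alternative is available. Descriptors mix units — areas (counts·cm$^{-1}$),
widths and frequencies (cm$^{-1}$) differ by orders of magnitude — so each
column is autoscaled (centered, unit sample sd over observed entries).
Missing cells (animal does not present the band at that stage) are imputed
with the column mean, i.e. zero after scaling, which is neutral under
centered PLS. Zero-variance columns are dropped with a warning. The inverse
transform restores observed values to better than $10^{-10}$ relative.

# PLS-DA, Q², component selection

Stages are encoded as a centered one-column-per-stage indicator matrix
(PLS2 discriminant coding; a `pls1` mode with numeric hpf as the single
response exists for comparison). Components are extracted by NIPALS with
convergence $10^{-12}$ on the weight vector, deflating both X and Y. The
usual per-component sign ambiguity is fixed by making each weight vector's
largest-magnitude element positive. Scores are mutually orthogonal to
$10^{-8}$ by construction, and an independent SVD-based PLS2 implementation
(weights from the leading left singular vector of $X^\top Y$) reproduces
NIPALS predictions to $10^{-6}$ RMS — this identity is exercised in the test
suite rather than assumed.

$Q^2(a) = 1 - \mathrm{PRESS}(a)/\mathrm{SS}$ comes from leave-one-animal-out
cross-validation: all rows of one animal are held out together; within each
fold X and Y are re-centered on the training rows. The retained component
count $A^*$ is the largest $a$ such that every incremental gain
$Q^2(i)-Q^2(i-1)$, $i \le a$, strictly exceeds `q2_gain` (default 0.01,
compared with $10^{-9}$ floating-point slack), with a floor of one
component. The gain threshold is this package's own concrete reading of
"compare $R^2$ and $Q^2$"; it is deliberately conservative, and both traces
are reported so users can override $A^*$.

# Scalar projections and vector modules

In the space of the first $A^*$ components, stage $k$ has the Y-loading
vector $q_k$ and descriptor $j$ the X-loading vector $p_j$. Two signed
projection conventions are implemented:

* **default (`direction = "stage"`)**: $s_{kj} = (p_j \cdot q_k)/\lVert q_k
  \rVert$ — the descriptor loading projected onto each stage direction. Its
  magnitude scales with the descriptor's loading, so the per-descriptor
  module ranks descriptor importance;
* **`direction = "descriptor"`**: $s_{kj} = (q_k \cdot p_j)/\lVert p_j
  \rVert = \lVert q_k\rVert \cos\angle(q_k, p_j)$ — the stage vector
  projected onto the descriptor direction. This is purely directional: a
  descriptor with a tiny but aligned loading scores as high as a dominant
  one, and with $A^*=1$ every descriptor's module is identical.

The default was chosen because the vector module is used as an importance
measure that should track VIP (variable importance in projection), which the
directional convention structurally cannot do; the package computes VIP
independently and the test suite checks the rank agreement (Spearman
$\rho$). Under both conventions positive projections mean above-average
descriptor values at that stage, and the per-component sign ambiguity
cancels.

The vector module aggregates a descriptor's projections across stages.
Three definitions are available because the literal phrase "length of the
sum of the scalar projections" is ambiguous:

* `norm` (default): $m_j = \sqrt{\sum_k s_{kj}^2}$ — the Euclidean length of
  the stage-projection vector;
* `abs_sum`: $|\sum_k s_{kj}|$ — the literal summed projection, which lets
  opposite-signed stages cancel and can zero out genuinely discriminating
  bipolar descriptors;
* `sum_abs`: $\sum_k |s_{kj}|$.

The default avoids the cancellation pathology while preserving the
"length" reading. An optional normalisation divides by the largest module
(the published per-organ tables appear on a 0–1 scale); it is off by
default so that the module equals the literal column norm.

# The synthetic generator

`defaultBandLibrary()` fixes the 24 canonical frequencies with per-band
damping widths (10–20 cm$^{-1}$ below 1800, 12–20 in the CH-stretch region,
45–55 for the broad O–H bands) and peak heights (45–110 counts), and the
per-organ membership sets. The published constraints pin most memberships
(three universal bands, heart- and muscle-exclusive sets, the 980/1409 trio,
set sizes 6/8/9/9/12/17); the remaining slots are filled with fixed,
documented choices from the unconstrained pool {1002, 1032, 1156, 1519,
3058, 3213} such that *only* {1603, 2929, 3431} occur in all six organs.
Widths and heights are stand-ins — the source data report none — chosen so
that every within-organ band pair (closest: 19 cm$^{-1}$) is resolvable at
the default signal-to-noise ratio.

`simulateBandParameters()` draws, per (animal, organ, stage, band), the true
$F$, $W$ and peak height: a baseline value modulated by a stage trend
(linear ramp or Gaussian pulse with 24 h width), a lognormal animal effect
(sd 0.15 for heights, 0.08 for widths; normal 0.8 cm$^{-1}$ shifts for
frequencies) and lognormal/normal residuals. The non-flat trends mirror, per
organ, the descriptors the published analysis found most discriminating
(e.g. F980/A980/A1409/A2929/W2929/W1409 in the iris). Presence can be
sub-unit; it is decided per (animal, band), so an absent band is absent at
every stage of that animal. `simulateDataset()` renders each spectrum on a
100–4000 cm$^{-1}$ grid (1 cm$^{-1}$ step) as a jittered cubic baseline plus
DHO profiles plus Gaussian noise with sd = (largest default height)/SNR,
SNR 20 by default, and writes two-column ASCII spectra, the manifest and the
exact truth table. Everything is reproducible byte-for-byte from one seed.

What the generator does **not** emulate: melanin/flavin fluorescence
physics, cosmic-ray spikes, detector etaloning, wavenumber-calibration
drift, session-to-session intensity changes, or any correlation structure
between bands beyond shared animal effects. Passing the planted-truth tests
therefore demonstrates the correctness and calibration of the algorithms
under the stated noise model, not instrument-grade robustness; the synthetic
band magnitudes must not be read as estimates of real tissue values.

# Problem sizes used in the automated checks

The packaged checks run the full study design — 216 spectra (6 animals ×
36 organ/stage cells: iris and forebrain over 7 stages, melanocytes, heart
and muscle over 6, swim bladder over 4) at SNR 20 — once, verifying that the
pipeline recovers exactly the planted per-organ band sets. Determinism is
exercised on a two-organ subset (iris + swim bladder, 66 spectra, run
twice), deconvolution recovery on 50 replicates of the six-band iris-like
spectrum, and the chemometric calibration checks (null $Q^2$, planted-signal
ranking, VIP agreement) on 50 replicates each at the feature level, where
the generator's truth tables stand in for fitted descriptors. These sizes
are the package's own choice of a thorough-but-quick verification design;
all of them can be scaled up through the exported functions.

# Known limitations

* The >60% retention rule is applied to canonical bands found by gap
  clustering; with extremely dense band structures (gaps below $\delta$
  everywhere) single-linkage chaining can fuse distinct bands — $\delta$ is
  configurable per dataset.
* $Q^2$ folds are animals; designs with fewer than three animals cannot be
  cross-validated.
* With a $K$-class indicator encoding, one latent component can explain at
  most a structural fraction of the Y variance; absolute $Q^2(1)$ values are
  therefore not comparable across organs with different stage counts.
* Band areas depend on the fit window; truncated broad bands (O–H near the
  4000 cm$^{-1}$ edge) are integrated over the window only, consistently
  between generator and fitter.
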