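---
title: "Phase-synchronization networks from induced EEG activity: models, parameters, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-synchronization networks from induced EEG activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psinet)
```

## The analysis model

`psinet` quantifies how task conditions reorganize oscillatory brain
networks measured with scalp EEG. The chain is: isolate induced activity,
estimate pairwise phase synchrony per frequency band, build weighted
graphs at fixed edge densities, and compare their small-world organization
and node-degree topography across conditions and groups.

**Induced vs. evoked activity.** Event-related EEG mixes an evoked
component (time- *and* phase-locked to the stimulus; survives trial
averaging, i.e. the ERP) with induced oscillations (time- but not
phase-locked). Phase-synchrony measures are contaminated by any common
phase-locked transient, so each subject's per-condition ERP is subtracted
from that condition's epochs before analysis (`remove_evoked()`). This
assumes the ERP is identical across trials — the standard, imperfect
convention; single-trial ERP estimation is out of scope. After
subtraction the per-condition mean trace is *exactly* zero (a property the
tests assert), and a dataset that was purely evoked becomes degenerate
(zero band-limited signal); `psi_matrix()` raises an error there rather
than silently reporting perfect synchrony.

**Instantaneous phase and PSI.** Each epoch is band-pass filtered
(zero-phase Butterworth, order 4 per pass, per band), the analytic signal
z(t) = s(t) + i·H[s](t) is computed over the *full* epoch, and only then
are phases cropped to the analysis window, so Hilbert and filter edge
transients fall outside the retained samples. The phase-synchronization
index between two channels is the resultant length of the phase-difference
distribution (mean phase coherence),
ρ = sqrt(⟨cos Δφ⟩² + ⟨sin Δφ⟩²) ∈ [0, 1], computed per epoch and averaged
over all epochs of a condition into a symmetric association matrix
(diagonal fixed at 0 and excluded from thresholding — self-synchrony
would otherwise always occupy top-K edges). Only 1:1 synchrony is
considered. For N i.i.d. uniform phase differences E[ρ] ≈ √π/2 · N^(−1/2)
(Rayleigh); the tests verify both this null and the constant-offset
invariance ρ(φ, φ + c) = 1.

**Graphs and small-worldness.** A PSI matrix is thresholded to exactly K
edges — the K largest upper-triangle values under a deterministic total
order (descending PSI, ties by ascending node-pair lexicographic order).
Exact-K keeps density = K/(n(n−1)/2) analytic; the published "K-th
largest value" rule can retain more than K edges under ties. Metrics:

* node strength Dᵢ = Σⱼ wᵢⱼ;
* weighted clustering (Onnela): Cᵢ = [kᵢ(kᵢ−1)]⁻¹ Σⱼ,ₕ (ŵᵢⱼ ŵᵢₕ ŵⱼₕ)^{1/3}
  with ŵ = w/max(w) and kᵢ the binary degree; nodes with kᵢ < 2 contribute
  0. A "literal" variant dividing by the *weighted* degree Dᵢ(Dᵢ−1) is
  available as a switch because that denominator occasionally appears in
  print, but it is dimensionally inconsistent with the cited definition
  and is not the default;
* characteristic path length in harmonic form, L = [n(n−1)]⁻¹ Σ 1/dᵢⱼ
  inverted, with edge length 1/w (strong synchrony = short distance; the
  convention of the standard brain-connectivity toolboxes — the weight-to-
  length map is not dictated by the formulas themselves). Disconnected
  pairs contribute 0 = 1/∞, so no special-casing. An arithmetic-mean
  variant is available as a switch.

Normalization uses degree-preserving double-edge-swap rewiring
(Maslov–Sneppen): the binary degree sequence is preserved exactly, no
self-loops or multi-edges, 10·K attempted swaps, and the multiset of edge
weights is randomly reassigned to the rewired edges (the null's weight
handling is not pinned down in the literature this design follows; the
permutation scheme was chosen and is kept fixed). With n_random = 20
nulls, γ = C/C_rand, λ = L/L_rand, σ = γ/λ; σ > 1 with γ > 1, λ ≈ 1 is
the small-world signature. Both the sweep K = 60…180 step 20 (densities
≈ 0.16–0.48 for 28 nodes) and the K = 120 level for node-degree analysis
(density 120/378 = 0.3175, near the cost-efficiency optimum reported for
brain graphs) are configurable defaults.

**Statistics.** γ, λ, σ are compared with a two-way mixed-design ANOVA
(Task within; Age between; classical sums-of-squares, between effect
against subject-within-group error, within and interaction against the
task × subject residual; no sphericity correction — plain F, with the
test suite checking against `aov()` Error-stratum output). Because graphs
across the density sweep are strongly dependent, no multiple-comparison
correction is applied across K; instead an effect counts as significant
only if p < α at ≥ 3 of the 7 levels. Node-degree contrasts use paired t
per channel (t-maps) and ROI means; group contrasts of relative change
use Welch's t (fractional df).

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| sampling rate | 1000 | Hz | matches the target recording setup |
| epoch window | −200…800 | ms | covers the inhibition-related window |
| analysis window | 200…700 | ms | 500 ms is near-optimal for band-wise PSI; covers N2/P3 latencies |
| baseline window | −500…0 | ms (pre-cue) | reference segment |
| bands | 4–8, 8–13, 13–30 | Hz | theta/alpha/beta; half-open bin assignment [low, high) |
| broadband filter | 0.1–40, order 2/pass | Hz | 12 dB/oct per edge per pass |
| artifact criteria | 150 (200/50), 100, 40 (400/10), 50 (−200…200) | µV (ms) | moving-window ptp, absolute, HEOG, VEOG |
| K sweep | 60…180 step 20 | edges | densities ≈ 0.16–0.48 |
| degree K | 120 | edges | density 0.3175 |
| n_random | 20 | networks | null sample size |
| rule | ≥ 3 of 7 | levels | dependence-aware convention |

## The synthetic world

`generate_epochs()` emulates the recording geometry so the pipeline can be
validated against known ground truth. Per epoch, channel, and band, the
signal is A_b·cos(φ(t)) where φ integrates an instantaneous frequency
drawn uniformly inside the band (redrawn each epoch) plus a Wiener phase
jitter (sd 0.05 rad/√sample). A `coupling_spec(condition, band, channels,
kappa)` mixes a shared common-oscillator phase into each member channel,
φ = (1−κ)·φ_indep + κ·φ_common: the simplest mechanism that gives
tunable mean phase coherence without committing to a dynamical model.
Fixed choices, made once: band amplitudes theta/alpha/beta = 10/8/5 µV
and noise sd 5 µV (plausible scalp scale); the evoked transient is a
Gaussian-windowed (sd 60 ms) 5 Hz cosine peaking at 350 ms with 10 µV
default amplitude, added identically (phase-locked) to every Go/NoGo
epoch, mimicking the N2/P3 latency range; 90 epochs per condition by
default (a six-block session's order of magnitude; tests and the
acceptance script scale this down to 6–20 epochs to stay inside time
budgets — stated here once, and the thresholds are never adjusted to
compensate). All randomness flows from one explicit seed; per-subject and
per-null seeds are derived from it, so every result bundle is a pure
function of (inputs, config, seed).

What the generator does **not** emulate: volume conduction / leadfield
mixing, spatially graded background synchrony, realistic ERP morphology,
1/f background spectra, or eye-movement artifacts beyond
threshold-exceeding transients. Consequently a green end-to-end test
establishes that the pipeline recovers *designed* coupling structure
(direction, monotonicity in κ, ROI localization), not that it reproduces
every statistical property of real recordings.

### What the clique scenario can and cannot show

One validation scenario couples the 14 frontal-central channels at
κ = 0.6 and leaves everything else independent. This recovers the ROI
degree contrast essentially always (the coupled ROI's node strength
roughly doubles), but it does **not** produce σ > 1 at K = 120: a
uniformly coupled 14-channel set puts 91 of the 120 edges into a single
clique, and that rich-club degree sequence forces degree-preserving
rewired nulls to retain most of the clustering (two nodes of binary
degree ≈ 15 among 28 nodes are almost always adjacent in any
degree-matched graph), so γ ≈ 0.95, λ ≈ 1.1, σ ≈ 0.8–0.9. Measured scalp
networks show σ > 1 because synchrony decays smoothly with electrode
distance, yielding many overlapping local neighborhoods — a lattice-like
organization, not one clique. The σ-detection machinery itself is
validated on exactly such inputs: a ring lattice (σ ≈ 5), a locally
ordered synthetic association matrix with distance-decaying weights
(σ > 1 at K = 120), and self-normalization (a rewired null re-normalized
against further rewirings gives γ, λ, σ ≈ 1). The acceptance report
nevertheless computes the clique-scenario σ exactly as specified and
reports the honest value.

## Numerical choices

* **Filters.** No DSP dependency is available, so Butterworth design
  (analog prototype → LP-to-BP transform → bilinear with pre-warping) and
  forward–backward filtering are implemented in-package; coefficients
  were cross-checked against an independent reference implementation
  during development. Narrow bands (4–8 Hz at 1000 Hz) make the expanded
  transfer-function polynomial numerically singular, so band filters run
  as second-order-section cascades with per-section steady-state initial
  conditions and odd end-extension. Edge transients of zero-phase
  narrowband filtering on finite epochs are unavoidable (the reference
  implementation behaves identically); the analyze-only-the-interior
  policy is the mitigation.
* **Windows.** All time windows are half-open [start, end) in ms with 0 at
  stimulus onset, so sample counts are unambiguous (200–700 ms at 1000 Hz
  = exactly 500 samples).
* **Artifact windows.** Moving windows advance by the stated step and
  include a final partial window (conservative rejection). The VEOG rule
  is implemented as max − min within −200…200 ms; whether the published
  criterion meant peak-to-peak or deviation-from-baseline is ambiguous,
  and the choice is exposed in the criteria object.
* **Spectra.** Per-epoch Hamming-tapered periodograms without
  zero-padding (2 Hz resolution for the 500 ms window; padding silently
  changes bin counts), averaged as *power* across trials (the standard
  reading of "spectral power"; amplitude averaging would differ), band
  bins assigned half-open. A Parseval identity is asserted in tests.
* **Ties and determinism.** Edge selection uses a total order; rewiring
  and null seeds derive deterministically from the master seed; the same
  (config, seed) reproduces results bit-for-bit.
* **Relative change.** The symmetric percent difference
  100·(a−b)/((a+b)/2) is the default (antisymmetric, bounded); the
  asymmetric 100·(a−b)/b is a switch. Published relative-change values
  depend on the unstated convention, so the choice is recorded in output
  metadata.
* **Calibration of the 3-of-7 rule.** The type-I calibration test draws
  the 7 per-level p-values from *independent* null datasets, for which
  the nominal rate is P(Binom(7, 0.05) ≥ 3) ≈ 0.0038. Real sweeps are
  dependent across K (that dependence is the rule's raison d'être), and
  no analytic nominal exists there; the independent-sweep check verifies
  the rule's implementation and monotonicity, not its operating
  characteristics on correlated sweeps.

## Known limitations

* EDF input/output is not implemented (no suitable R package in the
  supported dependency set); the delimited long-format table is the
  interchange format.
* ICA ocular correction, bad-channel interpolation, source projection,
  and wavelet/multitaper time-frequency analysis are out of scope.
* The mixed ANOVA assumes every subject contributes every within-level
  (balanced within); unequal group sizes are supported, missing cells are
  an error. No sphericity correction is applied by default.
* The generator's flat background synchrony understates the spatial
  structure of real recordings (see the clique-scenario discussion
  above).
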