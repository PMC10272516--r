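---
title: "Models and methods behind meglat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind meglat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the forward model, the automatic single-dipole algorithm, the three
distributed comparators, the synthetic-data generator that stands in for
recorded MEG, and the numerical decisions taken where the design was
genuinely open.  It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## Forward model

The head is a spherically symmetric volume conductor.  For MEG this is a
remarkably strong assumption to buy so cheaply: the external magnetic
field of a current dipole then has the closed-form Sarvas solution, is
independent of the conductivity profile, and depends on the sphere only
through its centre.  Two consequences structure everything downstream:

* **Silent radial sources.** A dipole moment parallel to its position
  vector produces no external field; every lead-field block is rank 2.
  The package therefore inverts 3×3 source-space brackets on their
  tangential subspace (`pinv3`), simulates benchmark dipoles along the
  two *principal* lead-field orientations, and treats tiny ridge terms in
  least-squares solves as acting only on the null direction.
* **No conductivity parameter.** Only geometry enters; the default sphere
  (radius 0.09 m, centred at the origin) is generic and configurable, as
  subject-specific sphere parameters are inherently study-specific.

Planar gradiometers are modelled as two-point finite differences of the
field component along the site normal, sampled at ±baseline/2 along each
of two orthogonal tangential axes (baseline 16.8 mm, the physical scale
of common whole-head arrays).  This captures planar-gradiometer physics —
maximal response directly above a tangential source — without coil
integration, which is out of scope.  The implementation is pinned by two
independent checks in the test suite: frozen field values computed with
an external sphere-model implementation (MNE-Python's kernel), and the
analytic identity that the radial field component equals the free-space
Biot–Savart term of the primary current alone.

The synthetic helmet places 102 sites on a Fibonacci lattice over the
upper ~2/3 of a 0.12 m sphere.  The real 102-site layout is not
reproduced; what matters for the algorithm is quasi-uniform coverage with
a realistic minimum inter-site spacing, because the channel-selection
constants below are expressed in normalized layout units.

## The automatic single-dipole algorithm

The algorithm runs on the averaged evoked field, once per time step
(1 ms steps when the sampling rate is ≥ 1 kHz, otherwise every sample):

1. **Combine.** Each site's two gradiometer readings are merged by
   root-sum-of-squares into one non-negative value, invariant to the
   orientation of the tangential gradient.
2. **Smooth.** Site values are smoothed on the 2-D layout with a
   normalized Gaussian kernel whose SD is the minimum pairwise site
   distance `min(d)` — the finest scale the array can resolve.  The 2-D
   layout is an azimuthal-equidistant projection about the mean site
   direction, rescaled to a unit-diameter disk; this projection preserves
   small distances, which is what makes the printed constants (0.4, 0.1,
   0.25) geometrically meaningful.  The projection itself was an open
   choice; azimuthal-equidistant was selected precisely for its
   small-distance fidelity.
3. **Maxima.** Local maxima are defined on the Delaunay adjacency of the
   layout (parameter-free and respectful of irregular spacing; the
   triangulation is a built-in Bowyer–Watson implementation validated
   against a brute-force empty-circumcircle oracle).  Up to 5 maxima at
   ≥ 10% of the global maximum survive; they are split by hemisphere
   (sign of the layout left–right coordinate) and kept at ≥ 75% of their
   hemisphere's maximum.  The 75% rule is applied *after* the 5-maximum
   cap, following the order in which the rules are stated.
4. **Channel subset.** Around each surviving maximum a 1-D Gaussian
   `a·exp(−d²/2σ²)` is least-squares fitted to smoothed value versus
   layout distance over sites with `d ≤ 0.4`; all sites with
   `d < min(max(σ, 0.1), 0.25)` contribute both gradiometers.  A
   non-decreasing profile (no dipolar structure) falls back to σ = 0.1.
5. **Fit.** Stage 1 scans every grid point, solving the moment by linear
   least squares against the selected-channel lead field (closed-form
   3×3 solves, vectorized over the grid).  Stage 2 refines the best
   point by Nelder–Mead over location with the moment re-solved at every
   step, a penalty pushing iterates back inside the sphere.  Fits with
   fewer than 8 channels are refused as under-determined.
6. **Accept, rank, prune.** Accepted dipoles (field correlation ≥ 0.90,
   relative residual variance < 20%, both computed over the selected
   channels) are ranked by
   `Rank_i = Σ_j exp(−d_ij²/2σ_s²)·exp(−t_ij²/2σ_t²)` with σ_s = 10 mm,
   σ_t = 50 ms, and the top 70% (by rank quantile, ties kept) retained.
   "Top 70%" is read as retaining the upper 70% of dipoles — the only
   reading that removes isolated dipoles.  A single accepted dipole has
   rank 0 and is retained by convention.

Hemisphere membership of a fitted dipole is the sign of its
x-coordinate; dipoles within 2 mm of the midline are counted in neither
hemisphere (the boundary had to be set somewhere; it is configurable).
ROI membership comes from the nearest grid point's atlas label.  The
laterality index is `LI = (L − R)/(L + R)` over language-ROI dipole
counts; `L + R = 0` is reported as "no language source" rather than a
number.

A property worth knowing: the acceptance statistics (correlation,
relative residual variance) are scale-free, so pure noise snapshots are
occasionally accepted (about 1–2% of fits in the test suite's
measurement) — it is the spatiotemporal ranking that removes them, since
noise dipoles do not cluster.  Expecting literally zero accepted noise
dipoles would be wrong.

## Distributed comparators

**MNE.** `W = R Aᵀ(A R Aᵀ + λ²C)⁻¹`, with the source covariance an
identity scaled so `trace(A R Aᵀ) = trace(C)`, noise covariance from an
empty-room recording (with 1e-10 relative diagonal loading), the lead
field pre-whitened, and λ² = 3 — a widely used default.  The operator is
computed in the whitened basis for conditioning; the test suite verifies
equality with the dense unwhitened textbook formula to 1e-8, so the
algebraic route is immaterial.  Free orientation, three components per
point; no depth weighting (deliberately, matching the comparator as
used).  The source space is the same volumetric grid used by the dipole
and beamformer paths; cortical-surface source spaces are out of scope,
and this is the one documented deviation from common MNE/dSPM practice.

**dSPM.** The per-point MNE power divided by its projected noise
variance, `q_i(t) = Σ_j (w_j x)² / Σ_j w_j C w_jᵀ`; F(3, dof) under the
null with dof the number of empty-room samples behind C.  Window-mean
maps are thresholded at p = 0.05 Bonferroni-corrected over source
points.  The null calibration (mean q ≈ 1 under covariance-matched
noise) is checked explicitly.

**DICS.** Hanning-windowed FFT spectra per epoch; CSD `Q(f)` as the
epoch mean of `X(f)X(f)ᴴ`; filters
`Wᵀ = [AᵀQ̃⁻¹A]⁻¹AᵀQ̃⁻¹` from the *real part* of the combined
baseline+active CSD (complex filters have no biophysical reading),
regularized by 10% of the mean eigenvalue; condition power as the
dominant eigenvalue of `Re(WᵀQW)`.  The combined CSD is the
epoch-count-weighted mean of the condition CSDs (identical to
concatenation when counts match, as they do here).  Per-epoch source
power — needed for a paired test, which the published descriptions leave
implicit — is the band-mean of `‖Wᵀx_e(f)‖²` through the common filter;
baseline/active labels are permuted within epochs (sign flips of the
paired differences, fully vectorized), giving the dependent-sample t its
null.  Cluster correction uses two-sided t at p 0.05 as the
cluster-forming threshold and cluster mass Σ|t| on the grid's
6-neighbour adjacency.  Canonical bands: alpha 8–12, low beta 12–20,
high beta 20–30, low gamma 30–50, high gamma 50–110 Hz; FFT bins are
assigned by bin centre, so shared band edges resolve to the lower band
except for exact-edge bins.

## Synthetic data: what it emulates and what it does not

`simulate_evoked` produces a one-cycle 10 Hz raised-cosine burst peaking
at 300 ms with a 20 nA·m moment — the shape, latency and magnitude of a
typical auditory evoked deflection inside a 150–600 ms analysis window —
projected through the forward model, plus white channel noise.  The SNR
convention (the published one being unstated) is amplitude-domain:
noise SD = RMS of the noiseless record over all channels and samples,
divided by the requested SNR.  `simulate_erd_epochs` gives each trial a
band-limited oscillation with independent phase, amplitude-scaled by
√(1+power_change) inside the active window: the effect vanishes from the
trial average (invisible to ECD/MNE/dSPM) but not from the spectral
power (visible to DICS) — exactly the evoked-versus-induced dichotomy the
method comparison is about.  `simulate_empty_room` is i.i.d. Gaussian.

Real MEG differs in ways these generators deliberately omit: spatially
correlated environmental and physiological noise, ocular/cardiac
artifacts, head movement, non-spherical conductor geometry, and
sources extended over cortex rather than points.  Passing tests
therefore demonstrate internal correctness and the algorithms' behaviour
under their own assumptions, not clinical performance.

The fixture atlas is a mirrored Voronoi partition of the grid around
randomly placed seeds (default 20 ROIs per hemisphere, 40% flagged as
"language"), giving the laterality machinery the structure it needs —
labels, hemispheres, symmetric language flags, centroids — with no
anatomical claim.  The grid offsets its x-planes by half a spacing so no
point sits on the midline and mirrored source pairs are exact grid
points.

## Preprocessing notes

Filters are 4th-order Butterworth applied forward–backward (zero phase,
preserving the latencies the dipole algorithm indexes by).  The
0.1–170 Hz band-pass is implemented as a high-pass/low-pass cascade: a
direct band design with a 0.1 Hz edge at MEG sampling rates is
numerically unstable in double precision, the cascade is not, and it
meets the stated ripple/attenuation specs.  Band-stops are ±2 Hz around
60 and 120 Hz.

Artifact rejection is fully automatic (the usual semi-automated visual
procedure is not reproducible): per trial, the maxima over channels of
variance, absolute amplitude and excess kurtosis, z-scored across trials
with *robust* (median/MAD) scaling and thresholds (3, 5, 3).  Robust
scaling is forced by arithmetic: a plain mean/SD z-score across n trials
is bounded by (n−1)/√n, so a threshold of 5 could never fire on typical
trial counts.

The multitaper time–frequency analysis uses DPSS tapers (computed via
the symmetric tridiagonal eigenproblem, since no installed package
provides them) with the conventional frequency-dependent plan: below
30 Hz, 7-cycle windows and ±0.4·f Hz smoothing; at and above 30 Hz,
250 ms windows and ±12 Hz; taper count `max(1, floor(2TW) − 1)`.
Baseline correction is relative change (power/baseline − 1) over
−500…−100 ms — the standard display convention for ERD/ERS; the
correction mode is configurable since the published choice is unstated.

## Numerical choices

* Grid scans solve the rank-2 3×3 Gram systems with a 1e-12 relative
  ridge; since the right-hand side lies in the Gram's range, the ridge
  only suppresses the silent direction.
* Nelder–Mead runs with `parscale` set to the grid spacing, 400
  iteration cap and 1e-9 relative tolerance; iterates outside 99.5% of
  the sphere radius are projected back with a penalty.
* Final dipole moments are re-solved with an SVD pseudo-inverse
  (tolerance 1e-10 relative).
* Ties in maxima ordering break towards lower site index; rank-pruning
  keeps ties at the quantile boundary; categorical laterality places the
  closed interval [−0.1, 0.1] in "bilateral".
* The epochs container serializes doubles with 17 significant digits, so
  write–read round trips are bitwise.

## Desk-scale study sizes

The default configurations the tests and the acceptance script run are
deliberate reductions of a full study, chosen once: 40 ROI-centroid
source locations × 2 principal orientations × 20 noise repetitions for
the localization benchmark (SNR 5 and 1; the SNR sweep test adds levels
2, 3 and ∞ at 12 locations × 4 repetitions); 200 simulated datasets at
1000 permutations for the beamformer false-positive calibration; 10
seeds for the bilateral laterality recovery; full-window dipole runs
simulated at 250 Hz (the algorithm then steps once per sample, as
specified for sub-kHz data — the laterality outcome is step-size
independent).  The full-scale protocol (246 locations, 100 repetitions,
SNR 1–10, 10,000 permutations, 1 kHz) is available through the same
function arguments.

## Known limitations

Single-sphere conductor only (no BEM/FEM); point sources; magnetometers
and axial gradiometers are not modelled; no head-movement or
interference suppression (tSSS/SSS, ICA); volumetric grid for all
methods including MNE/dSPM; the fixture atlas is anatomically
meaningless; the bilateral LI threshold (0.1) is a convention — published
category counts may use a different, unpublished cut-off, so categorical
agreement with any particular study is not to be expected.
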