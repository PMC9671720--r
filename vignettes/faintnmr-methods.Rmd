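---
title: "Reference-free quantitative NMR: model, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-free quantitative NMR: model, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faintnmr)
```

## The intensity model

NMR signal intensity is proportional to the molar amount of nuclei producing
the signal. For a fully relaxed 1D proton experiment, the absolute integral
of a signal from `n_H` protons of an analyte at concentration `c` (mM),
recorded with `NS` co-added scans at receiver gain `RG`, is modeled as

$$ I = \mathrm{IG} \cdot NS \cdot g(RG) \cdot n_H \cdot c $$

where $g(RG)$ is the amplifier's true response at the nominal setting and
IG (*intensity gain*) is a spectrometer constant: intensity per scan, per RG
unit, per proton, per mM. Everything in this package follows from that one
identity:

* **Calibration.** Each observed integral of a known-concentration sample is
  normalized to an increment $I/(NS \cdot RG \cdot c \cdot n_H)$; the IG
  factor is the arithmetic mean of the pooled increments
  (`calibrate_ig()`). The mean matches the way such calibrations scatter
  around a central value; a median is available behind the `center` flag for
  outlier-contaminated sets. With a nonlinear amplifier the calibrated IG
  absorbs the mean gain deviation $\overline{g(RG)/RG}$ — IG and $g$ are not
  separately identifiable from intensities alone, and they need not be,
  because back-calculation uses the same products.
* **Linearization.** Increments grouped by RG step expose the amplifier
  nonlinearity: the per-step correction is the step's mean increment divided
  by the global IG, and the linearized gain is `RG` times that correction
  (`estimate_linearization()`). No smoothing is applied across steps —
  empirical gain corrections are not monotone, so each step is estimated
  independently. Consequently at least two distinct RG steps are required,
  and queries between tabulated steps are linearly interpolated; outside the
  table they are an error unless nearest-edge extrapolation is explicitly
  enabled.
* **Back-calculation.** Each (signal × experiment) observation yields an
  independent concentration estimate $c = I/(\mathrm{IG} \cdot NS \cdot
  RG_\mathrm{eff} \cdot n_H)$; per sample the pool is aggregated to a mean.
  Units: concentrations are millimoles per litre (mM) throughout.

### Aggregation and reported uncertainty

How the per-signal, per-replicate estimates are grouped before averaging is
a genuine design choice. The default pools all estimates of a sample with
equal weight (`pooling = "flat"`); `pooling = "per_signal"` first averages
within each signal label and then across labels, which de-weights signals
measured more often. Two spread measures are reported: `sigma_mM`, the
sample standard deviation of the estimate pool (the scatter of individual
back-calculations, comparable to a per-sample σ quoted next to a mean of
many signals and replicates), and `sem_mM`, the standard error of the
aggregated mean, which shrinks with the square root of the pool size. They
answer different questions — "how consistent are my estimates" versus "how
well is the mean determined" — and conflating them is a common source of
overstated precision.

## The synthetic generator

`simulate_spectrum()` builds spectra directly in the frequency domain as
sums of complex Lorentzians (absorption plus dispersion) whose analytic
areas follow the intensity model exactly; `fid_from_spectrum()` provides the
matching time-domain signal as the exact inverse of `fourier_transform()`.
Generating in the frequency domain decouples the simulator's correctness
from the processing code it is used to test.

What it emulates: Lorentzian multiplets with per-component weights, the
linearity of intensity in NS, concentration and proton count, a configurable
amplifier response $g(RG)$ per gain step, and additive white Gaussian noise
on both quadratures with realized standard deviation
$\sigma \cdot g(RG) \cdot \sqrt{NS}$ — signal adds linearly over scans,
noise as the square root, and both pass through the amplifier. The noise
model is an assumption (the underlying statistics of a given spectrometer
are not specified by intensity tables); Gaussian frequency-domain noise is
the standard idealization and is what the SNR-based contracts are stated
against. `noise_sigma_for_snr()` inverts the model to place the weakest
signal at a chosen SNR (default 200, the floor reported for well-designed
quantitative acquisitions).

What it does not emulate: relaxation during acquisition beyond the
lineshape, J-coupling evolution, temperature effects, solvent signals,
baseline artifacts from pulse breakthrough, or radiation damping. Passing
tests on this generator therefore demonstrate the correctness of the
*method's arithmetic and the pipeline's numerics*, not robustness to every
artifact of real spectra.

The default gain model (`default_gain_model()`) uses per-step deviations in
the 0.92–0.97 range with non-monotone structure across the 17-step RG ladder
from 25.4 to 161 — the magnitude regime a receiver-gain linearization is
needed for.

### Study conditions

Two condition grids are fixed as package API. `calibration_conditions()`
crosses the five gravimetrically prepared concentrations (5.29 to 108.35 mM)
with four shared (NS, RG) settings spanning 2–64 scans and gains 25.4–90.5,
in duplicates — the balanced design for IG-recovery checks.
`gravimetric_conditions()` reflects the instrument reality that concentrated
samples saturate the receiver earlier: each sample only reaches its highest
non-clipping RG (161 down to 36 across the series). This asymmetry is what
converts an uncorrected gain nonlinearity into a concentration-dependent
bias, i.e. a regression slope away from 1, and its removal by linearization
is the method's headline benefit.

## Numerical choices

**Grid and quadrature.** Spectra live on a descending ppm axis of $n$ points
(default 16384 complex points over a 14 ppm window at 400.13 MHz, the
acquisition geometry the model targets). Region integrals use the
trapezoidal rule with a half-open assignment of grid points (a point exactly
on the lower bound belongs to the region, one on the upper bound does not),
so adjacent regions never double-count. Trapezoidal quadrature of a
Lorentzian is exponentially accurate once the half width at half maximum
spans at least ~1.5 grid steps; at the default 1 Hz linewidth and 16384
points the quadrature error is below 0.03%. Coarser grids degrade quickly —
at 8192 points the same line is under-resolved and percent-level quadrature
bias appears — which is why all integral-accuracy contracts are stated at
16384 points.

**Tail truncation.** A Lorentzian of half-width $h$ integrated over a region
of half-width $w$ captures $(2/\pi)\arctan(w/h)$ of its mass
(`lorentzian_region_fraction()`). The default test geometry (±0.5 ppm
regions, 1 Hz lines) captures 99.84%, so a noiseless IG calibration lands
~0.16% below the generator's true value. This bias is *shared* by
calibration and quantification (same regions), so it cancels exactly in
back-calculated concentrations; only comparisons of the calibrated IG with
the generator's `ig_true` see it. Expectations in the tests are
truncation-aware rather than hiding the physics behind renormalized
lineshapes.

**Phase correction.** `auto_phase()` chooses zeroth- and first-order phases
in two stages: a coarse grid over (ph0, ph1) scored by a hybrid objective —
the entropy of the absolute first derivative plus a heavily weighted penalty
on negative intensity, which rejects the 180° sign flip — followed by
Nelder-Mead refinement of the negativity penalty alone. The refinement
objective is exactly zero at the true phase of a clean absorption spectrum
(any dispersion admixture creates negative lobes), so its minimum is
unbiased, whereas the entropy term has a nonzero gradient there and would
drag the optimum a few degrees off if kept in the refinement. On noiseless
synthetic input the recovered phases are exact to well under 0.1°; the
stated contract is 1° and ≤1% integral error for dephasing up to (45°, 20°).
Manual phases remain available (`apply_phase()`, `process_fid(phase =
"manual")`) for pathological input.

**Baseline.** A polynomial of degree ≤ 2 is fitted by iterative asymmetric
clipping: fit to all points, drop points more than 2.5 residual standard
deviations *above* the fit (absorption signals are positive), refit until
stable. This removes constant offsets and slow ramps while ignoring peaks.
Its resolution limit is physical: a baseline feature orders of magnitude
below the Lorentzian tails cannot be separated from them by any low-order
model, so baseline contracts are stated for offsets that are a realistic
fraction of the spectrum's dynamic range. A degenerate all-clipped fit falls
back to the last stable solution; a flat zero spectrum passes through
unchanged.

**No apodization.** Window functions redistribute intensity and conserve
integrals only approximately, so quantification-oriented processing applies
none; zero-filling (factors 1, 2, 4) is available and conserves region
integrals for causal, decayed FIDs.

**Determinism.** All simulation randomness flows through explicit seeds
(recorded in manifests and provenance, restored on exit so library calls do
not disturb the session RNG); processing is fully deterministic, and the CLI
writes doubles in shortest round-trip decimal form so chained file-based
runs are bit-identical to in-memory results.

## File formats

The Bruker-style reader handles the subset of the directory dialect needed
here: a JCAMP-style `acqus` text file (keys NS, RG, D1, TE, SW, TD, SFO1,
optionally O1P, BYTORDA, DTYPA) plus a binary `fid` in int32 or float64,
either endianness. NS and RG are never defaulted — their absence is an
error, since silently assumed values would corrupt every downstream
concentration. The internal `.fnmr` format is a text header plus
little-endian float64 binary, versioned, and round-trips FIDs and spectra
(including provenance) losslessly. The digitizer encoding of any particular
instrument's deposit is outside what can be pinned down offline; the dialect
is fixed by the writer in this package, which the tests use to generate
fixtures.

## Metadata checks

`validate_for_quantification()` warns — it never edits data — when the
inter-scan delay is below five times the longest T1 (incomplete relaxation
attenuates integrals nonuniformly; e.g. a D1 of 16 s comfortably covers a
longest T1 of ~2 s) and when temperature varies across a measurement set
(it shifts positions and intensities). NS and RG are deliberately *not*
flagged for varying: normalizing them out is the point of the method.
`check_snr()` warns for signals below 200:1, where integration noise starts
to contribute visibly to concentration estimates.

## Problem sizes used in tests and the acceptance script

Simulated sets are 20–40 spectra of 16384 complex points (three signals,
five concentrations, two to four settings, duplicates); phase-correction and
pipeline checks run on one to two FIDs each. These sizes exercise every code
path at full spectral resolution while keeping the whole suite in the
seconds range; the method's arithmetic is size-independent, so larger sets
only narrow stochastic tolerances already met at this scale.

## Known limitations

* Overlapping signals are the user's responsibility: regions may overlap
  (with a warning), but no deconvolution is attempted — signals unusable due
  to overlap should simply not be given regions, as in the reference
  workflow.
* The linearization is a lookup over calibrated RG steps; a step never seen
  in calibration is interpolated linearly, which assumes locally smooth gain
  deviation between neighboring steps.
* The published per-sample back-calculations can be validated against the
  published regression only to the printed precision; with two-decimal
  inputs the linearized-fit intercept reproduces to ~0.004 rather than the
  fourth decimal, a rounding floor of the printed table, not of the method.
* Real-spectrum effects not in the generator (solvent suppression residues,
  T1 bias from too-short D1, probe background) must be controlled
  experimentally; the metadata checks flag the relaxation and temperature
  conditions but cannot repair violations.
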