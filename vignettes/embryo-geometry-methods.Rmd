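---
title: "Measuring morphogen gradients along the embryo perimeter: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring morphogen gradients along the embryo perimeter: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bcdgeom)
```

## The scientific problem

The Bicoid (Bcd) protein forms an exponential anterior-posterior (A-P)
concentration gradient in the early *Drosophila* embryo and switches on its
target genes — most prominently Hunchback (Hb) — in a concentration-dependent
manner. Position along the A-P axis can be quantified in two inequivalent
ways: the **projected distance** `x`, the straight-line coordinate of a point
projected onto the A-P axis, and the **contour distance** `c`, the arc length
along the dorsal or ventral perimeter from the anterior pole. Because the
ventral side of the embryo is more strongly curved than the dorsal side, the
ventral perimeter is longer, and the two coordinate systems disagree in a
side-dependent way. Comparing Bcd profiles and Hb boundary positions between
the two sides in both coordinate systems therefore discriminates whether the
gradient measures distance through space (`x`) or along the nuclear layer
(`c`).

`bcdgeom` implements this comparison end to end: embryo outline geometry and
the two distance systems; sliding-window extraction of cortical intensity
traces; exponential gradient fits (`B = B0 e^(-c/lambda)`); half-maximal
boundary detection; Hill input-output fits
(`H = (B/K_d)^n / (1 + (B/K_d)^n)`); intensity-noise and positional-error
profiles (`sigma_c = deltaB / |dB/dc|`); iso-concentration contours on an
average embryo frame; and a 3-D nuclear-cycle reaction-diffusion simulator
that asks whether a curvature difference alone can produce the observed
dorsoventral gradient differences.

## The synthetic cohort: what it emulates and what it does not

No raw experimental images or traces are publicly deposited for this system;
the quantitative anchors are cohort-level summary statistics. The
synthetic-data generator therefore emulates cohorts whose *statistical
structure* matches those anchors, with every generating parameter known, so
each pipeline stage can be validated by parameter recovery.

A generated embryo consists of:

* a **shape**: two half-ellipses joined on the A-P axis, sampled around the
  asymmetric reference geometry (length 560 um, lateral diameter 220 um,
  dorsal/ventral heights 92/128 um — the same idealization used by the
  simulator). Shape SDs (15/8/6/6 um) are chosen to give cohort variability
  of the same order as the reported contour-length SDs (about 18 um).
  Shapes with a height below 20 um are rejected as degenerate.
* **Bcd traces**: exponential in contour distance with length constants
  104.8 um (dorsal) and 115.5 um (ventral), multiplicative per-window noise
  (CV 0.20 dorsal, 0.30 ventral — the ventral excess produces the observed
  higher ventral intensity noise), a shared per-embryo amplitude factor
  (CV 0.15, the embryo-to-embryo reproducibility term), and additive imaging
  background 2.19/2.13 intensity units.
* **Hb traces**: a Hill switch (K_d = 5 intensity units, n = 5) applied to
  the background-free Bcd level, plus additive Gaussian noise (SD 0.10 in
  normalized units), clipped at zero.

The default amplitudes are fixed by a calibration with known truth: the
background-free gradient crosses K_d exactly at contour distances
284.6/279.1 um, the reference wild-type Hb boundary positions. This single
choice reproduces, simultaneously, the dorsal-greater-than-ventral amplitude
ordering, a contour-distance boundary separation of ~5.5 um, and a much
larger projected-distance separation — the geometric convergence effect the
analysis is designed to detect.

The generator does **not** emulate: nucleus-scale texture (traces are window
means by construction), the posterior Hb expression domain, staining batch
effects, or any A-P/D-V regulatory interaction. Passing recovery tests
therefore demonstrates correctness of the estimators under the stated noise
model, not robustness to every artifact of real immunostaining data.

Windows are laid along the perimeter offset 6 um inward (the nuclear layer),
one window per pixel (0.5 um) by default. Tests and the acceptance study use
a 2-um window spacing: the scanning window itself has a ~5.6 um diameter, so
2-um spacing still oversamples the 5.5-um analysis bins while keeping 200
replicate cohorts cheap.

## Estimator design choices

**Exponential fits** are linear least squares on log-intensity, restricted
to the window `[0.10, 0.60]` of each profile's position support: the
anterior-most region deviates from a single exponential (and is excluded for
that reason), the posterior region approaches the background floor.
Non-positive background-subtracted values are excluded and counted.
Log-space fitting is standard for strictly positive decay data and makes the
fit scale-equivariant (amplitude rescaling changes `B0`, never `lambda`).

**Hb normalization** maps, per embryo, the mean over an anterior plateau
window to 1 and the mean over a non-expression trough window to 0. The
defaults are x/L in [0.10, 0.30] (plateau) and [0.65, 0.80] (trough). Both
windows were placed where the noiseless calibrated readout is flat: with the
default amplitudes the Hill readout still rides at ~0.85 near x/L = 0.35 on
the ventral side and its tail is ~0.03 near x/L = 0.55, so windows extending
there would bias the normalization anchors and steepen every downstream
Hill fit. Both windows are arguments, not constants.

**Boundary detection** takes the most anterior downward half-maximum
crossing after an 11-window running mean (spurious noise crossings trigger a
warning and are skipped by the smoother); the projected and contour boundary
coordinates are interpolated from the same bracketing window pair, so the
two coordinate systems describe the identical biological location.

**K_d** is reported exactly as operationally defined: the
background-subtracted Bcd intensity interpolated at the embryo's own contour
boundary position.

**Per-embryo Hill coefficients** are fitted by nonlinear least squares with
a multi-start over n in {1, 3, 5, 8}. The default input variable is the
embryo's own fitted exponential gradient evaluated at each window
(regression calibration), with K_d co-fitted. Regressing on the raw windowed
intensities instead (available via `hill_input = "windowed"`) attenuates the
Hill coefficient by roughly 20% at the calibrated window noise — the classic
errors-in-variables flattening of a steep response curve — and fixing K_d at
a single noisy measured value has a similar effect; the calibrated input
removes both at no cost on noiseless data. Whether the original per-embryo
estimates fixed or co-fitted K_d is not decisive here: both modes are
implemented in `fit_hill()`.

**Noise and positional error.** Intensity noise deltaB/B is the
across-embryo SD of per-embryo bin means divided by the across-embryo mean;
bins with fewer than 3 embryos are dropped, and measurement/background noise
is deliberately *not* subtracted. The conversion to positional error uses a
local linear regression of the mean profile over 5 bins for the slope; for
an exponential profile this reproduces `sigma_c = lambda (deltaB/B)` to
within ~1% when the regression span stays below about half the length
constant.

**Side comparisons** use the classical pooled-variance two-tailed Student
t-test (Welch available by flag), and no multiple-testing correction is
applied by default — the analysis reports raw per-bin p-values. Boundary
slant statistics are paired within embryos. Bootstrap SDs resample embryos
with replacement.

**Iso-concentration contours** invert the binned mean profiles on their
monotone anterior section (posterior of the profile maximum, anterior 55% of
the support) and interpolate the position where each side's profile equals a
threshold; threshold series default to steps of 0.5/1/1.5 intensity units
for 1x/2x/3x-dosage cohorts so the contour lines spread legibly.

## The 3-D nuclear-cycle reaction-diffusion model

The simulator implements gradient formation on the asymmetric
semi-ellipsoid embryo:

* **Synthesis**: constant aggregate rate J = 1000 molecules/s spread
  uniformly over an anterior mRNA sphere (radius 45 um, centre (75, 0, 0)
  um), making J independent of the voxel size.
* **Diffusion**: only free Bcd diffuses, between 6 face neighbours, with
  zero-flux boundaries at the embryo surface (a closed syncytium).
* **Degradation**: first-order, rate omega = 5e-5 /s, applied to total Bcd
  (the degradation rate is described as spatially uniform, with no
  restriction to the free pool).
* **Nuclear binding**: instantaneous local equilibrium with non-specific
  DNA, parameterized by the bound-to-free ratio r; free = total/(1 + r).
  This is the standard retarded-diffusion formulation of fast equilibrium
  binding. Total binding capacity doubles every nuclear cycle. Before cycle
  10 the nuclei (and their capacity) occupy the whole interior; at the onset
  of cycle 10 the capacity relocates to a 10-um cortical layer, where
  r = 0.15 at cycle 10 and doubles per cycle thereafter (r = 2.4 at cycle
  14). The pre-cycle-10 interior ratio is scaled by the cortical-to-interior
  volume ratio so that capacity is conserved across the relocation.
* **Schedule**: cycles 1-9 at 8 min each, cycles 10-13 at 9/10/12/21 min,
  readout 14 min into cycle 14 (about 138 min total). The late-cycle
  interphase lengthening follows published blastoderm staging; the schedule
  is fully configurable.

The explicit scheme requires `dt < h^2/(6D)`; initialization refuses
unstable settings and reports the admissible step. With zero degradation the
scheme conserves mass to floating-point accuracy, which the tests verify
over 10^4 steps. A pure-R reference implementation of the step is kept
alongside the compiled kernel and the two are tested for exact agreement; a
1-D rod harness checks the analytic screening length
`lambda = sqrt(D/omega)` (200 um at the reference parameters).

The cortical layer is defined by the exact Euclidean distance to the
side-specific ellipsoid surface (solved by bisection on the closest-point
problem), so the 10-um nuclear layer has uniform thickness regardless of
local curvature. Simulated profiles are read out with the same
sliding-window geometry as the experimental pipeline (windows inset 6 um
from the midsagittal outline, averaging cortical voxels of the midsagittal
slab), so every downstream statistic applies to simulated and synthetic
data identically.

Reference runs in the tests and the acceptance study use a 5-um grid and
dt = 0.5 s. Discretization robustness is checked in the test suite on a
half-scale embryo: halving the voxel edge and dividing the time step by
five changes the fitted length constants by well under the 5% bound asserted
there, and preserves the dorsoventral orderings.

### Known limitations of the simulator

Within-cycle nucleocytoplasmic shuttling, mitotic release, dorsoventral
nuclear-density differences and cortical nuclear flow are not modelled. The
absolute concentration scale depends on bookkeeping choices for the nuclear
binding capacity that the available description underdetermines: with the
capacity-conserving relocation used here, the peak dorsal cortical
concentration at the reference J is about 5 molecules/um^3, well below the
published peak of 37.1 molecules/um^3 — amplitude scales linearly with J and
with the assumed capacity concentration, whereas the three comparative
observables (dorsal > ventral peak, ventral > dorsal length constants,
projected > contour threshold separations) are insensitive to both, and are
the quantities this package is designed to reproduce.

## Problem sizes used by the tests and the acceptance study

The test suite and `scripts/acceptance.R` use: the 5-um/0.5-s simulator
grid; synthetic cohorts of 28 embryos at 2-um window spacing; 200 replicate
cohorts for the recovery study; 1000 bootstrap replicates. These sizes were
chosen so the full study re-runs comfortably on a single CPU while keeping
every Monte-Carlo rate estimate within a few percent.

## A worked example

```{r example, eval = FALSE}
library(bcdgeom)

spec <- cohort_spec(n_embryos = 28, window_spacing = 2, seed = 1)
cohort <- generate_cohort(spec)
res <- analyze_cohort(cohort_traces(cohort),
                      contours = lapply(cohort, `[[`, "contour"))

res$fit_summary          # lambda per side and axis
res$slant                # boundary separations Delta x_Hb, Delta c_Hb
res$io_summary           # K_d and Hill n per side, with D-vs-V p-values
res$sigma_c              # positional error at the boundary, per side
head(res$iso)            # iso-concentration contour table
```

Every number in the README's worked example is the output of exactly this
code at the stated seed.
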