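---
title: "Quantifying stain penetration in matrix-embedded spheroids: models and estimator design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying stain penetration in matrix-embedded spheroids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spherostain)
```

## Scope

This package quantifies whole-mount immunofluorescence staining of
multicellular spheroids embedded in thick hydrogels, from a single
confocal center slice per spheroid. It covers five linked analyses:

1. segmentation and background estimation with one threshold per channel
   across an image set;
2. background-corrected intensity statistics (signed mean intensity, total
   normalized intensity) per spheroid and channel;
3. the half-maximum radial penetration depth and its fractional form;
4. staining-time-course regression and a variance-gated two-group
   comparison;
5. staining-protocol schedules and total processing-time arithmetic.

Because raw microscope data for this kind of experiment are rarely
deposited, the package ships a synthetic image generator with exact ground
truth. The generator is first-class, tested code: every downstream
estimator is validated by recovering known fronts and intensities from
images it has never "seen" outside pixel space.

## The staining-front model

Antibody penetration into a dense spheroid is modeled as a radial front at
depth $d^\*(t) = v\,t$ from the spheroid surface after staining time $t$
(minutes), capped at the radius. `front_velocity` ($v$, µm/min) is the one
free parameter of the kinetic model; the default 0.91 µm/min makes a
100-µm-radius spheroid reach complete penetration at about 110 min, the
regime the densely packed epithelial preset emulates. The cancer-line
preset uses a higher velocity (2.25 µm/min) because spheroids with weak
cell–cell junctions present less of a diffusional barrier and stain to
completion in tens of minutes at comparable radii.

A sharp front (`front_width = 0`) multiplies each antibody-stain structure
by an indicator `depth <= v t`. A positive `front_width` replaces the step
with a complementary-error-function shoulder centered on the front (value
exactly 0.5 at the front), the natural profile of a diffusion-limited
boundary. Linearity of front advance is an empirical simplification, not a
diffusion solution; it matches the regime where depth-vs-time plots are
well fit by a line.

The nuclear counterstain is deliberately *not* front-limited: it is a
separate, saturating small-molecule staining step, so the nuclear channel
is rendered at full intensity at every depth. This mirrors real protocols
(the nuclear stain is applied after the primary antibodies and penetrates
much faster) and is what makes the nuclear channel usable for spheroid
delineation even when antibody penetration is partial. Its ground-truth
front depth is recorded as the radius.

## What the generator emulates — and what it does not

Cells are placed by seeded blue-noise (minimum-distance dart throwing)
inside the spheroid disk; `cell_min_spacing` is the single density knob
(8 µm dense vs 11 µm loose in the presets). Four channels are rendered
from the packing: nuclei as disks (radius 3 µm), nuclear-envelope rings as
1-µm annuli, Golgi as 0.8-µm puncta offset from each nucleus, and the
cell-junction stain as 1-µm ridges along the boundaries between
neighboring cells (the Voronoi boundary network of the packing). Matrix
pixels outside the spheroid carry `rim_intensity ×
matrix_background_fraction` of residual, un-washed-out stain (default
fraction 0.1). The field is blurred with a Gaussian PSF (default σ
0.75 µm), degraded with Poisson shot noise (`poisson_scale`, default 1,
i.e. variance = mean) plus Gaussian read noise (default SD 50), clipped
and quantized to 16 bits. Identical parameters and seed give bit-identical
images; all child seeds derive deterministically from one master seed.

Default geometry is 0.5 µm/pixel on a 1024×1024 field so a 200-µm spheroid
is well resolved while images stay small; tests and the acceptance script
pass a 512-pixel field where the spheroid fits, and state so below. No
intensity scale is physically meaningful: `rim_intensity` (default 10 000
detector units) is configuration, not biology.

Not emulated: 3-D volumetric rendering (only a 2-D center slice, with a
thin-stack helper for mid-slice selection), depth-dependent optical
attenuation, collagen-fiber (second-harmonic) channels, cell morphology
changes, or spatial heterogeneity of packing. Passing recovery tests on
these images therefore demonstrates correctness of the *estimators* under
realistic sparsity, blur and detector noise — not robustness to every
artifact of real confocal data (refractive-index mismatch, bleaching,
mosaic stitching).

## Segmentation and intensity statistics

Thresholds are determined once per analysis set — either fixed per channel
from configuration, or automatically as Otsu's criterion on the pooled
per-channel histogram of all images — and applied identically to every
image, so intensity statistics are comparable across conditions. A
constant channel makes the automatic threshold undefined and is an error.

The spheroid is delineated from the nuclear channel: threshold,
morphological closing with a 5-µm disc (configurable) to bridge the gaps
between nuclei, hole filling, largest connected component. The centroid,
pixel area, µm² area and equivalent circular diameter
$2\sqrt{A/\pi}$ are reported. On ideal disks the measured area is within
2% of $\pi r^2$; on cell-packed spheroids the mask scallops between
surface nuclei and is conservative by a few percent — the worked numbers
in the README show the effect (equivalent diameter 194.5 µm for a 200-µm
spheroid).

Mean background comes from the sub-threshold ("inverse") region; three
region conventions are provided: the whole field (default), matrix only
(outside the spheroid mask), and cytoplasm (inside it), the latter for
stains with nonspecific intracellular background. The signed mean
intensity is *positive mean − background mean*: the sign convention is
chosen so that a negative value reads "background outstains the spheroid",
which is the interpretation used when reporting such values. Total
normalized intensity divides the background-corrected positive total by
the spheroid area, in pixels by default (TNI in intensity per pixel);
a µm² denominator is available and flagged in the output, since the units
of the area term are a genuine ambiguity. TNI is homogeneous of degree 1
under joint scaling of image, threshold and background — a property the
test suite asserts directly.

## The half-maximum depth estimator

The headline statistic is measured per spheroid and channel:

1. **Profiles.** `n_lines` (default 36) evenly angled rays run from the
   perimeter to the center, sampled every `step` (default one pixel) µm of
   depth. Each sample is the mean of bilinear interpolants spread along a
   circular arc of length `transverse_width` (default 10 µm) at constant
   distance from the center. The arc — rather than a straight transverse
   chord — keeps every sample at exactly the nominal depth; with a chord,
   off-axis samples sit at slightly larger radius and smear the front
   outward by up to ~1 µm near the center. Thick-line sampling exists
   because the stains are sparse: a one-pixel profile of a boundary-network
   stain is zero between cells, and any half-max rule on it would fire at
   the first inter-cell gap. The transverse average estimates the local
   azimuthal-mean intensity envelope that the half-max rule presupposes.
2. **Rim reference.** One pooled mean of all samples with depth ≤
   `rim_band` (default 5 µm) across all lines — a single perimeter
   reference per spheroid/channel, not per line.
3. **Crossing.** After a centered moving average of `smoothing_window`
   samples (default 3), the front on each line is the smallest depth at
   which the smoothed profile falls below half the rim reference *and
   stays below* for at least `persistence` µm (default 12, about one cell
   diameter) or until the center. The interpolated crossing of the
   bracketing samples is reported. The persistence requirement is the key
   robustness device: transient dips shorter than a cell are gaps in the
   stain pattern, not the front. A profile with no sustained crossing is
   flagged complete and contributes the full radius to the average — the
   unbiased choice near completeness.
4. **Summary.** Mean and SD of per-line depths; fractional depth =
   mean depth / radius, clipped to [0, 1]; `complete` when every line is.

Fractional depth is normalized by the *radius* (half the equivalent
diameter), the only reading under which "complete penetration" of a
~200-µm spheroid at ~100-µm radial depth maps to fraction 1.0.

With noise and blur off and sharp fronts at 10–90% of the radius, the
estimator recovers the true front within one pixel (0.5 µm); the test
suite sweeps this. With default noise the residual errors are at the
1-µm scale and unbiased enough that the time-course slope recovers the
generator's front velocity within its standard error.

## Regression and group comparison

The time course is ordinary least squares of response (depth in µm, or
fractional depth) on staining time, not forced through the origin (real
depth-vs-time data show nonzero intercepts). R² is defined as 0 when the
responses have zero variance. The predicted complete-penetration time
solves `intercept + slope t = 1` for the fractional fit and requires a
positive slope. Note one structural bias: once spheroids reach complete
penetration, fractional depth saturates at 1, which flattens the fitted
line and pushes the solved time a few minutes late relative to the true
first-completion time; with times 20–120 min and completion near 110 min
the effect is ≈5 min and sits well inside the stochastic tolerance used in
validation.

Group comparison follows the two-stage convention: a two-sided F-test of
variance equality at α (two-sided because the reporting convention being
matched does not state a direction; `p = 2·min(tails)`), then Welch's
t-test if variances differ, otherwise the pooled-variance Student's
t-test, both two-tailed, with significance at p < 0.05 and the usual star
labels (\*\*\* p ≤ 0.001, \*\*\*\* p ≤ 0.0001). No multiple-testing
correction is applied across channels — deliberately matching the
single-comparison-per-channel reporting style this pipeline mirrors; users
comparing many channels should apply their own correction. Implementations
are `stats::var.test`, `stats::t.test` and `stats::lm`; the test suite
verifies them against independent closed-form oracles to 1e-9 on random
fixtures, and summaries are mean ± sample SD (n − 1), with SD reported as
0 and flagged for n = 1.

## Protocol schedules

Staining protocols are ordered step tables (stage, solution, minutes,
temperature) for the microwave-assisted, benchtop and longform-benchtop
variants, with per-sample primary staining times (120 min for the dense
epithelial line in collagen, 90 min in basement-membrane matrix, 40 min
for the cancer line, and a 15-h longform primary). Totals are plain sums;
fixation (45 or 20 min, stored separately) is excluded by default because
it is performed identically on the bench in all variants, and included on
request for end-to-end claims. Hours are rounded half-up to one decimal.
The ratio of two totals quantifies workflow speedup; the built-in tables
give 186 min (3.1 h) for the microwave workflow vs 1300 min (21.7 h)
longform — a 7.0× ratio — and these arithmetic identities are asserted in
the test suite. Schedules round-trip bit-exactly through a plain
tab-separated file format. The reference thicknesses of the two-layer
embedding gel (197.5 and 607.7 µm, summing to ≈800 µm) are provided as a
lookup for reports.

## Numerical choices and degenerate inputs

* Pixel indexing is 0-based at the top-left; physical coordinates are µm
  from the top-left pixel center; bilinear samples are clamped to the
  pixel-center hull.
* Mid-slice selection takes the slice nearest `(z_top + z_bottom)/2`; an
  exact tie goes to the lower index; equal top and bottom positions are an
  error.
* Thresholding uses `>=` for positive pixels so the masks partition the
  field exactly.
* Empty positive masks give mean intensity NA-with-error (undefined mean)
  but TNI 0 (an empty sum is a measurement, not an error).
* Errors name their context: the failing spheroid id in pipeline runs, the
  background region mode when a region is empty, the channel when a
  histogram is degenerate.
* All randomness flows from explicit integer seeds; child seeds are
  derived with a fixed linear congruence and stay below 2³¹.

## Problem sizes used in validation

The shipped tests run spheroids of 60–120 µm diameter on 128–320-pixel
fields for unit-level checks, and the acceptance checks use 200–220-µm
spheroids on 512-pixel fields: a 30-image noisy time course (5 spheroids ×
6 times) for the completion-time regression and a single noiseless
spheroid for deterministic front recovery. These sizes were chosen so the
full validation cycle runs in minutes on one core while keeping the
spheroid-to-pixel scale identical to the default configuration.

## Known limitations

* The half-max estimator assumes a bright rim; a stain absent from the
  perimeter (rim mean ≤ 0 after correction) is an error, not a depth of 0.
* Fractional depth inherits the segmentation's conservative radius, so it
  is biased upward by a few percent on densely packed spheroids.
* The completion-time estimate inherits the saturation bias described
  above; fitting only pre-completion times removes it at the cost of
  discarding data.
* The generator's front is angularly uniform; real spheroids show angular
  heterogeneity that would widen the per-line depth SD without changing
  the mean estimator.
* Only 2-D center-slice analysis is implemented; no spherical-shell
  (3-D) penetration measurement.
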