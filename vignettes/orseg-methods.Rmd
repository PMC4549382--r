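---
title: "Phantom-validated retinotopy-informed tractography of the optic radiation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phantom-validated retinotopy-informed tractography of the optic radiation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orseg)
```

## The scientific question and the pipeline

The optic radiation (OR) carries visual input from the lateral geniculate
nucleus (LGN) to occipital cortex. Whether the OR projects directly not only
to primary visual cortex (V1) but also to extrastriate areas V2 and V3 can
be asked in vivo by combining two measurements: functional delineation of
the visual areas from retinotopic mapping, and diffusion-based streamline
tractography seeded in the LGN with those areas as targets. `orseg`
implements that full analysis as a tested pipeline:

1. **Stimulus construction** — rotating-wedge and expanding/contracting-ring
   apertures on a discretized visual field, plus a photic-burst schedule.
2. **pRF modeling** — a single isotropic Gaussian population receptive
   field per vertex, forward-modeled through the apertures and a
   double-gamma HRF, fitted in two stages (exhaustive grid search, then
   Nelder-Mead refinement).
3. **Area delineation** — automated detection of polar-angle reversals on a
   flat cortical sheet, yielding V1d/V1v, V2d/V2v, V3d/V3v and the V3A
   control region, with per-region surface areas.
4. **Diffusion modeling and tracking** — log-linear tensor fits, FA/MD
   maps, an FA >= 0.7 eroded white-matter skeleton, and bidirectional
   probabilistic streamline propagation (step 0.2 mm, FA threshold 0.1,
   10,000 streamlines).
5. **Streamline screening and segmentation** — four geometric rejection
   heuristics, termination labeling, and two Boolean segmentation schemes
   (visual-field-based: dorsal/ventral; hierarchy-based: V1/V2/V3), with
   percentages, area-normalized counts, and a control-region
   false-positive ratio.
6. **Statistics** — visitation-map sampling of FA/MD, paired t tests with
   Bonferroni correction, and two-way within-subject ANOVAs.

Because no subject data are distributed with the package, every stage is
exercised on synthetic phantoms with known ground truth. The phantoms are
first-class, seeded generators, not fixtures; all headline numbers in the
test suite and acceptance script are recomputed from them at run time.

## Stimulus model

The visual field is rasterized on a square grid of `grid_n x grid_n` pixel
centers spanning `[-R, R]` degrees (default `grid_n = 101`,
`R = 10.40` degrees). The wedge subtends 17.14 degrees of polar angle and
advances `360/21` degrees per 2.376 s volume; the ring's width scales
logarithmically from 0.11 to 4.62 degrees over 15 volumes per revolution.
The raster resolution is a numerical choice: for pRF sizes of 1.5 degrees
and above, predictions change by under 1% RMS when the grid is doubled,
which the test suite asserts. Quantization error grows as sigma approaches
the pixel spacing (about 6% at sigma = 0.5 degrees on the default raster),
so studies of near-foveal, sub-degree pRFs should raise `grid_n`.

Two choices are under-determined by the protocol and fixed here once: the
wedge starts on the right horizontal meridian with angles measured
counter-clockwise, and the ring's inner radius follows
`inner = (R - w) * (w - w_min) / (w_max - w_min)` so that the ring sweeps
from fixation to the field edge within each revolution while inheriting the
logarithmic pacing of the width sequence. A mapping run combines 10 wedge
with 14 ring revolutions (both 210 stimulation volumes) plus 24 blank
volumes, i.e. 234 volumes per run; the burst condition presents 1 stimulus
volume followed by 14 rest volumes, 10 times (150 volumes).

## pRF model and the two-stage fit

Each vertex's drive is the area-weighted overlap between the binary
aperture and a Gaussian receptive field `exp(-((x-x0)^2+(y-y0)^2)/(2s^2))`,
convolved with a difference-of-gammas HRF and z-scored. The HRF
parameterization uses the gamma mean as the "delay" (shape =
delay/dispersion, scale = dispersion), so the kernel mode sits at
`delay - dispersion`; the subject-level fit estimates the two delays and
the peak/undershoot ratio from the event-locked average burst response,
with both dispersions fixed at 1 s to keep the three-parameter fit
well-posed on a 15-volume epoch. Fits explaining less than half the epoch
variance (`r2_floor = 0.5`) are flagged degenerate; on pure-noise series
the epoch average can still absorb roughly 20-40% of the variance, so a
lower floor would pass noise as signal.

The grid stage evaluates a polar lattice (12 angles x 8 log-spaced
eccentricities up to the field radius, 6 log-spaced sigmas in
[0.2, 5] degrees) by Pearson correlation on spatially smoothed series
(FWHM 8.3 mm); the winner seeds a Nelder-Mead simplex over
`(x0, y0, log s)` on the unsmoothed series. Correlation is
scale-invariant, so amplitude is recovered afterwards by least squares.
The refinement returns its starting point (flagged) whenever the simplex
fails to improve the starting correlation, which makes the grid-to-refine
correlation non-decreasing by construction — asserted per vertex in the
tests. Vertices whose grid correlation falls below 0.1 are excluded from
delineation; the threshold for map inclusion is not prescribed by the
protocol and 0.1 simply removes the unresponsive tail.

## Sheet geometry and delineation

The package delineates areas on a flat rectangular sheet — a deliberate
stand-in for a folded, FreeSurfer-reconstructed surface. Smoothing is
therefore plain 2D Gaussian kernel smoothing over vertex coordinates, and
delineation reduces to 1D reversal detection: polar angle is averaged
along iso-eccentricity lines, local extrema of the profile (with a
30-degree prominence guard against noise wiggles) become band boundaries,
the band spanning the largest polar-angle range (a full hemifield with no
internal reversal) is V1, and bands are labeled outward as V2 and V3 on
each side, with the band beyond dorsal V3 labeled V3A. The dorsal/ventral
split inside V1 follows the sign of the pRF center's vertical coordinate.
This automates what is done manually on real surfaces, and is validated
only against the phantom's construction — the tests require at least 95%
vertex agreement on noiseless maps and localize any disagreement to within
two rows of a true boundary.

## Tensor model, tracking, and the curvature constraint

Tensors are fitted by weighted log-linear least squares (weights = squared
signal); FA and MD follow the standard eigenvalue formulas with the zero
tensor assigned FA 0. The white-matter skeleton retains FA >= 0.7 and
applies 6-connected erosion.

Tracking propagates bidirectionally from uniformly sampled seed-ROI
points in 0.2 mm steps. The protocol's curvature setting is stated in
millimeters; it is interpreted here as a minimum radius of curvature of
1 mm, giving a maximum turning angle per step of
`2 asin(step / (2 radius))` (about 11.5 degrees at the default step).
This is an interpretation, not a protocol fact, and is isolated in
`tracking_params()` where it can be overridden.

Direction sampling perturbs the local principal eigenvector with an
isotropic Gaussian of standard deviation `dispersion * (1 - FA)` before
renormalization, sign-aligned with the previous step: sampling is sharper
where FA is high, collapses to deterministic eigenvector tracking as
`dispersion -> 0` (asserted as a pathwise-convergence test), and requires
no fiber-ODF machinery, which is out of scope for tensor phantoms. When a
draw repeatedly violates the curvature cone while the eigenvector itself
satisfies it, the eigenvector is used for that step; termination on
unlucky draws would conflate the curvature constraint with the dispersion
model. Randomness is organized as one master seed plus per-streamline
counter-indexed PCG32 substreams, so any subset of streamlines is
bit-reproducible.

## Rejection heuristics and segmentation

The four anatomical rejection rules are geometric predicates: (a) any
point across the midsagittal plane; (b) initial 5 mm mean direction from
the LGN elevated above 45 degrees; (c) any point simultaneously anterior
to the temporal-pole plane and inferior to the LGN; (d) at least 50% of
points within one voxel of the ventricle medial-wall mask with local
tangent within 20 degrees of the wall plane. The thresholds (5 mm, 45
degrees, 50%, 20 degrees, one voxel, and the 2 mm termination-assignment
radius) are configuration defaults — the original screening was done
manually in a viewer, so these values are validated only against
constructed ground truth, where recovery must be exact. Rules are reported
with precedence a > b > c > d.

Termination labels are the area labels within 2 mm of the cortical
endpoint (the endpoint farther from the LGN). The visual-field scheme
assigns streamlines terminating exclusively in dorsal (ventral) areas to
the dorsal (ventral) segment; the hierarchy scheme assigns streamlines
projecting exclusively to one area (dorsal and ventral components
combined) to that area's segment; mixed or unlabeled terminations are
excluded. Percentages are taken over a hemisphere's non-excluded
streamlines and must total 100.

## Statistics

Per-segment FA/MD are unweighted means over the segment's visitation-map
support (a voxel counts once per streamline; with 0.2 mm steps against
1 mm voxels, point-in-voxel membership approximates exact segment-voxel
intersection). The repeated-measures ANOVA uses the classical univariate
within-subject partition — subject as a blocking factor, each effect
tested against its own subject-by-effect stratum — implemented through
`stats::aov()` error strata and verified in the tests against a
brute-force sums-of-squares partition on a hand-worked 3 x 2 x 2 table.
No sphericity correction is applied (a limitation; with two-level factors
the question does not arise, and three-level hierarchy contrasts should be
read accordingly). Bonferroni correction is `min(1, m p)`.

## The phantoms: what they emulate, and what they do not

**Retinotopic sheet.** Bands ordered V3v, V2v, V1, V2d, V3d, V3A carry a
continuous piecewise-linear polar-angle path with reversals at the
vertical- and horizontal-meridian representations; eccentricity runs along
the orthogonal axis and pRF size grows linearly with eccentricity
(`sigma = 0.5 + 0.25 ecc` by default). BOLD noise is white Gaussian with
sd 0.5 relative to the unit-variance signal — the condition used in the
recovery studies. The sheet is flat, noise is white (no physiological
autocorrelation), and V3A is simplified to one full-hemifield band, so
passing tests demonstrate correctness of the machinery, not performance on
folded cortex with structured noise.

**OR tensor phantom.** Six prolate bundles (eigenvalues
1.7/0.2/0.2 x 1e-3 mm^2/s — literature-typical magnitudes, as are the
background 0.8/0.7/0.7 and CSF 3.0 values) run from an LGN-analogue seed
region to cortical target blocks along laterally bowed C-shaped
centerlines, medio-laterally nested V1 < V2 < V3 and split
dorsal/ventral. An isotropic CSF slab sits beneath the posterior ventral
route, and ventral bundle voxels adjacent to it receive a 30%
partial-volume blend, so the ventral segment's mean MD exceeds the
dorsal's by construction — the phantom analogue of the ventral route's
proximity to the ventricle's posterior horn. The V3A target block receives
no bundle, making it a true-negative control: its termination count
estimates the tracker's false-positive behavior. Geometry constants
(4 mm start-lane spacing, 1.45 mm tube radius, 6 mm end-lane spacing,
12 mm dorsal/ventral separation) were chosen so that tubes clear each
other (construction refuses intersecting tubes) while target blocks stay
farther apart than the 2 mm assignment radius; the voxelized tubes are
only 2-3 voxels wide, so a substantial fraction of streamlines leaves the
corridor early and never reaches a target — realistic in spirit, and the
reason counts, not yields, are the quantity of interest.

**Labeled tractogram.** Streamlines with known termination labels plus
planted violations of each rejection rule, jittered and resampled to exact
step spacing; classification must match construction exactly.

## Problem sizes and numerical choices

The shipped studies use a 25 x 8-vertex sheet (200 vertices) with a
61-pixel stimulus raster for the recovery study, the 40 x 50 x 40-voxel
phantom with 10,000 streamlines per run (about a second per run), ten
seeded repetitions for the control-condition comparison, and 300-500
simulations for the ANOVA null calibration. These sizes make the full
suite and the analysis scripts comfortably reproducible on a single CPU
while keeping every Monte-Carlo margin wide. Ties in the grid stage break
toward the lowest lattice index; degenerate predictions (zero-variance
drive) are excluded from correlation rather than scored; eigenvalue
decomposition uses a cyclic Jacobi sweep, exact for symmetric 3 x 3
tensors to near machine precision.

## Known limitations

- Flat-sheet delineation and Euclidean smoothing do not model cortical
  folding; boundary placement on real surfaces needs geodesic machinery.
- The tensor phantom cannot represent crossing fibers, so the tracking
  validation exercises geometry and stopping rules, not fiber-model
  selection.
- BOLD and diffusion noise models are Gaussian and noiseless
  respectively; Rician DWI noise and physiological BOLD confounds are out
  of scope.
- The cohort in the statistics driver varies only by tracking seed, so
  between-subject variance reflects sampling alone.
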