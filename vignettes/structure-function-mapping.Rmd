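---
title: "Structure-function mapping of intact hearts with cardiomapr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-function mapping of intact hearts with cardiomapr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 5)
library(cardiomapr)
library(dplyr)
```

## The problem

After myocardial infarction the surviving myocardium bordering dense scar —
the border zone (BZ) — remodels both structurally (disordered myofibers,
sympathetic nerve sprouting) and functionally (slow, anisotropic
conduction, altered repolarisation control). Relating the two requires
putting panoramic optical voltage maps and cleared-tissue structural
imaging of the *same* heart into one coordinate frame and then quantifying
each side with statistics suited to the data: axial angles for fiber axes,
full angles for conduction directions, micrometre-binned lengths for nerve
fibers, and exact small-sample rank tests for designs with a handful of
hearts.

`cardiomapr` implements that pipeline end to end: voltage-movie processing
into activation and APD80 maps; conduction-vector fields and tissue
activation times; axial fiber-orientation fields and a regional anisotropy
index; tubular nerve tracing with diameter binning and a prevalence index;
fiducial-homography registration; and the circular, permutation and exact
rank statistics the composite analyses need. A seeded synthetic-heart
generator supplies ground truth for every stage, so the whole chain is
testable without any imaging data.

## The two indices

**Anisotropy index.** For an ROI, fiber angles are summarised by axial
circular statistics and the index is the coefficient of variation divided
by the ROI area:

$$\mathrm{AI} = \frac{\sigma_\theta / \bar\theta}{A},$$

with $\bar\theta$ the axial circular mean, $\sigma_\theta$ the axial
circular SD (both in degrees) and $A$ the ROI area in mm².  Axial data are
$\pi$-periodic, so all statistics run through the double-angle transform:
$\bar R = |\langle e^{2i\theta}\rangle|$, $\sigma_\theta =
\tfrac12\sqrt{-2\ln\bar R}$.  Without this transform a field mixing
near-0° and near-180° fibers would average to a meaningless 90°.  Note the
CoV depends on the angular reference frame (the mean sits in the
denominator); `anisotropy_index()` therefore exposes
`reference_angle_deg`, reports the mean and SD separately, and refuses
means within 2° of the axial wrap where the ratio diverges.

**Prevalence index.** Traced nerve segments are binned by mean diameter
into small [1.2, 3), medium [3, 5) and large [5, 100] µm classes (1.2 µm is
the detection floor that excludes background staining; bins are half-open
with the top bin closed).  For a bin $b$,

$$\mathrm{PI}_b = \frac{L_{\mathrm{ROI},b}/\sum_b L_{\mathrm{ROI},b}}
{L_{\mathrm{heart},b}/\sum_b L_{\mathrm{heart},b}},$$

so 1 means the ROI mirrors the whole-heart composition and values above 1
mean local enrichment.  Prevalences weighted by whole-heart bin
proportions sum to 1 exactly.

```{r indices}
f <- orientation_field(matrix(rep(c(80, 90, 100) * pi / 180, 12), 6, 6),
                       pixel_pitch = 1000)
anisotropy_index(f, matrix(TRUE, 6, 6))
```

## Signal processing choices

Optical traces are processed in the standard order — per-frame 3×3
Gaussian spatial filter, per-pixel morphological top-hat (signal minus its
greyscale opening) for baseline drift, then Savitzky–Golay temporal
smoothing.  The top-hat window must exceed the action-potential duration
to preserve the AP; the default is 100 ms, with a 9-sample order-3 SG
filter.  Neither window is dictated by the upstream analyses, so both are
arguments.

Activation time is the maximum of the first difference (`dvdt_max`,
earliest sample on ties) or the linearly interpolated 50% crossing
(`midpoint`).  APD is measured from the depolarisation midpoint to the
interpolated $(1-\mathrm{level})$ crossing; the midpoint anchor is a
documented, configurable choice (`anchor = "dvdt_max"` is also available).
Flat pixels — below a *relative* amplitude threshold, so maps are
invariant to global gain — are masked invalid rather than raising, which
lets maps from infarcted hearts with signal-void scar process cleanly.

Conduction vectors come from a local least-squares plane fit
$t(x,y) \approx ax + by + c$ over a 7-px window (≥ 60% valid neighbours
required); the velocity is $(a,b)/(a^2+b^2)$ scaled to mm/ms.  Gradients
below $10^{-3}$ ms/px are masked: these are conduction-block interfaces
where the plane fit would report unbounded speeds.  Tissue activation time
is the 10–90% quantile spread of ROI activation times; because the raw
spread grows with region size, the default normalisation divides by
$\sqrt{A}$ (ms/mm).  The unnormalised spread is available via
`normalize = "none"` since other conventions exist and none is canonical.

## Registration

Structural data are brought into the optical frame (the frame that hosts
the functional measurements) by a homography fitted to 5–10 paired
fiducials — vascular bifurcations, sutures, scars — via the
Hartley-normalised DLT followed by geometric (reprojection-error)
refinement; an optional consensus mode (random minimal subsets, 3 px
inlier gate) guards against a mispicked landmark.  `rmse` is the
per-coordinate RMS residual: with jitter of SD $\sigma$ added
independently in both frames and 8 points, its expectation is $\sigma$
itself, which the residual-vs-jitter slope test exploits.  Orientation
fields are warped covariantly — the axis is rotated by the local Jacobian
of the map, never copied — because copying angle values under rotation is
a correctness bug that the 90°-rotation test explicitly excludes.
Volumetric structural stacks are reduced to the outer 100 µm shell
(`shell_projection()`, 13 voxels at the 8.29 µm z-step) to match the
depth optical mapping actually sees.

## Nerve tracing

The tracer targets rendered-tube-like images: hysteresis thresholding of a
lightly smoothed, max-normalised image; Zhang–Suen thinning; an
8-neighbour skeleton graph (diagonal shortcuts that triangulate two
orthogonal steps are dropped); per-node radius from the Euclidean distance
transform of the *half-maximum* mask, minus half a pixel of edge bias. For
tubes with Gaussian cross-section the half-maximum contour equals the FWHM
diameter, which is why the renderer defines diameter as FWHM. Large images
are traced in overlapping tiles whose core regions are stitched by
endpoint matching within 2 px. Post-filters mirror standard practice:
nodes below the 1.2 µm floor are dropped, and short junction-to-junction
bridges (≤ 10 µm) joining two fibers whose local tangents differ by less
than 20° axially are removed as parallel-fiber artifacts — thresholds are
arguments, calibrated on phantoms, since no canonical values exist.
Genuine steep-angle crossings are kept. Externally traced morphologies
enter through `read_swc()`.

## Statistics

Paired angle maps are compared with the Jammalamadaka–SenGupta circular
correlation (axial data doubled first), and map-level association is
tested by a Mantel-style permutation test: one random permutation per
iteration applied jointly to the rows and columns of one matrix, which
preserves within-map spatial structure while breaking the cross-map
pairing. Pixel-wise shuffling would be anticonservative for spatially
smooth maps and is deliberately not the default. With all entries valid
the circular means are permutation-invariant, so the implementation
precomputes the sin-residuals and each of the 1000 iterations costs one
indexed sum; p-values use the $(1 + \#\{ \geq \})/(1 + N)$ estimator and
are seeded.

The small designs this field works with (4 hearts per group, 9 regions)
make asymptotic rank tests inaccurate, so `mann_whitney_exact()`,
`kruskal_wallis()` and `spearman()` take full-enumeration paths whenever
the design allows (combined n ≤ 20 without ties, total n ≤ 12, and n ≤ 9
respectively — thresholds chosen so those designs always enumerate) and
fall back to flagged approximations otherwise:

```{r exact}
tidy(mann_whitney_exact(c(1, 2, 3, 4), c(5, 6, 7, 8)))
tidy(spearman(1:9, c(4, 2, 3, 1, 6, 5, 7, 8, 9)))
```

## The synthetic heart

`make_phantom()` builds an elliptical tissue frame with a low-order
harmonic fiber field (random phase and amplitude per seed, mean held near
90° so the anisotropy index's reference-frame guard never triggers), axial
von Mises jitter whose dispersion rises with `disorder_level` inside an
annular BZ around an optional signal-void scar, and a lognormal-noise
autofluorescence image. Activation is the anisotropic shortest travel
time on a 16-neighbour grid graph whose edge speeds follow the velocity
ellipse (`speed_along`, `speed_across`); the 16-neighbour stencil bounds
metrication error at about 3% (8 neighbours would allow ~8%). Scar pixels
are excluded from the graph entirely: dense scar is modelled as
non-conducting and signal-void, matching its exclusion from all
quantitative analyses. Two properties of this graph metric deserve note:
along-axis travel times are exact up to metrication, but the across-axis
time is *below* $d/v_\perp$ because oblique zigzag paths are faster — the
closed form across fibers is an upper bound only. And for a point source
in uniformly anisotropic tissue the front normal lies mostly across the
fibers (fronts are elongated ellipses), so conduction–fiber cosine
similarity approaches 1 only where fibers follow the propagation paths.

AP movies place a sigmoidal upstroke at each pixel's activation time and a
plateau-then-fall repolarisation $\exp(-\ln 5\,(s/\mathrm{APD})^3)$ that
reaches 20% of amplitude exactly APD ms after the upstroke midpoint;
amplitude is normalised to 1 and no ionic model is implied. Vessel scenes
render a trunk with bifurcating branches; the secondary bifurcations,
spread across the tissue, are the fiducials (points along a single trunk
would be near-collinear and useless for a projective fit). Nerve scenes
render Gaussian-profile tubes at 0.4 µm/px — finer than the 1.661 µm
confocal grid, so 1.2–3 µm fibers stay resolvable; coarser pitches are a
degradation mode.

What the generator does *not* emulate: optical blurring and
depth-averaging of the voltage signal, motion artifact, real BZ fiber
texture (the spatial statistics of real border-zone disorder are unknown;
`disorder_level` is a free parameter, not calibrated to data), true
vascular anatomy, or 3D nerve geometry. Passing the recovery tests
therefore demonstrates the *analysis chain* is correct and self-consistent
at realistic scales, not that it is robust to every artifact of real
recordings.

## An end-to-end study

`phantom_heart_study()` processes one phantom like a mapped heart:
activation from an LV pacing site, ROIs segmented from autofluorescence
(scar below 0.3× the remote median intensity — a configurable default,
as the criterion is not canonical — BZ within 300 µm of scar, the rest
split by landmark lines), then the per-ROI metric table. Conditions are
fixed in the function: MI = disorder 0.7 with a 2 mm scar, sham =
disorder 0.15 without; 64×64 frames at 220 µm/px (a desk-scale stand-in
for 256×256 at 55 µm/px), speeds 0.45–0.6 mm/ms along fibers at a 2.5:1
anisotropy ratio — values in the range reported for mouse ventricle.
Per-heart variation (field phase, pacing site, landmark placement, speed)
is drawn from the seed so replicate hearts differ the way biological
replicates do.

```{r study, message = FALSE, warning = FALSE}
mi <- phantom_family_table(101, "mi")      # 3 hearts x (LV base, RV, BZ)
sham <- phantom_family_table(601, "sham")  # 3 hearts x (LV base, apex, RV)
comp <- bz_composite(mi)
comp$tests
bz_composite(sham)$tests
```

The MI families place the BZ in the high-anisotropy, slow-activation
quadrant with a positive within-family Spearman correlation, while sham
families scatter near zero — the qualitative structure-function pattern
the composite is designed to detect. Because a 9-point rank correlation
is noisy under the null, the acceptance checks aggregate the median over
five independent families rather than asserting a single draw.

## Numerical details and limitations

* Matrices are `[row = y, col = x]`, y downward; exported files use pixel
  centers, 0-based, x rightward, y downward. Angles are radians from +x
  toward +y; fiber axes live in $[0, \pi)$.
* Axial smoothing (`smooth_orientation()`, default σ = 100 µm) averages
  coherence-weighted doubled-angle vectors; the resultant length becomes
  the new coherence and collapses at antipodal boundaries — a feature, as
  it flags unreliable orientation estimates.
* Degenerate inputs error early and informatively: < 4 fiducials,
  collinear fiducials, empty ROIs, constant rank inputs, zero circular
  variance, pacing inside scar.
* Tests and the acceptance script run at 48–128 px frames and 3–5 phantom
  families; these sizes were chosen as the smallest at which every
  discretisation tolerance in the checks is comfortably met.
* The tracer is tuned for well-separated tubular signal; densely
  overlapping plexuses and genuinely 3D branching are out of scope, as is
  any biophysical AP model or pharmacokinetic model of the repolarisation
  intervention (regional APD changes are imposed, not modelled).
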