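---
title: "Quantifying GUV microscopy assays with guvquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying GUV microscopy assays with guvquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(guvquant)
```

## Scope and interface

Giant unilamellar vesicles (GUVs, 1–100 µm single-bilayer vesicles) are
imaged directly by confocal microscopy, and a typical platform experiment
chains several quantification steps: detect vesicles in the recorded stacks,
characterize the formation (how many vesicles, what sizes, what fraction of
deposited lipid ended up as GUVs), standardize slide coating across slide
formats, score how many vesicles survive a wash flow (immobilization), score
membrane tightness against a hydrophilic dye and against protons, and
finally quantify lipid/protein transfer from charge-mediated SUV→GUV fusion.
`guvquant` implements that entire chain as ordinary R functions, plus a
synthetic-microscopy generator that produces seeded, ground-truth-annotated
datasets with the statistical structure each stage assumes. The functions
(together with `read_stack()`/`write_stack()`/`write_results()` for I/O and
`scripts/acceptance.R` for a full reproduction run) are the interface; there
is no separate command-line binary, because every step is a short, scriptable
function call.

## Detection: the two-stage particle workflow

Z-stack detection runs, in order:

1. **Rolling-ball background subtraction** on every slice (radius 100 px by
   default). The background is estimated by greyscale opening with a flat
   disc; for large radii the image is first shrunk by block minimum and the
   opened background enlarged back by bilinear interpolation — the standard
   speed-up. The greyscale erosion/dilation is implemented in C++
   (`src/morphology.cpp`) as sliding-window extrema over the disc's row
   segments, O(N·r). With `light_background = TRUE` (used for dye-exclusion
   stacks where the exterior dye is bright) the image is inverted about its
   maximum, subtracted, and re-inverted, so the background plateau maps to
   the bright level and dark lumens remain dips — this matters because the
   leakage profiles are later normalized to the top-of-stack background.
2. **Average Z-projection.** Membrane rings at different depths project into
   a filled disc with a bright rim.
3. **Bandpass filtering** (suppress structures larger than 40 px and smaller
   than 5 px) implemented as a difference of Gaussians with σ = size/2 and
   replicated-edge boundary handling (circular convolution would wrap the
   background ramp into spurious edge ridges). A difference of Gaussians is
   exactly a Gaussian-tapered annular mask in frequency space. The output is
   autoscaled to [0, 1] with 0.5 % tail saturation. `suppress_stripes` and
   `tolerance_direction` are accepted and ignored: they parameterize a
   directional variant that has no effect in this formulation.
4. **Thresholding.** The original workflow thresholds manually; the scripted
   stand-in is Otsu's method, with a numeric override, and the value applied
   is always recorded in the result's provenance. A consequence worth
   knowing: automatic thresholding assumes at least one object in view. On a
   noisy but completely empty field Otsu lands inside the noise and can
   fabricate speckle objects, exactly as an unsupervised threshold would in
   any tool; an analyst looking at an empty field would set the threshold
   above the noise. Empty-field behavior is therefore guaranteed (and
   tested) for noise-free input, and precision on populated fields is what
   the acceptance checks measure.
5. **Mask clean-up**: fill holes, one erosion pass (4-connected element),
   and a distance-transform watershed that splits touching vesicles
   (boundary pixels between distinct watershed labels are cleared).
   One subtlety: a thin ring outline can be closed only in 8-connectivity,
   in which case the background leaks through the diagonal gaps and hole
   filling does nothing. The mask is therefore dilated by one pixel before
   filling and eroded back afterwards — a closing with hole filling in
   between — which seals discretization gaps without changing solid shapes.
6. **Particle measurement and filtering.** Components are measured (area,
   perimeter, circularity `4πA/P²`, maximum-caliper Feret diameter,
   centroid), converted to physical units, and filtered: area
   0.75 µm²–∞ (Z-stack path) or 19.6–314.1 µm² (single-image path, i.e.
   5–20 µm circles), circularity 0.70–1.00, edge-touching components
   dropped. The perimeter estimator is the convex-hull perimeter of the
   pixel centers plus π pixels (the half-pixel boundary offset); it is exact
   in the convex limit, which is the regime the circularity filter selects
   for anyway. Circularity of small discrete regions can exceed 1; filtering
   uses the raw value with the upper bound 1.00 interpreted as "anything
   circular enough", and reported values are clamped to 1. The Feret
   diameter is the maximal hull-vertex distance plus one pixel.

Single-image detection omits steps 1–3 and thresholds the frame directly.

## Formation statistics

The size measure everywhere is the Feret diameter. The bilayer surface of a
vesicle counts both leaflets:

$$A_\mathrm{GUV} = 4\pi\left(\frac{d}{2}\right)^2 +
  4\pi\left(\frac{d}{2} - d_\mathrm{bilayer}\right)^2,$$

with a 5 nm bilayer by default. Both leaflets must be counted because the
lipid number is obtained by dividing this area by the per-lipid headgroup
area (0.71 nm²); a one-leaflet area would undercount lipids two-fold.

Vesicle concentration scales the in-band (5–20 µm) count per imaged area
(0.9968 mm² for nine 332.8 µm tiles) to the whole well bottom (80.91 mm²)
and divides by the loaded volume. Lipid yield converts the summed
surface area into a lipid count, extrapolates by
`A_Well·V_Form / (A_Img·V_Well)`, converts to mass via the Avogadro constant
and a mean molar mass of 790 g/mol (70:30 PC:PG), and reports the percentage
of the 20 µg of deposited lipid. Every default is a
`formation_context()` field that can be overridden.

The slide-geometry calculations reproduce the reference worked examples for
the two slide formats exactly, which pins down the rounding conventions:
the rectangular 8-well chain derives the wall height from the coating
volume and *rounds it to two decimals* (200 µL / 80.91 mm² → 2.47 mm, wall
88.92 mm², total 169.83 mm²), while the circular-well chain *truncates*
intermediate areas to two decimals (bottom 23.75 mm², wall 29.37 mm², minus
1 mm² of channel openings → 52.12 mm²). `slide_geometry()` exposes this as a rounding policy so other
slide formats can choose their own convention. Streptavidin density is then
simply applied mass over coated area, in ng/mm² (µg/mL × µL = ng).

## Immobilization scoring

The flow assay counts vesicles on the last frame before visible flow (an
explicit `pre_flow_frame` index — the original choice is made by eye, so the
package does not pretend to auto-detect it), then averages all during-flow
frames: moving vesicles smear into faint streaks, immobilized ones keep
their intensity, and re-thresholding the projection counts only the latter.
The projection is deliberately thresholded at the *pre-flow* threshold so
the two counts are comparable — re-running Otsu on the projection could
drift with the smeared content. The score is `100·n_immobilized/n_before`,
capped at 100 with a warning in the pathological case and undefined (NA)
when nothing was there before flow.

## Leakage

**Dye exclusion.** With a membrane-impermeant dye outside, a tight vesicle
is a dark hole in a bright sea. Per-vesicle Z-profiles (ROI mean per slice)
are normalized to the mean of the first 20 slices — background-only by
construction, since vesicles rest near the bottom of the 72-step stack —
then the averaged background-ROI profile is subtracted and the sign flipped,
so the score `max_z(bg − vesicle)` is the largest *absence* of dye. The
classifier thresholds at 25 % of the mean of control-condition score
medians; the controls must be named explicitly rather than inferred.
Analysis caps mirror the original bookkeeping: at most 148 vesicles per
sample, diameters below 7 µm discarded (too few slices, prone to drifting),
at most 85 analyzed, every exclusion logged with a reason. Caps are applied
in detection order.

**Proton leakage.** The encapsulated pH dye (HPTS/pyranine) is ratiometric:
the 470 nm-excitation intensity rises with pH while 395 nm serves as
reference, so `R = I470/I395` cancels dye amount and bleaching. Under an
outward 0.6-unit pH gradient, the 20-minute leakage percentage is
`100·(R(20) − R(0)) / (R(end) − R(0))`, where the endpoint is taken after a
protonophore (gramicidin) collapses the gradient. Vesicles with a
non-positive early ratio change are excluded (leakage can only raise the
lumen pH; negative drifts indicate prior dye leakage or stage drift), as are
vesicles with no protonophore response. The endpoint may be a single nearest
sample or the mean over a post-protonophore plateau window (`end_window`);
the plateau mean is the default in the acceptance runs because the 5 s
sampling of the final series makes single frames noisy. A useful property
falls out of the ratio algebra: any additive camera offset common to both
channels cancels in the *differences* of ratios, so the percentage is
unbiased even without background subtraction — this is why the assay works
on raw ROI means.

## Fusion

Charge-mediated fusion transfers membrane dye (and reconstituted protein)
from SUVs into the GUV membrane. Traces are per-frame ROI means minus a
*paired* background ROI; the automatic pairing places an annulus 2–4
vesicle radii from each centroid, excluding all vesicle footprints — the
reproducible analogue of hand-drawing a region next to each vesicle, and
local enough that smooth illumination gradients cancel. Replicate
aggregation is two-level: mean over vesicles within a replicate, then mean
± sample sd (n−1) across replicates.

For the protein-incorporation estimate, endpoint tables report per-vesicle
*gains* (endpoint minus pre-addition baseline, both background-corrected):
the GUV membrane is unlabeled before fusion, so the gain is the fused
material itself, and static offsets cancel exactly. Ordinary least squares
of protein-channel gain on membrane-channel gain then yields a slope
proportional to the fraction of protein-carrying SUVs in the mix — the
quantitative basis for estimating reconstitution without labeling the
protein in every experiment. The fit is unweighted OLS, matching how such
calibration lines are conventionally drawn.

## The synthetic generator

The generator replaces raw microscopy data (none are deposited) with scenes
whose statistics the pipeline can be scored against:

- **Geometry.** 2048² px fields at 0.1625 µm/px. The pixel size is not
  stated anywhere in the protocol; 0.1625 µm/px is adopted because
  2048 × 0.1625 µm reproduces the printed 332.8 µm field edge exactly, and
  it is overridable. Z-stacks use 1 µm steps, 72 slices, recorded top to
  bottom; vesicles rest on the slide plane near the bottom, so the top ~20
  slices are background (the normalization anchor relies on this).
- **Populations.** Diameters are lognormal by default (meanlog log 8,
  sdlog 0.4, truncated to 1–40 µm), with uniform and fixed-list options.
  Placement is rejection sampling with non-overlap *in the xy projection* —
  immobilized GUVs settle as a monolayer — plus a 2 µm edge margin.
  Impossible packings error out after a bounded number of tries. For dense
  benchmark scenes (200 vesicles in a 1024-px field) a small-biased
  lognormal (meanlog log 6, sdlog 0.3, truncated to 5–20 µm) is used: a
  5–20 µm population drawn uniformly cannot physically fit that field, and
  settled GUV size distributions are right-skewed toward small diameters
  anyway.
- **Rendering.** A membrane ring of radius `sqrt((d/2)² − (z − z_c)²)` per
  intersecting slice, with a Gaussian radial profile (sd = 0.3 µm lateral
  blur; no protocol states a PSF, so an isotropic Gaussian is the chosen
  idealization); lumen channels fill the disc interior with half-pixel
  antialiasing; a uniform exterior dye level supports dye-exclusion scenes.
  Time-series assays are rendered at the equatorial focal plane.
- **Noise.** Poisson shot noise (scale 0.25 counts/AFU), Gaussian read
  noise (sd 10 AFU), a background of 100 AFU with a ±10 % linear ramp, and
  16-bit integer quantization. Intensity scales are arbitrary units —
  nothing in the protocol fixes exposure or gain — so all analyses are
  designed to be invariant to them. Noiseless renders stay
  continuous-valued.
- **Kinetics.** Leakage is first-order (`1 − e^{−kt}`); only endpoint
  percentages are ever compared, so any monotone kinetics with a
  controllable 20-min fraction would do, and first-order is the natural
  choice. Proton traces relax from the pH-7.4 ratio (1.0) toward the pH-8.0
  ratio (1.8) and jump to the equilibrated ratio at the gramicidin event.
  Fusion gains rise along a saturating exponential after SUV addition, with
  a lognormal per-vesicle fusogenicity, and the protein channel scales by
  `proteo_fraction × calibration`.
- **Determinism.** Every stochastic step runs under a seed derived from the
  scene seed, so identical scenes reproduce bit-identically.

What the generator does *not* emulate — and hence what passing tests do not
demonstrate about real data: optical aberration and depth-dependent PSF
broadening, multilamellar or nested vesicles, adhesion-cap deformation of
strongly attached vesicles, debris and lipid aggregates, photobleaching,
stage drift, and vesicles entering or leaving the field except under flow.
The detection thresholds that work here with Otsu may still need the manual
override on real stacks with such artifacts.

## Numerical choices and degenerate inputs

- Problem sizes in the validation runs: detection is scored on 200-vesicle
  1024-px stacks with 40 slices, formation recovery on 500-vesicle 2048-px
  single frames, immobilization on 50 vesicles over 30 frames, proton
  leakage on 50 vesicles across three rate constants, fusion on 40 vesicles
  at four mixing ratios. These sizes give stable statistics while a full
  validation pass stays in the minutes range on one CPU.
- Thresholding a near-constant image returns an empty mask rather than an
  Otsu failure; an empty ROI table propagates as zero-row results, not
  errors. A 0/0 size fraction is defined as 0 with a warning.
- Watershed tolerance is 1 px with 1-px extension; a smaller tolerance
  over-splits large discs, a larger one under-splits close pairs.
- The rounding policies in `slide_geometry()` exist solely to reproduce the
  printed worked-example chains digit for digit; disable them (digits = Inf)
  for maximum-precision geometry.
- The formation quality judgment (e.g. "at least 1.5 × 10⁵ GUVs/mL is
  sufficient") is a configurable QC comparison for the caller, not a
  hard-coded constant.
- The 85-vesicle analysis cap originally stems from a plotting-software
  limitation; it is kept (in detection order) for comparability and fully
  logged, not because the statistic needs it.

## Known limitations

Detection is strictly 2-D (projections or frames); no volumetric
segmentation, no sub-pixel membrane localization, no tracking of individual
vesicles across frames. Bit-level equivalence with any particular GUI
implementation of the same operations is not attempted — equivalence is
asserted behaviorally, on synthetic fixtures with known truth. Absolute
proton permeability coefficients and pH calibration of the HPTS ratio are
out of scope: the analysis works on raw ratios. The fusion statistic cannot
distinguish full fusion from hemifusion or docking; it quantifies signal
transfer.
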