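---
title: "Intracortical T1w/T2w ratio mapping: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Intracortical T1w/T2w ratio mapping: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement and its assumptions

Myelin raises T1-weighted signal and lowers T2-weighted signal, so the
voxelwise ratio T1w/T2w amplifies myelin-related contrast in the cortex.
The key algebraic property is that a multiplicative receive-coil bias
`b(x)` common to both acquisitions cancels exactly:

    (t1 * b) / (t2 * b) = t1 / t2.

Transmit bias differs between the two sequences and does not cancel; in the
absence of measured B1 maps it is attenuated by the square-root-product
estimate `sqrt(t1 * t2)` (the two contrasts are approximately inverted, so
their product varies mostly with the shared bias), normalized to unit mean
in the cerebrum, smoothed, and divided out of both images. What remains is
handled statistically by an imaging-site regressor.

The analysis samples the corrected ratio at the middle depth of the
cortical ribbon (away from partial-volume contamination at both surfaces),
averages it over a cortical parcellation, and fits, per region of interest
(ROI), a weighted linear model

    signal ~ age + site + group

with the healthy-control group as reference and a Holm-Bonferroni stepdown
correction over ROIs, separately within each disease-stage contrast.

## The phantom cohort: what it emulates, and what it does not

Because suitable clinical MRI datasets are not freely redistributable, the
package ships a synthetic cohort generator that produces the statistical
and artifactual structure the pipeline has to cope with, together with full
ground truth (`make_brain_phantom()`, `simulate_cohort()`):

* a nested head geometry — WM core, 4 mm cortical GM ribbon, 2 mm CSF gap,
  1 mm dura shell — as perturbed ellipsoids. The sinusoidal surface
  perturbation (relative amplitude 0.12, angular frequency 4) gives the
  cortex curvature and, critically, angular structure: a rotationally
  symmetric head leaves rigid rotation unidentifiable for *any*
  registration algorithm, so the phantom must break the symmetry the way a
  gyrified brain does. Head radii scale with the field of view; ribbon,
  CSF and dura keep their physical thickness, since cortex does not scale
  with head size.
* piecewise-constant clean intensities per tissue and contrast (defaults:
  T1w WM 1.0 > GM 0.7 > CSF 0.25, dura bright at 0.85; T2w CSF 1.3 > GM
  0.8 > WM 0.5, dura dark), so every downstream quantity has an exact
  closed-form truth;
* a disease effect injected as a fractional ratio increase `delta` in
  chosen ROIs for chosen groups, realized by dividing GM T2w by
  `1 + delta` (scaling T2w down rather than T1w up is an arbitrary but
  fixed bookkeeping choice). The magnitude of the real-data effect is not
  published numerically; the default `delta = 0.05` in 6 ROIs for the two
  manifest-disease stages is a free simulation parameter;
* smooth multiplicative bias fields as exponentials of random quadratic
  polynomials, drawn per site: one receive field shared by both contrasts
  and two contrast-specific transmit fields;
* a linear age trend on the GM ratio (default -0.001/year around age 45)
  and per-site global intensity scales (lognormal, sdlog 0.05) — something
  real for the age and site regressors to absorb;
* additive Gaussian noise clipped at zero (magnitude images are
  nonnegative), sigma expressed as a fraction of the mean GM T1w intensity
  (default 0.02), with a Rician option; and
* a small random rigid T2w misalignment (1 degree / 1 mm SD, truncated at
  3 SD).

Group sizes and age distributions default to the proportions of a
five-group observational staging cohort (controls, two premanifest strata
split by predicted years to onset, two early-disease stages by functional
capacity), e.g. ages 46.1 (10.5) years for controls and 50.9 (8.8) for the
most advanced stage.

The phantom deliberately omits realistic gyrification, sequence signal
equations, coil geometry and motion. Passing tests therefore demonstrate
that the implementation is faithful to the method and that the method's
internal logic (bias cancellation, depth geometry, error control) is sound
— not that the pipeline performs equivalently on clinical data.

## Pipeline stages and the parameters that matter

`process_subject()` chains the stages; every default is exposed through
`pipeline_options()`.

**Rigid registration** (`rigid_register()`). Six parameters (3 rotations in
degrees, 3 translations in mm, centre at the foreground centre of mass),
recovered by maximizing normalized cross-correlation between the two
images' *gradient magnitudes* over a coarse-to-fine pyramid (Nelder-Mead,
seeded by an exhaustive translation scan at the coarsest level). Raw
intensity NCC is the textbook choice but has the wrong sign structure for
inverted-contrast T2w-to-T1w pairs — aligned tissue is anticorrelated while
the head silhouette correlates positively, so the signed metric can prefer
misalignment; gradient magnitudes light up at tissue interfaces in both
contrasts regardless of polarity and remain informative at every pyramid
level. The pipeline profile stops the pyramid at half resolution
(`levels = c(4, 2)`, adequate for the sub-voxel offsets the cohorts carry);
full-resolution polish (`levels = c(4, 2, 1)`) recovers offsets of up to
5 mm / 5 degrees to within 0.25 mm / 0.5 degrees at 2% noise.

**Local intensity normalization** (`local_intensity_normalize()`). A 3x3x3
maximum filter followed by Gaussian smoothing of the result builds a local
intensity envelope; dividing by it flattens slow bias so the pial surface
thresholds cleanly. The 10 mm kernel is read as FWHM (sigma = 10/2.355 mm),
the neuroimaging convention. The smoothing is renormalized at the grid
boundary, and when a head mask is supplied it is confined to the mask —
otherwise the empty background drags the envelope below GM at the pial
surface (on whole-head images with scalp signal the variants agree). A
division floor at 5% of the field median guards the background; floored
voxels are flagged and excluded from masks. The normalized image is used
*only* for masking and segmentation; the ratio analysis consumes original
intensities, since normalization would also flatten the biology of
interest.

**Cerebrum masking** (`skull_strip()`), fixed order: mask with the head
mask, upsample 2x (linear), unsharp-mask sharpen (amount 1, radius 1
upsampled voxel), apply the histogram CSF threshold, remove connected
components under 100 upsampled voxels, erode then dilate with a 3x3x3
cross, downsample, re-apply the same threshold, keep the dominant
component. The CSF threshold is the deepest valley of the kernel-smoothed
intensity histogram between the darkest mode and the next; a unimodal
histogram falls back to a two-class variance-maximizing split with a
warning. The thin dura shell survives thresholding (dura is bright on T1w)
but not the opening: at upsampled resolution it is two voxels thick and one
erosion removes it.

**Tissue segmentation** (`fuzzy_segment()`). Two-class fuzzy c-means
(fuzziness m = 2, centroid tolerance 1e-4, at most 200 iterations,
deterministic quantile initialization at the 25th/75th percentiles) with an
optional 6-neighbour membership-smoothness penalty weighted by
`spatial_beta`. The penalty only matters when intensity noise actually
causes misclassification; at mild noise the residual errors are geometric
(partial volume at the mask edge) and the penalty is inert, which is why
the paired-improvement test runs at 5% noise.

**Cortical depth** (`solve_laplace_depth()`). Laplace's equation over the
ribbon with Dirichlet conditions 0 at the WM side and 1 at the CSF side,
red-black Gauss-Seidel, 6-neighbour Laplacian with 1/h^2 weights, update
tolerance 1e-5. The Dirichlet surface is placed on the *face* between a
free and a fixed voxel (one-sided Shortley-Weller stencil, boundary
neighbour weight doubled): imposing boundary values at voxel centres
instead carries a half-voxel offset that alone exceeds the discretization
tolerance of the spherical-shell oracle. On a slab the discrete solution is
then exactly `(i + 0.5)/T`; on a spherical shell it matches the harmonic
closed form `(1/a - 1/r)/(1/a - 1/b)` to 0.024 at the reference resolution.
Ribbon components that do not reach both boundaries are a topology error,
or are dropped with a count under `on_topology = "drop"` (the pipeline
default, since a noisy segmentation can strand a few voxels).

**Equivolume option** (`equivolume_fraction()`, default off). With local
boundary area proxies `A_in`, `A_out` and cross-sectional area linear in
depth, the cumulative-volume fraction is
`f(d) = (2 A_in d + (A_out - A_in) d^2) / (A_in + A_out)` — identity for
equal areas, strictly increasing, and for an outward-bulging cortex the
half-volume surface lies *farther* from the white surface than the
equidistant midpoint (on a spherical shell at radii a, b it sits at
`((a^3 + b^3)/2)^(1/3)`; volume accumulates faster at larger radius). The
default proxies are global interface-face counts; voxelwise proxy maps can
be supplied for per-streamline correction. The equidistant mid-surface is
the pipeline default because the phantom's parcellation is angular and a
global depth shift moves all ROIs together; the option exists and is
tested for its identity, sign and monotonicity properties.

**Mid-depth shell and smoothing** (`extract_middepth_shell()`,
`smooth_on_shell()`). The shell is `|depth - 0.5| <= w` with `w = 0.1` (at
least one voxel thick on a 3-4 mm ribbon at 1 mm spacing — a surface has
zero thickness, so a volumetric sampling must pick a band width; `w` is a
free parameter). ROI identifiers are copied voxelwise from the ground-truth
labels, the declared stand-in for mesh-based inter-subject surface
registration. Signal smoothing on the shell uses a 6 mm FWHM Gaussian in
3D distance, truncated at 3 sigma and renormalized over in-shell
neighbours, so constants are preserved and nothing leaks across CSF or WM;
missing (excluded) voxels neither give nor receive weight.

**Bias field and ratio** (`estimate_bias_field()`, `correct_bias()`,
`compute_ratio()`). The square-root-product field is normalized to unit
in-mask mean, smoothed within the mask (Gaussian, sigma 5 mm — this kernel
is quoted as a standard deviation, unlike the 10 mm and 6 mm kernels which
are FWHM; each convention is documented where it is used), floored for
positivity and renormalized (the order normalize-then-smooth is fixed here;
the final renormalization enforces the unit-mean invariant exactly).
Masked smoothing is `smooth(f * m)/smooth(m)`, preventing background zeros
from biasing edge voxels. The ratio divides the two corrected images where
the T2w denominator exceeds its in-mask 1st percentile; excluded voxels
carry `NA` and never reach ROI means, and more than 20% exclusion is a
quality error.

## Group statistics

`qc_exclude()` implements the gain-difference rule: subjects whose mean
mid-depth cortical ratio lies outside mean +/- 1.5 SD of the whole cohort
are dropped (computed once, not iterated) with reason "gain difference".

`fit_roi_wls()` fits the weighted model per ROI with treatment coding and
two-sided p-values (disease stages have shown both increases and a
decrease trend). Two readings of "weight = 1/SD of the signal for each
ROI" are implemented. Weighting each subject by its within-ROI voxel SD is
the reading closest to down-weighting artifact-laden images, but with only
~10 smoothed, spatially correlated voxels per ROI the estimated weights
correlate with the residuals and inflate the t-statistics — in a factorial
null experiment on oracle tables it produced Holm-corrected false
positives in 8 of 20 null cohorts at n = 60, versus 1-2 of 20 for the
per-ROI across-subject SD weights. The per-ROI scheme is therefore the
default; the per-subject scheme remains available
(`weight_scheme = "per_subject"`). SDs are floored at the cohort 5th
percentile so weights stay bounded.

`holm_bonferroni()` applies the stepdown rule with family size `m` equal to
the number of ROIs, separately within each group contrast (matching a
correction "accounting for the parcellation"; a single family across all
group contrasts is available via `adjust_within = "family"`). The
implementation delegates to `stats::p.adjust(method = "holm")`; the test
suite checks it against an independently coded brute-force stepdown on
1000 random p-vectors, exactly.

`vertexwise_group_maps()` produces per-voxel covariate-adjusted group mean
maps (intercept plus group coefficient at the cohort mean age and
reference site) and per-group coefficient maps relative to the reference
group, whose own map is identically zero under treatment coding.

## Problem sizes used by the shipped experiments

The acceptance experiments run single subjects at 64^3 (1 mm), the depth
oracle at 96^3, and cohorts at 48^3: 20 replicate effect cohorts of 60
subjects in the proportions 20/10/9/13/8 across two sites with
`delta = 0.05` in 6 ROIs for the two manifest stages, and 20 replicate
null cohorts of 32 subjects with all effects zero. At these sizes the full
suite completes on a single CPU in well under half an hour;
`scripts/acceptance.R` re-runs the same computations with scaled-down
replicate counts. These sizes are the package's own choice of a
desk-reproducible experiment; all of them are parameters.

## Numerical choices and degenerate inputs

* Convergence: FCM stops on a 1e-4 centroid shift; Gauss-Seidel on a 1e-5
  maximum update; registration Nelder-Mead on a relative tolerance of
  1e-5 (pipeline profile) to 1e-8 (polish), with one fresh-simplex restart
  if the simplex stalls at the iteration cap, and a classed
  registration-failure error carrying the best-so-far transform otherwise.
* Ties and initialization are deterministic throughout (quantile centroid
  init; seeds drawn from a master seed and recorded in the manifest), so
  identical seeds give bit-identical cohorts.
* Degenerate inputs error early with classed messages: all-zero images,
  unimodal histograms (warning + fallback split), fewer distinct
  intensities than classes, empty shells, masks below 100 voxels, p-values
  outside [0, 1], cohorts without a control per site.
* Resampling uses trilinear interpolation (or nearest-neighbour for label
  volumes) with out-of-fov voxels zeroed and flagged; its round-trip error
  is curvature-limited, so the 2%-of-range bound applies to band-limited
  volumes, not across step edges.

## Known limitations

* The phantom's cortex is a smoothly perturbed shell; registration,
  segmentation and depth performance on real gyral geometry will be worse
  than the phantom numbers, and the ground-truth ROI transfer sidesteps
  inter-subject surface registration entirely.
* The transmit-bias residual after square-root-product correction is only
  attenuated, not removed — exactly as in the method being implemented —
  and lands in the site regressor.
* Per-subject weighting, the closest reading of the published weighting
  rule, is statistically unreliable at few voxels per ROI (see above);
  conclusions drawn with it at desk scale should be checked against the
  per-ROI scheme.
* The 6 mm on-shell smoothing spreads a focal effect into neighbouring
  ROIs of a fine parcellation; neighbour-ROI significance adjacent to a
  true effect is expected behaviour, not a false-positive pathology.
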