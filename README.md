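# cortexratio

Intracortical T1w/T2w ratio mapping for structural MRI, with a synthetic
phantom-cohort generator that makes every stage of the analysis testable
against ground truth.

## What it does, and for whom

The T1-weighted/T2-weighted intensity ratio amplifies myelin-related
contrast in the cerebral cortex and cancels the multiplicative receive-coil
bias common to both acquisitions:

    (t1 · b) / (t2 · b) = t1 / t2.

`cortexratio` implements the full volumetric analysis around that identity,
aimed at neuroimaging researchers studying cortical tissue composition in
neurodegenerative disease (the design case is staging cohorts in
Huntington's disease, but nothing is disease-specific):

1. **Rigid intra-subject registration** of the T2w to the T1w volume
   (normalized cross-correlation of gradient magnitudes, multi-resolution
   Nelder-Mead);
2. **Cerebrum masking and tissue segmentation** from the T1w image: local
   intensity normalization (3×3×3 maximum filter, 10 mm FWHM Gaussian
   envelope), histogram CSF threshold, morphological dura removal, and
   spatially regularized fuzzy c-means for GM/WM;
3. **Cortical depth** by solving Laplace's equation over the GM ribbon
   (depth 0 at the white surface, 1 at the pial surface), with an optional
   equivolume reparameterization, and extraction of the **mid-depth shell**
   (|depth − 0.5| ≤ w);
4. **Bias correction** by the square-root-product estimate
   `smooth(sqrt(t1 · t2))`, applied to both images, and the corrected
   **ratio image**, sampled on the shell and smoothed along it (6 mm FWHM);
5. **Group statistics**: per-subject/per-ROI signal tables, the ±1.5 SD
   gain-difference exclusion rule, weighted regression
   `signal ~ age + site + group` per ROI, and Holm-Bonferroni family-wise
   error control across ROIs within each group contrast, with broom-style
   `tidy()`/`glance()` accessors and ggplot2 `autoplot()`.

Because the clinical images such analyses run on are not redistributable,
the package also ships a first-class **phantom cohort generator**
(`make_brain_phantom()`, `simulate_cohort()`): multi-site T1w/T2w cohorts
of a perturbed-ellipsoid head with known tissue labels, an 82-sector
cortical parcellation, per-site bias fields and intensity scales, age
trends, acquisition noise, rigid misalignment, and group effects injected
as exact fractional ratio increases — so recovery can be checked against
truth, voxel for voxel. See the methods vignette
(`vignettes/cortexratio-methods.Rmd`) for the models, parameter
conventions and design decisions.

## Worked example

Simulate a 32-subject, two-site cohort with a 5% ratio increase injected
in 6 ROIs for the two manifest disease stages, run the full pipeline, and
fit the group model:

```r
library(cortexratio)
library(dplyr)

spec    <- cohort_spec(seed = 42)       # 48^3 phantoms, 82 ROIs
cohort  <- simulate_cohort(spec)
processed <- run_cohort_pipeline(cohort)
analysis  <- analyze_cohort(processed)
analysis
#> <cohort_analysis> 32 subjects (3 QC-excluded)
#> <roi_fit> 82 ROIs x 4 group terms, 29 subjects (per_roi weights)
#>   18 significant ROI x group effects at alpha 0.05 (Holm, m = 82)

tidy(analysis$fit) |> filter(significant) |> arrange(p_adjusted)
#> # A tibble: 18 × 8
#>   roi_id term  estimate std_error statistic      p_value p_adjusted significant
#>    <int> <chr>    <dbl>     <dbl>     <dbl>        <dbl>      <dbl> <lgl>
#> 1     35 HD1     0.0238   0.00272      8.72 0.0000000137 0.00000113 TRUE
#> 2     22 HD1     0.0238   0.00288      8.29 0.0000000328 0.00000266 TRUE
#> 3     47 HD1     0.0196   0.00268      7.31 0.000000256  0.0000205  TRUE
#> 4     34 HD1     0.0119   0.00169      7.04 0.000000460  0.0000363  TRUE
#> 5     10 HD1     0.0170   0.00262      6.49 0.00000157   0.000122   TRUE
#> # …
```

Three subjects were dropped by the gain-difference rule. The effect was
injected in ROIs 10, 22, 35, 47, 60, 72; the top hits are those ROIs (for
the HD1 and HD2 contrasts), with estimates around 0.012–0.024 ratio units —
the injected 5% of a GM baseline ratio of 0.875 (= 0.044), attenuated by
the 6 mm on-shell smoothing over small ROIs. Hits such as ROI 34 and ROI 9
are spatial neighbours of injected ROIs picking up smoothing leakage, and
no premanifest contrast reaches significance. `autoplot(analysis$fit)`
draws the coefficient map; `glance(analysis$fit)` summarizes the fit.

A thin command-line wrapper (`exec/cortexratio`) exposes the stages as
`cortexratio simulate | register | preprocess | depth | ratio | stats` for
shell pipelines over NIfTI files.

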