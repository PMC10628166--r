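# tomoshell

Label-free 3D cell morphometry and shell-density analysis for
refractive-index tomograms, with a compact 3D dense-block classifier.

## The problem

Holotomographic microscopy reconstructs a three-dimensional refractive
index (RI) map of a single living cell without staining. Because the RI
elevation of cytoplasm over the medium is proportional to local protein
concentration (refraction increment α ≈ 0.19 mL/g), a tomogram is a
quantitative biochemical measurement: segmenting the cell and averaging
its RI yields its volume *V* (fL), protein density
*C* = 100·(n̄ − n_m)/α (g/dL) and dry mass *m* = C·V·10⁻² (pg). In
immune cells these quantities track activation state, so single-cell
CD8⁺ T-cell morphometry is a candidate rapid biomarker for conditions
such as sepsis, where cohorts compare healthy controls (H) with patients
at septic-shock onset (T1), shock resolution (T2) and pre-discharge
(T3), plus survivor/non-survivor outcomes at T1.

`tomoshell` is for computational biologists who want that whole analysis
chain as tested, reusable R functions:

* **Simulation** — ellipsoidal cell/nucleus phantoms with noise,
  peripheral-density rims, subject-level random effects and clinical
  covariates calibrated in closed form to target correlations
  (`phantom_spec()`, `make_phantom()`, `make_cohort()`).
* **I/O + QC** — multi-page TIFF or raw float32 volumes with JSON
  sidecars; automated rejection of crowded, truncated or empty fields
  (`read_tomogram()`, `write_tomogram()`, `qc_filter()`).
* **Morphometry** — RI-threshold segmentation (largest 26-connected
  component), volume, protein density, dry mass, sectional overall and
  nuclear (RI > 1.38) features (`cell_morphometry()`,
  `extract_features()`).
* **Shell analysis** — each central section's pixels are ranked by
  distance from the cell centre and split into eight equal-count shells
  (Shell 1 innermost); a shell's density is its fraction of pixels above
  an RI threshold (`shell_partition()`, `shell_profiles_for_cohort()`).
* **Cohort statistics** — one-way ANOVA across status groups, pooled
  t-tests with Bonferroni correction, per-shell comparisons, Pearson
  correlations against clinical covariates (`group_comparisons()`,
  `shell_comparisons()`, `correlate_features()`).
* **Classifier** — a from-scratch 3D DenseNet-style CNN (Rcpp backward
  passes verified against finite differences), SGD with cosine
  annealing, early stopping, and bootstrap AUROC over 1–5 sampled cells
  with percentile confidence intervals (`train_classifier()`,
  `eval_classifier()`, `saliency()`).
* **Pipeline** — `run_all()` chains simulate → qc → extract → shells →
  stats → train → eval from one config with derived seeds and a JSON
  manifest. A thin CLI lives in `inst/scripts/tomoshell.R`.

## Worked example

```r
library(tomoshell)

spec <- phantom_spec(cell_radius_um = 5, voxel_spacing_um = 0.2,
                     grid_shape = c(64, 64, 64), noise_sd = 0.002)
tom <- make_phantom(spec, seed = 1)
cell_morphometry(tom)[, c("volume_fl", "protein_density_gdl", "dry_mass_pg",
                          "mean_overall_ri", "mean_nuclear_ri")]
#>   volume_fl protein_density_gdl dry_mass_pg mean_overall_ri mean_nuclear_ri
#> 1   526.736             12.9976      68.463          1.3665          1.3899
```

A 5 µm sphere has volume (4/3)π·5³ ≈ 523.6 fL; the extracted 526.7 fL
differs only by voxelization. The density 13.0 g/dL is the
nucleus/cytoplasm mixture mean RI excess divided by α, and dry mass is
exactly `C·V/100`. The shell profile of the same cell decays with radius,
and its nuclear component is confined to the inner shells:

```r
shell_profile(tom)$nuclear
#> <shell_profile> threshold 1.38
#>     d1     d2     d3     d4     d5     d6     d7     d8
#> 1.0000 0.1875 0.0000 0.0000 0.0000 0.0000 0.0000 0.0000
```

On a simulated four-group cohort (40 cells/group, T1 largest and
densest), the group comparisons reproduce the expected contrasts:

```r
ch <- make_cohort(groups, base = base, seed = 42)   # see ?default_cohort_groups
feats <- extract_features(ch$tomograms)
group_comparisons(feats)$anova
#>           feature       F          p stars
#> 1       volume_fl   28.64  8.296e-15   ***
#> 2     dry_mass_pg  238.31  5.051e-58   ***
#> 3 mean_overall_ri 1230.17 2.632e-108   ***
#> 4 mean_nuclear_ri  381.42  1.389e-71   ***

correlate_features(merged, c("CRP", "IL10", "lymphocyte_pct"),
                   mode = "timepoint_means")
#>        covariate    rho n
#> 1            CRP  0.993 4
#> 2           IL10  0.999 4
#> 3 lymphocyte_pct -0.991 4
```

The F statistics say every morphometric feature separates the status
groups; the correlations recover the configured relationship between
mean cellular RI and the clinical covariates, with the lymphocyte
percentage moving in the opposite direction.

See `vignettes/tomoshell-methods.Rmd` for the models, parameter
defaults, numerical conventions and limitations.

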