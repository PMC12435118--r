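# specdiff

Spectral diffusion analysis (SDA) of multi-b-value diffusion MRI in R.

Diffusion-weighted signal decay in brain tissue mixes contributions from
restricted parenchymal water, fluid-like interstitial water, and
microvascular pseudo-diffusion. SDA models the normalized decay of a voxel
as a non-negative sum of mono-exponentials over a fixed dictionary of
candidate diffusion coefficients,

    S(b_i)/S(b_0) = sum_j A_j * exp(-b_i * D_j),   A_j >= 0,

solves for the amplitude spectrum `A` by non-negative least squares (NNLS),
and integrates the spectrum over three diffusivity windows: parenchymal
(D < 1.5), intermediate (1.5 <= D <= 4.0) and microvascular (D > 4.0), in
units of 1e-3 mm²/s. Two markers summarize the intermediate window:

* **F_int** — the amplitude fraction inside it, a surrogate of
  interstitial-fluid *volume* (reported in %);
* **D_int** — the dictionary diffusivity at the maximum amplitude inside
  it, a surrogate of interstitial-fluid *diffusivity*.

The package is aimed at researchers evaluating interstitial-fluid markers
in conditions such as normal pressure hydrocephalus, and at methodologists
studying how b-value schemes and dictionary designs affect spectral
estimates. It provides:

* dictionary constructors — 200 log-spaced atoms (`Log200`) and the
  component-linear design with 66/68/66 atoms per window (`Lin200`) — plus
  classification, CSV export and import;
* a deterministic Lawson–Hanson NNLS solver with column equilibration and a
  scale-free KKT tolerance, validated against exhaustive support
  enumeration;
* a Monte-Carlo framework (random multi-compartment ground truths, Rician
  noise, normalized-RMSE accuracy surfaces, condition ranking) reproducing
  the reference evaluation design of 50 compartment counts x 1000 patterns
  x 50 noise levels;
* voxelwise F_int / D_int map computation with NIfTI + FSL `.bval` I/O;
* a synthetic 4D DWI phantom and a cohort generator with ground truth;
* ROI statistics: zero-F_int exclusion, Kruskal–Wallis with Dunn post hoc
  comparisons, Spearman age correlations.

## Worked example

Fit one periventricular-hyperintensity-like mixture (component fractions
0.45/0.50/0.05) sampled at fifteen b-values, then compute maps for a small
zero-noise phantom and summarize its two regions:

```r
library(specdiff)

lin200 <- build_component_linear_dictionary()
lin200
#> Diffusion dictionary (component_linear): 200 atoms, 0.100 to 1000.000 x1e-3 mm^2/s
#>   components: 66 parenchymal, 68 intermediate, 66 microvascular

b <- b_scheme_previous()                  # 15 b-values, 0..1000 s/mm^2
tissue <- phantom_tissues()$iNPH_PVH      # 0.45 / 0.50 / 0.05 mixture
sig <- decay_signal(b, synthesize_signal(tissue, b))
fit_decay(sig, lin200)
#> F_int = 50.11%  D_int = 2.507 x1e-3 mm^2/s  (par 44.88%, micro 5.01%)

ph <- make_default_phantom(noise_sd = 0, seed = 1, shape = c(12, 12, 6),
                           b_values = b_scheme_previous())
maps <- fit_volume(ph$dwi)
extract_roi(maps, ph$labels, region_names = ph$regions$name)
#>     region label n_voxels n_f f_int n_d d_int
#> 1    HC_WM     1      200 200 15.10 200 2.470
#> 2 iNPH_PVH     2      200 200 50.11 200 2.507
```

The fitted F_int values (15.10% and 50.11%) sit within ~0.1 percentage
point of the generative fractions because fifteen b-values identify a
three-compartment mixture almost exactly; `d_int` lands on the dictionary
atom nearest the generative intermediate diffusivity of 2.5e-3 mm²/s. At
the six-b-value clinical scheme the same mixtures are *not* identifiable —
several exact non-negative spectra fit five samples — so six-b-value maps
are estimator outputs whose accuracy is quantified by the Monte-Carlo
framework (see the vignette for the full analysis).

```r
grid <- simulation_grid(n_range = 1:10, patterns_per_n = 100,
                        noise_levels = seq(0, 0.05, length.out = 10),
                        seed = 42)
records <- run_grid(grid, list(
  fit_condition("lin200_6b", b_scheme_current(), lin200),
  fit_condition("log200_6b", b_scheme_current(), build_log_dictionary())))
compare_conditions(list(build_surface(records, "f_int", "lin200_6b"),
                        build_surface(records, "f_int", "log200_6b")))
#>   condition grand_mean_nrmse wins n_cells
#> 1 lin200_6b           1.0668   80     100
#> 2 log200_6b           1.0949   20     100
```

The component-linear dictionary, with three times the atom density inside
the intermediate window, attains the lower grand-mean F_int error at the
clinical b-value scheme.

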