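# tke4d — turbulence mapping for 4D flow MRI of the thoracic aorta

`tke4d` is an R package for simulating and analysing 4D flow MRI
turbulence measurements in the thoracic aorta, built around the question of
how turbulence intensity responds to pharmacological (dobutamine) stress.
It targets researchers in cardiovascular MR physics who want a fully
synthetic, ground-truth-controlled testbed for the turbulence-mapping
processing chain: no scanner data are required, and every reconstruction
step can be validated against the generator's known fields.

## The method

Phase-contrast MRI encodes velocity in the signal phase. With velocity
encoding VENC (here 140 cm/s) and `k_v = π/VENC`, a voxel whose intravoxel
velocity distribution is Gaussian with mean `v_i` and standard deviation
`σ_i` (the IVSD) along encoding direction `i` produces

    S(k_v) = S(0) · exp(−k_v² σ_i² / 2) · exp(i k_v v_i)

so the mean velocity sets the phase (wrapping beyond VENC) and the
turbulent spread attenuates the magnitude. Inverting the magnitude ratio
`r = |S(k_v)|/|S(0)|` gives `σ_i = sqrt(2 ln(1/r)) / k_v`, and the
turbulent kinetic energy density is

    TKE = ρ/2 · (σ_x² + σ_y² + σ_z²)   [J/m³],  ρ = 1060 kg/m³.

The package implements the full chain:

1. **synthetic data** — an analytic candy-cane aorta (ascending limb,
   half-torus arch, descending limb; regional volumes ≈ 35/11/37 ml),
   pulsatile blunted-plug flow integrating to the stroke volume, an IVSD
   template with post-valvular and proximal-descending hot spots, simple
   four-point encoding and complex Gaussian noise at configurable SNR;
2. **turbulence mapping** — phase differences, automatic temporal and 4D
   Laplacian phase unwrapping (spectral Poisson solve, DCT in space / FFT
   in cycle time), IVSD/TKE estimation with a Rician noise-floor cap
   `σ_max = sqrt(2 ln SNR)/k_v`, and a 3×3×3 median filter for the
   maximum-TKE pathway;
3. **regional analysis** — division of the aorta at two centerline
   arc-length cuts into AAo/AoA/DAo (whole aorta TAo), the five
   hemodynamic parameters per timeframe (V_avg, V_max, TKE_total, TKE_max,
   TKE_med) and their cardiac-cycle peaks;
4. **cohort statistics** — Shapiro-Wilk-gated paired t / Wilcoxon tests,
   ANOVA+Tukey / Kruskal-Wallis+Dunn inter-region comparisons, fold
   changes, OLS regression of peak TKE_total on cardiac output, and
   ICC(A,k) observer-agreement estimates.

## Worked example

A full 12-subject rest/stress experiment, simulated, reconstructed and
analysed end to end (about one minute on one CPU):

```r
library(tke4d)
run <- run_pipeline(run_config(n_subjects = 12, seed = 1))
print(run)
#> pipeline run: 12 subjects x 2 conditions, seed 1
#>   TAo peak TKE_total: 3.85 -> 9.63 mJ (fold 2.5, wilcoxon p=0.000488)
#>   peak TKE_total ~ CO (TAo): R^2 = 0.61, p = 5.98e-06
#>   max |recovery error| of TAo peak TKE_total: 0.346
```

Reading this: across the simulated cohort, dobutamine stress raises the
whole-aorta peak total TKE from 3.85 to 9.63 mJ (the generator's
ground-truth fold is 2.8; noise-floor bias adds roughly 1 mJ to every
reconstruction, which compresses the recovered fold to 2.5 and dominates
the rest-condition recovery error), the paired Wilcoxon test is decisive,
and peak total TKE is significantly related to cardiac output. The
clinical anchors of the simulation are recomputable exactly:

```r
reproduce_table_arithmetic()[, c("id", "description", "computed", "pass")]
#>  t1  TAo peak TKE_total fold change   2.8  TRUE
#>  t2  AAo peak TKE_total fold change   2.8  TRUE
#>  t3  DAo peak TKE_total fold change   2.9  TRUE
#>  t4  combined AAo+AoA rest value      1.8  TRUE
#>  t5  rest CO from HR x SV             5.8  TRUE
#>  t6  dobutamine CO from HR x SV      11.0  TRUE
```

Single stages are exposed directly, e.g. a noiseless round trip:

```r
g   <- aorta_geometry()
ff  <- make_flow_field(g, flow_scenario("rest"), acquisition_config(snr = Inf))
sig <- synthesize_signals(ff)
maps <- reconstruct_maps(sig)          # velocity + TKE maps, unwrapped
```

## Command line

`inst/cli/tke4d` exposes `simulate`, `reconstruct`, `analyze`, `stats`,
`reproduce-targets` and `all` subcommands with YAML/JSON run configs, e.g.

```sh
Rscript inst/cli/tke4d all --config cfg.yaml --out run/ --seed 1
```

## Vignette

`vignettes/turbulence-mapping.Rmd` documents the signal model and its
assumptions, what the synthetic generator does and does not emulate, the
unwrapping design (including the guarded Laplacian cleanup mode), numerical
tolerances, and known limitations.
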