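---
title: "MR turbulence mapping in a synthetic thoracic aorta: models, design choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MR turbulence mapping in a synthetic thoracic aorta}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tke4d)
```

# The measurement model

4D flow MRI acquires a flow-compensated reference segment `S(0)` and three
velocity-encoded segments `S(k_v)`, one per spatial direction, over the
cardiac cycle. Within one voxel the blood velocity is not a single number
but a distribution; turbulence mapping assumes that distribution is
Gaussian with mean `v_i` and standard deviation `σ_i` (the intravoxel
velocity standard deviation, IVSD). Under that assumption the encoded
signal is

$$S(k_v) = S(0)\, e^{-k_v^2 \sigma_i^2 / 2}\, e^{i k_v v_i},
\qquad k_v = \pi / \mathrm{VENC},$$

so the phase difference between the encoded and reference segments carries
the mean velocity (aliasing — "wrapping" — when $|v_i| > \mathrm{VENC}$)
and the magnitude ratio carries the turbulent spread. The turbulent
kinetic energy density is the quadratic reduction
$\mathrm{TKE} = \tfrac{\rho}{2}\sum_i \sigma_i^2$ in J/m³.

Assumptions worth stating explicitly:

* **Gaussian intravoxel distribution.** This is the standard model behind
  the σ-from-magnitude inversion; non-Gaussian distributions change the
  attenuation law and are out of scope.
* **Four-point encoding.** One reference plus three one-sided encodings.
  The underlying product sequence's actual segment scheme is not public;
  four-point is the simplest faithful stand-in, and nothing downstream
  depends on the choice.
* **Blood density ρ = 1060 kg/m³**, the standard literature value; it
  enters only as a linear scale on TKE and is configurable everywhere.
* **k_v = π/VENC**: a phase of π at the encoding velocity.

# The synthetic world

`aorta_geometry()` builds an analytic candy-cane tube — vertical ascending
limb, half-torus arch, vertical descending limb — voxelized at 2.8 mm
isotropic, with a linearly tapering lumen radius (11.2 → 10.0 mm). The
default dimensions were chosen once so that cutting the centerline at arc
lengths `s₁ = 0.376` and `s₂ = 0.510` yields regional volumes close to a
healthy adult cohort (ascending ≈ 36, arch ≈ 12, descending ≈ 39 ml).
Supra-aortic branches are deliberately absent.

`make_flow_field()` realizes one physiological condition: axial velocity
along the centerline tangent with a blunted plug profile `1 − (r/R)^8`,
scaled per frame by a half-sine systolic waveform occupying 45% of the
cycle and rescaled discretely so the inlet-plane flow integral equals the
stroke volume exactly. The profile exponent and systolic fraction were
chosen once so the default rest condition lands in the measured range of
healthy subjects (peak V_max ≈ 1.3 m/s, just below VENC 1.4 m/s — i.e.
wrap-free at rest, wrapping under stress, as in vivo) rather than for any
test outcome. An optional diastolic baseline (`waveform$baseline`)
sustains flow through diastole; it exists to construct data in which whole
voxels stay aliased for the entire cycle.

The IVSD field is isotropic by default (anisotropy is a multiplier
option), separable into a spatial template — two Gaussian lobes in arc
length at `s = 0.25` (post-valvular) and `s = 0.60` (proximal descending),
width 0.065 — and a temporal Gaussian bump peaking at 22% of the cycle,
shortly after peak systole. With the default amplitude
`σ_peak = 0.33 m/s`, the ground-truth whole-aorta peak total TKE is
≈ 2.9 mJ and the peak voxel TKE ≈ 160 J/m³, matching the magnitudes
reported for healthy adults at rest. The dobutamine scenario multiplies
heart rate by 108/66, stroke volume by 102/88 and σ_peak by √2.8, so
ground-truth peak total TKE rises 2.8-fold while the aortic volume is
unchanged.

What the generator does **not** emulate: partial-volume effects at the
lumen wall, anatomical variability, supra-aortic branching, navigator
gating, k-space undersampling, eddy currents, or motion. A green test
therefore establishes correctness of the *processing chain*, not fidelity
to any individual scanner; in particular the in-vivo group SDs, p-values
and the reported R² of 0.90 between cardiac output and TKE are not
reproduction targets (the cohort draws turbulence amplitude independently
of cardiac output unless you construct it otherwise).

Noise is zero-mean complex Gaussian per channel, SD = tissue magnitude /
SNR in each of the real and imaginary parts, so magnitudes are Rician in
the lumen and Rayleigh in the (signal-free) background. The noise floor
this creates caps the resolvable IVSD at
`σ_max = sqrt(2 ln SNR)/k_v` (≈ 1.16 m/s at SNR 30, VENC 1.4); ratios at
or below 1/SNR saturate to σ_max and are flagged. Ratios ≥ 1 (noise
pushing the encoded magnitude above the reference) clip to σ = 0 — a
conservative, zero-biased choice in laminar voxels. The same mechanism
explains why reconstructed median TKE is nonzero even in laminar flow:
magnitude noise alone produces σ̂ of order 0.1 m/s per direction at
SNR 30, i.e. a TKE pedestal of tens of J/m³, which is also seen in vivo.

# Phase unwrapping: order and the guarded cleanup mode

Two automatic unwrappers are provided and run in the order *temporal
first, Laplacian second* (each optional):

* **Temporal**: per voxel, the frame of minimum |phase| anchors the series
  (diastolic velocities are lowest, so that frame is most likely
  alias-free) and successive cyclic differences are forced into (−π, π].
  This resolves systolic aliasing exactly whenever the phase changes by
  less than π between frames and at least one frame is alias-free.
* **4D Laplacian**: the classic wrap-invariant Poisson estimate
  $\nabla^2\varphi_{est} = \cos\varphi_w \nabla^2 \sin\varphi_w -
  \sin\varphi_w \nabla^2 \cos\varphi_w$, solved spectrally (orthonormal
  DCT-II over the three spatial axes — Neumann boundaries — and an FFT
  over the periodic cycle-time axis), the zero eigenvalue dropped and the
  input mean restored as gauge, then snapped to congruence so the output
  differs from the input by exact integer multiples of 2π.

Two departures from the textbook solver were forced by the data, and both
are visible in the code:

1. **Background fill.** The synthetic background holds noise (or nothing),
   so the lumen boundary is a phase cliff that corrupts the smooth Poisson
   estimate in wall voxels. When a lumen mask is available, background
   voxels are replaced before the solve by a Jacobi-diffused harmonic
   extension of the boundary values — phasor components when the input is
   still wrapped, raw values when it is already unwrapped (which continues
   the steep end-face phase smoothly instead of re-wrapping it).
2. **Cleanup guard.** At 2.8 mm resolution the lumen is only ~4 voxels in
   radius, and near the wall the *true* phase difference between adjacent
   voxels legitimately exceeds π under stress. No spatial unwrapper can
   distinguish such gradients from wraps, so an unguarded congruence snap
   corrupts wall voxels that temporal unwrapping had already restored.
   Temporal failures have a sharp signature, though: anchoring on a
   wrapped frame offsets the voxel's *entire* cycle by one constant
   multiple of 2π. When the Laplacian stage receives already-unwrapped
   input it therefore applies only corrections that are constant and
   nonzero across the whole cycle. On wrapped input (standalone use) the
   full snap applies.

With this design the chain is exact on wrap-containing vessel data (peak
speeds up to ~1.9 × VENC), the standalone Laplacian exactly unwraps smooth
full-grid phantoms, and the cleanup stage repairs whole-cycle aliasing
that temporal unwrapping cannot — which is the stage-necessity property
the tests assert. A manual override hook
(`apply_phase_corrections()`) accepts a voxel list of ±2π corrections,
replacing the human operator of the original workflow.

# Regional parameters and rounding conventions

`V_avg`/`V_max` operate on speed (the velocity-vector magnitude).
`TKE_total` is the volume integral over the region (reported in mJ) and
`TKE_med` the voxel median, both from the *unfiltered* TKE map; `TKE_max`
uses the 3×3×3 median-filtered map, since an isolated noise voxel would
otherwise set the regional maximum — the filter kernel is restricted to
masked voxels, and medians of even counts take the midpoint of the two
central values. Peaks are maxima over timeframes, ties resolved to the
earliest frame, identified independently per parameter and region. Voxels
with undefined reconstruction (zero reference magnitude) are excluded from
every reduction rather than zero-filled.

Printed-value reproduction rounds half away from zero at the printed
precision (`round_half_up()`); base R's banker's rounding would turn
2.85 into 2.8.

# Statistical layer

Normality gating uses Shapiro-Wilk at α = 0.05 — on the paired
*differences* for paired tests, per group for the inter-region comparison
(the source protocol names the tests but not the gated quantity; these are
the conventional choices). Gated routes: paired t vs Wilcoxon signed-rank;
one-way ANOVA with Tukey's HSD vs Kruskal-Wallis with Dunn's post-hoc
(tie-corrected, Bonferroni-adjusted pairwise p-values). All tests are
two-sided at α = 0.05 and no correction is applied across the many
parameter/region combinations, faithful to the original analysis. The
gated paired procedure's measured type-I error is 4.97 ± 0.3% at n = 12
(20 000 null replicates), the inter-region familywise rate 5.06 ± 0.4%.

Degenerate inputs are reported, not hidden: zero-variance paired
differences yield an infinite t statistic with p = 0 when the shift is
nonzero and no p-value at all when the vectors are identical; identical
groups return p = 1 everywhere; all-identical ratings return ICC = 1 with
a degeneracy flag.

ICC uses the two-way, absolute-agreement, average-measures form —
ICC(A,k) — from the standard mean-squares decomposition, with
McGraw-Wong F-based confidence bounds (Satterthwaite degrees of freedom);
it was verified to 12 decimals against an independent reference
implementation on fixed matrices. Note ICC(A,k) is unbounded below: with
discordant raters it can be well under 0, which the tests exercise.

# Numerical tolerances and degenerate inputs

* The noiseless round trip recovers velocity to machine precision
  (asserted at 10⁻¹⁰ relative to VENC) and σ to 10⁻¹⁰ *relative* wherever
  σ ≥ 10⁻³ m/s. Below that the magnitude ratio is 1 − O(ε) and no
  floating-point implementation can invert it relatively exactly; tiny σ
  are recovered to absolute 10⁻³ m/s instead.
* The discrete waveform is rescaled so the frame-sum times the frame
  spacing equals the stroke volume exactly; the analytic 2% tolerance
  remains the contract for user-supplied waveforms.
* Empty regions produce NA parameters; series that are NA at every frame
  are an error at peak identification.
* The cardiac cycle is periodic: temporal operators treat frame n as
  adjacent to frame 1, and the frame spacing rescales with heart rate so a
  cycle always holds `n_frames` samples.

# Interfaces

Datasets and maps are serialized as R `.rds` containers with the groups
`signals` / `truth` / `geometry` / `meta` (the deployment environment has
no R HDF5 or NIfTI bindings; the container layout mirrors that design so a
later swap is mechanical). Tabular artifacts are CSV/JSON; run configs
round-trip through YAML or JSON. The CLI mirrors the pipeline stages:
`simulate`, `reconstruct` (with `--no-laplacian`, `--no-temporal-unwrap`,
`--rho`), `analyze`, `stats`, `reproduce-targets`, `all`.

# Known limitations

* Voxelized analytic geometry: no partial volume, no wall motion, static
  mask across the cycle (the per-frame "volume at peak TKE_total" slot is
  therefore frame-independent here).
* The Laplacian solver assumes smoothness the vessel boundary violates;
  the fill + guard design handles the synthetic world's failure modes but
  is not a general quality-guided unwrapper.
* Group-level in-vivo statistics (SDs, p-values, R² = 0.90) are not
  reproducible from a generator whose turbulence amplitude is drawn
  independently of cardiac output; only the printed-table arithmetic and
  method-chain properties are asserted.
* Turbulent shear stresses, viscous energy loss and multi-VENC estimation
  are out of scope.
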