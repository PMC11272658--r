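---
title: "Wall shear stress models and endothelial polarity quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wall shear stress models and endothelial polarity quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fahraeus)
```

## The problem

Wall shear stress (WSS) — the tangential frictional force per unit area
that flowing blood exerts on the endothelium — is a central quantity in
vascular mechanobiology, but it is not measured directly in vivo. It is
computed from quantities that can be measured: the vessel inner diameter
$D$, the Doppler maximal (centerline) blood velocity $V_{max}$, the
hematocrit $Ht$, and blood or plasma viscosity. This package implements
three closed-form estimators for small arteries such as the mouse common
carotid, together with the sensitivity analysis that compares them, an
image-analysis pipeline that quantifies the endothelium's planar-polarity
response to flow, and ground-truthed synthetic generators so that every
stage can be exercised and validated without any experimental data.

## The three WSS models

**Theoretical Newtonian (tN) method.** Blood is treated as a homogeneous
Newtonian fluid in Poiseuille flow, where the centerline-to-mean velocity
ratio is 2 and the wall shear rate is $4 V_{max} / D$:

$$\tau_t = \eta_b \cdot \frac{4\,V_{max}}{D},$$

with $\eta_b$ the measured total blood viscosity. `wss_theoretical_newtonian()`
implements this.

**Corrected Newtonian (cN) method.** In small arteries the velocity
profile is blunter than parabolic ($V_{max}/V_m$ empirically near 1.45
rather than 2) and the apparent viscosity is lower than in large vessels.
The corrected estimator replaces the coefficient 4 = 8/2 by
$8/(V_{max}/V_m)$:

$$\tau_c = \eta \cdot \frac{5.5\,V_{max}}{D},$$

where 5.5 is the conventional rounded value of $8/1.45 = 5.5172\ldots$
`wss_corrected_newtonian()` uses the rounded coefficient by default for
fidelity to how the estimator is printed and used in the field;
`use_exact_coefficient = TRUE` switches to the exact ratio form (the two
differ by 0.3%). The viscosity $\eta$ is the caller's choice — plasma
viscosity $\eta_p$, total blood viscosity $\eta_b$, or the apparent
viscosity $\eta_{app} = 1.78\,\eta_p$ — because the three choices give
very different stresses and comparing them is part of the analysis
(`compute_wss(..., cn_variants = c("plasma", "blood", "apparent"))`).

**Plug/sheath (F) method.** The Fåhræus–Lindqvist view of small-vessel
flow: red cells concentrate in a central plug that travels at $V_{max}$,
surrounded by a cell-free plasma sheath across which the velocity falls to
zero at the wall. The wall stress is then borne entirely by plasma, and
the shear rate amplification depends only on hematocrit:

$$\tau_F = \eta_p \cdot \frac{4 V_{max}}{D} \cdot f(Ht), \qquad
f(Ht) = \frac{1 - Ht}{1 - Ht\,(1 - \ln Ht)}.$$

$f$ is dimensionless, greater than 1, strictly increasing in $Ht$, tends
to 1 as $Ht \to 0$ (pure-plasma Poiseuille limit) and diverges as
$Ht \to 1$. The shear-stress vector points against the flow; the package
reports magnitudes, per the universal positive-WSS convention. Published
variants of this formula differ in one printed sign/factor
($1 - 2\ln Ht$ vs $1 - \ln Ht$); the form above is the one that
reproduces the published group-mean WSS values from their group-mean
inputs (within 5%, the scale expected when a mean of per-animal ratios is
compared to a ratio of means), and the package treats it as canonical.
The test suite pins both the closed form and the published values.

**Hematocrit–viscosity model.** Measured total blood viscosity relates to
hematocrit approximately linearly over the physiological range:
$\eta_b[\mathrm{Pa\,s}] = 0.01258\,Ht - 0.001443$ with $Ht$ a fraction
(`blood_viscosity_from_hematocrit()`). At $Ht = 0.43$ this gives
$3.97\times 10^{-3}$ Pa·s ≈ 4 cP, matching measured values; interpreting
the coefficients on a percent hematocrit scale gives a nonsensical
0.5 cP, which is why the fraction/Pa·s reading is the package's fixed
convention. The line is only valid above its positivity root
($Ht \approx 0.115$); below it the function raises an error rather than
returning a negative viscosity.

Units are SI internally; mm, mm/s and cP appear only at the I/O boundary
with the fixed conversion 1 cP = $10^{-3}$ Pa·s.

## Method comparison

Because $\tau_t$ and $\tau_F$ share the $4 V_{max}/D$ kernel, their
normalized difference

$$100 \cdot \frac{\tau_t - \tau_F}{(\tau_t + \tau_F)/2}$$

is invariant in diameter and velocity and depends only on hematocrit and
the two viscosities. `run_sweep()` demonstrates this on the same grids
used in practice (0.1–1.0 mm diameter, 100–1100 mm/s velocity,
38%–48% hematocrit):

```{r sweep}
run_sweep(sweep_spec("hematocrit"))
method_difference_at_ht(0.43)
```

With the Newtonian arm's viscosity taken from the regression line and the
plug/sheath arm using the sex-pooled plasma viscosity 1.265 cP, the
difference is 13.0% at $Ht = 0.43$ at every diameter and velocity, rising
from about 7% to about 16% across the physiological hematocrit range. The
sweep's held-constant inputs default to sex-pooled diastolic means
(diameter 0.3815 mm, $V_{max}$ 162 mm/s); the exact pooled values are
configurable but, by the invariance above, immaterial to these numbers.
The pooled plasma viscosity 1.265 cP is the mean of the two sex-group
values (1.26 and 1.27 cP); either sex's value changes the plateau by less
than 0.1 percentage point.

## The polarity pipeline

Endothelial cells polarize against flow: the Golgi apparatus positions on
a preferred side of the nucleus, and the nucleus elongates. The pipeline
quantifies this from two-channel 8-bit fluorescence images (nucleus,
Golgi) with known pixel size and flow direction:

1. **Background thresholding** (`gaussian_background_threshold()`). The
   background grey-level distribution is modelled as Gaussian; foreground
   is everything strictly above $\mu_{bg} + 3.89\,\sigma_{bg}$, which
   retains 99.995% of a Gaussian background ($\Phi(3.89) = 0.99995$).
   $\mu_{bg}, \sigma_{bg}$ are estimated by fitting a parabola to the log
   counts around the dominant *lowest-intensity* histogram mode — robust
   both to a sparse bright foreground and to a second, brighter foreground
   mode — with a documented fallback to the whole-image mean/SD when the
   fit is degenerate (near-constant images). The exact estimator behind
   the published pipeline is not specified; this mode fit is this
   package's own documented choice, and the pure-noise tail property is
   what the tests pin down.
2. **Despeckling** (`despeckle()`): one pass of a 3×3 binary median
   (majority of 9, zero-padded), which removes isolated voxels and
   preserves solid interiors. A brute-force median is kept as a test
   oracle.
3. **Object identification** (`identify_objects()`): 8-connected
   components (4-connected labeling plus a diagonal-merge pass), size
   segmentation at 10 µm² for nuclei and 2 µm² for Golgi, then sub-pixel
   centroids and ellipse-equivalent major/minor axes from second-order
   moments (including the 1/12 px² pixel-extent term). Touching organelles
   merge into one component — a known limitation shared by any
   connected-component approach without instance splitting.
4. **Pairing** (`pair_nucleus_to_golgi()`): each nucleus takes its
   nearest Golgi centroid (Euclidean). A Golgi may serve several nuclei
   by default (the conservative reading of "nearest"); ties break to the
   lowest Golgi id; `one_to_one = TRUE` gives a greedy unique assignment.
5. **Orientation** (`angle_to_flow()`, `classify_orientation()`): the
   nucleus→Golgi angle to the flow direction on the semicircle [0°, 180°],
   classified as dromic [0°, 60°), lateral [60°, 120°), antidromic
   [120°, 180°]. The half-open convention resolves the boundary overlap of
   the printed class definitions; for continuous angles the boundary has
   measure zero, so the choice is cosmetic but fixed.
6. **Polarity metrics** (`polarity_metrics()`): mean ± SEM of N-G vector
   length and nucleus elongation (major/minor).

Because the two channels are processed digitally in separation, the
RGB-merge/colour-threshold step of bench pipelines is unnecessary: colour
segmentation collapses to per-channel processing with identical results.

## Synthetic data: what it emulates and what it does not

`generate_cohort()` draws per-animal measurements from the reference
group means and SDs (truncated normal at zero — the minimal distributional
assumption when only mean ± SD are reported), with diameter and velocity
per cardiac phase and hematocrit/viscosity/heart-rate per animal. The
optional `viscosity_coupling` mode draws viscosity from the regression
line plus residual noise; the default residual SD of 0.43 cP makes the
population $R^2$ about 0.35 given the reference hematocrit spread of
0.02–0.03 — consistent with the published fit quality and with the
measured viscosity SDs (0.4–0.6 cP). A real per-animal $R^2$ depends on
the actual residuals, which are not published; only its emulation is
testable.

`generate_endothelium_image()` renders a 160×160 µm field at 78 nm pixels
(2051²) by default: elliptical nuclei (12 ± 1 × 6 ± 0.5 µm, random
orientation, so elongation ≈ 2 — typical of flow-aligned endothelium),
one Golgi disc (4 ± 1 µm²) per nucleus at an N-G distance of 5 ± 1 µm and
a class-controlled angle, over Gaussian 8-bit noise (20 ± 8 background,
200 ± 8 foreground). Placement is sequential rejection sampling that
enforces, for every earlier cell: centroid separation ≥ 14 µm,
non-touching nuclei (bounding circles + 1 µm), non-merging Golgi blobs,
and *pairing dominance* — every foreign Golgi is farther from a nucleus
than its own — so the ground-truth pairing is unambiguous by
construction. Infeasible densities raise an explicit packing error rather
than degrading silently. The generator does not simulate a confocal
point-spread function, photon shot noise, intensity gradients, partial
cells at field edges, or touching nuclei; recovery tests on these images
therefore validate the pipeline's geometry and bookkeeping, not its
robustness to real staining variability.

## Statistical contracts

Group contrasts use the two-sided Mann–Whitney test (`compare_groups()`;
exact for tie-free samples up to n = 25 per group, normal approximation
with continuity correction beyond — the published analyses do not state a
convention, so the package fixes this one). Orientation distributions are
tested against the equiprobable one-third null by χ² goodness of fit
(df = 2) or between groups by contingency χ²
(`test_orientation_uniformity()`). Nucleus elongation is tested against 1
by a one-sample Wilcoxon signed-rank test (`test_elongation()`); for
n ≤ 15 the p-value comes from exact sign-flip enumeration, which remains
valid under tied absolute differences, above that from the continuity-
corrected normal approximation. Values exactly at the null carry no
information and are dropped, per the usual signed-rank convention; an
all-at-null sample yields an undefined statistic, reported as
non-significant with a warning. The viscosity regression is ordinary
least squares on hematocrit as a fraction with viscosity in Pa·s,
reported on both coefficient scales. Significance is declared at
p < 0.05 throughout, without multiplicity correction, matching the
reporting conventions the package mirrors.

## Numerical and design notes

- **Problem sizes.** The bundled tests validate the pipeline on ten
  2051² synthetic images of 50 cells (500 cells total) and calibrate each
  statistical test on 10,000 null replicates; the cohort generator is
  checked at n = 60 per group for distributional properties and n = 13
  for regression recovery, matching the scale of the emulated study.
- **Thresholding tolerance.** The empirical foreground fraction of a
  pure-noise field is compared to the analytic $5\times10^{-5}$ within
  about four binomial standard deviations plus estimator slack (accepted
  range $[10^{-5}, 10^{-4}]$ at 2048²), fixed a priori.
- **Degenerate inputs.** Constant images threshold to an empty mask (not
  an error); empty masks yield empty object tables; empty pairings yield
  `NULL` summaries; zero-length N-G vectors are excluded from
  classification with a warning.
- **Determinism.** Both generators are bit-reproducible under a fixed
  seed, and every stochastic test in the suite fixes one.

## Reference inputs

`carotid_reference_groups()` carries the group-level summary
(sex × cardiac phase means and SDs for diameter, velocity, hematocrit,
viscosities, heart rate) that anchors the synthetic cohort defaults and
the acceptance computations:

```{r groups}
carotid_reference_groups()
```
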