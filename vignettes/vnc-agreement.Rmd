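---
title: "Quantifying TNC/VNC agreement for emphysema imaging: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying TNC/VNC agreement for emphysema imaging: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Emphysema is quantified on non-contrast chest CT from the lung attenuation
histogram: the low-attenuation volume (LAV) at or below −950 HU is the
standard emphysema proxy, and the 10th/15th percentiles of the histogram
proxy pre-emphysema. Iodinated contrast raises parenchymal attenuation and
depresses these scores, so contrast-enhanced scans are unusable for
emphysema scoring — unless a *virtual non-contrast* (VNC) reconstruction
from a spectral acquisition can stand in for a *true non-contrast* (TNC)
scan. Whether it can is an agreement question: paired TNC/VNC
measurements per patient, compared overall and within body-size and dose
strata, since residual iodine signal after spectral subtraction depends on
photon penetration and hence on patient size.

`vncqct` implements that full analysis — segmentation, histogram metrics,
water-equivalent-diameter (DW) dosimetry, and paired/stratified
nonparametric statistics — and, because clinical scan pairs cannot be
redistributed, ships a synthetic paired-phantom generator with analytic
ground truth so every stage is testable end to end.

## The phantom model

A phantom is an elliptical soft-tissue cylinder (+40 HU) containing two
ellipsoidal lungs at a parenchymal baseline, with spherical emphysema
clusters placed by seeded rejection sampling (non-overlapping, clipped to
the lung) until a target volume fraction is reached; everything outside
the body is air at −1000 HU. The VNC member is the same clean anatomy
with a constant offset added inside the lung mask plus an independent
noise realization. A constant offset is the minimal model of imperfect
iodine subtraction; the spatial structure of real TNC/VNC disagreement is
unknown, and we deliberately do not invent one.

Default study conditions (all overridable via `phantom_spec()`):

| parameter | default | rationale |
|---|---|---|
| slice thickness | 0.9 mm | typical thin-slice axial chest reconstruction |
| in-plane grid | 256 × 256 @ 1.6 mm | fine enough that clusters span several pixels, as lucencies do clinically |
| body | 105 × 145 mm semi-axes, +40 HU | adult thorax cross-section, soft tissue |
| parenchyma | −900 HU | severely hyperinflated COPD lung |
| emphysema clusters | −1000 HU, radius 12 mm, 15% of lung | confluent, air-density destruction |
| voxel noise | σ = 40 HU, i.i.d. Gaussian | thin-slice chest CT noise; no texture/streaks |
| VNC offset | +4 HU in-lung | small residual attenuation after subtraction |
| CTDIvol | ~4 mGy | matches low-dose chest protocols |

Two of these deserve comment because they interact with the noise
suppression stage. The analysis median-filters the lung (3×3×3) before
scoring, so emphysema must be *resolvable*: clusters several voxels across
at the default sampling. And for filtering to be the right choice at all,
unfiltered noise must bias the score — with parenchyma at −900 HU, the
σ = 40 noise tail crosses −950 HU and inflates raw LAV by about 7
percentage points, which the filter removes. Both values are clinically
sensible for the severe-COPD setting this models and were fixed as the
package's study conditions.

`analytic_truth()` gives closed forms: lung volume as $\tfrac{4}{3}\pi abc$
per ellipsoid, and DW from per-slice region areas (below). The generated
truth additionally counts the actually rasterized voxels, so
parameter-recovery tests compare against exact counts, not just the
target fraction.

What the phantoms do **not** emulate: airways, lobar anatomy, partial
volume at interfaces, CT noise correlation, beam hardening, or the
spectral physics of VNC reconstruction. Passing tests therefore validate
the *measurement and statistics chain*, not the clinical fidelity of VNC
imaging itself.

## Segmentation

Vendor COPD tools segment the lungs with undisclosed rules; `segment_lungs()`
is an explicit replacement: threshold air-like voxels (< −320 HU), remove
exterior air as anything connected to the in-plane border (a 2-D per-slice
pass, then a 3-D 26-connectivity pass), keep the largest components
(default 2) above 50 cm³, and close morphologically with a 2 mm sphere.
On noise-free phantoms this recovers the rasterized lung label with Dice
≥ 0.99 and the analytic volume within 2%. Equivalence with any particular
vendor tool cannot be claimed — only internal ground-truth recovery.
Airway removal is reserved (`remove_airways`) but unimplemented: phantoms
have no airway tree.

## Emphysema metrics

From the masked attenuation distribution, `emphysema_metrics()` reports:

* **LAV** in cm³ and % of lung volume, counting voxels *at or below* the
  threshold (inclusive, "−950 HU and less");
* **percentile densities** PD10/PD15: the smallest HU value h such that at
  least p% of lung voxels are ≤ h (lower empirical quantile, no
  interpolation — reproducible across platforms, ties toward lower HU);
* **percentile volumes** pvol10/pvol15 = p% × lung volume, the
  definitional cm³ reading of a percentile.

Both the HU and the cm³ readings are reported because clinical reports
label percentile panels in cm³ even though a histogram percentile is an
HU value; the definitional cm³ reading is proportional to lung volume by
construction, so TNC/VNC differences in it reflect only segmentation
differences. The ambiguity is real in vendor outputs and is documented,
not resolved.

Noise suppression is a 3-D median filter (3×3×3, odd kernels only),
applied in-mask and drawing only on in-mask neighbours so soft tissue
never bleeds across the pleura; it runs before the histogram by default,
matching routine use of vendor noise-suppression functions. Histogram
binning is left-closed right-open over [−1024, 3071] HU; the histogram
quantile path agrees with the direct voxel-sort path within one bin width.

## Dosimetry

The water-equivalent area of a slice is
$A_w = \sum_{\text{pixels}} \max(\mathrm{HU}/1000 + 1,\, 0)\cdot a_{\text{pixel}}$
and $D_W = 2\sqrt{A_w/\pi}$. Air contributes zero, so the sum runs over
the full slice with no body contour; the clamp keeps sub-air voxels from
producing negative area. The study-level DW is the arithmetic mean over
all slices, computed from the TNC member as in clinical practice — and
also from the VNC member, since the delta is itself a cheap agreement
check. SSDE multiplies CTDIvol by $f(D_W) = a e^{-b D_W}$; the default
coefficients (a = 3.704369, b = 0.003671937 per mm) are the 32-cm
body-phantom fit of the AAPM size-specific-dose reports and live in
configuration (`ssde_coefficients()`), with a 16-cm head alternative —
they are conversion conventions, not measured truths.

## Statistics

All comparisons are two-sided at α = 0.05, on VNC − TNC differences so
that a VNC-lowering effect has a negative sign.

* **Normality gate**: D'Agostino–Pearson omnibus K² (skewness z by
  D'Agostino's transformation, kurtosis z by Anscombe–Glynn, K² ~ χ²₂),
  n ≥ 8 required. Its type-I error at n = 1000 sits at the nominal 5%.
* **Wilcoxon signed-rank**: zero differences discarded before ranking
  (classic treatment; Pratt's variant available), midranks for tied
  magnitudes, exact tie-aware null by count convolution up to 25 nonzero
  pairs, tie-corrected normal approximation with continuity correction
  beyond. Exact p-values equal full 2ⁿ enumeration bit for bit.
* **Mann–Whitney U**: reported as U = min(U₁, U₂) with midranks; exact
  null (subset-sum counting) for tie-free samples up to combined n = 20,
  tie-corrected normal approximation otherwise; two groups whose values
  are all tied carry no information and report p = 1 rather than failing.
* **Pairing effectiveness r**: the Pearson correlation of the paired
  values — the "r" conventionally printed next to paired tests. This
  definition is a choice (the quantity is rarely defined in reports) and
  is stated prominently wherever r appears.
* **Bland–Altman**: bias = mean difference, limits of agreement
  bias ± 1.96 × SD of differences; ~95% of Gaussian differences fall
  inside by construction.
* **Stratified analysis**: within each stratum a paired Wilcoxon; between
  the two strata of a split, a Mann–Whitney on the per-patient
  differences. Default splits: sex; contrast phase; DW at 270 mm; SSDE at
  3.2 mGy; BMI 18.5–25 vs > 25 kg/m²; age < 50 vs > 69 years (the middle
  band deliberately excluded); iodine amount, iodine/weight ratio and
  acquisition time gap as cohort-median splits, since no standard cut
  points exist for them. Rows missing a stratum variable are excluded
  from that split and counted.
* **Multiple testing**: none by default, mirroring common radiology
  practice of reporting each contrast as-is; `adjust = "holm"` is
  available. One published value this package cannot reproduce by design:
  a non-integer "U = 44.05" reported for a time-difference contrast —
  standard U statistics are half-integers at most through midranks, so
  the package computes standard U and flags the discrepancy here rather
  than matching it.

Degenerate inputs are contracts, not accidents: identical paired members
report "identical" instead of a p-value; an all-zero difference vector
raises a degenerate-pairs error at the test level; empty strata are
skipped with a warning and single-stratum splits report their contrast as
not applicable.

## The synthetic cohort and reproducibility

`simulate_cohort()` draws per-patient covariates matching a typical COPD
spectral-CT cohort (56% male; ages 18–85; BMI 25.5 ± 4 so about half are
elevated; pulmonary-arterial phase 21%; iodine 27.3 ± 5.9 g; TNC/VNC gap
0–54 days; CTDIvol 4 ± 1 mGy) and one phantom pair per patient, scaling
the soft-tissue body (×0.9–1.3) so DW varies realistically at similar
lung volume, and drawing the emphysema fraction from 5–30%. Every
patient's phantom and covariates derive from a per-patient seed hashed
from the master seed, so a cohort can be extended without perturbing
existing patients, and a fixed master seed makes the whole study —
including CSV outputs — byte-identical across runs.

Problem sizes were chosen to keep a full run desk-sized: the default
grid is 40 × 256 × 256 (≈ 2.6 M voxels), a 20-pair study runs in about a
minute, and the exact-test verification enumerates instances of n ≤ 10
(Wilcoxon) and m, n ≤ 8 (Mann–Whitney), where brute force is a sound
oracle.

## Known limitations

* VNC error is modelled as a spatially constant in-lung offset; any
  size- or depth-dependent structure of real spectral subtraction error
  is out of scope.
* The segmentation is density-based and phantom-oriented; on real scans
  with effusions or consolidations it would need the reserved airway and
  pathology handling.
* The definitional percentile-volume reading makes TNC/VNC percentile
  "volume" comparisons insensitive by construction; the HU-valued
  percentile densities carry the pre-emphysema signal.
* i.i.d. Gaussian noise understates the spatial correlation of real CT
  noise; the median filter's benefit on real data will differ in degree.
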