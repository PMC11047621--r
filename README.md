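# vncqct

Quantitative-CT agreement analysis for **true non-contrast (TNC)** versus
**virtual non-contrast (VNC)** chest imaging in COPD.

Routine chest CT is usually contrast-enhanced, but emphysema scoring needs
non-contrast attenuation: iodine raises lung density and suppresses the
scores. Spectral (dual-layer) scanners can reconstruct VNC images from
contrast scans, promising emphysema assessment without an extra
non-contrast acquisition — *if* VNC agrees with TNC. `vncqct` implements
the measurement and statistics chain needed to answer that question, for
radiology physicists and imaging scientists:

* **Emphysema metrics** from the masked lung attenuation histogram: the
  low-attenuation volume LAV = volume of lung voxels with HU ≤ −950 (in
  cm³ and % of lung volume), percentile densities PD10/PD15 (the HU value
  h at which at least p% of lung voxels are ≤ h), and the definitional
  percentile volumes (p% × lung volume); optional 3-D median noise
  suppression.
* **Lung segmentation**: explicit density-based extraction (threshold,
  border-connected air removal, component filtering, morphological
  closing) standing in for undisclosed vendor tools.
* **Dosimetry**: per-slice water-equivalent diameter
  `DW = 2·sqrt(A_w/π)` with `A_w = Σ max(HU/1000 + 1, 0)·pixel area`
  (the AAPM TG-220 relation), its volume mean, and the size-specific dose
  estimate `SSDE = CTDIvol · a·exp(−b·DW)`.
* **Paired statistics**: D'Agostino–Pearson normality gate, exact
  Wilcoxon signed-rank and Mann–Whitney U (enumeration-verified small-
  sample nulls), pairing-effectiveness r, Bland–Altman bias and limits of
  agreement, and a configurable stratified confounder analysis (sex, age,
  BMI bands, contrast phase, iodine, time gap, SSDE at 3.2 mGy, DW at
  270 mm).
* **Synthetic paired phantoms**: thoracic TNC/VNC pairs with analytically
  known lung volume, emphysema fraction and DW, plus a whole-cohort
  simulator — so every stage is validated against ground truth.
* **I/O**: NIfTI-1 (via RNifti) and a minimal CT DICOM series codec, with
  JSON sidecars for dose and patient metadata.

## Worked example

```r
library(vncqct)

ps <- generate_phantom(phantom_spec(seed = 42))  # paired TNC/VNC phantom
m  <- segment_lungs(ps$tnc)
emphysema_metrics(ps$tnc, m)
#> <emphysema_metrics>
#>   lung volume : 522.8 cm^3
#>   LAV (<= -950 HU): 80.5 cm^3 (15.40%)
#>   PD10: -989 HU   (percentile volume 52.3 cm^3)
#>   PD15: -955 HU   (percentile volume 78.4 cm^3)
dosimetry(ps$tnc)
#> <dosimetry_result> mean DW 218.2 mm over 40 slices (range 189.7-256.5)
#>   CTDIvol 4.00 mGy x f=1.663 -> SSDE 6.65 mGy
```

The phantom was built with a 15% emphysema fraction; the pipeline
(segmentation → median filtering → histogram) measures LAV = 15.40%, and
PD15 = −955 HU sits just above the cluster attenuation because slightly
more than 15% of the lung is at air density. The mean water-equivalent
diameter of 218 mm describes a mid-sized thorax, giving an SSDE
conversion factor of 1.66 on the nominal 4 mGy CTDIvol.

A full paired study — simulate a cohort, build the per-patient table, run
overall and stratified TNC-vs-VNC comparisons, write CSVs, plots and
provenance:

```r
study <- run_study(n = 20, seed = 42, out_dir = "study-out")
study$comparison$summary          # per-metric paired Wilcoxon + Bland-Altman
study$comparison$by_metric$lav_cm3$contrasts  # between-strata Mann-Whitney
```

A thin CLI over the same functions is in
`inst/scripts/vncqct-cli.R` (`simulate`, `dw`, `metrics`, `run`).

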