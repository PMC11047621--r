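Package: vncqct
Title: Quantitative CT Agreement Analysis for True and Virtual Non-Contrast Chest Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for assessing whether virtual non-contrast (VNC) chest CT
    reconstructions can replace true non-contrast (TNC) acquisitions for
    emphysema quantification in COPD. Implements histogram-based emphysema
    metrics (low-attenuation volume at -950 HU, percentile densities),
    density-based lung segmentation, AAPM TG-220 water-equivalent diameter
    and size-specific dose estimates, and paired/stratified nonparametric
    agreement statistics (exact Wilcoxon signed-rank and Mann-Whitney U,
    D'Agostino-Pearson normality gate, Bland-Altman analysis). A synthetic
    paired thoracic phantom generator with analytically known ground truth
    supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
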