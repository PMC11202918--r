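# fundusHSI

Hyperspectral conversion, spectral band selection and classification of
retinal fundus images, aimed at glaucoma screening research.

Glaucoma alters the reflectance of the optic nerve head: thinning of the
retinal nerve fiber layer reduces short-wavelength scattering, shifting
reflectance toward longer wavelengths. Ordinary fundus cameras record only
three broad channels, so this package analyses fundus photographs in the
spectral domain instead:

1. **Calibration** — a 24-patch color checker with spectrometer-measured
   reflectances fits a transform from camera RGB to full reflectance spectra
   (gray-world white balance, Bradford chromatic adaptation to D65, then a
   PCA reflectance basis with ridge-regularized polynomial regression). Each
   photograph becomes a hyperspectral cube on a 380–780 nm grid.
2. **Band selection** — for two groups (glaucoma / normal) the per-class
   mean `m_k(λ)` and across-subject standard deviation `s_k(λ)` of ROI
   reflectance define the per-wavelength statistic

   `SNRdiff(λ) = | m₁(λ)/s₁(λ) − m₂(λ)/s₂(λ) |`.

   Its peaks are ranked; the second-highest peak supplies a threshold, and
   the selected interval runs from the last upward threshold crossing
   (linearly interpolated) to the grid maximum.
3. **Localization** — a frozen-backbone regressor predicts the optic-disc
   bounding box and a fixed-size ROI is cropped (reflection-padded), with
   the same coordinates applied to the cube.
4. **Classification** — band-limited images reconstructed from the cube
   (colorimetric rendering via CIE color-matching functions) are classified
   by a frozen Vision Transformer feature extractor with a trainable dense
   head (512 → 256 → 2, dropout 0.25/0.50, cross-entropy, SGD 1e-4 with
   Nesterov momentum, early stopping patience 3 / min-delta 0.03), reporting
   accuracy, macro precision/recall/F1 and AUC-ROC per band.

A synthetic phantom generator plants a known discriminative interval in
two-class fundus phantoms, so calibration, band selection, localization and
classification are all testable without clinical data or downloads. See
`vignettes/methods.Rmd` for the model, parameter and design details.

## Worked example

Forty phantom scenes, checker calibration, localization, band selection and
per-band classification, end to end:

```r
library(fundusHSI)

cfg <- pipeline_config(out_dir = "run1", seed = 7, n_per_class = 30,
                       image_size = 96, grid_step = 5,
                       intervals = list(`610-780` = band_interval(610, 780),
                                        `440-485` = band_interval(440, 485)))
res <- run_pipeline(cfg)
print(res$selected)
#> <band_interval> 565-780 nm (threshold 0.6252, crossing 569.14 nm)
print(res$metrics_table, digits = 3)
#>            band accuracy precision recall    f1 auc_roc
#> 610-780 610-780    1.000     1.000  1.000 1.000   1.000
#> 440-485 440-485    0.833     0.875  0.833 0.829   0.889
#> RGB         RGB    1.000     1.000  1.000 1.000   1.000
round(mean(res$localizer_iou), 2)
#> [1] 0.72
```

Reading the output: the phantom cohort's SNR-difference curve crosses its
reference-peak threshold at 569.1 nm, so the selected interval is
565–780 nm — the planted 610–780 nm contrast is recovered, with the edge
smeared toward shorter wavelengths because these cubes were reconstructed
from three-channel RGB and the conversion redistributes the planted offset
within its metamer class. For the same reason some class signal leaks into
every band: the classifier on the selected band separates the test split
perfectly, the disjoint 440–485 nm band does measurably worse, and the RGB
baseline (which sees the long-wavelength contrast directly through its red
channel) performs well. The localizer finds held-out optic discs with mean
IoU 0.72. `run1/` contains the per-band metric table
(`band_metrics.csv`), the curve, peaks and selected interval, the dataset
manifest, and a provenance JSON with the seed and configuration.

A subcommand CLI wrapping the same functions is installed at
`inst/cli/fundus_hsi.R`
(`simulate`, `calibrate`, `convert`, `reconstruct`, `select-bands`,
`run-all`).

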