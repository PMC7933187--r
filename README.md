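# naquant

Disentangling intracellular sodium concentration and extracellular volume
fraction in breast tissue from multinuclear MRI.

## The problem

Total sodium concentration (TSC) measured by sodium (²³Na) MRI is elevated
in malignant breast lesions, but the elevation is ambiguous: it can come
from a higher intracellular sodium concentration (C_IC, a marker of
cell-viability and Na⁺/K⁺-pump dysfunction) or from an expanded
extracellular volume fraction (ECV, which changes with cell death and
edema), or both. `naquant` implements a quantification pipeline that
resolves the two by combining the sodium measurement with two
high-SNR proton (¹H) measurements, plus a digital phantom simulator so
every stage can be validated against exact ground truth without scanner
data. It is aimed at quantitative-MRI researchers building or evaluating
compartmental sodium analyses.

## The model

An imaging voxel is split into three compartments — extracellular water,
intracellular water and fat — each with its own sodium concentration and
volume fraction:

    TSC = ECV * C_EC + ICV * C_IC + (1 - WF) * C_fat,   ICV = WF - ECV

* **TSC** comes from the sodium image through a phantom calibration chain:
  B1 normalization against a uniform phantom, Richardson–Lucy
  deconvolution with the T2-weighted point spread function of the
  center-out readout, and relaxation correction by

      lambda = (1 - e^(-TR/T1)) / (1 - cos(FA) e^(-TR/T1))
               * (0.6 e^(-TE/T2s) + 0.4 e^(-TE/T2l))

* **WF** (water fraction) comes from multi-echo gradient-echo data via
  IDEAL-style iterative water/fat separation with a field-map estimate.
* **ECV** comes from pre/post-contrast T1 maps, normalizing the
  relaxation-rate change by that of a pectoral-muscle reference of known
  ECV_ref = 0.12:

      ECV = ECV_ref * (R1_post - R1_pre) / mean_muscle(R1_post - R1_pre)

* **C_EC** is fixed at 140 mM; **C_fat** is estimated as the mean TSC in
  voxels with WF < 10%. Solving the model voxel-wise yields C_IC and ICV.

The package also provides sodium relaxometry fitting (saturation-recovery
T1, biexponential T2 with the 60:40 quadrupolar split), deterministic
error-propagation sweeps over C_EC, ECV_ref and the relaxation times with
the mean-uncertainty statistic `100 * (max - min) / (2 * c0)`, and a
`simulate / fit-t1 / fit-t2 / ecv / invert` command line at
`inst/cli/naquant.R`.

## Worked example

Calibrate against a simulated five-gel phantom, then quantify a simulated
breast acquisition (48³ sodium grid, sodium SNR 20) and compare the tumor
ROI with the phantom's ground truth:

```r
library(naquant)
acq <- acq_spec(matrix_size = 48)          # TR 60 ms, TE 0.2 ms, FA 80
cfg <- naquant_config(sodium_acq = acq)

cal_ph <- make_calibration_phantom(acq = acq, snr = 30, seed = 2)
cal <- calibrate_from_phantom(cal_ph, config = cfg)
print(cal)
#> calibration: signal = 0.7459 * C + -0.1737  (R^2 = 1.0000, 5 gels)

ph <- make_breast_phantom(acq = acq, snr = 20, seed = 1)
res <- run_pipeline(list(
  sodium = ph$sodium,
  b1_reference = make_b1_reference(acq, ph$b1),
  echoes = ph$echoes, t1_pre = ph$t1_pre, t1_post = ph$t1_post,
  muscle_mask = ph$muscle_mask, calibration = cal),
  cfg, rois = list(tumor = ph$labels_sodium == 3L))
res$roi_stats
#>   roi_name quantity       mean         sd   n
#> 1    tumor      tsc 53.6154863 2.85387184 324
#> 2    tumor      ecv  0.2431247 0.01656024 324
#> 3    tumor      icv  0.6541729 0.01173744 324
#> 4    tumor     c_ic 28.1219348 4.83371467 324
res$c_fat_mM
#> [1] 11.3
```

The simulated tumor was built with TSC 55.5 mM, ECV 0.25 and C_IC 30 mM:
the pipeline recovers the tumor-ROI means within about 4% (TSC), 0.007
absolute (ECV) and 6% (C_IC) at this noise level; the residual low bias
comes from partial voluming of the small tumor with surrounding
fibroglandular tissue. The mean ± SD over an N-voxel ROI is the same
reporting form used for in-vivo lesion statistics.

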