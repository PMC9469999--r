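# lgeseg

Segmentation and quantification of myocardial infarct lesions on
short-axis late gadolinium enhancement (LGE) cardiac MR images, as a
scriptable R library with a thin command-line front end.

Infarct size measured on LGE images is a standard surrogate endpoint after
acute myocardial infarction, but the thresholding methods behind it are
usually locked inside closed tools, which makes results hard to reproduce
and methods hard to compare. `lgeseg` implements the full measurement chain
in the open — myocardial contouring, six lesion-segmentation methods,
no-reflow (MVO) handling, AHA 17-segment statistics and endocardial surface
metrics — together with a synthetic phantom generator so that every method
can be benchmarked against known ground truth at controlled
contrast-to-noise ratio (CNR), without any clinical data.

## What is implemented

**Myocardial segmentation** — two-click initialization (LV center + one
epicardial point), refinement of both contours by a polar B-spline active
contour driven by localized in/out mean separation (the BEAS family),
millimetre endo/epi offsets, and linear propagation of keyed contours
across slices.

**Lesion segmentation** (all operate inside the myocardial mask; a pixel is
lesion when its intensity is strictly above the threshold T):

| method | threshold |
|---|---|
| n-SD (STRM) | `T = mu + c * sigma` of a remote reference region, `c` in 2..10 |
| histogram range | `lo <= I <= hi`, two interactive cursors |
| FWHM max / region | `T = I_max / 2`; `I_max` from the whole wall or a 3x3-smoothed seed region |
| Rician-Gaussian mixture (GMM) | EM fit of `w Rice(nu, sigma_r) + (1-w) N(mu_g, sigma_g^2)`; T at the weighted density crossing |
| FACT (Hsu modified) | iterative threshold + 8-connected minimum-region filtering + re-estimation |
| HMRF-EM | two-class Gaussian emissions with a Potts prior (weight `beta`), ICM E-steps |

FACT and HMRF-EM also detect microvascular obstruction: enclosed
hypointense cores inside the lesion are promoted to the MVO class, and MVO
is counted into infarct size (`merge_mvo()` adds or removes it manually).

**Quantification** — AHA 17-segment assignment anchored on the LV/RV
junction landmark, per-segment/per-class statistics tables, bullseye
export; endocardial surface length `ESL = 100 * arc / perimeter`, its
multi-slice area analogue ESA, per-sector transmural extent, and wiper
clipping.

**Phantom + benchmark** — ring myocardium with a wedge lesion of arbitrary
angular extent, %SE and (possibly sinusoidally varying) transmural depth,
optional MVO core, and seeded Gaussian or Rician noise calibrated so that
`CNR = (lesion - remote) / noise SD` hits a target;
`run_cnr_benchmark()` sweeps every method over a CNR grid and reports
relative error `RE = (area_method - area_truth) / area_truth` and its
absolute value ARE.

**I/O** — single-frame DICOM series (explicit VR little endian, rescale
slope/intercept honoured), NIfTI label maps with JSON provenance sidecars,
CSV statistics, JSON contours and bullseyes.

## Worked example

```r
library(lgeseg)

spec <- phantom_spec(lesion_extent_deg = 70, transmural_mean = 0.7,
                     noise = "rician", target_cnr = 5, seed = 7)
ph  <- generate_phantom(spec)
ph
#> <lge_phantom> 1 slice(s), infarct 200 mm^2 (lesion 200 + MVO 0),
#>               noise sd 60, realized CNR 5.47

img <- ph$stack$slices[[1]]
myo <- class_mask(ph$truth[[1]], "myocardium")

seg <- threshold_nsd(img, myo, auto_remote_roi(spec), c = 5)
seg
#> <lge_threshold> 5-SD: T = 412.8, 102 lesion pixel(s)
infarct_size(as_label_map(seg, myo))$n_infarct
#> [1] 102        # 5-SD misses half of a 200-px subendocardial lesion at CNR 5

for (m in c("3sd", "5sd", "gmm", "hmrf")) {
  lm <- run_method(ph, m)
  cat(sprintf("%-5s infarct %3d px  RE %+.3f\n", m,
              infarct_size(lm)$n_infarct,
              relative_error(infarct_size(lm)$n_infarct, 200)))
}
#> 3sd   infarct 198 px  RE -0.010
#> 5sd   infarct 102 px  RE -0.490
#> gmm   infarct 202 px  RE +0.010
#> hmrf  infarct 200 px  RE +0.000

lm <- run_method(ph, "hmrf")
attr(transmurality(myo, class_mask(lm, "infarct"), spec$center),
     "mean_transmurality")
#> [1] 0.672      # the wedge was generated at transmural fraction 0.7
```

The numbers tell the expected story: at moderate CNR a high n-SD cutoff
under-calls a partial-thickness lesion, while the histogram-model and
random-field methods recover the true area to within a few pixels.

A full sweep is one call:

```r
bench <- run_cnr_benchmark(n_replicates = 20, master_seed = 1)
glance(bench)      # mean RE / ARE per method x CNR
autoplot(bench)    # error-vs-CNR curves
```

## Command-line use

```sh
inst/cli/lgeseg phantom --cnr 5 --seed 7 --out phantom_out
inst/cli/lgeseg segment-lesion --image phantom_out/phantom.nii.gz \
    --myo phantom_out/truth.nii.gz --method hmrf --out lesion.nii.gz
inst/cli/lgeseg benchmark --replicates 20 --seed 1 --out bench.csv
```

Every flag can also be given through `--config file.yaml`.

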