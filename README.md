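# mngmm — multigrid nonlocal Gaussian mixture segmentation of brain MRI

`mngmm` segments skull-stripped T1-weighted brain MR images into
cerebrospinal fluid (CSF), gray matter (GM) and white matter (WM). It is
aimed at anyone who needs a self-contained, dependency-light tissue
classifier that stays accurate when the image carries **noise** and
**intensity inhomogeneity** (a smooth multiplicative bias field), the
two artifacts that defeat plain intensity clustering — without
estimating or correcting the bias field first.

## The method

The observed image is modeled as `Y = X·B + N` (true signal × smooth
bias + noise). Intensities inside the brain mask follow a K = 3
Gaussian mixture

```
p(Y_i | θ) = Σ_k π_k N(Y_i; μ_k, σ²_k)
```

fitted by EM and classified by maximum posterior. Robustness is added in
two orthogonal ways:

* **Nonlocal posterior regularization** (noise): each voxel's class
  posteriors are replaced by a patch-similarity-weighted average,
  `NLp(k|Y_i) = Σ_j W(i,j) p(k|Y_j)` with
  `W(i,j) ∝ exp(−‖Δ_i − Δ_j‖²_{2,r}/h²)`, so voxels with similar
  neighborhoods — almost surely the same tissue — vote on each other's
  labels while edges are preserved.
* **Adaptive multigrid with fusion** (bias): the brain is tiled into
  6×6 cells, cells are merged into patches guided by the fuzzy-c-means
  *inner distance* `min(|C_CSF − C_GM|, |C_WM − C_GM|)` (small exactly
  where a tissue is missing), a nonlocal mixture is fitted per patch —
  where the bias is nearly constant — and every voxel's posteriors are
  fused with those induced by the adjacent patches' models using
  per-class likelihood weights, which removes seams at patch borders.

A ground-truthed synthetic phantom generator (elliptical brain, gyral WM
folds, ventricles, controllable noise % and INU % following the MNI
simulator conventions) and Jaccard-index evaluation make the whole
pipeline testable offline. The methods vignette
(`vignettes/mngmm-methods.Rmd`) documents the models, defaults and
design decisions in detail.

## Worked example

```r
library(mngmm)

ph  <- simulate_phantom(phantom_spec(shape = c(128, 128),
                                     noise_level = 9, inu_level = 80,
                                     seed = 1))
res <- segment_mngmm(ph$intensity)   # full multigrid nonlocal pipeline
res
#> <mngmm_segmentation> 128 x 128 | bg/CSF/GM/WM: 6136/3208/3915/3125 | patches: 9
evaluate_segmentation(res, ph$truth)
#> <mngmm_eval> JS  CSF: 0.9314  GM: 0.9091  WM: 0.9531  mean: 0.9312
evaluate_segmentation(segment_gmm(ph$intensity), ph$truth)  # baseline
#> <mngmm_eval> JS  CSF: 0.8543  GM: 0.7836  WM: 0.8651  mean: 0.8343
```

The phantom here is heavily degraded (9% noise, 80% INU: the bias spans
0.6–1.4). The per-class numbers are Jaccard overlaps with the ground
truth (1 = perfect): the multigrid nonlocal model keeps all three
tissues above 0.9 while the plain mixture loses about 0.1 of Jaccard
everywhere, mostly to bias-induced misclassification between GM and its
neighbors. `segment_ngmm()` provides the intermediate noise-robust,
bias-naive variant.

A thin command-line front end ships in `inst/cli/mngmm.R`:

```sh
Rscript inst/cli/mngmm.R simulate --shape 128x128 --noise 5 --inu 80 \
    --seed 7 --out phantom.nii.gz --out-truth truth.nii.gz
Rscript inst/cli/mngmm.R segment phantom.nii.gz --out-labels labels.nii.gz
Rscript inst/cli/mngmm.R evaluate --pred labels.nii.gz --truth truth.nii.gz
```

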