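# mmtdfcm

Noise-robust fuzzy c-means segmentation of 8-bit grayscale images, built for
medical-imaging use cases (MR tissue slices) where intensity clustering must
survive acquisition noise.

## The problem and the method

Classical fuzzy c-means (FCM) clusters the pixels of a gray image by
alternating two updates until the centers stop moving:

    u_ik = 1 / sum_j (d_ik / d_jk)^(2/(m-1)),      d_ik = |x_k - v_i|
    v_i  = sum_k u_ik^m x_k / sum_k u_ik^m

with fuzzifier `m > 1` and crisp membership for a pixel that coincides with a
center. Because `u_ik` depends only on the pixel's own gray level, FCM is
blind to spatial context and mislabels noisy pixels.

`mmtdfcm` implements a spatially regularized variant (MMTDFCM). A
*medium-truth-degree* similarity between gray levels `f` and `x`,

    hh(f, x) = [ h(f, x) + h(x, f) ] / 2,
    h(f, x)  = (f + 1)/(x + 1)      if f < x
             = 1                    if f = x
             = (256 - f)/(256 - x)  if f > x

(anchored at the points -1 and 256 just outside the gray range) is averaged
over each pixel's eight 3x3 neighbors to give a similarity map `hbar` in
(0, 1], computed once per image. Each iteration then replaces the fuzzy
membership by the *medium membership*

    u'_ik = hbar_k * ubar_ik + (1 - hbar_k) * u_ik

where `ubar_ik` is the mean membership over the pixel's eight neighbors:
pixels that resemble their neighborhood are smoothed toward it, pixels that
do not keep their own membership. Centers are updated with `u'`, and labels
come from the maximum-membership rule.

The package also provides the evaluation metrics used for such algorithms —
reconstruction PSNR, Bezdek's partition coefficient `vpc` and partition
entropy `vpe`, and a permutation-minimized misclassification rate — plus a
seeded synthetic-phantom module (piecewise-constant images with
salt-and-pepper or Gaussian noise) so everything is testable without external
data, PNG/TIFF I/O, and a command-line driver.

## Worked example

```r
library(mmtdfcm)

ph    <- make_phantom()                                  # 128x128, grays 0/160/255
noisy <- add_gaussian(ph$image, variance = 0.01, seed = 7)
res   <- run_mmtdfcm(noisy, clusters = 3)
res
#> MMTDFCM segmentation: 3 clusters, m = 2, eps = 1e-05
#>   image: 128 x 128 pixels
#>   iterations: 9 (converged)
#>   centers: 10.038, 159.105, 244.665
metrics_report(res, ph$image, truth = ph$labels)
#> psnr: 28.5422 dB
#> vpc:  0.8708
#> vpe:  0.2560
#> misclassification: 0.0031
```

The centers recover the three phantom gray levels (pulled slightly inward by
the clipped noise), and only 0.31% of pixels are mislabeled despite noise
with a standard deviation of ~25 gray levels. The paired driver runs both
algorithms from a shared initialization per condition:

```r
compare_experiment(ph$image, ph$labels, clusters = 3, seed = 1)
#>    condition algorithm  psnr    vpc     vpe misclassification n_iter converged
#>        clean       fcm   Inf 1.0000 0.00000          0.000000      1      TRUE
#>        clean   mmtdfcm   Inf 0.9877 0.01827          0.000000      2      TRUE
#>  salt_pepper       fcm 16.70 1.0000 0.00000          0.032776      1      TRUE
#>  salt_pepper   mmtdfcm 16.73 0.9347 0.11058          0.032776      3      TRUE
#>     gaussian       fcm 23.91 0.9140 0.16931          0.025146     14      TRUE
#>     gaussian   mmtdfcm 28.15 0.8726 0.25295          0.003479      9      TRUE
```

Under Gaussian noise MMTDFCM cuts the error rate about sevenfold and gains
more than 4 dB of reconstruction PSNR. Under impulse (salt-and-pepper) noise
the two algorithms assign impulse pixels identically — the methods vignette
(`vignettes/mmtdfcm-methods.Rmd`) explains why that is a structural property
of the membership blend — while MMTDFCM still edges ahead on PSNR through
better center estimates.

The same pipeline is scriptable from a shell:

```sh
inst/cli/mmtdfcm phantom --noise gauss --seed 7 --out noisy.png
inst/cli/mmtdfcm segment --input noisy.png --clusters 3 --variant mmtdfcm --out-dir seg/
inst/cli/mmtdfcm compare --seed 1
```

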