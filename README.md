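# harmonyseg

Intensity-based segmentation of grayscale biomedical images (for example MR
brain slices) with fuzzy c-means whose cluster centers are optimized by an
improved harmony search, for image-analysis work where randomly initialized
fuzzy clustering is too unstable to trust.

Fuzzy c-means (FCM) minimizes the fuzzified within-cluster objective

    J_m(U, V) = Σ_i Σ_j u_ij^m d(x_j, v_i)²,   Σ_i u_ij = 1,

by alternating the closed-form membership update
`u_ij ∝ (1/d_ij²)^(1/(m−1))` and the center update
`v_i = Σ_j u_ij^m x_j / Σ_j u_ij^m`.  `J_m` is non-convex in V, and random
initialization regularly lands FCM in poor local minima.  This package
initializes V with a harmony search (HS) optimizer minimizing the
within-cluster sum of squared distances, improved in two ways:

* **Rough-set harmony memory** — instead of a uniform random population,
  the harmony memory is built from the data: candidate centers are iterated
  through a rough lower/upper-approximation assignment (points whose
  second-nearest center is within a margin of the nearest become boundary
  points), a weighted center update
  `v_i = w_low · mean(lower_i) + (1 − w_low) · mean(boundary_i)` with
  `0.5 < w_low < 1`, and a k-nearest-neighbour majority vote that resolves
  the boundary region.  With margin 0 this is exactly Lloyd's k-means.
* **Adaptive schedules** — the pitch adjusting rate ramps linearly
  `PAR(t) = PAR_min + (PAR_max − PAR_min) · t / T`, and the bandwidth
  responds to the feedback statistic
  `T_fb = Σ|x_best − x_worst| / Σ(x_best − x_worst)²`:
  `BW = BW_min + (BW_max − BW_min) · T_fb · t / T_max` while
  `T_fb < T_max/2`, else `BW_max`.

Resulting fuzzy partitions are scored by the partition coefficient
`V_pc = (1/n) Σ u²` and partition entropy `V_pe = −(1/n) Σ u log u`
(higher V_pc / lower V_pe = crisper segmentation), and compared against
randomly initialized FCM.  A seeded phantom generator (k tissue classes,
Gaussian noise, optional multiplicative bias field, ground-truth labels)
makes the whole pipeline testable without any image downloads.

## Worked example

```r
library(harmonyseg)

ph  <- generate_phantom(c(64, 64), class_means = c(0.2, 0.5, 0.8),
                        class_stds = 0.05, seed = 7)
res <- segment_image(ph$image, c_clusters = 3, algorithm = "improved", seed = 7)
res
#> <segmentation> improved | c = 3 | vpc = 0.9239, vpe = 0.1627 | 4 FCM iterations
sort(res$fcm_result$centers)
#> [1] 0.1995 0.4999 0.8005
segmentation_accuracy(res$label_map, ph$truth)
#> [1] 0.9985352

compare_segmentations(ph$image, 3, seed = 7)
#>     algorithm       vpc       vpe iterations     best   worst  average
#>      improved 0.9238891 0.1627126          4 12.45837 12.4626 12.46153
#>  baseline_fcm 0.9238887 0.1627129          7 63.22360 63.2236 63.22360
```

The recovered centers match the phantom's class means to ~1e-3; 99.85% of
pixels are labeled correctly (up to label permutation).  In the comparison
table, `best/worst/average` are the optimizer-fitness triple over the final
harmony memory (for the random-initialization baseline, the fitness of its
single random start): the improved memory starts and ends far closer to
the within-cluster-sum-of-squares optimum, while both routes reach fuzzy
partitions of similar crispness on this easy phantom.  `select_c()` picks
the number of classes by maximum V_pc, and `load_image()` /
`write_label_map()` handle PNG/TIFF/NIfTI input and 8-bit PNG label output.

A command-line wrapper with `segment`, `compare` and `synth` subcommands
lives at `inst/cli/harmonyseg.R`:

```sh
Rscript inst/cli/harmonyseg.R synth --shape 128x128 --means 0.2,0.5,0.8 \
    --stds 0.05 --seed 7 --out img.png --out-truth truth.png
Rscript inst/cli/harmonyseg.R segment img.png --clusters 3 \
    --out-labels labels.png --out-report report.json
```

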