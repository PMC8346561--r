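# rhizoseg

Fully automated segmentation of plant roots in noisy soil images, with
skeleton-based extraction of root-system-architecture traits.

Rhizotron and minirhizotron imaging produces grayscale images in which
roots appear as thin, low-contrast curvilinear structures on a bright,
heterogeneous soil background. Root and soil pixel intensities overlap, so
thresholding cannot separate them; `rhizoseg` segments them with a
patch-based U-Net encoder–decoder network and then phenotypes the
segmented root system. The package contains the whole workflow — no
external data or deep-learning runtime is required:

* **Tiling geometry** — zero-padding to tile multiples, 256×256 patch
  extraction, exact stitch-back (`pad_to_multiple()`, `extract_tiles()`,
  `stitch_tiles()`).
* **Dataset construction** — mask dilation, class-balance patch filtering,
  seeded 85:15 train/validation split (`build_dataset()`, `split_dataset()`).
* **The network** — a depth-3 U-Net with 7×7 kernels, batch normalization,
  16/32/64 channels and a 128-channel bridge at 32×32 (preset `"faria256"`),
  plus a resize-based full-image variant (`"faria1024"`). Forward and
  backward passes are implemented natively in Rcpp/RcppArmadillo.
* **Training** — Adam on mean binary cross-entropy with per-epoch
  Dice/precision/recall monitoring and best-epoch checkpointing (`fit()`).
* **Inference** — pad → tile → predict → stitch → crop → threshold, with
  the inclusive high-confidence threshold `T ≥ 0.9` (`segment()`).
* **Evaluation** — Dice coefficient `DC = 2|P∩G| / (|P|+|G|)`, precision,
  recall, and the harmonic-mean identity
  `DC = 2·precision·recall / (precision+recall)` (`dice()`,
  `precision_recall()`, `dice_from_pr()`).
* **Traits** — 75 named traits in 12 groups (area, objects, length,
  surface, volume, branch/end points, x/y profile distributions, width,
  orientation, convex hull, extent) from a Zhang–Suen skeleton with
  distance-transform widths (`extract_traits()`).
* **Synthetic data** — a seeded generator of soil-root image/mask pairs
  emulating band-limited soil texture, illumination gradients and
  branching, tapering root systems (`generate_synthetic()`,
  `benchmark_suite()`).

## Worked example

Train a reduced-width network on synthetic soil-root images and phenotype
a held-out image:

```r
library(rhizoseg)

suite <- benchmark_suite(seed = 20240)   # 40 train / 10 test, 512x512 px
ds    <- build_dataset(suite$train, tile_size = 256, se_radius = 0)
sp    <- split_dataset(ds, seed = 1)

net <- build_model(faria_preset("faria256", filter_scale = 0.1875), seed = 1)
res <- fit(net, sp$train, sp$val, benchmark_train_config(seed = 1))

seg <- segment(res$net, suite$test[[1]]$image, threshold = 0.9)
dice(seg$mask, suite$test[[1]]$mask)
traits <- extract_traits(seg$mask, boot_seed = 1)
print(traits)
```

The training run takes about 15 minutes on one CPU core (the network
kernels are native code driven by BLAS). Output of this run (seed 1):

```
> dice(seg$mask, suite$test[[1]]$mask)
[1] 0.9977974   # overlap between prediction and ground truth; 1 = perfect
> print(traits)
<trait_table: 75 traits in 12 groups>
        area    n_objects total_length surface_area       volume
    2267.000        3.000     2204.915     8094.929     2772.780
```

`area` counts root pixels; `total_length` sums skeleton steps in px;
`surface_area`/`volume` come from a per-step cylinder model over the local
root width. The full vector holds all 75 traits; see
`vignette("rhizoseg-methods")` for each definition.

A command-line wrapper is installed with the package
(`system.file("exec", "rhizoseg", package = "rhizoseg")`) with subcommands
`simulate`, `prepare`, `train`, `segment`, `traits`, `evaluate`.

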