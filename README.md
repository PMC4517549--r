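# mrinorm

Histogram-based intensity normalization for skull-stripped brain MR
volumes.

MR gray values have no absolute unit: the same head scanned on two
scanners — or with different repetition/echo times or flip angles — lands
on incompatible intensity scales, which degrades registration,
intensity-driven segmentation and tissue volumetry. `mrinorm` harmonizes
a set of scans in three steps:

1. **Quality ranking.** Magnitude-MRI background noise is Rayleigh
   distributed, and the Rayleigh mode equals its scale parameter, so the
   noise index of an image *M* is `σ̂ₙ = mode{M(x)}` — no segmentation
   needed. The scan with the smallest index becomes the reference.
2. **Intensity scaling (IS).** The reference is rescaled over its
   decile-trimmed intensity range: `f′ = (f − LIR) / (HIR − LIR)`, where
   LIR/HIR are the 10th/90th-percentile landmarks of its foreground.
3. **Histogram normalization (HN).** Each input scan is mapped onto the
   reference scale by two mean-anchored linear segments,

   ```
   N(g) = ⌈ μs + (g − μi) (LIR − μs)/(S₁ − μi) ⌉   for g ≤ μi
   N(g) = ⌈ μs + (g − μi) (HIR − μs)/(S₂ − μi) ⌉   for g ≥ μi
   ```

   with `(S₁, μi, S₂)` the input's low/mean/high landmarks, linear
   continuation over the tails out to the observed extrema, and an
   optional ceiling quantization. The map is monotone and
   rank-preserving by construction.

The package also ships the evaluation metrics (voxelwise MSE against a
reference, Dice overlap of segmentations), a k-means three-tissue
segmenter and tissue-volume counter to exercise them, and a seeded
two-scanner brain phantom simulator with ground-truth labels, so the
whole pipeline is testable without any MRI download. See the methods
vignette (`vignettes/mrinorm-methods.Rmd`) for the model, parameter
defaults and design decisions.

## Worked example

```r
library(mrinorm)

# one anatomy, two virtual scanners: B has a 4x noisier background and a
# monotone intensity transfer (1.6 * v^0.9 + 20)
pair <- simulate_pair(phantom_spec(seed = 7))

# quality ranking picks scanner A (smaller noise index = higher quality)
select_reference(list(pair$vol_a, pair$vol_b))$index
#> [1] 1

# normalize B onto A's intensity scale
res <- normalize_volume(pair$vol_b, pair$vol_a)
res
#> normalization_result
#>   W1 distance to reference: 18.2841 -> 1.29228
#>   clamped voxels: 0 below, 0 above
#> normalization_map (2 segment(s), ceiling on, reference_scale)
#>   input:     landmark_set: low 112.56, mean 142.632, high 179.616 (observed range [26.3077, 219.997])
#>   reference: landmark_set: low 92.5364, mean 124.459, high 165.476 (observed range [4.53014, 201.877])
#>   slopes: 1.06154 / 1.10904

c(before = mse(pair$vol_b, pair$vol_a), after = mse(res$volume, pair$vol_a))
#>   before    after
#> 545.2224 219.2062
```

The Wasserstein-1 distance between the foreground histograms drops
fourteen-fold (18.28 → 1.29 gray levels) and the voxelwise MSE against
the reference is more than halved (the residual ~219 is the floor set by
the two scans' independent tissue noise, 2σ² = 200). A k-means
segmentation of the normalized scan recovers the ground-truth tissues
with Dice 0.998 / 0.989 / 0.982 (CSF / GM / WM).

The same workflow runs on NIfTI files, either in R —

```r
run_pipeline(c("scan_a.nii.gz", "scan_b.nii.gz"), run_config(), out_dir = "out/")
#> reference: scan_a.nii.gz (sigma_hat = 9.467)
#> normalized scan_b.nii.gz: W1 13.16 -> 4.392
```

— or from a shell via the bundled front end
(`system.file("cli", "mrinorm.R", package = "mrinorm")`) with subcommands
`estimate-noise`, `normalize`, `evaluate`, `simulate` and `pipeline`, all
emitting JSON reports.

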