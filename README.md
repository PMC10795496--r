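# leafcomplete

Single-view 3D reconstruction of plants whose leaves are partially hidden
by occlusion. Depth cameras deliver 2.5D data: only surfaces visible from
the sensor are captured, so overlapping leaves leave holes in the point
cloud, and phenotypic parameters measured from such clouds — leaf area
first of all — are systematically biased. `leafcomplete` implements the
full workflow that repairs this at the level of individual leaves:

1. **Preprocess** a raw RGB-D capture: pass-through filtering,
   excess-green color thresholding, statistical outlier removal, and
   region-growing segmentation into single-leaf clouds.
2. **Normalize** each incomplete leaf into a canonical frame (centroid
   *G*, scale *K* to the unit sphere, plane-fit attitude correction *R*).
3. **Complete** the missing region with a point-fractal completion
   network: a multi-resolution encoder (IFPS downsampling to 2,048 /
   1,024 / 512 points, combined multi-layer perception features) and a
   point-pyramid decoder that predicts the missing region coarse-to-fine
   (64 → 128 → 512 points). Observed points are never modified; the
   prediction is fused with the input.
4. **Recover** the completed leaf to world coordinates with the recorded
   (*G*, *K*, *R*).
5. **Measure** leaf area via Delaunay 2.5D triangulation, Laplacian
   smoothing with a fixed boundary, and summed triangle areas (cm²).

The training corpus is built by simulated occlusion: each complete leaf is
normalized to the unit sphere, observed from 21 lattice viewpoints, and the
points farthest from each viewpoint are eliminated at missing ratios of
20 / 35 / 50%. Every sample is a fixed-size pair — a 2,048-point incomplete
cloud and its 512-point missing ground truth, both IFPS subsamples. The
network trains on the multi-stage chamfer loss

    L = d_cd(Y1, Ygt) + alpha d_cd(Y2, Ygt2) + beta d_cd(Y3, Ygt3)

where `d_cd` is the (mean-reduced) symmetric squared-nearest-neighbour
chamfer distance, `Ygt2`/`Ygt3` are IFPS subsamples of the missing ground
truth, and (alpha, beta) follow a coarse-to-fine schedule: (0.01, 0.02)
for the first 30% of epochs, (0.05, 0.1) to 80%, (0.1, 0.2) after.
Training is two-stage: a first stage on photogrammetry-style (SFM-like)
corpora, then transfer learning on RGB-D-style corpora with unchanged
hyperparameters.

A parametric synthetic-leaf generator with analytically integrated
reference areas (`leaf_spec()`, `sample_leaf()`, `make_plant()`,
`simulate_rgbd_view()`) stands in for real cabbage captures, so the whole
pipeline is testable end to end without any downloads.

## Worked example

```r
library(leafcomplete)

# a small corpus of synthetic leaves, pose-canonicalised
specs  <- random_leaf_specs(10, seed = 11, points = 4100, noise_sd = 0.5)
leaves <- lapply(specs, function(s) normalize_pose(sample_leaf(s)$cloud)$cloud)
ds <- build_dataset(leaves, ratios = 0.35, n_viewpoints = 21, seed = 5)
ds <- split_dataset(ds, seed = 5)
print(ds)
#> completion_dataset: 210 samples (0 rejected) from 10 leaves x 21 viewpoints x 1 ratios [sfm_like]
#>   split: 147 train / 63 validation (by leaf)

fit <- pfnet(ds, net = pfnet_config("tiny"),
             control = train_control(batch_size = 8, learning_rate = 1e-3,
                                     epochs = 10, seed = 1))
print(fit)
#> Point-fractal completion network
#> Call: pfnet(data = ds, net = pfnet_config("tiny"), control = train_control(...))
#> pfnet_config (tiny): scales 2048/1024/512 | CMLP 16-32-64 (pool last 3 -> 112) | latent 128 | outputs 512/128/64
#> Parameters: 356,768 | init: cold_start
#> Trained 10 epochs | final train loss 0.01412 | final validation CD 0.00916
```

The validation chamfer distance falls from 0.077 (after the first epoch)
to 0.0092 — about 18x below the untrained network (0.165; all values in
squared unit-sphere coordinates). Completing an occluded leaf and
measuring its area:

```r
fx   <- sample_leaf(leaf_spec(seed = 42))          # ground truth: fx$reference_area
norm <- normalize_unit_sphere(fx$cloud)
occ  <- occlude(norm$cloud, generate_viewpoints(21)[3, ], ratio = 0.2)
kept <- point_cloud(sweep(occ$kept$points * norm$K, 2, norm$G, "+"))

np    <- normalize_pose(kept)                       # records G, K, R
inc   <- np$cloud$points[ifps_sample(np$cloud, 2048), ]
fused <- predict(fit, inc, type = "fused")          # 2,560 points
world <- recover_pose(fused, np$record)
leaf_area_pipeline(world)$area_cm2
```

On the synthetic benchmark (nine held-out leaves occluded at 20%,
completed by a model trained on a mirror-augmented deployment-frame
corpus; see the methods vignette and `scripts/acceptance.R`), the median
relative leaf-area error after completion is smaller than the
occluded-only error on every fixture — the direction of improvement the
method exists for.

A thin command-line wrapper over the same functions lives at
`inst/cli/leafcomplete.R` (subcommands `simulate`, `preprocess`,
`build-dataset`, `complete`, `reconstruct`, `area`, `eval`, `pipeline`).

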