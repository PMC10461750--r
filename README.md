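# mbvelo — localization-free super-resolution microbubble velocimetry

`mbvelo` is an R toolkit for estimating super-resolved blood-flow velocity
maps from contrast-enhanced ultrasound without localizing or tracking
individual microbubbles. Conventional ultrasound localization microscopy
(ULM) requires sparse, separable bubble signals and therefore long
acquisitions; `mbvelo` instead trains a convolutional LSTM-UNet to regress a
dense two-channel velocity map — magnitude in pixels/ms and flow direction
scaled to [0, 1] — directly from a 16-frame sequence of diffraction-limited
magnitude images. Training data comes entirely from a physics-based
simulator included in the package.

The pipeline, end to end:

1. **Vessel graphs** (`segment_vessels`, `skeletonize_mask`,
   `build_undirected_graph`, `orient_graph`): a binary vascular template is
   thinned to a skeleton with local radii from the distance transform and
   converted to a directed forest (breadth-first search from the widest
   endpoint of each component). Centerline reference velocities are drawn
   per edge from a radius-velocity table, `v_ref ~ N(μ, σ²)` over the pairs
   within ±0.5 px of the edge's mean radius (`assign_reference_velocity`),
   or averaged from a co-registered velocity map
   (`assign_velocity_from_map`).
2. **Flow simulation** (`simulate_flow`): microbubbles `(e_orig, e_curr,
   d_ax, d_lat, amp)` advect at `v_ax = v_ref (1 − (|d_lat|/r)^p)`
   (`p = 1` default), branch at junctions with probability `π r_j² / Σ π
   r_i²`, and are re-injected at their origin edge when they exit a leaf —
   the population count is exactly conserved.
3. **Frame synthesis** (`render_sequence`, `add_noise`,
   `rasterize_ground_truth`, `make_training_set`): PSF patches are splatted
   at sub-pixel bubble positions (one patch per bubble for its lifetime,
   slight per-frame rotation/distortion), Rayleigh noise is added, and
   dense ground-truth velocity maps are rasterized from the graph.
4. **Network** (`net_config`, `train_velocity_net`,
   `predict_velocity_map`): a ConvLSTM-UNet implemented from scratch in
   R + RcppArmadillo (conv/pool/upsample kernels in C++, batch norm,
   ConvLSTM gates, backpropagation through time and Adam in R); gradients
   are verified against finite differences in the test suite.
5. **Inference & evaluation** (`infer_blocks`, `to_physical`,
   `accumulate_maps`, `split_events`, `roi_trace`, `velocity_rmse`, `fwhm`,
   `frc_resolution`, `channel_reference_velocity`): block-wise application
   with state reset every 16 frames, calibration to mm/s, accumulation and
   odd/even splitting for Fourier-ring-correlation resolution, and
   mass-conservation references `v_mean = Q/(π(d/2)²)`, `v_peak = 2 v_mean`
   for flow-channel phantoms.
6. **Baseline** (`localize`, `link_tracks`, `tracks_to_map`): a simplified
   conventional ULM chain (NCC localization, sub-pixel centroid, greedy
   nearest-neighbour linking) used as an independent oracle on sparse
   simulations.

## Worked example

```r
library(mbvelo)

# synthetic branching template -> directed, velocity-annotated graph
tab <- synthetic_radius_velocity_table(seed = 1)   # 0.2-4 px/frame
tpl <- synthetic_vessel_template(64, 64, n_trees = 2,
                                 radius_range = c(2, 5), seed = 7)
g   <- template_to_graph(tpl, tab, seed = 2)
print(g)
#> <vessel_graph> directed, 5 vertices, 3 edges, grid 64x64
#>   total volume 2070.3 px^3-equivalent; v_ref assigned

# simulate 50 bubbles for 8 frames and render through a Gaussian PSF
rec <- simulate_flow(g, sim_config(N = 50, T_steps = 8, seed = 11))
fs  <- render_sequence(rec, psf_bank(list(gaussian_psf(3, 4))), seed = 3)
fs  <- add_noise(fs, 0.1 * max(fs$frames), seed = 4)

# ground truth and physical units
gt <- rasterize_ground_truth(g)
range(gt$magnitude)
#> [1] 0.000000 2.722482        # px/ms; 2.72 px/frame = 13.3 mm/s at 4.9 um
to_physical(velocity_map(matrix(0.19, 1, 1), matrix(0.5, 1, 1)))$speed
#> [1] 0.931                    # 0.19 px/frame -> 0.931 mm/s

# train a reduced network on simulated clips and evaluate
ds  <- make_training_set(tpl, n_samples = 8, clip_len = 8, patch = 64,
                         table = tab, seed = 5)
net <- train_velocity_net(ds, net_config(depth = 2, base_width = 8),
                          train_config(epochs = 10, seed = 6))
pred <- predict_velocity_map(net, ds$samples[[ds$validation[1]]]$input)
truth <- velocity_map(ds$samples[[ds$validation[1]]]$target[1, , ],
                      ds$samples[[ds$validation[1]]]$target[2, , ])
velocity_rmse(pred, truth)$mm_per_s   # vessel-masked RMSE in mm/s
```

The numbers shown are what the code printed for the seeds above: the
example graph spans centerline speeds up to 2.72 px/frame (13.3 mm/s), and
the calibration identity 0.19 px/frame = 0.931 mm/s is the package's unit
conversion at the default 4.9 µm / 1 ms grid.

A configuration-driven run of the same pipeline:

```r
run_pipeline(list(stages = c("template", "graph", "simulate", "render",
                             "dataset", "train", "infer", "evaluate"),
                  seed = 1))
```

or from the shell via `inst/cli/mbvelo <subcommand> --config run.yaml`.

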