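# nucsplit3d

Instance segmentation of fluorescently labeled nuclei in 3D microscopy
volumes. Nuclei in cleared-tissue confocal stacks are densely packed,
axially blurred, and frequently touch; semantic (foreground/background)
segmentation followed by connected-component labeling merges touching
nuclei into single objects. `nucsplit3d` separates them by regressing, at
every foreground voxel, the 3D offset **v**(x, y, z) to the centroid of
the nucleus that owns the voxel. Across the interface between two touching
nuclei this vector field flips direction, so its axis-wise spatial
derivatives expose the interface even where intensity does not.

The pipeline:

1. **Vector field** — for a label volume `I_label`, every voxel of nucleus
   k carries `v = (x_k, y_k, z_k) − (x, y, z)`; background carries **0**
   (`generate_vector_field()`).
2. **Multi-task 3D U-Net** — a natively implemented encoder–decoder with
   residual blocks, attention-gated skips, a logistic mask head and a
   linear 3-channel vector head (`nn_unet3d()`, `train_unet3d()`), trained
   with the combined loss
   `L = λ_TL · L_Tversky + λ_FL · L_focal + λ_MSE · L_MSE`
   (defaults λ = 1, 10, 10; Tversky α_FN = 0.3, α_FP = 0.7; focal β = 0.8,
   γ = 2; Adam, constant learning rate).
3. **Instance splitting** — unnormalized 3D Sobel derivatives of the
   predicted field give a gradient map `G`; `relu(mask − (G ≥ T_m))`
   carves inter-nucleus boundary voxels out of the mask; conditional
   erosion (coarse, then fine structuring element, size thresholds `t_c`,
   `t_f`) shrinks the remaining blobs into markers; a 3D marker-controlled
   watershed on the negative distance transform assigns every foreground
   voxel to one nucleus; instances under 20 voxels are removed
   (`segment_instances()`).
4. **Tiled inference** — K-voxel windows at stride K/2, padded K/4 per
   border, stitching only each window's centered K/2 interior, so volumes
   of any size segment seamlessly (`predict_tiled()`, default K = 128).
5. **Synthesis** — ground-truth generators for testing and training:
   overlap-constrained random ellipsoids (`place_nuclei()`), elastic
   deformation from a coarse Gaussian displacement grid
   (`make_deformation_field()`, `apply_deformation()`), and a classical
   PSF-blur + noise renderer (`render_volume()`).
6. **Evaluation** — IoU-matched object-level metrics mP/mR/mF1/mAP over a
   threshold set (default {0.25, …, 0.45}) and the Aggregated Jaccard
   Index (`evaluate_instances()`).

## Worked example

Generate a synthetic volume, segment it from its own ground-truth mask and
vector field (oracle mode), and score the result:

```r
library(nucsplit3d)

cfg <- synth_config(shape = c(96, 96, 96), n_nuclei = 40,
                    a_min = 4, a_max = 8, t_ov = 10, d = 5, sigma = 2)
labels <- synth_labels(cfg, seed = 11)
vf     <- generate_vector_field(labels)
seg    <- segment_instances(labels > 0, vf, seg_params())
evaluate_instances(labels, seg)
#> Instance detection metrics over 5 IoU thresholds
#>  threshold tp fp fn precision recall  f1  ap
#>       0.25 40  0  0       100    100 100 100
#>       0.30 40  0  0       100    100 100 100
#>       0.35 40  0  0       100    100 100 100
#>       0.40 40  0  0       100    100 100 100
#>       0.45 40  0  0       100    100 100 100
#> mP = 100.00  mR = 100.00  mF1 = 100.00  mAP = 100.00
#> AJI = 0.9988
```

All 40 nuclei are recovered at every IoU threshold; the AJI of 0.999
means the recovered voxel extents almost perfectly tile the ground truth.
With plain connected-component labeling instead, touching nuclei would
fuse: on the package's "touching" fixture, `segment_instances()` recovers
strictly more instances than component labeling of the same mask.

Training works on the same synthetic data:

```r
data  <- lapply(1:8, function(i) {
  lab <- synth_labels(synth_config(c(32, 32, 32), 5, 3, 6, 10, 5, 2))
  list(intensity = render_volume(lab), labels = lab)
})
model <- nn_unet3d(levels = 3, base_width = 8, seed = 1)
train_unet3d(model, data, epochs = 30, lr = 0.015, seed = 1)
pred  <- predict(model, data[[1]]$intensity)  # $prob and $vec
```

A thin command-line front end is installed at `inst/cli/nucsplit3d`
(subcommands `synth`, `render`, `vecfield`, `segment`, `evaluate`,
`fixture`, `pipeline`).

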