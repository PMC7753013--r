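# dvn: cross-hair convolutional networks for 3-D vessel segmentation

`dvn` is an R toolkit for segmenting vascular structures — vessels,
centerlines and bifurcations — in 3-D angiographic volumes (TOF-MRA,
micro-CT angiography) with small fully convolutional networks. It is
aimed at methods researchers who want the building blocks of this
approach as tested, inspectable code rather than a framework: every
operator has an independent oracle in the test suite, and the whole
pipeline verifies end-to-end on generated data with no downloads.

The four building blocks:

1. **Cross-hair convolution.** A dense 3-D kernel $M$ of shape
   $(k_x,k_y,k_z)$ is approximated by three 2-D kernels
   $M^i, M^j, M^k$ on the orthogonal planes through each voxel, summed
   with plane weights $\beta$. Cost drops from $k_xk_yk_z$ to
   $k_yk_z+k_xk_z+k_xk_y$ multiplications per voxel
   ($125 \to 75$ for a $5^3$ kernel) while retaining 3-D context at
   every layer. `convolve_full()`, `convolve_crosshair()`,
   `count_ops_*()`, `verify_count_inequality()`.
2. **Extreme class-balancing loss.** $L = L_1 + L_2$ where $L_1$ is a
   per-class-mean balanced cross entropy (stable under batch-size
   changes, unlike the summed weighted form) and $L_2$ re-penalises
   thresholded false predictions with data-dependent weights
   $\gamma_1,\gamma_2 \in [0.5,1]$, keeping precision and recall in
   balance when positives are ~2% of voxels. `loss_deepvesselnet()`
   and friends.
3. **Constrained synthetic vasculature.** Trees that satisfy Murray's
   law $r_p^\gamma = r_l^\gamma + r_r^\gamma$ and the minimum-volume
   branching angles exactly, voxelised to vessel/centerline/bifurcation
   labels and rendered with configurable noise. `synth_config()`,
   `sample_tree()`, `generate_dataset()`, `validate_tree()`.
4. **A sub-sampling-free FCN.** Four cross-hair layers (1→5→10→20→50,
   kernels 3, 5, 5, 3) plus a 1×1×1 sigmoid classifier: 46,021
   parameters (0.05 M), same-size output for arbitrary input sizes,
   trained with plain SGD on 64³ boxes. `default_fcn_spec()`,
   `build_fcn()`, `train_model()`, `predict()`, `seg_metrics()`,
   `evaluate_bifurcations()`.

## Worked example

```r
library(dvn)

# cost of convolving a 128^3 volume with a 5^3 kernel
count_ops_full(c(5, 5, 5), c(128, 128, 128))
#> <op_count_report> 262,144,000 multiplications, 260,046,848 additions
count_ops_crosshair(c(5, 5, 5), c(128, 128, 128))
#> <op_count_report> 157,286,400 multiplications, 155,189,248 additions

# the default network is tiny
count_parameters(default_fcn_spec())$total   # 46021  (0.05 M)

# the combined loss on a worked micro-batch
loss_deepvesselnet(p = c(0.4, 0.6, 0.2, 0.2), y = c(1, 0, 0, 0))
#> <loss_terms> L = 2.103516
#>    L1 = 1.370483
#>    L2 = 0.7330326
#>    gamma1 = 0.6
#>    gamma2 = 0.6

# a constrained vascular tree and its labelled volume
cfg <- synth_config(volume_shape = c(32, 32, 32))
tree <- sample_tree(cfg, seed = 19)
tree
#> <vessel_tree> 22 nodes (9 bifurcations), 21 segments, volume 32 x 32 x 32
validate_tree(tree)$n_violations   # 0
ds <- generate_dataset(cfg, 1, seed = 19)
ds[[1]]
#> <labeled_volume> 32 x 32 x 32 voxels; class fractions: vessel 5.328%,
#>   centerline 0.330%, bifurcation 3.348%
```

Reading the numbers: the cross-hair operator saves 104.9 million
multiplications on that volume/kernel pair (a 40% reduction); the loss
decomposes into the stable balanced term (1.3705) and the
false-prediction correction (0.7330) whose weights sit at 0.6 because the
wrong predictions are mildly confident (0.1 from the 0.5 center); the
sampled tree passes all Murray/angle/topology checks; and the rendered
volume shows the class imbalance the loss exists for (at the default 64³
scale vessel fractions are ~2%). Training on such volumes:

```r
model <- build_fcn(default_fcn_spec(), seed = 1)
fit <- train_model(model,
                   inputs = lapply(ds, function(d) d$image$data),
                   targets = lapply(ds, function(d) d$vessel_mask),
                   train_config(iterations = 200, box_size = 32,
                                input_scale = 1/255))
prob <- predict(fit$model, ds[[1]]$image$data / 255)
seg_metrics(prob, ds[[1]]$vessel_mask)
```

## Command line

An installed launcher (`system.file("cli", "dvn", package = "dvn")`)
exposes the pipeline; all metric-emitting commands print JSON and every
run writes a manifest (version, config hash, seed) for bit-identical
regeneration:

```sh
dvn count-ops --kernel 5,5,5 --volume 128,128,128 --mode crosshair
dvn synth    --config cfg.json --n 10 --seed 42 --out data/
dvn train    --config train.json --data data/ --task vessel --out model.json
dvn predict  --model model.json --in vol.nii.gz --out prob.nii.gz
dvn evaluate --pred prob.nii.gz --gt mask.nii.gz --task seg
dvn validate-tree --tree data/vol_001_tree.json
```

Volumes are NIfTI-1 (`.nii`/`.nii.gz`), trees and configs are JSON.

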