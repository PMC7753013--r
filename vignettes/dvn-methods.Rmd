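---
title: "Methods: cross-hair networks for 3-D vessel segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-hair networks for 3-D vessel segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the science it implements:
the model and its assumptions, the parameters that matter, what the
synthetic generator does and does not emulate, the numerical choices, and
the design decisions taken where the design was genuinely open. It states
no empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## The problem

Segmenting vessels, their centerlines and their bifurcations in 3-D
angiographic volumes (TOF-MRA of the human brain, micro-CT angiography of
rodent brains) faces three coupled obstacles:

1. **Cost of 3-D convolution.** A dense kernel of shape
   $(k_x, k_y, k_z)$ costs $k_x k_y k_z$ multiplications per output
   voxel; volumes have $10^7$–$10^9$ voxels.
2. **Extreme class imbalance.** Vessels are a few percent of voxels,
   centerlines a few tenths of a percent, bifurcations rarer still.
   Standard cross entropy learns to predict background; naive
   class-balancing weights over-segment and are numerically unstable.
3. **Annotation scarcity.** Dense voxel-accurate 3-D vessel annotations
   are prohibitively expensive, which motivates training on simulated
   vasculature with exact labels.

The package implements one answer to each obstacle and an end-to-end
pipeline that is verifiable on generated data with no downloads.

## Cross-hair convolution

The dense operator (`convolve_full()`) is defined with greatest-integer
centering: output voxel $(i,j,k)$ sums $I_{R,S,T}\,M_{r,s,t}$ over kernel
positions with $R = i + r - 1 - \lfloor k_x/2\rfloor$ and likewise for
$S, T$; out-of-bounds contributions are zero, so output and input shapes
match. The cross-hair approximation replaces $M$ by three 2-D kernels
$M^i$ ($k_y\times k_z$), $M^j$ ($k_x\times k_z$), $M^k$ ($k_x\times k_y$)
applied on the orthogonal planes through each voxel and summed with plane
weights $\beta_c, \beta_s, \beta_a$ (default 1, exposed for anisotropic
grids). Per voxel this costs $k_yk_z + k_xk_z + k_xk_y$ multiplications
against $k_xk_yk_z$, with
$k_yk_z + k_xk_z + k_xk_y \le 3k_{m1}k_{m2} \le k_xk_yk_z$ for sorted
sides $k_{m1}\ge k_{m2}\ge k_{m3}$ — the second inequality requires
$k_{m3}\ge 3$ and is strict exactly when $k_{m3} > 3$ (the package's
`verify_count_inequality()` reports both parts; the test suite checks the
formula exhaustively up to side 9, including the sub-3 shapes where the
bound genuinely fails).

Three implementations coexist deliberately:

* `convolve_crosshair_pointwise()` — the literal per-voxel definition in
  plain R, kept as the independent oracle;
* `convolve_crosshair()` — the efficient form: each plane kernel is a
  3-D kernel flat along one axis, applied to the whole volume, holding
  one response volume at a time;
* `crosshair_embed()` — the dense kernel whose support is exactly the
  three planes, connecting the operator back to `convolve_full()`.

The three agree to floating-point accuracy on random volumes; the layer
implementation inherits this triple-checked core.

## The class-balancing loss with false-prediction correction

With positives $Y_+$ and negatives $Y_-$, the stable balanced term is the
per-class mean

$$L_1 = -\tfrac{1}{|Y_+|}\textstyle\sum_{Y_+}\log p_j
        -\tfrac{1}{|Y_-|}\textstyle\sum_{Y_-}\log(1-p_j),$$

invariant under batch duplication — unlike the summed class-weighted loss
(`loss_balanced()`), whose value grows linearly with batch size and which
the package retains purely to demonstrate that instability as a test.
Thresholding at 0.5 defines false positives $Y_{f+}$ and false negatives
$Y_{f-}$, and the correction term

$$L_2 = -\tfrac{\gamma_1}{|Y_+|}\textstyle\sum_{Y_{f+}}\log(1-p_j)
        -\tfrac{\gamma_2}{|Y_-|}\textstyle\sum_{Y_{f-}}\log p_j,\qquad
  \gamma = 0.5 + \text{mean}\,|p - 0.5|\in[0.5,1],$$

re-penalises confident mistakes. Note the deliberate asymmetry: the
false-positive sum is normalised by $|Y_+|$, not by $|Y_{f+}|$, which
preserves the class-balancing ratio and makes the correction strong
exactly when positives are rare.

Numerical and differentiation choices:

* probabilities are clipped to $[10^{-7}, 1-10^{-7}]$ before logarithms;
* a class absent from a batch contributes nothing — including to $L_2$'s
  normalisers, an extension beyond the obvious $L_1$ case that matters in
  practice because box sampling routinely yields all-background batches
  (an all-background batch with borderline predictions would otherwise
  divide by $|Y_+| = 0$);
* a prediction exactly at the threshold is not positive (strict $>$), so
  a positive example at $p = 0.5$ is a false negative;
* set membership and $\gamma_1,\gamma_2$ are recomputed each batch but
  held constant in the gradient (plain backpropagation; the gradient test
  in `test-loss.R` checks the analytic forms against finite differences
  of the frozen loss);
* the 0.5 center of the $\gamma$ weights is a parameter (`center`).

## Synthetic vascular trees

The generator is a *geometric surrogate* of an angiogenesis simulator:
it enforces every structural constraint the method relies on without
modelling the oxygen/growth-factor biophysics. A tree grows from a root
on a random face of the volume. Each segment has length
`length_ratio` × radius (default 4, jittered ±20%). At a branch point,
the asymmetry ratio $r_r/r_l$ is drawn from a Beta(5, 2) distribution
(mostly near-symmetric branchings, occasional strongly asymmetric ones,
as in arterial trees), daughter radii follow Murray's law
$r_p^\gamma = r_l^\gamma + r_r^\gamma$ exactly via the closed form
$r_l = r_p(1+a^\gamma)^{-1/\gamma}$ (default $\gamma = 3$), and daughter
directions leave the parent at the minimum-volume branching angles
$\cos\phi_l = (r_p^4 + r_l^4 - r_r^4)/(2r_p^2r_l^2)$ (and symmetrically),
rotated about a uniform azimuth; the two daughters are coplanar with the
parent on opposite sides. Growth stops at a terminal radius (default 0.6
voxels), at the volume boundary (the final segment is truncated there),
or at a node budget. `validate_tree()` re-checks Murray residuals, angle
residuals, bounds and tree topology independently of the generator.

Rendering: segments are capsules (cylinders with hemispherical caps); a
voxel is vessel iff its center lies within the radius of some segment
axis. Centerlines are 26-connected line rasterisations of segment axes;
in labelled volumes the centerline is intersected with the vessel mask
so the label hierarchy holds even for sub-voxel radii (a diagonal line
voxel can lie up to $\sqrt3/2$ from the axis after rounding). Bifurcation
labels are 5³ cubes centered on bifurcation nodes — the detection task
predicts a neighbourhood cube, not a single voxel. Intensities are drawn
once per volume (vessels uniform on [128, 255], background on [0, 100]),
then Gaussian noise is added with a per-volume mean offset in [−5, 5] and
standard deviation $\max(0, 20 + u)$, $u$ uniform on [−15, 30] — a
negative draw is an *offset* from the base deviation, clipped at zero,
since a negative standard deviation is undefined.

At the default 64³ shape with root radii 3–4 voxels these choices yield
vessel fractions of order 2% and centerline fractions of order 0.2%
(asserted as a stochastic test over 20 volumes), matching the imbalance
regime of the reference synthetic dataset. Cube-dilated bifurcation
labels occupy about 1% of voxels, more than the ~0.05% a single-voxel
labelling would give; whether the reference labels were dilated is not
documented, so the cube size is configurable and the fraction is reported
rather than tuned. What the generator does **not** emulate: venous loops
and anastomoses, vessel-wall and partial-volume effects, spatially
correlated scanner noise, and intensity variation along a vessel. A green
test on this data establishes that the pipeline learns and evaluates
correctly under realistic geometry and imbalance — not clinical-grade
accuracy.

## The fully convolutional network

The default network is deliberately tiny and has **no sub-sampling**:
four cross-hair layers (channels 1→5→10→20→50, cubic kernels of sides
3, 5, 5, 3) plus a 1×1×1 sigmoid classifier; all layers zero-pad to the
input shape, so a volume of arbitrary size maps to a same-size
probability map and full volumes can be predicted in one pass.
Sub-sampling is avoided because centerlines and bifurcations are
voxel-sized structures that pooling averages away. The closed-form
parameter count — $(k_yk_z + k_xk_z + k_xk_y)\,C_{in}C_{out} + C_{out}$
per cross-hair layer — gives 46,021 trainable values (0.05 M at two
decimals) for the default, 58,521 for the dense variant of the same
shape; the count is asserted to equal the value count of a built model.
The layer widths are a design choice: only the 0.05 M total is published
for this architecture, and (5, 10, 20, 50) with kernels (3, 5, 5, 3)
reproduces it exactly.

Weights initialise uniformly on $(-1/\sqrt{k_xk_yk_z},
+1/\sqrt{k_xk_yk_z})$ — the published description of the interval is
typographically garbled, and this fan-in-style reading is the standard
one. Biases start at zero (initial output probability exactly 0.5). The
hidden activation is unnamed in the source description; the package
defaults to a rectifier with tanh and sigmoid as options, and the
training experiments in the test suite use tanh (see below).

## Training, evaluation, and the scaled-down experiments

Training is plain SGD (no momentum, no regularisation), one zero-padded
box per step, learning rate 0.01 (pre-training) or 0.001 (fine-tuning)
decayed by 0.99 after every 200 iterations. Boxes are 64³ at full scale;
the box grid tiles the volume, remainders zero-padded, and all-background
boxes are kept (the empty-class rules handle them). The
precision/recall ratio of the thresholded prediction is recorded every 5
iterations; because per-box ratios are degenerate at extreme imbalance
(most boxes contain no foreground), `train_model()` can monitor a fixed
training volume instead, which is also closer to the original protocol
of tracking the ratio on the training volumes.

Two empirical properties are asserted at desk scale (single CPU, minutes
not GPU-days), with all generator and training parameters frozen before
the final verification runs:

* **Learnability** — a 1→4→8 cross-hair net trained 300 iterations on
  eight low-noise 16³ tube volumes exceeds 80% Dice on four held-out
  volumes (at design time: 86.9–93.6% across five build seeds).
* **Precision/recall balance** — on a ~2%-positive task (three 24³
  volumes, thin branches, moderate noise), the mean of
  $|\text{precision}/\text{recall} - 1|$ over an 800-iteration trace,
  averaged over three matched seeds, is smaller with $L_1+L_2$ than with
  $L_1$ alone. Two scaled-down findings are worth recording. First, with
  16³ *sub-boxes* the combined loss enters a false-positive-suppression
  limit cycle — every recovery of recall produces a burst of false
  positives whose penalty (normalised by the small per-box $|Y_+|$)
  slams the network back to all-background; training on whole volumes
  restores the stable regime. Second, tiny rectifier networks die under
  the extreme reweighting (units saturate at zero and never recover), so
  the toy experiments use tanh. Both phenomena are properties of the
  loss at small scale, not of the full-scale method, and are the reason
  the experiment configuration is what it is.

Segmentation metrics are voxel-wise precision, recall and Dice (as
percentages, with 0/0 conventions: empty prediction against empty truth
is perfect; empty prediction against non-empty truth has precision 0).
Bifurcation detection uses hit-or-miss scoring: a ground-truth point is
hit if the 5³ cube centered on it overlaps any predicted voxel;
predicted positives are grouped into 26-connected components and a
component with no ground-truth point within its cube counts as **one**
false positive (voxel-wise counting would multiply-count a single wrong
blob). The localisation error of a hit is the Euclidean distance to the
nearest predicted voxel — the published tables do not define their error
column, so this interpretation is stated explicitly. The reported
"recall" equals the detection rate, the published distinction between
those two columns being likewise undefined.

## Input/output and reproducibility

Volumes are NIfTI-1 (`.nii`/`.nii.gz`); the package carries a minimal
codec (no NIfTI reader exists in the supported R dependency set) that is
cross-validated against an independent Python reader in the test suite.
Masks are stored as uint8, images as float32; array axes map to NIfTI
voxel axes directly with spacing in `pixdim`, and no reorientation is
performed. Trees serialise to a JSON node/edge document; configurations
are JSON (the dependency set has no YAML parser); every CLI run writes a
manifest with the tool version, a configuration hash and the seed, and
regeneration from the same manifest inputs is bit-identical. Coordinates
are 1-based continuous voxel indices, matching R array indexing; voxel
centers sit at integer coordinates.

## Known limitations

* The angiogenesis surrogate reproduces printed structural constraints
  only; radii distributions and tortuosity are not calibrated to any
  real vascular bed (`scale` exists precisely because the published
  voxel-scaling is unquantified).
* Clinical-scale accuracy claims (Dice in the high 80s on TOF-MRA) are
  out of reach at desk scale and are not asserted anywhere.
* The trainer is single-threaded plain SGD; it is meant for method
  verification and small studies, not production training.
* The NIfTI codec reads the common scalar dtypes with a diagonal
  affine; exotic orientations, extensions and slope/intercept scaling
  beyond the basics are out of scope.
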