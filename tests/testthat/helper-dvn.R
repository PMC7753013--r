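# shared fixtures and independent oracles for the test suite

# literal six-nested-loop evaluation of the dense convolution definition:
# out[i,j,k] = sum_{r,s,t} I[i + r - 1 - floor(kx/2), ...] * M[r,s,t]
# with zero contribution outside the volume. Kept deliberately naive and
# independent of the package implementation.
brute_conv3 <- function(I, M) {
  d <- dim(I); kd <- dim(M)
  off <- kd %/% 2
  out <- array(0, d)
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    acc <- 0
    for (t in seq_len(kd[3])) for (s in seq_len(kd[2])) for (r in seq_len(kd[1])) {
      R <- i + r - 1L - off[1]; S <- j + s - 1L - off[2]; T <- k + t - 1L - off[3]
      if (R >= 1 && R <= d[1] && S >= 1 && S <= d[2] && T >= 1 && T <= d[3])
        acc <- acc + I[R, S, T] * M[r, s, t]
    }
    out[i, j, k] <- acc
  }
  out
}

random_crosshair_kernel <- function(k, beta = c(1, 1, 1)) {
  crosshair_kernel(matrix(stats::rnorm(k * k), k),
                   matrix(stats::rnorm(k * k), k),
                   matrix(stats::rnorm(k * k), k), beta = beta)
}

# a small two-hidden-layer cross-hair spec used by the training tests
tiny_spec <- function(widths = c(3L, 6L), kernels = c(3L, 5L),
                      activation = "tanh", in_channels = 1L) {
  network_spec(lapply(seq_along(kernels), function(i)
    layer_spec(c(in_channels, widths)[i], widths[i], kernels[i],
               mode = "crosshair", activation = activation)))
}

# easy bright-tube volumes for the training smoke test: low noise, thick
# single tubes in a 16^3 volume
tube_config <- function() {
  synth_config(volume_shape = c(16, 16, 16), root_radius = c(1.5, 2),
               min_radius = 1.2, length_ratio = 8, base_sd = 5,
               noise_sd_offset = c(-2, 2), noise_mean = c(-2, 2))
}

# harder ~2%-positive task for the loss-ablation experiment: one 24^3
# volume per box, thin branches, moderate noise
ablation_config <- function() {
  synth_config(volume_shape = c(24, 24, 24), root_radius = c(1.8, 2.2),
               min_radius = 0.6, base_sd = 12, noise_sd_offset = c(-4, 4))
}

aggregate_dice <- function(model, dataset, threshold = 0.5) {
  tp <- fp <- fn <- 0
  for (d in dataset) {
    pr <- predict(model, d$image$data / 255)$data > threshold
    g <- d$vessel_mask
    tp <- tp + sum(pr & g); fp <- fp + sum(pr & !g); fn <- fn + sum(!pr & g)
  }
  100 * 2 * tp / (2 * tp + fp + fn)
}
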