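#' Training configuration
#'
#' Plain stochastic gradient descent (no momentum, no regularisation)
#' with a stepped exponential decay: the learning rate at step `s`
#' (0-based) is `learning_rate * decay^floor(s / decay_every)`. Training
#' consumes one box per step, sampled without replacement within an
#' epoch from the non-overlapping box tiling of the training volumes.
#'
#' @param learning_rate initial learning rate; 0.01 is the pre-training
#'   value, 0.001 the fine-tuning value.
#' @param decay multiplicative decay in `(0, 1]`.
#' @param decay_every apply the decay after this many iterations.
#' @param iterations number of SGD steps.
#' @param box_size side of the cubic training boxes (64 for full-scale
#'   volumes; use smaller boxes for small volumes).
#' @param loss loss name, see [loss_by_name()].
#' @param metric_interval record the precision/recall ratio every this
#'   many iterations.
#' @param threshold probability threshold for the false sets and the
#'   recorded metrics.
#' @param center reference probability of the correction weights, see
#'   [loss_l2()].
#' @param input_scale multiplier applied to input intensities before the
#'   network (use `1/255` for 8-bit-range images).
#' @param seed seed for box shuffling.
#' @return A validated `train_config` list.
#' @export
train_config <- function(learning_rate = 0.01, decay = 0.99,
                         decay_every = 200L, iterations = 1000L,
                         box_size = 64L, loss = "deepvesselnet",
                         metric_interval = 5L, threshold = 0.5,
                         center = 0.5, input_scale = 1, seed = 1L) {
  if (learning_rate <= 0) stop("`learning_rate` must be > 0", call. = FALSE)
  if (decay <= 0 || decay > 1) stop("`decay` must be in (0, 1]",
                                    call. = FALSE)
  if (decay_every < 1) stop("`decay_every` must be >= 1", call. = FALSE)
  if (iterations < 0) stop("`iterations` must be >= 0", call. = FALSE)
  if (box_size < 1) stop("`box_size` must be >= 1", call. = FALSE)
  if (threshold <= 0 || threshold >= 1)
    stop("`threshold` must be in (0,1)", call. = FALSE)
  loss <- match.arg(loss, c("deepvesselnet", "l1_only", "cross_entropy",
                            "balanced"))
  structure(list(learning_rate = as.numeric(learning_rate),
                 decay = as.numeric(decay),
                 decay_every = as.integer(decay_every),
                 iterations = as.integer(iterations),
                 box_size = as.integer(box_size), loss = loss,
                 metric_interval = as.integer(metric_interval),
                 threshold = as.numeric(threshold),
                 center = as.numeric(center),
                 input_scale = as.numeric(input_scale),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Learning-rate schedule
#'
#' @param step 0-based iteration index.
#' @param config a [train_config()].
#' @return The learning rate
#'   `learning_rate * decay^floor(step / decay_every)`.
#' @examples
#' cfg <- train_config()
#' lr_schedule(0, cfg)     # 0.01
#' lr_schedule(200, cfg)   # 0.0099
#' @export
lr_schedule <- function(step, config) {
  stopifnot(step >= 0)
  config$learning_rate * config$decay^(step %/% config$decay_every)
}

#' Tile a volume into non-overlapping boxes
#'
#' Regular grid of cubic boxes covering the whole volume; boundary
#' remainders are zero-padded up to the full box size. Image and label
#' boxes stay aligned. Cropping each box back to its unpadded region and
#' reassembling reproduces the volume exactly.
#'
#' @param volume 3-D array (or `volume3d`), or 4-D array with trailing
#'   channel dimension.
#' @param labels optional binary 3-D array aligned with `volume`.
#' @param size box side, default 64.
#' @return A list of boxes, each a list with `image` (padded to
#'   `size^3`), `label` (or `NULL`), `origin` (1-based corner) and
#'   `extent` (unpadded size).
#' @export
extract_boxes <- function(volume, labels = NULL, size = 64L) {
  x <- vol_data(volume)
  d <- dim(x)
  ch <- if (length(d) == 4L) d[4] else 1L
  if (length(d) == 3L) dim(x) <- c(d, 1L)
  sp <- dim(x)[1:3]
  if (size < 1) stop("`size` must be >= 1", call. = FALSE)
  if (!is.null(labels)) {
    labels <- vol_data(labels)
    stopifnot(all(dim(labels) == sp))
  }
  starts <- lapply(sp, function(n) seq.int(1L, n, by = size))
  boxes <- list()
  for (k0 in starts[[3]]) for (j0 in starts[[2]]) for (i0 in starts[[1]]) {
    ext <- pmin(c(i0, j0, k0) + size - 1L, sp) - c(i0, j0, k0) + 1L
    img <- array(0, c(size, size, size, ch))
    img[seq_len(ext[1]), seq_len(ext[2]), seq_len(ext[3]), ] <-
      x[i0 + seq_len(ext[1]) - 1L, j0 + seq_len(ext[2]) - 1L,
        k0 + seq_len(ext[3]) - 1L, , drop = FALSE]
    if (ch == 1L) dim(img) <- c(size, size, size)
    lab <- NULL
    if (!is.null(labels)) {
      lab <- array(0, c(size, size, size))
      lab[seq_len(ext[1]), seq_len(ext[2]), seq_len(ext[3])] <-
        labels[i0 + seq_len(ext[1]) - 1L, j0 + seq_len(ext[2]) - 1L,
               k0 + seq_len(ext[3]) - 1L]
    }
    boxes[[length(boxes) + 1L]] <- list(image = img, label = lab,
                                        origin = c(i0, j0, k0),
                                        extent = ext)
  }
  boxes
}

#' Train a model with plain SGD on box samples
#'
#' One zero-padded box per SGD step, shuffled per epoch with the config
#' seed; loss gradients are taken with the thresholded false sets and
#' the correction weights held constant (plain backpropagation). The
#' precision/recall ratio of the thresholded prediction on the current
#' box is recorded every `metric_interval` iterations (NA when the box
#' has no positive voxel or no positive prediction). Training aborts
#' with a diagnostic if the loss becomes non-finite.
#'
#' @param model a [build_fcn()] model.
#' @param inputs list of input volumes (3-D arrays/`volume3d`, or 4-D
#'   arrays for multi-channel inputs, e.g. probability maps feeding the
#'   centerline and bifurcation networks).
#' @param targets list of binary label volumes aligned with `inputs`.
#' @param config a [train_config()].
#' @param monitor optional index into `inputs`: when given, the recorded
#'   precision/recall ratio is computed on a full prediction of that
#'   volume instead of the current box, giving a stable trace on
#'   imbalanced data (most boxes contain no foreground).
#' @return A list with `model` (trained), and `trace`, a data frame with
#'   one row per recorded interval: `iteration`, `loss`, `lr`,
#'   `precision`, `recall`, `pr_ratio`.
#' @export
train_model <- function(model, inputs, targets, config, monitor = NULL) {
  stopifnot(inherits(model, "dvn_model"), inherits(config, "train_config"),
            length(inputs) >= 1L, length(inputs) == length(targets))
  boxes <- list()
  for (v in seq_along(inputs)) {
    img <- vol_data(inputs[[v]]) * config$input_scale
    boxes <- c(boxes, extract_boxes(img, vol_data(targets[[v]]),
                                    config$box_size))
  }
  nb <- length(boxes)
  L <- length(model$layers)
  trace <- list()
  if (config$iterations == 0L)
    return(list(model = model,
                trace = data.frame(iteration = integer(), loss = numeric(),
                                   lr = numeric(), precision = numeric(),
                                   recall = numeric(), pr_ratio = numeric())))
  local_seed(config$seed, {
    ord <- sample.int(nb)
    pos <- 0L
    for (step in seq_len(config$iterations) - 1L) {
      pos <- pos + 1L
      if (pos > nb) { ord <- sample.int(nb); pos <- 1L }
      bx <- boxes[[ord[pos]]]
      fwd <- model_forward(model, bx$image, keep = TRUE)
      p <- as.numeric(fwd$out)
      y <- as.numeric(bx$label)
      lt <- loss_by_name(config$loss)(p, y)
      if (!is.finite(lt$L))
        stop("non-finite loss (", format(lt$L), ") at iteration ", step + 1,
             "; lower the learning rate or check the inputs", call. = FALSE)
      lr <- lr_schedule(step, config)
      gz <- loss_grad_logit(config$loss, p, y, config$threshold,
                            config$center)
      g <- array(gz, dim(fwd$out))
      for (i in L:1) {
        if (i < L)
          g <- g * activation_grad(fwd$z[[i]],
                                   apply_activation(
                                     fwd$z[[i]],
                                     model$spec$layers[[i]]$activation),
                                   model$spec$layers[[i]]$activation)
        bw <- layer_linear_bwd(fwd$inputs[[i]], model$layers[[i]], g)
        for (nm in names(bw$grads))
          model$layers[[i]][[nm]] <- model$layers[[i]][[nm]] -
            lr * bw$grads[[nm]]
        g <- bw$gx
      }
      if ((step + 1L) %% config$metric_interval == 0L) {
        if (is.null(monitor)) {
          m <- seg_metrics(p, y, config$threshold)
          empty <- sum(y) == 0
        } else {
          mon <- model_forward(model,
                               vol_data(inputs[[monitor]]) *
                                 config$input_scale)$out
          m <- seg_metrics(as.numeric(mon),
                           as.numeric(vol_data(targets[[monitor]])),
                           config$threshold)
          empty <- sum(vol_data(targets[[monitor]])) == 0
        }
        ratio <- if (m$recall > 0) m$precision / m$recall else NA_real_
        if (empty) ratio <- NA_real_
        trace[[length(trace) + 1L]] <-
          data.frame(iteration = step + 1L, loss = lt$L, lr = lr,
                     precision = m$precision, recall = m$recall,
                     pr_ratio = ratio)
      }
    }
  })
  list(model = model,
       trace = if (length(trace)) do.call(rbind, trace)
       else data.frame(iteration = integer(), loss = numeric(),
                       lr = numeric(), precision = numeric(),
                       recall = numeric(), pr_ratio = numeric()))
}

#' Voxel-wise segmentation metrics
#'
#' Precision `TP/(TP+FP)`, recall `TP/(TP+FN)` and Dice
#' `2TP/(2TP+FP+FN)`, reported as percentages. Empty denominators use
#' the conventions: an empty prediction against an empty ground truth is
#' perfect (100); an empty prediction against a non-empty ground truth
#' scores precision 0; ratios `0/0` never occur.
#'
#' @param prob probability map (array or `volume3d`), or an already
#'   thresholded binary mask.
#' @param gt binary ground-truth mask of the same shape.
#' @param threshold probability threshold, default 0.5 (strict `>`).
#' @return A list with `precision`, `recall`, `dice` (percent) and the
#'   raw `tp`, `fp`, `fn` counts.
#' @export
seg_metrics <- function(prob, gt, threshold = 0.5) {
  p <- vol_data(prob) > threshold
  g <- vol_data(gt) > 0
  if (!identical(dim(p), dim(g)) && length(p) != length(g))
    stop("shape mismatch between prediction and ground truth", call. = FALSE)
  tp <- sum(p & g); fp <- sum(p & !g); fn <- sum(!p & g)
  precision <- if (tp + fp == 0) (if (sum(g) == 0) 100 else 0) else
    100 * tp / (tp + fp)
  recall <- if (tp + fn == 0) 100 else 100 * tp / (tp + fn)
  dice <- if (2 * tp + fp + fn == 0) 100 else
    100 * 2 * tp / (2 * tp + fp + fn)
  list(precision = precision, recall = recall, dice = dice,
       tp = tp, fp = fp, fn = fn)
}

#' Hit-or-miss bifurcation detection scoring
#'
#' A ground-truth bifurcation point is a hit (TP) if the cube of side
#' `cube` centered on its nearest voxel overlaps any predicted positive
#' voxel, and a miss (FN) otherwise. Predicted positives are grouped
#' into 26-connected components; a component is a false positive if none
#' of its voxels has a ground-truth point within its own cube (so one
#' spurious blob counts once, not once per voxel). The localisation
#' error of a hit is the Euclidean distance from the ground-truth point
#' to the nearest predicted positive voxel.
#'
#' @param pred_mask binary 3-D prediction (array, `volume3d`, or a
#'   probability map thresholded at 0.5).
#' @param gt_points numeric matrix with one `(x, y, z)` row per
#'   ground-truth bifurcation, 1-based voxel coordinates.
#' @param cube odd cube side, default 5.
#' @return A list with counts `tp`, `fp`, `fn`, percentages `precision`,
#'   `recall`, `detection_rate` (recall and detection rate coincide
#'   under this protocol), and `mean_err` / `err_std` in voxels over the
#'   hits (NA if there is none).
#' @export
evaluate_bifurcations <- function(pred_mask, gt_points, cube = 5) {
  if (cube < 1 || cube %% 2 == 0)
    stop("`cube` must be odd and >= 1", call. = FALSE)
  mask <- vol_data(pred_mask) > 0.5
  d <- dim(mask)
  gt_points <- matrix(as.numeric(gt_points), ncol = 3)
  h <- (cube - 1) / 2
  pred_idx <- which(mask, arr.ind = TRUE)
  tp <- 0L; fn <- 0L
  errs <- numeric(0)
  for (g in seq_len(nrow(gt_points))) {
    c0 <- round(gt_points[g, ])
    rng <- lapply(1:3, function(a)
      max(1, c0[a] - h):min(d[a], c0[a] + h))
    if (any(mask[rng[[1]], rng[[2]], rng[[3]]])) {
      tp <- tp + 1L
      dx <- sweep(pred_idx, 2, gt_points[g, ])
      errs <- c(errs, sqrt(min(rowSums(dx^2))))
    } else fn <- fn + 1L
  }
  # component-wise false positives
  fp <- 0L
  n_comp <- 0L
  if (nrow(pred_idx)) {
    lab <- cpp_label26(as.logical(mask), as.integer(d))
    comp_of <- lab[pred_idx]
    n_comp <- max(comp_of)
    gt_vox <- round(gt_points)
    for (cc in seq_len(n_comp)) {
      vox <- pred_idx[comp_of == cc, , drop = FALSE]
      near <- FALSE
      if (nrow(gt_points)) for (g in seq_len(nrow(gt_points))) {
        cheb <- pmax(abs(vox[, 1] - gt_vox[g, 1]),
                     pmax(abs(vox[, 2] - gt_vox[g, 2]),
                          abs(vox[, 3] - gt_vox[g, 3])))
        if (any(cheb <= h)) { near <- TRUE; break }
      }
      if (!near) fp <- fp + 1L
    }
  }
  detection <- if (tp + fn == 0) 100 else 100 * tp / (tp + fn)
  precision <- if (n_comp == 0) (if (nrow(gt_points) == 0) 100 else 0) else
    100 * (n_comp - fp) / n_comp
  list(tp = tp, fp = fp, fn = fn,
       precision = precision, recall = detection, detection_rate = detection,
       mean_err = if (length(errs)) mean(errs) else NA_real_,
       err_std = if (length(errs) > 1) stats::sd(errs) else
         if (length(errs) == 1) 0 else NA_real_)
}

#' Quadratic intensity preprocessing
#'
#' Clips intensities at a high quantile, applies the bright-structure
#' enhancing map `v -> (v / v_max)^2` and rescales to `[0, 255]`.
#' Squaring on `[0, 1]` is convex, so relatively dark structures are
#' suppressed and bright (vessel) structures are enhanced. A constant
#' volume maps to zeros.
#'
#' @param volume array or `volume3d`.
#' @param clip_quantile upper quantile at which intensities are clipped,
#'   default 0.999.
#' @return A `volume3d` with values in `[0, 255]`.
#' @export
preprocess_intensity <- function(volume, clip_quantile = 0.999) {
  v <- as_volume3d(volume)
  x <- v$data
  x <- x - min(x)
  hi <- stats::quantile(x, clip_quantile, names = FALSE)
  x <- pmin(x, hi)
  if (max(x) == 0) return(volume3d(array(0, dim(x)), v$spacing))
  volume3d(255 * (x / max(x))^2, v$spacing)
}
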