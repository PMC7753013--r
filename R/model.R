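#' Describe one convolutional layer
#'
#' @param in_channels,out_channels positive channel counts.
#' @param kernel integer length-3 kernel shape `(k_x, k_y, k_z)`; a
#'   scalar is recycled to a cube.
#' @param mode `"crosshair"` (three orthogonal 2-D plane kernels per
#'   channel pair) or `"full3d"` (dense kernel).
#' @param activation `"relu"`, `"tanh"`, `"sigmoid"` or `"identity"`.
#' @return A `layer_spec` list.
#' @export
layer_spec <- function(in_channels, out_channels, kernel,
                       mode = c("crosshair", "full3d"),
                       activation = "relu") {
  mode <- match.arg(mode)
  if (length(kernel) == 1L) kernel <- rep(kernel, 3L)
  kernel <- as.integer(check_shape(kernel, "kernel"))
  if (in_channels < 1 || out_channels < 1)
    stop("channel counts must be >= 1", call. = FALSE)
  activation <- match.arg(activation,
                          c("relu", "tanh", "sigmoid", "identity"))
  structure(list(in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 kernel = kernel, mode = mode, activation = activation),
            class = "layer_spec")
}

#' Assemble a fully convolutional network specification
#'
#' Chains the given hidden layers and appends a `1 x 1 x 1` sigmoid
#' classification layer mapping the last hidden width to a single
#' probability channel. All layers are same-size (zero padding), so the
#' network has no sub-sampling anywhere and maps a volume of arbitrary
#' size to a probability map of the same size.
#'
#' @param layers list of [layer_spec()]s with chaining channel counts.
#' @return A `network_spec`: the hidden layers plus the classifier layer.
#' @export
network_spec <- function(layers) {
  stopifnot(length(layers) >= 1L,
            all(vapply(layers, inherits, logical(1), "layer_spec")))
  for (i in seq_along(layers)[-1])
    if (layers[[i]]$in_channels != layers[[i - 1]]$out_channels)
      stop("channel counts do not chain at layer ", i, call. = FALSE)
  classifier <- layer_spec(layers[[length(layers)]]$out_channels, 1L,
                           c(1L, 1L, 1L), mode = "full3d",
                           activation = "sigmoid")
  structure(list(layers = c(layers, list(classifier))),
            class = "network_spec")
}

#' Default vessel-segmentation FCN specification
#'
#' Four cross-hair convolutional layers with channel widths
#' `1 -> 5 -> 10 -> 20 -> 50` and cubic kernels of sides 3, 5, 5, 3,
#' followed by the `1 x 1 x 1` sigmoid classifier: 46,021 trainable
#' values in cross-hair mode (0.05 M at two decimals), 58,521 for the
#' dense-kernel variant of the same shape.
#'
#' @param mode convolution mode for the hidden layers.
#' @param in_channels input channel count (1 for raw volumes; centerline
#'   and bifurcation networks consume 1 or 2 probability-map channels).
#' @param activation hidden-layer activation.
#' @return A `network_spec`.
#' @examples
#' count_parameters(default_fcn_spec())$total  # 46021
#' @export
default_fcn_spec <- function(mode = c("crosshair", "full3d"),
                             in_channels = 1L, activation = "relu") {
  mode <- match.arg(mode)
  widths <- c(in_channels, 5L, 10L, 20L, 50L)
  kernels <- c(3L, 5L, 5L, 3L)
  network_spec(lapply(seq_along(kernels), function(i)
    layer_spec(widths[i], widths[i + 1], kernels[i], mode = mode,
               activation = activation)))
}

layer_param_count <- function(ls) {
  k <- ls$kernel
  per_pair <- if (ls$mode == "crosshair")
    k[2] * k[3] + k[1] * k[3] + k[1] * k[2]
  else prod(k)
  per_pair * ls$in_channels * ls$out_channels + ls$out_channels
}

#' Count trainable parameters of a network specification
#'
#' Closed form, biases included: a dense layer holds
#' `k_x k_y k_z * C_in * C_out + C_out` values; a cross-hair layer holds
#' `(k_y k_z + k_x k_z + k_x k_y) * C_in * C_out + C_out`. Equals the
#' number of values in a model built from the spec.
#'
#' @param spec a `network_spec`.
#' @return A list with `per_layer` (integer vector, classifier last) and
#'   `total`.
#' @export
count_parameters <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  per <- vapply(spec$layers, layer_param_count, numeric(1))
  list(per_layer = per, total = sum(per))
}

#' @export
print.network_spec <- function(x, ...) {
  cat("<network_spec> ", length(x$layers), " layers, ",
      count_parameters(x)$total, " parameters\n", sep = "")
  for (l in x$layers)
    cat(sprintf("  %s %d->%d kernel (%s) %s\n", l$mode, l$in_channels,
                l$out_channels, paste(l$kernel, collapse = ","),
                l$activation))
  invisible(x)
}

init_weight <- function(dims, bound) {
  array(stats::runif(prod(dims), -bound, bound), dims)
}

#' Build a fully convolutional model from a specification
#'
#' Weights are initialised uniformly on
#' `(-1/sqrt(k_x k_y k_z), +1/sqrt(k_x k_y k_z))` per layer (the
#' fan-in-style symmetric interval implied by the kernel size); biases
#' start at zero, so the initial output probability is 0.5 everywhere.
#' Cross-hair layers hold one kernel triplet per (input, output) channel
#' pair with fixed plane weights `beta = 1`.
#'
#' @param spec a `network_spec`.
#' @param seed integer seed for the weight draw.
#' @return A `dvn_model` (spec, layer weights, seed). Use
#'   [predict.dvn_model()] for inference and [train_model()] to fit.
#' @export
build_fcn <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "network_spec"))
  local_seed(seed, {
    layers <- lapply(spec$layers, function(ls) {
      k <- ls$kernel; ci <- ls$in_channels; co <- ls$out_channels
      bound <- 1 / sqrt(prod(k))
      w <- if (ls$mode == "crosshair")
        list(Wi = init_weight(c(1L, k[2], k[3], ci, co), bound),
             Wj = init_weight(c(k[1], 1L, k[3], ci, co), bound),
             Wk = init_weight(c(k[1], k[2], 1L, ci, co), bound),
             beta = c(1, 1, 1))
      else list(W = init_weight(c(k, ci, co), bound))
      w$b <- numeric(co)
      w$spec <- ls
      structure(w, class = "dvn_layer")
    })
    structure(list(spec = spec, layers = layers, seed = as.integer(seed)),
              class = "dvn_model")
  })
}

#' @export
print.dvn_model <- function(x, ...) {
  cat("<dvn_model> seed", x$seed, "\n")
  print(x$spec)
  invisible(x)
}

as_input_4d <- function(x, in_channels) {
  x <- vol_data(x)
  d <- dim(x)
  if (length(d) == 3L) {
    dim(x) <- c(d, 1L)
    d <- dim(x)
  }
  if (length(d) != 4L || d[4] != in_channels)
    stop("input must have ", in_channels, " channel(s)", call. = FALSE)
  x
}

apply_activation <- function(z, act) {
  switch(act,
         relu = pmax(z, 0),
         tanh = tanh(z),
         sigmoid = 1 / (1 + exp(-z)),
         identity = z)
}

activation_grad <- function(z, a, act) {
  switch(act,
         relu = (z > 0) + 0,
         tanh = 1 - a^2,
         sigmoid = a * (1 - a),
         identity = array(1, dim(z)))
}

# forward through one layer (linear part, no activation)
layer_linear <- function(x, lw) {
  xd <- as.integer(dim(x))
  if (lw$spec$mode == "full3d")
    return(cpp_layer_fwd(as.numeric(x), xd, as.numeric(lw$W),
                         as.integer(dim(lw$W)), lw$b, TRUE))
  y <- lw$beta[1] * cpp_layer_fwd(as.numeric(x), xd, as.numeric(lw$Wi),
                                  as.integer(dim(lw$Wi)), lw$b, FALSE)
  y <- y + lw$beta[2] * cpp_layer_fwd(as.numeric(x), xd, as.numeric(lw$Wj),
                                      as.integer(dim(lw$Wj)), lw$b, FALSE)
  y <- y + lw$beta[3] * cpp_layer_fwd(as.numeric(x), xd, as.numeric(lw$Wk),
                                      as.integer(dim(lw$Wk)), lw$b, FALSE)
  y <- y + rep(lw$b, each = prod(xd[1:3]))
  dim(y) <- c(xd[1:3], lw$spec$out_channels)
  y
}

# backward through one layer's linear part: returns gx and gradients
layer_linear_bwd <- function(x, lw, gy) {
  xd <- as.integer(dim(x))
  if (lw$spec$mode == "full3d") {
    g <- cpp_layer_bwd(as.numeric(x), xd, as.numeric(lw$W),
                       as.integer(dim(lw$W)), as.numeric(gy))
    return(list(gx = g$gx, grads = list(W = g$gw, b = g$gb)))
  }
  gi <- cpp_layer_bwd(as.numeric(x), xd, as.numeric(lw$Wi),
                      as.integer(dim(lw$Wi)), as.numeric(gy))
  gj <- cpp_layer_bwd(as.numeric(x), xd, as.numeric(lw$Wj),
                      as.integer(dim(lw$Wj)), as.numeric(gy))
  gk <- cpp_layer_bwd(as.numeric(x), xd, as.numeric(lw$Wk),
                      as.integer(dim(lw$Wk)), as.numeric(gy))
  gx <- lw$beta[1] * gi$gx + lw$beta[2] * gj$gx + lw$beta[3] * gk$gx
  dim(gx) <- xd
  list(gx = gx,
       grads = list(Wi = lw$beta[1] * gi$gw, Wj = lw$beta[2] * gj$gw,
                    Wk = lw$beta[3] * gk$gw, b = gi$gb))
}

#' Apply one cross-hair layer to a multi-channel volume
#'
#' For each output channel, sums the cross-hair convolutions of all input
#' channels plus a bias. Identical (to accumulation order) to a dense
#' layer whose kernels are the [crosshair_embed()]dings of the plane
#' triplets.
#'
#' @param x input array `(n1, n2, n3, C_in)` (a 3-D array is treated as
#'   one channel).
#' @param layer a layer of a built [build_fcn()] model (class
#'   `dvn_layer`) in crosshair mode.
#' @return Array `(n1, n2, n3, C_out)`, linear output (no activation).
#' @export
crosshair_layer_forward <- function(x, layer) {
  stopifnot(inherits(layer, "dvn_layer"), layer$spec$mode == "crosshair")
  x <- as_input_4d(x, layer$spec$in_channels)
  layer_linear(x, layer)
}

# full forward pass; returns activations for backprop when keep = TRUE
model_forward <- function(model, x, keep = FALSE) {
  x <- as_input_4d(x, model$spec$layers[[1]]$in_channels)
  d <- dim(x)
  mk <- vapply(model$spec$layers, function(l) max(l$kernel), integer(1))
  if (any(d[1:3] < max(mk)))
    stop("input sides (", paste(d[1:3], collapse = ","),
         ") smaller than the largest kernel (", max(mk), ")", call. = FALSE)
  acts <- if (keep) vector("list", length(model$layers))
  zs <- if (keep) vector("list", length(model$layers))
  a <- x
  for (i in seq_along(model$layers)) {
    if (keep) acts[[i]] <- a
    z <- layer_linear(a, model$layers[[i]])
    a <- apply_activation(z, model$spec$layers[[i]]$activation)
    if (keep) zs[[i]] <- z
  }
  list(out = a, inputs = acts, z = zs)
}

#' Predict a probability map for a full volume
#'
#' Runs the fully convolutional model over the whole volume in one pass
#' (no tiling is needed at test time) and returns the same-shape
#' probability map.
#'
#' @param object a `dvn_model`.
#' @param volume a `volume3d` or array; each side must be at least the
#'   largest kernel side.
#' @param ... unused.
#' @return A `volume3d` of probabilities in `(0, 1)` (single-channel
#'   output), or a 4-D array for multi-channel outputs.
#' @export
predict.dvn_model <- function(object, volume, ...) {
  out <- model_forward(object, volume)$out
  d <- dim(out)
  sp <- if (inherits(volume, "volume3d")) volume$spacing else c(1, 1, 1)
  if (d[4] == 1L) {
    dim(out) <- d[1:3]
    volume3d(out, sp)
  } else out
}

# flatten trainable values of a model (for counting / determinism checks)
model_parameters <- function(model) {
  unlist(lapply(model$layers, function(lw)
    lapply(lw[intersect(names(lw), c("W", "Wi", "Wj", "Wk", "b"))],
           as.numeric)))
}
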