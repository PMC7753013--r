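#' @name losses
#' @title Class-balancing losses for extremely imbalanced voxel labelling
#'
#' @description
#' Binary segmentation of vessels, centerlines and bifurcations is an
#' extreme class-imbalance problem: the foreground occupies a few percent
#' of voxels at best. This module provides the loss family used to train
#' the networks in this package:
#'
#' * [loss_cross_entropy()] -- standard mean cross entropy;
#' * [loss_balanced()] -- class-weighted cross entropy with weights
#'   `beta = |Y-|/|Y|` and `1 - beta`, as a *sum* (not a mean). Its value
#'   grows with batch size, which is exactly the numerical-instability
#'   defect it is kept around to demonstrate;
#' * [loss_l1()] -- the stable balanced term: per-class means, so the
#'   value is invariant under batch duplication;
#' * [loss_l2()] -- the false-prediction-rate correction: thresholded
#'   false positives/negatives are re-penalised with data-dependent
#'   weights `gamma_1, gamma_2 in [0.5, 1]`;
#' * [loss_deepvesselnet()] -- the combination `L = L1 + L2`.
#'
#' All losses clip probabilities to `[1e-7, 1 - 1e-7]` before taking
#' logarithms. Losses return a `loss_terms` list with fields `L`, `L1`,
#' `L2`, `beta`, `gamma1`, `gamma2` (unused fields are `NA`).
#'
#' A note on normalisation of the correction term: the false-positive sum
#' in `L2` is divided by `|Y+|` and the false-negative sum by `|Y-|` --
#' not by the false-set sizes. This asymmetry is deliberate (it preserves
#' the class-balancing ratio) and easy to misread.
NULL

PROB_EPS <- 1e-7

clip_prob <- function(p) pmin(pmax(p, PROB_EPS), 1 - PROB_EPS)

check_batch <- function(p, y) {
  if (length(p) == 0L) stop("empty batch", call. = FALSE)
  if (length(p) != length(y))
    stop("`p` and `y` must have equal length", call. = FALSE)
  if (!all(is.finite(p)))
    stop("`p` contains non-finite values", call. = FALSE)
  if (any(p < 0 | p > 1)) stop("`p` must lie in [0,1]", call. = FALSE)
  if (!all(y %in% c(0, 1))) stop("`y` must be binary", call. = FALSE)
}

loss_terms <- function(L, L1 = NA_real_, L2 = NA_real_, beta = NA_real_,
                       gamma1 = NA_real_, gamma2 = NA_real_) {
  structure(list(L = L, L1 = L1, L2 = L2, beta = beta,
                 gamma1 = gamma1, gamma2 = gamma2),
            class = "loss_terms")
}

#' @export
print.loss_terms <- function(x, ...) {
  cat("<loss_terms> L =", format(x$L), "\n")
  for (f in c("L1", "L2", "beta", "gamma1", "gamma2"))
    if (!is.na(x[[f]])) cat("  ", f, "=", format(x[[f]]), "\n")
  invisible(x)
}

#' Standard mean cross-entropy loss
#'
#' @param p numeric vector of predicted probabilities of the positive
#'   class, in `[0, 1]`.
#' @param y binary label vector of the same length.
#' @return A `loss_terms` object; `L` is the mean negative log-likelihood.
#' @examples
#' loss_cross_entropy(c(0.5, 0.5), c(1, 0))$L  # log(2)
#' @export
loss_cross_entropy <- function(p, y) {
  check_batch(p, y)
  pc <- clip_prob(p)
  loss_terms(L = -mean(y * log(pc) + (1 - y) * log(1 - pc)))
}

#' Class-balanced cross-entropy loss (summed form)
#'
#' Weighted *sum* with `beta = |Y-|/|Y|` on the positive terms and
#' `1 - beta` on the negative terms. Because the weights do not rescale
#' the sums to means, the value grows linearly with batch size -- for a
#' perfectly balanced batch `beta = 0.5` regardless of `|Y|`, so doubling
#' the batch doubles the loss. Retained to demonstrate that instability;
#' prefer [loss_l1()] for training.
#'
#' @inheritParams loss_cross_entropy
#' @return A `loss_terms` object with `beta` filled in.
#' @export
loss_balanced <- function(p, y) {
  check_batch(p, y)
  pc <- clip_prob(p)
  beta <- mean(y == 0)
  pos <- y == 1
  loss_terms(L = -beta * sum(log(pc[pos])) -
               (1 - beta) * sum(log(1 - pc[!pos])),
             beta = beta)
}

#' Partition a batch by label and thresholded correctness
#'
#' Splits example indices into positives `Y+`, negatives `Y-`, false
#' positives `Yf+ = {j in Y- : p_j > threshold}` and false negatives
#' `Yf- = {j in Y+ : p_j <= threshold}`. A prediction exactly at the
#' threshold is not positive (strict `>`), so a positive example with
#' `p = threshold` counts as a false negative.
#'
#' @inheritParams loss_cross_entropy
#' @param threshold probability cut in `(0, 1)`, default 0.5.
#' @return A `batch_partition` list with integer index vectors `Y_plus`,
#'   `Y_minus`, `Yf_plus`, `Yf_minus` and the `threshold`.
#' @examples
#' partition_batch(c(0.4, 0.6, 0.2, 0.2), c(1, 0, 0, 0))
#' @export
partition_batch <- function(p, y, threshold = 0.5) {
  check_batch(p, y)
  if (threshold <= 0 || threshold >= 1)
    stop("`threshold` must lie in (0,1)", call. = FALSE)
  Y_plus <- which(y == 1)
  Y_minus <- which(y == 0)
  structure(list(Y_plus = Y_plus, Y_minus = Y_minus,
                 Yf_plus = Y_minus[p[Y_minus] > threshold],
                 Yf_minus = Y_plus[p[Y_plus] <= threshold],
                 threshold = threshold),
            class = "batch_partition")
}

#' Stable class-balanced term L1
#'
#' Per-class mean negative log-likelihood:
#' `-(1/|Y+|) sum_{Y+} log p_j - (1/|Y-|) sum_{Y-} log(1 - p_j)`.
#' A class absent from the batch contributes 0 (box-sampled batches can
#' be all background).
#'
#' @inheritParams loss_cross_entropy
#' @param partition a [partition_batch()] result; computed at 0.5 if
#'   omitted.
#' @return Numeric scalar.
#' @export
loss_l1 <- function(p, y, partition = partition_batch(p, y)) {
  check_batch(p, y)
  pc <- clip_prob(p)
  t_pos <- if (length(partition$Y_plus))
    -mean(log(pc[partition$Y_plus])) else 0
  t_neg <- if (length(partition$Y_minus))
    -mean(log(1 - pc[partition$Y_minus])) else 0
  t_pos + t_neg
}

#' False-prediction-rate correction term L2
#'
#' Re-penalises thresholded false predictions with weights that grow with
#' their mean confidence: `gamma1 = center + mean_{Yf+} |(1-p_j) - center|`
#' and `gamma2 = center + mean_{Yf-} |p_j - center|` (both in
#' `[center, 1]` for the default `center = 0.5`), then
#' `L2 = -(gamma1/|Y+|) sum_{Yf+} log(1-p_j)
#'       - (gamma2/|Y-|) sum_{Yf-} log p_j`.
#' An empty false set contributes 0 and its gamma is `NA`.
#'
#' @inheritParams loss_l1
#' @param center the reference probability from which confidence of a
#'   false prediction is measured (default 0.5; can be moved to suit the
#'   task).
#' @return A list with `L2`, `gamma1`, `gamma2`.
#' @export
loss_l2 <- function(p, y, partition = partition_batch(p, y), center = 0.5) {
  check_batch(p, y)
  pc <- clip_prob(p)
  fp <- partition$Yf_plus
  fn <- partition$Yf_minus
  gamma1 <- if (length(fp)) center + mean(abs((1 - p[fp]) - center)) else NA_real_
  gamma2 <- if (length(fn)) center + mean(abs(p[fn] - center)) else NA_real_
  # the 1/|Y+| and 1/|Y-| normalisers inherit the empty-class rule: a
  # class absent from the batch contributes nothing (its sum is empty
  # anyway whenever the partition is consistent with the labels)
  t_fp <- if (length(fp) && length(partition$Y_plus))
    -gamma1 / length(partition$Y_plus) * sum(log(1 - pc[fp])) else 0
  t_fn <- if (length(fn) && length(partition$Y_minus))
    -gamma2 / length(partition$Y_minus) * sum(log(pc[fn])) else 0
  list(L2 = t_fp + t_fn, gamma1 = gamma1, gamma2 = gamma2)
}

#' Combined extreme class-balancing loss L = L1 + L2
#'
#' @inheritParams loss_l2
#' @param threshold probability threshold defining the false sets.
#' @return A `loss_terms` object with `L`, `L1`, `L2`, `gamma1`, `gamma2`.
#' @examples
#' loss_deepvesselnet(c(0.4, 0.6, 0.2, 0.2), c(1, 0, 0, 0))
#' @export
loss_deepvesselnet <- function(p, y, threshold = 0.5, center = 0.5) {
  part <- partition_batch(p, y, threshold)
  l1 <- loss_l1(p, y, part)
  l2 <- loss_l2(p, y, part, center)
  loss_terms(L = l1 + l2$L2, L1 = l1, L2 = l2$L2,
             gamma1 = l2$gamma1, gamma2 = l2$gamma2)
}

#' Look up a loss function by configuration name
#'
#' @param name one of `"cross_entropy"`, `"balanced"`, `"deepvesselnet"`,
#'   `"l1_only"` (the combined loss without the correction term).
#' @return A function `(p, y) -> loss_terms`.
#' @export
loss_by_name <- function(name) {
  switch(match.arg(name,
                   c("deepvesselnet", "l1_only", "cross_entropy", "balanced")),
         cross_entropy = loss_cross_entropy,
         balanced = loss_balanced,
         l1_only = function(p, y) {
           l1 <- loss_l1(p, y)
           loss_terms(L = l1, L1 = l1, L2 = 0)
         },
         deepvesselnet = loss_deepvesselnet)
}

# Gradient of each loss w.r.t. the pre-sigmoid logit, with the partition
# and the gamma weights treated as constants (plain backpropagation does
# not differentiate through the threshold). Closed forms use
# d/dz log p = 1 - p and d/dz log(1-p) = -p.
loss_grad_logit <- function(name, p, y, threshold = 0.5, center = 0.5) {
  n <- length(p)
  g <- numeric(n)
  if (name == "cross_entropy") return((p - y) / n)
  if (name == "balanced") {
    beta <- mean(y == 0)
    pos <- y == 1
    g[pos] <- beta * (p[pos] - 1)
    g[!pos] <- (1 - beta) * p[!pos]
    return(g)
  }
  part <- partition_batch(p, y, threshold)
  np <- length(part$Y_plus); nn <- length(part$Y_minus)
  if (np) g[part$Y_plus] <- (p[part$Y_plus] - 1) / np
  if (nn) g[part$Y_minus] <- p[part$Y_minus] / nn
  if (name == "deepvesselnet") {
    l2 <- loss_l2(p, y, part, center)
    fp <- part$Yf_plus; fn <- part$Yf_minus
    if (length(fp) && np) g[fp] <- g[fp] + l2$gamma1 * p[fp] / np
    if (length(fn) && nn) g[fn] <- g[fn] + l2$gamma2 * (p[fn] - 1) / nn
  } else if (name != "l1_only") {
    stop("unknown loss: ", name, call. = FALSE)
  }
  g
}
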