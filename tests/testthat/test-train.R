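test_that("lr_schedule applies stepped exponential decay", {
  cfg <- train_config()
  expect_equal(lr_schedule(0, cfg), 0.01)
  expect_equal(lr_schedule(199, cfg), 0.01)
  expect_equal(lr_schedule(200, cfg), 0.0099)
  expect_equal(lr_schedule(2000, cfg), 0.01 * 0.99^10)
  cfg2 <- train_config(learning_rate = 0.001)
  expect_equal(lr_schedule(0, cfg2), 0.001)
  expect_error(train_config(decay = 1.5), "decay")
  expect_error(train_config(learning_rate = 0), "learning_rate")
})

test_that("extract_boxes tiles with zero padding and reassembles exactly", {
  v <- array(seq_len(128^3) %% 97, c(128, 128, 128))
  b <- extract_boxes(v, size = 64)
  expect_length(b, 8L)
  expect_identical(dim(b[[1]]$image), c(64L, 64L, 64L))
  # 100^3 also gives 2 boxes per axis, padded remainders
  v2 <- array(rnorm(40^3), c(40, 40, 40))
  lab <- array(rbinom(40^3, 1, 0.1), c(40, 40, 40))
  b100 <- extract_boxes(array(0, c(100, 100, 100)), size = 64)
  expect_length(b100, 8L)
  # reassembly of the unpadded regions reproduces the volume
  b2 <- extract_boxes(v2, lab, size = 16)
  expect_length(b2, 27L)
  rec <- array(NA_real_, c(40, 40, 40))
  recl <- array(NA_real_, c(40, 40, 40))
  for (bx in b2) {
    e <- bx$extent; o <- bx$origin
    rec[o[1] + seq_len(e[1]) - 1, o[2] + seq_len(e[2]) - 1,
        o[3] + seq_len(e[3]) - 1] <-
      bx$image[seq_len(e[1]), seq_len(e[2]), seq_len(e[3])]
    recl[o[1] + seq_len(e[1]) - 1, o[2] + seq_len(e[2]) - 1,
         o[3] + seq_len(e[3]) - 1] <-
      bx$label[seq_len(e[1]), seq_len(e[2]), seq_len(e[3])]
  }
  expect_identical(rec, v2)
  expect_identical(recl, lab + 0)
  # padded remainder region is zero
  last <- b2[[27]]
  expect_identical(sum(last$image[9:16, , ]), 0)
})

test_that("training is deterministic and a zero-iteration run is a no-op", {
  set.seed(60)
  x <- array(runif(12^3), c(12, 12, 12))
  y <- array(0, c(12, 12, 12)); y[5:8, 5:8, 5:8] <- 1
  model <- build_fcn(tiny_spec(widths = c(2L, 3L), kernels = c(3L, 3L)), 4)
  cfg0 <- train_config(iterations = 0, box_size = 12)
  fit0 <- train_model(model, list(x), list(y), cfg0)
  expect_identical(dvn:::model_parameters(fit0$model),
                   dvn:::model_parameters(model))
  expect_identical(nrow(fit0$trace), 0L)
  cfg <- train_config(iterations = 12, box_size = 12, metric_interval = 4,
                      seed = 9)
  f1 <- train_model(model, list(x), list(y), cfg)
  f2 <- train_model(model, list(x), list(y), cfg)
  expect_identical(f1$trace, f2$trace)
  expect_identical(dvn:::model_parameters(f1$model),
                   dvn:::model_parameters(f2$model))
  expect_identical(f1$trace$iteration, c(4L, 8L, 12L))
})

test_that("training aborts with a diagnostic on non-finite loss", {
  x <- array(NaN, c(8, 8, 8))
  y <- array(0, c(8, 8, 8))
  model <- build_fcn(tiny_spec(widths = 2L, kernels = 3L), 4)
  cfg <- train_config(iterations = 3, box_size = 8)
  expect_error(train_model(model, list(x), list(y), cfg), "non-finite")
})

test_that("full-volume prediction equals stitched box predictions inside", {
  set.seed(61)
  model <- build_fcn(tiny_spec(widths = c(2L, 3L), kernels = c(3L, 3L)), 7)
  v <- array(rnorm(20^3), c(20, 20, 20))
  full <- predict(model, v)$data
  stitched <- array(NA_real_, c(20, 20, 20))
  for (bx in extract_boxes(v, size = 10)) {
    p <- predict(model, bx$image)$data
    o <- bx$origin
    stitched[o[1]:(o[1] + 9), o[2]:(o[2] + 9), o[3]:(o[3] + 9)] <- p
  }
  # receptive-field radius of two 3^3 layers is 2: compare voxels deeper
  # than that inside each box
  rf <- 2
  core <- function(a) {
    keep <- array(FALSE, c(20, 20, 20))
    for (o in c(1, 11)) for (p in c(1, 11)) for (q in c(1, 11))
      keep[(o + rf):(o + 9 - rf), (p + rf):(p + 9 - rf),
           (q + rf):(q + 9 - rf)] <- TRUE
    a[keep]
  }
  expect_lt(max(abs(core(full) - core(stitched))), 1e-10)
})

test_that("seg_metrics implements the conventions and the Dice identity", {
  g <- array(0, c(4, 4, 4)); g[1:2, 1, 1] <- 1
  m <- seg_metrics(g, g)
  expect_equal(c(m$precision, m$recall, m$dice), c(100, 100, 100))
  m <- seg_metrics(array(0, dim(g)), g)
  expect_equal(m$recall, 0); expect_equal(m$dice, 0)
  expect_equal(m$precision, 0)
  # hand-computed triple
  p <- array(0, c(4, 4, 4)); gt <- array(0, c(4, 4, 4))
  gt[1:8] <- 1; p[3:10] <- 1   # TP=6, FP=2, FN=2
  m <- seg_metrics(p, gt)
  expect_equal(c(m$precision, m$recall, m$dice), c(75, 75, 75))
  # empty prediction and empty ground truth are perfect
  z <- array(0, c(3, 3, 3))
  expect_equal(seg_metrics(z, z)$precision, 100)
  # Dice identity against precision/recall
  set.seed(12)
  for (i in 1:10) {
    pr <- array(runif(64), c(4, 4, 4))
    gt <- array(rbinom(64, 1, 0.3), c(4, 4, 4))
    m <- seg_metrics(pr, gt)
    if (m$precision + m$recall > 0)
      expect_equal(m$dice,
                   2 * m$precision * m$recall / (m$precision + m$recall))
  }
})

test_that("hit-or-miss bifurcation scoring follows the cube protocol", {
  d <- c(24, 24, 24)
  mk <- function(pts) {
    m <- array(FALSE, d)
    for (i in seq_len(nrow(pts))) m[pts[i, 1], pts[i, 2], pts[i, 3]] <- TRUE
    m
  }
  gt <- matrix(c(10, 10, 10), ncol = 3)
  # exact hit
  ev <- evaluate_bifurcations(mk(matrix(c(10, 10, 10), ncol = 3)), gt)
  expect_identical(c(ev$tp, ev$fp, ev$fn), c(1L, 0L, 0L))
  expect_equal(ev$mean_err, 0)
  expect_equal(ev$detection_rate, 100)
  # 2-voxel offset still overlaps the 5^3 cube
  ev <- evaluate_bifurcations(mk(matrix(c(12, 12, 12), ncol = 3)), gt)
  expect_identical(c(ev$tp, ev$fn), c(1L, 0L))
  expect_identical(ev$fp, 0L)
  expect_equal(ev$mean_err, sqrt(12))
  # 3-voxel offset misses and is a false positive
  ev <- evaluate_bifurcations(mk(matrix(c(13, 13, 13), ncol = 3)), gt)
  expect_identical(c(ev$tp, ev$fn, ev$fp), c(0L, 1L, 1L))
  # empty prediction
  ev <- evaluate_bifurcations(array(FALSE, d), gt)
  expect_identical(c(ev$tp, ev$fn, ev$fp), c(0L, 1L, 0L))
  expect_equal(ev$detection_rate, 0)
  # permutation invariance in the ground-truth order
  gt2 <- rbind(c(10, 10, 10), c(20, 20, 20), c(4, 18, 6))
  pred <- mk(rbind(c(10, 10, 10), c(20, 21, 20)))
  a <- evaluate_bifurcations(pred, gt2)
  b <- evaluate_bifurcations(pred, gt2[c(3, 1, 2), ])
  expect_identical(a[c("tp", "fp", "fn")], b[c("tp", "fp", "fn")])
  # monotonicity: adding a predicted voxel never decreases TP
  pred2 <- pred; pred2[4, 18, 6] <- TRUE
  expect_gte(evaluate_bifurcations(pred2, gt2)$tp, a$tp)
  # one connected blob counts one FP, not one per voxel
  blob <- array(FALSE, d); blob[2:4, 2:4, 2:4] <- TRUE
  ev <- evaluate_bifurcations(blob, gt)
  expect_identical(ev$fp, 1L)
})

test_that("quadratic preprocessing enhances bright structures", {
  set.seed(13)
  v <- array(rexp(16^3, 1 / 50), c(16, 16, 16))
  out <- preprocess_intensity(v)$data
  expect_gte(min(out), 0); expect_lte(max(out), 255)
  # order preserved away from the clipped tail
  q <- stats::quantile(v, c(0.2, 0.6))
  i1 <- which(v <= q[1])[1]; i2 <- which(v >= q[2] & v < max(v))[1]
  expect_lt(out[i1], out[i2])
  # median/max contrast ratio decreases (bright structures enhanced)
  expect_lt(stats::median(out) / max(out), stats::median(v) / max(v))
  expect_identical(preprocess_intensity(array(5, c(4, 4, 4)))$data,
                   array(0, c(4, 4, 4)))
})

test_that("train_model fits an easy box and the trace records the schedule", {
  set.seed(70)
  x <- array(20, c(12, 12, 12))
  y <- array(0, c(12, 12, 12)); y[4:9, 4:9, 4:9] <- 1
  x[y == 1] <- 200
  model <- build_fcn(tiny_spec(widths = c(2L, 3L), kernels = c(3L, 3L)), 15)
  cfg <- train_config(iterations = 150, box_size = 12, input_scale = 1 / 255,
                      metric_interval = 25, seed = 15)
  fit <- train_model(model, list(x), list(y), cfg)
  expect_equal(fit$trace$lr, lr_schedule(fit$trace$iteration - 1, cfg))
  m <- seg_metrics(predict(fit$model, x / 255)$data, y)
  expect_gt(m$dice, 95)
})
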