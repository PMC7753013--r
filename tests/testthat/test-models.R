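test_that("default FCN spec chains channels and counts 46,021 parameters", {
  spec <- default_fcn_spec()
  widths <- vapply(spec$layers, `[[`, integer(1), "in_channels")
  expect_identical(widths, c(1L, 5L, 10L, 20L, 50L))
  pc <- count_parameters(spec)
  expect_identical(pc$per_layer, c(140, 3760, 15020, 27050, 51))
  expect_identical(pc$total, 46021)
  expect_identical(round(pc$total / 1e6, 2), 0.05)
  # dense-kernel variant of the same shape
  pcf <- count_parameters(default_fcn_spec("full3d"))
  expect_identical(pcf$per_layer, c(140, 6260, 25020, 27050, 51))
  expect_identical(pcf$total, 58521)
})

test_that("single-layer counts match arithmetic in both modes", {
  s_full <- network_spec(list(layer_spec(1, 1, 3, "full3d")))
  expect_identical(count_parameters(s_full)$per_layer[1], 28)
  s_ch <- network_spec(list(layer_spec(1, 1, 3, "crosshair")))
  expect_identical(count_parameters(s_ch)$per_layer[1], 28)
  expect_error(network_spec(list(layer_spec(1, 4, 3), layer_spec(5, 2, 3))),
               "chain")
})

test_that("per-layer crosshair/full parameter ratio obeys the corollary", {
  for (k in c(3L, 5L, 7L)) {
    ch <- count_parameters(network_spec(list(
      layer_spec(2, 3, k, "crosshair"))))$per_layer[1] - 3
    fu <- count_parameters(network_spec(list(
      layer_spec(2, 3, k, "full3d"))))$per_layer[1] - 3
    ratio <- ch / fu
    expect_equal(ratio, 3 * k^2 / k^3)
    if (k == 3L) expect_equal(ratio, 1) else expect_lt(ratio, 1)
  }
})

test_that("count_parameters equals the built model's value count", {
  for (mode in c("crosshair", "full3d")) {
    spec <- network_spec(list(layer_spec(1, 3, 3, mode),
                              layer_spec(3, 4, 5, mode)))
    model <- build_fcn(spec, 2)
    expect_identical(length(dvn:::model_parameters(model)),
                     as.integer(count_parameters(spec)$total))
  }
  m <- build_fcn(default_fcn_spec(), 2)
  expect_identical(length(dvn:::model_parameters(m)), 46021L)
})

test_that("initialisation is seeded, bounded and biases start at zero", {
  spec <- tiny_spec()
  m1 <- build_fcn(spec, 31); m2 <- build_fcn(spec, 31)
  expect_identical(dvn:::model_parameters(m1), dvn:::model_parameters(m2))
  expect_false(identical(dvn:::model_parameters(m1),
                         dvn:::model_parameters(build_fcn(spec, 32))))
  for (i in seq_along(m1$layers)) {
    lw <- m1$layers[[i]]
    bound <- 1 / sqrt(prod(lw$spec$kernel))
    for (nm in intersect(names(lw), c("W", "Wi", "Wj", "Wk")))
      expect_lte(max(abs(lw[[nm]])), bound)
    expect_identical(lw$b, numeric(lw$spec$out_channels))
  }
})

test_that("the model maps arbitrary-size volumes to same-size probabilities", {
  model <- build_fcn(tiny_spec(), 5)
  for (d in list(c(16L, 16L, 16L), c(7L, 11L, 9L))) {
    out <- predict(model, array(rnorm(prod(d)), d))
    expect_identical(dim(out$data), d)
    expect_true(all(out$data > 0 & out$data < 1))
  }
  expect_error(predict(model, array(0, c(3, 16, 16))), "smaller")
})

test_that("crosshair layers equal dense layers on embedded kernels", {
  set.seed(55)
  spec <- network_spec(list(layer_spec(1, 1, 3, "crosshair")))
  model <- build_fcn(spec, 8)
  lw <- model$layers[[1]]
  x <- array(rnorm(8^3), c(8, 8, 8, 1))
  out <- crosshair_layer_forward(x, lw)
  K <- crosshair_kernel(matrix(lw$Wi[1, , , 1, 1], 3),
                        matrix(lw$Wj[, 1, , 1, 1], 3),
                        matrix(lw$Wk[, , 1, 1, 1], 3))
  ref <- convolve_full(x[, , , 1], crosshair_embed(K))$data + lw$b
  expect_lt(max(abs(out[, , , 1] - ref)), 1e-5)
  # zero plane kernels leave only the bias
  lw0 <- lw; lw0$Wi[] <- 0; lw0$Wj[] <- 0; lw0$Wk[] <- 0; lw0$b <- 0.37
  expect_equal(max(abs(crosshair_layer_forward(x, lw0) - 0.37)), 0)
  # linearity in the input
  x2 <- array(rnorm(8^3), c(8, 8, 8, 1))
  lwnb <- lw; lwnb$b <- 0
  lhs <- crosshair_layer_forward(2 * x + 3 * x2, lwnb)
  rhs <- 2 * crosshair_layer_forward(x, lwnb) +
    3 * crosshair_layer_forward(x2, lwnb)
  expect_lt(max(abs(lhs - rhs)), 1e-9)
})

test_that("backpropagation matches finite differences end to end", {
  spec <- network_spec(list(layer_spec(1, 2, 3, "crosshair",
                                       activation = "tanh"),
                            layer_spec(2, 2, 3, "full3d")))
  model <- build_fcn(spec, 42)
  set.seed(3)
  x <- array(rnorm(5^3), c(5, 5, 5))
  y <- array(rbinom(125, 1, 0.1), c(5, 5, 5))
  fwd <- dvn:::model_forward(model, x, keep = TRUE)
  g <- array(dvn:::loss_grad_logit("l1_only", as.numeric(fwd$out),
                                   as.numeric(y)), dim(fwd$out))
  L <- length(model$layers)
  grads <- vector("list", L)
  for (i in L:1) {
    if (i < L) {
      a <- dvn:::apply_activation(fwd$z[[i]],
                                  model$spec$layers[[i]]$activation)
      g <- g * dvn:::activation_grad(fwd$z[[i]], a,
                                     model$spec$layers[[i]]$activation)
    }
    bw <- dvn:::layer_linear_bwd(fwd$inputs[[i]], model$layers[[i]], g)
    grads[[i]] <- bw$grads
    g <- bw$gx
  }
  lossval <- function(m)
    loss_l1(as.numeric(dvn:::model_forward(m, x)$out), as.numeric(y))
  eps <- 1e-6
  set.seed(4)
  for (i in seq_len(L)) for (nm in names(grads[[i]])) {
    W <- model$layers[[i]][[nm]]
    for (idx in sample(length(W), min(4, length(W)))) {
      mp <- model; mp$layers[[i]][[nm]][idx] <- W[idx] + eps
      mm <- model; mm$layers[[i]][[nm]][idx] <- W[idx] - eps
      num <- (lossval(mp) - lossval(mm)) / (2 * eps)
      expect_equal(as.numeric(grads[[i]][[nm]])[idx], num,
                   tolerance = 1e-4)
    }
  }
})

test_that("models survive a JSON save/load round trip", {
  model <- build_fcn(tiny_spec(), 13)
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  save_model(model, path)
  m2 <- load_model(path)
  x <- array(rnorm(8^3), c(8, 8, 8))
  expect_equal(predict(m2, x)$data, predict(model, x)$data)
})
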