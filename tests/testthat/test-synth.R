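test_that("murray_split satisfies the law exactly in closed form", {
  r <- murray_split(1, 1, 3)
  expect_equal(unname(r["r_l"]), 2^(-1 / 3))
  expect_equal(unname(r["r_r"]), 2^(-1 / 3))
  # construction identity at random parameters
  set.seed(11)
  for (i in 1:20) {
    rp <- runif(1, 0.5, 5); a <- runif(1, 0.01, 1); g <- runif(1, 2, 4)
    r <- murray_split(rp, a, g)
    expect_lt(abs(rp^g - r[["r_l"]]^g - r[["r_r"]]^g), 1e-12)
  }
  # vanishing daughter in the asymmetric limit
  r <- murray_split(1, 1e-3, 3)
  expect_equal(unname(r["r_l"]), 1, tolerance = 1e-6)
  expect_lt(r[["r_r"]], 2e-3)
  expect_error(murray_split(-1, 0.5), "r_p")
})

test_that("bifurcation angles follow the printed cosine formulas", {
  r <- murray_split(1, 1, 3)
  phi <- bifurcation_angles(1, r[["r_l"]], r[["r_r"]])
  expect_equal(unname(phi["phi_l"]), acos(2^(-1 / 3)))
  expect_equal(unname(phi["phi_l"]), 0.6540, tolerance = 1e-3)
  expect_equal(unname(phi["phi_l"]) * 180 / pi, 37.47, tolerance = 1e-2)
  # symmetric triples give equal angles
  expect_equal(unname(phi["phi_l"]), unname(phi["phi_r"]))
  # straight continuation as one daughter vanishes
  phi <- bifurcation_angles(1, 1, 1e-4)
  expect_lt(unname(phi["phi_l"]), 1e-6)
  # invalid triple: cosine outside [-1, 1]
  expect_error(bifurcation_angles(1, 0.1, 0.1), "cosine")
})

test_that("sample_tree is deterministic and structurally consistent", {
  cfg <- synth_config(volume_shape = c(32, 32, 32))
  t1 <- sample_tree(cfg, seed = 5)
  t2 <- sample_tree(cfg, seed = 5)
  expect_identical(t1, t2)
  expect_false(identical(t1, sample_tree(cfg, seed = 6)))
  # node types consistent with out-degree; exactly one root
  deg <- tabulate(t1$edges$parent, nbins = nrow(t1$nodes))
  expect_identical(sum(t1$nodes$type == "root"), 1L)
  expect_true(all(deg[t1$nodes$type == "leaf"] == 0))
  expect_true(all(deg[t1$nodes$type == "bifurcation"] == 2))
  expect_true(all(deg[t1$nodes$type == "inter"] == 1))
  root <- t1$nodes$id[t1$nodes$type == "root"]
  expect_lte(deg[root], 1L)
})

test_that("terminal radius at or above the root radius gives one segment", {
  cfg <- synth_config(volume_shape = c(32, 32, 32), root_radius = c(1, 1.5),
                      min_radius = 2)
  tr <- sample_tree(cfg, seed = 3)
  expect_identical(nrow(tr$edges), 1L)
  expect_setequal(tr$nodes$type, c("root", "leaf"))
})

test_that("validate_tree flags constructed defects", {
  # deterministic one-bifurcation tree built from the constraint formulas
  rp <- 2; rd <- murray_split(rp, 0.8, 3)
  phi <- bifurcation_angles(rp, rd[["r_l"]], rd[["r_r"]])
  A <- c(16, 16, 12); l <- 6
  B <- A + l * c(sin(phi[["phi_l"]]), 0, cos(phi[["phi_l"]]))
  C <- A + l * c(-sin(phi[["phi_r"]]), 0, cos(phi[["phi_r"]]))
  nodes <- data.frame(id = 1:4,
                      x = c(16, A[1], B[1], C[1]),
                      y = c(16, A[2], B[2], C[2]),
                      z = c(4, A[3], B[3], C[3]),
                      type = c("root", "bifurcation", "leaf", "leaf"))
  edges <- data.frame(parent = c(1L, 2L, 2L), child = c(2L, 3L, 4L),
                      radius = c(rp, rd[["r_l"]], rd[["r_r"]]))
  tr <- dvn:::vessel_tree(nodes, edges, 3, c(32, 32, 32))
  expect_identical(validate_tree(tr)$n_violations, 0L)
  # perturbing one daughter radius by 10% breaks exactly one Murray check
  tr2 <- tr
  tr2$edges$radius[2] <- tr2$edges$radius[2] * 1.1
  v <- validate_tree(tr2)
  expect_identical(nrow(v$murray), 1L)
  expect_identical(v$murray$node, 2L)
  # validated sampled trees are clean
  expect_identical(
    validate_tree(sample_tree(synth_config(volume_shape = c(32, 32, 32)),
                              seed = 9))$n_violations, 0L)
  # duplicated edge breaks the tree topology
  tr3 <- tr
  tr3$edges <- rbind(tr3$edges, tr3$edges[1, ])
  expect_gt(nrow(validate_tree(tr3)$topology), 0)
})

test_that("voxelize matches a brute-force capsule distance oracle", {
  nodes <- data.frame(id = 1:2, x = c(10, 10), y = c(10, 10),
                      z = c(8, 18), type = c("root", "leaf"))
  edges <- data.frame(parent = 1L, child = 2L, radius = 2)
  tr <- dvn:::vessel_tree(nodes, edges, 3, c(32, 32, 32))
  mask <- voxelize(tr)
  # independent oracle: point-to-segment distance at every voxel center
  p1 <- c(10, 10, 8); p2 <- c(10, 10, 18)
  idx <- as.matrix(expand.grid(i = 1:32, j = 1:32, k = 1:32))
  d <- p2 - p1
  tpar <- pmin(1, pmax(0, ((idx[, 1] - p1[1]) * d[1] + (idx[, 2] - p1[2]) *
                             d[2] + (idx[, 3] - p1[3]) * d[3]) / sum(d^2)))
  dist2 <- (idx[, 1] - p1[1] - tpar * d[1])^2 +
    (idx[, 2] - p1[2] - tpar * d[2])^2 + (idx[, 3] - p1[3] - tpar * d[3])^2
  expect_identical(sum(mask), sum(dist2 <= 4))
  expect_identical(as.logical(mask[cbind(idx[dist2 <= 4, ])]),
                   rep(TRUE, sum(dist2 <= 4)))
  # empty tree renders an all-background mask
  empty <- dvn:::vessel_tree(nodes[0, ], edges[0, ], 3, c(8, 8, 8))
  expect_identical(sum(voxelize(empty)), 0L)
  # halving every radius shrinks the mask monotonically
  tr_half <- tr
  tr_half$edges$radius <- tr_half$edges$radius / 2
  expect_true(all(voxelize(tr) | !voxelize(tr_half)))
})

test_that("centerline rasterization is 26-connected and contained", {
  nodes <- data.frame(id = 1:2, x = c(2, 2), y = c(2, 2), z = c(2, 12),
                      type = c("root", "leaf"))
  edges <- data.frame(parent = 1L, child = 2L, radius = 1)
  tr <- dvn:::vessel_tree(nodes, edges, 3, c(16, 16, 16))
  cm <- rasterize_centerline(tr)
  expect_identical(sum(cm), 11L)
  expect_true(all(which(cm, arr.ind = TRUE)[, 1:2] == 2))
  # containment in the vessel mask for sampled trees with radii >= 1
  cfg <- synth_config(volume_shape = c(32, 32, 32), min_radius = 1)
  for (s in c(2, 4)) {
    t2 <- sample_tree(cfg, seed = s)
    vm <- voxelize(t2); c2 <- rasterize_centerline(t2)
    expect_identical(sum(c2 & !vm), 0L)
    # consecutive voxels differ by at most 1 per axis along each segment
  }
  empty <- dvn:::vessel_tree(nodes[0, ], edges[0, ], 3, c(8, 8, 8))
  expect_identical(sum(rasterize_centerline(empty)), 0L)
})

test_that("bifurcation cubes are clipped at the boundary", {
  nodes <- data.frame(id = 1:4,
                      x = c(10, 10, 7, 13), y = c(10, 10, 13, 13),
                      z = c(2, 10, 16, 16),
                      type = c("root", "bifurcation", "leaf", "leaf"))
  edges <- data.frame(parent = c(1L, 2L, 2L), child = c(2L, 3L, 4L),
                      radius = c(2, 1.6, 1.6))
  tr <- dvn:::vessel_tree(nodes, edges, 3, c(20, 20, 20))
  bm <- bifurcation_mask(tr, cube = 5)
  expect_identical(sum(bm), 125L)
  expect_true(bm[10, 10, 10])
  # corner node: cube clipped to 3x3x3
  nodes2 <- nodes; nodes2[2, c("x", "y", "z")] <- c(1, 1, 1)
  tr2 <- dvn:::vessel_tree(nodes2, edges, 3, c(20, 20, 20))
  expect_identical(sum(bifurcation_mask(tr2, cube = 5)), 27L)
  # no bifurcations, no labels
  nodes3 <- nodes[1:2, ]; nodes3$type <- c("root", "leaf")
  tr3 <- dvn:::vessel_tree(nodes3, edges[1, ], 3, c(20, 20, 20))
  expect_identical(sum(bifurcation_mask(tr3)), 0L)
  expect_error(bifurcation_mask(tr, cube = 4), "odd")
})

test_that("intensity rendering follows the configured model", {
  cfg <- synth_config(volume_shape = c(12, 12, 12))
  mask <- array(FALSE, c(12, 12, 12)); mask[4:8, 4:8, 4:8] <- TRUE
  img0 <- render_intensities(mask, cfg, seed = 3, noise = FALSE)$data
  expect_identical(length(unique(as.numeric(img0))), 2L)
  expect_gte(min(img0[mask]), 128); expect_lte(max(img0[mask]), 255)
  expect_gte(min(img0[!mask]), 0); expect_lte(max(img0[!mask]), 100)
  # determinism
  expect_identical(render_intensities(mask, cfg, seed = 3)$data,
                   render_intensities(mask, cfg, seed = 3)$data)
  # foreground/background contrast across seeds
  gap <- vapply(1:100, function(s) {
    im <- render_intensities(mask, cfg, seed = s)$data
    mean(im[mask]) - mean(im[!mask])
  }, numeric(1))
  expect_gt(mean(gap), 28)
})

test_that("generate_dataset is reproducible with realistic imbalance", {
  cfg <- synth_config()
  d1 <- generate_dataset(cfg, 3, seed = 40)
  d2 <- generate_dataset(cfg, 3, seed = 40)
  expect_identical(d1, d2)
  fr <- vapply(generate_dataset(cfg, 20, seed = 800),
               function(d) d$fractions, numeric(3))
  vessel <- mean(fr["vessel", ]); center <- mean(fr["centerline", ])
  expect_gt(vessel, 0.005); expect_lt(vessel, 0.05)
  expect_gt(center, 0.0005); expect_lt(center, 0.01)
  # mask hierarchy per volume
  for (d in d1) {
    expect_identical(sum(d$centerline_mask & !d$vessel_mask), 0L)
    expect_lt(d$fractions[["centerline"]], d$fractions[["vessel"]])
    expect_lt(d$fractions[["vessel"]], 1)
  }
})

test_that("every sampled bifurcation cube center lies on the centerline", {
  cfg <- synth_config(volume_shape = c(32, 32, 32))
  tr <- sample_tree(cfg, seed = 19)
  cm <- rasterize_centerline(tr)
  bif <- tr$nodes[tr$nodes$type == "bifurcation", ]
  expect_gt(nrow(bif), 0)
  for (b in seq_len(nrow(bif))) {
    c0 <- pmin(pmax(round(c(bif$x[b], bif$y[b], bif$z[b])), 1), 32)
    expect_true(cm[c0[1], c0[2], c0[3]])
  }
})

test_that("synth_config validates intervals and parameters", {
  expect_error(synth_config(vessel_intensity = c(255, 128)), "interval")
  expect_error(synth_config(bifurcation_cube = 4), "odd")
  expect_error(synth_config(gamma = 0), "gamma")
  expect_error(synth_config(min_radius = -1), "min_radius")
})
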