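#' @name vessel_synth
#' @title Constrained synthetic vascular trees
#'
#' @description
#' Generator for physiologically constrained synthetic vascular trees and
#' the labelled volumes derived from them. Trees grow recursively from a
#' root on the volume boundary; every bifurcation satisfies Murray's law
#' `r_p^gamma = r_l^gamma + r_r^gamma` exactly (daughter radii come from
#' the closed form in [murray_split()]) and the daughters leave the parent
#' direction at the optimal branching angles of [bifurcation_angles()],
#' rotated about a uniformly random azimuth. Growth stops at a minimum
#' terminal radius, the volume boundary, or a node budget. Trees are then
#' voxelised into vessel masks (capsule rasterisation), centerline masks
#' (26-connected line rasterisation) and bifurcation masks (cubes around
#' bifurcation nodes), and rendered into noisy intensity images.
#'
#' The full angiogenesis biophysics (oxygen demand, growth-factor
#' diffusion) that motivates such simulators is *not* modelled: this is a
#' geometric surrogate that enforces the structural constraints the
#' downstream networks rely on and reproduces realistic foreground
#' fractions (vessels of order 2% of voxels, centerlines of order 0.2%).
NULL

# Run code with a temporary RNG seed, restoring the caller's RNG state.
local_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(as.integer(seed))
  force(code)
}

check_interval <- function(x, name, lo = -Inf) {
  x <- as.numeric(x)
  if (length(x) != 2L || any(!is.finite(x)) || x[1] > x[2] || x[1] < lo)
    stop("`", name, "` must be an ordered interval",
         if (is.finite(lo)) paste0(" with lower bound >= ", lo),
         call. = FALSE)
  x
}

#' Configuration of the synthetic data generator
#'
#' Defaults emulate angiographic training volumes: one arterial tree per
#' volume with a root radius of a few voxels, segment length proportional
#' to radius, vessel intensities drawn per volume from `[128, 255]`,
#' background from `[0, 100]`, and additive Gaussian noise whose mean and
#' standard deviation are jittered per volume (mean offset in `[-5, 5]`,
#' standard deviation `base_sd` plus an offset in `[-15, 30]`, floored at
#' zero). At the default 64^3 volume shape the defaults produce a vessel
#' fraction of order 2% and a centerline fraction of order 0.2%.
#'
#' @param volume_shape integer length-3 volume shape in voxels.
#' @param root_radius length-2 interval (voxels) the root radius is drawn
#'   from uniformly.
#' @param gamma bifurcation exponent of Murray's law (classical value 3).
#' @param asymmetry_shape length-2 Beta distribution parameters for the
#'   daughter asymmetry ratio `r_r / r_l` in `(0, 1]`.
#' @param length_ratio segment length as a multiple of segment radius.
#' @param length_jitter relative uniform jitter on segment length.
#' @param min_radius terminal radius (voxels); branches thinner than this
#'   are not grown.
#' @param max_nodes node budget per tree (growth safety stop).
#' @param scale multiplier applied to all radii and lengths, to match
#'   vessel sizes of a target modality (default 1).
#' @param vessel_intensity,background_intensity per-volume intensity
#'   intervals.
#' @param noise_mean interval of the per-volume noise mean offset.
#' @param noise_sd_offset interval of the per-volume offset added to
#'   `base_sd`; negative totals are clipped to 0.
#' @param base_sd base noise standard deviation.
#' @param bifurcation_cube odd side of the cube labelled around each
#'   bifurcation node.
#' @param seed default random seed used when none is passed explicitly.
#' @return A validated `synth_config` list.
#' @examples
#' cfg <- synth_config(volume_shape = c(32, 32, 32))
#' @export
synth_config <- function(volume_shape = c(64, 64, 64),
                         root_radius = c(3, 4),
                         gamma = 3,
                         asymmetry_shape = c(5, 2),
                         length_ratio = 4,
                         length_jitter = 0.2,
                         min_radius = 0.6,
                         max_nodes = 1000,
                         scale = 1,
                         vessel_intensity = c(128, 255),
                         background_intensity = c(0, 100),
                         noise_mean = c(-5, 5),
                         noise_sd_offset = c(-15, 30),
                         base_sd = 20,
                         bifurcation_cube = 5,
                         seed = 1L) {
  cfg <- list(
    volume_shape = as.integer(check_shape(volume_shape, "volume_shape")),
    root_radius = check_interval(root_radius, "root_radius", lo = 0),
    gamma = as.numeric(gamma),
    asymmetry_shape = as.numeric(asymmetry_shape),
    length_ratio = as.numeric(length_ratio),
    length_jitter = as.numeric(length_jitter),
    min_radius = as.numeric(min_radius),
    max_nodes = as.integer(max_nodes),
    scale = as.numeric(scale),
    vessel_intensity = check_interval(vessel_intensity, "vessel_intensity"),
    background_intensity = check_interval(background_intensity,
                                          "background_intensity"),
    noise_mean = check_interval(noise_mean, "noise_mean"),
    noise_sd_offset = check_interval(noise_sd_offset, "noise_sd_offset"),
    base_sd = as.numeric(base_sd),
    bifurcation_cube = as.integer(bifurcation_cube),
    seed = as.integer(seed))
  if (cfg$gamma <= 0) stop("`gamma` must be positive", call. = FALSE)
  if (cfg$min_radius <= 0) stop("`min_radius` must be positive", call. = FALSE)
  if (cfg$length_ratio <= 0) stop("`length_ratio` must be positive",
                                  call. = FALSE)
  if (length(cfg$asymmetry_shape) != 2L || any(cfg$asymmetry_shape <= 0))
    stop("`asymmetry_shape` must be two positive Beta parameters",
         call. = FALSE)
  if (cfg$bifurcation_cube < 1L || cfg$bifurcation_cube %% 2L == 0L)
    stop("`bifurcation_cube` must be odd and >= 1", call. = FALSE)
  if (cfg$base_sd < 0) stop("`base_sd` must be >= 0", call. = FALSE)
  if (cfg$scale <= 0) stop("`scale` must be positive", call. = FALSE)
  if (cfg$max_nodes < 2L) stop("`max_nodes` must be >= 2", call. = FALSE)
  structure(cfg, class = "synth_config")
}

#' Split a parent radius by Murray's law
#'
#' Closed-form daughter radii under `r_p^gamma = r_l^gamma + r_r^gamma`
#' with a prescribed asymmetry `r_r = asymmetry * r_l`:
#' `r_l = r_p / (1 + asymmetry^gamma)^(1/gamma)`.
#'
#' @param r_p parent radius, positive.
#' @param asymmetry daughter ratio in `(0, 1]`.
#' @param gamma bifurcation exponent, positive.
#' @return Named numeric vector `c(r_l, r_r)` satisfying Murray's law
#'   exactly (to floating point).
#' @examples
#' murray_split(1, 1)  # both daughters 2^(-1/3)
#' @export
murray_split <- function(r_p, asymmetry, gamma = 3) {
  if (r_p <= 0 || asymmetry <= 0 || asymmetry > 1 || gamma <= 0)
    stop("need r_p > 0, asymmetry in (0,1], gamma > 0", call. = FALSE)
  r_l <- r_p / (1 + asymmetry^gamma)^(1 / gamma)
  c(r_l = r_l, r_r = asymmetry * r_l)
}

#' Optimal bifurcation angles from the radii
#'
#' Branching angles of the daughters relative to the parent direction
#' under the minimum-volume principle:
#' `cos(phi_l) = (r_p^4 + r_l^4 - r_r^4) / (2 r_p^2 r_l^2)` and
#' symmetrically for `phi_r`.
#'
#' @param r_p,r_l,r_r parent and daughter radii, positive.
#' @return Named numeric vector `c(phi_l, phi_r)` in radians, in
#'   `[0, pi]`.
#' @examples
#' r <- murray_split(1, 1)
#' bifurcation_angles(1, r["r_l"], r["r_r"])  # acos(2^(-1/3)) each
#' @export
bifurcation_angles <- function(r_p, r_l, r_r) {
  if (any(c(r_p, r_l, r_r) <= 0))
    stop("radii must be positive", call. = FALSE)
  cl <- (r_p^4 + r_l^4 - r_r^4) / (2 * r_p^2 * r_l^2)
  cr <- (r_p^4 + r_r^4 - r_l^4) / (2 * r_p^2 * r_r^2)
  tol <- 1e-12
  if (cl > 1 + tol || cl < -1 - tol || cr > 1 + tol || cr < -1 - tol)
    stop("invalid radius triple: bifurcation cosine outside [-1, 1]",
         call. = FALSE)
  c(phi_l = acos(min(1, max(-1, cl))), phi_r = acos(min(1, max(-1, cr))))
}

# unit vector orthogonal pair spanning the plane normal to d
orthonormal_pair <- function(d) {
  a <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- a - sum(a * d) * d
  u <- u / sqrt(sum(u^2))
  v <- c(d[2] * u[3] - d[3] * u[2],
         d[3] * u[1] - d[1] * u[3],
         d[1] * u[2] - d[2] * u[1])
  list(u = u, v = v)
}

vessel_tree <- function(nodes, edges, gamma, shape) {
  structure(list(nodes = nodes, edges = edges, gamma = gamma,
                 shape = as.integer(shape)),
            class = "vessel_tree")
}

#' @export
print.vessel_tree <- function(x, ...) {
  cat("<vessel_tree> ", nrow(x$nodes), " nodes (",
      sum(x$nodes$type == "bifurcation"), " bifurcations), ",
      nrow(x$edges), " segments, volume ",
      paste(x$shape, collapse = " x "), "\n", sep = "")
  invisible(x)
}

#' Sample a constrained vascular tree
#'
#' Grows one directed tree from a root on a randomly chosen face of the
#' volume. Each segment has length `length_ratio * radius` (jittered);
#' at each branch point daughter radii follow [murray_split()] with a
#' Beta-distributed asymmetry and daughter directions leave the parent
#' direction at the [bifurcation_angles()], rotated about a uniform
#' random azimuth (the two daughters are coplanar with the parent, on
#' opposite sides). Branches stop at the terminal radius, at the volume
#' boundary (the last segment is truncated there), or when the node
#' budget is reached.
#'
#' @param config a [synth_config()].
#' @param seed integer seed; defaults to `config$seed`. The same
#'   `(config, seed)` pair always yields the identical tree.
#' @return A `vessel_tree`: node table (`id, x, y, z, type` with types
#'   root/bifurcation/inter/leaf), edge table (`parent, child, radius`),
#'   the `gamma` used and the volume shape. Coordinates are 1-based
#'   continuous voxel indices (voxel centers at integers), matching R
#'   array indexing.
#' @export
sample_tree <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "synth_config"))
  rr <- config$root_radius * config$scale
  if (rr[2] <= 0)
    stop("degenerate tree: root radius must be positive", call. = FALSE)
  local_seed(seed, {
    shape <- config$volume_shape
    # root on a random face, pointing inward
    face <- sample.int(6L, 1L)
    axis <- (face + 1L) %/% 2L
    hi <- face %% 2L == 0L
    pos <- 1 + stats::runif(3) * (shape - 1)
    pos[axis] <- if (hi) shape[axis] else 1
    dir <- c(0, 0, 0)
    dir[axis] <- if (hi) -1 else 1
    # small jitter so trees are not axis-locked
    jit <- stats::rnorm(3, 0, 0.15)
    dir <- dir + jit - sum(jit * dir) * dir
    dir <- dir / sqrt(sum(dir^2))
    r0 <- stats::runif(1, rr[1], rr[2])

    nodes <- list()
    edges <- list()
    nid <- 0L
    add_node <- function(p, type) {
      nid <<- nid + 1L
      nodes[[nid]] <<- list(id = nid, x = p[1], y = p[2], z = p[3],
                            type = type)
      nid
    }
    root_id <- add_node(pos, "root")
    # stack of branches to grow: (parent node id, position, direction, radius)
    stack <- list(list(parent = root_id, pos = pos, dir = dir, radius = r0))
    min_r <- config$min_radius * config$scale
    while (length(stack) > 0L && nid < config$max_nodes) {
      br <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      len <- config$length_ratio * br$radius *
        stats::runif(1, 1 - config$length_jitter, 1 + config$length_jitter)
      end <- br$pos + len * br$dir
      # truncate at the boundary; a truncated branch becomes a leaf
      t_max <- 1
      for (a in 1:3) {
        if (br$dir[a] > 0) t_max <- min(t_max, (shape[a] - br$pos[a]) /
                                          (len * br$dir[a]))
        if (br$dir[a] < 0) t_max <- min(t_max, (1 - br$pos[a]) /
                                          (len * br$dir[a]))
      }
      truncated <- t_max < 1
      if (truncated) {
        if (t_max <= 1e-6) next  # degenerate: branch starts on the boundary
        end <- br$pos + t_max * len * br$dir
      }
      child <- add_node(end, "leaf")  # type fixed up afterwards
      edges[[length(edges) + 1L]] <- list(parent = br$parent, child = child,
                                          radius = br$radius)
      if (truncated || nid >= config$max_nodes) next
      # branch: Murray split with Beta-distributed asymmetry
      asym <- stats::rbeta(1, config$asymmetry_shape[1],
                           config$asymmetry_shape[2])
      asym <- min(1, max(1e-3, asym))
      rd <- murray_split(br$radius, asym, config$gamma)
      keep <- rd >= min_r
      if (!any(keep)) next  # terminal radius reached: leaf
      phi <- bifurcation_angles(br$radius, rd[1], rd[2])
      ouv <- orthonormal_pair(br$dir)
      psi <- stats::runif(1, 0, 2 * pi)
      w <- cos(psi) * ouv$u + sin(psi) * ouv$v
      dirs <- list(cos(phi[1]) * br$dir + sin(phi[1]) * w,
                   -sin(phi[2]) * w + cos(phi[2]) * br$dir)
      for (q in which(keep))
        stack[[length(stack) + 1L]] <- list(parent = child, pos = end,
                                            dir = dirs[[q]], radius = rd[[q]])
    }
    nodes <- do.call(rbind, lapply(nodes, as.data.frame))
    edges <- if (length(edges))
      do.call(rbind, lapply(edges, as.data.frame))
    else data.frame(parent = integer(), child = integer(), radius = numeric())
    # assign node types from out-degree
    deg <- tabulate(edges$parent, nbins = nrow(nodes))
    nodes$type <- ifelse(nodes$id == root_id, "root",
                         ifelse(deg == 0L, "leaf",
                                ifelse(deg == 1L, "inter", "bifurcation")))
    vessel_tree(nodes, edges, config$gamma, shape)
  })
}

#' Validate the structural constraints of a vessel tree
#'
#' Checks every bifurcation for Murray's law and the optimal-angle
#' constraints, every node for volume bounds, and the edge set for tree
#' topology (single parent per node, no cycles, connected to the root).
#'
#' @param tree a `vessel_tree`.
#' @param gamma bifurcation exponent to check against (defaults to the
#'   tree's own).
#' @param tol residual tolerance for the Murray and cosine checks.
#' @return A list of violation data frames (`murray`, `angles`, `bounds`,
#'   `topology`) plus `n_violations`, the total count.
#' @export
validate_tree <- function(tree, gamma = tree$gamma, tol = 1e-9) {
  stopifnot(inherits(tree, "vessel_tree"))
  nodes <- tree$nodes; edges <- tree$edges
  pos <- as.matrix(nodes[, c("x", "y", "z")])
  murray <- list(); angles <- list(); topo <- list()
  # topology: single parent, edges reference known ids, no cycles
  if (nrow(edges)) {
    if (any(!(edges$parent %in% nodes$id)) || any(!(edges$child %in% nodes$id)))
      topo[[length(topo) + 1L]] <- data.frame(kind = "dangling_edge")
    tab <- table(edges$child)
    multi <- names(tab)[tab > 1L]
    for (m in multi)
      topo[[length(topo) + 1L]] <- data.frame(kind = "multiple_parents",
                                              node = as.integer(m))
    roots <- setdiff(nodes$id, edges$child)
    if (length(roots) != 1L)
      topo[[length(topo) + 1L]] <- data.frame(kind = "root_count",
                                              node = length(roots))
    if (nrow(edges) != nrow(nodes) - 1L)
      topo[[length(topo) + 1L]] <- data.frame(kind = "edge_count",
                                              node = nrow(edges))
  }
  parent_of <- integer(nrow(nodes)); parent_of[] <- NA_integer_
  parent_of[edges$child] <- edges$parent
  radius_in <- numeric(nrow(nodes)); radius_in[] <- NA_real_
  radius_in[edges$child] <- edges$radius
  for (id in nodes$id[nodes$type == "bifurcation"]) {
    ch <- edges[edges$parent == id, ]
    if (nrow(ch) != 2L || is.na(radius_in[id])) next
    r_p <- radius_in[id]
    r1 <- ch$radius[1]; r2 <- ch$radius[2]
    res <- abs(r_p^gamma - r1^gamma - r2^gamma) / r_p^gamma
    if (res > tol)
      murray[[length(murray) + 1L]] <- data.frame(node = id, residual = res)
    # angle constraint: measured daughter angle vs the radii formula
    pdir <- pos[id, ] - pos[parent_of[id], ]
    pn <- sqrt(sum(pdir^2))
    if (pn > 0) {
      pdir <- pdir / pn
      r_l <- max(r1, r2); r_r <- min(r1, r2)
      phi <- bifurcation_angles(r_p, r_l, r_r)
      want <- if (r1 >= r2) phi else phi[c(2, 1)]
      for (q in 1:2) {
        cdir <- pos[ch$child[q], ] - pos[id, ]
        cn <- sqrt(sum(cdir^2))
        if (cn == 0) next
        resa <- abs(sum(pdir * cdir) / cn - cos(want[q]))
        if (resa > tol)
          angles[[length(angles) + 1L]] <-
            data.frame(node = id, child = ch$child[q], residual = resa)
      }
    }
  }
  oob <- nodes$id[pos[, 1] < 1 - tol | pos[, 1] > tree$shape[1] + tol |
                    pos[, 2] < 1 - tol | pos[, 2] > tree$shape[2] + tol |
                    pos[, 3] < 1 - tol | pos[, 3] > tree$shape[3] + tol]
  bind0 <- function(x, proto) if (length(x)) do.call(rbind, x) else proto
  out <- list(
    murray = bind0(murray, data.frame(node = integer(), residual = numeric())),
    angles = bind0(angles, data.frame(node = integer(), child = integer(),
                                      residual = numeric())),
    bounds = data.frame(node = oob),
    topology = bind0(topo, data.frame(kind = character())))
  out$n_violations <- nrow(out$murray) + nrow(out$angles) +
    nrow(out$bounds) + nrow(out$topology)
  out
}

#' Voxelize a vessel tree into a binary mask
#'
#' Each segment is a capsule: a finite cylinder of the segment's radius
#' with hemispherical caps at the nodes. A voxel is foreground iff its
#' center lies within the radius of some segment's axis; the mask is the
#' union over segments.
#'
#' @param tree a `vessel_tree`.
#' @param shape volume shape (defaults to the tree's).
#' @return A logical 3-D array.
#' @export
voxelize <- function(tree, shape = tree$shape) {
  stopifnot(inherits(tree, "vessel_tree"))
  shape <- as.integer(check_shape(shape, "shape"))
  mask <- array(FALSE, shape)
  if (!nrow(tree$edges)) return(mask)
  pos <- as.matrix(tree$nodes[, c("x", "y", "z")])
  for (e in seq_len(nrow(tree$edges))) {
    p1 <- pos[tree$edges$parent[e], ]
    p2 <- pos[tree$edges$child[e], ]
    mask <- cpp_capsule_fill(mask, shape, p1, p2, tree$edges$radius[e])
  }
  mask
}

# 26-connected rasterisation of one segment; returns integer voxel rows
raster_segment <- function(p1, p2) {
  n <- max(1L, ceiling(max(abs(p2 - p1))))
  t <- seq(0, 1, length.out = n + 1L)
  unique(cbind(round(p1[1] + t * (p2[1] - p1[1])),
               round(p1[2] + t * (p2[2] - p1[2])),
               round(p1[3] + t * (p2[3] - p1[3]))))
}

#' Rasterize the centerline of a vessel tree
#'
#' 26-connected line rasterisation of every segment axis (consecutive
#' voxels differ by at most one along each axis). Contained in the
#' [voxelize()] mask whenever radii are at least `sqrt(3)/2` voxels (the
#' worst-case rounding distance of a diagonal line); thinner segments can
#' place isolated line voxels just outside their capsule.
#'
#' @inheritParams voxelize
#' @return A logical 3-D array.
#' @export
rasterize_centerline <- function(tree, shape = tree$shape) {
  stopifnot(inherits(tree, "vessel_tree"))
  shape <- as.integer(check_shape(shape, "shape"))
  mask <- array(FALSE, shape)
  if (!nrow(tree$edges)) return(mask)
  pos <- as.matrix(tree$nodes[, c("x", "y", "z")])
  for (e in seq_len(nrow(tree$edges))) {
    pts <- raster_segment(pos[tree$edges$parent[e], ],
                          pos[tree$edges$child[e], ])
    ok <- pts[, 1] >= 1 & pts[, 1] <= shape[1] &
      pts[, 2] >= 1 & pts[, 2] <= shape[2] &
      pts[, 3] >= 1 & pts[, 3] <= shape[3]
    mask[pts[ok, , drop = FALSE]] <- TRUE
  }
  mask
}

#' Cube labels around bifurcation nodes
#'
#' Marks an odd-sided cube centered on the voxel nearest each bifurcation
#' node, clipped at the volume boundary. Detection networks are trained
#' to predict this neighbourhood cube rather than the single point.
#'
#' @inheritParams voxelize
#' @param cube odd cube side, default 5.
#' @return A logical 3-D array.
#' @export
bifurcation_mask <- function(tree, shape = tree$shape, cube = 5) {
  stopifnot(inherits(tree, "vessel_tree"))
  shape <- as.integer(check_shape(shape, "shape"))
  if (cube < 1 || cube %% 2 == 0)
    stop("`cube` must be odd and >= 1", call. = FALSE)
  mask <- array(FALSE, shape)
  h <- (cube - 1L) %/% 2L
  bif <- tree$nodes[tree$nodes$type == "bifurcation", , drop = FALSE]
  for (b in seq_len(nrow(bif))) {
    c0 <- round(c(bif$x[b], bif$y[b], bif$z[b]))
    rng <- lapply(1:3, function(a)
      max(1L, c0[a] - h):min(shape[a], c0[a] + h))
    mask[rng[[1]], rng[[2]], rng[[3]]] <- TRUE
  }
  mask
}

#' Render a vessel mask into a noisy intensity image
#'
#' Draws one vessel intensity (uniform on the vessel interval) and one
#' background intensity per volume, then adds Gaussian noise with a
#' per-volume mean offset and standard deviation `max(0, base_sd +
#' offset)`. The result is clipped to `[0, 255]`.
#'
#' @param vessel_mask logical 3-D array.
#' @param config a [synth_config()].
#' @param seed integer seed (defaults to `config$seed`).
#' @param noise set `FALSE` for a clean two-valued image.
#' @return A `volume3d` image.
#' @export
render_intensities <- function(vessel_mask, config, seed = config$seed,
                               noise = TRUE) {
  stopifnot(inherits(config, "synth_config"))
  mask <- vol_data(vessel_mask)
  local_seed(seed, {
    fg <- stats::runif(1, config$vessel_intensity[1],
                       config$vessel_intensity[2])
    bg <- stats::runif(1, config$background_intensity[1],
                       config$background_intensity[2])
    img <- array(bg, dim(mask))
    img[mask > 0] <- fg
    if (noise) {
      mu <- stats::runif(1, config$noise_mean[1], config$noise_mean[2])
      sd <- max(0, config$base_sd + stats::runif(1, config$noise_sd_offset[1],
                                                 config$noise_sd_offset[2]))
      img <- img + stats::rnorm(length(img), mu, sd)
    }
    volume3d(array(pmin(255, pmax(0, img)), dim(mask)))
  })
}

labeled_volume <- function(image, vessel_mask, centerline_mask,
                           bifurcation_mask, tree, fractions) {
  structure(list(image = image, vessel_mask = vessel_mask,
                 centerline_mask = centerline_mask,
                 bifurcation_mask = bifurcation_mask,
                 tree = tree, fractions = fractions),
            class = "labeled_volume")
}

#' @export
print.labeled_volume <- function(x, ...) {
  cat("<labeled_volume> ", paste(dim(x$vessel_mask), collapse = " x "),
      sprintf(" voxels; class fractions: vessel %.3f%%, centerline %.3f%%, bifurcation %.3f%%\n",
              100 * x$fractions["vessel"], 100 * x$fractions["centerline"],
              100 * x$fractions["bifurcation"]), sep = "")
  invisible(x)
}

#' Generate a labelled synthetic dataset
#'
#' For each volume: sample a tree, voxelize the vessel mask, rasterize
#' the centerline, label bifurcation cubes and render a noisy image.
#' Volume `v` uses seed `seed + v - 1`, so regeneration with the same
#' `(config, seed)` is bit-identical and individual volumes can be
#' reproduced in isolation. The centerline label is intersected with the
#' vessel mask so the label hierarchy (centerline inside vessel) holds
#' even for sub-voxel radii.
#'
#' @param config a [synth_config()].
#' @param n_volumes number of volumes.
#' @param seed base seed (defaults to `config$seed`).
#' @return A list of `labeled_volume` objects, each carrying the image
#'   (`volume3d`), the three binary masks, the source tree and the
#'   per-volume class fractions.
#' @export
generate_dataset <- function(config, n_volumes, seed = config$seed) {
  stopifnot(inherits(config, "synth_config"), n_volumes >= 1)
  lapply(seq_len(n_volumes), function(v) {
    sv <- as.integer(seed) + v - 1L
    tree <- sample_tree(config, seed = sv)
    vm <- voxelize(tree)
    cm <- rasterize_centerline(tree) & vm
    bm <- bifurcation_mask(tree, cube = config$bifurcation_cube)
    img <- render_intensities(vm, config, seed = sv)
    labeled_volume(img, vm, cm, bm, tree,
                   c(vessel = mean(vm), centerline = mean(cm),
                     bifurcation = mean(bm)))
  })
}
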