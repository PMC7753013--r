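#' Cross-hair kernel: three orthogonal 2-D filters
#'
#' A cross-hair filter approximates a dense 3-D convolution kernel of shape
#' `(k_x, k_y, k_z)` by three intersecting 2-D kernels applied on the
#' orthogonal planes through each voxel: `M_i` (k_y x k_z, the plane at
#' fixed sagittal index), `M_j` (k_x x k_z) and `M_k` (k_x x k_y). The
#' three plane responses are summed with weights `beta = (beta_c, beta_s,
#' beta_a)`, all 1 by default; the weights are exposed for anisotropic
#' voxel grids.
#'
#' @param M_i numeric matrix, `k_y x k_z`.
#' @param M_j numeric matrix, `k_x x k_z`.
#' @param M_k numeric matrix, `k_x x k_y`.
#' @param beta numeric length-3 plane weights `(beta_c, beta_s, beta_a)`
#'   applied to the `M_i`, `M_j`, `M_k` responses respectively.
#' @return A `crosshair_kernel` object with fields `M_i`, `M_j`, `M_k`,
#'   `beta` and the implied 3-D shape `kshape = (k_x, k_y, k_z)`.
#' @examples
#' K <- crosshair_kernel(matrix(1, 3, 3), matrix(1, 3, 3), matrix(1, 3, 3))
#' K$kshape
#' @export
crosshair_kernel <- function(M_i, M_j, M_k, beta = c(1, 1, 1)) {
  M_i <- as.matrix(M_i); M_j <- as.matrix(M_j); M_k <- as.matrix(M_k)
  kx <- nrow(M_j); ky <- nrow(M_i); kz <- ncol(M_i)
  if (nrow(M_k) != kx || ncol(M_j) != kz || ncol(M_k) != ky)
    stop("plane shapes inconsistent: need M_i (ky x kz), M_j (kx x kz), ",
         "M_k (kx x ky)", call. = FALSE)
  beta <- as.numeric(beta)
  if (length(beta) != 3L || any(!is.finite(beta)))
    stop("`beta` must be 3 finite numbers", call. = FALSE)
  structure(list(M_i = M_i, M_j = M_j, M_k = M_k, beta = beta,
                 kshape = c(kx, ky, kz)),
            class = "crosshair_kernel")
}

check_kernel_fits <- function(vshape, kshape) {
  if (any(kshape > vshape))
    stop("kernel shape (", paste(kshape, collapse = ","),
         ") exceeds volume shape (", paste(vshape, collapse = ","), ")",
         call. = FALSE)
}

#' Full (dense) 3-D convolution
#'
#' Same-size zero-padded 3-D convolution of a volume with a dense kernel.
#' Each output voxel is the sum over kernel positions of
#' `I[i + r - 1 - floor(k_x/2), ...] * M[r, s, t]` (greatest-integer
#' centering; contributions falling outside the volume are zero). This is
#' the exact operator that cross-hair filtering approximates, and it is
#' kept as the reference implementation.
#'
#' @param I a `volume3d` or 3-D array.
#' @param M numeric 3-D array (a 1- or 2-D kernel is promoted), no larger
#'   than the volume along any axis.
#' @return A `volume3d` the same shape (and spacing) as the input.
#' @examples
#' I <- array(rnorm(6^3), c(6, 6, 6))
#' M <- array(rnorm(27), c(3, 3, 3))
#' out <- convolve_full(I, M)
#' @export
convolve_full <- function(I, M) {
  v <- as_volume3d(I)
  M <- as.array(M)
  kd <- dim(M)
  if (length(kd) < 3L) kd <- c(kd, rep(1L, 3L - length(kd)))
  dim(M) <- kd
  check_kernel_fits(dim(v$data), kd)
  out <- cpp_conv3(as.numeric(v$data), as.integer(dim(v$data)),
                   as.numeric(M), as.integer(kd))
  volume3d(out, v$spacing)
}

#' Cross-hair convolution, literal per-voxel form
#'
#' Evaluates the cross-hair approximation voxel by voxel in plain R:
#' for each output voxel the three 2-D plane sums are accumulated directly
#' from their definition. This form is deliberately naive -- it exists as
#' the independent oracle for [convolve_crosshair()] and is far too slow
#' for real volumes.
#'
#' @param I a `volume3d` or 3-D array.
#' @param K a [crosshair_kernel()].
#' @return A `volume3d` of the same shape.
#' @export
convolve_crosshair_pointwise <- function(I, K) {
  v <- as_volume3d(I)
  stopifnot(inherits(K, "crosshair_kernel"))
  d <- dim(v$data)
  check_kernel_fits(d, K$kshape)
  kx <- K$kshape[1]; ky <- K$kshape[2]; kz <- K$kshape[3]
  ox <- kx %/% 2; oy <- ky %/% 2; oz <- kz %/% 2
  A <- array(0, d)
  X <- v$data
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    acc_i <- 0; acc_j <- 0; acc_k <- 0
    for (s in 1:ky) for (t in 1:kz) {
      S <- j + s - 1L - oy; T <- k + t - 1L - oz
      if (S >= 1 && S <= d[2] && T >= 1 && T <= d[3])
        acc_i <- acc_i + X[i, S, T] * K$M_i[s, t]
    }
    for (r in 1:kx) for (t in 1:kz) {
      R <- i + r - 1L - ox; T <- k + t - 1L - oz
      if (R >= 1 && R <= d[1] && T >= 1 && T <= d[3])
        acc_j <- acc_j + X[R, j, T] * K$M_j[r, t]
    }
    for (r in 1:kx) for (s in 1:ky) {
      R <- i + r - 1L - ox; S <- j + s - 1L - oy
      if (R >= 1 && R <= d[1] && S >= 1 && S <= d[2])
        acc_k <- acc_k + X[R, S, k] * K$M_k[r, s]
    }
    A[i, j, k] <- K$beta[1] * acc_i + K$beta[2] * acc_j + K$beta[3] * acc_k
  }
  volume3d(A, v$spacing)
}

#' Cross-hair convolution, efficient slice-stack form
#'
#' Efficient implementation of the cross-hair operator: each 2-D plane
#' kernel is applied to the whole volume as a stack of 2-D convolutions
#' (realised as a 3-D convolution with a kernel that is flat along the
#' remaining axis), and the three plane responses are summed with the
#' `beta` weights. Only one response volume is held at a time. Numerically
#' equal to [convolve_crosshair_pointwise()].
#'
#' @inheritParams convolve_crosshair_pointwise
#' @return A `volume3d` of the same shape.
#' @examples
#' I <- array(rnorm(8^3), c(8, 8, 8))
#' K <- crosshair_kernel(matrix(rnorm(9), 3), matrix(rnorm(9), 3),
#'                       matrix(rnorm(9), 3))
#' out <- convolve_crosshair(I, K)
#' @export
convolve_crosshair <- function(I, K) {
  v <- as_volume3d(I)
  stopifnot(inherits(K, "crosshair_kernel"))
  d <- as.integer(dim(v$data))
  check_kernel_fits(d, K$kshape)
  kx <- K$kshape[1]; ky <- K$kshape[2]; kz <- K$kshape[3]
  x <- as.numeric(v$data)
  acc <- K$beta[1] * cpp_conv3(x, d, as.numeric(K$M_i),
                               as.integer(c(1L, ky, kz)))
  acc <- acc + K$beta[2] * cpp_conv3(x, d, as.numeric(K$M_j),
                                     as.integer(c(kx, 1L, kz)))
  acc <- acc + K$beta[3] * cpp_conv3(x, d, as.numeric(K$M_k),
                                     as.integer(c(kx, ky, 1L)))
  dim(acc) <- d
  volume3d(acc, v$spacing)
}

#' Embed a cross-hair kernel in a dense 3-D kernel
#'
#' Returns the dense `(k_x, k_y, k_z)` kernel whose support is exactly the
#' three orthogonal planes of the cross-hair filter (beta weights folded
#' in). Convolving with the embedding via [convolve_full()] reproduces
#' [convolve_crosshair()]; used for cross-checking the operator and the
#' layer implementation against dense convolution.
#'
#' @param K a [crosshair_kernel()].
#' @return A numeric 3-D array.
#' @export
crosshair_embed <- function(K) {
  stopifnot(inherits(K, "crosshair_kernel"))
  kx <- K$kshape[1]; ky <- K$kshape[2]; kz <- K$kshape[3]
  E <- array(0, c(kx, ky, kz))
  cx <- kx %/% 2 + 1L; cy <- ky %/% 2 + 1L; cz <- kz %/% 2 + 1L
  E[cx, , ] <- E[cx, , ] + K$beta[1] * K$M_i
  E[, cy, ] <- E[, cy, ] + K$beta[2] * K$M_j
  E[, , cz] <- E[, , cz] + K$beta[3] * K$M_k
  E
}

op_count_report <- function(mult, add, per_voxel) {
  structure(list(multiplications = mult, additions = add,
                 per_voxel = per_voxel),
            class = "op_count_report")
}

#' @export
print.op_count_report <- function(x, ...) {
  cat("<op_count_report> ", format(x$multiplications, big.mark = ","),
      " multiplications, ", format(x$additions, big.mark = ","),
      " additions", if (x$per_voxel) " per voxel", "\n", sep = "")
  invisible(x)
}

check_shape <- function(shape, name) {
  shape <- as.numeric(shape)
  if (length(shape) != 3L || any(shape < 1) || any(shape != round(shape)))
    stop("`", name, "` must be 3 positive integers", call. = FALSE)
  shape
}

#' Operation count of a dense 3-D convolution
#'
#' Closed-form cost model: a dense `(k_x, k_y, k_z)` kernel costs
#' `k_x*k_y*k_z` multiplications and one fewer addition per output voxel;
#' whole-volume totals scale by the voxel count.
#'
#' @param kernel_shape integer length-3 kernel shape.
#' @param volume_shape optional integer length-3 volume shape; when given,
#'   whole-volume totals are reported instead of per-voxel counts.
#' @return An `op_count_report` with `multiplications`, `additions` and a
#'   `per_voxel` flag.
#' @examples
#' count_ops_full(c(3, 3, 3))               # 27 / 26 per voxel
#' count_ops_full(c(5, 5, 5), c(128, 128, 128))
#' @export
count_ops_full <- function(kernel_shape, volume_shape = NULL) {
  k <- check_shape(kernel_shape, "kernel_shape")
  m <- prod(k)
  if (is.null(volume_shape)) return(op_count_report(m, m - 1, TRUE))
  v <- prod(check_shape(volume_shape, "volume_shape"))
  op_count_report(m * v, (m - 1) * v, FALSE)
}

#' Operation count of a cross-hair convolution
#'
#' Closed-form cost model for the three-plane approximation:
#' `k_y*k_z + k_x*k_z + k_x*k_y` multiplications and one fewer addition
#' per output voxel.
#'
#' @inheritParams count_ops_full
#' @return An `op_count_report`.
#' @examples
#' count_ops_crosshair(c(5, 5, 5))          # 75 / 74 per voxel
#' @export
count_ops_crosshair <- function(kernel_shape, volume_shape = NULL) {
  k <- check_shape(kernel_shape, "kernel_shape")
  m <- k[2] * k[3] + k[1] * k[3] + k[1] * k[2]
  if (is.null(volume_shape)) return(op_count_report(m, m - 1, TRUE))
  v <- prod(check_shape(volume_shape, "volume_shape"))
  op_count_report(m * v, (m - 1) * v, FALSE)
}

#' Verify the cross-hair operation-count inequality
#'
#' For kernel sides sorted as `k_m1 >= k_m2 >= k_m3`, checks the chain
#' `k_y k_z + k_x k_z + k_x k_y <= 3 k_m1 k_m2 <= k_x k_y k_z`. The first
#' inequality always holds; the second holds if and only if the smallest
#' side is at least 3, with strict inequality exactly when it exceeds 3.
#'
#' @param kernel_shape integer length-3 kernel shape.
#' @return A list with the three counts (`crosshair`, `bound`, `full`),
#'   logicals `holds_first`, `holds_second`, `holds` (both) and `strict`
#'   (strict second inequality), and `margin = full - crosshair`.
#' @examples
#' verify_count_inequality(c(5, 5, 5))  # 75 <= 75 < 125, strict overall
#' @export
verify_count_inequality <- function(kernel_shape) {
  k <- check_shape(kernel_shape, "kernel_shape")
  ks <- sort(k, decreasing = TRUE)
  ch <- k[2] * k[3] + k[1] * k[3] + k[1] * k[2]
  bound <- 3 * ks[1] * ks[2]
  full <- prod(k)
  list(crosshair = ch, bound = bound, full = full,
       holds_first = ch <= bound,
       holds_second = bound <= full,
       holds = ch <= bound && bound <= full,
       strict = bound < full,
       margin = full - ch)
}
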