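#' 3-D scalar volume
#'
#' Light container for a 3-D scalar grid: a numeric array plus a voxel
#' spacing. Used as the carrier for images, probability maps and binary
#' masks throughout the package. Most functions also accept a plain 3-D
#' array and coerce it with [as_volume3d()].
#'
#' @param data numeric 3-D array with finite values.
#' @param spacing numeric length-3 voxel spacing (defaults to isotropic 1).
#' @return An object of class `volume3d`: a list with elements `data`
#'   (3-D array) and `spacing`.
#' @examples
#' v <- volume3d(array(0, c(4, 4, 4)))
#' dim(v$data)
#' @export
volume3d <- function(data, spacing = c(1, 1, 1)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L)
    stop("`data` must be a 3-D array, got ", length(dim(data)),
         " dimensions", call. = FALSE)
  if (any(dim(data) < 1L)) stop("all dimensions must be >= 1", call. = FALSE)
  if (!all(is.finite(data))) stop("`data` must be finite", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive numbers", call. = FALSE)
  structure(list(data = data, spacing = spacing), class = "volume3d")
}

#' Coerce to a `volume3d`
#'
#' @param x a `volume3d` or a 3-D numeric array.
#' @param spacing spacing used when `x` is a bare array.
#' @return A `volume3d`.
#' @export
as_volume3d <- function(x, spacing = c(1, 1, 1)) {
  if (inherits(x, "volume3d")) return(x)
  volume3d(x, spacing)
}

#' @export
print.volume3d <- function(x, ...) {
  cat("<volume3d> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing (", paste(format(x$spacing), collapse = ", "),
      "), range [", format(min(x$data)), ", ", format(max(x$data)), "]\n",
      sep = "")
  invisible(x)
}

#' @export
dim.volume3d <- function(x) dim(x$data)

# internal: extract the data array from a volume3d or array
vol_data <- function(x) {
  if (inherits(x, "volume3d")) x$data else as.array(x)
}
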