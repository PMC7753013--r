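#' @name nifti_io
#' @title Minimal NIfTI-1 volume input/output
#'
#' @description
#' Reader and writer for single-file NIfTI-1 volumes (`.nii`, `.nii.gz`),
#' the standard interchange format for angiographic volumes. Only the
#' subset this package needs is implemented: 3-D volumes, scalar dtypes
#' (uint8, int16, int32, float32, float64), voxel spacing via `pixdim`,
#' and a diagonal sform. Round-trips preserve data, shape and spacing
#' bit-exactly for the supported dtypes. No reorientation is performed:
#' array axis order maps to NIfTI voxel axes directly.
NULL

nifti_dtypes <- list(
  uint8   = list(code = 2L,  bitpix = 8L),
  int16   = list(code = 4L,  bitpix = 16L),
  int32   = list(code = 8L,  bitpix = 32L),
  float32 = list(code = 16L, bitpix = 32L),
  float64 = list(code = 64L, bitpix = 64L))

is_gz <- function(path) grepl("\\.gz$", path, ignore.case = TRUE)

#' Write a volume as NIfTI-1
#'
#' @param volume a `volume3d` or 3-D array (logical masks are coerced).
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @param datatype on-disk scalar type: `"float32"` (default for
#'   images), `"uint8"` (masks), `"int16"`, `"int32"` or `"float64"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, datatype = "float32") {
  v <- as_volume3d(if (is.logical(volume)) array(as.integer(volume),
                                                 dim(volume)) else volume)
  dt <- nifti_dtypes[[match.arg(datatype, names(nifti_dtypes))]]
  d <- dim(v$data)
  con <- if (is_gz(path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L,
                             endian = "little")
  wi(348L, 4L)                                   # sizeof_hdr
  writeBin(raw(36L), con)                        # data_type..dim_info
  wi(c(3L, d, 1L, 1L, 1L, 1L), 2L)               # dim[8]
  writeBin(raw(14L), con)                        # intent_p*, intent_code
  wi(dt$code, 2L); wi(dt$bitpix, 2L); wi(0L, 2L) # datatype, bitpix, slice_start
  wf(c(1, v$spacing, 1, 1, 1, 1))                # pixdim[8] (qfac = 1)
  wf(352); wf(1); wf(0)                          # vox_offset, scl_slope/inter
  wi(0L, 2L); writeBin(raw(2L), con)             # slice_end, slice_code, units
  wf(c(0, 0, 0, 0)); wi(c(0L, 0L), 4L)           # cal/slice_dur/toffset, gl*
  writeBin(raw(104L), con)                       # descrip, aux_file
  wi(c(0L, 1L), 2L)                              # qform_code 0, sform_code 1
  wf(rep(0, 6))                                  # quatern, qoffset
  wf(c(v$spacing[1], 0, 0, 0))                   # srow_x
  wf(c(0, v$spacing[2], 0, 0))                   # srow_y
  wf(c(0, 0, v$spacing[3], 0))                   # srow_z
  writeBin(raw(16L), con)                        # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0L)), con) # magic
  writeBin(raw(4L), con)                         # extension flag
  x <- as.numeric(v$data)
  if (dt$code %in% c(2L, 4L, 8L))
    writeBin(as.integer(round(x)), con, size = dt$bitpix %/% 8L,
             endian = "little")
  else writeBin(x, con, size = dt$bitpix %/% 8L, endian = "little")
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' @param path a `.nii` or `.nii.gz` file.
#' @return A `volume3d` with the voxel data and the `pixdim` spacing.
#' @export
read_volume <- function(path) {
  if (!file.exists(path))
    stop("volume file not found: ", path, call. = FALSE)
  con <- if (is_gz(path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  raw4 <- readBin(con, "raw", 4L)
  if (length(raw4) < 4L)
    stop("not a NIfTI-1 file (too short): ", path, call. = FALSE)
  endian <- if (identical(readBin(raw4, "integer", 1L, size = 4L,
                                  endian = "little"), 348L)) "little"
  else if (identical(readBin(raw4, "integer", 1L, size = 4L,
                             endian = "big"), 348L)) "big"
  else stop("not a NIfTI-1 file (bad header size): ", path, call. = FALSE)
  readBin(con, "raw", 36L)
  dims <- readBin(con, "integer", 8L, size = 2L, endian = endian)
  if (dims[1] < 1L || dims[1] > 7L)
    stop("malformed NIfTI header (dim[0] = ", dims[1], "): ", path,
         call. = FALSE)
  readBin(con, "raw", 14L)
  datatype <- readBin(con, "integer", 1L, size = 2L, endian = endian)
  readBin(con, "raw", 4L)  # bitpix, slice_start
  pixdim <- readBin(con, "numeric", 8L, size = 4L, endian = endian)
  vox_offset <- readBin(con, "numeric", 1L, size = 4L, endian = endian)
  scl_slope <- readBin(con, "numeric", 1L, size = 4L, endian = endian)
  scl_inter <- readBin(con, "numeric", 1L, size = 4L, endian = endian)
  readBin(con, "raw", as.integer(vox_offset) - 120L)
  d <- dims[2:4]
  if (dims[1] < 3L) d[seq.int(dims[1] + 1L, 3L)] <- 1L
  n <- prod(d)
  x <- switch(as.character(datatype),
              "2" = readBin(con, "integer", n, size = 1L, signed = FALSE),
              "4" = readBin(con, "integer", n, size = 2L, endian = endian),
              "8" = readBin(con, "integer", n, size = 4L, endian = endian),
              "16" = readBin(con, "numeric", n, size = 4L, endian = endian),
              "64" = readBin(con, "numeric", n, size = 8L, endian = endian),
              stop("unsupported NIfTI datatype code ", datatype, ": ", path,
                   call. = FALSE))
  if (length(x) < n)
    stop("truncated NIfTI data: ", path, call. = FALSE)
  x <- as.numeric(x)
  if (scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    x <- x * scl_slope + scl_inter
  volume3d(array(x, d), pixdim[2:4])
}

#' Write a vessel tree as a JSON document
#'
#' Nodes (`id, x, y, z, type`), edges (`parent, child, radius`) and
#' metadata (`gamma`, volume `shape`); the round-trip through
#' [read_tree()] is lossless.
#'
#' @param tree a `vessel_tree`.
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
write_tree <- function(tree, path) {
  stopifnot(inherits(tree, "vessel_tree"))
  jsonlite::write_json(
    list(nodes = tree$nodes, edges = tree$edges,
         metadata = list(gamma = tree$gamma, shape = tree$shape)),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a vessel tree from JSON
#'
#' @param path a `.json` file written by [write_tree()] (or matching its
#'   schema).
#' @return A `vessel_tree`.
#' @export
read_tree <- function(path) {
  if (!file.exists(path))
    stop("tree file not found: ", path, call. = FALSE)
  doc <- jsonlite::fromJSON(path)
  nodes <- as.data.frame(doc$nodes)
  edges <- as.data.frame(doc$edges)
  if (nrow(nodes) == 0L)
    nodes <- data.frame(id = integer(), x = numeric(), y = numeric(),
                        z = numeric(), type = character())
  if (nrow(edges) == 0L)
    edges <- data.frame(parent = integer(), child = integer(),
                        radius = numeric())
  need <- c("id", "x", "y", "z", "type")
  if (!all(need %in% names(nodes)))
    stop("tree schema error: nodes need fields ",
         paste(need, collapse = ", "), call. = FALSE)
  if (anyDuplicated(nodes$id))
    stop("tree schema error: duplicate node ids", call. = FALSE)
  bad <- setdiff(unique(nodes$type),
                 c("root", "leaf", "bifurcation", "inter"))
  if (length(bad))
    stop("tree schema error: unknown node type(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (nrow(edges) &&
      (any(!(edges$parent %in% nodes$id)) ||
       any(!(edges$child %in% nodes$id))))
    stop("tree schema error: edge references unknown node id",
         call. = FALSE)
  md <- doc$metadata
  vessel_tree(nodes, edges,
              gamma = if (!is.null(md$gamma)) md$gamma else 3,
              shape = if (!is.null(md$shape)) md$shape else
                c(max(c(1, ceiling(nodes$x))), max(c(1, ceiling(nodes$y))),
                  max(c(1, ceiling(nodes$z)))))
}

#' Load a validated configuration from JSON
#'
#' The file holds a flat object of configuration keys plus an optional
#' `"type"` field (`"synth"` or `"train"`). Missing keys take the
#' defaults of [synth_config()] / [train_config()]; unknown keys are
#' rejected; values are validated by the constructors. An empty file
#' yields the full default configuration.
#'
#' @param path JSON file.
#' @param type `"synth"` or `"train"`; inferred from the file's `type`
#'   field when omitted.
#' @return A `synth_config` or `train_config`.
#' @export
load_config <- function(path, type = NULL) {
  if (!file.exists(path))
    stop("config file not found: ", path, call. = FALSE)
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  doc <- if (nchar(trimws(txt)) == 0) list() else
    jsonlite::fromJSON(txt, simplifyVector = TRUE)
  if (is.null(type)) type <- doc$type
  if (is.null(type))
    stop("config type not given and no `type` field in ", path,
         call. = FALSE)
  type <- match.arg(type, c("synth", "train"))
  doc$type <- NULL
  ctor <- if (type == "synth") synth_config else train_config
  known <- names(formals(ctor))
  unknown <- setdiff(names(doc), known)
  if (length(unknown))
    stop("unknown config key(s) in ", path, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  do.call(ctor, doc)
}

#' Save a configuration as JSON
#'
#' @param config a `synth_config` or `train_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  type <- if (inherits(config, "synth_config")) "synth" else
    if (inherits(config, "train_config")) "train" else
      stop("not a config object", call. = FALSE)
  jsonlite::write_json(c(list(type = type), unclass(config)), path,
                       digits = NA, auto_unbox = FALSE)
  invisible(path)
}

# stable hash of an R object via its canonical JSON serialisation
config_hash <- function(x) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(x, tf, digits = NA, auto_unbox = FALSE)
  unname(tools::md5sum(tf))
}

#' Write a run manifest
#'
#' Records tool version, configuration hash, seeds, per-volume class
#' fractions and a timestamp next to generated artifacts, so a run can
#' be reproduced exactly from its manifest inputs.
#'
#' @param path output JSON path.
#' @param config the configuration used.
#' @param seed the seed used.
#' @param extra named list of additional fields (e.g. class fractions).
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(path, config, seed, extra = list()) {
  m <- c(list(tool = "dvn",
              version = as.character(utils::packageVersion("dvn")),
              config_hash = config_hash(unclass(config)),
              seed = seed,
              created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
         extra)
  jsonlite::write_json(m, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(m)
}

#' Save a trained model to a single JSON file
#'
#' Stores the layer specifications, all weights at full precision, the
#' build seed and the spec hash.
#'
#' @param model a `dvn_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "dvn_model"))
  layers <- lapply(model$layers, function(lw) {
    out <- list(spec = unclass(lw$spec), b = lw$b)
    for (nm in intersect(names(lw), c("W", "Wi", "Wj", "Wk"))) {
      out[[nm]] <- list(dim = dim(lw[[nm]]), values = as.numeric(lw[[nm]]))
    }
    if (!is.null(lw$beta)) out$beta <- lw$beta
    out
  })
  jsonlite::write_json(list(seed = model$seed, layers = layers,
                            spec_hash = config_hash(lapply(
                              model$spec$layers, unclass))),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load a model saved by [save_model()]
#'
#' @param path JSON model file.
#' @return A `dvn_model`.
#' @export
load_model <- function(path) {
  if (!file.exists(path))
    stop("model file not found: ", path, call. = FALSE)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  layers <- lapply(doc$layers, function(ld) {
    sp <- ld$spec
    ls <- layer_spec(sp$in_channels, sp$out_channels,
                     unlist(sp$kernel), sp$mode, sp$activation)
    lw <- list()
    for (nm in intersect(names(ld), c("W", "Wi", "Wj", "Wk")))
      lw[[nm]] <- array(unlist(ld[[nm]]$values), unlist(ld[[nm]]$dim))
    if (!is.null(ld$beta)) lw$beta <- unlist(ld$beta)
    lw$b <- unlist(ld$b)
    lw$spec <- ls
    structure(lw, class = "dvn_layer")
  })
  specs <- lapply(layers, `[[`, "spec")
  spec <- structure(list(layers = specs), class = "network_spec")
  structure(list(spec = spec, layers = layers,
                 seed = as.integer(doc$seed)),
            class = "dvn_model")
}
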