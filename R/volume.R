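#' Grayscale 3D volume
#'
#' The carrier object of the processing chain: a 3D numeric array with a
#' voxel size in micrometers and a nominal bit depth. Arrays are stored in
#' R's column-major order with `dim = c(nx, ny, nz)`, so `v$data[x, y, z]`
#' addresses column `x`, row `y` of slice `z`. Slice `z = 1` is the top of
#' the pot; the stack is explored downwards along z.
#'
#' @param data 3D numeric array; all values must lie in
#'   `[0, 2^bit_depth - 1]`.
#' @param voxel_size_um positive voxel edge length in micrometers
#'   (45 for the benchmark scans this workflow was designed around).
#' @param bit_depth 8 or 16.
#' @return An object of class `gray_volume`.
#' @export
gray_volume <- function(data, voxel_size_um = 45, bit_depth = 8L) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("not a 3D volume: `data` must be a 3D array", call. = FALSE)
  if (!is.numeric(voxel_size_um) || length(voxel_size_um) != 1L ||
      voxel_size_um <= 0)
    stop("`voxel_size_um` must be a positive scalar", call. = FALSE)
  if (!bit_depth %in% c(8L, 16L))
    stop("unsupported bit depth: ", bit_depth, call. = FALSE)
  storage.mode(data) <- "double"
  rng <- range(data)
  if (rng[1] < 0 || rng[2] > 2^bit_depth - 1)
    stop("values outside [0, ", 2^bit_depth - 1, "] for bit depth ",
         bit_depth, call. = FALSE)
  structure(list(data = data, voxel_size_um = as.numeric(voxel_size_um),
                 bit_depth = as.integer(bit_depth)),
            class = "gray_volume")
}

#' Binary 3D volume
#'
#' Carrier of segmentation results; foreground (`TRUE`) marks root
#' candidate voxels. Same shape contract as [gray_volume()].
#'
#' @param data 3D logical array.
#' @param voxel_size_um positive voxel edge length in micrometers.
#' @return An object of class `binary_volume`.
#' @export
binary_volume <- function(data, voxel_size_um = 45) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("not a 3D volume: `data` must be a 3D array", call. = FALSE)
  if (!is.logical(data)) {
    if (!all(data %in% c(0, 1)))
      stop("`data` must be logical (or 0/1)", call. = FALSE)
    data <- array(as.logical(data), dim(data))
  }
  if (!is.numeric(voxel_size_um) || length(voxel_size_um) != 1L ||
      voxel_size_um <= 0)
    stop("`voxel_size_um` must be a positive scalar", call. = FALSE)
  structure(list(data = data, voxel_size_um = as.numeric(voxel_size_um)),
            class = "binary_volume")
}

#' @export
print.gray_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<gray_volume> %d x %d x %d, %d-bit, voxel %.4g um, GV [%g, %g]\n",
              d[1], d[2], d[3], x$bit_depth, x$voxel_size_um,
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.binary_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<binary_volume> %d x %d x %d, voxel %.4g um, %d foreground voxels\n",
              d[1], d[2], d[3], x$voxel_size_um, sum(x$data)))
  invisible(x)
}

is_gray_volume <- function(x) inherits(x, "gray_volume")
is_binary_volume <- function(x) inherits(x, "binary_volume")

vol_dim <- function(x) dim(x$data)

#' Read a 3D volume from disk
#'
#' Supports multipage TIFF stacks (one page per z slice, uncompressed,
#' 8- or 16-bit grayscale) and raw-encoded NRRD. TIFF carries no voxel
#' size, so it must be supplied (or defaults to 45 um); NRRD spacings are
#' honored when present.
#'
#' @param path file to read.
#' @param format `"auto"` (by extension), `"tiff"` or `"nrrd"`.
#' @param voxel_size_um voxel size used when the format does not carry one.
#' @return A [gray_volume()].
#' @export
read_volume <- function(path, format = c("auto", "tiff", "nrrd"),
                        voxel_size_um = 45) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     tif = , tiff = "tiff",
                     nrrd = "nrrd",
                     stop("cannot infer format from extension of ", path,
                          call. = FALSE))
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "tiff") {
    r <- read_tiff_stack(path)
    gray_volume(r$data, voxel_size_um = voxel_size_um, bit_depth = r$bit_depth)
  } else {
    r <- read_nrrd(path)
    vs <- if (!is.null(r$voxel_size_um)) r$voxel_size_um else voxel_size_um
    gray_volume(r$data, voxel_size_um = vs, bit_depth = r$bit_depth)
  }
}

#' Write a 3D volume to disk
#'
#' Binary volumes are written as 8-bit with foreground 255.
#'
#' @param vol a [gray_volume()] or [binary_volume()].
#' @param path destination file.
#' @param format `"auto"` (by extension), `"tiff"` or `"nrrd"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, format = c("auto", "tiff", "nrrd")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     tif = , tiff = "tiff",
                     nrrd = "nrrd",
                     stop("cannot infer format from extension of ", path,
                          call. = FALSE))
  }
  if (is_binary_volume(vol)) {
    data <- array(ifelse(vol$data, 255, 0), dim(vol$data))
    bit_depth <- 8L
    vs <- vol$voxel_size_um
  } else if (is_gray_volume(vol)) {
    data <- round(vol$data)
    bit_depth <- vol$bit_depth
    vs <- vol$voxel_size_um
  } else stop("`vol` must be a gray_volume or binary_volume", call. = FALSE)
  if (format == "tiff") write_tiff_stack(data, path, bit_depth)
  else write_nrrd(data, path, bit_depth, voxel_size_um = vs)
  invisible(path)
}

#' Downscale a volume by block-mean pooling
#'
#' Each output voxel is the mean of the corresponding `factor^3` block
#' (anti-aliased pooling, not decimation); trailing voxels that do not fill
#' a complete block are dropped. The voxel size is multiplied by `factor`.
#' Used to process coarse roots at half resolution without significant
#' loss of information.
#'
#' @param vol a [gray_volume()].
#' @param factor positive integer block size.
#' @return A [gray_volume()] with each dimension `floor(n / factor)`.
#' @export
downscale <- function(vol, factor) {
  stopifnot(is_gray_volume(vol))
  factor <- as.integer(factor)
  if (factor < 1L) stop("`factor` must be >= 1", call. = FALSE)
  if (factor == 1L) return(vol)
  d <- vol_dim(vol)
  nd <- d %/% factor
  if (any(nd < 1L))
    stop("`factor` larger than a volume dimension", call. = FALSE)
  a <- vol$data[seq_len(nd[1] * factor), seq_len(nd[2] * factor),
                seq_len(nd[3] * factor), drop = FALSE]
  dim(a) <- c(factor, nd[1], factor, nd[2], factor, nd[3])
  a <- aperm(a, c(1, 3, 5, 2, 4, 6))
  dim(a) <- c(factor^3, prod(nd))
  out <- array(colMeans(a), nd)
  gray_volume(out, voxel_size_um = vol$voxel_size_um * factor,
              bit_depth = vol$bit_depth)
}

#' Upscale a binary mask by nearest-neighbor replication
#'
#' Inverse plumbing for [downscale()]: each mask voxel becomes a
#' `factor^3` block. The target shape may exceed the replicated extent by
#' up to `factor - 1` voxels per axis (the voxels dropped during
#' downscaling); these are padded with background.
#'
#' @param mask a [binary_volume()].
#' @param target_shape integer vector of length 3 (nx, ny, nz).
#' @return A [binary_volume()] of shape `target_shape`.
#' @export
upscale_mask <- function(mask, target_shape) {
  stopifnot(is_binary_volume(mask))
  d <- vol_dim(mask)
  target_shape <- as.integer(target_shape)
  factor <- as.integer(round(target_shape / d))
  if (length(unique(factor)) != 1L || any(factor < 1L) ||
      any(target_shape < d * factor[1]) ||
      any(target_shape >= d * (factor[1] + 1L)))
    stop("incompatible shapes: target must be ~ factor x mask shape",
         call. = FALSE)
  f <- factor[1]
  rep_d <- d * f
  out <- array(FALSE, target_shape)
  out[seq_len(rep_d[1]), seq_len(rep_d[2]), seq_len(rep_d[3])] <-
    mask$data[rep(seq_len(d[1]), each = f),
              rep(seq_len(d[2]), each = f),
              rep(seq_len(d[3]), each = f)]
  binary_volume(out, voxel_size_um = mask$voxel_size_um / f)
}
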