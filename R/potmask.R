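# Pot-wall masking: three user-supplied circular ROIs are linearly
# interpolated along z into a tilted cylindrical mask; an extended ROI
# (default +50 voxels) keeps the pot wall inside the histogram so the
# wall peak P1 and soil-matrix peak P2 can be located.

#' Circular region of interest on one slice
#'
#' @param z slice index (1-based).
#' @param cx,cy circle center in voxel coordinates.
#' @param r radius in voxels (> 0).
#' @return An object of class `circle_roi`.
#' @export
circle_roi <- function(z, cx, cy, r) {
  if (r <= 0) stop("`r` must be > 0", call. = FALSE)
  structure(list(z = as.numeric(z), cx = as.numeric(cx), cy = as.numeric(cy),
                 r = as.numeric(r)), class = "circle_roi")
}

#' Interpolate the pot-wall mask over all slices
#'
#' The bounded ROI (a circle inside the pot wall) is defined manually at
#' the first, a middle and the last slice; centers and radii are linearly
#' interpolated on `[first, middle]` and `[middle, last]` independently,
#' which follows pots tilted during scanning. The extended ROI adds
#' `extension` voxels to every radius so the pot wall contributes a
#' characteristic histogram peak.
#'
#' @param first,middle,last [circle_roi()] anchors with
#'   `first$z == 1`, `last$z == nz`, `first$z < middle$z < last$z`.
#' @param nz stack depth.
#' @param extension radius extension in voxels for the extended ROI.
#' @param slice_shape optional `c(nx, ny)`; when given, every interpolated
#'   bounded circle is checked to fit inside the slice.
#' @return An object of class `pot_mask`: per-slice `(cx, cy, r)` plus the
#'   extension.
#' @export
interpolate_roi <- function(first, middle, last, nz, extension = 50,
                            slice_shape = NULL) {
  stopifnot(inherits(first, "circle_roi"), inherits(middle, "circle_roi"),
            inherits(last, "circle_roi"))
  nz <- as.integer(nz)
  if (!(first$z == 1 && last$z == nz && first$z < middle$z && middle$z < last$z))
    stop("anchors out of order: need first$z = 1 < middle$z < last$z = nz",
         call. = FALSE)
  interp <- function(field) {
    v <- c(first[[field]], middle[[field]], last[[field]])
    zs <- c(first$z, middle$z, last$z)
    stats::approx(zs, v, xout = seq_len(nz))$y
  }
  df <- data.frame(z = seq_len(nz), cx = interp("cx"), cy = interp("cy"),
                   r = interp("r"))
  if (!is.null(slice_shape)) {
    bad <- df$cx - df$r < 0.5 | df$cx + df$r > slice_shape[1] + 0.5 |
           df$cy - df$r < 0.5 | df$cy + df$r > slice_shape[2] + 0.5
    if (any(bad))
      stop("bounded circle exceeds slice bounds at z = ",
           paste(utils::head(df$z[bad], 5), collapse = ", "), call. = FALSE)
  }
  structure(list(circles = df, extension = as.numeric(extension)),
            class = "pot_mask")
}

#' @export
print.pot_mask <- function(x, ...) {
  cat(sprintf("<pot_mask> %d slices, r %.1f..%.1f voxels, extension %g\n",
              nrow(x$circles), min(x$circles$r), max(x$circles$r),
              x$extension))
  invisible(x)
}

# logical disk for one slice; voxel centers at integer coordinates
disk_mask <- function(nx, ny, cx, cy, r) {
  dx2 <- (seq_len(nx) - cx)^2
  dy2 <- (seq_len(ny) - cy)^2
  outer(dx2, dy2, "+") <= r^2
}

#' Apply the pot mask to a volume
#'
#' Voxels outside the (bounded or extended) circle of their slice are set
#' to 0; the logical AND that removes the pot wall and everything beyond
#' it before segmentation.
#'
#' @param vol a [gray_volume()].
#' @param mask a [interpolate_roi()] result.
#' @param extended use the extended radius instead of the bounded one.
#' @return A masked [gray_volume()].
#' @export
apply_mask <- function(vol, mask, extended = FALSE) {
  stopifnot(is_gray_volume(vol), inherits(mask, "pot_mask"))
  d <- vol_dim(vol)
  if (nrow(mask$circles) != d[3])
    stop("depth mismatch: mask has ", nrow(mask$circles), " slices, volume ",
         d[3], call. = FALSE)
  out <- vol$data
  ext <- if (extended) mask$extension else 0
  for (z in seq_len(d[3])) {
    ci <- mask$circles[z, ]
    out[, , z] <- out[, , z] * disk_mask(d[1], d[2], ci$cx, ci$cy, ci$r + ext)
  }
  gray_volume(out, voxel_size_um = vol$voxel_size_um, bit_depth = vol$bit_depth)
}

#' Locate the pot-wall and soil-matrix histogram peaks
#'
#' The 256-bin gray-value histogram of the extended ROI is smoothed with a
#' 3-bin moving average and its maxima are read in the lower half
#' (`[0, split)`, the pot-wall peak P1) and the upper half
#' (`[split, 256)`, the soil-matrix peak P2). Ties break toward the lower
#' gray value. The two peaks anchor the root average gray value of the
#' background removal step.
#'
#' @param vol an 8-bit [gray_volume()].
#' @param mask a `pot_mask`; the histogram is taken over the extended ROI.
#' @param split boundary between the two search ranges (default 128).
#' @return A `peak_pair`: list with elements `P1` and `P2` (gray values).
#' @export
find_peaks <- function(vol, mask, split = 128L) {
  stopifnot(is_gray_volume(vol), inherits(mask, "pot_mask"))
  if (vol$bit_depth != 8L) stop("`vol` must be 8-bit", call. = FALSE)
  d <- vol_dim(vol)
  if (nrow(mask$circles) != d[3])
    stop("depth mismatch between mask and volume", call. = FALSE)
  counts <- numeric(256)
  for (z in seq_len(d[3])) {
    ci <- mask$circles[z, ]
    inside <- disk_mask(d[1], d[2], ci$cx, ci$cy, ci$r + mask$extension)
    v <- vol$data[, , z][inside]
    if (length(v))
      counts <- counts + tabulate(as.integer(round(v)) + 1L, nbins = 256)
  }
  if (sum(counts) == 0) stop("empty ROI", call. = FALSE)
  # 3-bin (1,2,1)/4 smoothing: robust to single-bin noise spikes without
  # displacing an isolated peak off its bin
  padded <- c(counts[1], counts, counts[256])
  sm <- (padded[1:256] + 2 * padded[2:257] + padded[3:258]) / 4
  split <- as.integer(split)
  lower <- sm[seq_len(split)]
  upper <- sm[(split + 1):256]
  if (sum(counts[seq_len(split)]) == 0)
    stop("no pot-wall peak found below GV ", split, call. = FALSE)
  if (sum(counts[(split + 1):256]) == 0)
    stop("no matrix peak found at or above GV ", split, call. = FALSE)
  p1 <- which.max(lower) - 1L          # which.max takes the first (lowest) tie
  p2 <- split + which.max(upper) - 1L
  structure(list(P1 = as.numeric(p1), P2 = as.numeric(p2)),
            class = "peak_pair")
}

#' @export
print.peak_pair <- function(x, ...) {
  cat(sprintf("<peak_pair> P1 (pot wall) = %g, P2 (soil matrix) = %g\n",
              x$P1, x$P2))
  invisible(x)
}
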