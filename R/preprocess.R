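# Grayscale conditioning chain: percentile stretch, stack stitching,
# per-slice attenuation correction, non-local-means denoising with the
# 16-bit offset round trip, and unsharp-mask edge enhancement.

# separable Gaussian blur of a plain 3D array (reflect boundary)
gaussian_blur <- function(a, sigma) {
  d <- dim(a)
  radius <- max(1L, as.integer(4 * sigma + 0.5))
  x <- (-radius):radius
  k <- exp(-0.5 * x^2 / sigma^2)
  k <- k / sum(k)
  v <- as.double(a)
  for (axis in 0:2) v <- .conv_axis_cpp(v, d, k, axis)
  array(v, d)
}

#' Contrast stretch by percentiles to 8-bit
#'
#' The `p` quantile of the gray values maps to 0 and the `1 - p` quantile
#' to 255, linearly in between, clipping outside; the benchmark
#' reconstruction uses `p = 0.002` (0.2% of the darkest and brightest
#' voxels saturate).
#'
#' @param vol a [gray_volume()].
#' @param p saturated fraction per tail, in `[0, 0.5)`.
#' @return An 8-bit [gray_volume()].
#' @export
percentile_stretch <- function(vol, p = 0.002) {
  stopifnot(is_gray_volume(vol))
  if (p < 0 || p >= 0.5) stop("`p` must be in [0, 0.5)", call. = FALSE)
  q <- quantile(vol$data, c(p, 1 - p), names = FALSE)
  if (q[2] <= q[1])
    stop("undefined stretch: volume is constant over the stretch range",
         call. = FALSE)
  out <- (vol$data - q[1]) / (q[2] - q[1]) * 255
  out[out < 0] <- 0
  out[out > 255] <- 255
  gray_volume(round(out), voxel_size_um = vol$voxel_size_um, bit_depth = 8L)
}

#' Stitch two overlapping sub-stacks
#'
#' Pots taller than the detector are scanned at two depth intervals with an
#' overlapping region; the overlap is removed once before concatenation,
#' split evenly: `ceiling(o/2)` slices dropped from the lower (deep) end of
#' the top stack, `floor(o/2)` from the upper end of the bottom stack.
#' Slice 1 of the result is the top of the pot.
#'
#' @param bottom,top [gray_volume()] sub-stacks with equal x-y dimensions.
#' @param overlap_slices number of z slices shared by the two scans.
#' @return A [gray_volume()] of depth `nz_top + nz_bottom - overlap_slices`.
#' @export
stitch_stacks <- function(bottom, top, overlap_slices) {
  stopifnot(is_gray_volume(bottom), is_gray_volume(top))
  db <- vol_dim(bottom); dt <- vol_dim(top)
  if (db[1] != dt[1] || db[2] != dt[2])
    stop("shape mismatch: x-y dimensions differ", call. = FALSE)
  o <- as.integer(overlap_slices)
  if (o < 0 || o >= db[3] || o >= dt[3])
    stop("`overlap_slices` must be smaller than each stack depth",
         call. = FALSE)
  drop_top <- ceiling(o / 2)
  drop_bottom <- o - drop_top
  top_keep <- top$data[, , seq_len(dt[3] - drop_top), drop = FALSE]
  bottom_keep <- bottom$data[, , (drop_bottom + 1):db[3], drop = FALSE]
  out <- array(0, c(db[1], db[2], dim(top_keep)[3] + dim(bottom_keep)[3]))
  out[, , seq_len(dim(top_keep)[3])] <- top_keep
  out[, , (dim(top_keep)[3] + 1):dim(out)[3]] <- bottom_keep
  gray_volume(out, voxel_size_um = bottom$voxel_size_um,
              bit_depth = bottom$bit_depth)
}

#' Per-slice attenuation correction
#'
#' Illumination drift along z (for instance the gray-value discontinuity at
#' a stitch boundary) is corrected by a linear transform per slice,
#' `v' = a v + b`, chosen so the background mean and standard deviation of
#' every slice match those of a reference slice: `a = sd_ref / sd_slice`,
#' `b = mean_ref - a * mean_slice`. The background defaults to the whole
#' slice; a per-slice region (2D mask applied to all slices, or a full 3D
#' mask) can be supplied instead, e.g. the annulus between the bounded and
#' extended pot ROI.
#'
#' @param vol a [gray_volume()].
#' @param reference_slice z index (1-based) of the reference slice.
#' @param background optional logical 2D matrix (nx x ny) or 3D array
#'   selecting the background region used for the statistics.
#' @return A [gray_volume()] with slice statistics equalized, clipped to the
#'   bit-depth range. Slices with zero background spread are left unchanged
#'   with a warning.
#' @export
attenuation_correct <- function(vol, reference_slice, background = NULL) {
  stopifnot(is_gray_volume(vol))
  d <- vol_dim(vol)
  z_ref <- as.integer(reference_slice)
  if (z_ref < 1L || z_ref > d[3])
    stop("`reference_slice` out of range", call. = FALSE)
  sel <- function(z) {
    s <- vol$data[, , z]
    if (is.null(background)) as.vector(s)
    else if (length(dim(background)) == 2L) s[background]
    else s[background[, , z]]
  }
  bg_ref <- sel(z_ref)
  mu_ref <- mean(bg_ref); sd_ref <- sd(bg_ref)
  if (!is.finite(sd_ref) || sd_ref == 0)
    stop("reference slice has zero background standard deviation",
         call. = FALSE)
  out <- vol$data
  vmax <- 2^vol$bit_depth - 1
  flat <- integer()
  for (z in seq_len(d[3])) {
    if (z == z_ref) next
    bg <- sel(z)
    s <- sd(bg)
    if (!is.finite(s) || s == 0) { flat <- c(flat, z); next }
    a <- sd_ref / s
    b <- mu_ref - a * mean(bg)
    sl <- a * vol$data[, , z] + b
    sl[sl < 0] <- 0
    sl[sl > vmax] <- vmax
    out[, , z] <- sl
  }
  if (length(flat))
    warning("slices with zero background spread left unchanged: ",
            paste(flat, collapse = ", "))
  gray_volume(out, voxel_size_um = vol$voxel_size_um, bit_depth = vol$bit_depth)
}

#' Non-local means denoising with the 16-bit offset round trip
#'
#' The volume is converted to 16-bit, shifted by a constant offset of
#' 50,000 gray values, denoised with a patch-based non-local-means filter,
#' shifted back and reconverted to 8-bit. The offset keeps implementations
#' built around a Rician noise model (designed for magnetic resonance data)
#' in their linear regime, avoiding a contrast shift for weakly attenuating
#' materials; it is carried here as a hard contract of the conditioning
#' chain. Filter strength scales with the contrast threshold `t_con`
#' (decay constant `h = 0.4 * t_con`; `t_con` is of the order of four times
#' the noise standard deviation).
#'
#' @param vol an 8-bit [gray_volume()].
#' @param t_con contrast threshold controlling the degree of smoothing
#'   (default 60, suited to noise of sd ~ 15).
#' @param patch_radius,search_radius patch and search-window radii in
#'   voxels.
#' @param offset constant gray-value offset added in 16-bit space.
#' @return A denoised 8-bit [gray_volume()].
#' @export
nlm_denoise <- function(vol, t_con = 60, patch_radius = 1L,
                        search_radius = 2L, offset = 50000) {
  stopifnot(is_gray_volume(vol))
  if (vol$bit_depth != 8L) stop("`vol` must be 8-bit", call. = FALSE)
  d <- vol_dim(vol)
  v16 <- as.double(vol$data) + offset
  h <- 0.4 * t_con
  den <- .nlm_cpp(v16, d, h, as.integer(patch_radius),
                  as.integer(search_radius))
  out <- round(den - offset)
  out[out < 0] <- 0
  out[out > 255] <- 255
  gray_volume(array(out, d), voxel_size_um = vol$voxel_size_um, bit_depth = 8L)
}

#' Unsharp-mask edge enhancement
#'
#' Sharpens with `v' = (v - w * G_sigma(v)) / (1 - w)`, the normalization
#' used by the common interactive tools: a Gaussian-blurred copy (std
#' `blur_radius`) weighted by `mask_weight` is subtracted and the result is
#' rescaled so flat regions keep their value. Output is clipped to the
#' input bit depth. Increases local contrast between root edges and the
#' surrounding matrix and pores.
#'
#' @param vol a [gray_volume()].
#' @param blur_radius Gaussian std in voxels (> 0).
#' @param mask_weight strength in (0, 1).
#' @return A sharpened [gray_volume()].
#' @export
unsharp_mask <- function(vol, blur_radius = 1, mask_weight = 0.7) {
  stopifnot(is_gray_volume(vol))
  if (blur_radius <= 0) stop("`blur_radius` must be > 0", call. = FALSE)
  if (mask_weight <= 0 || mask_weight >= 1)
    stop("`mask_weight` must be in (0, 1)", call. = FALSE)
  g <- gaussian_blur(vol$data, blur_radius)
  out <- (vol$data - mask_weight * g) / (1 - mask_weight)
  vmax <- 2^vol$bit_depth - 1
  out[out < 0] <- 0
  out[out > vmax] <- vmax
  gray_volume(round(out), voxel_size_um = vol$voxel_size_um,
              bit_depth = vol$bit_depth)
}
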