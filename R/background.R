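# Gray-value background removal: the root average gray value is anchored
# between the pot-wall and soil-matrix histogram peaks, every voxel is
# remapped by an absolute difference transform (ADT) that brightens
# root-like gray values, and a threshold derived from the root gray-value
# range masks out everything else.

#' Root average gray value
#'
#' `v_r = f_r * (P2 - P1) + P1`: the root gray value is assumed to shift
#' with the characteristic peaks, so one factor `f_r` calibrated on a
#' representative image transfers across differently contrasted scans.
#' Kept as a real number (no rounding).
#'
#' @param peaks a `peak_pair` from [find_peaks()].
#' @param f_r root gray-value factor in `[0, 1]` (0.10 for the noisy
#'   benchmark scenario, 0.18 for the clean one).
#' @return The root average gray value, numeric.
#' @export
root_gv <- function(peaks, f_r) {
  stopifnot(inherits(peaks, "peak_pair"))
  if (f_r < 0 || f_r > 1) stop("`f_r` must be in [0, 1]", call. = FALSE)
  f_r * (peaks$P2 - peaks$P1) + peaks$P1
}

#' Absolute difference transform
#'
#' `v_ADT = 255 - |v - v_r|`: voxels near the root average gray value map
#' to bright values, pores and soil matrix (whose gray values differ from
#' the roots') darken. Values are rounded half-up unless `round = FALSE`.
#'
#' @param vol an 8-bit [gray_volume()].
#' @param v_bar_r root average gray value from [root_gv()].
#' @param round round to integer gray values (half-up).
#' @return An 8-bit [gray_volume()].
#' @export
adt <- function(vol, v_bar_r, round = TRUE) {
  stopifnot(is_gray_volume(vol))
  if (vol$bit_depth != 8L) stop("`vol` must be 8-bit", call. = FALSE)
  out <- 255 - abs(vol$data - v_bar_r)
  if (round) out <- floor(out + 0.5)
  out[out < 0] <- 0
  gray_volume(out, voxel_size_um = vol$voxel_size_um, bit_depth = 8L)
}

#' ADT threshold from the root gray-value range
#'
#' `t_ADT = 255 - R_r / 2`; voxels whose ADT value falls below it deviate
#' more than `R_r / 2` from the root average gray value and are masked out.
#'
#' @param R_r root gray-value range in gray values, in `(0, 255]`
#'   (65 for the noisy benchmark scenario, 70 for the clean one).
#' @return The threshold, numeric (can be half-integral).
#' @export
adt_threshold <- function(R_r) {
  if (R_r <= 0 || R_r > 255) stop("`R_r` must be in (0, 255]", call. = FALSE)
  255 - R_r / 2
}

#' Threshold an ADT volume
#'
#' Voxels with `v_ADT < t_ADT` are set to 0; the rest keep their ADT
#' value, leaving a dark background for the tubeness stage.
#'
#' @param vol an ADT-transformed [gray_volume()].
#' @param t_adt threshold from [adt_threshold()].
#' @return A [gray_volume()].
#' @export
apply_adt_threshold <- function(vol, t_adt) {
  stopifnot(is_gray_volume(vol))
  out <- vol$data
  out[out < t_adt] <- 0
  gray_volume(out, voxel_size_um = vol$voxel_size_um, bit_depth = vol$bit_depth)
}

#' Full background removal
#'
#' Composes [adt()] and [apply_adt_threshold()] with the comparison done on
#' the unrounded ADT values (the threshold `255 - R_r/2` is half-integral
#' for odd `R_r`, so rounding first would shift the band boundary by half a
#' gray value); survivors are exactly the voxels with
#' `|v - v_r| <= R_r / 2`. The surviving ADT values are rounded half-up.
#'
#' @param vol an 8-bit [gray_volume()].
#' @param v_bar_r root average gray value.
#' @param R_r root gray-value range.
#' @return A [gray_volume()] with background set to 0.
#' @export
remove_background <- function(vol, v_bar_r, R_r) {
  stopifnot(is_gray_volume(vol))
  t_adt <- adt_threshold(R_r)
  raw <- 255 - abs(vol$data - v_bar_r)
  out <- floor(raw + 0.5)
  out[raw < t_adt] <- 0
  out[out < 0] <- 0
  gray_volume(out, voxel_size_um = vol$voxel_size_um, bit_depth = 8L)
}
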