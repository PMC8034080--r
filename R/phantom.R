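# Synthetic root-in-soil CT phantom with exact ground truth: a bright
# cylindrical pot wall, granular soil matrix, dark pores, and branching
# root tubes whose gray value lies between the pore and matrix values.
# Exercises every pipeline stage without CT data.

#' Phantom specification
#'
#' Describes a synthetic repacked-soil CT scan. The defaults emulate the
#' benchmark composition: a 256^3 volume at 45 um; a pot wall of gray
#' value 60 (the histogram peak P1, below the half-split at 128) thick
#' enough to fill the 50-voxel extended-ROI annulus; a soil matrix at gray
#' value 150 (P2) with blurred granular texture; dark pores (GV 20, 5% of
#' the soil); six branching roots of diameters 4 to 28 voxels at gray
#' value `P1 + 0.18 (P2 - P1) ~ 76`, between pore and matrix, close to the
#' wall as in real scans; a detector point-spread blur of 0.5 voxels; and
#' no global noise (the noisy variant adds clipped additive Gaussian
#' noise on the 8-bit values).
#'
#' @param shape volume shape `c(nx, ny, nz)` or scalar cube side.
#' @param voxel_size_um voxel size.
#' @param roi_radius bounded ROI radius in voxels (inside the pot wall).
#' @param wall_gv,wall_thickness pot-wall gray value and radial thickness.
#' @param wall_tilt `c(dcx, dcy)` drift of the pot center from top to
#'   bottom slice, in voxels (pots are always slightly tilted).
#' @param matrix_gv soil-matrix gray value (P2).
#' @param texture_sd granular texture amplitude (gray values).
#' @param pore_fraction,pore_gv pore volume fraction of the soil and pore
#'   gray value.
#' @param root_gv,root_gv_sd root gray value and its within-root spread.
#' @param root_diameters diameters (voxels) of the primary roots, one root
#'   each, all in `[2, 40]`.
#' @param branch_prob per-step probability that a root spawns a lateral.
#' @param branch_angle_range lateral deflection angle range, degrees.
#' @param branch_diameter_frac lateral diameter as a fraction of its
#'   parent's (floored at 4 voxels, the smallest diameter the detection
#'   schedule targets).
#' @param noise_sd global additive Gaussian noise sd (8-bit gray values).
#' @param psf_sigma Gaussian blur emulating the detector point spread.
#' @param seed integer seed; the phantom is fully determined by it.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(shape = 256, voxel_size_um = 45,
                         roi_radius = NULL, wall_gv = 60,
                         wall_thickness = 50, wall_tilt = c(3, 2),
                         matrix_gv = 150, texture_sd = 6,
                         pore_fraction = 0.05, pore_gv = 20,
                         root_gv = NULL, root_gv_sd = 3,
                         root_diameters = c(4, 8, 12, 16, 20, 28),
                         branch_prob = 0.02,
                         branch_angle_range = c(30, 70),
                         branch_diameter_frac = 0.5,
                         noise_sd = 0, psf_sigma = 0.5, seed = 1L) {
  if (length(shape) == 1L) shape <- rep(shape, 3L)
  if (is.null(roi_radius)) roi_radius <- floor(min(shape[1:2]) / 2) - 5 -
    wall_thickness
  if (is.null(root_gv)) root_gv <- wall_gv + 0.18 * (matrix_gv - wall_gv)
  if (any(root_diameters < 2 | root_diameters > 40))
    stop("root diameters must lie in [2, 40] voxels", call. = FALSE)
  structure(list(shape = as.integer(shape), voxel_size_um = voxel_size_um,
                 roi_radius = roi_radius, wall_gv = wall_gv,
                 wall_thickness = wall_thickness, wall_tilt = wall_tilt,
                 matrix_gv = matrix_gv, texture_sd = texture_sd,
                 pore_fraction = pore_fraction, pore_gv = pore_gv,
                 root_gv = root_gv, root_gv_sd = root_gv_sd,
                 root_diameters = root_diameters, branch_prob = branch_prob,
                 branch_angle_range = branch_angle_range,
                 branch_diameter_frac = branch_diameter_frac,
                 noise_sd = noise_sd, psf_sigma = psf_sigma,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Grow one root as a polyline: biased random walk downwards with
# persistence, steered away from the pot wall and from previously grown
# roots (roots are solid; tubes must not interpenetrate, or the ground
# truth centerlines would disagree with the rasterized union). Returns
# the polyline plus branch requests (start, direction, diameter) spawned
# along the way; `occupied` is a matrix (x, y, z, r) of dense centerline
# points of earlier roots.
grow_root <- function(start, dir, diameter, spec, occupied,
                      origin_allowance = 0) {
  step_len <- 4
  nz <- spec$shape[3]
  cx <- spec$shape[1] / 2; cy <- spec$shape[2] / 2
  r_max <- spec$roi_radius - diameter / 2 - 3
  collides <- function(p, travelled) {
    if (is.null(occupied) || nrow(occupied) == 0) return(FALSE)
    if (travelled < origin_allowance) return(FALSE) # still leaving the parent
    nn <- FNN::get.knnx(occupied[, 1:3, drop = FALSE],
                        matrix(p, 1), k = 1)
    nn$nn.dist[1, 1] < diameter / 2 + occupied[nn$nn.index[1, 1], 4] + 1.5
  }
  pts <- list(start)
  branch_requests <- list()
  p <- start
  v <- dir / sqrt(sum(dir^2))
  travelled <- 0
  while (p[3] < 0.92 * nz) {
    turn <- rnorm(3, 0, 0.12)
    v <- v + turn + c(0, 0, 0.25)          # gravitropic pull
    v <- v / sqrt(sum(v^2))
    if (v[3] < 0.2) { v[3] <- 0.2; v <- v / sqrt(sum(v^2)) }
    pn <- p + step_len * v
    rad <- sqrt((pn[1] - cx)^2 + (pn[2] - cy)^2)
    if (rad > r_max) {
      # bounce off the wall: reflect the outward radial velocity component
      # so roots leave the boundary instead of riding along it
      n_hat <- c(pn[1] - cx, pn[2] - cy, 0) / rad
      v_rad <- sum(v * n_hat)
      if (v_rad > 0) v <- v - 1.6 * v_rad * n_hat
      v <- v / sqrt(sum(v^2))
      pn <- p + step_len * v
      rad2 <- sqrt((pn[1] - cx)^2 + (pn[2] - cy)^2)
      if (rad2 > r_max) {                   # corner case: steer inward
        inward <- c(cx - pn[1], cy - pn[2], 0)
        inward <- inward / sqrt(sum(inward^2))
        v <- v + 0.8 * inward
        v <- v / sqrt(sum(v^2))
        pn <- p + step_len * v
      }
    }
    if (collides(pn, travelled + step_len)) {
      # try deflected directions before giving up on this root
      ok <- FALSE
      basis <- orthonormal_pair(v)
      for (ang in c(0.6, -0.6, 1.1, -1.1, 1.6, -1.6)) {
        vd <- cos(ang) * v + sin(ang) * basis$u1
        if (vd[3] < 0.1) next
        vd <- vd / sqrt(sum(vd^2))
        pd <- p + step_len * vd
        if (!collides(pd, travelled + step_len)) {
          v <- vd; pn <- pd; ok <- TRUE; break
        }
      }
      if (!ok) break
    }
    pts[[length(pts) + 1L]] <- pn
    travelled <- travelled + step_len
    if (length(pts) > 3L && runif(1) < spec$branch_prob) {
      d_child <- max(4, diameter * spec$branch_diameter_frac)
      ang <- runif(1, spec$branch_angle_range[1],
                   spec$branch_angle_range[2]) * pi / 180
      basis <- orthonormal_pair(v)
      phi <- runif(1, 0, 2 * pi)
      axis <- cos(phi) * basis$u1 + sin(phi) * basis$u2
      vb <- cos(ang) * v + sin(ang) * axis
      branch_requests[[length(branch_requests) + 1L]] <-
        list(start = pn, dir = vb, diameter = d_child,
             allowance = diameter / 2 + d_child / 2 + 4)
    }
    p <- pn
  }
  poly <- do.call(rbind, pts)
  list(poly = data.frame(x = poly[, 1], y = poly[, 2], z = poly[, 3],
                         diameter = diameter),
       branch_requests = branch_requests)
}

# resample a coarse polyline through a cubic spline at quarter-step
# resolution, removing the polygonal creases of the random walk
smooth_polyline <- function(poly) {
  n <- nrow(poly)
  if (n < 4L) return(poly)
  s <- seq_len(n)
  t_out <- seq(1, n, by = 0.25)
  data.frame(x = stats::spline(s, poly$x, xout = t_out)$y,
             y = stats::spline(s, poly$y, xout = t_out)$y,
             z = stats::spline(s, poly$z, xout = t_out)$y,
             diameter = poly$diameter[1])
}

# two unit vectors orthogonal to v and each other
orthonormal_pair <- function(v) {
  ref <- if (abs(v[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u1 <- ref - sum(ref * v) * v
  u1 <- u1 / sqrt(sum(u1^2))
  u2 <- c(v[2] * u1[3] - v[3] * u1[2],
          v[3] * u1[1] - v[1] * u1[3],
          v[1] * u1[2] - v[2] * u1[1])
  list(u1 = u1, u2 = u2)
}

# accumulate tube coverage for one polyline into `cov` (pmax semantics)
rasterize_tube <- function(cov, poly, shape) {
  R <- poly$diameter[1] / 2
  for (i in seq_len(nrow(poly) - 1L)) {
    a <- as.numeric(poly[i, 1:3]); b <- as.numeric(poly[i + 1L, 1:3])
    lo <- pmax(floor(pmin(a, b) - R - 1), 1)
    hi <- pmin(ceiling(pmax(a, b) + R + 1), shape)
    if (any(lo > hi)) next
    xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
    gx <- rep(xs, times = length(ys) * length(zs))
    gy <- rep(rep(ys, each = length(xs)), times = length(zs))
    gz <- rep(zs, each = length(xs) * length(ys))
    ab <- b - a
    len2 <- sum(ab^2)
    t <- ((gx - a[1]) * ab[1] + (gy - a[2]) * ab[2] + (gz - a[3]) * ab[3]) / len2
    t <- pmin(pmax(t, 0), 1)
    dx <- gx - (a[1] + t * ab[1])
    dy <- gy - (a[2] + t * ab[2])
    dz <- gz - (a[3] + t * ab[3])
    cv <- pmin(pmax(R + 0.5 - sqrt(dx^2 + dy^2 + dz^2), 0), 1)
    sub <- cov[xs, ys, zs]
    cov[xs, ys, zs] <- pmax(sub, array(cv, dim = c(length(xs), length(ys),
                                                   length(zs))))
  }
  cov
}

#' Generate a synthetic root-in-soil phantom
#'
#' Deterministic for a fixed seed. Tubes are rasterized with anti-aliased
#' (partial-volume) edges: boundary voxels receive a gray value
#' proportional to their root coverage, emulating the gradual transitions
#' that make fine-root segmentation hard in real scans.
#'
#' @param spec a [phantom_spec()].
#' @return A list: `volume` (the [gray_volume()]), `truth`
#'   (a `phantom_truth`: binary root mask, centerline polylines with
#'   per-point diameter, total root length in um, and length per diameter
#'   class), and `roi` (the [interpolate_roi()] pot mask matching the
#'   rendered wall).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                           globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(spec$seed)
  d <- spec$shape
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  cx0 <- nx / 2; cy0 <- ny / 2
  # background: soil matrix with blurred granular texture
  vol <- array(spec$matrix_gv, d)
  if (spec$texture_sd > 0) {
    tex <- array(rnorm(prod(d), 0, spec$texture_sd * 2.2), d)
    tex <- gaussian_blur(tex, 1)           # blur shrinks sd by ~2.2 at sigma 1
    vol <- vol + tex
  }
  # pores: dark spheres filling ~pore_fraction of the soil
  soil_vox <- pi * spec$roi_radius^2 * nz
  pore_cov <- array(0, d)
  if (spec$pore_fraction > 0) {
    target <- spec$pore_fraction * soil_vox
    placed <- 0
    while (placed < target) {
      pr <- runif(1, 2, 6)
      ang <- runif(1, 0, 2 * pi)
      rad <- sqrt(runif(1)) * (spec$roi_radius - pr - 1)
      ctr <- c(cx0 + rad * cos(ang), cy0 + rad * sin(ang), runif(1, 1, nz))
      lo <- pmax(floor(ctr - pr - 1), 1)
      hi <- pmin(ceiling(ctr + pr + 1), d)
      xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
      dist <- sqrt(outer(outer((xs - ctr[1])^2, (ys - ctr[2])^2, "+"),
                         (zs - ctr[3])^2, "+"))
      cv <- pmin(pmax(pr + 0.5 - dist, 0), 1)
      pore_cov[xs, ys, zs] <- pmax(pore_cov[xs, ys, zs], cv)
      placed <- placed + 4 / 3 * pi * pr^3
    }
    vol <- vol * (1 - pore_cov) + spec$pore_gv * pore_cov
  }
  # roots: branching tubes entering from the top, grown one after the
  # other so later roots can steer around earlier ones
  polylines <- list()
  root_cov <- array(0, d)
  occupied <- NULL
  queue <- lapply(seq_along(spec$root_diameters), function(i) {
    di <- spec$root_diameters[i]
    ang <- 2 * pi * (i - 1) / length(spec$root_diameters) + runif(1, 0, 0.5)
    rad <- runif(1, 0.35, 0.8) * spec$roi_radius
    list(start = c(cx0 + rad * cos(ang), cy0 + rad * sin(ang), 1),
         dir = c(rnorm(2, 0, 0.15), 1), diameter = di, allowance = 0)
  })
  start_blocked <- function(p, dmtr) {
    if (is.null(occupied) || nrow(occupied) == 0) return(FALSE)
    nn <- FNN::get.knnx(occupied[, 1:3, drop = FALSE], matrix(p, 1), k = 1)
    nn$nn.dist[1, 1] < dmtr / 2 + occupied[nn$nn.index[1, 1], 4] + 1.5
  }
  while (length(queue)) {
    req <- queue[[1]]
    queue <- queue[-1]
    if (req$allowance == 0) {
      # primaries enter at the top: resample a free entry point if the
      # drawn one would start inside an earlier root
      tries <- 0
      while (start_blocked(req$start, req$diameter) && tries < 30) {
        ang <- runif(1, 0, 2 * pi)
        rad <- runif(1, 0.35, 0.8) * spec$roi_radius
        req$start <- c(cx0 + rad * cos(ang), cy0 + rad * sin(ang), 1)
        tries <- tries + 1
      }
    }
    g <- grow_root(req$start, req$dir, req$diameter, spec, occupied,
                   origin_allowance = req$allowance)
    if (nrow(g$poly) < 2L) next
    # interpolate the coarse walk with a cubic spline: real roots are
    # smooth, and polygonal creases every walk step would put ridge rings
    # on the tube surface that no real scan shows
    polylines[[length(polylines) + 1L]] <- smooth_polyline(g$poly)
    dense <- densify_centerlines(list(g$poly))
    occupied <- rbind(occupied,
                      cbind(dense[, 1:3, drop = FALSE], g$poly$diameter[1] / 2))
    queue <- c(queue, g$branch_requests)
  }
  for (poly in polylines) root_cov <- rasterize_tube(root_cov, poly, d)
  gv_root <- spec$root_gv +
    if (spec$root_gv_sd > 0) array(rnorm(prod(d), 0, spec$root_gv_sd), d)
    else 0
  vol <- vol * (1 - root_cov) + gv_root * root_cov
  truth_mask <- root_cov >= 0.5
  # pot wall: annulus outside the (tilted) bounded ROI
  tilt <- spec$wall_tilt
  zfrac <- (seq_len(nz) - 1) / max(1, nz - 1)
  for (z in seq_len(nz)) {
    czx <- cx0 + tilt[1] * (zfrac[z] - 0.5)
    czy <- cy0 + tilt[2] * (zfrac[z] - 0.5)
    rr <- sqrt(outer((seq_len(nx) - czx)^2, (seq_len(ny) - czy)^2, "+"))
    sl <- vol[, , z]
    wall <- rr > spec$roi_radius & rr <= spec$roi_radius + spec$wall_thickness
    sl[wall] <- spec$wall_gv + if (spec$texture_sd > 0)
      rnorm(sum(wall), 0, 1.5) else 0
    sl[rr > spec$roi_radius + spec$wall_thickness] <- 5  # air outside the pot
    vol[, , z] <- sl
  }
  if (spec$psf_sigma > 0) vol <- gaussian_blur(vol, spec$psf_sigma)
  if (spec$noise_sd > 0) vol <- vol + rnorm(prod(d), 0, spec$noise_sd)
  vol[vol < 0] <- 0
  vol[vol > 255] <- 255
  vol <- round(vol)
  # truth bookkeeping from the polylines
  seg_len <- function(p) sum(sqrt(diff(p$x)^2 + diff(p$y)^2 + diff(p$z)^2))
  lens_vox <- vapply(polylines, seg_len, numeric(1))
  diams <- vapply(polylines, function(p) p$diameter[1], numeric(1))
  per_class <- tapply(lens_vox, factor(diams), sum)
  truth <- structure(list(
    mask = binary_volume(truth_mask, voxel_size_um = spec$voxel_size_um),
    centerlines = polylines,
    total_length_um = sum(lens_vox) * spec$voxel_size_um,
    length_per_class_um = setNames(as.numeric(per_class) *
                                     spec$voxel_size_um, names(per_class))),
    class = "phantom_truth")
  roi <- interpolate_roi(
    circle_roi(1, cx0 + tilt[1] * -0.5, cy0 + tilt[2] * -0.5,
               spec$roi_radius),
    circle_roi(ceiling(nz / 2),
               cx0 + tilt[1] * (zfrac[ceiling(nz / 2)] - 0.5),
               cy0 + tilt[2] * (zfrac[ceiling(nz / 2)] - 0.5),
               spec$roi_radius),
    circle_roi(nz, cx0 + tilt[1] * 0.5, cy0 + tilt[2] * 0.5,
               spec$roi_radius),
    nz, extension = spec$wall_thickness)
  list(volume = gray_volume(vol, voxel_size_um = spec$voxel_size_um,
                            bit_depth = 8L),
       truth = truth, roi = roi)
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("<phantom_truth> %d centerlines, total length %.1f mm\n",
              length(x$centerlines), x$total_length_um / 1000))
  invisible(x)
}

#' Export phantom truth centerlines as a data frame
#'
#' @param truth a `phantom_truth`.
#' @return Data frame with columns `root`, `x`, `y`, `z`, `diameter`.
#' @export
truth_centerline_table <- function(truth) {
  stopifnot(inherits(truth, "phantom_truth"))
  do.call(rbind, lapply(seq_along(truth$centerlines), function(i) {
    p <- truth$centerlines[[i]]
    cbind(root = i, p)
  }))
}

# resample polylines to points at most 1 voxel apart, with diameters
densify_centerlines <- function(polylines) {
  pts <- lapply(polylines, function(p) {
    n <- nrow(p)
    out <- list()
    for (i in seq_len(n - 1L)) {
      a <- as.numeric(p[i, 1:3]); b <- as.numeric(p[i + 1L, 1:3])
      L <- sqrt(sum((b - a)^2))
      k <- max(1L, ceiling(L))
      t <- seq(0, 1, length.out = k + 1L)[-(k + 1L)]
      out[[i]] <- cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]),
                        a[3] + t * (b[3] - a[3]), p$diameter[1])
    }
    do.call(rbind, out)
  })
  do.call(rbind, pts)
}

#' Score a segmentation against phantom ground truth
#'
#' The segmented mask is skeletonized and each skeleton voxel is matched
#' to the nearest truth centerline point; a voxel matches when it lies
#' within `tolerance` voxels of a centerline of compatible diameter: the
#' local-thickness diameter must be within a factor of two of the truth
#' diameter, with one voxel of slack for discretization (local thickness
#' of a thin digitized tube has a floor near 2 voxels and a downward bias
#' of about one voxel). Recall is the matched skeleton length over the
#' truth length;
#' precision is the matched fraction of the skeleton length. Per-class
#' diameter errors compare local thickness against the truth diameter.
#'
#' @param segmented a [binary_volume()] on the truth grid.
#' @param truth a `phantom_truth`.
#' @param tolerance matching distance in voxels (default 2).
#' @param skel,thick optional precomputed [skeletonize()] and
#'   [local_thickness()] results for `segmented`, to avoid recomputation.
#' @return A list: `length_recall`, `length_precision`,
#'   `matched_length_um`, `skeleton_length_um`, `truth_length_um`, and
#'   `diameter_error` (data frame per truth diameter class, voxels).
#' @export
evaluate_against_truth <- function(segmented, truth, tolerance = 2,
                                   skel = NULL, thick = NULL) {
  stopifnot(is_binary_volume(segmented), inherits(truth, "phantom_truth"))
  if (!identical(vol_dim(segmented), vol_dim(truth$mask)))
    stop("grid mismatch between segmentation and truth", call. = FALSE)
  if (!any(segmented$data))
    return(list(length_recall = 0, length_precision = NA_real_,
                matched_length_um = 0, skeleton_length_um = 0,
                truth_length_um = truth$total_length_um,
                diameter_error = data.frame(diameter_vox = numeric(),
                                            mean_error_vox = numeric(),
                                            n = integer())))
  if (is.null(skel)) skel <- skeletonize(segmented)
  if (is.null(thick)) thick <- local_thickness(segmented)
  ref <- densify_centerlines(truth$centerlines)
  match_co <- if (!is.null(skel$coords_ref)) skel$coords_ref else skel$coords
  nn <- FNN::get.knnx(ref[, 1:3], match_co, k = 1)
  truth_d <- ref[nn$nn.index[, 1], 4]
  lt_d <- thick$data[skel$coords]
  compatible <- lt_d >= truth_d / 2 - 1 & lt_d <= 2 * truth_d + 1
  matched <- nn$nn.dist[, 1] <= tolerance & compatible
  matched_len <- sum(skel$step_length_um[matched])
  err <- data.frame(diameter_vox = truth_d[matched],
                    error = lt_d[matched] - truth_d[matched])
  diameter_error <- if (nrow(err)) {
    agg <- aggregate(error ~ diameter_vox, err,
                     function(e) c(mean = mean(e), n = length(e)))
    data.frame(diameter_vox = agg$diameter_vox,
               mean_error_vox = agg$error[, "mean"],
               n = as.integer(agg$error[, "n"]))
  } else {
    data.frame(diameter_vox = numeric(), mean_error_vox = numeric(),
               n = integer())
  }
  list(length_recall = matched_len / truth$total_length_um,
       length_precision = matched_len / skel$total_length_um,
       matched_length_um = matched_len,
       skeleton_length_um = skel$total_length_um,
       truth_length_um = truth$total_length_um,
       diameter_error = diameter_error)
}
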