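# Multi-scale cylindrical shape detection: Hessian tubeness filtering,
# the synthetic-cylinder calibration that links the normalized smoothing
# strength q = sigma / d to the optimal lower hysteresis threshold, the
# sigma schedule over target root diameters and resolutions, hysteresis
# thresholding and the MAX combination of all detection passes.

#' Hessian tubeness filter
#'
#' The volume is probed at scale `sigma` with Gaussian derivative kernels;
#' at each voxel the Hessian's eigenvalues `e1 <= e2 <= e3` are computed
#' and the response is `sqrt(e1 * e2)` when both are negative (a bright
#' tube on dark background curves downward in the two directions across
#' its axis), 0 otherwise. The result is contrast-normalized per volume so
#' the highest response maps to gray value 255.
#'
#' @param vol a [gray_volume()].
#' @param sigma Gaussian scale in voxels (>= 0.5); for a root of diameter
#'   `d` the matched scale is `sigma = q * d` with `q = 0.5`.
#' @return An 8-bit [gray_volume()] of normalized tubeness.
#' @export
tubeness <- function(vol, sigma) {
  stopifnot(is_gray_volume(vol))
  if (sigma < 0.5) stop("`sigma` must be >= 0.5", call. = FALSE)
  d <- vol_dim(vol)
  resp <- .tubeness_cpp(as.double(vol$data), d, sigma)
  m <- max(resp)
  if (m == 0) {
    warning("tubeness response is zero everywhere")
    out <- array(0, d)
  } else {
    out <- array(round(resp / m * 255), d)
  }
  gray_volume(out, voxel_size_um = vol$voxel_size_um, bit_depth = 8L)
}

#' Render a synthetic cylinder volume
#'
#' A bright cylinder (gray value 255) on black background, axis along z,
#' centered in the slice, with an anti-aliased edge (boundary voxels get a
#' value proportional to their coverage). The calibration target of
#' [calibrate_opt_threshold()].
#'
#' @param d cylinder diameter in voxels.
#' @param shape volume shape `c(nx, ny, nz)` or a scalar for a cube.
#' @param voxel_size_um voxel size of the returned volume.
#' @return A [gray_volume()].
#' @export
render_cylinder <- function(d, shape = 96, voxel_size_um = 45) {
  if (length(shape) == 1L) shape <- rep(shape, 3L)
  R <- d / 2
  cx <- (shape[1] + 1) / 2
  cy <- (shape[2] + 1) / 2
  dist <- sqrt(outer((seq_len(shape[1]) - cx)^2,
                     (seq_len(shape[2]) - cy)^2, "+"))
  cov <- pmin(pmax(R + 0.5 - dist, 0), 1)
  slice <- cov * 255
  vol <- array(slice, dim = shape) # recycled along z
  gray_volume(round(vol), voxel_size_um = voxel_size_um, bit_depth = 8L)
}

# diametral gray-value transect of the mid z slice, averaged over the two
# center rows (the axis sits between voxel rows for an even-sized volume)
diametral_transect <- function(vol) {
  d <- vol_dim(vol)
  zmid <- max(1L, d[3] %/% 2L)
  cy <- (d[2] + 1) / 2
  rows <- unique(c(floor(cy), ceiling(cy)))
  sl <- vol$data[, , zmid]
  profile <- rowMeans(sl[, rows, drop = FALSE])
  profile
}

# value of a transect at distance `radius` from the axis, averaged over
# both sides, with linear interpolation between voxel centers
transect_at_radius <- function(profile, radius) {
  n <- length(profile)
  cx <- (n + 1) / 2
  sample_at <- function(x) {
    x0 <- floor(x); x1 <- ceiling(x)
    if (x0 < 1 || x1 > n) return(NA_real_)
    if (x0 == x1) return(profile[x0])
    profile[x0] * (x1 - x) + profile[x1] * (x - x0)
  }
  mean(c(sample_at(cx - radius), sample_at(cx + radius)))
}

# classify a transect as hollow (central local minimum flanked by two
# symmetric maxima inside the root outline) or concave (single central
# maximum); `R` is the root radius in voxels
transect_is_hollow <- function(profile, R, tol = 0.5) {
  n <- length(profile)
  cx <- (n + 1) / 2
  center <- transect_at_radius(profile, 0)
  inside <- profile[abs(seq_len(n) - cx) < R]
  center < max(inside) - tol
}

#' Calibrate the optimal lower hysteresis threshold against q
#'
#' Re-runs the synthetic calibration that ties the normalized smoothing
#' strength `q = sigma / d` to the lower hysteresis threshold which
#' recovers the original root outline: a bright cylinder of diameter `d`
#' is rendered, tubeness-filtered at `sigma = q * d` for every grid value,
#' normalized to 255, and the gray value of the diametral transect at the
#' original root outline (radius `d/2` from the axis) is recorded as
#' `t_opt(q)`. Grid points in the hollow regime (central local minimum:
#' the filtered root appears hollow when `q <= 0.125`) are excluded from
#' the fit with a message. A small model family (power `a*q^b`,
#' exponential `a*exp(b*q)`, quadratic) is fitted and the best R-squared
#' model is kept.
#'
#' Because `q` normalizes scale by diameter, the curve is (up to
#' discretization) independent of `d`; the pipeline evaluates it at the
#' fixed working point `q = 0.5`, where it reproduces the published
#' threshold of 79 within the discretization band.
#'
#' @param d diameter of the rendered cylinder in voxels (default 32).
#' @param q_grid grid of q values in `(0, 1]` with `q * d >= 0.5`.
#' @param shape volume shape passed to [render_cylinder()].
#' @return A `calibration_curve`: sampled points (with the hollow flag),
#'   the fitted family, coefficients, and R-squared.
#' @export
calibrate_opt_threshold <- function(d = 32,
                                    q_grid = c(0.1875, 0.25, 0.3125, 0.375,
                                               0.4375, 0.5, 0.625, 0.75, 1),
                                    shape = 96) {
  if (any(q_grid <= 0 | q_grid > 1))
    stop("`q_grid` must lie in (0, 1]", call. = FALSE)
  if (any(q_grid * d < 0.5))
    stop("`d` too small: q * d must be >= 0.5 for all grid points",
         call. = FALSE)
  cyl <- render_cylinder(d, shape)
  R <- d / 2
  pts <- data.frame(q = q_grid, sigma = q_grid * d, t_opt = NA_real_,
                    hollow = NA)
  for (i in seq_along(q_grid)) {
    tb <- tubeness(cyl, pts$sigma[i])
    profile <- diametral_transect(tb)
    pts$hollow[i] <- transect_is_hollow(profile, R)
    pts$t_opt[i] <- transect_at_radius(profile, R)
  }
  if (any(pts$hollow))
    message("excluded hollow-regime q values from the fit: ",
            paste(format(pts$q[pts$hollow]), collapse = ", "))
  fitpts <- pts[!pts$hollow, , drop = FALSE]
  if (nrow(fitpts) < 3L)
    stop("no concave-regime samples: all q values are in the hollow regime",
         call. = FALSE)
  fits <- fit_curve_family(fitpts$q, fitpts$t_opt)
  if (length(fits) == 0L)
    stop("no calibration model could be fitted", call. = FALSE)
  best <- fits[[which.max(vapply(fits, function(f) f$r2, numeric(1)))]]
  structure(list(points = pts, family = best$family,
                 coefficients = best$coefficients, r_squared = best$r2,
                 predict_fun = best$predict, d = d),
            class = "calibration_curve")
}

# fit the candidate model family; returns only models that converged
fit_curve_family <- function(q, t) {
  out <- list()
  r2 <- function(obs, pred) 1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)
  # quadratic
  fq <- lm(t ~ q + I(q^2))
  cf <- unname(coef(fq))
  out$quadratic <- list(
    family = "quadratic", coefficients = c(a = cf[1], b = cf[2], c = cf[3]),
    r2 = r2(t, fitted(fq)),
    predict = local({
      cf <- cf
      function(x) cf[1] + cf[2] * x + cf[3] * x^2
    }))
  # power: a * q^b
  fp <- tryCatch({
    pos <- t > 0
    start <- if (sum(pos) >= 2) {
      lf <- lm(log(t[pos]) ~ log(q[pos]))
      list(a = exp(coef(lf)[[1]]), b = coef(lf)[[2]])
    } else list(a = max(t), b = 2)
    nls(t ~ a * q^b, start = start,
        control = list(maxiter = 200, warnOnly = TRUE))
  }, error = function(e) NULL)
  if (!is.null(fp)) {
    cf <- coef(fp)
    out$power <- list(
      family = "power", coefficients = c(a = cf[["a"]], b = cf[["b"]]),
      r2 = r2(t, predict(fp)),
      predict = local({
        cf <- cf
        function(x) cf[["a"]] * x^cf[["b"]]
      }))
  }
  # exponential: a * exp(b * q)
  fe <- tryCatch({
    pos <- t > 0
    start <- if (sum(pos) >= 2) {
      lf <- lm(log(t[pos]) ~ q[pos])
      list(a = exp(coef(lf)[[1]]), b = coef(lf)[[2]])
    } else list(a = 1, b = 3)
    nls(t ~ a * exp(b * q), start = start,
        control = list(maxiter = 200, warnOnly = TRUE))
  }, error = function(e) NULL)
  if (!is.null(fe)) {
    cf <- coef(fe)
    out$exponential <- list(
      family = "exponential", coefficients = c(a = cf[["a"]], b = cf[["b"]]),
      r2 = r2(t, predict(fe)),
      predict = local({
        cf <- cf
        function(x) cf[["a"]] * exp(cf[["b"]] * x)
      }))
  }
  out
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "<calibration_curve> d = %g voxels, %d grid points (%d concave), %s fit, R^2 = %.3f\n",
    x$d, nrow(x$points), sum(!x$points$hollow), x$family, x$r_squared))
  cat(sprintf("  t_opt(q = 0.5) = %.1f\n", predict(x, 0.5)))
  invisible(x)
}

#' Evaluate a calibration curve
#'
#' @param object a `calibration_curve`.
#' @param q normalized smoothing strength value(s).
#' @param ... unused.
#' @return Predicted optimal lower threshold(s), clipped to `[0, 255]`.
#' @export
predict.calibration_curve <- function(object, q, ...) {
  pmin(pmax(object$predict_fun(q), 0), 255)
}

#' Build the multi-scale detection plan
#'
#' Lists the tubeness/hysteresis passes covering root diameters from
#' `d_min` to `d_max` in steps of `d_inc` (all in voxels at the original
#' resolution). Fine diameters (`d <= crossover_d`) are processed at the
#' original resolution (`f_s = 1`); coarser ones on the half-resolution
#' volume (`f_s = 0.5`), where `sigma_i = q * d_i * f_s`. The lower
#' hysteresis threshold is the calibrated `t_opt(q)` (identical for every
#' pass since `q` is fixed); the upper threshold is a constant seed
#' threshold.
#'
#' @param d_min,d_inc,d_max diameter schedule in voxels (defaults 4, 4, 28).
#' @param crossover_d largest diameter still processed at the original
#'   resolution (default 8).
#' @param q normalized smoothing strength (quasi-fixed at 0.5).
#' @param curve a `calibration_curve`, used for `t_low`; alternatively pass
#'   `t_low` directly.
#' @param t_low lower hysteresis threshold; overrides `curve`.
#' @param t_high upper (seed) hysteresis threshold, constant and high
#'   (default 200).
#' @return A `sigma_plan` data frame with columns
#'   `d_r, f_s, sigma, t_low, t_high`.
#' @export
build_sigma_plan <- function(d_min = 4, d_inc = 4, d_max = 28,
                             crossover_d = 8, q = 0.5, curve = NULL,
                             t_low = NULL, t_high = 200) {
  if (!(d_min <= crossover_d && crossover_d <= d_max))
    stop("need d_min <= crossover_d <= d_max", call. = FALSE)
  if (d_inc <= 0) stop("`d_inc` must be > 0", call. = FALSE)
  diameters <- seq(d_min, d_max, by = d_inc)
  if (length(diameters) == 0L) stop("empty plan", call. = FALSE)
  if (is.null(t_low)) {
    if (is.null(curve))
      stop("supply either `curve` or `t_low`", call. = FALSE)
    t_low <- predict(curve, q)
  }
  f_s <- ifelse(diameters <= crossover_d, 1, 0.5)
  plan <- data.frame(d_r = diameters, f_s = f_s,
                     sigma = q * diameters * f_s,
                     t_low = t_low, t_high = t_high)
  class(plan) <- c("sigma_plan", "data.frame")
  attr(plan, "q") <- q
  plan
}

#' Hysteresis thresholding
#'
#' Seed voxels at or above `t_high` definitively belong to roots; a region
#' growing process adds every voxel at or above `t_low` that is
#' 26-connected to a seed through such voxels. Improves edge continuity on
#' the gradual partial-volume boundaries of fine roots.
#'
#' @param vol a [gray_volume()].
#' @param t_low,t_high thresholds with `t_low <= t_high`.
#' @return A [binary_volume()].
#' @export
hysteresis <- function(vol, t_low, t_high) {
  stopifnot(is_gray_volume(vol))
  if (t_low > t_high) stop("`t_low` must be <= `t_high`", call. = FALSE)
  d <- vol_dim(vol)
  m <- .hysteresis_cpp(as.double(vol$data), d, t_low, t_high)
  binary_volume(array(m, d), voxel_size_um = vol$voxel_size_um)
}

#' Multi-scale root segmentation
#'
#' Runs every pass of a [build_sigma_plan()] plan on the
#' background-removed volume: passes with `f_s = 0.5` operate on the
#' block-mean half-resolution volume and their masks are upscaled back;
#' each pass is tubeness filtering at its `sigma` followed by hysteresis
#' thresholding. The passes are combined with a logical MAX (union): a
#' voxel is root if any resolution or scale detects it.
#'
#' @param vol the background-removed [gray_volume()] (dark background).
#' @param plan a `sigma_plan`.
#' @return A [binary_volume()].
#' @export
segment_roots <- function(vol, plan) {
  stopifnot(is_gray_volume(vol), inherits(plan, "sigma_plan"))
  d <- vol_dim(vol)
  acc <- array(FALSE, d)
  coarse <- if (any(plan$f_s == 0.5)) downscale(vol, 2L) else NULL
  for (i in seq_len(nrow(plan))) {
    p <- plan[i, ]
    if (p$f_s == 1) {
      m <- hysteresis(tubeness(vol, p$sigma), p$t_low, p$t_high)
    } else {
      mc <- hysteresis(tubeness(coarse, p$sigma), p$t_low, p$t_high)
      m <- upscale_mask(mc, d)
    }
    acc <- acc | m$data
  }
  binary_volume(acc, voxel_size_um = vol$voxel_size_um)
}
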