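# Pipeline orchestration: a single validated configuration drives the
# full chain (stitch -> attenuation -> denoise -> mask/peaks -> unsharp ->
# background removal -> multi-scale segmentation -> median -> keep-largest
# -> false-negative recovery -> skeleton/thickness/RLD) with stage logging
# and optional persisted intermediates for resumption.

#' Pipeline configuration
#'
#' Collects the ten tunable parameters of the workflow (contrast threshold,
#' blur radius, mask weight, root gray-value factor and range, minimum and
#' maximum root diameter, median kernel, size and vesselness thresholds)
#' together with the quasi-fixed ones (`q`, `d_r_inc`, the resolution
#' crossover, the upper hysteresis threshold) and the run inputs (ROI
#' anchors, stitch overlap, reference slice, paths). Defaults follow the
#' published benchmark calibration (clean-scenario column).
#'
#' @param t_con non-local-means contrast threshold.
#' @param blur_radius,mask_weight unsharp-mask parameters.
#' @param f_r,R_r background-removal root gray-value factor and range.
#' @param d_r_min,d_r_inc,d_r_max diameter schedule in voxels.
#' @param crossover_d largest diameter processed at full resolution.
#' @param q normalized smoothing strength (quasi-fixed, 0.5).
#' @param t_high upper hysteresis threshold.
#' @param median_kernel 3D median kernel size.
#' @param t_v,t_s false-negative recovery vesselness and size thresholds.
#' @param roi_anchors list of three `c(z, cx, cy, r)` vectors, or NULL for
#'   phantom runs that carry their own ROI.
#' @param roi_extension extended-ROI margin in voxels.
#' @param stitch_overlap overlap slices when two sub-stacks are supplied.
#' @param reference_slice attenuation-correction reference (NULL = skip).
#' @param denoise run the non-local-means stage.
#' @param voxel_size_um voxel size for inputs that do not carry one.
#' @param calibration_d,calibration_shape synthetic-cylinder settings for
#'   the threshold calibration.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(t_con = 60, blur_radius = 0.9, mask_weight = 0.8,
                            f_r = 0.18, R_r = 70,
                            d_r_min = 4, d_r_inc = 4, d_r_max = 28,
                            crossover_d = 8, q = 0.5, t_high = 200,
                            median_kernel = 2, t_v = 0.9, t_s = 25,
                            roi_anchors = NULL, roi_extension = 50,
                            stitch_overlap = 0, reference_slice = NULL,
                            denoise = TRUE, voxel_size_um = 45,
                            calibration_d = 32, calibration_shape = 96) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  fail <- function(...) stop("invalid configuration: ", ..., call. = FALSE)
  if (cfg$mask_weight <= 0 || cfg$mask_weight >= 1)
    fail("mask_weight must be in (0, 1)")
  if (cfg$blur_radius <= 0) fail("blur_radius must be > 0")
  if (cfg$f_r < 0 || cfg$f_r > 1) fail("f_r must be in [0, 1]")
  if (cfg$R_r <= 0 || cfg$R_r > 255) fail("R_r must be in (0, 255]")
  if (!(cfg$d_r_min <= cfg$crossover_d && cfg$crossover_d <= cfg$d_r_max))
    fail("need d_r_min <= crossover_d <= d_r_max")
  if (cfg$d_r_inc <= 0) fail("d_r_inc must be > 0")
  if (cfg$q <= 0 || cfg$q > 1) fail("q must be in (0, 1]")
  if (cfg$t_high < 0 || cfg$t_high > 255) fail("t_high must be in [0, 255]")
  if (cfg$median_kernel < 0) fail("median_kernel must be >= 0")
  if (cfg$t_v <= 0 || cfg$t_v >= 1) fail("t_v must be in (0, 1)")
  if (cfg$t_s <= 0) fail("t_s must be > 0")
  if (!is.null(cfg$roi_anchors)) {
    if (length(cfg$roi_anchors) != 3L)
      fail("roi_anchors must hold three (z, cx, cy, r) anchors")
    for (a in cfg$roi_anchors)
      if (length(a) != 4L || a[4] <= 0) fail("bad ROI anchor")
  }
  invisible(cfg)
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; keys match the arguments of [pipeline_config()],
#'   with `roi_anchors` a list of three 4-element sequences.
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown))
    stop("invalid configuration: unknown keys: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  do.call(pipeline_config, y)
}

# calibration curves are deterministic in (d, grid, shape): cache them
cached_calibration <- function(d, shape) {
  key <- paste0("calib_", d, "_", shape)
  if (is.null(.rootct_cache[[key]]))
    .rootct_cache[[key]] <- calibrate_opt_threshold(d = d, shape = shape)
  .rootct_cache[[key]]
}

stage_names <- c("stitch", "attenuation", "denoise", "mask", "unsharp",
                 "background", "segment", "median", "connect", "recover",
                 "quantify")

#' Run the full segmentation and quantification pipeline
#'
#' Executes the stages in workflow order on a grayscale volume (or two
#' sub-stacks to stitch), logging every derived scalar (P1, P2, the root
#' average gray value, the ADT threshold, the sigma schedule and the
#' hysteresis thresholds) into a run summary. All stages are
#' user-interaction free: every input comes from the configuration.
#'
#' @param config a `pipeline_config` or path to its YAML file.
#' @param volume a [gray_volume()], or path readable by [read_volume()];
#'   alternatively `bottom`/`top` for two sub-stacks.
#' @param bottom,top optional sub-stacks to stitch.
#' @param roi optional `pot_mask` (e.g. from a phantom) overriding
#'   `config$roi_anchors`.
#' @param output_dir optional run directory; when given, the final mask
#'   and skeleton (TIFF), the diameter distribution and object shape
#'   tables (CSV), the resolved configuration (YAML) and the run summary
#'   (JSON) are written there.
#' @param keep_intermediates persist each stage's volume as NRRD in
#'   `output_dir/intermediates` and reuse them on resumption.
#' @param from resume from this stage (requires intermediates persisted by
#'   a previous run in the same `output_dir`).
#' @return A list with the final `mask`, `skeleton`, `thickness`,
#'   `distribution`, `shapes`, and `summary` (the logged scalars).
#' @export
run_pipeline <- function(config, volume = NULL, bottom = NULL, top = NULL,
                         roi = NULL, output_dir = NULL,
                         keep_intermediates = FALSE, from = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  validate_config(config)
  if (!is.null(from) && !from %in% stage_names)
    stop("unknown stage '", from, "'", call. = FALSE)
  if (!is.null(output_dir))
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  int_dir <- if (!is.null(output_dir)) file.path(output_dir, "intermediates")
  if (keep_intermediates && !is.null(int_dir))
    dir.create(int_dir, showWarnings = FALSE, recursive = TRUE)
  summary <- list(stages = list())
  t_start <- Sys.time()
  log_stage <- function(name, ...) {
    info <- list(...)
    summary$stages[[name]] <<- info
    message(sprintf("[%s] %s", name,
                    paste(names(info), vapply(info, function(x)
                      paste(format(x, digits = 6), collapse = " "),
                      character(1)),
                      sep = "=", collapse = " ")))
  }
  persist <- function(name, vol) {
    if (keep_intermediates && !is.null(int_dir))
      write_volume(vol, file.path(int_dir, paste0(name, ".nrrd")))
    vol
  }
  resume_from <- function(name) {
    if (is.null(from) || is.null(int_dir)) return(NULL)
    skip_to <- match(from, stage_names)
    here <- match(name, stage_names)
    if (here > skip_to) return(NULL)
    f <- file.path(int_dir, paste0(name, ".nrrd"))
    if (file.exists(f)) read_volume(f) else NULL
  }
  wrap_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  # ---- input / stitch
  vol <- wrap_stage("stitch", {
    if (!is.null(bottom) || !is.null(top)) {
      if (is.character(bottom)) bottom <- read_volume(bottom,
        voxel_size_um = config$voxel_size_um)
      if (is.character(top)) top <- read_volume(top,
        voxel_size_um = config$voxel_size_um)
      v <- stitch_stacks(bottom, top, config$stitch_overlap)
      log_stage("stitch", overlap = config$stitch_overlap,
                shape = vol_dim(v))
      v
    } else {
      if (is.character(volume)) volume <- read_volume(volume,
        voxel_size_um = config$voxel_size_um)
      stopifnot(is_gray_volume(volume))
      log_stage("stitch", skipped = TRUE, shape = vol_dim(volume))
      volume
    }
  })
  d <- vol_dim(vol)

  # ---- attenuation correction
  if (!is.null(config$reference_slice)) {
    vol <- wrap_stage("attenuation", {
      v <- attenuation_correct(vol, config$reference_slice)
      log_stage("attenuation", reference_slice = config$reference_slice)
      persist("attenuation", v)
    })
  } else log_stage("attenuation", skipped = TRUE)

  # ---- denoise
  if (isTRUE(config$denoise)) {
    cached <- resume_from("denoise")
    vol <- wrap_stage("denoise", {
      if (!is.null(cached)) {
        log_stage("denoise", resumed = TRUE)
        cached
      } else {
        v <- nlm_denoise(vol, t_con = config$t_con)
        log_stage("denoise", t_con = config$t_con)
        persist("denoise", v)
      }
    })
  } else log_stage("denoise", skipped = TRUE)

  # ---- pot mask + peaks
  peaks <- NULL
  masked <- wrap_stage("mask", {
    if (is.null(roi)) {
      if (is.null(config$roi_anchors))
        stop("no ROI: supply `roi` or config$roi_anchors")
      a <- config$roi_anchors
      roi <- interpolate_roi(
        circle_roi(a[[1]][1], a[[1]][2], a[[1]][3], a[[1]][4]),
        circle_roi(a[[2]][1], a[[2]][2], a[[2]][3], a[[2]][4]),
        circle_roi(a[[3]][1], a[[3]][2], a[[3]][3], a[[3]][4]),
        d[3], extension = config$roi_extension)
    }
    peaks <- find_peaks(vol, roi)
    v <- apply_mask(vol, roi)
    log_stage("mask", P1 = peaks$P1, P2 = peaks$P2,
              extension = roi$extension)
    v
  })

  # ---- unsharp mask
  masked <- wrap_stage("unsharp", {
    v <- unsharp_mask(masked, config$blur_radius, config$mask_weight)
    log_stage("unsharp", blur_radius = config$blur_radius,
              mask_weight = config$mask_weight)
    persist("unsharp", v)
  })

  # ---- background removal
  v_bar_r <- root_gv(peaks, config$f_r)
  t_adt <- adt_threshold(config$R_r)
  bg <- wrap_stage("background", {
    v <- remove_background(masked, v_bar_r, config$R_r)
    log_stage("background", f_r = config$f_r, R_r = config$R_r,
              v_bar_r = v_bar_r, t_adt = t_adt)
    persist("background", v)
  })

  # ---- multi-scale segmentation
  seg <- wrap_stage("segment", {
    curve <- cached_calibration(config$calibration_d, config$calibration_shape)
    plan <- build_sigma_plan(config$d_r_min, config$d_r_inc, config$d_r_max,
                             config$crossover_d, config$q, curve = curve,
                             t_high = config$t_high)
    summary$plan <- plan
    log_stage("segment", t_low = plan$t_low[1], t_high = config$t_high,
              sigmas = plan$sigma, calibration_family = curve$family,
              calibration_r2 = curve$r_squared)
    segment_roots(bg, plan)
  })

  # ---- postprocessing
  seg <- wrap_stage("median", {
    v <- median3d(seg, config$median_kernel)
    log_stage("median", kernel = config$median_kernel)
    v
  })
  parts <- wrap_stage("connect", {
    p <- split_connected(seg, roi)
    log_stage("connect", n_unconnected = p$n_others)
    p
  })
  rec <- wrap_stage("recover", {
    r <- recover_false_negatives(parts$largest, parts$others,
                                 t_v = config$t_v, t_s = config$t_s)
    log_stage("recover", n_candidates = nrow(r$shapes),
              n_recovered = sum(r$shapes$recovered),
              t_v = config$t_v, t_s = config$t_s)
    r
  })
  final_mask <- rec$mask

  # ---- quantification
  quant <- wrap_stage("quantify", {
    if (!any(final_mask$data)) {
      log_stage("quantify", empty = TRUE)
      list(skeleton = NULL, thickness = NULL, distribution = NULL)
    } else {
      skel <- skeletonize(final_mask)
      thick <- local_thickness(final_mask)
      dist <- diameter_distribution(skel, thick)
      log_stage("quantify", total_length_mm = skel$total_length_um / 1000,
                rld_cm_per_cm3 = sum(dist$rld_cm_per_cm3))
      list(skeleton = skel, thickness = thick, distribution = dist)
    }
  })

  summary$derived <- list(P1 = peaks$P1, P2 = peaks$P2, v_bar_r = v_bar_r,
                          t_adt = t_adt,
                          total_length_um = if (!is.null(quant$skeleton))
                            quant$skeleton$total_length_um else 0)
  summary$elapsed_s <- as.numeric(difftime(Sys.time(), t_start, units = "secs"))

  if (!is.null(output_dir)) {
    write_volume(final_mask, file.path(output_dir, "root_mask.tif"))
    if (!is.null(quant$skeleton))
      write_volume(quant$skeleton$mask, file.path(output_dir, "skeleton.tif"))
    if (!is.null(quant$distribution))
      write.csv(quant$distribution,
                file.path(output_dir, "diameter_distribution.csv"),
                row.names = FALSE)
    write.csv(rec$shapes, file.path(output_dir, "object_shapes.csv"),
              row.names = FALSE)
    cfg_out <- config
    cfg_out$roi_anchors <- NULL
    yaml::write_yaml(unclass(cfg_out)[!vapply(unclass(cfg_out), is.null,
                                              logical(1))],
                     file.path(output_dir, "resolved_config.yaml"))
    json_summary <- summary
    json_summary$plan <- as.data.frame(summary$plan)
    jsonlite::write_json(json_summary,
                         file.path(output_dir, "run_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows")
  }

  list(mask = final_mask, skeleton = quant$skeleton,
       thickness = quant$thickness, distribution = quant$distribution,
       shapes = rec$shapes, summary = summary)
}
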