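# End-to-end pipeline driver: fixtures -> segment -> locate -> wound ->
# plan -> simulate, with a JSON report of per-stage metrics.

#' Pipeline configuration
#'
#' All stage parameters in one validated object. Referenced files (optional
#' camera/chain/servo YAMLs) must exist at validation time — a missing file
#' is a configuration error raised before any computation. All randomness
#' flows from the single `seed`.
#'
#' @param seed Integer seed (mandatory; drives every stochastic stage).
#' @param crater List: `kind`, `radius`, `depth`, `sample_step`, `margin`.
#' @param grid_step Reconstruction grid pitch, mm.
#' @param rig_params List: `baseline`, `fx`, `width`, `height`, `distance`,
#'   `depression`.
#' @param segmentation A [segmentation_config()].
#' @param plan List: `line_spacing`, `step`, `layer_height`,
#'   `threshold_volume`.
#' @param servo List: `kind`, `speed`, `duration`.
#' @param camera_yaml,chain_yaml,servo_yaml Optional config file paths.
#' @param log_level `"info"` or `"quiet"`.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            crater = list(kind = "hemisphere", radius = 5,
                                          depth = 5, sample_step = 0.25,
                                          margin = 3),
                            grid_step = 0.25,
                            rig_params = list(baseline = 60, fx = 1200,
                                              width = 640, height = 480,
                                              distance = 400,
                                              depression = pi / 2.4),
                            segmentation = segmentation_config(),
                            plan = list(line_spacing = 1.0, step = 0.5,
                                        layer_height = 0.5,
                                        threshold_volume = 20),
                            servo = list(kind = "circle", speed = 15,
                                         duration = 6),
                            camera_yaml = NULL, chain_yaml = NULL,
                            servo_yaml = NULL, log_level = "info") {
  for (f in c(camera_yaml, chain_yaml, servo_yaml)) {
    if (!is.null(f) && !file.exists(f)) {
      stop("config error: referenced file does not exist: ", f)
    }
  }
  stopifnot(is.numeric(seed), length(seed) == 1)
  structure(list(seed = as.integer(seed), crater = crater,
                 grid_step = grid_step, rig_params = rig_params,
                 segmentation = segmentation, plan = plan, servo = servo,
                 camera_yaml = camera_yaml, chain_yaml = chain_yaml,
                 servo_yaml = servo_yaml, log_level = log_level),
            class = "pipeline_config")
}

#' Run the full planning-and-tracking pipeline on synthetic fixtures
#'
#' Generates the crater scan and stereo wound renders, segments and
#' triangulates the wound, reconstructs the surface and computes the defect
#' volume, plans the bioink toolpath, and runs the tracking simulation.
#' Every stage writes versioned artifacts into `out_dir` plus a
#' `report.json` with per-stage metrics; the same config and seed reproduce
#' the report byte-for-byte.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created).
#' @return The report, invisibly (a nested list, also written as JSON).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("woundpath_")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_msg <- function(...) {
    if (identical(config$log_level, "info")) message("[woundpath] ", ...)
  }
  seed <- config$seed
  report <- list(package = "woundpath",
                 version = as.character(utils::packageVersion("woundpath")),
                 seed = seed, stages = list())

  # -- fixtures -----------------------------------------------------------
  log_msg("stage 1/5: fixtures")
  cr <- config$crater
  crater <- gen_crater_cloud(kind = cr$kind, radius = cr$radius,
                             depth = cr$depth, sample_step = cr$sample_step,
                             margin = cr$margin, seed = seed)
  rp <- config$rig_params
  rig0 <- make_stereo_rig(baseline = rp$baseline, fx = rp$fx, fy = rp$fx,
                          width = rp$width, height = rp$height)
  sw <- gen_stereo_wound(rig0, distance = rp$distance,
                         depression = rp$depression,
                         wound_radius = cr$radius, seed = seed)
  write_image_png(sw$left, file.path(out_dir, "wound_left.png"))
  write_image_png(sw$right, file.path(out_dir, "wound_right.png"))
  report$stages$fixtures <- list(
    crater_kind = cr$kind, crater_radius_mm = cr$radius,
    truth_volume_mm3 = crater$truth$volume_mm3,
    cloud_points = nrow(crater$cloud))

  # -- segmentation -------------------------------------------------------
  log_msg("stage 2/5: segmentation + 3D localization")
  seg_l <- segment_wound(sw$left, config$segmentation)
  seg_r <- segment_wound(sw$right, config$segmentation)
  if (!length(seg_l) || !length(seg_r)) {
    stop("stage failure (segment): no wound contour found in one of the views")
  }
  utils::write.csv(contours_table(seg_l), file.path(out_dir, "contours_left.csv"),
                   row.names = FALSE)
  utils::write.csv(contours_table(seg_r), file.path(out_dir, "contours_right.csv"),
                   row.names = FALSE)
  tri <- triangulate(sw$rig, seg_l[[1]]$centroid, seg_r[[1]]$centroid)
  locate_err <- sqrt(sum((tri$point - sw$truth$center3d)^2))
  report$stages$locate <- list(
    centroid_left_px = unname(seg_l[[1]]$centroid),
    centroid_right_px = unname(seg_r[[1]]$centroid),
    point_mm = tri$point,
    reprojection_residual_px = tri$reprojection_residual_px,
    location_error_mm = locate_err)

  # -- wound model --------------------------------------------------------
  log_msg("stage 3/5: surface reconstruction + defect volume")
  mesh <- reconstruct_surface(crater$cloud, grid_step = config$grid_step)
  model <- extract_wound(mesh)
  save_wound_model(model, file.path(out_dir, "wound"))
  vol_err <- abs(model$volume_mm3 - crater$truth$volume_mm3) /
    crater$truth$volume_mm3
  report$stages$wound <- list(
    volume_mm3 = model$volume_mm3,
    truth_volume_mm3 = crater$truth$volume_mm3,
    volume_rel_error = vol_err,
    rim_vertices = nrow(model$rim))

  # -- toolpath -----------------------------------------------------------
  log_msg("stage 4/5: toolpath planning + bioink allocation")
  pl <- config$plan
  tp <- plan_wound(model, line_spacing = pl$line_spacing, step = pl$step,
                   layer_height = pl$layer_height,
                   threshold_volume = pl$threshold_volume)
  write_toolpath_json(tp, file.path(out_dir, "toolpath.json"))
  write_toolpath_gcode(tp, file.path(out_dir, "toolpath.gcode"))
  report$stages$plan <- list(
    strategy = attr(tp, "strategy"),
    n_waypoints = nrow(tp),
    n_layers = length(unique(tp$layer)),
    total_extrude_ul = sum(tp$extrude),
    conservation_error_ul = abs(sum(tp$extrude) - model$volume_mm3))

  # -- servo simulation ---------------------------------------------------
  log_msg("stage 5/5: tracking simulation")
  sv <- config$servo
  traj <- make_trajectory(sv$kind, speed = sv$speed, duration = sv$duration)
  trace <- simulate_tracking(traj, servo_config(), seed = seed)
  write_trace_csv(trace, file.path(out_dir, "trace.csv"))
  st <- error_stats(trace)
  report$stages$servo <- list(
    kind = sv$kind, speed_mm_s = sv$speed,
    max_error_mm = st$max_mm[st$segment == "all"],
    mean_error_mm = st$mean_mm[st$segment == "all"],
    rms_error_mm = st$rms_mm[st$segment == "all"])

  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_msg("report written to ", file.path(out_dir, "report.json"))
  invisible(report)
}
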