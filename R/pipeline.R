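#' Path to a shipped fixture table
#'
#' The package ships the study's printed measurement tables as CSV fixtures:
#' `"table1_patients"` (cohort characteristics), `"table2_interobserver"`
#' (both observers' AoSA measurements), `"table3_aosa"` (per-patient AoSA
#' mean/SD, percent change, CV), `"table4_ascending"` (ascending-aorta
#' geometry per patient and phase).
#'
#' @param name fixture name (without extension).
#' @return file path.
#' @export
aosa_fixture <- function(name = c("table1_patients", "table2_interobserver",
                                  "table3_aosa", "table4_ascending")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".csv"), package = "aosa")
  if (path == "") stop("fixture not found: ", name)
  path
}

#' Per-patient geometric measurement pipeline
#'
#' Runs the full workflow: surface/volume ingestion, heat-conduction solve,
#' isoline extraction, centerline with cross-sections, segment metrics,
#' outer/inner curvature lines, cardiac axes, repeated AoSA measurement, and
#' ascending-aorta inclination. Deterministic given the seed in
#' `config$repeats`.
#'
#' @param config list with fields:
#' \describe{
#'   \item{meshes}{named list (`aorta`, `left_ventricle`, `left_atrium`) of
#'     [tri_surface()] objects or mesh file paths; alternatively supply
#'     `volume`.}
#'   \item{volume}{a [label_volume()] or NIfTI path (with `label_map`);
#'     structure surfaces are extracted with [mask_to_surface()] and the
#'     LVOT/mitral interfaces with [interface_surface()].}
#'   \item{interfaces}{named list (`lvot`, `mitral`) of
#'     [interface_surface()] objects; required with `meshes`, computed from
#'     `volume` otherwise.}
#'   \item{landmarks}{named list of [landmark()]s or a JSON path; needs
#'     `inlet_seed` and `outlet_seed`; `apex_seed` is optional (the apex
#'     falls back to the LV vertex farthest from the mitral centroid).}
#'   \item{clip_planes}{optional list of `list(point, normal)` applied to
#'     the aorta surface before the solve (used to open mask-derived
#'     surfaces at the STJ and distal end).}
#'   \item{n_levels, samples_per_contour, smooth_window_mm,
#'     resample_step_mm, aai_window_mm}{pipeline knobs (defaults 100, 64,
#'     10, 0.5, 20).}
#'   \item{ascending_segment}{`c(s_start, s_end)` in mm of centerline arc
#'     length (default: the whole analyzed segment).}
#'   \item{repeats}{`list(n, jitter_mm, seed)` for the repeated AoSA
#'     measurement (defaults 5, 2, 1).}
#'   \item{output_dir}{optional; writes `report.json`, `centerline.csv`,
#'     and VTP polylines there.}
#' }
#' @return list of class `patient_report`; see fields in the JSON it
#'   writes: `aosa_deg_mean`, `aosa_deg_sd`, `cv_percent`, `aai_deg`,
#'   `aai_sd_deg`, `segment` (length, tortuosity, mean diameter),
#'   `outer_line_length_mm`, `inner_line_length_mm`, and a provenance
#'   `manifest`.
#' @export
run_measure <- function(config) {
  cfg <- resolve_config(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  ingest <- stage("ingest", ingest_inputs(cfg))
  aorta <- ingest$aorta
  if (!is.null(cfg$clip_planes)) {
    aorta <- stage("clip", {
      for (cp in cfg$clip_planes)
        aorta <- clip_surface(aorta, cp$point, cp$normal)
      aorta
    })
  }
  field <- stage("harmonic_field",
                 solve_harmonic(aorta, ingest$landmarks$inlet_seed,
                                ingest$landmarks$outlet_seed))
  iso <- stage("isolines", extract_isolines(field, cfg$n_levels))
  cl <- stage("centerline",
              compute_centerline(field, iso, cfg$smooth_window_mm,
                                 cfg$resample_step_mm))
  cl <- stage("cross_sections", cross_section_areas(cl, aorta))
  seg_bounds <- cfg$ascending_segment
  if (is.null(seg_bounds)) seg_bounds <- c(0, max(cl$arc_length))
  seg <- stage("segment_metrics",
               segment_metrics(cl, seg_bounds[1], seg_bounds[2]))
  rings <- list(loop_points(field$surface, field$inlet_loop),
                loop_points(field$surface, field$outlet_loop))
  paths <- stage("curvature_lines",
                 extremal_paths(iso, cfg$samples_per_contour,
                                end_rings = rings))
  apex <- ingest$landmarks$apex_seed
  apex_fallback <- is.null(apex)
  if (apex_fallback) {
    if (is.null(ingest$left_ventricle))
      stop("[axes] no apex landmark and no LV surface for the fallback")
    apex <- auto_apex(ingest$left_ventricle, ingest$interfaces$mitral$centroid)
  }
  ao_axis <- stage("axes", aortic_axis(cl, ingest$interfaces$lvot))
  ve_axis <- stage("axes", ventricular_axis(apex, ingest$interfaces$mitral))
  pair <- stage("axes", aosa(ao_axis, ve_axis))
  reps <- stage("repeatability", repeat_measurement(
    list(centerline = cl, lvot_interface = ingest$interfaces$lvot,
         apex = apex, mitral_interface = ingest$interfaces$mitral),
    n_repeats = cfg$repeats$n, jitter_mm = cfg$repeats$jitter_mm,
    seed = cfg$repeats$seed))
  aai <- stage("inclination",
               ascending_inclination(cl, ao_axis, cfg$aai_window_mm))
  report <- list(
    aosa_deg_mean = mean(reps),
    aosa_deg_sd = stats::sd(reps),
    aosa_deg_single = pair$aosa_deg,
    cv_percent = if (abs(mean(reps)) > 1e-12)
      100 * stats::sd(reps) / mean(reps) else 0,
    aai_deg = aai$aai_deg,
    aai_sd_deg = aai$aai_sd_deg,
    segment = list(length_mm = seg$length_L,
                   endpoint_distance_mm = seg$endpoint_distance_D,
                   tortuosity = seg$tortuosity_T,
                   mean_diameter_mm = seg$mean_diameter),
    outer_line_length_mm = paths$outer$length,
    inner_line_length_mm = paths$inner$length,
    manifest = list(package_version = as.character(utils::packageVersion("aosa")),
                    apex_fallback = apex_fallback,
                    config = cfg[setdiff(names(cfg),
                                         c("meshes", "volume", "interfaces",
                                           "landmarks", "output_dir"))],
                    repeats = cfg$repeats))
  class(report) <- "patient_report"
  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(unclass(report),
                         file.path(cfg$output_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
    write_centerline_csv(cl, file.path(cfg$output_dir, "centerline.csv"))
    write_vtp_polylines(list(cl$points, paths$outer$points,
                             paths$inner$points),
                        file.path(cfg$output_dir, "lines.vtp"))
  }
  attr(report, "objects") <- list(field = field, isolines = iso,
                                  centerline = cl, paths = paths,
                                  axes = pair, surface = aorta)
  report
}

#' @export
print.patient_report <- function(x, ...) {
  cat(sprintf("<patient_report> AoSA %.2f +/- %.2f deg (CV %.2f%%); AAI %.2f +/- %.2f deg\n",
              x$aosa_deg_mean, x$aosa_deg_sd, x$cv_percent, x$aai_deg,
              x$aai_sd_deg))
  cat(sprintf("  segment: L %.2f mm, T %.4f, mean diameter %s mm; outer %.2f mm, inner %.2f mm\n",
              x$segment$length_mm, x$segment$tortuosity,
              ifelse(is.na(x$segment$mean_diameter_mm), "NA",
                     sprintf("%.2f", x$segment$mean_diameter_mm)),
              x$outer_line_length_mm, x$inner_line_length_mm))
  invisible(x)
}

resolve_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
    else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  defaults <- list(n_levels = 100L, samples_per_contour = 64L,
                   smooth_window_mm = 10, resample_step_mm = 0.5,
                   aai_window_mm = 20,
                   repeats = list(n = 5L, jitter_mm = 2, seed = 1L))
  cfg <- utils::modifyList(defaults, config)
  for (knob in c("n_levels", "samples_per_contour", "smooth_window_mm",
                 "resample_step_mm", "aai_window_mm")) {
    if (cfg[[knob]] <= 0) stop("config knob must be positive: ", knob)
  }
  cfg
}

ingest_inputs <- function(cfg) {
  lm <- cfg$landmarks
  if (is.character(lm)) lm <- read_landmarks(lm)
  if (is.null(lm$inlet_seed) || is.null(lm$outlet_seed))
    stop("landmarks must include inlet_seed and outlet_seed")
  out <- list(landmarks = lm)
  if (!is.null(cfg$volume)) {
    vol <- cfg$volume
    if (is.character(vol)) vol <- read_label_volume(vol, cfg$label_map)
    out$aorta <- mask_to_surface(vol, "aorta")
    out$left_ventricle <- mask_to_surface(vol, "left_ventricle")
    out$interfaces <- list(
      lvot = interface_surface(vol, "left_ventricle", "aorta"),
      mitral = interface_surface(vol, "left_ventricle", "left_atrium"))
  } else if (!is.null(cfg$meshes)) {
    load_mesh <- function(x) if (is.character(x)) read_surface(x) else x
    out$aorta <- load_mesh(cfg$meshes$aorta)
    if (!is.null(cfg$meshes$left_ventricle))
      out$left_ventricle <- load_mesh(cfg$meshes$left_ventricle)
    if (is.null(cfg$interfaces))
      stop("mesh input requires lvot and mitral interfaces")
    out$interfaces <- cfg$interfaces
  } else stop("config needs either meshes or volume")
  if (is.null(out$interfaces$lvot) || is.null(out$interfaces$mitral))
    stop("both lvot and mitral interfaces are required")
  out
}

#' Reproduce the study-level statistics from the fixture tables
#'
#' Runs the statistics layer on the shipped (or caller-supplied) CSVs of the
#' printed measurement tables: inter-observer ICC from the two observers'
#' AoSA measurements, intra-observer CV summaries, aneurysm-subgroup and
#' dissection AoSA changes, and per-metric cohort summaries with paired
#' pre/post tests for the ascending-aorta geometry.
#'
#' @param table2,table3,table4 CSV paths (defaults: the shipped fixtures).
#' @return list with `icc`, `icc_mean_k`, `cv`, `aosa_aneurysm`,
#'   `aosa_dissection`, `ascending` (per-metric summaries and paired
#'   comparisons).
#' @export
run_stats <- function(table2 = aosa_fixture("table2_interobserver"),
                      table3 = aosa_fixture("table3_aosa"),
                      table4 = aosa_fixture("table4_ascending")) {
  t2 <- utils::read.csv(table2)
  t3 <- utils::read.csv(table3)
  t4 <- utils::read.csv(table4)
  # inter-observer reliability: each patient-phase is a subject
  subj <- paste(t2$patient, t2$phase, sep = ":")
  wide <- tapply(t2$aosa_deg, list(subj, t2$observer), mean)
  icc <- icc_two_way_random(wide, form = "single")
  icc_k <- icc_two_way_random(wide, form = "mean_k")
  # intra-observer repeatability
  cv <- list(pre_mean = mean(t3$cv_pre_percent),
             pre_sd = stats::sd(t3$cv_pre_percent),
             post_mean = mean(t3$cv_post_percent),
             post_sd = stats::sd(t3$cv_post_percent))
  # AoSA by pathology subgroup
  an <- t3[t3$pathology == "aneurysm", ]
  di <- t3[t3$pathology == "dissection", ]
  aosa_aneurysm <- paired_t(an$aosa_pre_mean, an$aosa_post_mean,
                            metric_name = "aosa_deg")
  aosa_aneurysm$mean_patient_change_percent <-
    mean(100 * (an$aosa_post_mean - an$aosa_pre_mean) / an$aosa_pre_mean)
  aosa_dissection <- list(
    n = nrow(di),
    pre = di$aosa_pre_mean, post = di$aosa_post_mean,
    change_percent = 100 * (di$aosa_post_mean - di$aosa_pre_mean) /
      di$aosa_pre_mean)
  # ascending-aorta geometry: summaries and paired tests per metric
  metrics <- c("aai_deg", "diameter_mm", "tortuosity",
               "centerline_length_mm", "outer_line_mm", "inner_line_mm")
  long <- tidyr::pivot_longer(t4, dplyr::all_of(metrics),
                              names_to = "metric", values_to = "value")
  ascending <- cohort_summary(long, group_cols = c("metric", "phase"),
                              compare_phases = TRUE)
  list(icc = icc, icc_mean_k = icc_k, cv = cv,
       aosa_aneurysm = aosa_aneurysm, aosa_dissection = aosa_dissection,
       ascending = ascending)
}
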