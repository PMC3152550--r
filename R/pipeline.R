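#' Run the simulate-segment-quantify-screen pipeline
#'
#' Renders one synthetic plate under the configured scenario, segments every
#' field, pools per-cell measurements into well summaries, and runs the
#' plate-level screen. All randomness descends from `config$seed`, so two
#' runs of the same config produce identical reports. When `config$out_dir`
#' is set, the image set, truth tables, well summaries, extract calls and a
#' JSON report embedding the exact config are written there.
#'
#' @param config A [run_config()].
#' @return A `pipeline_result`: list with the `plate` (`ld_plate`),
#'   `well_summaries`, `screen` (`screen_report`) and the `config` used.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  lib <- scenario_library()
  if (!config$scenario %in% names(lib)) {
    abort(sprintf("pipeline stage 'simulate': unknown scenario '%s'.", config$scenario))
  }
  scenario <- lib[[config$scenario]]
  layout <- plate_layout(
    n_extracts = config$n_extracts,
    n_increasers = config$n_increasers,
    n_decreasers = config$n_decreasers,
    n_cytotoxic = config$n_cytotoxic,
    seed = derive_seed(config$seed, 777L)
  )
  scene <- do.call(plate_scene_params, config$scene)
  seg <- do.call(segmentation_params, config$segmentation)
  plate <- render_plate(layout, scenario, scene = scene,
                        fields_per_well = config$fields_per_well,
                        seed = config$seed)
  wells <- quantify_plate(plate, params = seg)
  report <- screen_plate(wells, layout, k = config$k, sd_type = config$sd_type)
  result <- structure(
    list(plate = plate, well_summaries = wells, screen = report,
         config = config),
    class = "pipeline_result"
  )
  if (!is.null(config$out_dir)) write_pipeline_result(result, config$out_dir)
  result
}

write_pipeline_result <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_image_set(result$plate, file.path(dir, "images"))
  wells_flat <- select(result$well_summaries, -"ld_histogram")
  write.csv(wells_flat, file.path(dir, "well_summaries.csv"), row.names = FALSE)
  write.csv(result$screen$extract_calls, file.path(dir, "extract_calls.csv"),
            row.names = FALSE)
  report <- list(
    config = unclass(result$config),
    seed = result$config$seed,
    plate_stats = result$screen$plate_stats,
    hit_counts = result$screen$hit_counts,
    cooccurrence = result$screen$cooccurrence,
    qc = result$screen$qc
  )
  jsonlite::write_json(report, file.path(dir, "screen_report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> scenario '%s', seed %d\n",
              x$config$scenario, x$config$seed))
  print(x$screen)
  invisible(x)
}
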