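#' Write and read 16-bit grayscale TIFF images
#'
#' Images are integer-valued matrices on the 0-65535 scale; on disk they are
#' standard 16-bit grayscale TIFFs, so a write/read round trip is
#' pixel-identical.
#'
#' @param image Numeric matrix with values in [0, 65535].
#' @param path Output path.
#' @export
write_image_tiff <- function(image, path) {
  assert_image(image)
  if (min(image) < 0 || max(image) > 65535) abort("image values outside 16-bit range.")
  tiff::writeTIFF(image / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' @rdname write_image_tiff
#' @export
read_image_tiff <- function(path) {
  round(tiff::readTIFF(path) * 65535)
}

field_filename <- function(plate, well_id, field, channel) {
  sprintf("P%d_W%s_F%d_C%d.tif", plate, well_id, field, channel)
}

#' Write a simulated plate as a TIFF image set plus truth tables
#'
#' One 16-bit TIFF per channel per field, named
#' `P{plate}_W{well}_F{field}_C{channel}.tif` (channel 1 = nuclei,
#' channel 2 = neutral lipid), with the per-cell and per-well ground truth
#' as CSV.
#'
#' @param plate An `ld_plate` from [render_plate()].
#' @param dir Output directory (created if needed).
#' @param plate_id Integer plate number used in filenames.
#' @return `dir`, invisibly.
#' @export
write_image_set <- function(plate, dir, plate_id = 1L) {
  stopifnot(inherits(plate, "ld_plate"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nrow(plate$fields))) {
    f <- plate$fields[i, ]
    write_image_tiff(f$nuclei[[1]], file.path(dir, field_filename(plate_id, f$well_id, f$field, 1L)))
    write_image_tiff(f$droplets[[1]], file.path(dir, field_filename(plate_id, f$well_id, f$field, 2L)))
  }
  truth_cells <- plate$fields %>%
    select("well_id", "field", "truth") %>%
    mutate(truth = map(.data$truth, ~ select(.x, -"ld_centroids"))) %>%
    tidyr::unnest("truth")
  write.csv(truth_cells, file.path(dir, sprintf("P%d_truth_cells.csv", plate_id)),
            row.names = FALSE)
  write.csv(plate$truth_wells, file.path(dir, sprintf("P%d_truth_wells.csv", plate_id)),
            row.names = FALSE)
  write.csv(plate$layout, file.path(dir, sprintf("P%d_plate_map.csv", plate_id)),
            row.names = FALSE)
  invisible(dir)
}

#' Read a plate image set from a directory of TIFFs
#'
#' Parses the `P{plate}_W{well}_F{field}_C{channel}.tif` naming convention
#' (strict), groups per well/field with deterministic ordering, and errors
#' naming the offending well/field when a channel is missing.
#'
#' @param dir Directory holding the TIFFs.
#' @return Tibble: `plate`, `well_id`, `field`, list-columns `nuclei` and
#'   `droplets`.
#' @export
read_image_set <- function(dir) {
  files <- list.files(dir, pattern = "^P\\d+_W[A-P]\\d{2}_F\\d+_C[12]\\.tif$")
  if (length(files) == 0L) abort(sprintf("no plate TIFFs found in '%s'.", dir))
  info <- tibble(
    file = files,
    plate = as.integer(sub("^P(\\d+)_.*", "\\1", files)),
    well_id = sub("^P\\d+_W([A-P]\\d{2})_.*", "\\1", files),
    field = as.integer(sub(".*_F(\\d+)_.*", "\\1", files)),
    channel = as.integer(sub(".*_C([12])\\.tif$", "\\1", files))
  )
  grouped <- info %>%
    tidyr::pivot_wider(id_cols = c("plate", "well_id", "field"),
                       names_from = "channel", values_from = "file",
                       names_prefix = "ch") %>%
    arrange(.data$plate, .data$well_id, .data$field)
  if (!all(c("ch1", "ch2") %in% names(grouped))) {
    grouped$ch1 <- grouped$ch1 %||% NA_character_
    grouped$ch2 <- grouped$ch2 %||% NA_character_
  }
  miss <- filter(grouped, is.na(.data$ch1) | is.na(.data$ch2))
  if (nrow(miss) > 0L) {
    abort(sprintf("missing channel for well %s field %d.",
                  miss$well_id[1], miss$field[1]))
  }
  grouped %>%
    mutate(nuclei = map(.data$ch1, ~ read_image_tiff(file.path(dir, .x))),
           droplets = map(.data$ch2, ~ read_image_tiff(file.path(dir, .x)))) %>%
    select("plate", "well_id", "field", "nuclei", "droplets")
}

#' Pipeline run configuration
#'
#' Collects every tunable of a simulate-segment-quantify-screen run in one
#' serialisable object. [write_run_config()] / [read_run_config()] round-trip
#' it through YAML without loss.
#'
#' @param scenario Scenario name resolved in [scenario_library()].
#' @param seed Top-level seed; all randomness descends from it.
#' @param n_extracts,fields_per_well Plate geometry.
#' @param n_increasers,n_decreasers,n_cytotoxic Planted actives.
#' @param k,sd_type Hit-calling parameters.
#' @param scene Named list of [scene_params()] overrides for plate fields.
#' @param segmentation Named list of [segmentation_params()] overrides.
#' @param out_dir Optional output directory; when set, [run_pipeline()]
#'   writes images, tables and the JSON report there.
#' @return A `run_config` list.
#' @export
run_config <- function(scenario = "screen-plate", seed = 1L,
                       n_extracts = 42L, fields_per_well = 1L,
                       n_increasers = 0L, n_decreasers = 0L, n_cytotoxic = 0L,
                       k = 1, sd_type = "population",
                       scene = list(), segmentation = list(),
                       out_dir = NULL) {
  cfg <- list(scenario = scenario, seed = as.integer(seed),
              n_extracts = as.integer(n_extracts),
              fields_per_well = as.integer(fields_per_well),
              n_increasers = as.integer(n_increasers),
              n_decreasers = as.integer(n_decreasers),
              n_cytotoxic = as.integer(n_cytotoxic),
              k = k, sd_type = sd_type,
              scene = scene, segmentation = segmentation,
              out_dir = out_dir)
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(run_config, cfg)
}
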