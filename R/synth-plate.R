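#' Default 96-well screening-plate layout
#'
#' Builds the standard screening layout: `n_extracts` extracts in duplicate
#' plus control wells (inactive extract, triacsin C, media only). Optionally
#' plants actives among the extracts — LD increasers, LD decreasers and
#' cytotoxic extracts — whose identities are recorded in the `planted` column
#' so downstream hit calls can be scored against truth.
#'
#' @param n_extracts Number of extracts, each in duplicate (default 42).
#' @param n_replicates Wells per extract (default 2).
#' @param n_increasers,n_decreasers,n_cytotoxic Number of planted actives.
#' @param n_inactive,n_triacsin,n_media Control wells per class.
#' @param seed Seed for choosing which extracts carry planted effects.
#' @return Tibble with one row per well: `well_id`, `role`, `extract_id`,
#'   `treatment` (scenario key), `concentration`, `conc_units`, `replicate`,
#'   `planted`.
#' @export
plate_layout <- function(n_extracts = 42L, n_replicates = 2L,
                         n_increasers = 0L, n_decreasers = 0L, n_cytotoxic = 0L,
                         n_inactive = 4L, n_triacsin = 4L, n_media = 4L,
                         seed = 1L) {
  n_active <- n_increasers + n_decreasers + n_cytotoxic
  if (n_active > n_extracts) abort("more planted actives than extracts.")
  planted <- rep("none", n_extracts)
  if (n_active > 0L) {
    idx <- with_seed(seed, sample.int(n_extracts, n_active))
    planted[idx] <- rep(c("ld_increase", "ld_decrease", "cytotoxic"),
                        c(n_increasers, n_decreasers, n_cytotoxic))
  }
  treatment_of <- c(none = "extract", ld_increase = "extract_increaser",
                    ld_decrease = "extract_decreaser", cytotoxic = "extract_cytotoxic")
  extracts <- tibble(
    extract_id = sprintf("E%02d", seq_len(n_extracts)),
    planted = planted,
    treatment = unname(treatment_of[planted])
  )
  ext_wells <- tidyr::crossing(extracts, replicate = seq_len(n_replicates)) %>%
    mutate(role = "extract", concentration = 50, conc_units = "ug/mL")
  ctrl <- function(role, treatment, n, conc, units) {
    if (n == 0L) return(NULL)
    tibble(extract_id = NA_character_, planted = NA_character_,
           treatment = treatment, replicate = seq_len(n), role = role,
           concentration = conc, conc_units = units)
  }
  wells <- bind_rows(
    ext_wells,
    ctrl("inactive-extract", "inactive_extract", n_inactive, 50, "ug/mL"),
    ctrl("triacsin-C", "triacsin_c", n_triacsin, 1, "uM"),
    ctrl("media-only", "media_only", n_media, NA_real_, NA_character_)
  )
  if (nrow(wells) > 384L) abort("layout exceeds 384 wells.")
  n_cols <- if (nrow(wells) <= 96L) 12L else 24L
  wells %>%
    mutate(
      well_id = sprintf("%s%02d", LETTERS[(row_number() - 1L) %/% n_cols + 1L],
                        (row_number() - 1L) %% n_cols + 1L)
    ) %>%
    select("well_id", "role", "extract_id", "treatment",
           "concentration", "conc_units", "replicate", "planted")
}

#' Default scene parameters for plate-scale simulation
#'
#' Compact 320 x 320 px fields with a nominal 40 cells per field, so a full
#' 96-well plate renders and segments in seconds while keeping per-well
#' sampling (cells per field) close to the assay's working density.
#'
#' @param ... Overrides passed to [scene_params()].
#' @export
plate_scene_params <- function(field_shape = c(320L, 320L), n_cells = 40L,
                               cytoplasm_radius_px = 28,
                               cytoplasm_radius_jitter = 2,
                               min_nucleus_spacing_px = 29, ...) {
  scene_params(field_shape = field_shape, n_cells = n_cells,
               cytoplasm_radius_px = cytoplasm_radius_px,
               cytoplasm_radius_jitter = cytoplasm_radius_jitter,
               min_nucleus_spacing_px = min_nucleus_spacing_px, ...)
}

#' Render a whole synthetic plate with per-well ground truth
#'
#' For every well in the layout, resolves its treatment in the scenario,
#' thins the nominal cell count binomially by the treatment's survival
#' fraction, draws the LD rate, and renders `fields_per_well` independent
#' fields. All randomness descends from `seed` through per-well substreams,
#' so a plate is reproducible well-by-well.
#'
#' @param layout A [plate_layout()] tibble.
#' @param scenario A [scenario_config()]; every `layout$treatment` must
#'   resolve in `scenario$treatments`.
#' @param scene Base [scene_params()]; `n_cells` is the nominal (pre-survival)
#'   count and `ld_rate` is overridden per treatment.
#' @param fields_per_well Imaging fields per well.
#' @param seed Top-level integer seed.
#' @return An `ld_plate` object: `fields` (tibble with list-columns `nuclei`,
#'   `droplets` and per-field `truth`), `truth_wells` (per-well true mean
#'   LDs/cell and surviving-cell counts), plus `layout`, `scenario`, `seed`.
#' @export
render_plate <- function(layout, scenario, scene = plate_scene_params(),
                         fields_per_well = 1L, seed = 1L) {
  stopifnot(inherits(scenario, "scenario_config"))
  unknown <- setdiff(unique(layout$treatment), scenario$treatments$treatment)
  if (length(unknown) > 0L) {
    abort(sprintf("treatment(s) not in scenario '%s': %s",
                  scenario$name, paste(unknown, collapse = ", ")),
          class = "dropscreen_treatment_error")
  }
  tr <- scenario$treatments
  fields <- vector("list", nrow(layout) * fields_per_well)
  k <- 0L
  for (w in seq_len(nrow(layout))) {
    t_i <- tr[match(layout$treatment[w], tr$treatment), ]
    for (f in seq_len(fields_per_well)) {
      k <- k + 1L
      sub <- derive_seed(seed, (w - 1L) * fields_per_well + f)
      n_surv <- with_seed(derive_seed(sub, 999983L),
                          rbinom(1L, scene$n_cells, t_i$survival))
      p <- scene
      p$n_cells <- n_surv
      p$ld_rate <- t_i$ld_rate
      sc <- render_scene(p, seed = sub)
      fields[[k]] <- tibble(
        well_id = layout$well_id[w], field = f,
        nuclei = list(sc$nuclei), droplets = list(sc$droplets),
        truth = list(sc$truth)
      )
    }
  }
  fields <- bind_rows(fields)
  truth_wells <- fields %>%
    group_by(.data$well_id) %>%
    summarise(
      true_n_cells = sum(map_int(.data$truth, nrow)),
      true_total_lds = sum(map_dbl(.data$truth, ~ sum(.x$ld_count))),
      n_fields = dplyr::n(),
      .groups = "drop"
    ) %>%
    mutate(
      true_mean_lds_per_cell = ifelse(.data$true_n_cells > 0,
                                      .data$true_total_lds / .data$true_n_cells, NA_real_),
      true_cells_per_field = .data$true_n_cells / .data$n_fields
    ) %>%
    left_join(select(layout, "well_id", "treatment"), by = "well_id")
  structure(
    list(fields = fields, truth_wells = truth_wells, layout = layout,
         scenario = scenario$name, scene = scene,
         fields_per_well = as.integer(fields_per_well), seed = as.integer(seed)),
    class = "ld_plate"
  )
}

#' @export
print.ld_plate <- function(x, ...) {
  cat(sprintf("<ld_plate> scenario '%s': %d wells x %d field(s) (seed %d)\n",
              x$scenario, nrow(x$layout), x$fields_per_well, x$seed))
  invisible(x)
}
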