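#' Per-cell measurements from a segmented field
#'
#' One record per cell territory: the assigned LD count, the territory area,
#' and the integrated cytoplasmic intensity — the sum of background-corrected
#' pixel values over the territory, clipped at zero. The background estimate
#' defaults to the image median.
#'
#' @param seg An `ld_segmentation` from [segment_field()].
#' @param droplet_image The intensity channel the territories were drawn on.
#' @param background `"median"` (default) or a numeric background level.
#' @return Tibble: `cell_id`, `ld_count`, `cytoplasm_area_px`,
#'   `integrated_cytoplasmic_intensity`.
#' @export
per_cell_measurements <- function(seg, droplet_image, background = "median") {
  stopifnot(inherits(seg, "ld_segmentation"))
  assert_image(droplet_image, "droplet_image")
  if (!all(dim(seg$cell_labels) == dim(droplet_image))) {
    abort("`droplet_image` does not match the segmentation frame.")
  }
  bg <- if (identical(background, "median")) stats::median(droplet_image) else background
  labs <- seg$cell_labels
  idx <- which(labs > 0)
  ids <- labs[idx]
  if (length(idx) == 0L) {
    return(tibble(cell_id = integer(0), ld_count = integer(0),
                  cytoplasm_area_px = integer(0),
                  integrated_cytoplasmic_intensity = numeric(0)))
  }
  uid <- sort(unique(ids))
  area <- tabulate(ids)[uid]
  intens <- as.vector(rowsum(pmax(droplet_image[idx] - bg, 0), ids))
  tibble(cell_id = as.integer(uid),
         cytoplasm_area_px = as.integer(area),
         integrated_cytoplasmic_intensity = intens) %>%
    left_join(seg$per_cell, by = "cell_id") %>%
    mutate(ld_count = ifelse(is.na(.data$ld_count), 0L, .data$ld_count)) %>%
    select("cell_id", "ld_count", "cytoplasm_area_px",
           "integrated_cytoplasmic_intensity")
}

#' Histogram of per-cell LD counts
#'
#' Unit-width bins from 0 up to `cap`; the last bin is open-ended (counts
#' of `cap` or more are lumped there).
#'
#' @param ld_counts Integer vector of per-cell LD counts.
#' @param cap Top (open-ended) bin.
#' @return Tibble `ld_count` (bin), `n_cells`.
#' @export
ld_histogram <- function(ld_counts, cap = 60L) {
  binned <- pmin(ld_counts, cap)
  tibble(ld_count = 0:cap,
         n_cells = as.integer(table(factor(binned, levels = 0:cap))))
}

#' Summarise the fields of one well
#'
#' Cells are pooled across fields; nuclei per field is the total cell count
#' divided by the number of fields. A well with zero cells gets an explicit
#' `NA` mean (never a silent zero).
#'
#' @param records Per-cell tibble ([per_cell_measurements()] rows, possibly
#'   from several fields bound together).
#' @param n_fields Number of imaging fields pooled.
#' @param well_id Optional well label carried into the output.
#' @param hist_cap Open-ended top bin of the LD-count histogram.
#' @return One-row tibble: `well_id`, `n_cells`, `mean_lds_per_cell`,
#'   `nuclei_per_field`, `mean_integrated_intensity`, and the histogram as a
#'   list-column `ld_histogram`.
#' @export
summarize_well <- function(records, n_fields = 1L, well_id = NA_character_,
                           hist_cap = 60L) {
  if (n_fields < 1L) abort("`n_fields` must be >= 1.")
  n_cells <- nrow(records)
  tibble(
    well_id = well_id,
    n_cells = n_cells,
    n_fields = as.integer(n_fields),
    mean_lds_per_cell = if (n_cells > 0) mean(records$ld_count) else NA_real_,
    nuclei_per_field = n_cells / n_fields,
    mean_integrated_intensity = if (n_cells > 0) {
      mean(records$integrated_cytoplasmic_intensity)
    } else NA_real_,
    ld_histogram = list(ld_histogram(records$ld_count, cap = hist_cap))
  )
}

hist_mean <- function(h) {
  tot <- sum(h$n_cells)
  if (tot == 0) return(NA_real_)
  sum(h$ld_count * h$n_cells) / tot
}

#' Signed shift between two LD-count distributions
#'
#' Difference of distribution means, `mean(B) - mean(A)`: positive when B is
#' right-shifted (more LDs per cell) relative to A. Histograms must share a
#' bin grid; an empty histogram gives an explicit `NA`.
#'
#' @param hist_a,hist_b Tibbles from [ld_histogram()].
#' @return Signed shift in LDs per cell (`NA_real_` if either is empty).
#' @export
distribution_shift <- function(hist_a, hist_b) {
  if (!identical(hist_a$ld_count, hist_b$ld_count)) {
    abort("histograms must share the same bin grid.")
  }
  ma <- hist_mean(hist_a)
  mb <- hist_mean(hist_b)
  if (is.na(ma) || is.na(mb)) return(NA_real_)
  mb - ma
}

#' Quantify a rendered plate into per-well summaries
#'
#' Runs segmentation and per-cell measurement over every field of an
#' [render_plate()] object (or a tibble in the same shape) and pools fields
#' into one [summarize_well()] row per well.
#'
#' @param plate An `ld_plate` or its `fields` tibble (columns `well_id`,
#'   `field`, `nuclei`, `droplets`).
#' @param params A [segmentation_params()] object.
#' @param hist_cap Top histogram bin.
#' @return Tibble of well summaries, one row per well.
#' @export
quantify_plate <- function(plate, params = segmentation_params(), hist_cap = 60L) {
  fields <- if (inherits(plate, "ld_plate")) plate$fields else plate
  per_field <- pmap(
    list(fields$well_id, fields$nuclei, fields$droplets),
    function(w, nuc, drop) {
      seg <- segment_field(nuc, drop, params)
      per_cell_measurements(seg, drop) %>% mutate(well_id = w)
    }
  )
  cells <- bind_rows(per_field)
  n_fields <- fields %>% count(.data$well_id, name = "n_fields")
  bind_rows(lapply(n_fields$well_id, function(w) {
    summarize_well(filter(cells, .data$well_id == w),
                   n_fields = n_fields$n_fields[n_fields$well_id == w],
                   well_id = w, hist_cap = hist_cap)
  }))
}
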