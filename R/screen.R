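#' Average replicate wells into per-extract metrics
#'
#' Joins well summaries to the plate layout and averages each extract's
#' replicate wells (arithmetic mean). Wells with an undefined metric (no
#' cells) are dropped from the average; an extract with no usable well keeps
#' an explicit `NA`.
#'
#' @param well_summaries Tibble from [quantify_plate()] / [summarize_well()].
#' @param layout A [plate_layout()] tibble.
#' @return Tibble with one row per extract: `extract_id`,
#'   `mean_lds_per_cell`, `nuclei_per_field`, `n_wells`, `planted`.
#' @export
average_duplicates <- function(well_summaries, layout) {
  joined <- layout %>%
    filter(.data$role == "extract") %>%
    left_join(well_summaries, by = "well_id")
  if (any(is.na(joined$n_cells))) {
    abort("layout refers to wells missing from the summaries.")
  }
  joined %>%
    group_by(.data$extract_id, .data$planted) %>%
    summarise(
      mean_lds_per_cell = if (all(is.na(.data$mean_lds_per_cell))) NA_real_ else
        mean(.data$mean_lds_per_cell, na.rm = TRUE),
      nuclei_per_field = mean(.data$nuclei_per_field),
      n_wells = dplyr::n(),
      .groups = "drop"
    ) %>%
    arrange(.data$extract_id)
}

#' Plate normal range (mean +/- k * SD)
#'
#' The screen's hit-calling band: mean and SD over the extract-level
#' (replicate-averaged) values, bounds at `mean +/- k * sd`. Control wells
#' are excluded upstream. Population SD (divide by n) is the default.
#'
#' @param values Numeric vector of extract-level metrics (>= 3 non-missing).
#' @param k SD multiplier (default 1).
#' @param sd_type `"population"` or `"sample"`.
#' @return One-row tibble: `mean`, `sd`, `lower`, `upper`, `k`, `n`.
#' @export
plate_normal_range <- function(values, k = 1, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  values <- values[!is.na(values)]
  if (length(values) < 3L) {
    abort("need at least 3 values to compute a plate normal range.")
  }
  m <- mean(values)
  s <- sd_by_type(values, sd_type)
  tibble(mean = m, sd = s, lower = m - k * s, upper = m + k * s,
         k = k, n = length(values))
}

#' Call hits from per-extract metrics
#'
#' Flags each extract against the plate normal ranges: `ld_increase` when
#' mean LDs/cell exceeds the upper bound, `ld_decrease` when below the lower
#' bound, and `cytotoxic` when nuclei/field falls below the lower bound of
#' its own range (cell loss; unusually high nuclei counts are not called
#' cytotoxic). Flags are independent; co-occurrence is reported, not merged.
#'
#' @param extract_metrics Tibble from [average_duplicates()].
#' @param k SD multiplier for both ranges.
#' @param sd_type SD convention, see [plate_normal_range()].
#' @return Tibble of extract calls with logical flag columns; the ranges used
#'   are attached as attribute `"plate_stats"` (a two-row tibble).
#' @export
call_hits <- function(extract_metrics, k = 1, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  rng_ld <- plate_normal_range(extract_metrics$mean_lds_per_cell, k, sd_type)
  rng_nuc <- plate_normal_range(extract_metrics$nuclei_per_field, k, sd_type)
  calls <- extract_metrics %>%
    mutate(
      ld_increase = !is.na(.data$mean_lds_per_cell) & .data$mean_lds_per_cell > rng_ld$upper,
      ld_decrease = !is.na(.data$mean_lds_per_cell) & .data$mean_lds_per_cell < rng_ld$lower,
      cytotoxic = .data$nuclei_per_field < rng_nuc$lower
    )
  attr(calls, "plate_stats") <- bind_rows(
    mutate(rng_ld, metric = "mean_lds_per_cell"),
    mutate(rng_nuc, metric = "nuclei_per_field")
  ) %>% select("metric", dplyr::everything())
  calls
}

#' Co-occurrence of cytotoxicity with LD flags
#'
#' @param calls Tibble from [call_hits()].
#' @return One-row tibble: counts of cytotoxic extracts and how many of them
#'   also carry an LD-increase or LD-decrease flag.
#' @export
hit_cooccurrence <- function(calls) {
  tox <- filter(calls, .data$cytotoxic)
  tibble(
    n_cytotoxic = nrow(tox),
    n_cytotoxic_and_ld_increase = sum(tox$ld_increase),
    n_cytotoxic_and_ld_decrease = sum(tox$ld_decrease)
  )
}

#' Hit rate as a whole-number percentage
#'
#' @param n_hits,n_screened Hit and screened counts.
#' @return `round(100 * n_hits / n_screened)` as an integer percentage.
#' @export
hit_rate <- function(n_hits, n_screened) {
  if (any(n_screened <= 0)) abort("`n_screened` must be > 0.")
  if (any(n_hits < 0 | n_hits > n_screened)) {
    abort("`n_hits` must lie in [0, n_screened].")
  }
  round(100 * n_hits / n_screened)
}

#' Percent inhibition against on-plate controls
#'
#' `100 * (1 - (treated - baseline) / (positive_control - baseline))`,
#' with the oleic-acid-loaded wells as the positive (uninhibited) control
#' and the delipidated wells as baseline. 0 percent = fully loaded,
#' 100 percent = down at baseline.
#'
#' @param treated Treated response(s) (vectorised).
#' @param positive_control Loaded-control response.
#' @param baseline Delipidated-baseline response.
#' @return Percent inhibition (numeric, same length as `treated`).
#' @export
percent_inhibition <- function(treated, positive_control, baseline) {
  if (isTRUE(all.equal(positive_control, baseline))) {
    abort("positive control equals baseline: inhibition undefined.")
  }
  100 * (1 - (treated - baseline) / (positive_control - baseline))
}

#' Fold change over baseline
#'
#' @param condition_mean,baseline_mean Condition and baseline means.
#' @return `condition_mean / baseline_mean`.
#' @export
fold_change <- function(condition_mean, baseline_mean) {
  if (any(baseline_mean == 0)) abort("baseline mean of zero: fold change undefined.")
  condition_mean / baseline_mean
}

#' Assay window and Z'-factor from control wells
#'
#' `Z' = 1 - 3 * (sd_pos + sd_neg) / |mean_neg - mean_pos|`, with the
#' inhibited (triacsin C) wells as the positive control and the loaded
#' (inactive extract) wells as the negative control. The window ratio
#' `mean_neg / mean_pos` is reported alongside.
#'
#' @param positive_wells Metric values from the inhibited control wells.
#' @param negative_wells Metric values from the loaded control wells.
#' @param sd_type SD convention (default sample SD).
#' @return One-row tibble: control means/SDs, `window`, `z_prime`, and a
#'   logical `defined` flag (FALSE when the control means coincide).
#' @export
assay_window <- function(positive_wells, negative_wells,
                         sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  if (length(positive_wells) < 2L || length(negative_wells) < 2L) {
    abort("need >= 2 wells per control class.")
  }
  mp <- mean(positive_wells); mn <- mean(negative_wells)
  sp <- sd_by_type(positive_wells, sd_type); sn <- sd_by_type(negative_wells, sd_type)
  defined <- !isTRUE(all.equal(mp, mn))
  tibble(
    mean_positive = mp, sd_positive = sp,
    mean_negative = mn, sd_negative = sn,
    window = if (mp != 0) mn / mp else NA_real_,
    z_prime = if (defined) 1 - 3 * (sp + sn) / abs(mn - mp) else NA_real_,
    defined = defined
  )
}

#' Run the full plate-level screen analysis
#'
#' Averages duplicates, computes normal ranges over the extracts, calls
#' hits, tallies hit rates and co-occurrence, and quantifies the assay
#' window from the on-plate controls.
#'
#' @param well_summaries Tibble from [quantify_plate()].
#' @param layout The [plate_layout()] used.
#' @param k SD multiplier for the normal ranges.
#' @param sd_type SD convention for the ranges.
#' @return A `screen_report`: list with `extract_calls`, `plate_stats`,
#'   `hit_counts`, `cooccurrence`, `qc`, and the parameters used.
#' @export
screen_plate <- function(well_summaries, layout, k = 1,
                         sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  metrics <- average_duplicates(well_summaries, layout)
  calls <- call_hits(metrics, k = k, sd_type = sd_type)
  ctrl <- layout %>%
    filter(.data$role != "extract") %>%
    left_join(well_summaries, by = "well_id")
  pos <- filter(ctrl, .data$role == "triacsin-C")$mean_lds_per_cell
  neg <- filter(ctrl, .data$role == "inactive-extract")$mean_lds_per_cell
  qc <- if (length(pos) >= 2L && length(neg) >= 2L) {
    assay_window(pos, neg)
  } else {
    NULL
  }
  n <- nrow(calls)
  hit_counts <- tibble(
    n_extracts = n,
    n_ld_increase = sum(calls$ld_increase),
    n_ld_decrease = sum(calls$ld_decrease),
    n_cytotoxic = sum(calls$cytotoxic),
    rate_ld_increase_pct = hit_rate(sum(calls$ld_increase), n),
    rate_ld_decrease_pct = hit_rate(sum(calls$ld_decrease), n),
    rate_cytotoxic_pct = hit_rate(sum(calls$cytotoxic), n)
  )
  structure(
    list(extract_calls = calls,
         plate_stats = attr(calls, "plate_stats"),
         hit_counts = hit_counts,
         cooccurrence = hit_cooccurrence(calls),
         qc = qc,
         k = k, sd_type = sd_type),
    class = "screen_report"
  )
}

#' @export
print.screen_report <- function(x, ...) {
  h <- x$hit_counts
  cat(sprintf(
    "<screen_report> %d extracts: %d LD-increase, %d LD-decrease, %d cytotoxic (k = %g, %s SD)\n",
    h$n_extracts, h$n_ld_increase, h$n_ld_decrease, h$n_cytotoxic, x$k, x$sd_type
  ))
  if (!is.null(x$qc)) cat(sprintf("  Z' = %.3f, window = %.2f\n", x$qc$z_prime, x$qc$window))
  invisible(x)
}
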