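#' Plot a rendered field
#'
#' Raster view of one channel of a synthetic scene, optionally overlaying
#' the planted LD centroids.
#'
#' @param scene An `ld_scene` from [render_scene()].
#' @param channel `"droplets"` or `"nuclei"`.
#' @param truth Overlay planted LD centroids.
#' @return A ggplot object.
#' @export
plot_field <- function(scene, channel = c("droplets", "nuclei"), truth = FALSE) {
  channel <- match.arg(channel)
  img <- scene[[channel]]
  df <- tidyr::expand_grid(row = seq_len(nrow(img)), col = seq_len(ncol(img)))
  df$intensity <- img[cbind(df$row, df$col)]
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row, fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "a.u.") +
    ggplot2::theme_minimal()
  if (truth && nrow(scene$truth) > 0) {
    pts <- bind_rows(map(scene$truth$ld_centroids, ~ tibble(row = .x[, 1], col = .x[, 2])))
    if (nrow(pts) > 0) {
      p <- p + ggplot2::geom_point(data = pts,
                                   ggplot2::aes(.data$col, .data$row),
                                   inherit.aes = FALSE,
                                   colour = "red", shape = 1, size = 2)
    }
  }
  p
}

#' Plate scatter of extract calls
#'
#' Mean LDs/cell against nuclei/field for every extract, with the plate
#' normal-range bounds drawn as dashed lines and hits coloured by flag — the
#' standard one-look view of a screening plate.
#'
#' @param object A `screen_report` from [screen_plate()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.screen_report <- function(object, ...) {
  calls <- object$extract_calls %>%
    mutate(flag = dplyr::case_when(
      .data$ld_increase ~ "LD increase",
      .data$ld_decrease ~ "LD decrease",
      .data$cytotoxic ~ "cytotoxic",
      TRUE ~ "none"
    ))
  st <- object$plate_stats
  ld <- st[st$metric == "mean_lds_per_cell", ]
  nuc <- st[st$metric == "nuclei_per_field", ]
  ggplot2::ggplot(calls, ggplot2::aes(.data$nuclei_per_field,
                                      .data$mean_lds_per_cell,
                                      colour = .data$flag)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = c(ld$lower, ld$upper), linetype = 2) +
    ggplot2::geom_vline(xintercept = nuc$lower, linetype = 2) +
    ggplot2::labs(x = "nuclei / field", y = "mean LDs / cell", colour = NULL) +
    ggplot2::theme_minimal()
}

#' LD-count distribution plot
#'
#' Frequency distribution of cells by LD count for one or more wells,
#' the view in which treatment effects appear as left/right shifts.
#'
#' @param histograms Named list of [ld_histogram()] tibbles (names label the
#'   treatments).
#' @param max_count Truncate the x axis.
#' @return A ggplot object.
#' @export
plot_ld_distribution <- function(histograms, max_count = 60L) {
  df <- bind_rows(
    purrr::imap(histograms, ~ mutate(.x, treatment = .y))
  ) %>%
    filter(.data$ld_count <= max_count) %>%
    group_by(.data$treatment) %>%
    mutate(frequency = .data$n_cells / sum(.data$n_cells)) %>%
    ungroup()
  ggplot2::ggplot(df, ggplot2::aes(.data$ld_count, .data$frequency,
                                   colour = .data$treatment)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "LDs per cell", y = "fraction of cells", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname dose_response
#' @param object A `dose_response` object.
#' @export
autoplot.dose_response <- function(object, ...) {
  tab <- object$table
  p <- ggplot2::ggplot(tab, ggplot2::aes(.data$concentration, .data$mean_response)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(x = "concentration", y = "mean response") +
    ggplot2::theme_minimal()
  if (!is.null(tab$sd_response) && any(!is.na(tab$sd_response))) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_response - .data$sd_response,
                   ymax = .data$mean_response + .data$sd_response),
      width = 0
    )
  }
  if (!is.null(object$fit)) {
    f <- object$fit
    grid <- tibble(concentration = seq(min(tab$concentration),
                                       max(tab$concentration), length.out = 200))
    grid$mean_response <- f$bottom + (f$top - f$bottom) /
      (1 + (grid$concentration / f$midpoint)^f$slope)
    p <- p + ggplot2::geom_line(data = grid, colour = "steelblue")
  }
  p
}

#' @rdname fit_uptake
#' @param object An `uptake_fit` object.
#' @export
autoplot.uptake_fit <- function(object, ...) {
  p <- ggplot2::ggplot(object$data, ggplot2::aes(.data$time_min, .data$intensity)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "time (min)", y = "integrated intensity (a.u.)") +
    ggplot2::theme_minimal()
  if (object$converged) {
    grid <- tibble(time_min = seq(0, max(object$data$time_min), length.out = 200))
    grid$intensity <- object$I_max * (1 - exp(-grid$time_min / object$tau))
    p <- p +
      ggplot2::geom_line(data = grid, colour = "steelblue") +
      ggplot2::geom_vline(xintercept = object$t_plateau, linetype = 2)
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
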