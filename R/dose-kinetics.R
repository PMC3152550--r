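#' Dose-response analysis of a concentration series
#'
#' Summarises replicate responses per concentration, computes percent
#' inhibition against on-plate controls when supplied, tests for a monotone
#' trend by Spearman rank correlation of mean response against
#' concentration, and optionally fits a four-parameter logistic
#' `y = bottom + (top - bottom) / (1 + (x / midpoint)^slope)`. The midpoint
#' is reported only when the fit converges and lies within the positive
#' concentration range of the data.
#'
#' @param data Data frame with one row per well/measurement.
#' @param concentration,response Column names (tidy-eval) holding the dose
#'   and the response.
#' @param positive_control,baseline Optional scalar controls for
#'   [percent_inhibition()] (loaded and delipidated reference responses).
#' @param fit_sigmoid Attempt the 4PL fit (default TRUE).
#' @return A `dose_response` object with a per-concentration `table`,
#'   `trend` (Spearman rho and p), and `fit` (or `NULL`).
#' @export
dose_response <- function(data, concentration, response,
                          positive_control = NULL, baseline = NULL,
                          fit_sigmoid = TRUE) {
  conc <- rlang::eval_tidy(rlang::enquo(concentration), data)
  resp <- rlang::eval_tidy(rlang::enquo(response), data)
  df <- tibble(concentration = conc, response = resp)
  tab <- df %>%
    group_by(.data$concentration) %>%
    summarise(mean_response = mean(.data$response),
              sd_response = if (dplyr::n() > 1) stats::sd(.data$response) else NA_real_,
              n = dplyr::n(), .groups = "drop") %>%
    arrange(.data$concentration)
  if (nrow(tab) < 3L) abort("need >= 3 distinct concentrations.")
  if (any(diff(tab$concentration) <= 0)) {
    abort("concentrations must be strictly increasing.")
  }
  if (!is.null(positive_control) && !is.null(baseline)) {
    tab$percent_inhibition <- percent_inhibition(tab$mean_response,
                                                 positive_control, baseline)
  }
  trend <- if (stats::sd(tab$mean_response) == 0) {
    list(rho = NA_real_, p_value = NA_real_, flat = TRUE)
  } else {
    ct <- suppressWarnings(
      cor.test(tab$concentration, tab$mean_response, method = "spearman")
    )
    list(rho = unname(ct$estimate), p_value = ct$p.value, flat = FALSE)
  }
  fit <- NULL
  if (fit_sigmoid && !trend$flat) {
    fit <- fit_sigmoid_4pl(tab$concentration, tab$mean_response)
  }
  structure(list(table = tab, trend = trend, fit = fit), class = "dose_response")
}

# 4PL fit on per-concentration means; returns NULL unless it converges with
# a midpoint bracketed by the data's positive concentrations.
fit_sigmoid_4pl <- function(conc, y) {
  pos <- conc[conc > 0]
  if (length(pos) < 2L) return(NULL)
  start <- list(bottom = min(y), top = max(y),
                midpoint = exp(mean(log(range(pos)))), slope = 1)
  f <- try(suppressWarnings(minpack.lm::nlsLM(
    y ~ bottom + (top - bottom) / (1 + (conc / midpoint)^slope),
    start = start,
    lower = c(-Inf, -Inf, min(pos) / 100, 0.1),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )), silent = TRUE)
  if (inherits(f, "try-error")) return(NULL)
  est <- as.list(coef(f))
  if (est$midpoint < min(pos) || est$midpoint > max(conc)) return(NULL)
  c(est, list(rss = sum(resid(f)^2)))
}

#' @export
print.dose_response <- function(x, ...) {
  cat(sprintf("<dose_response> %d concentrations, Spearman rho = %s\n",
              nrow(x$table),
              if (is.na(x$trend$rho)) "undefined (flat)" else sprintf("%.3f", x$trend$rho)))
  if (!is.null(x$fit)) {
    cat(sprintf("  4PL midpoint = %.3g, slope = %.2f\n", x$fit$midpoint, x$fit$slope))
  }
  invisible(x)
}

#' @rdname dose_response
#' @param x A `dose_response` object.
#' @param ... Unused.
#' @export
tidy.dose_response <- function(x, ...) x$table

#' @rdname dose_response
#' @export
glance.dose_response <- function(x, ...) {
  tibble(
    n_concentrations = nrow(x$table),
    rho = x$trend$rho,
    trend_p_value = x$trend$p_value,
    flat = x$trend$flat,
    sigmoid_converged = !is.null(x$fit),
    midpoint = if (is.null(x$fit)) NA_real_ else x$fit$midpoint,
    slope = if (is.null(x$fit)) NA_real_ else x$fit$slope
  )
}

#' Fit uptake kinetics by a saturating exponential
#'
#' Least-squares fit of `I(t) = I_max * (1 - exp(-t / tau))` to an intensity
#' time course; the time to plateau is reported as `3 * tau` (95 percent of
#' `I_max`). Degenerate inputs (all-zero or constant intensities) or
#' non-convergence give an explicit failure result, never silent defaults.
#'
#' @param times Times in minutes (>= 4 points, strictly increasing, t >= 0).
#' @param intensities Measured intensities.
#' @return An `uptake_fit`: `I_max`, `tau` (min), `t_plateau` (min),
#'   `converged`, `residual_sd`.
#' @export
fit_uptake <- function(times, intensities) {
  if (length(times) < 4L) abort("need >= 4 time points.")
  if (any(diff(times) <= 0)) abort("`times` must be strictly increasing.")
  if (times[1] < 0) abort("times must be >= 0.")
  if (length(intensities) != length(times)) abort("lengths differ.")
  fail <- structure(
    list(I_max = NA_real_, tau = NA_real_, t_plateau = NA_real_,
         converged = FALSE, residual_sd = NA_real_,
         data = tibble(time_min = times, intensity = intensities)),
    class = "uptake_fit"
  )
  if (stats::sd(intensities) == 0 || max(intensities) <= 0) return(fail)
  i_top <- max(intensities)
  t_half <- times[which(intensities >= 0.63 * i_top)[1]]
  if (is.na(t_half) || t_half <= 0) t_half <- max(times) / 3
  f <- try(suppressWarnings(minpack.lm::nlsLM(
    intensities ~ I_max * (1 - exp(-times / tau)),
    start = list(I_max = i_top, tau = t_half),
    lower = c(1e-12, 1e-12),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14, ptol = 1e-14)
  )), silent = TRUE)
  if (inherits(f, "try-error")) return(fail)
  est <- coef(f)
  if (!all(is.finite(est)) || est["I_max"] <= 0 || est["tau"] <= 0) return(fail)
  structure(
    list(I_max = unname(est["I_max"]), tau = unname(est["tau"]),
         t_plateau = 3 * unname(est["tau"]), converged = TRUE,
         residual_sd = stats::sd(resid(f)),
         data = tibble(time_min = times, intensity = intensities)),
    class = "uptake_fit"
  )
}

#' @export
print.uptake_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<uptake_fit> fit failed (degenerate data or non-convergence)\n")
  } else {
    cat(sprintf("<uptake_fit> I_max = %.3g, tau = %.3g min, plateau at %.3g min\n",
                x$I_max, x$tau, x$t_plateau))
  }
  invisible(x)
}

#' @rdname fit_uptake
#' @param x An `uptake_fit` object.
#' @param ... Unused.
#' @export
tidy.uptake_fit <- function(x, ...) {
  tibble(term = c("I_max", "tau", "t_plateau"),
         estimate = c(x$I_max, x$tau, x$t_plateau))
}

#' @rdname fit_uptake
#' @export
glance.uptake_fit <- function(x, ...) {
  tibble(I_max = x$I_max, tau = x$tau, t_plateau = x$t_plateau,
         converged = x$converged, residual_sd = x$residual_sd)
}

#' Broom-style generics
#'
#' `tidy()` and `glance()` methods are provided for `dose_response` and
#' `uptake_fit` objects.
#' @param x Object to tidy.
#' @param ... Method arguments.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidy
#' @export
glance <- function(x, ...) UseMethod("glance")
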