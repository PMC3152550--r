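#' Define a treatment scenario for the simulator
#'
#' A scenario maps treatment labels to the expected LDs per cell (the Poisson
#' rate lambda) and a cell-survival fraction, and may carry an uptake
#' time-course (`I_max`, `tau`) for intensity experiments.
#'
#' @param name Scenario label.
#' @param treatments Tibble with columns `treatment`, `ld_rate`, `survival`,
#'   and optionally `concentration` and `conc_units` for dose series.
#' @param uptake Optional list with elements `I_max` (plateau intensity, au)
#'   and `tau` (minutes) for the saturating-exponential uptake model.
#' @return A validated `scenario_config` object.
#' @export
scenario_config <- function(name, treatments, uptake = NULL) {
  treatments <- as_tibble(treatments)
  need <- c("treatment", "ld_rate", "survival")
  if (!all(need %in% names(treatments))) {
    abort("`treatments` needs columns treatment, ld_rate, survival.")
  }
  if (anyDuplicated(treatments$treatment)) abort("treatment labels must be unique.")
  if (any(treatments$ld_rate < 0)) abort("every ld_rate must be >= 0.")
  if (any(treatments$survival < 0 | treatments$survival > 1)) {
    abort("survival fractions must lie in [0, 1].")
  }
  if (!is.null(uptake)) {
    assert_scalar_number(uptake$I_max, "uptake$I_max", min = 0, strict_min = TRUE)
    assert_scalar_number(uptake$tau, "uptake$tau", min = 0, strict_min = TRUE)
  }
  structure(list(name = name, treatments = treatments, uptake = uptake),
            class = "scenario_config")
}

#' Built-in scenario library
#'
#' Ships the assay regimes the pipeline is exercised against. Lambda values
#' are calibrated to the screen's reference conditions: a delipidated baseline
#' below 5 LDs/cell and an oleic-acid-loaded state ten-fold higher; a
#' triacsin C dose ladder scaling the loaded rate by 1, 0.8, 0.5, 0.2, 0.05;
#' a generic inhibitor ladder reaching ~60 percent inhibition at 20 uM; a
#' cytotoxic-extract concentration series; a screening-plate scenario with
#' planted actives at desk-scale LD density; and an uptake time-course whose
#' plateau (3 tau) sits at 10 minutes.
#'
#' @return Named list of [scenario_config()] objects.
#' @export
scenario_library <- function() {
  base_lambda <- 3.5   # delipidated baseline, < 5 LDs/cell
  oleic_lambda <- 35   # ten-fold loading over baseline

  tri_scale <- c(1, 0.8, 0.5, 0.2, 0.05)
  tri_conc <- c(0, 0.1, 0.25, 0.5, 1)  # uM
  triacsin <- tibble(
    treatment = sprintf("triacsin_%g_uM", tri_conc),
    concentration = tri_conc, conc_units = "uM",
    ld_rate = oleic_lambda * tri_scale, survival = 1
  )

  inh_conc <- c(1, 5, 10, 20, 50)  # uM
  inh_frac <- c(0.05, 0.2, 0.35, 0.6, 0.8)
  inhibitor <- tibble(
    treatment = sprintf("inhibitor_%g_uM", inh_conc),
    concentration = inh_conc, conc_units = "uM",
    ld_rate = oleic_lambda - inh_frac * (oleic_lambda - base_lambda),
    survival = 1
  )

  tox_conc <- c(10, 25, 50, 100, 200)  # ug/mL
  tox_surv <- c(1, 1, 0.95, 0.6, 0.25)
  cytotoxic <- tibble(
    treatment = sprintf("extract_%g_ugml", tox_conc),
    concentration = tox_conc, conc_units = "ug/mL",
    ld_rate = oleic_lambda, survival = tox_surv
  )

  # Screening plates run at reduced LD density so spots stay resolvable in
  # compact plate-scale fields; effects are multiplicative on the rate.
  plate_lambda <- 10
  screen <- tibble(
    treatment = c("extract", "extract_increaser", "extract_decreaser",
                  "extract_cytotoxic", "inactive_extract", "triacsin_c", "media_only"),
    concentration = c(50, 50, 50, 50, 50, 1, NA),
    conc_units = c(rep("ug/mL", 5), "uM", NA),
    ld_rate = plate_lambda * c(1, 3, 0.4, 1, 1, 0.05, 1),
    survival = c(1, 1, 1, 0.3, 1, 1, 1)
  )

  list(
    `delipidated-baseline` = scenario_config(
      "delipidated-baseline",
      tibble(treatment = "delipidated", ld_rate = base_lambda, survival = 1)
    ),
    `oleic-loading` = scenario_config(
      "oleic-loading",
      tibble(treatment = c("delipidated", "oleic"),
             ld_rate = c(base_lambda, oleic_lambda), survival = 1)
    ),
    `triacsin-dose-series` = scenario_config("triacsin-dose-series", triacsin),
    `inhibitor-dose-series` = scenario_config("inhibitor-dose-series", inhibitor),
    `cytotoxic-extract` = scenario_config("cytotoxic-extract", cytotoxic),
    `screen-plate` = scenario_config("screen-plate", screen),
    `uptake-timecourse` = scenario_config(
      "uptake-timecourse",
      tibble(treatment = "bodipy_c12", ld_rate = 0, survival = 1),
      uptake = list(I_max = 100, tau = 10 / 3)
    )
  )
}

#' Simulate an uptake time course
#'
#' Draws noisy integrated-intensity readings from the saturating-exponential
#' uptake model `I(t) = I_max * (1 - exp(-t / tau))`.
#'
#' @param times Sampling times in minutes.
#' @param I_max,tau Model parameters (plateau intensity; time constant, min).
#' @param noise_sd SD of additive Gaussian noise, same units as `I_max`.
#' @param seed Integer seed.
#' @return Tibble with columns `time_min` and `intensity`.
#' @export
simulate_uptake <- function(times = seq(0, 60, by = 2), I_max = 100, tau = 10 / 3,
                            noise_sd = 2, seed = 1L) {
  if (any(times < 0)) abort("`times` must be >= 0.")
  with_seed(seed, {
    mu <- I_max * (1 - exp(-times / tau))
    tibble(time_min = as.numeric(times),
           intensity = mu + rnorm(length(times), 0, noise_sd))
  })
}
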