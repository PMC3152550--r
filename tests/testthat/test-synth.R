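test_that("empty and zero-rate scenes are rendered faithfully", {
  p <- scene_params(field_shape = c(128L, 128L), n_cells = 0L)
  sc <- render_scene(p, seed = 1)
  expect_equal(nrow(sc$truth), 0)
  # background + noise only: nothing near the nucleus peak
  expect_lt(max(sc$nuclei), p$background_level + 6 * p$noise_sd)

  p0 <- scene_params(field_shape = c(256L, 256L), n_cells = 5L, ld_rate = 0)
  sc0 <- render_scene(p0, seed = 2)
  expect_equal(sc0$truth$ld_count, rep(0L, 5))
  expect_lt(max(sc0$droplets), p0$background_level + 6 * p0$noise_sd)
})

test_that("identical seeds give bit-identical scenes", {
  p <- scene_params(field_shape = c(192L, 192L), n_cells = 5L, ld_rate = 5)
  a <- render_scene(p, seed = 42)
  b <- render_scene(p, seed = 42)
  expect_identical(a$nuclei, b$nuclei)
  expect_identical(a$droplets, b$droplets)
  expect_identical(a$truth$ld_count, b$truth$ld_count)
  c <- render_scene(p, seed = 43)
  expect_false(identical(a$droplets, c$droplets))
})

test_that("truth is internally consistent", {
  sc <- render_scene(scene_params(n_cells = 15L, ld_rate = 12), seed = 7)
  expect_equal(anyDuplicated(sc$truth$cell_id), 0)
  expect_equal(sc$truth$ld_count, vapply(sc$truth$ld_centroids, nrow, integer(1)))
  for (i in sc$truth$cell_id) {
    pts <- sc$truth$ld_centroids[[i]]
    for (j in seq_len(nrow(pts))) {
      expect_true(dropscreen:::truth_in_cytoplasm(sc$truth, i, pts[j, ]))
    }
  }
})

test_that("planted LD counts follow the configured Poisson rate", {
  # 600 cells at lambda 20: empirical mean within [18, 22]
  counts <- unlist(lapply(1:20, function(s) {
    render_scene(scene_params(n_cells = 30L, ld_rate = 20), seed = s)$truth$ld_count
  }))
  expect_gte(length(counts), 500)
  expect_gte(mean(counts), 18)
  expect_lte(mean(counts), 22)
})

test_that("an overfull field raises a capacity error", {
  expect_error(
    render_scene(scene_params(field_shape = c(64L, 64L), n_cells = 60L), seed = 1),
    class = "dropscreen_capacity_error"
  )
})

test_that("scenario library encodes the assay regimes", {
  lib <- scenario_library()
  expect_true(all(c("delipidated-baseline", "oleic-loading", "triacsin-dose-series",
                    "inhibitor-dose-series", "cytotoxic-extract",
                    "uptake-timecourse") %in% names(lib)))
  ol <- lib[["oleic-loading"]]$treatments
  lam <- setNames(ol$ld_rate, ol$treatment)
  expect_lt(lam[["delipidated"]], 5)
  expect_equal(unname(lam[["oleic"]] / lam[["delipidated"]]), 10)
  tri <- lib[["triacsin-dose-series"]]$treatments
  expect_true(all(diff(tri$concentration) > 0))
  expect_true(all(diff(tri$ld_rate) < 0))
  for (s in lib) {
    expect_true(all(s$treatments$ld_rate >= 0))
    expect_true(all(s$treatments$survival >= 0 & s$treatments$survival <= 1))
  }
  expect_error(
    scenario_config("bad", tibble::tibble(treatment = "x", ld_rate = -1, survival = 1)),
    "ld_rate"
  )
})

test_that("render_plate honours layout, survival and determinism", {
  layout <- plate_layout(n_extracts = 0L, n_inactive = 1L, n_triacsin = 1L, n_media = 0L)
  scen <- scenario_library()[["screen-plate"]]
  scene <- plate_scene_params(field_shape = c(128L, 128L), n_cells = 8L)
  pl <- render_plate(layout, scen, scene = scene, seed = 5)
  expect_equal(nrow(pl$fields), 2)
  expect_identical(pl$truth_wells$well_id, sort(layout$well_id))

  pl2 <- render_plate(layout, scen, scene = scene, seed = 5)
  expect_identical(pl$truth_wells, pl2$truth_wells)
  expect_identical(pl$fields$nuclei[[1]], pl2$fields$nuclei[[1]])

  bad_layout <- dplyr::mutate(layout, treatment = "no_such_treatment")
  expect_error(render_plate(bad_layout, scen, scene = scene, seed = 1),
               class = "dropscreen_treatment_error")
})

test_that("survival thins surviving cells binomially", {
  # survival 0.5 on 40 nominal cells: mean surviving count ~ 20 across seeds
  layout <- tibble::tibble(well_id = "A01", role = "extract", extract_id = "E01",
                           treatment = "extract_cytotoxic", concentration = 50,
                           conc_units = "ug/mL", replicate = 1L, planted = "cytotoxic")
  scen <- scenario_config(
    "half", tibble::tibble(treatment = "extract_cytotoxic", ld_rate = 2, survival = 0.5)
  )
  scene <- scene_params(field_shape = c(320L, 320L), n_cells = 40L,
                        cytoplasm_radius_px = 28, cytoplasm_radius_jitter = 2)
  n_surv <- vapply(1:20, function(s) {
    render_plate(layout, scen, scene = scene, seed = s)$truth_wells$true_n_cells
  }, numeric(1))
  se <- sqrt(40 * 0.5 * 0.5 / 20)
  expect_lt(abs(mean(n_surv) - 20), 3 * se)
})

test_that("simulated uptake follows the saturating-exponential model", {
  tc <- simulate_uptake(times = c(0, 5, 10, 60), I_max = 100, tau = 10 / 3,
                        noise_sd = 0, seed = 1)
  expect_equal(tc$intensity[1], 0)
  expect_equal(tc$intensity[4], 100 * (1 - exp(-18)), tolerance = 1e-10)
  # plateau definition: 95% of I_max at t = 3 * tau
  expect_equal(tc$intensity[3] / 100, 1 - exp(-3), tolerance = 1e-10)
})
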