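well_summary_stub <- function(well_id, lds, nuclei) {
  tibble::tibble(well_id = well_id, n_cells = round(nuclei), n_fields = 1L,
                 mean_lds_per_cell = lds, nuclei_per_field = nuclei,
                 mean_integrated_intensity = NA_real_,
                 ld_histogram = list(ld_histogram(integer(0))))
}

stub_plate <- function(lds_by_extract, nuclei_by_extract = NULL, n_extracts = length(lds_by_extract)) {
  layout <- plate_layout(n_extracts = n_extracts, n_inactive = 2L,
                         n_triacsin = 2L, n_media = 0L)
  if (is.null(nuclei_by_extract)) nuclei_by_extract <- rep(40, n_extracts)
  ext <- dplyr::filter(layout, role == "extract")
  idx <- as.integer(sub("E", "", ext$extract_id))
  wells <- well_summary_stub(ext$well_id, lds_by_extract[idx], nuclei_by_extract[idx])
  ctrl <- dplyr::filter(layout, role != "extract")
  ctrl_lds <- ifelse(ctrl$role == "triacsin-C", 0.5, 10)
  wells <- dplyr::bind_rows(wells, well_summary_stub(ctrl$well_id, ctrl_lds, 40))
  list(layout = layout, wells = wells)
}

test_that("replicate wells average arithmetically", {
  s <- stub_plate(rep(10, 3))
  ext <- dplyr::filter(s$layout, role == "extract")
  # make E01's duplicates 12 and 8
  s$wells$mean_lds_per_cell[s$wells$well_id %in% ext$well_id[ext$extract_id == "E01"]] <- c(12, 8)
  avg <- average_duplicates(s$wells, s$layout)
  expect_equal(avg$mean_lds_per_cell[avg$extract_id == "E01"], 10)
  expect_equal(avg$n_wells, rep(2L, 3))

  # single replicate passes through; triplicate averages
  lay1 <- plate_layout(n_extracts = 2L, n_replicates = 1L,
                       n_inactive = 0L, n_triacsin = 0L, n_media = 0L)
  w1 <- well_summary_stub(lay1$well_id, c(7, 9), 40)
  expect_equal(average_duplicates(w1, lay1)$mean_lds_per_cell, c(7, 9))
  lay3 <- plate_layout(n_extracts = 1L, n_replicates = 3L,
                       n_inactive = 0L, n_triacsin = 0L, n_media = 0L)
  w3 <- well_summary_stub(lay3$well_id, c(1, 2, 6), 40)
  expect_equal(average_duplicates(w3, lay3)$mean_lds_per_cell, 3)
})

test_that("plate normal range matches direct mean/SD arithmetic", {
  r <- plate_normal_range(c(8, 10, 12), k = 1)
  expect_equal(r$mean, 10)
  expect_equal(r$sd, sqrt(8 / 3))  # population SD 1.633
  expect_equal(r$lower, 10 - sqrt(8 / 3))
  expect_equal(r$upper, 10 + sqrt(8 / 3))
  r_samp <- plate_normal_range(c(8, 10, 12), k = 1, sd_type = "sample")
  expect_equal(r_samp$sd, 2)

  deg <- plate_normal_range(rep(10, 5))
  expect_equal(c(deg$sd, deg$lower, deg$upper), c(0, 10, 10))

  # translation equivariance
  base <- plate_normal_range(c(3, 7, 9, 14), k = 2)
  shifted <- plate_normal_range(c(3, 7, 9, 14) + 5, k = 2)
  expect_equal(shifted$lower, base$lower + 5)
  expect_equal(shifted$upper, base$upper + 5)

  expect_error(plate_normal_range(c(1, 2)), "at least 3")
})

test_that("hit calling flags only extracts outside the normal range", {
  s <- stub_plate(rep(10, 42))
  rep0 <- screen_plate(s$wells, s$layout, k = 1)
  expect_equal(sum(rep0$extract_calls$ld_increase), 0)
  expect_equal(sum(rep0$extract_calls$ld_decrease), 0)

  lds <- rep(10, 42); lds[7] <- 100
  rep1 <- screen_plate(stub_plate(lds)$wells, stub_plate(lds)$layout, k = 1)
  calls <- rep1$extract_calls
  expect_identical(calls$extract_id[calls$ld_increase], "E07")
  # direct mean/SD oracle: 100 clearly exceeds mean + sd
  m <- mean(lds); sdev <- sqrt(mean((lds - m)^2))
  expect_true(100 > m + sdev)
  expect_false(any(calls$ld_decrease))
})

test_that("cytotoxic flags use only the low side and co-occurrence is recounted", {
  lds <- rep(10, 42); nuc <- rep(40, 42)
  nuc[c(3, 11, 30)] <- 5          # 3 cytotoxic
  lds[3] <- 100                   # one of them also LD-increase
  nuc[20] <- 200                  # high nuclei count: not cytotoxic
  s <- stub_plate(lds, nuc)
  rep <- screen_plate(s$wells, s$layout, k = 1)
  calls <- rep$extract_calls
  expect_setequal(calls$extract_id[calls$cytotoxic], c("E03", "E11", "E30"))
  expect_false(calls$cytotoxic[calls$extract_id == "E20"])
  co <- rep$cooccurrence
  expect_equal(co$n_cytotoxic, 3)
  expect_equal(co$n_cytotoxic_and_ld_increase, 1)
  expect_equal(co$n_cytotoxic_and_ld_decrease, 0)
  # never both LD flags at once
  expect_false(any(calls$ld_increase & calls$ld_decrease))
})

test_that("hit calling is invariant to well order and control values", {
  lds <- rep(10, 42); lds[5] <- 30; lds[9] <- 2
  s <- stub_plate(lds)
  rep_a <- screen_plate(s$wells, s$layout, k = 1)
  shuffled <- s$wells[rev(seq_len(nrow(s$wells))), ]
  rep_b <- screen_plate(shuffled, s$layout, k = 1)
  expect_equal(rep_a$extract_calls, rep_b$extract_calls)
  # perturbing control wells never changes extract calls
  s2 <- s
  ctrl_ids <- dplyr::filter(s$layout, role != "extract")$well_id
  s2$wells$mean_lds_per_cell[s2$wells$well_id %in% ctrl_ids] <- 999
  rep_c <- screen_plate(s2$wells, s2$layout, k = 1)
  expect_equal(rep_a$extract_calls, rep_c$extract_calls)
})

test_that("hit rates reproduce the screen's printed arithmetic", {
  expect_equal(hit_rate(87, 2184), 4)
  expect_equal(hit_rate(27, 2184), 1)
  expect_equal(hit_rate(0, 50), 0)
  expect_error(hit_rate(1, 0), "n_screened")
  expect_error(hit_rate(5, 4))
})

test_that("percent inhibition interpolates between controls", {
  expect_equal(percent_inhibition(33, 33, 3), 0)
  expect_equal(percent_inhibition(3, 33, 3), 100)
  expect_equal(percent_inhibition(15, 33, 3), 60)
  expect_error(percent_inhibition(5, 10, 10), "undefined")
  # affine invariance: y -> a*y + b leaves inhibition unchanged
  a <- 2.7; b <- -14
  for (tr in c(5, 12, 28)) {
    expect_equal(percent_inhibition(a * tr + b, a * 33 + b, a * 3 + b),
                 percent_inhibition(tr, 33, 3))
  }
})

test_that("fold change is a guarded ratio", {
  expect_equal(fold_change(35, 3.5), 10)
  expect_equal(fold_change(7, 7), 1)
  expect_error(fold_change(5, 0), "zero")
})

test_that("assay window reproduces the Z-prime arithmetic", {
  # mu- = 35, sd- = 1; mu+ = 5, sd+ = 1  ->  Z' = 1 - 6/30 = 0.8
  qc <- assay_window(c(4, 6), c(34, 36), sd_type = "population")
  expect_equal(qc$sd_positive, 1)
  expect_equal(qc$z_prime, 0.8)
  expect_equal(qc$window, 7)
  qc0 <- assay_window(c(5, 5, 5), c(35, 35, 35))
  expect_equal(qc0$z_prime, 1)
  und <- assay_window(c(10, 10), c(10, 10))
  expect_false(und$defined)
  expect_true(is.na(und$z_prime))
})
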