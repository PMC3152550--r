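test_that("collapse_stack is a max projection with the expected identities", {
  a <- blank_image(32); a[5, 5] <- 100
  b <- blank_image(32); b[20, 20] <- 50
  expect_identical(collapse_stack(list(a)), a)
  m <- collapse_stack(list(a, b))
  expect_equal(m[5, 5], 100)
  expect_equal(m[20, 20], 50)
  expect_identical(collapse_stack(list(a, a, a)), a)
  expect_error(collapse_stack(list(a, blank_image(16))), "shape")
})

test_that("well-separated bright disks are each labelled once", {
  img <- blank_image(128)
  centres <- rbind(c(25, 25), c(25, 95), c(95, 25), c(95, 95))
  for (i in 1:4) img <- draw_disk(img, centres[i, 1], centres[i, 2], 8, 10000)
  labs <- segment_nuclei(img, segmentation_params())
  expect_equal(max(labs), 4)
  expect_equal(sort(unique(as.vector(labs))), 0:4)

  blank <- matrix(rnorm(128 * 128, 100, 5), 128, 128)
  expect_equal(max(segment_nuclei(blank, segmentation_params())), 0)
})

test_that("watershed declumping separates overlapping nuclei", {
  img <- blank_image(96)
  # centres 1.4 radii apart: masks overlap by ~30% of the radius
  img <- draw_disk(img, 48, 40, 10, 10000)
  img <- draw_disk(img, 48, 54, 10, 10000)
  labs <- segment_nuclei(img, segmentation_params(declump = TRUE))
  expect_equal(max(labs), 2)
  cent <- dropscreen:::label_centroids(labs)
  cent <- cent[order(cent[, 2]), , drop = FALSE]
  expect_lt(abs(cent[1, 1] - 48), 2)
  expect_lt(abs(cent[1, 2] - 40), 2)
  expect_lt(abs(cent[2, 2] - 54), 2)

  labs_off <- segment_nuclei(img, segmentation_params(declump = FALSE))
  expect_equal(max(labs_off), 1)
})

test_that("nucleus area gates and border exclusion apply", {
  img <- blank_image(128)
  img <- draw_disk(img, 40, 40, 3, 10000)   # area ~28 px, below the gate
  img <- draw_disk(img, 90, 90, 8, 10000)   # within gates
  img <- draw_disk(img, 2, 64, 8, 10000)    # touches the border
  labs <- segment_nuclei(img, segmentation_params())
  expect_equal(max(labs), 1)
  keep <- dropscreen:::label_centroids(labs)
  expect_equal(unname(round(keep[1, ])), c(90, 90))
})

test_that("cytoplasm territories match brute-force nearest-seed assignment", {
  nuc <- matrix(0L, 64, 64)
  nuc[draw_disk(blank_image(64), 32, 27, 4, 1) > 0] <- 1L
  nuc[draw_disk(blank_image(64), 32, 37, 4, 1) > 0] <- 2L
  p <- segmentation_params(cytoplasm_radius_px = 20)
  got <- delineate_cytoplasm(nuc, p)
  oracle <- brute_force_territories(nuc, 20)
  # perpendicular bisector up to 1 px of discretisation
  mism <- which(got != oracle, arr.ind = TRUE)
  if (nrow(mism) > 0) {
    expect_true(all(abs(mism[, 2] - 32) <= 1))
  }
  expect_gt(mean(got == oracle), 0.99)
  # boundary column between equidistant seeds splits at the bisector
  expect_true(all(got[, 1:30][got[, 1:30] > 0] == 1))
  expect_true(all(got[, 34:64][got[, 34:64] > 0] == 2))
})

test_that("single-nucleus territory is a clipped disk; empty input stays empty", {
  nuc <- matrix(0L, 64, 64)
  nuc[draw_disk(blank_image(64), 32, 32, 4, 1) > 0] <- 1L
  got <- delineate_cytoplasm(nuc, segmentation_params(cytoplasm_radius_px = 12))
  dn <- dropscreen:::ebi_mat(EBImage::distmap(EBImage::Image((nuc == 0) * 1)))
  expect_identical(got > 0, dn <= 12)
  empty <- delineate_cytoplasm(matrix(0L, 32, 32), segmentation_params())
  expect_true(all(empty == 0))
})

test_that("isolated spots are detected at their planted positions", {
  img <- blank_image(128, value = 100)
  pts <- rbind(c(30, 30), c(60, 90), c(100, 50))
  for (i in 1:3) img <- draw_gaussian(img, pts[i, 1], pts[i, 2], 5000, 1.8)
  set.seed(99)
  img <- img + matrix(rnorm(128 * 128, 0, 50), 128, 128)
  spots <- detect_droplets(img, segmentation_params())
  expect_equal(nrow(spots), 3)
  ord <- order(spots$row)
  expect_true(all(abs(spots$row[ord] - pts[, 1]) < 1))
  expect_true(all(abs(spots$col[ord] - pts[, 2]) < 1))

  expect_equal(nrow(detect_droplets(blank_image(64, value = 500),
                                    segmentation_params())), 0)
})

test_that("the blob detector also recovers isolated spots", {
  img <- blank_image(128, value = 100)
  pts <- rbind(c(30, 30), c(60, 90), c(100, 50))
  for (i in 1:3) img <- draw_gaussian(img, pts[i, 1], pts[i, 2], 5000, 1.8)
  set.seed(98)
  img <- img + matrix(rnorm(128 * 128, 0, 50), 128, 128)
  spots <- detect_droplets(img, segmentation_params(ld_detector = "log"))
  expect_equal(nrow(spots), 3)
  ord <- order(spots$row)
  expect_true(all(abs(spots$row[ord] - pts[, 1]) < 1.5))
})

test_that("spot assignment conserves counts and respects containment", {
  cells <- matrix(0L, 64, 64)
  cells[1:64, 1:30] <- 1L
  cells[1:30, 35:64] <- 3L
  spots <- tibble::tibble(spot_id = 1:3,
                          row = c(10, 10, 50), col = c(10, 40, 40),
                          area_px = 5L, diameter_px = 3,
                          integrated_intensity = 100)
  asg <- assign_droplets(spots, cells)
  expect_equal(asg$spots$cell_id, c(1L, 3L, NA))
  expect_equal(nrow(asg$unassigned), 1)
  expect_equal(sum(asg$per_cell$ld_count) + nrow(asg$unassigned), nrow(spots))
  # zero-count territories are present in per_cell
  expect_setequal(asg$per_cell$cell_id, c(1L, 3L))
})

test_that("count conservation holds on random scenes (brute-force oracle)", {
  for (s in 1:5) {
    sc <- render_scene(scene_params(field_shape = c(256L, 256L), n_cells = 8L,
                                    ld_rate = 10), seed = s)
    seg <- segment_field(sc$nuclei, sc$droplets)
    expect_equal(sum(seg$per_cell$ld_count) + nrow(seg$unassigned), nrow(seg$spots))
    # brute-force containment: every assigned spot centroid sits in its territory
    ok <- mapply(function(r, c, id) {
      lab <- seg$cell_labels[round(r), round(c)]
      if (is.na(id)) lab == 0 else lab == id
    }, seg$spots$row, seg$spots$col, seg$spots$cell_id)
    expect_true(all(ok))
  }
})

test_that("noiseless well-separated scenes are recovered exactly", {
  for (s in 1:3) {
    sc <- render_scene(clean_scene_params(), seed = s)
    seg <- segment_field(sc$nuclei, sc$droplets)
    expect_equal(max(seg$nuclei_labels), nrow(sc$truth))
    expect_equal(nrow(seg$spots), sum(sc$truth$ld_count))
    expect_equal(nrow(seg$unassigned), 0)
    # per-cell counts match truth after matching labels by nucleus position
    cent <- dropscreen:::label_centroids(seg$nuclei_labels)
    match_truth <- vapply(seq_len(nrow(cent)), function(i) {
      which.min((sc$truth$nucleus_row - cent[i, 1])^2 +
                  (sc$truth$nucleus_col - cent[i, 2])^2)
    }, integer(1))
    expect_equal(seg$per_cell$ld_count,
                 sc$truth$ld_count[match_truth])
  }
})

test_that("segmentation is equivariant under scene translation", {
  # wide border margin keeps all content clear of the wrap seam, and a
  # circular shift preserves the intensity histogram (hence thresholds)
  sc <- render_scene(clean_scene_params(border_margin_px = 60, noise_sd = 50),
                     seed = 11)
  p <- segmentation_params()
  dr <- 7L; dc <- 5L
  shift <- function(img) {
    img[c((nrow(img) - dr + 1):nrow(img), 1:(nrow(img) - dr)),
        c((ncol(img) - dc + 1):ncol(img), 1:(ncol(img) - dc))]
  }
  seg <- segment_field(sc$nuclei, sc$droplets, p)
  seg_s <- segment_field(shift(sc$nuclei), shift(sc$droplets), p)
  expect_equal(nrow(seg_s$spots), nrow(seg$spots))
  expect_equal(sort(seg_s$per_cell$ld_count), sort(seg$per_cell$ld_count))
  expect_equal(sort(seg_s$spots$row), sort(seg$spots$row + dr), tolerance = 1e-6)
  expect_equal(sort(seg_s$spots$col), sort(seg$spots$col + dc), tolerance = 1e-6)
})

test_that("detection recovers planted totals within 10% at screening SNR", {
  err <- vapply(1:6, function(s) {
    sc <- render_scene(scene_params(n_cells = 30L, ld_rate = 20), seed = s)
    seg <- segment_field(sc$nuclei, sc$droplets)
    abs(nrow(seg$spots) - sum(sc$truth$ld_count)) / sum(sc$truth$ld_count)
  }, numeric(1))
  expect_lt(mean(err), 0.10)
})
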