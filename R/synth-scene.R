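#' Parameters for a synthetic two-channel fluorescence field
#'
#' Bundles every knob of the scene simulator: field geometry, cell number and
#' size, the Poisson rate of lipid-droplet (LD) counts per cell, spot size and
#' brightness, optical blur and camera noise. Defaults describe an A431-like
#' field imaged at roughly 40x: a 512 x 512 px field holding 30 cells with
#' nuclei of ~9 px radius and LDs of 3-6 px diameter.
#'
#' @param field_shape Integer vector `(rows, cols)` of the field in pixels.
#' @param n_cells Number of cells to place.
#' @param nucleus_radius_px,nucleus_radius_jitter Mean nucleus radius and the
#'   SD of its per-cell jitter, in pixels.
#' @param cytoplasm_radius_px,cytoplasm_radius_jitter Mean maximum cytoplasm
#'   radius (around the nucleus centre) and its per-cell jitter, in pixels.
#'   Territories of neighbouring cells are clipped by the perpendicular
#'   bisector between nucleus centres so they never overlap.
#' @param ld_rate Expected LDs per cell; per-cell counts are Poisson with this
#'   rate.
#' @param ld_diameter_px Length-2 range of LD spot diameters (FWHM), pixels.
#' @param ld_min_separation_px Minimum centre-to-centre distance between
#'   planted LDs, pixels. Keeps planted spots resolvable; spots that cannot be
#'   placed after bounded retries are dropped (the emitted truth always counts
#'   what was actually planted).
#' @param ld_peak_intensity,nucleus_peak_intensity Peak amplitudes above
#'   background, in 16-bit grayscale units. Per-spot amplitudes are jittered
#'   uniformly by +/- 20 percent.
#' @param background_level Constant background, grayscale units.
#' @param psf_sigma_px Gaussian point-spread blur applied to both channels.
#' @param noise_sd SD of additive Gaussian read noise, grayscale units.
#' @param min_nucleus_spacing_px Minimum distance between nucleus centres;
#'   default `5 * nucleus_radius_px`.
#' @param border_margin_px Margin kept between nucleus centres and the field
#'   border; default `2 * nucleus_radius_px`.
#'
#' @return An object of class `scene_params` (a validated list).
#' @export
scene_params <- function(field_shape = c(512L, 512L),
                         n_cells = 30L,
                         nucleus_radius_px = 9,
                         nucleus_radius_jitter = 1,
                         cytoplasm_radius_px = 40,
                         cytoplasm_radius_jitter = 3,
                         ld_rate = 20,
                         ld_diameter_px = c(3, 6),
                         ld_min_separation_px = 8,
                         ld_peak_intensity = 6000,
                         nucleus_peak_intensity = 20000,
                         background_level = 400,
                         psf_sigma_px = 1,
                         noise_sd = 100,
                         min_nucleus_spacing_px = NULL,
                         border_margin_px = NULL) {
  if (length(field_shape) != 2L || any(field_shape < 8)) {
    abort("`field_shape` must be two pixel dimensions >= 8.")
  }
  assert_scalar_number(n_cells, "n_cells", min = 0)
  assert_scalar_number(nucleus_radius_px, "nucleus_radius_px", min = 0, strict_min = TRUE)
  assert_scalar_number(cytoplasm_radius_px, "cytoplasm_radius_px", min = 0, strict_min = TRUE)
  assert_scalar_number(ld_rate, "ld_rate", min = 0)
  if (length(ld_diameter_px) != 2L || ld_diameter_px[1] > ld_diameter_px[2] ||
      ld_diameter_px[1] <= 0) {
    abort("`ld_diameter_px` must be an increasing positive range (min, max).")
  }
  if (cytoplasm_radius_px <= nucleus_radius_px) {
    abort("`cytoplasm_radius_px` must exceed `nucleus_radius_px`.")
  }
  assert_scalar_number(background_level, "background_level", min = 0)
  assert_scalar_number(noise_sd, "noise_sd", min = 0)
  assert_scalar_number(psf_sigma_px, "psf_sigma_px", min = 0)
  if (background_level + nucleus_peak_intensity * 1.2 > 65535 ||
      background_level + ld_peak_intensity * 1.2 > 65535) {
    abort("peak intensities must fit the 16-bit range after rendering.")
  }
  if (is.null(min_nucleus_spacing_px)) {
    # wide default spacing keeps neighbouring territories from clipping the
    # LD-placement annulus, so empirical per-cell rates track lambda closely
    min_nucleus_spacing_px <- 5 * nucleus_radius_px
  }
  if (is.null(border_margin_px)) border_margin_px <- 2 * nucleus_radius_px
  structure(
    list(
      field_shape = as.integer(field_shape),
      n_cells = as.integer(n_cells),
      nucleus_radius_px = nucleus_radius_px,
      nucleus_radius_jitter = nucleus_radius_jitter,
      cytoplasm_radius_px = cytoplasm_radius_px,
      cytoplasm_radius_jitter = cytoplasm_radius_jitter,
      ld_rate = ld_rate,
      ld_diameter_px = as.numeric(ld_diameter_px),
      ld_min_separation_px = ld_min_separation_px,
      ld_peak_intensity = ld_peak_intensity,
      nucleus_peak_intensity = nucleus_peak_intensity,
      background_level = background_level,
      psf_sigma_px = psf_sigma_px,
      noise_sd = noise_sd,
      min_nucleus_spacing_px = min_nucleus_spacing_px,
      border_margin_px = border_margin_px
    ),
    class = "scene_params"
  )
}

# Rejection-sample `n` points with pairwise min distance `spacing` inside the
# margin-shrunk field. Errors once the retry budget is exhausted.
place_nuclei <- function(field_shape, n, spacing, margin) {
  if (n == 0L) return(matrix(numeric(0), ncol = 2))
  lo <- c(1 + margin, 1 + margin)
  hi <- c(field_shape[1] - margin, field_shape[2] - margin)
  if (any(hi <= lo)) {
    abort("field too small for the requested border margin.", class = "dropscreen_capacity_error")
  }
  pts <- matrix(NA_real_, nrow = n, ncol = 2)
  placed <- 0L
  tries <- 0L
  max_tries <- 300L * n
  while (placed < n) {
    tries <- tries + 1L
    if (tries > max_tries) {
      abort(
        sprintf("could not place %d nuclei with spacing %.1f px (field too small).", n, spacing),
        class = "dropscreen_capacity_error"
      )
    }
    cand <- c(runif(1, lo[1], hi[1]), runif(1, lo[2], hi[2]))
    if (placed > 0L) {
      d2 <- (pts[seq_len(placed), 1] - cand[1])^2 + (pts[seq_len(placed), 2] - cand[2])^2
      if (min(d2) < spacing^2) next
    }
    placed <- placed + 1L
    pts[placed, ] <- cand
  }
  pts
}

# Sample LD centres for one cell: uniform in the annulus between the nucleus
# edge and the cytoplasm radius, clipped to this cell's Voronoi territory and
# kept `min_sep` away from every LD already placed in the field.
place_droplets <- function(n_target, centre, r_nuc, r_cyt, centres_all, cell_index,
                           field_shape, min_sep, existing) {
  if (n_target == 0L) return(matrix(numeric(0), ncol = 2))
  out <- matrix(NA_real_, nrow = n_target, ncol = 2)
  placed <- 0L
  for (i in seq_len(n_target)) {
    for (try in seq_len(150L)) {
      rad <- sqrt(runif(1, (r_nuc + 1)^2, r_cyt^2))
      ang <- runif(1, 0, 2 * pi)
      p <- centre + rad * c(cos(ang), sin(ang))
      if (p[1] < 2 || p[2] < 2 || p[1] > field_shape[1] - 1 || p[2] > field_shape[2] - 1) next
      # stay on this cell's side of every bisector
      d2 <- (centres_all[, 1] - p[1])^2 + (centres_all[, 2] - p[2])^2
      if (which.min(d2) != cell_index) next
      if (placed > 0L) {
        dd <- (out[seq_len(placed), 1] - p[1])^2 + (out[seq_len(placed), 2] - p[2])^2
        if (min(dd) < min_sep^2) next
      }
      if (nrow(existing) > 0L) {
        dd <- (existing[, 1] - p[1])^2 + (existing[, 2] - p[2])^2
        if (min(dd) < min_sep^2) next
      }
      placed <- placed + 1L
      out[placed, ] <- p
      break
    }
  }
  out[seq_len(placed), , drop = FALSE]
}

# Local window of a 2-D Gaussian of amplitude `amp` (optionally elliptical,
# axes a/b rotated by theta) around (r, c): returns rows, cols and the patch.
# Adding patches in the caller's frame avoids copying the field per spot.
gauss_patch <- function(dim, r, c, amp, sigma_a, sigma_b = sigma_a, theta = 0) {
  half <- ceiling(3 * max(sigma_a, sigma_b))
  r0 <- max(1L, floor(r - half)); r1 <- min(dim[1], ceiling(r + half))
  c0 <- max(1L, floor(c - half)); c1 <- min(dim[2], ceiling(c + half))
  if (r0 > r1 || c0 > c1) return(NULL)
  rows <- r0:r1; cols <- c0:c1
  dr <- rows - r
  dc <- cols - c
  ct <- cos(theta); st <- sin(theta)
  u <- outer(dr * ct, dc * st, "+")
  v <- outer(-dr * st, dc * ct, "+")
  list(rows = rows, cols = cols,
       patch = amp * exp(-0.5 * ((u / sigma_a)^2 + (v / sigma_b)^2)))
}

#' Render one synthetic two-channel field with ground truth
#'
#' Places cells by rejection sampling, draws a Poisson LD count per cell,
#' plants LD spots inside each cell's cytoplasmic territory (outside its
#' nucleus), renders nuclei as Gaussian-shaded ellipses in channel 1 and LDs
#' as Gaussian spots in channel 2, then applies a Gaussian PSF blur and
#' additive Gaussian read noise and quantises to 16-bit grayscale.
#'
#' @param params A [scene_params()] object.
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @return An object of class `ld_scene`: a list with integer-valued matrices
#'   `nuclei` and `droplets` (16-bit grayscale), a `truth` tibble (one row per
#'   cell: `cell_id`, `nucleus_row`, `nucleus_col`, nucleus/cytoplasm radii,
#'   `ld_count` and a list-column `ld_centroids` of (row, col) matrices), and
#'   the `params` used.
#' @export
render_scene <- function(params = scene_params(), seed = 1L) {
  stopifnot(inherits(params, "scene_params"))
  with_seed(seed, {
    p <- params
    shape <- p$field_shape
    centres <- place_nuclei(shape, p$n_cells, p$min_nucleus_spacing_px, p$border_margin_px)
    n <- nrow(centres)

    r_nuc <- pmax(2, rnorm(n, p$nucleus_radius_px, p$nucleus_radius_jitter))
    r_cyt <- pmax(r_nuc + 2, rnorm(n, p$cytoplasm_radius_px, p$cytoplasm_radius_jitter))
    ecc <- if (n > 0) runif(n, 0.75, 1) else numeric(0)
    theta <- if (n > 0) runif(n, 0, pi) else numeric(0)
    counts <- if (n > 0) rpois(n, p$ld_rate) else integer(0)

    nuclei <- matrix(p$background_level, shape[1], shape[2])
    droplets <- matrix(p$background_level, shape[1], shape[2])

    ld_centroids <- vector("list", n)
    all_ld <- matrix(numeric(0), ncol = 2)
    for (i in seq_len(n)) {
      pts <- place_droplets(counts[i], centres[i, ], r_nuc[i], r_cyt[i],
                            centres, i, shape, p$ld_min_separation_px, all_ld)
      ld_centroids[[i]] <- pts
      if (nrow(pts) > 0) all_ld <- rbind(all_ld, pts)
      # nucleus: Gaussian-shaded ellipse, sd = semi-axis / 2
      amp <- p$nucleus_peak_intensity * runif(1, 0.8, 1.2)
      sa <- r_nuc[i] * sqrt(ecc[i]) / 2
      sb <- r_nuc[i] / sqrt(ecc[i]) / 2
      g <- gauss_patch(shape, centres[i, 1], centres[i, 2], amp, sa, sb, theta[i])
      if (!is.null(g)) nuclei[g$rows, g$cols] <- nuclei[g$rows, g$cols] + g$patch
      if (nrow(pts) > 0) {
        diam <- runif(nrow(pts), p$ld_diameter_px[1], p$ld_diameter_px[2])
        amps <- p$ld_peak_intensity * runif(nrow(pts), 0.8, 1.2)
        for (j in seq_len(nrow(pts))) {
          g <- gauss_patch(shape, pts[j, 1], pts[j, 2], amps[j], diam[j] / 2.355)
          if (!is.null(g)) droplets[g$rows, g$cols] <- droplets[g$rows, g$cols] + g$patch
        }
      }
    }
    counts <- map_int(ld_centroids, nrow)

    if (p$psf_sigma_px > 0) {
      nuclei <- ebi_mat(EBImage::gblur(nuclei, sigma = p$psf_sigma_px))
      droplets <- ebi_mat(EBImage::gblur(droplets, sigma = p$psf_sigma_px))
    }
    if (p$noise_sd > 0) {
      nuclei <- nuclei + matrix(rnorm(length(nuclei), 0, p$noise_sd), nrow(nuclei))
      droplets <- droplets + matrix(rnorm(length(droplets), 0, p$noise_sd), nrow(droplets))
    }
    nuclei <- round(pmin(pmax(nuclei, 0), 65535))
    droplets <- round(pmin(pmax(droplets, 0), 65535))

    truth <- tibble(
      cell_id = seq_len(n),
      nucleus_row = if (n > 0) centres[, 1] else numeric(0),
      nucleus_col = if (n > 0) centres[, 2] else numeric(0),
      nucleus_radius_px = r_nuc,
      cytoplasm_radius_px = r_cyt,
      ld_count = counts,
      ld_centroids = ld_centroids
    )
    structure(
      list(nuclei = nuclei, droplets = droplets, truth = truth,
           params = p, seed = as.integer(seed)),
      class = "ld_scene"
    )
  })
}

#' @export
print.ld_scene <- function(x, ...) {
  cat(sprintf(
    "<ld_scene> %d x %d px, %d cells, %d planted LDs (seed %d)\n",
    nrow(x$nuclei), ncol(x$nuclei), nrow(x$truth), sum(x$truth$ld_count), x$seed
  ))
  invisible(x)
}

# Truth-side cytoplasm membership test used by invariant checks: inside this
# cell's cytoplasm radius, outside its nucleus, nearest nucleus centre wins.
truth_in_cytoplasm <- function(truth, cell_id, pt) {
  i <- match(cell_id, truth$cell_id)
  centres <- cbind(truth$nucleus_row, truth$nucleus_col)
  d2 <- (centres[, 1] - pt[1])^2 + (centres[, 2] - pt[2])^2
  d <- sqrt(d2[i])
  which.min(d2) == i && d <= truth$cytoplasm_radius_px[i] && d > truth$nucleus_radius_px[i]
}
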