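#' Segmentation parameters
#'
#' Tunables for the image-analysis chain. Defaults: nucleus area gate
#' 80-2000 px^2 with global Otsu thresholding and watershed declumping of
#' touching nuclei; cytoplasm territories limited to 40 px from the nucleus;
#' LD detection by white top-hat filtering with a k * MAD threshold (k = 5)
#' and a 3-10 px spot-diameter gate; border-touching nuclei excluded.
#'
#' @param nucleus_min_area_px,nucleus_max_area_px Nucleus area gates, px^2.
#' @param nucleus_threshold_method `"otsu"` (global Otsu) or `"fixed"`.
#' @param nucleus_threshold Grayscale threshold used when method is `"fixed"`.
#' @param declump Split touching nuclei by watershed on the distance
#'   transform.
#' @param nucleus_split_tolerance Watershed tolerance (distance-map units)
#'   for declumping; larger values split less.
#' @param exclude_border_objects Drop nuclei touching the field border.
#' @param cytoplasm_radius_px Maximum territory reach from the nucleus, px.
#' @param ld_diameter_px Length-2 gate on detected spot diameter (measured at
#'   half maximum), px.
#' @param ld_detector `"tophat"` (white top-hat + threshold) or `"log"`
#'   (multi-scale Laplacian-of-Gaussian blob response).
#' @param ld_threshold_k Threshold multiplier over the robust noise scale
#'   (MAD) of the detector response.
#' @param ld_split_tolerance Intensity-watershed tolerance used to split
#'   merged spots; `NULL` uses the detection threshold itself.
#' @return A `segmentation_params` object.
#' @export
segmentation_params <- function(nucleus_min_area_px = 80,
                                nucleus_max_area_px = 2000,
                                nucleus_threshold_method = c("otsu", "fixed"),
                                nucleus_threshold = NULL,
                                declump = TRUE,
                                nucleus_split_tolerance = 2,
                                exclude_border_objects = TRUE,
                                cytoplasm_radius_px = 40,
                                ld_diameter_px = c(3, 10),
                                ld_detector = c("tophat", "log"),
                                ld_threshold_k = 5,
                                ld_split_tolerance = NULL) {
  nucleus_threshold_method <- match.arg(nucleus_threshold_method)
  ld_detector <- match.arg(ld_detector)
  if (nucleus_min_area_px >= nucleus_max_area_px) {
    abort("nucleus area gate must satisfy min < max.")
  }
  if (length(ld_diameter_px) != 2L || ld_diameter_px[1] >= ld_diameter_px[2] ||
      ld_diameter_px[1] <= 0) {
    abort("`ld_diameter_px` must be an increasing positive range.")
  }
  assert_scalar_number(cytoplasm_radius_px, "cytoplasm_radius_px", min = 0, strict_min = TRUE)
  assert_scalar_number(ld_threshold_k, "ld_threshold_k", min = 0, strict_min = TRUE)
  if (nucleus_threshold_method == "fixed" && is.null(nucleus_threshold)) {
    abort("`nucleus_threshold` is required when method is 'fixed'.")
  }
  structure(
    list(nucleus_min_area_px = nucleus_min_area_px,
         nucleus_max_area_px = nucleus_max_area_px,
         nucleus_threshold_method = nucleus_threshold_method,
         nucleus_threshold = nucleus_threshold,
         declump = declump,
         nucleus_split_tolerance = nucleus_split_tolerance,
         exclude_border_objects = exclude_border_objects,
         cytoplasm_radius_px = cytoplasm_radius_px,
         ld_diameter_px = as.numeric(ld_diameter_px),
         ld_detector = ld_detector,
         ld_threshold_k = ld_threshold_k,
         ld_split_tolerance = ld_split_tolerance),
    class = "segmentation_params"
  )
}

#' Collapse a z-stack by maximum-intensity projection
#'
#' @param stack List of same-shape numeric matrices (ordered slices).
#' @return Single matrix: the per-pixel maximum across slices.
#' @export
collapse_stack <- function(stack) {
  if (!is.list(stack) || length(stack) == 0L) abort("`stack` must be a non-empty list of matrices.")
  purrr::walk(stack, assert_image, name = "stack slice")
  dims <- map(stack, dim)
  if (length(unique(map(dims, paste, collapse = "x"))) != 1L) {
    abort("all slices must share the same shape.")
  }
  Reduce(pmax, stack)
}

# Relabel a label matrix to consecutive positive integers (0 = background).
relabel <- function(labels) {
  ids <- sort(unique(labels[labels > 0]))
  if (length(ids) == 0L) return(labels * 0L)
  lut <- integer(max(ids) + 1L)
  lut[ids + 1L] <- seq_along(ids)
  matrix(lut[labels + 1L], nrow(labels), ncol(labels))
}

label_areas <- function(labels) {
  if (!any(labels > 0)) return(integer(0))
  tabulate(labels[labels > 0])
}

#' Segment nuclei from the DNA-stain channel
#'
#' Global threshold (Otsu or fixed), connected-component labelling with
#' optional watershed declumping of touching nuclei, area gating, and
#' optional exclusion of border-touching objects.
#'
#' @param nuclei_image 2-D grayscale matrix (16-bit scale).
#' @param params A [segmentation_params()] object.
#' @return Integer label matrix (0 = background), labels consecutive from 1.
#' @export
segment_nuclei <- function(nuclei_image, params = segmentation_params()) {
  assert_image(nuclei_image, "nuclei_image")
  thr <- if (params$nucleus_threshold_method == "otsu") {
    rng <- range(nuclei_image)
    if (diff(rng) <= 0) return(matrix(0L, nrow(nuclei_image), ncol(nuclei_image)))
    scaled <- (nuclei_image - rng[1]) / diff(rng)
    rng[1] + EBImage::otsu(EBImage::Image(scaled), range = c(0, 1), levels = 256) * diff(rng)
  } else {
    params$nucleus_threshold
  }
  mask <- nuclei_image > thr
  if (!any(mask)) return(matrix(0L, nrow(nuclei_image), ncol(nuclei_image)))
  labels <- if (params$declump) {
    dm <- EBImage::distmap(EBImage::Image(mask * 1))
    ebi_mat(EBImage::watershed(dm, tolerance = params$nucleus_split_tolerance, ext = 1))
  } else {
    ebi_mat(EBImage::bwlabel(EBImage::Image(mask * 1)))
  }
  storage.mode(labels) <- "integer"
  areas <- label_areas(labels)
  bad <- which(areas < params$nucleus_min_area_px | areas > params$nucleus_max_area_px)
  if (params$exclude_border_objects) {
    border <- unique(c(labels[1, ], labels[nrow(labels), ], labels[, 1], labels[, ncol(labels)]))
    bad <- union(bad, border[border > 0])
  }
  if (length(bad) > 0L) labels[labels %in% bad] <- 0L
  relabel(labels)
}

label_centroids <- function(labels) {
  idx <- which(labels > 0)
  if (length(idx) == 0L) return(matrix(numeric(0), ncol = 2))
  ids <- labels[idx]
  rr <- (idx - 1L) %% nrow(labels) + 1L
  cc <- (idx - 1L) %/% nrow(labels) + 1L
  cbind(rowsum(rr, ids) / as.vector(table(ids)),
        rowsum(cc, ids) / as.vector(table(ids)))
}

#' Delineate cytoplasmic territories around segmented nuclei
#'
#' Every pixel within `cytoplasm_radius_px` of a nucleus is claimed by the
#' nucleus whose centroid is nearest (a distance-limited Voronoi partition),
#' so neighbouring territories meet at the perpendicular bisector between
#' nuclei and never overlap. Territory ids equal nucleus ids and include the
#' nucleus pixels themselves.
#'
#' @param nuclei_labels Integer label matrix from [segment_nuclei()].
#' @param params A [segmentation_params()] object.
#' @return Integer label matrix of cell territories.
#' @export
delineate_cytoplasm <- function(nuclei_labels, params = segmentation_params()) {
  assert_image(nuclei_labels, "nuclei_labels")
  out <- matrix(0L, nrow(nuclei_labels), ncol(nuclei_labels))
  ids <- sort(unique(nuclei_labels[nuclei_labels > 0]))
  if (length(ids) == 0L) return(out)
  # distance of every pixel to the nearest nucleus pixel (0 inside nuclei)
  dn <- ebi_mat(EBImage::distmap(EBImage::Image((nuclei_labels == 0) * 1)))
  within <- which(dn <= params$cytoplasm_radius_px)
  cent <- label_centroids(nuclei_labels)
  rr <- (within - 1L) %% nrow(out) + 1L
  cc <- (within - 1L) %/% nrow(out) + 1L
  best <- rep(Inf, length(within))
  lab <- integer(length(within))
  for (i in seq_along(ids)) {
    d2 <- (rr - cent[i, 1])^2 + (cc - cent[i, 2])^2
    take <- d2 < best
    best[take] <- d2[take]
    lab[take] <- ids[i]
  }
  out[within] <- lab
  # nucleus pixels always belong to their own territory
  nz <- nuclei_labels > 0
  out[nz] <- nuclei_labels[nz]
  out
}

#' Detect lipid-droplet spots in the neutral-lipid channel
#'
#' The default detector applies a white top-hat filter (disc radius = the
#' upper spot-radius gate) to suppress background and cell-scale structure,
#' thresholds the response at `ld_threshold_k` times its MAD, splits merged
#' spots by an intensity watershed, and gates detections on their diameter at
#' half maximum. The `"log"` detector instead thresholds a multi-scale
#' Laplacian-of-Gaussian (difference-of-Gaussians) blob response.
#'
#' @param droplet_image 2-D grayscale matrix (already stack-collapsed).
#' @param params A [segmentation_params()] object.
#' @return Tibble of spots: `spot_id`, `row`, `col` (intensity-weighted
#'   centroid), `area_px`, `diameter_px` (at half maximum),
#'   `integrated_intensity` (background-subtracted sum over the spot mask).
#' @export
detect_droplets <- function(droplet_image, params = segmentation_params()) {
  assert_image(droplet_image, "droplet_image")
  empty <- tibble(spot_id = integer(0), row = numeric(0), col = numeric(0),
                  area_px = integer(0), diameter_px = numeric(0),
                  integrated_intensity = numeric(0))
  d_gate <- params$ld_diameter_px
  if (params$ld_detector == "tophat") {
    brush_r <- ceiling(d_gate[2] / 2)
    kern <- EBImage::makeBrush(2L * brush_r + 1L, shape = "disc")
    resp <- ebi_mat(EBImage::whiteTopHat(EBImage::Image(droplet_image), kern))
  } else {
    sigmas <- seq(d_gate[1], d_gate[2], length.out = 4) / 2.355
    resp <- matrix(-Inf, nrow(droplet_image), ncol(droplet_image))
    img <- EBImage::Image(droplet_image)
    for (s in sigmas) {
      dog <- ebi_mat(EBImage::gblur(img, s)) - ebi_mat(EBImage::gblur(img, 1.6 * s))
      resp <- pmax(resp, dog / (1.6 - 1) * 1)  # scale-normalised DoG ~ LoG
    }
  }
  # Noise scale estimated from adjacent-pixel differences of the raw image:
  # robust to how much of the field the spots and their halos cover, unlike
  # any statistic of the response distribution itself, which densely loaded
  # cells inflate. The median response absorbs the top-hat's noise pedestal.
  # On a noiseless render sigma is 0 and the threshold falls back to the
  # median, so exact-zero background never triggers a detection.
  dif <- c(abs(diff(droplet_image)), abs(diff(t(droplet_image))))
  sigma <- stats::median(dif) / 0.9539
  med <- stats::median(resp)
  thr <- med + params$ld_threshold_k * sigma
  mask <- resp > thr
  if (!any(mask)) return(empty)
  split_tol <- params$ld_split_tolerance %||% max(params$ld_threshold_k * sigma, 1e-8)
  labs <- ebi_mat(EBImage::watershed(EBImage::Image(resp * mask),
                                       tolerance = split_tol, ext = 1))
  storage.mode(labs) <- "integer"
  idx <- which(labs > 0)
  ids <- labs[idx]
  rr <- (idx - 1L) %% nrow(labs) + 1L
  cc <- (idx - 1L) %/% nrow(labs) + 1L
  w <- resp[idx]
  bg <- stats::median(droplet_image)
  spot <- tibble(
    id = sort(unique(ids)),
    area_px = as.integer(tabulate(ids)[sort(unique(ids))]),
    row = as.vector(rowsum(rr * w, ids) / rowsum(w, ids)),
    col = as.vector(rowsum(cc * w, ids) / rowsum(w, ids)),
    integrated_intensity = as.vector(rowsum(pmax(droplet_image[idx] - bg, 0), ids))
  )
  # Spot diameter at half maximum of the detector response. When the
  # detection threshold sits above the half-max level (dense fields push the
  # threshold towards the peaks) the visible footprint is only the core, so
  # the half-max area is extrapolated from the Gaussian profile identity
  # A(L) = 2*pi*sigma^2 * log(peak / L).
  half_area <- vapply(split(seq_along(ids), ids), function(ii) {
    peak <- max(w[ii])
    if (0.5 * peak >= thr || length(ii) < 4L) {
      # direct count; near-threshold speckle (tiny cores) stays un-extrapolated
      sum(w[ii] >= 0.5 * peak)
    } else {
      length(ii) * log(2) / log(peak / thr)
    }
  }, numeric(1))
  spot$diameter_px <- 2 * sqrt(half_area / pi)
  spot <- filter(spot, .data$diameter_px >= d_gate[1], .data$diameter_px <= d_gate[2])
  if (nrow(spot) == 0L) return(empty)
  spot %>%
    arrange(.data$row, .data$col) %>%
    mutate(spot_id = row_number()) %>%
    select("spot_id", "row", "col", "area_px", "diameter_px", "integrated_intensity")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assign detected spots to cell territories
#'
#' Each spot is assigned to the territory containing its (rounded) centroid;
#' spots on background are collected as unassigned. The count identity
#' `sum(per-cell counts) + n(unassigned) = n(spots)` holds exactly.
#'
#' @param spots Spot tibble from [detect_droplets()].
#' @param cell_labels Territory label matrix from [delineate_cytoplasm()].
#' @return List with `spots` (input plus `cell_id`, `NA` = unassigned),
#'   `per_cell` (tibble `cell_id`, `ld_count`, one row per territory,
#'   zero-count cells included) and `unassigned` (subset of `spots`).
#' @export
assign_droplets <- function(spots, cell_labels) {
  assert_image(cell_labels, "cell_labels")
  ids <- sort(unique(cell_labels[cell_labels > 0]))
  if (nrow(spots) > 0L) {
    ri <- pmin(pmax(round(spots$row), 1), nrow(cell_labels))
    ci <- pmin(pmax(round(spots$col), 1), ncol(cell_labels))
    lab <- cell_labels[cbind(ri, ci)]
    spots$cell_id <- ifelse(lab > 0, lab, NA_integer_)
  } else {
    spots$cell_id <- integer(0)
  }
  counts <- table(factor(spots$cell_id, levels = ids))
  per_cell <- tibble(cell_id = as.integer(ids), ld_count = as.integer(counts))
  list(spots = spots,
       per_cell = per_cell,
       unassigned = filter(spots, is.na(.data$cell_id)))
}

#' Segment one two-channel field end to end
#'
#' Convenience wrapper: nuclei segmentation, cytoplasm delineation, droplet
#' detection and spot-to-cell assignment in one call.
#'
#' @param nuclei_image,droplet_image 2-D grayscale matrices.
#' @param params A [segmentation_params()] object.
#' @return An `ld_segmentation` object: label matrices `nuclei_labels` and
#'   `cell_labels`, the assigned `spots` tibble, `per_cell` counts,
#'   `unassigned` spots and the `params` used.
#' @export
segment_field <- function(nuclei_image, droplet_image,
                          params = segmentation_params()) {
  if (!all(dim(nuclei_image) == dim(droplet_image))) {
    abort("the two channels must share the same shape.")
  }
  nuc <- segment_nuclei(nuclei_image, params)
  cells <- delineate_cytoplasm(nuc, params)
  spots <- detect_droplets(droplet_image, params)
  asg <- assign_droplets(spots, cells)
  structure(
    list(nuclei_labels = nuc, cell_labels = cells, spots = asg$spots,
         per_cell = asg$per_cell, unassigned = asg$unassigned, params = params),
    class = "ld_segmentation"
  )
}

#' @export
print.ld_segmentation <- function(x, ...) {
  cat(sprintf("<ld_segmentation> %d nuclei, %d spots (%d unassigned)\n",
              max(0, x$nuclei_labels), nrow(x$spots), nrow(x$unassigned)))
  invisible(x)
}
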