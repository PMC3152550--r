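# Small constructed fixtures used across test files.

# Draw a filled disk of value `value` onto `img` (in place, returned).
draw_disk <- function(img, r, c, radius, value) {
  rows <- matrix(seq_len(nrow(img)), nrow(img), ncol(img))
  cols <- matrix(seq_len(ncol(img)), nrow(img), ncol(img), byrow = TRUE)
  img[(rows - r)^2 + (cols - c)^2 <= radius^2] <- value
  img
}

# Add an isotropic Gaussian spot of amplitude `amp`, sd `sigma`.
draw_gaussian <- function(img, r, c, amp, sigma) {
  rows <- matrix(seq_len(nrow(img)), nrow(img), ncol(img))
  cols <- matrix(seq_len(ncol(img)), nrow(img), ncol(img), byrow = TRUE)
  img + amp * exp(-((rows - r)^2 + (cols - c)^2) / (2 * sigma^2))
}

blank_image <- function(nr = 64, nc = nr, value = 0) matrix(value, nr, nc)

# Brute-force nearest-seed (nucleus centroid) assignment per pixel, limited
# to `radius` from the nucleus mask: the independent oracle for
# delineate_cytoplasm().
brute_force_territories <- function(nuclei_labels, radius) {
  ids <- sort(unique(nuclei_labels[nuclei_labels > 0]))
  out <- matrix(0L, nrow(nuclei_labels), ncol(nuclei_labels))
  if (length(ids) == 0) return(out)
  cent <- do.call(rbind, lapply(ids, function(i) {
    w <- which(nuclei_labels == i, arr.ind = TRUE)
    colMeans(w)
  }))
  nuc <- which(nuclei_labels > 0, arr.ind = TRUE)
  for (r in seq_len(nrow(out))) {
    for (c in seq_len(ncol(out))) {
      dmin <- sqrt(min((nuc[, 1] - r)^2 + (nuc[, 2] - c)^2))
      if (dmin > radius) next
      d2 <- (cent[, 1] - r)^2 + (cent[, 2] - c)^2
      out[r, c] <- ids[which.min(d2)]
    }
  }
  nz <- nuclei_labels > 0
  out[nz] <- nuclei_labels[nz]
  out
}

# A noiseless, well-separated scene for exact-recovery tests.
clean_scene_params <- function(noise_sd = 0, ...) {
  scene_params(field_shape = c(256L, 256L), n_cells = 6L, ld_rate = 8,
               noise_sd = noise_sd, psf_sigma_px = 1, ...)
}
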