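# Shared fixtures, all generated in code.

# Desk-scale phantom spec mirroring the batch scaling: smaller total counts
# give proportionally smaller stems with proportionally smaller bundles.
small_phantom_spec <- function(seed = 1L, n_total = 120L, ...) {
  s <- sqrt(n_total / 380)
  n_per <- as.integer(round(0.605 * n_total))
  phantom_spec(image_size = as.integer(2L * round(270 * s) + 60L),
               outer_radius = round(270 * s),
               inner_radius = round(228 * s),
               epidermis_width = max(6, round(16 * s)),
               n_periphery = n_per, n_inner = as.integer(n_total) - n_per,
               law_distance_scale = s, seed = seed, ...)
}

disk_mask <- function(r, pad = 6L) {
  n <- 2L * (r + pad) + 1L
  c0 <- r + pad + 1L
  m <- matrix(FALSE, n, n)
  for (i in seq_len(n))
    m[i, ] <- (i - c0)^2 + (seq_len(n) - c0)^2 <= r^2
  m
}

disk_image <- function(r, value = 200L, pad = 6L, pixel = 1) {
  m <- disk_mask(r, pad)
  slice_image(matrix(as.integer(m) * value, nrow(m)), pixel_size_mm = pixel)
}

annulus_mask <- function(r_in, r_out, pad = 6L) {
  disk_mask(r_out, pad) & !disk_mask_same(r_in, r_out, pad)
}

# inner disk on the same grid as disk_mask(r_out, pad)
disk_mask_same <- function(r, r_out, pad = 6L) {
  n <- 2L * (r_out + pad) + 1L
  c0 <- r_out + pad + 1L
  m <- matrix(FALSE, n, n)
  for (i in seq_len(n))
    m[i, ] <- (i - c0)^2 + (seq_len(n) - c0)^2 <= r^2
  m
}

# minimal zones object over a single inner disk (for candidate tests)
fake_inner_zones <- function(n = 101L, r = 40L, px = 1) {
  c0 <- (n + 1L) / 2
  inner <- matrix(FALSE, n, n)
  for (i in seq_len(n))
    inner[i, ] <- (i - c0)^2 + (seq_len(n) - c0)^2 <= r^2
  structure(list(inner_mask = inner,
                 periphery_mask = matrix(FALSE, n, n),
                 epidermis_mask = matrix(FALSE, n, n),
                 stem_center = c(c0 - 1, c0 - 1),
                 dim = c(n, n), pixel_size_mm = px),
            class = "function_zones")
}

# symmetric Hausdorff distance between two point sets (n x 2 matrices)
hausdorff_dist <- function(a, b) {
  d2 <- outer(a[, 1L], b[, 1L], "-")^2 + outer(a[, 2L], b[, 2L], "-")^2
  max(sqrt(max(apply(d2, 1L, min))), sqrt(max(apply(d2, 2L, min))))
}

# dumbbell: two disks of radius r bridged by a 2-px-wide bar
dumbbell_mask <- function(r = 8L, gap = 14L) {
  w <- 2L * r + 6L
  n_c <- 2L * r + gap + 2L * w
  m <- matrix(FALSE, 2L * w + 1L, n_c)
  c1 <- w; c2 <- w + 2L * r + gap
  cr <- w + 1L
  for (i in seq_len(nrow(m))) {
    m[i, ] <- pmin((seq_len(n_c) - c1)^2, (seq_len(n_c) - c2)^2) +
      (i - cr)^2 <= r^2
  }
  m[cr:(cr + 1L), c1:c2] <- TRUE
  m
}
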