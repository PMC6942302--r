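test_that("substance thresholding follows the strict-above rule", {
  img <- slice_image(matrix(0L, 10L, 10L))
  expect_false(any(threshold_substance(img, 0L)))
  px <- matrix(0L, 10L, 10L); px[4L, 7L] <- 100L
  m <- threshold_substance(slice_image(px), 0L)
  expect_identical(sum(m), 1L)
  expect_true(m[4L, 7L])
})

test_that("outermost contour takes the largest filled component, holes ignored", {
  d <- disk_mask(50L)
  ct <- outermost_contour(d)
  expect_lt(abs(ct$area_px - pi * 50^2) / (pi * 50^2), 0.02)
  # largest of two blobs wins
  m <- matrix(FALSE, 60L, 120L)
  m[10:45, 10:45] <- TRUE          # 36 x 36
  m[20:23, 100:102] <- TRUE        # small blob
  expect_equal(outermost_contour(m)$area_px, 36 * 36)
  # annulus: outer boundary, hole ignored
  ring <- disk_mask(30L) & !disk_mask_same(20L, 30L)
  ct2 <- outermost_contour(ring)
  expect_lt(abs(sqrt(ct2$area_px / pi) - 30), 1)
  expect_error(outermost_contour(matrix(FALSE, 5L, 5L)), "no object")
})

test_that("epidermis validation compares filled area against the convex hull", {
  d <- disk_mask(50L)
  v <- validate_epidermis(d)
  expect_true(v$is_valid)
  expect_gt(v$area_ratio, 0.98)
  # wedge notch of ~10% of the area cut to the boundary -> invalid
  n <- nrow(d); c0 <- (n + 1) / 2
  ang <- atan2(col(d) - c0, row(d) - c0)
  notched <- d & !(ang > 0 & ang < 0.2 * pi)   # 10% angular wedge
  vn <- validate_epidermis(notched)
  expect_false(vn$is_valid)
  expect_lt(abs(vn$area_ratio - 0.90), 0.03)
  # a discrete disk never reaches a ratio of exactly 1
  expect_false(validate_epidermis(d, ratio = 1)$is_valid)
})

test_that("boundary repair is a no-op on valid masks and closes broken rings", {
  d <- disk_mask(50L)
  r0 <- repair_boundary(d)
  expect_identical(r0$iterations, 0L)
  expect_equal(r0$contour1$area_px, validate_epidermis(d)$contour$area_px)
  expect_identical(r0$repaired_mask, d)
  # ring broken by a 4-px gap: repaired outline within 3% of the intact disk
  ring <- disk_mask(60L) & !disk_mask_same(56L, 60L)
  ring[1:66, 65:68] <- FALSE              # cut the top arc over 4 columns
  rep <- repair_boundary(ring)
  expect_gt(rep$iterations, 0L)
  expect_lt(abs(rep$contour1$area_px - pi * 60^2) / (pi * 60^2), 0.03)
  expect_true(validate_epidermis(rep$repaired_mask)$is_valid)
  # a wide-open arc cannot reach validity within a small dilation budget
  arc <- disk_mask(60L) & !disk_mask_same(56L, 60L)
  arc[, 1:67] <- FALSE                         # keep only half the ring
  expect_error(repair_boundary(arc, max_iter = 5L), "unrepairable")
})

test_that("the inner boundary is the largest interior cavity with holes filled", {
  ring <- disk_mask(60L) & !disk_mask_same(45L, 60L)
  c1 <- outermost_contour(ring)
  c2 <- inner_boundary(ring, c1)
  expect_lt(abs(sqrt(c2$area_px / pi) - 45), 1.5)
  # isolated disks inside the hole are holes of the cavity: same contour2
  withdisks <- ring
  n <- nrow(ring); c0 <- (n + 1) / 2
  for (off in list(c(-20, 0), c(15, 10), c(0, -18), c(10, -10), c(-8, 14))) {
    for (i in seq_len(n)) {
      withdisks[i, ] <- withdisks[i, ] |
        ((i - c0 - off[1])^2 + (seq_len(n) - c0 - off[2])^2 <= 16)
    }
  }
  c2b <- inner_boundary(withdisks, outermost_contour(withdisks))
  expect_equal(c2b$area_px, c2$area_px, tolerance = 0.01)
  expect_error(inner_boundary(disk_mask(30L), outermost_contour(disk_mask(30L))),
               "no inner zone")
})

test_that("adaptive mean segmentation: uniform empty, bright pixel kept,
           mean-shift invariant", {
  n <- 61L
  roi <- matrix(TRUE, n, n)
  uni <- slice_image(matrix(100L, n, n))
  expect_false(any(adaptive_mean_segment(uni, roi, 31L)))
  px <- matrix(10L, n, n); px[31L, 31L] <- 250L
  seg <- adaptive_mean_segment(slice_image(px), roi, 31L)
  expect_true(seg[31L, 31L])
  expect_identical(sum(seg), 1L)
  # adding a constant changes nothing
  set.seed(5)
  a <- matrix(sample(0:200, n * n, TRUE), n, n)
  s1 <- adaptive_mean_segment(slice_image(a), roi, 31L)
  s2 <- adaptive_mean_segment(slice_image(a + 50L), roi, 31L)
  expect_identical(s1, s2)
})

test_that("adaptive segmentation of the phantom periphery matches the truth", {
  ph <- generate_phantom(small_phantom_spec(seed = 21L, n_total = 160L))
  roi <- ph$zones$periphery_mask | ph$zones$epidermis_mask
  seg <- adaptive_mean_segment(ph$image, roi, 31L)
  truth_fg <- sum(ph$zones$epidermis_mask) +
    sum(ph$bundles$area_px[ph$bundles$zone == "periphery"])
  expect_lt(abs(sum(seg) - truth_fg) / truth_fg, 0.10)
})

test_that("cavity closing bridges gaps below the element size only", {
  base <- matrix(FALSE, 60L, 120L)
  base[20:39, 20:39] <- TRUE
  near <- base; near[20:39, 50:69] <- TRUE     # 10-px gap
  far <- base;  far[20:39, 70:89] <- TRUE      # 30-px gap
  blob <- close_cavities(base, 15L)
  expect_identical(max(label_components(blob, 8L)), 1L)
  expect_identical(max(label_components(close_cavities(near, 15L), 8L)), 1L)
  expect_identical(max(label_components(close_cavities(far, 15L), 8L)), 2L)
})

test_that("zone detection recovers analytic concentric annuli within 2 px", {
  n <- 221L; c0 <- 111
  px <- matrix(0L, n, n)
  rad <- sqrt((row(px) - c0)^2 + (col(px) - c0)^2)
  px[rad <= 100 & rad > 95] <- 200L     # epidermis ring
  px[rad <= 95 & rad > 80] <- 90L       # periphery matrix band
  for (off in list(c(-30, 0), c(20, 25), c(5, -35))) {
    px[(row(px) - c0 - off[1])^2 + (col(px) - c0 - off[2])^2 <= 36] <- 160L
  }
  z <- detect_function_zones(slice_image(px))
  expect_lt(abs(sqrt(z$contour1$area_px / pi) - 100), 2)
  expect_lt(abs(sqrt(z$contour3$area_px / pi) - 95), 2)
  expect_lt(abs(sqrt(z$contour2$area_px / pi) - 80), 2)
})

test_that("zone detection on a noise-free phantom matches ground truth", {
  ph <- generate_phantom(small_phantom_spec(seed = 13L, n_total = 150L))
  z <- detect_function_zones(ph$image)
  jac <- function(a, b) sum(a & b) / sum(a | b)
  expect_gte(jac(z$epidermis_mask, ph$zones$epidermis_mask), 0.95)
  expect_gte(jac(z$periphery_mask, ph$zones$periphery_mask), 0.95)
  expect_gte(jac(z$inner_mask, ph$zones$inner_mask), 0.95)
})

test_that("the three zone masks partition the slice region exactly and nest", {
  ph <- generate_phantom(small_phantom_spec(seed = 4L, n_total = 130L,
                                            noise_sd = 8))
  z <- detect_function_zones(ph$image)
  region1 <- contour_mask(z$contour1, z$dim)
  total <- z$epidermis_mask | z$periphery_mask | z$inner_mask
  expect_identical(total, region1)
  expect_false(any(z$epidermis_mask & z$periphery_mask))
  expect_false(any(z$epidermis_mask & z$inner_mask))
  expect_false(any(z$periphery_mask & z$inner_mask))
  region3 <- contour_mask(z$contour3, z$dim)
  region2 <- contour_mask(z$contour2, z$dim)
  expect_true(all(region1[z$inner_mask]))
  expect_gte(mean(region3[region2]), 0.999)    # contour2 inside contour3
  expect_true(all(region1[region3]))
  # stem center lies inside contour2
  sc <- round(z$stem_center) + 1L
  expect_true(region2[sc[1L], sc[2L]])
})

test_that("a repaired phantom with a broken epidermis still yields zones", {
  ph <- generate_phantom(small_phantom_spec(seed = 6L, n_total = 130L,
                                            boundary_break = 12))
  z <- detect_function_zones(ph$image)
  truth_r1 <- sqrt(ph$zones$contour1$area_px / pi)
  expect_lt(abs(sqrt(z$contour1$area_px / pi) - truth_r1), 3)
})
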