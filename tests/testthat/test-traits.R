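test_that("trait record of a digitized disk approaches the circle limits", {
  img <- disk_image(40L, value = 200L, pad = 10L)
  ct <- outermost_contour(img$pixels > 0L)
  c0 <- (nrow(img$pixels) - 1) / 2
  tr <- contour_traits(ct, img, c(c0, c0))
  expect_lt(abs(tr$CIR - 1), 0.05)
  expect_lt(abs(tr$SPH - 1), 0.05)
  expect_lt(abs(tr$CV - 1), 0.05)
  expect_lt(abs(tr$AR - 1), 0.05)
  expect_lt(abs(tr$ECC), 0.1)
  expect_lt(abs(tr$DC), 1e-9)                  # centered on the stem center
  expect_equal(tr$AI, 200)
  expect_lt(abs(tr$A - pi * 40^2) / (pi * 40^2), 0.02)
})

test_that("trait record of an axis-aligned rectangle matches closed forms", {
  px <- matrix(0L, 80L, 100L)
  px[20:49, 21:80] <- 150L                     # 30 rows x 60 cols
  img <- slice_image(px)
  tr <- contour_traits(outermost_contour(px > 0L), img, c(34, 50))
  expect_equal(tr$W, 60 * img$pixel_size_mm)
  expect_equal(tr$H, 30 * img$pixel_size_mm)
  expect_lt(abs(tr$AR - 0.5), 0.03)
  expect_lt(abs(tr$RA - 1), 0.05)
  expect_lt(abs(tr$ECC - sqrt(1 - 0.25)), 0.03)
  expect_equal(tr$A, tr$CHA)                   # convex shape
})

test_that("trait bound invariants hold structurally", {
  img <- disk_image(12L, value = 90L, pad = 8L)
  ct <- outermost_contour(img$pixels > 0L)
  tr <- contour_traits(ct, img, c(0, 0))
  expect_true(tr$MAW <= tr$MAL)
  expect_true(tr$ICR <= tr$CR)
  expect_true(tr$A <= tr$CHA + 1e-12)
  expect_true(tr$ECC >= 0 && tr$ECC < 1)
  expect_true(tr$AR > 0 && tr$AR <= 1)
})

test_that("zone histograms count grey levels 1..255 and exclude background", {
  img <- slice_image(matrix(0L, 20L, 20L))
  mask <- matrix(TRUE, 20L, 20L)
  expect_identical(sum(zone_histogram(img, mask)), 0L)
  px <- matrix(0L, 20L, 20L); px[3L, 1:10] <- 7L
  h <- zone_histogram(slice_image(px), mask)
  expect_identical(h[7L], 10L)
  expect_identical(sum(h), 10L)
  expect_error(zone_histogram(img, matrix(FALSE, 20L, 20L)), "empty")
})

test_that("phantom epidermis histogram peaks near the generator mean", {
  ph <- generate_phantom(small_phantom_spec(seed = 41L, n_total = 130L,
                                            noise_sd = 6))
  h <- zone_histogram(ph$image, ph$zones$epidermis_mask)
  expect_lt(abs(which.max(h) - 200), 25)       # per-slice mean jitter + noise
})

test_that("the exponential distance model recovers noise-free parameters", {
  curves <- list(perimeter = c(1.419, 1.22e-4, 0.589),
                 radius = c(0.249, 5.765e-4, 0.502),
                 area = c(0.129, 5.594e-4, 0.475))
  for (nm in names(curves)) {
    cv <- curves[[nm]]
    x <- seq(0, 12, by = 0.5)
    m <- fit_distance_model(data.frame(dc = x,
                                       value = cv[1] - cv[2] * exp(cv[3] * x)),
                            nm)
    expect_lt(abs(m$a - cv[1]) / cv[1], 0.01)
    expect_lt(abs(m$b - cv[2]) / cv[2], 0.01)
    expect_lt(abs(m$c - cv[3]) / cv[3], 0.01)
  }
})

test_that("the distance model handles flat data and recovers under noise", {
  flat <- fit_distance_model(data.frame(dc = seq(0, 10, 1), value = 5))
  expect_equal(flat$a, 5)
  expect_lt(flat$b, 1e-6)
  set.seed(91)
  for (rep in 1:5) {
    x <- runif(200, 0, 12)
    y <- 1.419 - 1.22e-4 * exp(0.589 * x) + rnorm(200, 0, 0.02)
    m <- fit_distance_model(data.frame(dc = x, value = y))
    expect_lt(abs(m$a - 1.419) / 1.419, 0.03)
  }
  expect_error(fit_distance_model(data.frame(dc = 1:5, value = 1:5)),
               "at least 10")
  expect_error(fit_distance_model(data.frame(dc = seq(1, 2, length.out = 12),
                                             value = rnorm(12))),
               "3 mm")
})

test_that("layer partitions tile the interior; EA areas are near-equal", {
  ph <- generate_phantom(small_phantom_spec(seed = 15L, n_total = 120L))
  z <- ph$zones
  ea <- layer_partition(z, 5L, "EA")
  areas <- vapply(1:5, function(k) sum(ea$label == k), 0)
  expect_lte(max(areas) / min(areas), 1.02)
  region3 <- contour_mask(z$contour3, z$dim)
  expect_identical(sum(ea$label > 0L), sum(region3))   # exact tiling
  ed <- layer_partition(z, 5L, "ED")
  r3 <- sqrt(z$contour3$area_px / pi)
  for (k in 1:4) {
    rk <- sqrt(ed$ring_contours[[k]]$area_px / pi)
    expect_lt(abs(rk - k / 5 * r3), 2)
  }
})

test_that("bundle density rising outward shows up in the layer counts", {
  ph <- generate_phantom(small_phantom_spec(seed = 16L, n_total = 150L))
  z <- detect_function_zones(ph$image)
  det <- detect_vascular_bundles(ph$image, z)
  sch <- layer_partition(z, 5L, "EA", bundles = det$bundles, img = ph$image)
  expect_gt(sch$layers$NVBEL[5L], sch$layers$NVBEL[1L])
  # per-layer counts add up to the bundles inside contour3
  expect_equal(sum(sch$layers$NVBEL), sum(!is.na(sch$bundle_layer)))
})

test_that("Voronoi growth space partitions the constrained region", {
  ph <- generate_phantom(small_phantom_spec(seed = 17L, n_total = 110L))
  z <- ph$zones
  region_area <- sum(contour_mask(z$contour3, z$dim))
  px <- z$pixel_size_mm
  v1 <- voronoi_growth_space(matrix(z$stem_center, 1L), z$contour3, z$dim, px)
  expect_equal(v1$areas_mm2[1L], region_area * px^2)
  ctr <- z$stem_center
  pair <- rbind(ctr + c(0, -30), ctr + c(0, 30))
  v2 <- voronoi_growth_space(pair, z$contour3, z$dim, px)
  expect_lt(abs(v2$areas_mm2[1L] - v2$areas_mm2[2L]) / mean(v2$areas_mm2), 0.01)
  set.seed(8)
  many <- cbind(runif(40, ctr[1L] - 60, ctr[1L] + 60),
                runif(40, ctr[2L] - 60, ctr[2L] + 60))
  v3 <- voronoi_growth_space(many, z$contour3, z$dim, px)
  expect_lt(abs(sum(v3$areas_mm2) - region_area * px^2) /
              (region_area * px^2), 0.005)
  expect_warning(voronoi_growth_space(rbind(ctr, ctr), z$contour3, z$dim, px),
                 "duplicate")
})

test_that("area k-means is deterministic with ordered labels", {
  areas <- c(1, 1, 1, 10, 10, 10)
  expect_identical(kmeans_area_classes(areas, 2L), c(0L, 0L, 0L, 1L, 1L, 1L))
  expect_identical(kmeans_area_classes(areas, 1L), rep(0L, 6L))
  set.seed(2); a2 <- runif(50)
  expect_identical(kmeans_area_classes(a2, 3L, seed = 5L),
                   kmeans_area_classes(a2, 3L, seed = 5L))
  expect_error(kmeans_area_classes(c(1, 1, 2), 3L), "distinct")
})

test_that("zone growth traits match phantom ground truth", {
  ph <- generate_phantom(small_phantom_spec(seed = 18L, n_total = 140L))
  z <- detect_function_zones(ph$image)
  det <- detect_vascular_bundles(ph$image, z)
  zt <- zone_growth_traits(z, det, ph$image)
  expect_identical(zt$NVBPZ, sum(ph$bundles$zone == "periphery"))
  expect_identical(zt$NVBIZ, sum(ph$bundles$zone == "inner"))
  px <- z$pixel_size_mm
  slice_area <- contour_mask(z$contour1, z$dim)
  expect_equal(sum(zt$AEFZ), sum(slice_area) * px^2)
  expect_true(zt$substance_ratio > 0 && zt$substance_ratio <= 1)
  # epidermis thickness from truth zones: close to the generated ring width
  w <- ph$spec$epidermis_width
  zt_truth <- zone_growth_traits(
    z, det, slice_image(matrix(200L, z$dim[1L], z$dim[2L]) *
                          (contour_mask(z$contour1, z$dim) * 1L),
                        pixel_size_mm = px))
  expect_equal(zt_truth$substance_ratio, 1)    # all-substance disk
  expect_lt(abs(zt$epidermis_thickness_mm - w * px) / (w * px), 0.15)
})

test_that("per-bundle trait table obeys every dimensionless bound", {
  ph <- generate_phantom(small_phantom_spec(seed = 19L, n_total = 130L,
                                            noise_sd = 8))
  z <- detect_function_zones(ph$image)
  det <- detect_vascular_bundles(ph$image, z)
  tt <- bundle_traits_table(det, z, ph$image)
  eps <- 0.05
  expect_true(all(tt$AI >= 0 & tt$AI <= 255))
  expect_true(all(tt$AR > 0 & tt$AR <= 1))
  expect_true(all(tt$ECC >= 0 & tt$ECC < 1))
  expect_true(all(tt$SPH > 0 & tt$SPH <= 1 + 1e-9))
  expect_true(all(tt$CV > 0 & tt$CV <= 1 + 1e-9))
  expect_true(all(tt$CIR <= 1 + eps))
  expect_true(all(tt$RA <= 1 + eps))
  expect_true(all(tt$MAW <= tt$MAL + 1e-12))
  expect_true(all(tt$ICR <= tt$CR + 1e-9))
  expect_true(all(tt$A <= tt$CHA + 1e-9))
  expect_true(all(tt$DC >= 0))
})
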