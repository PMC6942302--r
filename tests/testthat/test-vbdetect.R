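test_that("inner candidates: empty zone, exact counts, 8-connectivity", {
  z <- fake_inner_zones()
  blank <- slice_image(matrix(0L, 101L, 101L))
  expect_length(inner_candidates(blank, z), 0L)
  # two solid squares touching only diagonally form one 8-connected candidate
  px <- matrix(0L, 101L, 101L)
  px[40:45, 40:45] <- 160L
  px[46:51, 46:51] <- 160L
  expect_length(inner_candidates(slice_image(px), z), 1L)
  # separated by one pixel: two candidates
  px2 <- matrix(0L, 101L, 101L)
  px2[40:45, 40:45] <- 160L
  px2[47:52, 47:52] <- 160L
  expect_length(inner_candidates(slice_image(px2), z), 2L)
})

test_that("inner candidates on a noise-free phantom equal the ground truth", {
  ph <- generate_phantom(small_phantom_spec(seed = 31L, n_total = 130L))
  z <- detect_function_zones(ph$image)
  ic <- inner_candidates(ph$image, z)
  expect_identical(length(ic), sum(ph$bundles$zone == "inner"))
})

test_that("active-contour refinement locks onto sharp and blurred disks", {
  img <- disk_image(20L, value = 180L, pad = 15L)
  truth <- outermost_contour(img$pixels > 0L)
  # init: dilated disk
  init_mask <- disk_mask(25L, pad = 10L)
  init <- outermost_contour(init_mask)
  ref <- level_set_refine(img, init, iters = 50L)
  expect_lt(hausdorff_dist(ref$points, truth$points), 1.5)
  # init already on the edge stays put
  ref2 <- level_set_refine(img, truth, iters = 30L)
  expect_lt(hausdorff_dist(ref2$points, truth$points), 1.01)
  # blurred disk: recovered area within 10% of the unblurred area
  blur <- matrix(as.numeric(EBImage::gblur(img$pixels * 1, 2)), nrow(img$pixels))
  imgb <- slice_image(pmax(pmin(round(blur), 255), 0))
  refb <- level_set_refine(imgb, init, iters = 50L)
  expect_lt(abs(refb$area_px - truth$area_px) / truth$area_px, 0.10)
})

test_that("inscribed-circle decomposition follows the distance transform", {
  d <- disk_mask(10L, pad = 3L)
  circ <- inscribed_circle_decomposition(d, 3)
  expect_gte(length(circ), 1L)
  expect_lt(abs(circ[[1L]]$radius_px - 10), 0.51)
  c0 <- (nrow(d) - 1) / 2
  expect_lt(max(abs(circ[[1L]]$center - c0)), 1.01)
  # 40 x 6 rectangle: radii bounded by the half-width
  rect <- matrix(FALSE, 12L, 46L)
  rect[4:9, 4:43] <- TRUE
  cr <- inscribed_circle_decomposition(rect, 3)
  radii <- vapply(cr, `[[`, 0, "radius_px")
  expect_true(all(radii <= 3.5))
  expect_lt(abs(radii[1L] - 3), 0.51)
  # radii never increase; circles stay inside the region
  expect_true(all(diff(radii) <= 1e-9))
  db <- dumbbell_mask(8L)
  cd <- inscribed_circle_decomposition(db, 3)
  r2 <- vapply(cd, `[[`, 0, "radius_px")
  expect_true(all(abs(r2[1:2] - 8) < 0.51))
  for (ci in cd) {
    idx <- which(db, arr.ind = TRUE) - 1L
    inside <- (idx[, 1L] - ci$center[1L])^2 +
      (idx[, 2L] - ci$center[2L])^2 < (ci$radius_px - 0.5)^2
    # every pixel strictly inside the circle is region foreground
    expect_identical(sum(inside),
                     sum((row(db) - 1 - ci$center[1L])^2 +
                           (col(db) - 1 - ci$center[2L])^2 <
                           (ci$radius_px - 0.5)^2))
  }
})

test_that("candidate splitting conserves pixels and resolves dumbbell lobes", {
  d <- disk_mask(10L, pad = 3L)
  circ <- inscribed_circle_decomposition(d, 3)
  whole <- split_candidate(d, circ)
  expect_length(whole, 1L)
  expect_false(attr(whole, "split"))
  expect_equal(whole[[1L]]$area_px, sum(d))
  db <- dumbbell_mask(8L)
  parts <- split_candidate(db, inscribed_circle_decomposition(db, 3))
  expect_length(parts, 2L)
  expect_true(attr(parts, "split"))
  areas <- vapply(parts, `[[`, 0, "area_px")
  expect_equal(sum(areas), sum(db))            # pixel conservation
  lobe <- pi * 8^2
  expect_true(all(abs(areas - lobe) / lobe < 0.15))
  # empty circle list: candidate returned whole, unsplit
  none <- split_candidate(db, list())
  expect_length(none, 1L)
  expect_false(attr(none, "split"))
})

test_that("merged-candidate flagging follows the residual rule", {
  model <- structure(list(a = 0.2, b = 1e-3, c = 0.4, residual_sigma = 0.01,
                          trait = "area", n = 50L),
                     class = "distance_model")
  mk <- function(dc, area) list(dc_mm = dc, area_mm2 = area,
                                merged_flag = FALSE)
  on_curve <- mk(5, predict(model, 5))
  outlier <- mk(5, predict(model, 5) + 10 * 0.01)
  flagged <- flag_merged_candidates(list(on_curve, outlier), model, k = 3)
  expect_false(flagged[[1L]]$merged_flag)
  expect_true(flagged[[2L]]$merged_flag)
  expect_warning(out <- flag_merged_candidates(list(on_curve), NULL),
                 "unflagged")
  expect_false(out[[1L]]$merged_flag)
})

test_that("most deliberately fused clumps are flagged and split", {
  hits <- 0L; total <- 0L; recovered <- 0L; truth_n <- 0L
  for (sd in c(51L, 52L)) {
    # full-scale phantom: clump lobes must exceed the 3-px stop radius of
    # the inscribed-circle decomposition to be resolvable
    ph <- generate_phantom(phantom_spec(seed = sd, fusion_fraction = 0.1))
    z <- detect_function_zones(ph$image)
    det <- detect_vascular_bundles(ph$image, z)
    clumps <- unique(ph$bundles$clump_id[ph$bundles$clump_id > 0L])
    split_b <- Filter(function(b) b$merged_flag, det$bundles)
    for (cl in clumps) {
      total <- total + 1L
      members <- ph$bundles[ph$bundles$clump_id == cl, ]
      ctr <- c(mean(members$row), mean(members$col))
      near <- vapply(split_b, function(b)
        sqrt(sum((b$contour$centroid - ctr)^2)) < 3 * sqrt(sum(members$area_px) / pi),
        TRUE)
      if (any(near)) hits <- hits + 1L
    }
    truth_n <- truth_n + nrow(ph$bundles)
    recovered <- recovered + det$n_total
  }
  expect_gte(hits / total, 0.7)
  # fused slices still recover most individual bundles
  expect_gt(recovered / truth_n, 0.95)
})

test_that("end-to-end count recovery on noise-free unfused phantoms is exact", {
  for (sd in c(61L, 62L)) {
    ph <- generate_phantom(small_phantom_spec(seed = sd, n_total = 140L))
    z <- detect_function_zones(ph$image)
    det <- detect_vascular_bundles(ph$image, z)
    expect_identical(det$n_inner, sum(ph$bundles$zone == "inner"))
    expect_identical(det$n_periphery, sum(ph$bundles$zone == "periphery"))
  }
})

test_that("detected bundles stay disjoint and inside their zones", {
  ph <- generate_phantom(small_phantom_spec(seed = 77L, n_total = 150L,
                                            noise_sd = 6))
  z <- detect_function_zones(ph$image)
  det <- detect_vascular_bundles(ph$image, z)
  cover <- matrix(0L, z$dim[1L], z$dim[2L])
  for (b in det$bundles) cover <- cover + contour_mask(b$contour, z$dim)
  expect_lte(max(cover), 1L)                    # pairwise disjoint regions
  zone_ok <- vapply(det$bundles, function(b) {
    m <- if (b$zone == "inner") z$inner_mask else z$periphery_mask
    p <- round(b$contour$centroid) + 1L
    m[p[1L], p[2L]]
  }, TRUE)
  expect_true(all(zone_ok))
})
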