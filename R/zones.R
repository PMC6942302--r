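# Function-zone detection: a stem cross-section is partitioned into the
# epidermis rind, the dense periphery annulus and the inner (pith) zone by a
# hierarchy of three closed contours:
#   contour1 - outer epidermis boundary (slice outline)
#   contour3 - inner epidermis boundary (epidermis/periphery interface)
#   contour2 - periphery/inner interface
# with region(contour2) < region(contour3) < region(contour1).

#' Parameters of the function-zone detection
#'
#' @param threshold substance threshold: grey levels strictly above it are
#'   substance. The default 0 corresponds to the grey value of air after
#'   calibration.
#' @param area_ratio convexity ratio above which a slice outline counts as a
#'   valid (unbroken) epidermis boundary.
#' @param block odd side of the local window of the adaptive mean threshold,
#'   in px; chosen a little larger than the epidermis thickness so every
#'   window sees both rind and darker matrix.
#' @param close_size diameter (px) of the disc structuring element closing
#'   the periphery cavities; set from the largest bundle diameter.
#' @param min_cavity smallest cavity component (px) kept before closing;
#'   true periphery cavities (inter-bundle matrix) are far larger than
#'   this, isolated sub-threshold noise pixels are far smaller.
#' @param repair_max_iter dilation budget of the boundary repair loop.
#' @return a named list of class `zone_params`.
#' @export
zone_params <- function(threshold = 0L, area_ratio = 0.95, block = 31L,
                        close_size = 15L, min_cavity = 25L,
                        repair_max_iter = 50L) {
  stopifnot(threshold >= 0, threshold <= 255, area_ratio > 0, area_ratio <= 1,
            block >= 3L, block %% 2L == 1L, close_size >= 1L,
            min_cavity >= 1L, repair_max_iter >= 1L)
  structure(list(threshold = as.integer(threshold), area_ratio = area_ratio,
                 block = as.integer(block), close_size = as.integer(close_size),
                 min_cavity = as.integer(min_cavity),
                 repair_max_iter = as.integer(repair_max_iter)),
            class = "zone_params")
}

#' Substance mask of a slice
#'
#' @param img a [slice_image()].
#' @param t grey-level threshold in `[0, 255]`; pixels strictly above `t`
#'   are substance.
#' @return logical matrix.
#' @export
threshold_substance <- function(img, t = 0L) {
  stopifnot(inherits(img, "slice_image"), t >= 0, t <= 255)
  img$pixels > t
}

#' Outer boundary of the largest object in a mask
#'
#' Connected components use 8-connectivity; the component with the largest
#' filled area wins and its holes are ignored.
#'
#' @param mask logical or 0/1 matrix, non-empty.
#' @return a [contour_shape()].
#' @export
outermost_contour <- function(mask) {
  lab <- label_components(mask, 8L)
  if (max(lab) == 0L) stop("no object: the mask is empty")
  if (max(lab) > 1L) {
    # compare filled areas, not raw pixel counts (a broken ring must win by
    # the area it encloses)
    areas <- vapply(seq_len(max(lab)), function(l) {
      idx <- which(lab == l, arr.ind = TRUE)
      r0 <- min(idx[, 1L]); c0 <- min(idx[, 2L])
      w <- matrix(FALSE, max(idx[, 1L]) - r0 + 1L, max(idx[, 2L]) - c0 + 1L)
      w[cbind(idx[, 1L] - r0 + 1L, idx[, 2L] - c0 + 1L)] <- TRUE
      sum(.fill_holes(w))
    }, 0)
    keep <- which.max(areas)
    lab[lab != keep] <- 0L
    lab[lab == keep] <- 1L
  }
  .label_contours(lab)[[1L]]
}

#' Validate a slice outline against its convex hull
#'
#' A stem section is close to convex, so the filled area of a correct
#' outline must claim almost all of its convex hull. Broken epidermis rings
#' enclose far less.
#'
#' @param mask binary substance mask, non-empty.
#' @param ratio validity threshold on `filled_area / hull_area` (strict).
#' @return list with `is_valid`, `contour` (the outermost [contour_shape()])
#'   and `area_ratio`.
#' @export
validate_epidermis <- function(mask, ratio = 0.95) {
  stopifnot(ratio > 0, ratio <= 1)
  ct <- outermost_contour(mask)
  hull_pts <- ct$points[chull(ct$points[, 2L], ct$points[, 1L]), ,
                        drop = FALSE]
  hull_mask <- .fill_window(.densify_chain(hull_pts))$mask
  r <- ct$area_px / sum(hull_mask)
  list(is_valid = r > ratio, contour = ct, area_ratio = r)
}

#' Repair a broken slice outline
#'
#' Dilates the substance mask with a 3 x 3 element until its outermost
#' contour passes [validate_epidermis()], then erodes the filled contour
#' region the same number of times. Valid masks are returned unchanged.
#'
#' @param mask binary substance mask.
#' @param ratio validity threshold, as in [validate_epidermis()].
#' @param max_iter dilation budget.
#' @return list with `contour1` (a valid [contour_shape()]) and
#'   `repaired_mask` (the substance mask with the repaired boundary ring
#'   added).
#' @export
repair_boundary <- function(mask, ratio = 0.95, max_iter = 50L) {
  v <- validate_epidermis(mask, ratio)
  if (v$is_valid)
    return(list(contour1 = v$contour, repaired_mask = .as_binary(mask),
                iterations = 0L))
  dil <- .as_binary(mask)
  for (k in seq_len(max_iter)) {
    dil <- .dilate(dil, .box3)
    v <- validate_epidermis(dil, ratio)
    if (!v$is_valid) next
    region <- contour_mask(v$contour, dim(dil))
    for (i in seq_len(k)) region <- .erode(region, .box3)
    if (!any(region)) next
    ct <- tryCatch(outermost_contour(region), error = function(e) NULL)
    if (is.null(ct)) next
    vv <- validate_epidermis(region, ratio)
    if (!vv$is_valid) next
    ring <- region & !.erode(region, .box3)
    return(list(contour1 = vv$contour,
                repaired_mask = .as_binary(mask) | ring,
                iterations = k))
  }
  stop("unrepairable boundary: validity not reached within max_iter dilations")
}

#' Periphery/inner interface contour
#'
#' The inner zone is the largest connected non-substance region strictly
#' inside the slice outline (4-connectivity, the dual of the 8-connected
#' substance); its holes - the isolated inner bundles - are filled before
#' the boundary is traced.
#'
#' @param substance binary substance mask (boundary already repaired).
#' @param contour1 the slice outline from [repair_boundary()].
#' @return a [contour_shape()] (contour2).
#' @export
inner_boundary <- function(substance, contour1) {
  region1 <- contour_mask(contour1, dim(substance))
  cav <- region1 & !.as_binary(substance)
  lab <- label_components(cav, 4L)
  if (max(lab) == 0L) stop("no inner zone: the slice interior is solid")
  # drop cavities that touch the slice exterior (leaks through the outline)
  outside <- .dilate(!region1, .box3)
  bad <- unique(lab[outside & lab > 0L])
  sizes <- tabulate(lab[lab > 0L], nbins = max(lab))
  sizes[bad] <- 0L
  if (all(sizes == 0L)) stop("no inner zone: all cavities touch the boundary")
  keep <- which.max(sizes)
  comp <- lab == keep
  .label_contours(matrix(as.integer(.fill_holes(comp)), nrow(comp)))[[1L]]
}

#' Local adaptive mean segmentation
#'
#' A pixel is foreground iff its grey value strictly exceeds the mean of the
#' in-ROI pixels within the `block` x `block` window centred on it (zero
#' offset, ties to background). The zone of interest is segmented as an
#' extracted image: pixels outside `roi` contribute neither to the means nor
#' to the output. Invariant under adding a constant to the image.
#'
#' @param img a [slice_image()].
#' @param roi logical matrix, non-empty region of interest.
#' @param block odd window side, >= 3.
#' @return logical foreground mask inside `roi`.
#' @export
adaptive_mean_segment <- function(img, roi, block = 31L) {
  stopifnot(inherits(img, "slice_image"), block >= 3L, block %% 2L == 1L)
  roi <- .as_binary(roi)
  if (!any(roi)) stop("roi is empty")
  k <- (block - 1L) %/% 2L
  v <- matrix(as.numeric(img$pixels), nrow(roi))
  cnt <- .box_sum(roi * 1, k)
  s <- .box_sum(v * roi, k)
  mu <- s / pmax(cnt, 1)
  roi & (v > mu)
}

#' Close the periphery cavities
#'
#' Input is the reversed adaptive segmentation restricted to the slice: only
#' the inner zone and the cavity regions of the periphery are foreground.
#' Morphological closing with a disc of diameter `se_size` bridges the
#' cavities across the vascular bundles.
#'
#' @param mask binary cavity mask.
#' @param se_size disc diameter in px (rounded up to odd).
#' @return logical matrix.
#' @export
close_cavities <- function(mask, se_size = 15L) {
  stopifnot(se_size >= 1L)
  .closing(mask, .disc_brush(se_size))
}

#' Detect the three function zones of a stem cross-section
#'
#' Orchestrates the full zone pipeline: substance thresholding, boundary
#' validation/repair (contour1), inner-zone extraction (contour2), adaptive
#' mean segmentation of the extracted periphery+epidermis zone, cavity
#' reversal and closing, and the inner epidermis boundary (contour3). The
#' three masks partition the filled slice region exactly.
#'
#' @param img a [slice_image()].
#' @param params a [zone_params()].
#' @return an object of class `function_zones`: contours `contour1`,
#'   `contour2`, `contour3`; masks `epidermis_mask`, `periphery_mask`,
#'   `inner_mask`; `stem_center` (0-based `(row, col)` centroid of the slice
#'   region); plus `substance_mask` and `periphery_seg` (the adaptive
#'   segmentation, reused by bundle detection).
#' @export
detect_function_zones <- function(img, params = zone_params()) {
  stopifnot(inherits(img, "slice_image"), inherits(params, "zone_params"))
  sub <- threshold_substance(img, params$threshold)
  if (!any(sub)) stop("no object: blank image")
  rep <- repair_boundary(sub, params$area_ratio, params$repair_max_iter)
  c1 <- rep$contour1
  region1 <- contour_mask(c1, dim(sub))
  c2 <- inner_boundary(rep$repaired_mask, c1)
  region2 <- contour_mask(c2, dim(sub))
  roi <- region1 & !region2
  seg5 <- adaptive_mean_segment(img, roi, params$block)
  cav <- region1 & !seg5                  # inner zone + periphery cavities
  if (params$min_cavity > 1L) {           # drop noise specks posing as cavities
    clab <- label_components(cav, 4L)
    if (max(clab) > 1L) {
      sizes <- tabulate(clab[clab > 0L], nbins = max(clab))
      cav <- cav & matrix(sizes[pmax(clab, 1L)] >= params$min_cavity &
                            clab > 0L, nrow(cav))
    }
  }
  closed <- close_cavities(cav, params$close_size)
  c3 <- outermost_contour(closed)
  region3 <- contour_mask(c3, dim(sub)) & region1
  region2 <- region2 & region3
  zones <- structure(list(
    contour1 = c1, contour2 = c2, contour3 = c3,
    epidermis_mask = region1 & !region3,
    periphery_mask = region3 & !region2,
    inner_mask = region2,
    stem_center = c1$centroid,
    dim = dim(sub),
    pixel_size_mm = img$pixel_size_mm,
    substance_mask = .as_binary(rep$repaired_mask),
    periphery_seg = seg5,
    params = params), class = "function_zones")
  zones
}

#' @export
print.function_zones <- function(x, ...) {
  cat(sprintf(paste0("<function_zones> %d x %d px; areas (px):",
                     " epidermis %d, periphery %d, inner %d\n"),
              x$dim[1L], x$dim[2L], sum(x$epidermis_mask),
              sum(x$periphery_mask), sum(x$inner_mask)))
  invisible(x)
}
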