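# Zone-adaptive detection of vascular bundles. The inner zone holds sparse,
# large, isolated bundles on a near-zero pith background: a fixed threshold
# of 1 collects redundant candidates and a region-based active contour
# refines each boundary. The periphery holds small bundles densely embedded
# in bright lignified matrix: the adaptive-mean segmentation supplies
# candidates, and candidates deviating from the distance-size curve are
# split by maximum-inscribed-circle decomposition.

#' Parameters of vascular-bundle detection
#'
#' @param min_size minimum candidate size in px; smaller components are
#'   discarded as noise.
#' @param ls_iters iterations of the active-contour refinement.
#' @param ls_smoothing curvature-smoothing passes per iteration.
#' @param min_circle_radius stop radius (px) of the inscribed-circle
#'   decomposition; bundles have inscribed radii above it.
#' @param min_core_radius candidate verification: a candidate whose maximum
#'   inscribed circle is smaller than this radius (px) has no solid core
#'   and is rejected as noise. Default: half of `min_circle_radius` (ragged
#'   noise clusters pass an area floor but almost never contain a solid
#'   core; the smallest true bundles do).
#' @param flag_k residual multiplier: a periphery candidate is treated as
#'   merged when its area exceeds the distance-model prediction by more
#'   than `flag_k` robust standard deviations.
#' @return a named list of class `detect_params`.
#' @export
detect_params <- function(min_size = 5L, ls_iters = 50L, ls_smoothing = 1L,
                          min_circle_radius = 3,
                          min_core_radius = min_circle_radius / 2,
                          flag_k = 3) {
  stopifnot(min_size >= 1L, ls_iters >= 1L, ls_smoothing >= 0L,
            min_circle_radius >= 1, min_core_radius >= 0, flag_k > 0)
  structure(list(min_size = as.integer(min_size),
                 ls_iters = as.integer(ls_iters),
                 ls_smoothing = as.integer(ls_smoothing),
                 min_circle_radius = min_circle_radius,
                 min_core_radius = min_core_radius, flag_k = flag_k),
            class = "detect_params")
}

.make_candidate <- function(contour, zone, zones) {
  px <- zones$pixel_size_mm
  dc <- sqrt(sum((contour$centroid - zones$stem_center)^2)) * px
  list(contour = contour, zone = zone,
       hull = contour$points[chull(contour$points[, 2L],
                                   contour$points[, 1L]), , drop = FALSE],
       dc_mm = dc, area_mm2 = contour$area_px * px^2,
       merged_flag = FALSE)
}

.mask_candidates <- function(mask, zone, zones, min_size, min_core = 0) {
  lab <- label_components(mask, 8L)
  if (max(lab) == 0L) return(list())
  sizes <- tabulate(lab[lab > 0L], nbins = max(lab))
  keep <- which(sizes >= min_size)
  if (!length(keep)) return(list())
  lab[!(lab %in% keep)] <- 0L
  lab[lab > 0L] <- match(lab[lab > 0L], keep)
  cands <- lapply(.label_contours(lab, drop_degenerate = TRUE),
                  .make_candidate, zone = zone, zones = zones)
  if (min_core > 0) {
    keep <- vapply(cands, function(cd) {
      w <- .fill_window(cd$contour$points)
      if (max(.distmap(w$mask)) >= min_core) return(TRUE)
      # candidates truncated by the epidermis boundary are rind-fused
      # bundles, not speckle: an object brighter than a rind-dominated
      # neighbourhood is a strong detection even when its periphery-side
      # fragment is thin
      rr <- (w$r0):(w$r0 + nrow(w$mask) + 1L)
      cc <- (w$c0):(w$c0 + ncol(w$mask) + 1L)
      rr <- rr[rr >= 1L & rr <= nrow(zones$epidermis_mask)]
      cc <- cc[cc >= 1L & cc <= ncol(zones$epidermis_mask)]
      any(zones$epidermis_mask[rr, cc])
    }, TRUE)
    cands <- cands[keep]
  }
  cands
}

#' Vascular-bundle candidates of the inner zone
#'
#' Fixed threshold (grey >= 1) inside the inner-zone mask; each 8-connected
#' component at least `min_size` px large is one candidate.
#'
#' @param img a [slice_image()].
#' @param zones a [detect_function_zones()] result.
#' @param min_size noise floor in px.
#' @param min_core solid-core verification radius in px (0 disables).
#' @return list of candidates (contour, zone, hull, `dc_mm`, `area_mm2`).
#' @export
inner_candidates <- function(img, zones, min_size = 5L, min_core = 1.5) {
  stopifnot(inherits(img, "slice_image"), inherits(zones, "function_zones"))
  .mask_candidates(img$pixels >= 1L & zones$inner_mask, "inner", zones,
                   min_size, min_core)
}

#' Vascular-bundle candidates of the periphery zone
#'
#' Components of the adaptive-mean segmentation restricted to the periphery
#' mask (which excludes the epidermis ring), with the same noise floor.
#'
#' @param seg the Step-5 segmentation (`zones$periphery_seg` or a
#'   compatible binary mask).
#' @param zones a [detect_function_zones()] result.
#' @param min_size noise floor in px.
#' @param min_core solid-core verification radius in px (0 disables).
#' @return list of candidates.
#' @export
periphery_candidates <- function(seg, zones, min_size = 5L, min_core = 1.5) {
  stopifnot(inherits(zones, "function_zones"))
  .mask_candidates(.as_binary(seg) & zones$periphery_mask, "periphery",
                   zones, min_size, min_core)
}

#' Refine a candidate boundary with a region-based active contour
#'
#' Two-phase piecewise-constant (Chan-Vese-type) evolution: each iteration
#' reassigns pixels to the phase whose mean intensity is closer, then
#' applies morphological curvature smoothing (3 x 3 majority). The contour
#' is evolved inside a window of twice the initial bounding box and the
#' component best overlapping the initialization is returned.
#'
#' @param img a [slice_image()].
#' @param init initial [contour_shape()] enclosing at least one foreground
#'   pixel.
#' @param iters number of iterations.
#' @param smoothing smoothing passes per iteration.
#' @return a refined [contour_shape()]. If the contour vanishes, `init` is
#'   returned unchanged with a warning; a result outside `[0.2, 5]` times
#'   the initial area is an error.
#' @export
level_set_refine <- function(img, init, iters = 50L, smoothing = 1L) {
  stopifnot(inherits(img, "slice_image"), inherits(init, "contour_shape"))
  dm <- dim(img$pixels)
  p <- init$points
  r1 <- min(p[, 1L]); r2 <- max(p[, 1L])
  c1 <- min(p[, 2L]); c2 <- max(p[, 2L])
  hr <- max(1L, ceiling((r2 - r1 + 1L) / 2)); hc <- max(1L, ceiling((c2 - c1 + 1L) / 2))
  wr <- max(1L, r1 + 1L - hr):min(dm[1L], r2 + 1L + hr)   # 1-based rows
  wc <- max(1L, c1 + 1L - hc):min(dm[2L], c2 + 1L + hc)
  I <- matrix(as.numeric(img$pixels[wr, wc]), length(wr), length(wc))
  u <- matrix(FALSE, length(wr), length(wc))
  w0 <- .fill_window(p)
  rr <- (w0$r0 + 1L):(w0$r0 + nrow(w0$mask)) - wr[1L] + 1L
  cc <- (w0$c0 + 1L):(w0$c0 + ncol(w0$mask)) - wc[1L] + 1L
  u[rr, cc] <- w0$mask
  u0 <- u
  for (it in seq_len(iters)) {
    n_in <- sum(u)
    if (n_in == 0L || n_in == length(u)) break
    c_in <- mean(I[u]); c_out <- mean(I[!u])
    u <- (I - c_in)^2 < (I - c_out)^2
    for (s in seq_len(smoothing)) u <- .box_sum(u * 1, 1L) >= 5
  }
  if (!any(u)) {
    warning("active contour vanished; returning the initial contour")
    return(init)
  }
  lab <- label_components(u, 8L)
  ov <- tabulate(lab[u0 & lab > 0L], nbins = max(lab))
  keep <- if (length(ov) && max(ov) > 0L) which.max(ov) else {
    sizes <- tabulate(lab[lab > 0L], nbins = max(lab))
    which.max(sizes)
  }
  comp <- .fill_holes(lab == keep)
  ratio <- sum(comp) / init$area_px
  if (ratio < 0.2 || ratio > 5)
    stop(sprintf("active contour area guard violated (ratio %.2f)", ratio))
  ct <- .label_contours(matrix(as.integer(comp), nrow(comp)))[[1L]]
  contour_shape(ct$points + rep(c(wr[1L] - 1L, wc[1L] - 1L), each = nrow(ct$points)),
                area_px = ct$area_px,
                centroid = ct$centroid + c(wr[1L] - 1L, wc[1L] - 1L))
}

#' Greedy maximum-inscribed-circle decomposition of a blob
#'
#' Repeatedly takes the maximum of the Euclidean distance transform of the
#' remaining region as the next inscribed circle (arg-max ties broken by
#' smallest `(row, col)`), deletes the circle's pixels, and stops when the
#' radius falls below `min_radius`.
#'
#' @param region binary mask of one candidate object.
#' @param min_radius stop threshold in px.
#' @return list of circles, each `list(center, radius_px)` with a 0-based
#'   `(row, col)` center, in extraction order (radii non-increasing).
#' @export
inscribed_circle_decomposition <- function(region, min_radius = 3) {
  stopifnot(min_radius >= 1)
  rem <- .as_binary(region)
  nr <- nrow(rem)
  circles <- list()
  while (any(rem)) {
    dmap <- .distmap(rem)
    mx <- max(dmap)
    if (mx < min_radius) break
    idx <- which(dmap == mx)
    rws <- (idx - 1L) %% nr
    cls <- (idx - 1L) %/% nr
    o <- order(rws, cls)[1L]
    ctr <- c(rws[o], cls[o])
    allidx <- which(rem)
    ar <- (allidx - 1L) %% nr
    ac <- (allidx - 1L) %/% nr
    inside <- (ar - ctr[1L])^2 + (ac - ctr[2L])^2 <= mx^2
    rem[allidx[inside]] <- FALSE
    circles[[length(circles) + 1L]] <- list(center = ctr, radius_px = mx)
  }
  circles
}

#' Split a candidate region along its inscribed-circle groups
#'
#' Circles whose centers lie within the sum of their radii are merged into
#' seed groups (transitively); every region pixel is then assigned to the
#' nearest group by geodesic distance within the region, seeded from the
#' groups' circle interiors. One group returns the candidate whole.
#'
#' @param region binary mask of the candidate.
#' @param circles result of [inscribed_circle_decomposition()].
#' @return list of [contour_shape()] in the coordinates of `region`; an
#'   attribute `split` says whether splitting happened.
#' @export
split_candidate <- function(region, circles) {
  region <- .as_binary(region)
  whole <- function(split) {
    out <- .label_contours(matrix(as.integer(region), nrow(region)))
    attr(out, "split") <- split
    out
  }
  if (length(circles) == 0L) return(whole(FALSE))
  n <- length(circles)
  ctrs <- do.call(rbind, lapply(circles, `[[`, "center"))
  rads <- vapply(circles, `[[`, 0, "radius_px")
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (n > 1L) {
    pr <- utils::combn(n, 2L)
    d <- sqrt(colSums((t(ctrs[pr[1L, ], , drop = FALSE]) -
                         t(ctrs[pr[2L, ], , drop = FALSE]))^2))
    link <- d < rads[pr[1L, ]] + rads[pr[2L, ]]
    if (any(link))
      g <- igraph::add_edges(g, as.vector(pr[, link, drop = FALSE]))
  }
  grp <- igraph::components(g)$membership
  if (max(grp) == 1L) return(whole(FALSE))
  nr <- nrow(region)
  seeds <- matrix(0L, nr, ncol(region))
  idx <- which(region)
  ar <- (idx - 1L) %% nr
  ac <- (idx - 1L) %/% nr
  for (i in seq_len(n)) {
    rad <- max(0.5, rads[i] - 0.5)
    inside <- (ar - ctrs[i, 1L])^2 + (ac - ctrs[i, 2L])^2 <= rad^2
    seeds[idx[inside]] <- grp[i]
  }
  if (length(unique(seeds[seeds > 0L])) < 2L) return(whole(FALSE))
  lab <- EBImage::propagate(matrix(0, nr, ncol(region)), seeds,
                            mask = region, lambda = 1e8)
  lab <- matrix(as.integer(lab), nr, ncol(region))
  lab[!region] <- 0L
  # geodesically unreachable pixels (none for connected candidates) stay
  # with the largest group so pixels are conserved
  orphan <- region & lab == 0L
  if (any(orphan)) {
    major <- which.max(tabulate(lab[lab > 0L]))
    lab[orphan] <- major
  }
  out <- .label_contours(lab)
  attr(out, "split") <- TRUE
  out
}

#' Flag candidates that likely contain several merged bundles
#'
#' A candidate is flagged when its area exceeds the distance-model
#' prediction at its distance from the stem center by more than
#' `k` robust standard deviations of the fit residuals.
#'
#' @param cands list of candidates.
#' @param model a fitted [fit_distance_model()] for the area trait
#'   (or `NULL`: all candidates stay unflagged, with a warning).
#' @param k residual multiplier.
#' @return `cands` with the `merged_flag` field set.
#' @export
flag_merged_candidates <- function(cands, model, k = 3) {
  if (is.null(model) || !inherits(model, "distance_model")) {
    warning("no fitted distance model; candidates left unflagged")
    return(cands)
  }
  sig <- model$residual_sigma
  lapply(cands, function(cd) {
    pred <- predict(model, cd$dc_mm)
    cd$merged_flag <- is.finite(sig) && sig > 0 &&
      (cd$area_mm2 - pred) > k * sig
    cd
  })
}

#' Detect all vascular bundles of a slice
#'
#' Inner track: fixed-threshold candidates refined per candidate by
#' [level_set_refine()]. Periphery track: adaptive-segmentation candidates,
#' an exponential area-distance model fitted to all candidates of the
#' slice, deviating candidates split by [inscribed_circle_decomposition()]
#' and [split_candidate()]. Per-candidate failures degrade to the
#' unrefined/unsplit candidate instead of aborting the slice.
#'
#' @param img a [slice_image()].
#' @param zones a [detect_function_zones()] result.
#' @param params a [detect_params()].
#' @return an object of class `vb_detection`: `bundles` (list with fields
#'   `contour`, `zone`, `merged_flag`, `dc_mm`, `area_mm2`), counts
#'   `n_total`, `n_inner`, `n_periphery`, and the fitted `model`.
#' @export
detect_vascular_bundles <- function(img, zones, params = detect_params()) {
  stopifnot(inherits(img, "slice_image"), inherits(zones, "function_zones"),
            inherits(params, "detect_params"))
  px <- zones$pixel_size_mm
  ic <- inner_candidates(img, zones, params$min_size, params$min_core_radius)
  inner_b <- lapply(ic, function(cd) {
    ref <- tryCatch(
      suppressWarnings(level_set_refine(img, cd$contour, params$ls_iters,
                                        params$ls_smoothing)),
      error = function(e) cd$contour)
    dc <- sqrt(sum((ref$centroid - zones$stem_center)^2)) * px
    list(contour = ref, zone = "inner", merged_flag = FALSE,
         dc_mm = dc, area_mm2 = ref$area_px * px^2)
  })
  pc <- periphery_candidates(zones$periphery_seg, zones, params$min_size,
                             params$min_core_radius)
  samples <- data.frame(
    dc = c(vapply(inner_b, `[[`, 0, "dc_mm"), vapply(pc, `[[`, 0, "dc_mm")),
    value = c(vapply(inner_b, `[[`, 0, "area_mm2"),
              vapply(pc, `[[`, 0, "area_mm2")))
  model <- tryCatch(fit_distance_model(samples, "area"),
                    error = function(e) NULL)
  pc <- if (is.null(model)) {
    suppressWarnings(flag_merged_candidates(pc, NULL, params$flag_k))
  } else {
    flag_merged_candidates(pc, model, params$flag_k)
  }
  peri_b <- list()
  for (cd in pc) {
    if (!isTRUE(cd$merged_flag)) {
      peri_b[[length(peri_b) + 1L]] <-
        list(contour = cd$contour, zone = "periphery", merged_flag = FALSE,
             dc_mm = cd$dc_mm, area_mm2 = cd$area_mm2)
      next
    }
    w <- .fill_window(cd$contour$points)
    parts <- tryCatch({
      circles <- inscribed_circle_decomposition(w$mask,
                                                params$min_circle_radius)
      split_candidate(w$mask, circles)
    }, error = function(e) NULL)
    if (is.null(parts)) {
      parts <- list(cd$contour)
      attr(parts, "split") <- FALSE
      w$r0 <- 0L; w$c0 <- 0L
    }
    was_split <- isTRUE(attr(parts, "split"))
    for (pt in parts) {
      off <- c(w$r0, w$c0)
      ctr <- contour_shape(pt$points + rep(off, each = nrow(pt$points)),
                           area_px = pt$area_px,
                           centroid = pt$centroid + off)
      dc <- sqrt(sum((ctr$centroid - zones$stem_center)^2)) * px
      peri_b[[length(peri_b) + 1L]] <-
        list(contour = ctr, zone = "periphery", merged_flag = was_split,
             dc_mm = dc, area_mm2 = ctr$area_px * px^2)
    }
  }
  bundles <- c(inner_b, peri_b)
  structure(list(bundles = bundles, n_total = length(bundles),
                 n_inner = length(inner_b), n_periphery = length(peri_b),
                 model = model, params = params),
            class = "vb_detection")
}

#' @export
print.vb_detection <- function(x, ...) {
  cat(sprintf("<vb_detection> %d bundles (%d inner, %d periphery)\n",
              x$n_total, x$n_inner, x$n_periphery))
  invisible(x)
}
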