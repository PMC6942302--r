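# Trait catalogue. Abbreviations follow the field's convention:
#  AI average intensity; W/H bounding-box width/height; MAL/MAW main axis
#  length/width (minimum-area rotated rectangle); CR circumcircle radius;
#  ICR inscribed circle radius; A area; P perimeter; CHA convex hull area;
#  RA rectangularity; AR aspect ratio; CIR circularity; ECC eccentricity;
#  SPH sphericity; CV convexity; DC distance to stem center.

#' Full trait record of one contour
#'
#' Nine dimensional traits (mm or mm^2), six dimensionless shape traits and
#' the average intensity and stem-center distance:
#' \deqn{RA = A/(MAL \cdot MAW),\; AR = MAW/MAL,\; CIR = 4\pi A/P^2,}
#' \deqn{ECC = \sqrt{MAL^2 - MAW^2}/MAL,\; SPH = ICR/CR,\; CV = A/CHA.}
#' Dimensional measures treat a pixel as a unit square: `A` and `CHA` count
#' pixel area, `MAL`/`MAW`/`CR` are measured over the boundary pixels'
#' corner points, `ICR` is the distance-transform maximum, and `P` is the
#' bias-corrected chain length of the boundary.
#'
#' @param contour a [contour_shape()].
#' @param img a [slice_image()] (for the intensity trait).
#' @param stem_center 0-based `(row, col)` of the stem center.
#' @return one-row `data.frame` with columns
#'   `AI, W, H, MAL, MAW, CR, ICR, A, P, CHA, RA, AR, CIR, ECC, SPH, CV, DC`.
#' @export
contour_traits <- function(contour, img, stem_center) {
  stopifnot(inherits(contour, "contour_shape"), inherits(img, "slice_image"))
  px <- img$pixel_size_mm
  pts <- contour$points
  if (nrow(unique(pts)) < 3L) stop("degenerate contour")
  corners <- .corner_hull(pts)
  rect <- .min_area_rect(corners)
  if (rect[2L] <= 0) stop("degenerate (collinear) contour")
  mec <- .min_enclosing_circle(corners)
  w <- .fill_window(pts)
  icr_px <- max(.distmap(w$mask))
  vals <- img$pixels[w$r0 + 1L:nrow(w$mask), w$c0 + 1L:ncol(w$mask),
                     drop = FALSE][w$mask]
  vals <- vals[vals > 0L]
  A <- contour$area_px * px^2
  P <- .perimeter_px(pts) * px
  MAL <- rect[1L] * px; MAW <- rect[2L] * px
  CR <- mec$radius * px; ICR <- icr_px * px
  CHA <- .poly_area(corners) * px^2
  data.frame(
    AI = if (length(vals)) mean(vals) else 0,
    W = (max(pts[, 2L]) - min(pts[, 2L]) + 1L) * px,
    H = (max(pts[, 1L]) - min(pts[, 1L]) + 1L) * px,
    MAL = MAL, MAW = MAW, CR = CR, ICR = ICR, A = A, P = P, CHA = CHA,
    RA = A / (MAL * MAW), AR = MAW / MAL, CIR = 4 * pi * A / P^2,
    ECC = sqrt(max(MAL^2 - MAW^2, 0)) / MAL, SPH = ICR / CR, CV = A / CHA,
    DC = sqrt(sum((contour$centroid - stem_center)^2)) * px)
}

#' Grey-level histogram of a zone
#'
#' Counts of grey values 1..255 inside the mask; background (grey 0), which
#' dominates any zone, is excluded.
#'
#' @param img a [slice_image()].
#' @param mask logical matrix, non-empty.
#' @return integer vector of length 255 (bin i = count of grey value i).
#' @export
zone_histogram <- function(img, mask) {
  stopifnot(inherits(img, "slice_image"))
  mask <- .as_binary(mask)
  if (!any(mask)) stop("mask is empty")
  tabulate(img$pixels[mask], nbins = 255L)
}

#' Fit the exponential distance-size model
#'
#' Dimensional bundle traits decay with distance from the stem center as
#' \eqn{y = a - b e^{c x}}. Fitted by nonlinear least squares with the
#' deterministic initialization `a0 = max(y)`,
#' `b0 = max(a0 - min(y), 1e-6)` and `c0` from a log-linear fit of
#' `a0 - y`; the residual scale is `1.4826 * MAD`.
#'
#' @param samples `data.frame` with columns `dc` (mm) and `value`, at least
#'   10 rows spanning at least 3 mm of distance.
#' @param trait trait name tag (`"perimeter"`, `"radius"`, `"area"`, ...).
#' @return an object of class `distance_model` with fields `a`, `b`, `c`,
#'   `residual_sigma`, `trait`, `n`.
#' @export
fit_distance_model <- function(samples, trait = "area") {
  stopifnot(is.data.frame(samples), all(c("dc", "value") %in% names(samples)))
  samples <- samples[is.finite(samples$dc) & is.finite(samples$value), ]
  x <- samples$dc; y <- samples$value
  if (length(x) < 10L) stop("need at least 10 samples")
  if (diff(range(x)) < 3) stop("samples must span at least 3 mm of distance")
  if (sd(y) == 0) {           # degenerate flat response
    return(structure(list(a = mean(y), b = 0, c = 0, residual_sigma = 0,
                          trait = trait, n = length(x)),
                     class = "distance_model"))
  }
  a0 <- max(y)
  b0 <- max(a0 - min(y), 1e-6)
  dy <- a0 - y
  pos <- dy > 0
  c0 <- if (sum(pos) >= 2L && sd(x[pos]) > 0) {
    cf <- unname(coef(lm(log(dy[pos]) ~ x[pos]))[2L])
    if (is.finite(cf)) cf else 0.1
  } else 0.1
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a - b * exp(cc * x),
                      start = list(a = a0, b = b0, cc = c0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop(sprintf(
        "distance-model fit failed (init a=%.4g b=%.4g c=%.4g): %s",
        a0, b0, c0, conditionMessage(e))))
  cf <- coef(fit)
  res <- y - (cf[["a"]] - cf[["b"]] * exp(cf[["cc"]] * x))
  structure(list(a = cf[["a"]], b = cf[["b"]], c = cf[["cc"]],
                 residual_sigma = mad(res, center = median(res)),
                 trait = trait, n = length(x)),
            class = "distance_model")
}

#' @export
predict.distance_model <- function(object, newdata, ...) {
  x <- if (is.data.frame(newdata)) newdata$dc else newdata
  object$a - object$b * exp(object$c * x)
}

#' @export
print.distance_model <- function(x, ...) {
  cat(sprintf("<distance_model> %s: y = %.4g - %.4g * exp(%.4g x)  (n=%d, sigma=%.4g)\n",
              x$trait, x$a, x$b, x$c, x$n, x$residual_sigma))
  invisible(x)
}

#' Concentric layer partition of the stem interior
#'
#' The region inside the inner epidermis boundary (contour3) is divided
#' into `n` concentric layers by scaling contour3 about the stem center:
#' equal-distance (ED) layers use scale factors `k/n`, equal-area (EA)
#' layers `sqrt(k/n)` (similarity scaling makes EA areas exact up to
#' rasterization). Layer 1 is innermost. When bundles (and an image) are
#' supplied, per-layer traits are computed: layer area AEL, bundle count
#' NVBEL (membership by bundle center), bundle area AVBEL, mean Voronoi
#' growth space VAVBEL, and mean non-zero intensity AI.
#'
#' @param zones a [detect_function_zones()] result (or compatible).
#' @param n number of layers (>= 2).
#' @param mode `"EA"` or `"ED"`.
#' @param bundles optional list of bundles (fields `contour`, `area_mm2`).
#' @param img optional [slice_image()] for per-layer intensity.
#' @return an object of class `layer_scheme`: `ring_contours` (outward),
#'   `label` (integer matrix, 0 outside contour3), and a `layers`
#'   `data.frame` when bundles are given.
#' @export
layer_partition <- function(zones, n = 5L, mode = c("EA", "ED"),
                            bundles = NULL, img = NULL) {
  mode <- match.arg(mode)
  stopifnot(n >= 2L)
  ctr <- zones$stem_center
  region3 <- contour_mask(zones$contour3, zones$dim)
  if (!region3[round(ctr[1L]) + 1L, round(ctr[2L]) + 1L])
    stop("stem center lies outside contour3")
  px <- zones$pixel_size_mm
  s_of <- function(k) if (mode == "EA") sqrt(k / n) else k / n
  rings <- vector("list", n)
  label <- matrix(0L, zones$dim[1L], zones$dim[2L])
  prev <- matrix(FALSE, zones$dim[1L], zones$dim[2L])
  for (k in seq_len(n)) {
    if (k == n) {
      reg <- region3
      rings[[k]] <- zones$contour3
    } else {
      s <- s_of(k)
      pts <- sweep(zones$contour3$points, 2L, ctr) * s
      pts <- sweep(pts, 2L, ctr, `+`)
      rings[[k]] <- contour_shape(pts, dim = zones$dim)
      reg <- contour_mask(rings[[k]], zones$dim) & region3
    }
    label[reg & !prev] <- k
    prev <- prev | reg
  }
  scheme <- structure(list(mode = mode, n_layers = n, ring_contours = rings,
                           label = label, pixel_size_mm = px),
                      class = "layer_scheme")
  if (!is.null(bundles)) {
    centers <- do.call(rbind, lapply(bundles, function(b) b$contour$centroid))
    areas <- vapply(bundles, `[[`, 0, "area_mm2")
    lay <- .center_layer(centers, label)
    vor <- voronoi_growth_space(centers, zones$contour3, zones$dim, px)
    ai <- rep(NA_real_, n)
    if (!is.null(img)) {
      for (k in seq_len(n)) {
        v <- img$pixels[label == k]
        v <- v[v > 0L]
        ai[k] <- if (length(v)) mean(v) else NA_real_
      }
    }
    scheme$layers <- data.frame(
      layer = seq_len(n),
      AEL = vapply(seq_len(n), function(k) sum(label == k) * px^2, 0),
      NVBEL = vapply(seq_len(n),
                     function(k) as.numeric(sum(lay == k, na.rm = TRUE)), 0),
      AVBEL = vapply(seq_len(n), function(k) {
        a <- areas[!is.na(lay) & lay == k]
        if (length(a)) mean(a) else NA_real_
      }, 0),
      VAVBEL = vapply(seq_len(n), function(k) {
        a <- vor$areas_mm2[!is.na(lay) & lay == k]
        if (length(a)) mean(a) else NA_real_
      }, 0),
      AI = ai)
    scheme$bundle_layer <- lay
    scheme$voronoi <- vor
  }
  scheme
}

# layer index of each (row, col) 0-based center; NA outside all layers
.center_layer <- function(centers, label) {
  if (is.null(centers) || nrow(centers) == 0L) return(integer(0))
  r <- pmin(pmax(round(centers[, 1L]) + 1L, 1L), nrow(label))
  cc <- pmin(pmax(round(centers[, 2L]) + 1L, 1L), ncol(label))
  l <- label[cbind(r, cc)]
  ifelse(l == 0L, NA_integer_, l)
}

#' Voronoi growth space of vascular bundles
#'
#' The exclusive growth space of a bundle is the area of its Voronoi cell,
#' clipped to the stem interior (the inner epidermis boundary as the
#' constraint). Cells are computed by Euclidean nearest-center labelling on
#' the pixel raster, so the patches partition the constrained region
#' exactly.
#'
#' @param centers n x 2 matrix of 0-based `(row, col)` bundle centers.
#' @param boundary constraining [contour_shape()].
#' @param dim image dimensions.
#' @param pixel_size_mm physical pixel size.
#' @return list with `areas_mm2` (one per center), `labels` (integer
#'   matrix) and `centers`.
#' @export
voronoi_growth_space <- function(centers, boundary, dim, pixel_size_mm) {
  centers <- as.matrix(centers)
  stopifnot(ncol(centers) == 2L, nrow(centers) >= 1L)
  if (anyDuplicated(paste(centers[, 1L], centers[, 2L]))) {
    warning("duplicate centers perturbed by 1e-6 px")
    dup <- duplicated(paste(centers[, 1L], centers[, 2L]))
    centers[dup, ] <- centers[dup, , drop = FALSE] +
      1e-6 * seq_len(sum(dup))
  }
  mask <- contour_mask(boundary, dim)
  idx <- which(mask)
  rr <- (idx - 1L) %% dim[1L]
  cc <- (idx - 1L) %/% dim[1L]
  inside <- mask[cbind(pmin(pmax(round(centers[, 1L]) + 1L, 1L), dim[1L]),
                       pmin(pmax(round(centers[, 2L]) + 1L, 1L), dim[2L]))]
  if (!any(inside)) stop("no center lies inside the boundary")
  best <- rep.int(Inf, length(idx))
  lab <- integer(length(idx))
  for (i in seq_len(nrow(centers))) {
    d <- (rr - centers[i, 1L])^2 + (cc - centers[i, 2L])^2
    upd <- d < best
    best[upd] <- d[upd]
    lab[upd] <- i
  }
  labels <- matrix(0L, dim[1L], dim[2L])
  labels[idx] <- lab
  list(areas_mm2 = tabulate(lab, nbins = nrow(centers)) * pixel_size_mm^2,
       labels = labels, centers = centers)
}

#' Neighbour graph of the Voronoi patches
#'
#' Two bundles are linked when their clipped Voronoi cells share an edge -
#' the adjacency dual of the growth-space partition (the Delaunay relation
#' restricted to the constrained region).
#'
#' @param vor result of [voronoi_growth_space()].
#' @return two-column matrix of center index pairs.
#' @export
voronoi_neighbours <- function(vor) {
  L <- vor$labels
  pairs <- rbind(
    cbind(as.vector(L[-nrow(L), ]), as.vector(L[-1L, ])),
    cbind(as.vector(L[, -ncol(L)]), as.vector(L[, -1L])))
  pairs <- pairs[pairs[, 1L] > 0L & pairs[, 2L] > 0L &
                   pairs[, 1L] != pairs[, 2L], , drop = FALSE]
  if (!nrow(pairs)) return(matrix(integer(0), 0L, 2L))
  pairs <- cbind(pmin(pairs[, 1L], pairs[, 2L]),
                 pmax(pairs[, 1L], pairs[, 2L]))
  unique(pairs)
}

#' Classify bundle areas by 1-D k-means
#'
#' Deterministic quantile initialization; labels are 0-based and ordered by
#' ascending cluster mean, for pseudo-color rendering of the growth-space
#' patches.
#'
#' @param areas numeric vector of bundle areas (mm^2).
#' @param k number of classes; must not exceed the number of distinct areas.
#' @param seed RNG seed (the initialization is deterministic; the seed
#'   guards the k-means refinement).
#' @return integer vector of labels in `0..k-1`.
#' @export
kmeans_area_classes <- function(areas, k, seed = 1L) {
  stopifnot(is.numeric(areas), length(areas) >= 1L, k >= 1L)
  if (k > length(unique(areas)))
    stop("k exceeds the number of distinct area values")
  if (k == 1L) return(rep.int(0L, length(areas)))
  init <- quantile(unique(areas), probs = (seq_len(k) - 0.5) / k,
                   names = FALSE, type = 7L)
  if (anyDuplicated(init))
    init <- init + seq_along(init) * 1e-9 * max(abs(init), 1)
  km <- .with_seed(seed,
                   kmeans(matrix(areas, ncol = 1L),
                          centers = matrix(init, ncol = 1L), iter.max = 100L))
  ord <- order(km$centers[, 1L])
  match(km$cluster, ord) - 1L
}

#' Growth-related traits of the function zones
#'
#' Zone areas (AEFZ), per-zone bundle counts (NVBPZ/NVBIZ), mean bundle
#' areas (AVBPZ/AVBIZ), mean Voronoi growth spaces (VAVPZ/VAVIZ), slice
#' intensity and substance ratio, epidermis thickness (mean over 360 radial
#' rays of the contour1-contour3 distance), per-zone area ratios of
#' bundles, and the per-zone grey histograms.
#'
#' @param zones a [detect_function_zones()] result.
#' @param vbs a [detect_vascular_bundles()] result or a list of bundles.
#' @param img the [slice_image()].
#' @return an object of class `zone_traits` (a named list).
#' @export
zone_growth_traits <- function(zones, vbs, img) {
  stopifnot(inherits(zones, "function_zones"), inherits(img, "slice_image"))
  bundles <- if (inherits(vbs, "vb_detection")) vbs$bundles else vbs
  px <- zones$pixel_size_mm
  region1 <- contour_mask(zones$contour1, zones$dim)
  aefz <- c(epidermis = sum(zones$epidermis_mask),
            periphery = sum(zones$periphery_mask),
            inner = sum(zones$inner_mask)) * px^2
  zone_of <- vapply(bundles, `[[`, "", "zone")
  areas <- vapply(bundles, `[[`, 0, "area_mm2")
  mean_or_na <- function(v) if (length(v)) mean(v) else NA_real_
  vor_mean <- c(periphery = NA_real_, inner = NA_real_)
  if (length(bundles)) {
    centers <- do.call(rbind, lapply(bundles, function(b) b$contour$centroid))
    vor <- voronoi_growth_space(centers, zones$contour3, zones$dim, px)
    vor_mean <- c(periphery = mean_or_na(vor$areas_mm2[zone_of == "periphery"]),
                  inner = mean_or_na(vor$areas_mm2[zone_of == "inner"]))
  }
  slice_vals <- img$pixels[region1]
  slice_vals <- slice_vals[slice_vals > 0L]
  structure(list(
    AEFZ = aefz,
    NVBPZ = sum(zone_of == "periphery"),
    NVBIZ = sum(zone_of == "inner"),
    AVBPZ = mean_or_na(areas[zone_of == "periphery"]),
    AVBIZ = mean_or_na(areas[zone_of == "inner"]),
    VAVPZ = vor_mean[["periphery"]],
    VAVIZ = vor_mean[["inner"]],
    slice_AI = if (length(slice_vals)) mean(slice_vals) else 0,
    substance_ratio = sum(img$pixels[region1] > 0L) / sum(region1),
    epidermis_thickness_mm = .epidermis_thickness(zones) * px,
    area_ratio = c(
      periphery = sum(areas[zone_of == "periphery"]) / aefz[["periphery"]],
      inner = sum(areas[zone_of == "inner"]) / aefz[["inner"]]),
    histogram = list(
      epidermis = zone_histogram(img, zones$epidermis_mask),
      periphery = zone_histogram(img, zones$periphery_mask),
      inner = zone_histogram(img, zones$inner_mask))),
    class = "zone_traits")
}

# mean radial distance between contour1 and contour3 over 360 one-degree
# angular bins around the stem center, in px
.epidermis_thickness <- function(zones) {
  ctr <- zones$stem_center
  ray_max <- function(pts) {
    d <- sweep(pts, 2L, ctr)
    ang <- (atan2(d[, 2L], d[, 1L]) + pi) / (2 * pi) * 360
    bin <- pmin(floor(ang), 359) + 1L
    r <- sqrt(rowSums(d^2))
    out <- rep(NA_real_, 360L)
    agg <- tapply(r, bin, max)
    out[as.integer(names(agg))] <- agg
    out
  }
  r1 <- ray_max(zones$contour1$points)
  r3 <- ray_max(zones$contour3$points)
  ok <- !is.na(r1) & !is.na(r3)
  mean(r1[ok] - r3[ok])
}

#' Per-bundle trait table
#'
#' One row per bundle: the full [contour_traits()] record plus zone, layer
#' membership and Voronoi growth space.
#'
#' @param vbs a [detect_vascular_bundles()] result or list of bundles.
#' @param zones a [detect_function_zones()] result.
#' @param img the [slice_image()].
#' @param scheme optional [layer_partition()] (computed with `n = 5`,
#'   `mode = "EA"` when missing).
#' @return `data.frame`, one row per bundle.
#' @export
bundle_traits_table <- function(vbs, zones, img, scheme = NULL) {
  bundles <- if (inherits(vbs, "vb_detection")) vbs$bundles else vbs
  if (!length(bundles)) return(data.frame())
  if (is.null(scheme))
    scheme <- layer_partition(zones, 5L, "EA", bundles = bundles, img = img)
  tt <- do.call(rbind, lapply(bundles, function(b)
    contour_traits(b$contour, img, zones$stem_center)))
  tt$zone <- vapply(bundles, `[[`, "", "zone")
  tt$merged <- vapply(bundles, `[[`, TRUE, "merged_flag")
  tt$layer <- scheme$bundle_layer
  tt$voronoi_mm2 <- scheme$voronoi$areas_mm2
  tt$bundle <- seq_len(nrow(tt))
  tt
}
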