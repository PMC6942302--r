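# Contour representation: every detected object (slice boundary, zone
# boundaries, vascular bundles, layer rings) is an ordered closed polygon of
# pixel coordinates, 0-based (row, col), 8-connected along the chain.

#' Closed contour of a detected object
#'
#' @param points n x 2 matrix of 0-based `(row, col)` pixel coordinates
#'   forming a closed polygon (at least 3 points). Consecutive points
#'   further than one pixel apart are densified automatically so the chain
#'   is 8-connected.
#' @param dim image dimensions `c(nrow, ncol)`; required when `area_px` or
#'   `centroid` must be derived by rasterization.
#' @param area_px filled pixel count of the enclosed region; computed from
#'   `dim` when missing.
#' @param centroid 0-based `(row, col)` centroid of the filled region;
#'   computed when missing.
#' @return an object of class `contour_shape` with fields `points`,
#'   `area_px`, `centroid`.
#' @export
contour_shape <- function(points, dim = NULL, area_px = NULL,
                          centroid = NULL) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2L, is.numeric(points))
  if (anyNA(points) || any(!is.finite(points)))
    stop("contour points must be finite")
  pts <- matrix(as.integer(round(points)), nrow(points), 2L)
  pts <- .densify_chain(pts)
  if (nrow(unique(pts)) < 3L)
    stop("a contour needs at least 3 distinct points")
  if (is.null(area_px) || is.null(centroid)) {
    if (is.null(dim))
      stop("dim is required to derive area_px/centroid from points")
    w <- .fill_window(pts)
    n <- sum(w$mask)
    if (is.null(area_px)) area_px <- n
    if (is.null(centroid)) {
      idx <- which(w$mask, arr.ind = TRUE)
      centroid <- c(mean(idx[, 1L]) - 1 + w$r0, mean(idx[, 2L]) - 1 + w$c0)
    }
  }
  if (area_px <= 0) stop("contour encloses no pixels")
  structure(list(points = pts, area_px = as.numeric(area_px),
                 centroid = as.numeric(centroid)),
            class = "contour_shape")
}

#' @export
print.contour_shape <- function(x, ...) {
  cat(sprintf("<contour_shape> %d points, area %g px, centroid (%.1f, %.1f)\n",
              nrow(x$points), x$area_px, x$centroid[1L], x$centroid[2L]))
  invisible(x)
}

# Insert intermediate points so consecutive (and wrap-around) points are
# 8-adjacent; boundary-following output already is, synthetic polygons
# (e.g. scaled layer rings) are not.
.densify_chain <- function(pts) {
  n <- nrow(pts)
  d <- rbind(pts[-1L, , drop = FALSE], pts[1L, , drop = FALSE]) - pts
  step <- pmax(abs(d[, 1L]), abs(d[, 2L]))
  if (all(step <= 1L)) return(pts)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    if (step[i] <= 1L) {
      out[[i]] <- pts[i, , drop = FALSE]
    } else {
      t <- seq(0, 1, length.out = step[i] + 1L)[-(step[i] + 1L)]
      out[[i]] <- cbind(as.integer(round(pts[i, 1L] + t * d[i, 1L])),
                        as.integer(round(pts[i, 2L] + t * d[i, 2L])))
    }
  }
  res <- do.call(rbind, out)
  res[c(TRUE, rowSums(abs(diff(res))) > 0L), , drop = FALSE]
}

# Rasterize a closed 8-connected chain inside its own bounding window.
# Returns list(mask, r0, c0): logical window and 0-based offsets.
.fill_window <- function(pts) {
  r0 <- min(pts[, 1L]); c0 <- min(pts[, 2L])
  nr <- max(pts[, 1L]) - r0 + 1L
  nc <- max(pts[, 2L]) - c0 + 1L
  m <- matrix(FALSE, nr, nc)
  m[cbind(pts[, 1L] - r0 + 1L, pts[, 2L] - c0 + 1L)] <- TRUE
  list(mask = .fill_holes(m), r0 = r0, c0 = c0)
}

#' Rasterize a contour to a full-size binary mask
#'
#' @param contour a [contour_shape()].
#' @param dim image dimensions `c(nrow, ncol)`.
#' @return logical matrix; `TRUE` inside and on the contour.
#' @export
contour_mask <- function(contour, dim) {
  stopifnot(inherits(contour, "contour_shape"), length(dim) == 2L)
  w <- .fill_window(contour$points)
  out <- matrix(FALSE, dim[1L], dim[2L])
  rr <- (w$r0 + 1L):(w$r0 + nrow(w$mask))
  cc <- (w$c0 + 1L):(w$c0 + ncol(w$mask))
  keep_r <- rr >= 1L & rr <= dim[1L]
  keep_c <- cc >= 1L & cc <= dim[2L]
  out[rr[keep_r], cc[keep_c]] <- w$mask[keep_r, keep_c]
  out
}

# Outer contours of each labelled object, holes ignored. Boundary tracing
# follows 4-connected pieces; for an 8-connected object that splits into
# several 4-connected pieces the largest piece carries the contour (only
# noise speckles are affected - tissue objects are compact). With
# `drop_degenerate` objects too small to form a polygon are dropped.
.label_contours <- function(lab, drop_degenerate = FALSE) {
  labs <- sort(unique(lab[lab > 0L]))
  out <- vector("list", length(labs))
  for (i in seq_along(labs)) {
    idx <- which(lab == labs[i], arr.ind = TRUE)
    r0 <- min(idx[, 1L]); c0 <- min(idx[, 2L])
    w <- matrix(0, max(idx[, 1L]) - r0 + 1L, max(idx[, 2L]) - c0 + 1L)
    w[cbind(idx[, 1L] - r0 + 1L, idx[, 2L] - c0 + 1L)] <- 1
    w4 <- label_components(w, 4L)
    if (max(w4) > 1L) {
      big <- which.max(tabulate(w4[w4 > 0L]))
      w <- (w4 == big) * 1
    }
    ch <- EBImage::ocontour(w)[[1L]]
    filled <- .fill_holes(w)
    fidx <- which(filled, arr.ind = TRUE)
    out[[i]] <- tryCatch(
      contour_shape(
        cbind(ch[, 1L] + r0 - 1L, ch[, 2L] + c0 - 1L),
        area_px = sum(filled),
        centroid = c(mean(fidx[, 1L]) + r0 - 2L, mean(fidx[, 2L]) + c0 - 2L)),
      error = function(e) if (drop_degenerate) NULL else stop(e))
  }
  if (drop_degenerate) out[!vapply(out, is.null, TRUE)] else out
}

# ---- contour geometry ------------------------------------------------------

# Chain length in pixels. Raw 8-chain length overestimates smooth boundaries
# by ~5%, so axial/diagonal steps carry the Vossepoel-Smeulders weights
# (0.948 / 1.340); the +pi term shifts the measure from the pixel-centre
# polygon to the pixel-square boundary that pixel-count areas refer to
# (a half-pixel outward offset adds 2*pi*0.5 for convex shapes).
.perimeter_px <- function(pts) {
  if (nrow(pts) < 2L) return(2 * sqrt(pi))     # single pixel: degenerate
  d <- rbind(pts[-1L, , drop = FALSE], pts[1L, , drop = FALSE]) - pts
  step <- abs(d[, 1L]) + abs(d[, 2L])
  0.948 * sum(step == 1L) + 1.340 * sum(step == 2L) + pi
}

# Corner points of the boundary pixels (pixel = unit square centred on its
# coordinate), reduced to their convex hull. Used for MAL/MAW/CR/CHA so
# dimensional traits refer to the same pixel-square geometry as areas.
.corner_hull <- function(pts) {
  h <- pts[chull(pts[, 2L], pts[, 1L]), , drop = FALSE]
  corners <- rbind(
    cbind(h[, 1L] - 0.5, h[, 2L] - 0.5), cbind(h[, 1L] - 0.5, h[, 2L] + 0.5),
    cbind(h[, 1L] + 0.5, h[, 2L] - 0.5), cbind(h[, 1L] + 0.5, h[, 2L] + 0.5))
  corners[chull(corners[, 2L], corners[, 1L]), , drop = FALSE]
}

.poly_area <- function(p) {
  x <- p[, 2L]; y <- p[, 1L]
  abs(sum(x * c(y[-1L], y[1L]) - c(x[-1L], x[1L]) * y)) / 2
}

# Minimum-area enclosing rectangle by rotating calipers over hull edges.
# Returns c(long, short) side lengths.
.min_area_rect <- function(hull) {
  n <- nrow(hull)
  if (n < 2L) return(c(0, 0))
  e <- hull[c(seq_len(n)[-1L], 1L), , drop = FALSE] - hull
  len <- sqrt(rowSums(e^2))
  keep <- len > 0
  if (!any(keep)) return(c(0, 0))
  e <- e[keep, , drop = FALSE] / len[keep]
  best <- c(Inf, 0, 0)
  for (i in seq_len(nrow(e))) {
    u <- e[i, ]; v <- c(-u[2L], u[1L])
    pu <- hull %*% u; pv <- hull %*% v
    w <- max(pu) - min(pu); h <- max(pv) - min(pv)
    if (w * h < best[1L]) best <- c(w * h, w, h)
  }
  c(max(best[2L], best[3L]), min(best[2L], best[3L]))
}

# Minimum enclosing circle (Welzl, move-to-front). Deterministic: the MEC is
# unique, so no shuffling is needed. Returns list(center, radius).
.min_enclosing_circle <- function(P) {
  eps <- 1e-9
  inc <- function(C, p) sum((p - C[[1L]])^2) <= (C[[2L]] + eps)^2
  c2 <- function(a, b) list((a + b) / 2, sqrt(sum((a - b)^2)) / 2)
  c3 <- function(a, b, cc) {
    d <- 2 * (a[1L] * (b[2L] - cc[2L]) + b[1L] * (cc[2L] - a[2L]) +
                cc[1L] * (a[2L] - b[2L]))
    if (abs(d) < 1e-12) {
      cand <- list(c2(a, b), c2(a, cc), c2(b, cc))
      return(cand[[which.max(vapply(cand, function(z) z[[2L]], 0))]])
    }
    ux <- ((sum(a^2)) * (b[2L] - cc[2L]) + (sum(b^2)) * (cc[2L] - a[2L]) +
             (sum(cc^2)) * (a[2L] - b[2L])) / d
    uy <- ((sum(a^2)) * (cc[1L] - b[1L]) + (sum(b^2)) * (a[1L] - cc[1L]) +
             (sum(cc^2)) * (b[1L] - a[1L])) / d
    ctr <- c(ux, uy)
    list(ctr, sqrt(sum((a - ctr)^2)))
  }
  n <- nrow(P)
  C <- list(P[1L, ], 0)
  if (n >= 2L) for (i in 2L:n) {
    if (!inc(C, P[i, ])) {
      C <- list(P[i, ], 0)
      for (j in seq_len(i - 1L)) {
        if (!inc(C, P[j, ])) {
          C <- c2(P[i, ], P[j, ])
          if (j >= 2L) for (k in seq_len(j - 1L)) {
            if (!inc(C, P[k, ])) C <- c3(P[i, ], P[j, ], P[k, ])
          }
        }
      }
    }
  }
  list(center = C[[1L]], radius = C[[2L]])
}
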