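# Synthetic cross-section phantom with full ground truth. The phantom
# emulates the structure of a freeze-dried stem section in calibrated
# micro-CT: a bright closed epidermis ring, a periphery annulus of small
# bright elliptical bundles densely embedded in lignified matrix (some
# fused with each other or with the rind), and an inner pith zone of
# sparse, larger, isolated bundles on an air-level background. Bundle
# sizes follow the exponential distance law observed in real sections.

#' Phantom specification
#'
#' Defaults describe a desk-scale section: 0.04 mm pixels, stem radius
#' 10.8 mm (slice ~366 mm^2), inner zone at 84 percent of the radius and a
#' periphery bundle area fraction near 0.35, matching the zone statistics
#' of field-grown maize at tasseling.
#'
#' @param image_size image side in px.
#' @param outer_radius,epidermis_width,inner_radius zone geometry in px
#'   (`inner_radius < outer_radius - epidermis_width`).
#' @param n_periphery,n_inner bundle counts per zone.
#' @param size_law `c(a, b, c)` of the equivalent-radius law
#'   `r(x) = a - b*exp(c*x)` in mm against distance-to-center x in mm.
#' @param law_distance_scale spatial scale `s` of the law: bundle radius is
#'   `s * r(x / s)`, so scaled-down stems carry proportionally smaller
#'   bundles.
#' @param size_jitter_sdlog lognormal jitter of bundle sizes.
#' @param axis_ratio range of the ellipse minor/major axis ratio.
#' @param intensity named list of tissue grey means: `epidermis`,
#'   `periphery_matrix`, `bundle`, `inner_parenchyma`, `background`.
#' @param tissue_sd SD of the per-region/per-bundle mean jitter (grey).
#' @param fusion_fraction fraction of periphery bundles placed in touching
#'   clumps of 2-4 (the merged candidates the splitter must resolve).
#' @param touch_epidermis_fraction fraction of periphery bundles placed
#'   overlapping the epidermis inner edge.
#' @param noise_sd additive Gaussian pixel noise (grey levels). Air sits at
#'   `-2 * noise_sd` before clipping, emulating the saturation of the
#'   calibration floor, so most air pixels stay at grey 0.
#' @param boundary_break arc length (px) of an epidermis gap, 0 for none.
#' @param blur_sigma optional Gaussian point-spread sigma in px (0 = off).
#' @param pixel_size_mm physical pixel size.
#' @param seed RNG seed; the phantom is a pure function of (spec, seed).
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_size = 600L, outer_radius = 270,
                         epidermis_width = 16, inner_radius = 228,
                         n_periphery = 230L, n_inner = 150L,
                         size_law = c(a = 0.249, b = 5.765e-4, c = 0.502),
                         law_distance_scale = 1,
                         size_jitter_sdlog = 0.12,
                         axis_ratio = c(0.65, 1),
                         intensity = list(epidermis = 200,
                                          periphery_matrix = 90,
                                          bundle = 160,
                                          inner_parenchyma = 0,
                                          background = 0),
                         tissue_sd = 10,
                         fusion_fraction = 0,
                         touch_epidermis_fraction = 0.08,
                         noise_sd = 0, boundary_break = 0,
                         blur_sigma = 0, pixel_size_mm = 0.04,
                         seed = 1L) {
  spec <- list(image_size = as.integer(image_size),
               outer_radius = outer_radius,
               epidermis_width = epidermis_width,
               inner_radius = inner_radius,
               n_periphery = as.integer(n_periphery),
               n_inner = as.integer(n_inner),
               size_law = size_law,
               law_distance_scale = law_distance_scale,
               size_jitter_sdlog = size_jitter_sdlog,
               axis_ratio = axis_ratio,
               intensity = intensity, tissue_sd = tissue_sd,
               fusion_fraction = fusion_fraction,
               touch_epidermis_fraction = touch_epidermis_fraction,
               noise_sd = noise_sd, boundary_break = boundary_break,
               blur_sigma = blur_sigma, pixel_size_mm = pixel_size_mm,
               seed = as.integer(seed))
  if (spec$inner_radius >= spec$outer_radius - spec$epidermis_width)
    stop("inner_radius must be below outer_radius - epidermis_width")
  if (spec$outer_radius * 2 + 2 > spec$image_size)
    stop("stem does not fit in image_size")
  mus <- unlist(spec$intensity)
  if (any(mus < 0 | mus > 255)) stop("intensity means must be in [0, 255]")
  if (spec$n_periphery < 0L || spec$n_inner < 0L)
    stop("bundle counts must be non-negative")
  structure(spec, class = "phantom_spec")
}

.law_radius_mm <- function(spec, dc_mm) {
  s <- spec$law_distance_scale
  r <- s * (spec$size_law[[1L]] -
              spec$size_law[[2L]] * exp(spec$size_law[[3L]] * dc_mm / s))
  max(r, 0.05 * s)
}

# jittered bundle equivalent radius in px, floored at the resolvability
# limit of the raster imaging model (~2.2 px)
.draw_r_eq_px <- function(spec, dc_mm, jit) {
  max(.law_radius_mm(spec, dc_mm) * jit / spec$pixel_size_mm, 2.2)
}

# radius of an ellipse (a, b, orientation theta) along direction phi
.dir_radius <- function(a, b, theta, phi) {
  psi <- phi - theta
  a * b / sqrt((b * cos(psi))^2 + (a * sin(psi))^2)
}

# TRUE when the new ellipse keeps at least `gap` px of clearance from every
# placed one, measured along the center-connecting line (directional radii)
.clear_of <- function(placed, pos, a, b, theta, gap) {
  if (!nrow(placed)) return(TRUE)
  dr <- placed[, 1L] - pos[1L]
  dc <- placed[, 2L] - pos[2L]
  dd <- sqrt(dr^2 + dc^2)
  phi <- atan2(dc, dr)
  r_old <- .dir_radius(placed[, 3L], placed[, 4L], placed[, 5L], phi)
  r_new <- .dir_radius(a, b, theta, phi)
  all(dd >= r_old + r_new + gap)
}

# 1-based linear indices of the pixels inside an ellipse (0-based center)
.ellipse_px <- function(n, row, col, a, b, theta) {
  wr <- max(0L, floor(row - a - 1)):min(n - 1L, ceiling(row + a + 1))
  wc <- max(0L, floor(col - a - 1)):min(n - 1L, ceiling(col + a + 1))
  gr <- matrix(rep(wr, length(wc)), length(wr), length(wc))
  gc <- t(matrix(rep(wc, length(wr)), length(wc), length(wr)))
  u <- (gr - row) * cos(theta) + (gc - col) * sin(theta)
  v <- -(gr - row) * sin(theta) + (gc - col) * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  (gc[inside]) * n + gr[inside] + 1L
}

# TRUE when no pixel of the ellipse touches (8-connectivity) an occupied one
.free_px <- function(occ, idx, n) {
  nb <- c(0L, -1L, 1L, -n, n, -n - 1L, -n + 1L, n - 1L, n + 1L)
  probe <- unique(as.vector(outer(idx, nb, `+`)))
  probe <- probe[probe >= 1L & probe <= n * n]
  !any(occ[probe])
}

# sample one bundle position with edge-to-edge spacing against accepted ones
.place_bundle <- function(spec, placed, occ, rmin, rmax, gap, ctr) {
  n <- spec$image_size
  for (att in seq_len(4000L)) {
    d <- sqrt(runif(1L, rmin^2, rmax^2))
    th <- runif(1L, 0, 2 * pi)
    pos <- ctr + d * c(cos(th), sin(th))
    dc_mm <- d * spec$pixel_size_mm
    r_eq <- .draw_r_eq_px(spec, dc_mm,
                          exp(rnorm(1L, 0, spec$size_jitter_sdlog)))
    ratio <- runif(1L, spec$axis_ratio[1L], spec$axis_ratio[2L])
    a <- r_eq / sqrt(ratio); b <- r_eq * sqrt(ratio)
    theta <- runif(1L, 0, pi)
    r_rad <- .dir_radius(a, b, theta, th)   # extent along the radial line
    if (d - r_rad < rmin - 1 || d + r_rad > rmax + 1) next
    if (!.clear_of(placed, pos, a, b, theta, gap)) next
    if (.free_px(occ, .ellipse_px(n, pos[1L], pos[2L], a, b, theta), n))
      return(c(pos, a, b, ratio, theta, r_eq))
  }
  NULL
}

#' Generate a synthetic cross-section phantom
#'
#' @param spec a [phantom_spec()].
#' @return an object of class `phantom_truth`: `image` (a
#'   [slice_image()]), `zones` (ground-truth contours, masks and stem
#'   center, shaped like a [detect_function_zones()] result), `bundles`
#'   (`data.frame` with 0-based centers, `dc_mm`, realized equivalent
#'   radius `r_eq_mm`, `area_px`, `zone`, `clump_id`), and `spec`.
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  .with_seed(spec$seed, .generate_phantom_impl(spec))
}

.generate_phantom_impl <- function(spec) {
  n <- spec$image_size
  ctr <- rep((n - 1) / 2, 2L)                     # 0-based
  rr <- matrix(rep(0:(n - 1L), n), n, n)
  cc <- t(rr)
  D <- sqrt((rr - ctr[1L])^2 + (cc - ctr[2L])^2)
  r_out <- spec$outer_radius
  r_epi <- r_out - spec$epidermis_width
  r_in <- spec$inner_radius
  slice <- D <= r_out
  epi <- D > r_epi & slice
  peri <- D > r_in & D <= r_epi
  inner <- D <= r_in
  floor_v <- -2 * spec$noise_sd
  eps_mean <- rnorm(1L, spec$intensity$epidermis, spec$tissue_sd)
  mat_mean <- rnorm(1L, spec$intensity$periphery_matrix, spec$tissue_sd)
  vals <- matrix(floor_v, n, n)
  vals[epi] <- eps_mean
  vals[peri] <- mat_mean
  if (spec$intensity$inner_parenchyma > 0)
    vals[inner] <- spec$intensity$inner_parenchyma
  break_angle <- runif(1L, 0, 2 * pi)             # drawn even when unused
  if (spec$boundary_break > 0) {
    half <- (spec$boundary_break / 2) / r_out
    ang <- atan2(cc - ctr[2L], rr - ctr[1L])
    dd <- abs(((ang - break_angle + pi) %% (2 * pi)) - pi)
    vals[epi & dd <= half] <- floor_v
  }

  bundles <- list()
  placed <- matrix(0, 0L, 5L)                     # row, col, a, b, theta
  occ <- matrix(FALSE, n, n)                      # occupied bundle pixels
  add <- function(p, zone, clump) {
    placed <<- rbind(placed, c(p[1L], p[2L], p[3L], p[4L], p[6L]))
    occ[.ellipse_px(n, p[1L], p[2L], p[3L], p[4L], p[6L])] <<- TRUE
    bundles[[length(bundles) + 1L]] <<-
      list(row = p[1L], col = p[2L], a = p[3L], b = p[4L],
           theta = p[6L], r_eq = p[7L], zone = zone, clump_id = clump,
           value = rnorm(1L, spec$intensity$bundle, spec$tissue_sd))
  }
  # inner bundles: well separated, clear of the zone boundary
  for (i in seq_len(spec$n_inner)) {
    p <- .place_bundle(spec, placed, occ, 0, r_in - 3, 3, ctr)
    if (is.null(p)) stop("infeasible packing: inner zone too crowded")
    add(p, "inner", 0L)
  }
  # periphery: fused clumps, epidermis touchers, then free singles
  n_per <- spec$n_periphery
  n_fused <- round(spec$fusion_fraction * n_per)
  clump_id <- 0L
  left <- n_fused
  clump_margin <- max(3, 0.15 * (r_epi - r_in))
  while (left >= 2L) {
    m <- min(sample(2:4, 1L), left)
    anchor <- .place_bundle(spec, placed, occ, r_in + clump_margin,
                            r_epi - clump_margin, 3, ctr)
    if (is.null(anchor)) stop("infeasible packing: no room for clump")
    occ_snapshot <- occ                  # members may touch their own clump
    clump_id <- clump_id + 1L
    add(anchor, "periphery", clump_id)
    prev <- anchor
    for (j in seq_len(m - 1L)) {
      ok <- FALSE
      for (att in seq_len(200L)) {
        ratio <- runif(1L, 0.55, 0.7)
        jit <- exp(rnorm(1L, 0, spec$size_jitter_sdlog))
        phi <- runif(1L, 0, 2 * pi)
        dc_mm <- sqrt(sum((prev[1:2] - ctr)^2)) * spec$pixel_size_mm
        # fixed-point pass so the size law is evaluated at the final center
        for (it in 1:3) {
          r_eq <- .draw_r_eq_px(spec, dc_mm, jit)
          a <- r_eq / sqrt(ratio); b <- r_eq * sqrt(ratio)
          d <- 0.85 * (prev[3L] + a)
          pos <- prev[1:2] + d * c(cos(phi), sin(phi))
          dc_mm <- sqrt(sum((pos - ctr)^2)) * spec$pixel_size_mm
        }
        dpos <- sqrt(sum((pos - ctr)^2))
        if (dpos - a < r_in + 2 || dpos + a > r_epi - 2) next
        # orient the major axis along the connection for resolvable lobes
        theta <- atan2(pos[2L] - prev[2L], pos[1L] - prev[1L])
        if (!.free_px(occ_snapshot,
                      .ellipse_px(n, pos[1L], pos[2L], a, b, theta), n)) next
        add(c(pos, a, b, ratio, theta, r_eq), "periphery", clump_id)
        prev <- c(pos, a, b)
        ok <- TRUE
        break
      }
      if (!ok) break
    }
    left <- left - m
  }
  n_placed_per <- sum(vapply(bundles, function(b) b$zone == "periphery", TRUE))
  n_touch <- round(spec$touch_epidermis_fraction * n_per)
  for (i in seq_len(max(0L, min(n_touch, n_per - n_placed_per)))) {
    # touchers sit tangent to the epidermis inner edge (fused with the rind
    # by pixel adjacency, body inside the periphery zone)
    p <- NULL
    for (att in seq_len(2000L)) {
      th <- runif(1L, 0, 2 * pi)
      jit <- exp(rnorm(1L, 0, spec$size_jitter_sdlog))
      ratio <- runif(1L, spec$axis_ratio[1L], spec$axis_ratio[2L])
      theta <- runif(1L, 0, pi)
      d <- r_epi
      for (it in 1:3) {                  # law evaluated at the final center
        r_eq <- .draw_r_eq_px(spec, d * spec$pixel_size_mm, jit)
        a <- r_eq / sqrt(ratio); b <- r_eq * sqrt(ratio)
        d <- r_epi - .dir_radius(a, b, theta, th)
      }
      pos <- ctr + d * c(cos(th), sin(th))
      if (!.clear_of(placed, pos, a, b, theta, 1)) next
      if (.free_px(occ, .ellipse_px(n, pos[1L], pos[2L], a, b, theta), n)) {
        p <- c(pos, a, b, ratio, theta, r_eq)
        break
      }
    }
    if (is.null(p)) stop("infeasible packing: epidermis edge too crowded")
    add(p, "periphery", 0L)
  }
  n_placed_per <- sum(vapply(bundles, function(b) b$zone == "periphery", TRUE))
  for (i in seq_len(max(0L, n_per - n_placed_per))) {
    p <- .place_bundle(spec, placed, occ, r_in + 1, r_epi - 1, 1, ctr)
    if (is.null(p)) stop("infeasible packing: periphery zone too crowded")
    add(p, "periphery", 0L)
  }

  # bundles within the lignification gradient of the rind (ellipse reaching
  # within ~0.5 mm / 12 px of the epidermis inner edge) image brighter,
  # like the hypodermal tissue they are embedded in
  bright_mu <- (spec$intensity$epidermis + spec$intensity$bundle) / 2
  for (i in seq_along(bundles)) {
    b <- bundles[[i]]
    if (b$zone == "periphery" &&
        sqrt((b$row - ctr[1L])^2 + (b$col - ctr[2L])^2) + b$a >= r_epi - 12)
      bundles[[i]]$value <- rnorm(1L, bright_mu, spec$tissue_sd)
  }

  # render bundles (later bundles overwrite earlier at overlaps)
  for (b in bundles) {
    wr <- max(0L, floor(b$row - b$a - 1)):min(n - 1L, ceiling(b$row + b$a + 1))
    wc <- max(0L, floor(b$col - b$a - 1)):min(n - 1L, ceiling(b$col + b$a + 1))
    gr <- matrix(rep(wr, length(wc)), length(wr), length(wc))
    gc <- t(matrix(rep(wc, length(wr)), length(wc), length(wr)))
    dr <- gr - b$row; dc <- gc - b$col
    u <- dr * cos(b$theta) + dc * sin(b$theta)
    v <- -dr * sin(b$theta) + dc * cos(b$theta)
    inside <- (u / b$a)^2 + (v / b$b)^2 <= 1
    sub <- vals[wr + 1L, wc + 1L, drop = FALSE]
    sub[inside] <- b$value
    vals[wr + 1L, wc + 1L] <- sub
  }
  area_px <- vapply(bundles, function(b) {
    wr <- max(0L, floor(b$row - b$a - 1)):min(n - 1L, ceiling(b$row + b$a + 1))
    wc <- max(0L, floor(b$col - b$a - 1)):min(n - 1L, ceiling(b$col + b$a + 1))
    gr <- matrix(rep(wr, length(wc)), length(wr), length(wc))
    gc <- t(matrix(rep(wc, length(wr)), length(wc), length(wr)))
    u <- (gr - b$row) * cos(b$theta) + (gc - b$col) * sin(b$theta)
    v <- -(gr - b$row) * sin(b$theta) + (gc - b$col) * cos(b$theta)
    sum((u / b$a)^2 + (v / b$b)^2 <= 1)
  }, 0)

  if (spec$blur_sigma > 0)
    vals <- matrix(as.numeric(EBImage::gblur(vals, spec$blur_sigma)), n, n)
  if (spec$noise_sd > 0)
    vals <- vals + rnorm(n * n, 0, spec$noise_sd)
  pixels <- pmin(pmax(round(vals), 0), 255)
  img <- slice_image(pixels, pixel_size_mm = spec$pixel_size_mm,
                     source_id = sprintf("phantom-seed%d", spec$seed))

  mk_contour <- function(mask)
    .label_contours(matrix(as.integer(mask), n, n))[[1L]]
  zones <- structure(list(
    contour1 = mk_contour(slice),
    contour2 = mk_contour(inner),
    contour3 = mk_contour(D <= r_epi),
    epidermis_mask = epi,
    periphery_mask = peri,
    inner_mask = inner,
    stem_center = ctr,
    dim = c(n, n),
    pixel_size_mm = spec$pixel_size_mm,
    substance_mask = NULL, periphery_seg = NULL, params = NULL),
    class = "function_zones")
  truth <- data.frame(
    row = vapply(bundles, `[[`, 0, "row"),
    col = vapply(bundles, `[[`, 0, "col"),
    dc_mm = vapply(bundles, function(b)
      sqrt((b$row - ctr[1L])^2 + (b$col - ctr[2L])^2), 0) * spec$pixel_size_mm,
    r_eq_mm = vapply(bundles, `[[`, 0, "r_eq") * spec$pixel_size_mm,
    area_px = area_px,
    zone = vapply(bundles, `[[`, "", "zone"),
    clump_id = vapply(bundles, function(b) as.integer(b$clump_id), 0L))
  structure(list(image = img, zones = zones, bundles = truth, spec = spec),
            class = "phantom_truth")
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("<phantom_truth> %d x %d px, %d bundles (%d periphery, %d inner)\n",
              x$zones$dim[1L], x$zones$dim[2L], nrow(x$bundles),
              sum(x$bundles$zone == "periphery"),
              sum(x$bundles$zone == "inner")))
  invisible(x)
}

#' Generate a batch of phantoms over parameter ranges
#'
#' Per-slice parameters are drawn uniformly from the stated ranges with a
#' seeded generator. Stem geometry and the bundle-size law scale with
#' `sqrt(n_total / n_base)`, so sparse slices are smaller stems with
#' proportionally smaller bundles and the packing density stays constant.
#'
#' @param base_spec a [phantom_spec()] providing all fixed parameters.
#' @param n_slices number of phantoms.
#' @param vary named list of `c(min, max)` ranges; supported names:
#'   `n_total` (total bundle count), `noise_sd`, `fusion_fraction`,
#'   `touch_epidermis_fraction`, `boundary_break`.
#' @param seed RNG seed of the batch.
#' @return list of [generate_phantom()] results.
#' @export
phantom_batch <- function(base_spec = phantom_spec(), n_slices = 20L,
                          vary = list(n_total = c(100, 500),
                                      noise_sd = c(5, 15),
                                      fusion_fraction = c(0, 0.1)),
                          seed = 1L) {
  stopifnot(inherits(base_spec, "phantom_spec"), n_slices >= 1L)
  n_base <- base_spec$n_periphery + base_spec$n_inner
  frac_per <- base_spec$n_periphery / n_base
  draws <- .with_seed(seed, {
    d <- lapply(vary, function(rg) runif(n_slices, rg[1L], rg[2L]))
    d$slice_seed <- sample.int(2147483646L, n_slices)
    d
  })
  lapply(seq_len(n_slices), function(i) {
    sp <- unclass(base_spec)
    if (!is.null(draws$n_total)) {
      n_tot <- round(draws$n_total[i])
      s <- sqrt(n_tot / n_base)
      sp$n_periphery <- as.integer(round(frac_per * n_tot))
      sp$n_inner <- as.integer(n_tot - sp$n_periphery)
      sp$outer_radius <- round(base_spec$outer_radius * s)
      # above the base density the annulus widens so the periphery packing
      # fraction stays below its feasibility ceiling
      s_in <- s * (1 - 0.15 * max(0, n_tot / n_base - 1))
      sp$inner_radius <- round(base_spec$inner_radius * s_in)
      sp$epidermis_width <- max(6, round(base_spec$epidermis_width * s))
      sp$image_size <- as.integer(2L * sp$outer_radius + 60L)
      sp$law_distance_scale <- base_spec$law_distance_scale * s
    }
    for (nm in setdiff(names(draws), c("n_total", "slice_seed")))
      sp[[nm]] <- draws[[nm]][i]
    sp$seed <- draws$slice_seed[i]
    generate_phantom(structure(sp, class = "phantom_spec"))
  })
}
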