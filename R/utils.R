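# Internal raster utilities shared by the pipeline modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is left untouched.
.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

.as_binary <- function(mask) {
  matrix(as.numeric(mask) > 0.5, nrow(mask), ncol(mask))
}

#' Label connected components of a binary mask
#'
#' Foreground objects use 8-connectivity by default (diagonal neighbours
#' touch); background/cavity analyses use 4-connectivity, the standard dual
#' pairing that keeps digital Jordan curves consistent.
#'
#' @param mask logical or 0/1 matrix.
#' @param connectivity 4 or 8.
#' @return integer matrix of labels, 0 for background. Labels are numbered
#'   deterministically in column-major order of first occurrence.
#' @export
label_components <- function(mask, connectivity = 8) {
  stopifnot(connectivity %in% c(4L, 8L))
  nr <- nrow(mask); nc <- ncol(mask)
  m <- matrix(as.numeric(mask) > 0.5, nr, nc)
  if (connectivity == 4L) {
    lab <- matrix(as.integer(EBImage::bwlabel(m * 1)), nr, nc)
    # bwlabel numbers objects already; renumber for a fixed scan order
    idx <- which(lab > 0L)
    if (length(idx)) lab[idx] <- match(lab[idx], unique(lab[idx]))
    return(lab)
  }
  lab <- matrix(0L, nr, nc)
  idx <- which(m)
  if (!length(idx)) return(lab)
  r <- (idx - 1L) %% nr
  cc <- (idx - 1L) %/% nr
  el <- vector("list", 4L)
  i <- 1L
  for (d in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))) {
    r2 <- r + d[1L]; c2 <- cc + d[2L]
    ok <- r2 >= 0L & r2 < nr & c2 >= 0L & c2 < nc
    nidx <- c2[ok] * nr + r2[ok] + 1L
    keep <- m[nidx]
    el[[i]] <- cbind(idx[ok][keep], nidx[keep])
    i <- i + 1L
  }
  el <- do.call(rbind, el)
  if (nrow(el)) {
    g <- igraph::make_graph(edges = as.vector(t(el)), n = nr * nc,
                            directed = FALSE)
    memb <- igraph::components(g)$membership[idx]
  } else {
    memb <- seq_along(idx)
  }
  lab[idx] <- match(memb, unique(memb))
  lab
}

# Windowed box sum with window half-width k; the window is truncated at the
# matrix borders (used together with a count matrix, so truncation cancels).
.box_sum <- function(m, k) {
  nr <- nrow(m); nc <- ncol(m)
  S <- matrix(0, nr + 1L, nc + 1L)
  S[-1L, -1L] <- t(apply(apply(m, 2L, cumsum), 1L, cumsum))
  r1 <- pmax(seq_len(nr) - k, 1L); r2 <- pmin(seq_len(nr) + k, nr)
  c1 <- pmax(seq_len(nc) - k, 1L); c2 <- pmin(seq_len(nc) + k, nc)
  S[r2 + 1L, c2 + 1L, drop = FALSE] - S[r1, c2 + 1L, drop = FALSE] -
    S[r2 + 1L, c1, drop = FALSE] + S[r1, c1, drop = FALSE]
}

.disc_brush <- function(size) {
  size <- as.integer(size)
  if (size < 3L) return(matrix(1, 1L, 1L))
  if (size %% 2L == 0L) size <- size + 1L   # EBImage brushes must be odd
  EBImage::makeBrush(size, shape = "disc")
}

.box3 <- EBImage::makeBrush(3L, shape = "box")

.dilate <- function(mask, brush) {
  .as_binary(EBImage::dilate(.as_binary(mask) * 1, brush))
}

.erode <- function(mask, brush) {
  .as_binary(EBImage::erode(.as_binary(mask) * 1, brush))
}

.closing <- function(mask, brush) {
  .as_binary(EBImage::closing(.as_binary(mask) * 1, brush))
}

.fill_holes <- function(mask) {
  .as_binary(EBImage::fillHull(.as_binary(mask) * 1))
}

# Euclidean distance transform (distance to nearest background pixel); the
# image border counts as background so off-image space never inflates radii.
.distmap <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(0, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- .as_binary(mask) * 1
  d <- EBImage::distmap(pad)
  matrix(as.numeric(d), nr + 2L, nc + 2L)[2:(nr + 1L), 2:(nc + 1L)]
}
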