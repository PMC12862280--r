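# --- exact segment predicates -------------------------------------------
# cross product of (b - a) and (c - a)
.cross3 <- function(ax, ay, bx, by, cx, cy) {
  (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
}

# does point c lie on segment a-b (collinearity already established)?
.within_bbox <- function(ax, ay, bx, by, cx, cy, tol) {
  cx >= min(ax, bx) - tol && cx <= max(ax, bx) + tol &&
    cy >= min(ay, by) - tol && cy <= max(ay, by) + tol
}

# TRUE iff closed segments p1-p2 and q1-q2 share at least one point.
# With tol = 0 the test is exact for coordinates representable in doubles
# (lattice and grid-snapped polygons); tol > 0 relaxes the collinearity
# and bbox comparisons for dirty real-world geometry.
.segments_touch <- function(p1x, p1y, p2x, p2y, q1x, q1y, q2x, q2y, tol = 0) {
  d1 <- .cross3(q1x, q1y, q2x, q2y, p1x, p1y)
  d2 <- .cross3(q1x, q1y, q2x, q2y, p2x, p2y)
  d3 <- .cross3(p1x, p1y, p2x, p2y, q1x, q1y)
  d4 <- .cross3(p1x, p1y, p2x, p2y, q2x, q2y)
  if (((d1 > tol && d2 < -tol) || (d1 < -tol && d2 > tol)) &&
      ((d3 > tol && d4 < -tol) || (d3 < -tol && d4 > tol))) return(TRUE)
  if (abs(d1) <= tol && .within_bbox(q1x, q1y, q2x, q2y, p1x, p1y, tol)) return(TRUE)
  if (abs(d2) <= tol && .within_bbox(q1x, q1y, q2x, q2y, p2x, p2y, tol)) return(TRUE)
  if (abs(d3) <= tol && .within_bbox(p1x, p1y, p2x, p2y, q1x, q1y, tol)) return(TRUE)
  if (abs(d4) <= tol && .within_bbox(p1x, p1y, p2x, p2y, q2x, q2y, tol)) return(TRUE)
  FALSE
}

# TRUE iff the boundaries of two rings share at least one point
.rings_touch <- function(a, b, tol = 0) {
  na <- nrow(a); nb <- nrow(b)
  for (i in seq_len(na - 1L)) {
    ax1 <- a[i, 1L]; ay1 <- a[i, 2L]; ax2 <- a[i + 1L, 1L]; ay2 <- a[i + 1L, 2L]
    exlo <- min(ax1, ax2) - tol; exhi <- max(ax1, ax2) + tol
    eylo <- min(ay1, ay2) - tol; eyhi <- max(ay1, ay2) + tol
    for (j in seq_len(nb - 1L)) {
      bx1 <- b[j, 1L]; by1 <- b[j, 2L]; bx2 <- b[j + 1L, 1L]; by2 <- b[j + 1L, 2L]
      if (max(bx1, bx2) < exlo || min(bx1, bx2) > exhi ||
          max(by1, by2) < eylo || min(by1, by2) > eyhi) next
      if (.segments_touch(ax1, ay1, ax2, ay2, bx1, by1, bx2, by2, tol))
        return(TRUE)
    }
  }
  FALSE
}

new_spatial_weights <- function(neighbours, weights, ids, style) {
  n <- length(neighbours)
  islands <- which(lengths(neighbours) == 0L)
  structure(list(neighbours = neighbours, weights = weights, ids = ids,
                 style = style, islands = islands, n = n),
            class = "spatial_weights")
}

#' Queen-contiguity spatial weights
#'
#' Builds the queen-contiguity neighbor structure of a polygon tessellation:
#' two tracts are neighbors if and only if their boundaries share at least
#' one point (a common edge *or* a single corner). The diagonal is always
#' excluded (a tract is never its own neighbor), and tracts with no
#' neighbors are recorded as islands. Detection uses exact segment
#' predicates; `tolerance` (in coordinate units) can relax them for
#' imperfectly snapped real-world geometry.
#'
#' @param geom a [tract_geometry()] with pairwise non-overlapping interiors.
#' @param style `"W"` for row-standardized weights (each non-island row sums
#'   to 1; the default, and the convention under which the mean of the local
#'   Moran statistics equals the global statistic) or `"B"` for binary 0/1
#'   weights.
#' @param tolerance non-negative numeric; 0 (default) means exact predicates.
#' @return An object of class `spatial_weights`: neighbor index lists,
#'   per-pair weights, tract ids, the standardization `style`, and the
#'   indices of `islands`. Island rows have no weights and are excluded
#'   from all Moran computations downstream.
#' @seealso [row_standardize()], [weights_matrix()], [write_gal()]
#' @examples
#' w <- queen_weights(make_lattice(3, 3))
#' neighbor_counts(w)  # corners 3, edges 5, center 8
#' @export
queen_weights <- function(geom, style = c("W", "B"), tolerance = 0) {
  stopifnot(inherits(geom, "tract_geometry"))
  style <- match.arg(style)
  if (!is.numeric(tolerance) || length(tolerance) != 1L || tolerance < 0)
    stop("`tolerance` must be a single non-negative number")
  n <- geom$n
  if (n == 0L) stop("empty polygon collection")
  polys <- geom$polygons
  bb <- t(vapply(polys, function(p)
    c(min(p[, 1L]), min(p[, 2L]), max(p[, 1L]), max(p[, 2L])), numeric(4)))
  nb <- vector("list", n)
  for (i in seq_len(n)) nb[[i]] <- integer(0)
  tol <- tolerance
  for (i in seq_len(n - 1L)) {
    # bounding-box prefilter keeps the exact test near-linear on lattices
    cand <- which(bb[(i + 1L):n, 1L] <= bb[i, 3L] + tol &
                  bb[(i + 1L):n, 3L] >= bb[i, 1L] - tol &
                  bb[(i + 1L):n, 2L] <= bb[i, 4L] + tol &
                  bb[(i + 1L):n, 4L] >= bb[i, 2L] - tol) + i
    for (j in cand) {
      if (.rings_touch(polys[[i]], polys[[j]], tol)) {
        nb[[i]] <- c(nb[[i]], j)
        nb[[j]] <- c(nb[[j]], i)
      }
    }
  }
  nb <- lapply(nb, sort)
  wts <- lapply(nb, function(x) rep(1, length(x)))
  w <- new_spatial_weights(nb, wts, geom$ids, style = "B")
  if (style == "W") w <- row_standardize(w) else w
}

#' Row-standardize a binary spatial weights object
#'
#' Rescales each tract's weights to sum to 1 (weight `1/k` for each of `k`
#' neighbors). Island rows have no weights and are left untouched.
#'
#' @param w a `spatial_weights` object with binary (`"B"`) style.
#' @return The weights object with `style = "W"`.
#' @export
row_standardize <- function(w) {
  stopifnot(inherits(w, "spatial_weights"))
  if (w$style == "W") stop("weights are already row-standardized")
  w$weights <- lapply(w$weights, function(x) {
    s <- sum(x)
    if (s > 0) x / s else x
  })
  w$style <- "W"
  w
}

#' @export
print.spatial_weights <- function(x, ...) {
  cat(sprintf("spatial_weights: %d tracts, style %s\n", x$n, x$style))
  k <- lengths(x$neighbours)
  cat(sprintf("  links: %d (avg %.2f neighbors), islands: %d\n",
              sum(k), mean(k), length(x$islands)))
  invisible(x)
}

#' Neighbor counts
#'
#' Number of queen neighbors of each tract (the cardinality of each row of
#' the weights structure).
#'
#' @param w a `spatial_weights`.
#' @return integer vector of length `n`.
#' @export
neighbor_counts <- function(w) {
  stopifnot(inherits(w, "spatial_weights"))
  lengths(w$neighbours)
}

#' Dense weights matrix
#'
#' Expands a `spatial_weights` object into the full n-by-n matrix
#' \eqn{w_{ij}} used in the Moran cross-product formulas (zero diagonal;
#' island rows all zero).
#'
#' @param w a `spatial_weights`.
#' @return numeric matrix with tract ids as dimnames.
#' @export
weights_matrix <- function(w) {
  stopifnot(inherits(w, "spatial_weights"))
  m <- matrix(0, w$n, w$n, dimnames = list(w$ids, w$ids))
  for (i in seq_len(w$n))
    if (length(w$neighbours[[i]])) m[i, w$neighbours[[i]]] <- w$weights[[i]]
  m
}

#' Spatial lag
#'
#' The weighted average (row-standardized style) or weighted sum (binary
#' style) of `z` over each tract's neighbors, \eqn{\sum_j w_{ij} z_j}.
#' Islands get `NA`.
#'
#' @param w a `spatial_weights`.
#' @param z numeric vector aligned with the weights object.
#' @return numeric vector of spatial lags.
#' @export
spatial_lag <- function(w, z) {
  stopifnot(inherits(w, "spatial_weights"), length(z) == w$n)
  out <- rep(NA_real_, w$n)
  for (i in seq_len(w$n)) {
    nb <- w$neighbours[[i]]
    if (length(nb)) out[i] <- sum(w$weights[[i]] * z[nb])
  }
  out
}

#' Induced subgraph of a weights object
#'
#' Restricts the contiguity structure to a subset of tracts (used when
#' tracts with missing data are excluded from a fit). Binary adjacency is
#' subset and, for row-standardized input, re-standardized over the
#' remaining neighbors; tracts that lose all neighbors become islands.
#'
#' @param w a `spatial_weights`.
#' @param keep logical vector of length `n`, or integer indices, of tracts
#'   to retain.
#' @return a `spatial_weights` over the retained tracts (original order).
#' @export
subset_weights <- function(w, keep) {
  stopifnot(inherits(w, "spatial_weights"))
  idx <- if (is.logical(keep)) {
    stopifnot(length(keep) == w$n)
    which(keep)
  } else sort(unique(as.integer(keep)))
  pos <- match(seq_len(w$n), idx)  # old index -> new index (NA if dropped)
  nb <- lapply(idx, function(i) {
    new <- pos[w$neighbours[[i]]]
    sort(new[!is.na(new)])
  })
  wts <- lapply(nb, function(x) rep(1, length(x)))
  out <- new_spatial_weights(nb, wts, w$ids[idx], style = "B")
  if (w$style == "W") row_standardize(out) else out
}

#' Read and write GAL neighbor-list files
#'
#' Plain-text interchange of the contiguity structure in the GAL format
#' used by GeoDa and friends: a header line with the number of units, then
#' for each unit a line `id k` followed by a line listing its `k`
#' neighbors' ids. Only the binary adjacency travels through GAL; apply
#' [row_standardize()] after reading if row-standardized weights are
#' needed.
#'
#' @param w a `spatial_weights` (its binary adjacency is written).
#' @param path file path.
#' @return `read_gal()`: a binary-style `spatial_weights`.
#' @export
write_gal <- function(w, path) {
  stopifnot(inherits(w, "spatial_weights"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(w$n), con)
  for (i in seq_len(w$n)) {
    nb <- w$neighbours[[i]]
    writeLines(paste(w$ids[i], length(nb)), con)
    writeLines(paste(w$ids[nb], collapse = " "), con)
  }
  invisible(path)
}

#' @rdname write_gal
#' @export
read_gal <- function(path) {
  lines <- readLines(path)
  header <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  n <- as.integer(header[length(header)])  # tolerate "0 n ..." style headers
  if (is.na(n) || n < 1L) stop("invalid GAL header")
  ids <- character(n); nb_ids <- vector("list", n)
  pos <- 2L
  for (i in seq_len(n)) {
    head_i <- strsplit(trimws(lines[pos]), "\\s+")[[1L]]
    ids[i] <- head_i[1L]
    k <- as.integer(head_i[2L])
    nb_ids[[i]] <- if (k > 0L) strsplit(trimws(lines[pos + 1L]), "\\s+")[[1L]]
                   else character(0)
    if (k != length(nb_ids[[i]]))
      stop("GAL record for ", ids[i], " announces ", k, " neighbors but lists ",
           length(nb_ids[[i]]))
    pos <- pos + 2L
  }
  nb <- lapply(nb_ids, function(x) sort(match(x, ids)))
  if (anyNA(unlist(nb))) stop("GAL file references unknown ids")
  wts <- lapply(nb, function(x) rep(1, length(x)))
  new_spatial_weights(nb, wts, ids, style = "B")
}
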