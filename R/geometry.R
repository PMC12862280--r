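#' Tract polygon geometry
#'
#' A lightweight container for tract polygons. Each polygon is a closed ring:
#' a numeric matrix with two columns (x, y) whose first and last rows
#' coincide. Holes are not supported; the container is intended for
#' census-tract style tessellations (no overlapping interiors).
#'
#' @param polygons list of numeric matrices, one closed ring per tract.
#' @param ids character vector of unique tract identifiers, one per polygon.
#'
#' @return An object of class `tract_geometry`: a list with elements
#'   `polygons`, `ids`, and `n`.
#' @export
tract_geometry <- function(polygons, ids = NULL) {
  if (!is.list(polygons) || length(polygons) == 0L)
    stop("`polygons` must be a non-empty list of coordinate matrices")
  polygons <- lapply(polygons, function(p) {
    p <- as.matrix(p)
    if (!is.numeric(p) || ncol(p) != 2L || nrow(p) < 4L)
      stop("each polygon must be a numeric matrix with 2 columns and >= 4 rows")
    if (any(!is.finite(p))) stop("polygon coordinates must be finite")
    # close the ring if the caller did not
    if (any(p[1L, ] != p[nrow(p), ])) p <- rbind(p, p[1L, ])
    dimnames(p) <- NULL
    p
  })
  n <- length(polygons)
  if (is.null(ids)) ids <- sprintf("T%04d", seq_len(n))
  ids <- as.character(ids)
  if (length(ids) != n) stop("`ids` must match the number of polygons")
  if (anyDuplicated(ids)) stop("tract ids must be unique")
  structure(list(polygons = polygons, ids = ids, n = n),
            class = "tract_geometry")
}

#' @export
print.tract_geometry <- function(x, ...) {
  cat("tract_geometry:", x$n, "polygons\n")
  bb <- geometry_bbox(x)
  cat(sprintf("  bbox: x [%g, %g], y [%g, %g]\n", bb[1], bb[3], bb[2], bb[4]))
  invisible(x)
}

#' @export
length.tract_geometry <- function(x) x$n

geometry_bbox <- function(geom) {
  xs <- unlist(lapply(geom$polygons, function(p) range(p[, 1L])))
  ys <- unlist(lapply(geom$polygons, function(p) range(p[, 2L])))
  c(xmin = min(xs), ymin = min(ys), xmax = max(xs), ymax = max(ys))
}

#' Polygon areas and centroids
#'
#' Shoelace-formula areas and area-weighted centroids of a
#' [tract_geometry()]. Areas are in squared coordinate units (square miles
#' by the package convention).
#'
#' @param geom a `tract_geometry`.
#' @return `tract_areas()`: numeric vector of areas. `tract_centroids()`:
#'   two-column matrix of centroid coordinates.
#' @export
tract_areas <- function(geom) {
  stopifnot(inherits(geom, "tract_geometry"))
  vapply(geom$polygons, function(p) {
    x <- p[, 1L]; y <- p[, 2L]
    n <- length(x)
    abs(sum(x[-n] * y[-1L] - x[-1L] * y[-n])) / 2
  }, numeric(1))
}

#' @rdname tract_areas
#' @export
tract_centroids <- function(geom) {
  stopifnot(inherits(geom, "tract_geometry"))
  t(vapply(geom$polygons, function(p) {
    x <- p[, 1L]; y <- p[, 2L]
    n <- length(x)
    cross <- x[-n] * y[-1L] - x[-1L] * y[-n]
    a <- sum(cross) / 2
    if (abs(a) < .Machine$double.eps) return(c(mean(x[-n]), mean(y[-n])))
    cx <- sum((x[-n] + x[-1L]) * cross) / (6 * a)
    cy <- sum((y[-n] + y[-1L]) * cross) / (6 * a)
    c(cx, cy)
  }, numeric(2)))
}

#' Build a rectangular lattice of square tracts
#'
#' Tiles an `n_rows` by `n_cols` rectangle with square cells of side
#' `cell_size`. Tract ids are assigned in row-major order (row 1 first),
#' which is the ordering every downstream structure preserves. Each cell's
#' land area is `cell_size^2` (square miles by convention).
#'
#' @param n_rows,n_cols positive integers, lattice dimensions.
#' @param cell_size positive side length of each square cell.
#' @return A `tract_geometry` with `n_rows * n_cols` polygons.
#' @examples
#' geom <- make_lattice(2, 3)
#' tract_areas(geom)
#' @export
make_lattice <- function(n_rows, n_cols, cell_size = 1) {
  if (length(n_rows) != 1L || length(n_cols) != 1L ||
      is.na(n_rows) || is.na(n_cols) || n_rows < 1 || n_cols < 1 ||
      n_rows != round(n_rows) || n_cols != round(n_cols))
    stop("`n_rows` and `n_cols` must be positive integers")
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("`cell_size` must be a positive number")
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  s <- cell_size
  polys <- vector("list", n_rows * n_cols)
  k <- 0L
  for (i in seq_len(n_rows)) {
    y0 <- (n_rows - i) * s  # row 1 on top, purely cosmetic
    for (j in seq_len(n_cols)) {
      x0 <- (j - 1L) * s
      k <- k + 1L
      polys[[k]] <- cbind(c(x0, x0 + s, x0 + s, x0, x0),
                          c(y0, y0, y0 + s, y0 + s, y0))
    }
  }
  geom <- tract_geometry(polys)
  attr(geom, "lattice") <- c(n_rows = n_rows, n_cols = n_cols)
  attr(geom, "cell_size") <- s
  geom
}

#' Read and write tract polygons as GeoJSON
#'
#' A minimal GeoJSON layer for the package's interchange format: a
#' FeatureCollection of Polygon features. `write_geojson()` stores the
#' tract id and any per-tract `properties` columns on each feature;
#' `read_geojson()` returns the geometry together with a data frame of the
#' feature properties (in feature order).
#'
#' @param geom a `tract_geometry`.
#' @param path file path.
#' @param properties optional data frame of per-tract attributes, recycled
#'   onto features by position.
#' @return `read_geojson()`: a list with elements `geometry`
#'   (a `tract_geometry`) and `properties` (a data frame).
#' @export
write_geojson <- function(geom, path, properties = NULL) {
  stopifnot(inherits(geom, "tract_geometry"))
  if (!is.null(properties)) {
    properties <- as.data.frame(properties)
    if (nrow(properties) != geom$n)
      stop("`properties` must have one row per tract")
  }
  features <- lapply(seq_len(geom$n), function(i) {
    props <- list(tract_id = jsonlite::unbox(geom$ids[i]))
    if (!is.null(properties)) {
      for (nm in names(properties)) {
        v <- properties[[nm]][i]
        props[[nm]] <- jsonlite::unbox(if (is.factor(v)) as.character(v) else v)
      }
    }
    ring <- geom$polygons[[i]]
    coords <- lapply(seq_len(nrow(ring)), function(r) c(ring[r, 1L], ring[r, 2L]))
    list(type = jsonlite::unbox("Feature"),
         properties = props,
         geometry = list(type = jsonlite::unbox("Polygon"),
                         coordinates = list(coords)))
  })
  fc <- list(type = jsonlite::unbox("FeatureCollection"), features = features)
  writeLines(jsonlite::toJSON(fc, digits = NA, auto_unbox = FALSE,
                              null = "null"), path)
  invisible(path)
}

#' @rdname write_geojson
#' @export
read_geojson <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(gj$type, "FeatureCollection"))
    stop("expected a GeoJSON FeatureCollection")
  feats <- gj$features
  if (length(feats) == 0L) stop("GeoJSON contains no features")
  polys <- vector("list", length(feats))
  props <- vector("list", length(feats))
  for (i in seq_along(feats)) {
    f <- feats[[i]]
    g <- f$geometry
    if (is.null(g) || !identical(g$type, "Polygon"))
      stop("feature ", i, ": only Polygon geometries are supported")
    ring <- g$coordinates[[1L]]
    polys[[i]] <- do.call(rbind, lapply(ring, function(pt)
      c(as.numeric(pt[[1L]]), as.numeric(pt[[2L]]))))
    props[[i]] <- lapply(f$properties, function(v) if (is.null(v)) NA else v)
  }
  prop_names <- unique(unlist(lapply(props, names)))
  pdf <- as.data.frame(
    lapply(prop_names, function(nm)
      unlist(lapply(props, function(p) p[[nm]] %||% NA))),
    stringsAsFactors = FALSE)
  names(pdf) <- prop_names
  ids <- if ("tract_id" %in% prop_names) as.character(pdf$tract_id) else NULL
  list(geometry = tract_geometry(polys, ids = ids), properties = pdf)
}
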