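#' Fit a LISA model: local Moran's I with conditional-permutation inference
#'
#' `lisa()` is the package's central fitting function. It standardizes the
#' input variable(s), computes global and local Moran's I (univariate, or
#' bivariate between a focal variable `x` and the spatial lag of a second
#' variable `y`), attaches conditional-permutation pseudo p-values, and
#' classifies each tract into the HH/LL/HL/LH cluster typology at one or
#' more significance levels.
#'
#' In the bivariate form the left-hand side of the formula is the focal
#' variable (e.g. the proportion of high flood-risk properties) and the
#' right-hand side supplies the spatial lag (e.g. an inverted inequality
#' index), so an `HH` tract reads "high flood risk surrounded by high
#' inequality". Only the lagged variable is permuted during inference; the
#' focal value at each tract is held fixed. Inequality indices are expected
#' post-inversion (see [invert()]).
#'
#' Tracts with no neighbors (islands) are excluded from standardization,
#' statistics, and inference, and are labeled `ISLAND` — they never receive
#' a p-value.
#'
#' @param x a formula (`focal ~ lagged` for the bivariate model, `~ var` or
#'   `var ~ var` for the univariate one) or a numeric vector of focal
#'   values.
#' @param ... further arguments passed to methods.
#' @return An object of class `"lisa"`; see Details for its components and
#'   [print.lisa()], [summary.lisa()], [plot.lisa()],
#'   [as.data.frame.lisa()] for methods.
#' @examples
#' st <- synthesize_tracts(sim_config(n_rows = 8, n_cols = 8, seed = 7))
#' tab <- compute_indices(st)
#' fit <- lisa(p_flood_high ~ ice_income, data = tab, weights = st$weights,
#'             permutations = 199, seed = 1)
#' summary(fit)
#' @export
lisa <- function(x, ...) UseMethod("lisa")

#' @rdname lisa
#' @param data data frame containing the formula variables.
#' @param weights a [queen_weights()] object over the same tracts, in data
#'   row order.
#' @inheritParams lisa_pvalues
#' @param alpha numeric vector of significance levels; the first is the
#'   primary level used for the reported quadrant labels, the others yield
#'   additional label columns (the conventional trio is
#'   `c(0.05, 0.01, 0.001)`).
#' @export
lisa.formula <- function(x, data, weights, permutations = 999, seed = NULL,
                         alpha = 0.05,
                         alternative = c("directed", "two.sided",
                                         "greater", "less"), ...) {
  formula <- x
  data <- as.data.frame(data)
  rhs <- all.vars(formula[[length(formula)]])
  if (length(rhs) != 1L) stop("formula must have exactly one right-hand variable")
  yv <- rhs
  xv <- if (length(formula) == 3L) all.vars(formula[[2L]]) else yv
  if (length(xv) != 1L) stop("formula must have exactly one left-hand variable")
  for (v in c(xv, yv)) if (!v %in% names(data))
    stop("variable `", v, "` not found in `data`")
  fit <- lisa.default(data[[xv]], y = if (identical(xv, yv)) NULL else data[[yv]],
                      weights = weights, permutations = permutations,
                      seed = seed, alpha = alpha,
                      alternative = alternative, ...)
  fit$call <- match.call()
  fit$x_name <- xv
  fit$y_name <- yv
  fit
}

#' @rdname lisa
#' @param y optional numeric vector of the variable supplying the spatial
#'   lag; omit for the univariate model.
#' @export
lisa.default <- function(x, y = NULL, weights, permutations = 999,
                         seed = NULL, alpha = 0.05,
                         alternative = c("directed", "two.sided",
                                         "greater", "less"), ...) {
  stopifnot(inherits(weights, "spatial_weights"))
  alternative <- match.arg(alternative)
  w <- weights
  n <- w$n
  if (length(x) != n) stop("`x` and `weights` cover different tract sets")
  univariate <- is.null(y)
  if (!univariate && length(y) != n)
    stop("`y` and `weights` cover different tract sets")
  if (!is.numeric(alpha) || any(alpha <= 0 | alpha >= 1))
    stop("`alpha` levels must lie in (0, 1)")
  if (anyNA(x) || (!univariate && anyNA(y))) {
    bad <- which(is.na(x) | (if (univariate) FALSE else is.na(y)))
    stop("missing values in ", length(bad),
         " tract(s); drop or impute before fitting (first: ", bad[1L], ")")
  }
  act <- .active_index(w)
  if (length(act) < 2L) stop("fewer than 2 connected tracts")
  zx <- rep(NA_real_, n); zy <- rep(NA_real_, n)
  zx[act] <- standardize(x[act])
  zy[act] <- if (univariate) zx[act] else standardize(y[act])
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  seed <- as.integer(seed)

  lag <- spatial_lag(w, zy)
  ii <- zx * lag
  gI <- global_moran(zx, w, zy)
  p <- lisa_pvalues(zx, w, zy, permutations = permutations, seed = seed,
                    alternative = alternative)
  quads <- lapply(alpha, function(a) classify_quadrants(zx, lag, p, a))
  names(quads) <- paste0("alpha_", format(alpha, trim = TRUE))

  structure(list(
    call = match.call(),
    x_name = "x", y_name = if (univariate) "x" else "y",
    univariate = univariate,
    n = n, n_used = length(act),
    ids = w$ids,
    zx = zx, zy = zy, lag = lag,
    local = ii, p = p,
    quadrant = quads[[1L]], quadrants = quads,
    global = gI,
    permutations = as.integer(permutations), seed = seed,
    alpha = alpha, alternative = alternative,
    weights_style = w$style, islands = w$islands
  ), class = "lisa")
}

#' @export
print.lisa <- function(x, ...) {
  kind <- if (x$univariate) "univariate" else "bivariate"
  cat(sprintf("Local Moran's I (%s LISA)\n", kind))
  cat(sprintf("  variables: %s ~ %s   tracts: %d (%d islands)\n",
              x$x_name, x$y_name, x$n, x$n - x$n_used))
  cat(sprintf("  global Moran's I: %.4f   permutations: %d   seed: %d\n",
              x$global, x$permutations, x$seed))
  tab <- table(x$quadrant)
  cat(sprintf("  clusters at alpha = %g: ", x$alpha[1L]))
  cat(paste(names(tab), tab, sep = "=", collapse = "  "), "\n")
  invisible(x)
}

#' Methods for LISA fits
#'
#' `summary()` tabulates cluster counts at every requested significance
#' level and reports the global statistic; `as.data.frame()` returns the
#' per-tract results table (id, focal z, lag, local I, pseudo p, quadrant
#' label per level); `plot()` draws a Moran scatterplot of the focal
#' z-values against the spatial lag, colored by quadrant, or a lattice
#' cluster map when a geometry is supplied.
#'
#' @param object,x a `lisa` fit.
#' @param ... unused.
#' @export
summary.lisa <- function(object, ...) {
  counts <- vapply(object$quadrants, table, integer(6))
  out <- list(global = object$global, counts = counts,
              alpha = object$alpha, n = object$n, n_used = object$n_used,
              permutations = object$permutations,
              alternative = object$alternative,
              x_name = object$x_name, y_name = object$y_name,
              univariate = object$univariate)
  class(out) <- "summary.lisa"
  out
}

#' @export
print.summary.lisa <- function(x, ...) {
  kind <- if (x$univariate) "univariate" else "bivariate"
  cat(sprintf("%s LISA: %s ~ %s\n", kind, x$x_name, x$y_name))
  cat(sprintf("global Moran's I = %.4f  (n = %d, %d permutations, %s p)\n",
              x$global, x$n_used, x$permutations, x$alternative))
  cat("cluster counts by significance level:\n")
  print(x$counts)
  invisible(x)
}

#' @rdname summary.lisa
#' @param row.names,optional passed through to [base::data.frame()].
#' @export
as.data.frame.lisa <- function(x, row.names = NULL, optional = FALSE, ...) {
  out <- data.frame(tract_id = x$ids, z = x$zx, lag = x$lag,
                    local_i = x$local, p = x$p,
                    stringsAsFactors = FALSE)
  for (nm in names(x$quadrants)) out[[paste0("label_", nm)]] <-
    as.character(x$quadrants[[nm]])
  out$quadrant <- as.character(x$quadrant)
  if (!is.null(row.names)) rownames(out) <- row.names
  out
}

quadrant_colors <- function() {
  c(HH = "#b2182b", LL = "#2166ac", LH = "#92c5de", HL = "#f4a582",
    NS = "grey85", ISLAND = "grey50")
}

#' @rdname summary.lisa
#' @param type `"scatter"` for the Moran scatterplot, `"map"` for a polygon
#'   cluster map (requires `geometry`).
#' @param geometry optional [tract_geometry()] for `type = "map"`.
#' @export
plot.lisa <- function(x, type = c("scatter", "map"), geometry = NULL, ...) {
  type <- match.arg(type)
  cols <- quadrant_colors()
  if (type == "scatter") {
    graphics::plot(x$zx, x$lag, col = cols[as.character(x$quadrant)],
                   pch = 19, cex = 0.7,
                   xlab = paste0("z(", x$x_name, ")"),
                   ylab = paste0("spatial lag of z(", x$y_name, ")"),
                   main = sprintf("Moran scatterplot (I = %.3f)", x$global), ...)
    graphics::abline(h = 0, v = 0, col = "grey60", lty = 2)
    ok <- !is.na(x$lag)
    if (sum(ok) > 1) graphics::abline(stats::lm(x$lag[ok] ~ x$zx[ok]),
                                      col = "grey30")
    graphics::legend("topleft", legend = names(cols), col = cols, pch = 19,
                     bty = "n", cex = 0.8)
  } else {
    if (is.null(geometry) || !inherits(geometry, "tract_geometry"))
      stop("`type = \"map\"` needs a `tract_geometry`")
    if (geometry$n != x$n) stop("geometry does not match the fitted tracts")
    bb <- geometry_bbox(geometry)
    graphics::plot(NA, xlim = bb[c(1, 3)], ylim = bb[c(2, 4)], asp = 1,
                   xlab = "", ylab = "", axes = FALSE,
                   main = sprintf("LISA clusters: %s ~ %s (alpha = %g)",
                                  x$x_name, x$y_name, x$alpha[1L]), ...)
    for (i in seq_len(geometry$n))
      graphics::polygon(geometry$polygons[[i]],
                        col = cols[as.character(x$quadrant[i])],
                        border = "white", lwd = 0.4)
    graphics::legend("bottomleft", legend = names(cols), fill = cols,
                     bty = "n", cex = 0.8, border = NA)
  }
  invisible(x)
}
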