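#' Index of Concentration at the Extremes (ICE)
#'
#' The ICE contrasts the concentration of a privileged and a deprived
#' extreme within an area: \deqn{ICE = (privileged - deprived) / total.}
#' Scores range from -1 (everyone in the deprived extreme, e.g. 100\%
#' nonwhite or low-income) to +1 (everyone in the privileged extreme, e.g.
#' 100\% white and/or affluent). The three conventional variants are
#' income (households at or below $25,000 vs at or above $125,000), race
#' (Black or non-white Hispanic vs white residents), and the race-income
#' cross.
#'
#' @param privileged count of the privileged extreme group (persons or
#'   households).
#' @param deprived count of the deprived extreme group.
#' @param total area total (same units). Tracts with `total = 0` are
#'   returned as `NA` with a warning: missing, never imputed as 0.
#' @return numeric vector in `[-1, 1]`.
#' @examples
#' ice(privileged = 0, deprived = 100, total = 100)  # -1
#' ice(privileged = 80, deprived = 80, total = 200)  # 0
#' @export
ice <- function(privileged, deprived, total) {
  if (any(privileged < 0, na.rm = TRUE) || any(deprived < 0, na.rm = TRUE))
    stop("group counts must be non-negative")
  if (any(privileged + deprived > total, na.rm = TRUE))
    stop("extreme-group counts exceed the area total")
  out <- (privileged - deprived) / total
  zero <- !is.na(total) & total <= 0
  if (any(zero)) {
    warning(sum(zero), " tract(s) with zero denominator: ICE set to NA")
    out[zero] <- NA_real_
  }
  out
}

#' Named tract-level index vector
#'
#' A thin wrapper marking a per-tract analysis variable with its name and
#' inversion state. [invert()] negates the values so that *higher* values
#' mean *greater* inequality (the orientation under which an HH cluster
#' reads "high flood risk surrounded by high inequality"), and refuses to
#' invert twice.
#'
#' @param values numeric per-tract values.
#' @param name label of the variable.
#' @param inverted has the vector already been inverted?
#' @return numeric vector of class `index_vector` with attributes
#'   `index_name` and `inverted`.
#' @export
index_vector <- function(values, name, inverted = FALSE) {
  stopifnot(is.numeric(values), is.character(name), length(name) == 1L)
  structure(as.numeric(values), index_name = name,
            inverted = isTRUE(inverted), class = "index_vector")
}

#' @rdname index_vector
#' @param x an `index_vector`.
#' @export
invert <- function(x) {
  if (!inherits(x, "index_vector")) stop("`x` must be an index_vector")
  if (isTRUE(attr(x, "inverted")))
    stop("index `", attr(x, "index_name"), "` is already inverted")
  index_vector(-unclass(x), attr(x, "index_name"), inverted = TRUE)
}

#' @export
print.index_vector <- function(x, ...) {
  cat(sprintf("index_vector `%s`%s, n = %d\n", attr(x, "index_name"),
              if (attr(x, "inverted")) " (inverted)" else "", length(x)))
  print(summary(as.numeric(x)))
  invisible(x)
}

#' Flood-risk property proportions
#'
#' `flood_risk_proportions()` splits one tract's FloodFactor scores into
#' the proportions of low (FF at most 2), moderate (FF 3 to 6), and high
#' (FF at least 7) risk properties; the three shares sum to 1.
#' `flood_level_proportion()` is the sensitivity-analysis variant: the
#' share of properties at exactly one high-risk level (7, 8, 9, or 10).
#'
#' @param ff integer vector of FloodFactor scores in 1..10 for one tract.
#' @return `flood_risk_proportions()`: named numeric vector
#'   `c(low, moderate, high)`.
#' @export
flood_risk_proportions <- function(ff) {
  if (length(ff) == 0L) stop("tract has zero properties: flag as missing, not 0")
  if (any(is.na(ff)) || any(ff < 1 | ff > 10 | ff != round(ff)))
    stop("FloodFactor scores must be integers in 1..10")
  c(low = mean(ff <= 2), moderate = mean(ff >= 3 & ff <= 6),
    high = mean(ff >= 7))
}

#' @rdname flood_risk_proportions
#' @param level one of 7, 8, 9, 10.
#' @export
flood_level_proportion <- function(ff, level) {
  if (!level %in% 7:10) stop("`level` must be one of 7, 8, 9, 10")
  if (length(ff) == 0L) stop("tract has zero properties: flag as missing, not 0")
  if (any(is.na(ff)) || any(ff < 1 | ff > 10 | ff != round(ff)))
    stop("FloodFactor scores must be integers in 1..10")
  mean(ff == level)
}

# aggregate per-tract flood proportions over a property table, preserving
# the requested tract order; tracts with no properties come back NA
.tract_flood_table <- function(properties, ids) {
  stopifnot(all(c("tract_id", "ff") %in% names(properties)))
  split_ff <- split(properties$ff, properties$tract_id)
  out <- data.frame(tract_id = ids,
                    p_flood_low = NA_real_, p_flood_moderate = NA_real_,
                    p_flood_high = NA_real_,
                    p_ff7 = NA_real_, p_ff8 = NA_real_, p_ff9 = NA_real_,
                    p_ff10 = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(ids)) {
    ff <- split_ff[[ids[i]]]
    if (is.null(ff) || length(ff) == 0L) next
    pr <- flood_risk_proportions(ff)
    out$p_flood_low[i] <- pr[["low"]]
    out$p_flood_moderate[i] <- pr[["moderate"]]
    out$p_flood_high[i] <- pr[["high"]]
    for (lv in 7:10)
      out[[paste0("p_ff", lv)]][i] <- flood_level_proportion(ff, lv)
  }
  out
}

#' Gini coefficient from grouped income-bracket data
#'
#' The standard grouped-data estimator: each bracket's households sit at
#' the bracket midpoint (an open-top bracket is valued at 1.5 times its
#' lower bound), and the Gini is the mean absolute difference between all
#' household pairs divided by twice the mean,
#' \deqn{G = \sum_{ij} c_i c_j |m_i - m_j| / (2 N^2 \bar{m}).}
#' Under the midpoint convention a single occupied bracket gives exactly
#' 0; the estimator is scale-invariant and bounded above by (N-1)/N.
#'
#' @param counts non-negative household counts per bracket, at least one
#'   positive.
#' @param brackets list of `c(lower, upper)` bounds, ordered and
#'   non-overlapping; the last upper bound may be `Inf`.
#' @return a number in `[0, 1)`.
#' @export
gini_grouped <- function(counts, brackets) {
  if (length(counts) != length(brackets))
    stop("`counts` and `brackets` lengths differ")
  if (any(counts < 0)) stop("bracket counts must be non-negative")
  if (sum(counts) <= 0) stop("all bracket counts are zero")
  lowers <- vapply(brackets, `[`, numeric(1), 1L)
  uppers <- vapply(brackets, `[`, numeric(1), 2L)
  if (any(lowers >= uppers) || any(diff(lowers) <= 0))
    stop("brackets must be ordered with lower < upper")
  mids <- ifelse(is.finite(uppers), (lowers + uppers) / 2, 1.5 * lowers)
  N <- sum(counts)
  mu <- sum(counts * mids) / N
  if (mu == 0) return(0)
  g <- sum(outer(counts, counts) * abs(outer(mids, mids, "-"))) / (2 * N^2 * mu)
  as.numeric(g)
}

#' Index of Dissimilarity
#'
#' The evenness measure \deqn{D = \frac{1}{2} \sum_k |b_k/B - w_k/W|} over
#' subunits k: the share of one group that would need to relocate for the
#' two groups to be evenly distributed. `dissimilarity_index()` computes D
#' for one set of subunits; `dissimilarity_by_region()` computes D within
#' each enclosing region (tracts as subunits) and assigns every tract its
#' region's D, which is this package's tract-level IOD convention.
#'
#' @param b,w non-negative counts of the two groups per subunit; each
#'   group's total must be positive.
#' @return `dissimilarity_index()`: a number in `[0, 1]`.
#' @export
dissimilarity_index <- function(b, w) {
  if (length(b) != length(w)) stop("`b` and `w` lengths differ")
  if (length(b) < 2L) stop("need at least 2 subunits")
  if (any(b < 0) || any(w < 0)) stop("counts must be non-negative")
  B <- sum(b); W <- sum(w)
  if (B <= 0 || W <= 0) stop("each group must have a positive total")
  sum(abs(b / B - w / W)) / 2
}

#' @rdname dissimilarity_index
#' @param region factor/character of region membership per tract; regions
#'   with fewer than 2 tracts or a zero group total get `NA`.
#' @export
dissimilarity_by_region <- function(b, w, region) {
  stopifnot(length(b) == length(w), length(b) == length(region))
  out <- rep(NA_real_, length(b))
  for (r in unique(region)) {
    idx <- which(region == r)
    if (length(idx) < 2L) next
    if (sum(b[idx]) <= 0 || sum(w[idx]) <= 0) next
    out[idx] <- dissimilarity_index(b[idx], w[idx])
  }
  out
}

#' Compute every tract-level analysis variable
#'
#' Augments a tract table with all the variables the spatial analysis
#' consumes: the three ICE variants (**inverted**, so higher = more
#' unequal), the low/moderate/high flood-risk property proportions and the
#' per-level FF7-FF10 shares, the grouped-data Gini coefficient, and the
#' regional Index of Dissimilarity. Prevalence columns pass through
#' unchanged. Tracts with zero population, zero households, or zero
#' properties get `NA` in the affected columns (with a logged count); they
#' are never imputed.
#'
#' @param x a `tract_data` bundle, or a tract data frame (then `properties`
#'   must be given).
#' @param properties property table with columns `tract_id`, `ff`
#'   (ignored when `x` is a `tract_data`).
#' @param brackets income bracket bounds matching the `hh_inc_b*` columns
#'   (defaults to the generator's brackets).
#' @param verbose log exclusion counts?
#' @return the tract data frame with the index columns appended:
#'   `ice_income`, `ice_race`, `ice_race_income` (inverted),
#'   `p_flood_low/moderate/high`, `p_ff7`..`p_ff10`, `gini`, `iod`.
#' @export
compute_indices <- function(x, properties = NULL, brackets = NULL,
                            verbose = FALSE) {
  if (inherits(x, "tract_data")) {
    tracts <- x$tracts
    properties <- x$properties
    brackets <- brackets %||% x$config$income_brackets
  } else {
    tracts <- as.data.frame(x)
    if (is.null(properties)) stop("`properties` is required with a plain table")
    brackets <- brackets %||% default_income_brackets()
  }
  need <- c("tract_id", "pop_total", "hh_total", "pop_nonwhite", "pop_white",
            "hh_low_income", "hh_high_income", "pop_nonwhite_low_income",
            "pop_white_high_income")
  miss <- setdiff(need, names(tracts))
  if (length(miss)) stop("tract table lacks columns: ", paste(miss, collapse = ", "))

  out <- tracts
  suppress_zero <- function(expr) withCallingHandlers(expr,
    warning = function(w) {
      flood_log("%s", conditionMessage(w), verbose = verbose)
      invokeRestart("muffleWarning")
    })
  out$ice_income <- suppress_zero(invert(index_vector(
    ice(tracts$hh_high_income, tracts$hh_low_income, tracts$hh_total),
    "ice_income")))
  out$ice_race <- suppress_zero(invert(index_vector(
    ice(tracts$pop_white, tracts$pop_nonwhite, tracts$pop_total),
    "ice_race")))
  out$ice_race_income <- suppress_zero(invert(index_vector(
    ice(tracts$pop_white_high_income, tracts$pop_nonwhite_low_income,
        tracts$pop_total), "ice_race_income")))
  out$ice_income <- as.numeric(out$ice_income)
  out$ice_race <- as.numeric(out$ice_race)
  out$ice_race_income <- as.numeric(out$ice_race_income)

  fl <- .tract_flood_table(properties, tracts$tract_id)
  out <- cbind(out, fl[, -1L, drop = FALSE])
  n_missing <- sum(is.na(fl$p_flood_high))
  if (n_missing > 0)
    flood_log("%d tract(s) with zero properties: flood proportions NA",
              n_missing, verbose = verbose)

  bcols <- grep("^hh_inc_b", names(tracts), value = TRUE)
  if (length(bcols) == length(brackets)) {
    out$gini <- vapply(seq_len(nrow(tracts)), function(i) {
      cts <- as.numeric(tracts[i, bcols])
      if (sum(cts) <= 0) return(NA_real_)
      gini_grouped(cts, brackets)
    }, numeric(1))
  } else {
    flood_log("no bracket columns matching the given brackets: gini skipped",
              verbose = verbose)
  }
  if ("region" %in% names(tracts)) {
    out$iod <- dissimilarity_by_region(tracts$pop_nonwhite, tracts$pop_white,
                                       tracts$region)
  }
  out
}
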