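#' Population z-standardization
#'
#' Centers and scales a variable with the population (divide-by-n) standard
#' deviation, the convention under which \eqn{\sum_i z_i^2 = n} and the
#' Moran cross-product formulas take their simple forms.
#'
#' @param x numeric vector with at least two distinct, non-missing values.
#' @return numeric vector with mean 0 and mean square 1.
#' @export
standardize <- function(x) {
  if (!is.numeric(x)) stop("`x` must be numeric")
  if (anyNA(x)) stop("`x` contains missing values; drop or flag them first")
  n <- length(x)
  if (n < 2L) stop("need at least 2 values to standardize")
  s <- sqrt(sum((x - mean(x))^2) / n)
  if (s == 0) stop("degenerate variable: zero variance")
  (x - mean(x)) / s
}

# restrict a weights object to its non-island subgraph; neighbors of a
# non-island are never islands, so the subgraph is self-contained
.active_index <- function(w) {
  if (length(w$islands) == 0L) return(seq_len(w$n))
  setdiff(seq_len(w$n), w$islands)
}

#' Global Moran's I (univariate or bivariate)
#'
#' Computes \eqn{I = (n/S_0) \sum_{ij} w_{ij} z_{x,i} z_{y,j} / \sum_i
#' z_{x,i}^2} over non-island tracts. With `zy = zx` this is the classical
#' univariate statistic; otherwise it is the bivariate form relating `zx`
#' to the spatial lag of `zy`. With row-standardized weights and
#' population-standardized inputs it reduces to the mean of
#' \eqn{z_{x,i} \cdot \mathrm{lag}_i(z_y)}.
#'
#' @param zx,zy standardized numeric vectors (see [standardize()]), aligned
#'   with the weights object. `zy` defaults to `zx`.
#' @param w a `spatial_weights`.
#' @return the global Moran's I, a single number.
#' @export
global_moran <- function(zx, w, zy = zx) {
  stopifnot(inherits(w, "spatial_weights"))
  if (length(zx) != w$n || length(zy) != w$n)
    stop("variables and weights cover different tract sets")
  act <- .active_index(w)
  if (length(act) == 0L) stop("all tracts are islands; Moran's I undefined")
  s0 <- sum(unlist(w$weights[act]))
  lag_raw <- spatial_lag(w, zy)
  num <- sum(zx[act] * lag_raw[act])
  (length(act) / s0) * num / sum(zx[act]^2)
}

#' Local Moran's I (univariate or bivariate)
#'
#' Per-tract statistics \eqn{I_i = z_{x,i} \sum_j w_{ij} z_{y,j}}. Islands
#' get `NA`. Under row-standardized weights the mean of the local
#' statistics over non-island tracts equals [global_moran()].
#'
#' @inheritParams global_moran
#' @return numeric vector of local statistics, `NA` for islands.
#' @export
local_moran <- function(zx, w, zy = zx) {
  stopifnot(inherits(w, "spatial_weights"))
  if (length(zx) != w$n || length(zy) != w$n)
    stop("variables and weights cover different tract sets")
  zx * spatial_lag(w, zy)
}

#' Conditional-permutation pseudo p-values for local Moran statistics
#'
#' For each tract i the focal value \eqn{z_{x,i}} is held fixed and the
#' values of `zy` at *all other* tracts are randomly reassigned to i's
#' neighbor positions (conditional randomization), `permutations` times.
#' The pseudo p-value is \eqn{(R+1)/(M+1)} where R counts permuted
#' statistics at least as extreme as the observed one.
#'
#' The default `alternative = "directed"` counts extremeness in the
#' direction of the observed statistic (the GeoDa convention). Note that
#' under the null this behaves like a two-tailed test run at twice the
#' nominal level: about 2\eqn{\alpha} of tracts reach `p <` \eqn{\alpha}
#' on spatially random data. `"two.sided"` doubles the smaller tail and is
#' calibrated at its nominal level; `"greater"`/`"less"` are fixed
#' one-tailed alternatives.
#'
#' Each tract draws from its own RNG substream derived from `(seed, tract
#' index)`, so results do not depend on evaluation order.
#'
#' @inheritParams global_moran
#' @param permutations number of conditional permutations M (at least 99;
#'   9999 is the conventional reporting choice).
#' @param seed integer seed governing all permutation draws.
#' @param alternative extremeness convention, see Details.
#' @return numeric vector of pseudo p-values in (0, 1]; `NA` for islands.
#' @export
lisa_pvalues <- function(zx, w, zy = zx, permutations = 999, seed = NULL,
                         alternative = c("directed", "two.sided",
                                         "greater", "less")) {
  stopifnot(inherits(w, "spatial_weights"))
  alternative <- match.arg(alternative)
  M <- as.integer(permutations)
  if (is.na(M) || M < 99L) stop("`permutations` must be at least 99")
  if (length(zx) != w$n || length(zy) != w$n)
    stop("variables and weights cover different tract sets")
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  n <- w$n
  act <- .active_index(w)  # islands contribute neither p-values nor pool draws
  p <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    nb <- w$neighbours[[i]]
    k <- length(nb)
    if (k == 0L) next  # island: no p-value, ever
    wts <- w$weights[[i]]
    obs <- sum(wts * zy[nb]) * zx[i]
    pool <- zy[setdiff(act, i)]
    npool <- length(pool)
    perm <- with_seed(stream_seed(seed, i), {
      m <- matrix(0, nrow = k, ncol = M)
      for (r in seq_len(M)) m[, r] <- pool[sample.int(npool, k)]
      m
    })
    iperm <- as.numeric(crossprod(wts, perm)) * zx[i]
    # ties: permuted sums of the same values in another order can differ
    # from `obs` by one ulp; "at least as extreme" must count them
    eps <- 1e-10 * max(1, abs(obs))
    r_hi <- sum(iperm >= obs - eps)
    r_lo <- sum(iperm <= obs + eps)
    p[i] <- switch(alternative,
      directed  = if (obs >= 0) (r_hi + 1) / (M + 1) else (r_lo + 1) / (M + 1),
      greater   = (r_hi + 1) / (M + 1),
      less      = (r_lo + 1) / (M + 1),
      two.sided = min(1, 2 * (min(r_hi, r_lo) + 1) / (M + 1)))
  }
  p
}

#' Cluster/outlier quadrant classification
#'
#' Labels each tract by the sign of its focal z-value and of its spatial
#' lag, gated by significance: `HH` (high surrounded by high), `LL`, `HL`
#' (high outlier in a low neighborhood), `LH`, `NS` for non-significant
#' tracts, and `ISLAND` where no statistic exists. The sign reference is
#' the standardized mean (z = 0); an exact zero in either coordinate is a
#' tie and classified `NS`.
#'
#' @param zx standardized focal variable.
#' @param lag spatial lag of the (standardized) second variable.
#' @param p pseudo p-values from [lisa_pvalues()] (`NA` for islands).
#' @param alpha significance threshold (a tract is labeled only if
#'   `p < alpha`).
#' @return factor with levels `HH, LL, LH, HL, NS, ISLAND`.
#' @export
classify_quadrants <- function(zx, lag, p, alpha = 0.05) {
  stopifnot(length(zx) == length(lag), length(zx) == length(p))
  out <- rep("NS", length(zx))
  out[is.na(p)] <- "ISLAND"
  sig <- !is.na(p) & p < alpha & zx != 0 & !is.na(lag) & lag != 0
  out[sig & zx > 0 & lag > 0] <- "HH"
  out[sig & zx < 0 & lag < 0] <- "LL"
  out[sig & zx > 0 & lag < 0] <- "HL"
  out[sig & zx < 0 & lag > 0] <- "LH"
  factor(out, levels = c("HH", "LL", "LH", "HL", "NS", "ISLAND"))
}
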