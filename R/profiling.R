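#' Rural-urban commuting area classes
#'
#' Collapses RUCA codes 1..10 into the three-way classification used for
#' cluster profiling: urban (codes 1-3), suburban (4-7), rural (8-10).
#'
#' @param code integer vector of RUCA codes in 1..10.
#' @return factor with levels `urban`, `suburban`, `rural`.
#' @examples
#' ruca_class(c(1, 3, 4, 7, 8, 10))
#' @export
ruca_class <- function(code) {
  if (any(is.na(code)) || any(code < 1 | code > 10 | code != round(code)))
    stop("RUCA codes must be integers in 1..10")
  cls <- cut(code, breaks = c(0, 3, 7, 10),
             labels = c("urban", "suburban", "rural"))
  factor(cls, levels = c("urban", "suburban", "rural"))
}

# coerce a lisa fit or a label vector to cluster labels
.as_labels <- function(labels) {
  if (inherits(labels, "lisa")) labels <- labels$quadrant
  factor(as.character(labels), levels = c("HH", "LL", "LH", "HL", "NS", "ISLAND"))
}

#' RUCA cross-tabulation of one cluster type
#'
#' Counts and percentages of urban/suburban/rural tracts within one LISA
#' cluster type. Percentages are `100 * count / cluster size`; an empty
#' cluster yields zero counts and missing percentages.
#'
#' @param labels cluster labels (a factor/character vector or a [lisa()]
#'   fit).
#' @param ruca RUCA codes (1..10) or a factor from [ruca_class()], aligned
#'   with `labels`.
#' @param cluster_type one of `"HH"`, `"LL"`, `"LH"`, `"HL"`.
#' @return list with integer `counts` and numeric `percentages`, both named
#'   `rural`, `suburban`, `urban`.
#' @export
crosstab_ruca <- function(labels, ruca, cluster_type) {
  labels <- .as_labels(labels)
  cls <- if (is.factor(ruca) &&
             all(levels(ruca) %in% c("urban", "suburban", "rural")))
    ruca else ruca_class(ruca)
  stopifnot(length(labels) == length(cls))
  cluster_type <- match.arg(cluster_type, c("HH", "LL", "LH", "HL"))
  member <- labels == cluster_type
  counts <- c(rural = sum(member & cls == "rural"),
              suburban = sum(member & cls == "suburban"),
              urban = sum(member & cls == "urban"))
  total <- sum(counts)
  pct <- if (total > 0) 100 * counts / total
         else stats::setNames(rep(NA_real_, 3), names(counts))
  list(counts = counts, percentages = pct, cluster_type = cluster_type,
       n = total)
}

#' Membership, population, and density of one cluster type
#'
#' Tract count, summed population, and population density of a cluster.
#' Density is the ratio of sums (total population over total land area,
#' persons per square mile), not the mean of tract densities.
#'
#' @inheritParams crosstab_ruca
#' @param tracts tract data frame with `pop_total` and `area_sqmi` columns.
#' @return list with `tracts`, `population`, `density` (density is `NA`
#'   for an empty cluster or zero total area).
#' @export
cluster_population_summary <- function(labels, tracts, cluster_type) {
  labels <- .as_labels(labels)
  stopifnot(length(labels) == nrow(tracts),
            all(c("pop_total", "area_sqmi") %in% names(tracts)))
  cluster_type <- match.arg(cluster_type,
                            c("HH", "LL", "LH", "HL", "NS", "ISLAND"))
  member <- labels == cluster_type
  pop <- sum(tracts$pop_total[member])
  area <- sum(tracts$area_sqmi[member])
  list(cluster_type = cluster_type,
       tracts = sum(member),
       population = pop,
       density = if (sum(member) == 0L || area <= 0) NA_real_ else pop / area)
}

#' Demographic comparison of a cluster against the state
#'
#' For each indicator, the cluster mean (unweighted over member tracts),
#' the state mean (over *all* tracts), their difference (`delta`, the
#' value conventionally printed in parentheses next to a cluster mean),
#' and a Welch two-sample t-test of member versus non-member tracts with
#' `*`/`**`/`***` significance stars. A one-sample mode tests the member
#' tracts against the all-tract mean treated as a fixed reference.
#'
#' An indicator that is constant within both groups has an undefined t
#' statistic: when the two constants differ the statistic is reported as
#' infinite with the p-value at the numerical floor, and when they
#' coincide the test is reported missing.
#'
#' @inheritParams cluster_population_summary
#' @param indicators character vector of numeric column names in `tracts`.
#' @param alpha significance level used only for the `significant` flag.
#' @param mode `"two.sample"` (Welch, member vs non-member tracts; default)
#'   or `"one.sample"` (members vs the fixed all-tract mean).
#' @param weighted population-weight the means by `pop_total`?
#' @return data frame with one row per indicator: `indicator`,
#'   `cluster_mean`, `state_mean`, `delta`, `t`, `df`, `p`, `stars`,
#'   `significant`.
#' @export
demographic_comparison <- function(labels, tracts, cluster_type, indicators,
                                   alpha = 0.05,
                                   mode = c("two.sample", "one.sample"),
                                   weighted = FALSE) {
  labels <- .as_labels(labels)
  mode <- match.arg(mode)
  stopifnot(length(labels) == nrow(tracts))
  cluster_type <- match.arg(cluster_type, c("HH", "LL", "LH", "HL"))
  miss <- setdiff(indicators, names(tracts))
  if (length(miss)) stop("indicators not in table: ", paste(miss, collapse = ", "))
  member <- labels == cluster_type
  if (sum(member) < 2L)
    stop("cluster ", cluster_type, " has fewer than 2 member tracts")

  wmean <- function(v, idx) {
    if (weighted) stats::weighted.mean(v[idx], tracts$pop_total[idx])
    else mean(v[idx])
  }
  rows <- lapply(indicators, function(ind) {
    v <- tracts[[ind]]
    cm <- wmean(v, member)
    sm <- wmean(v, rep(TRUE, length(v)))
    inside <- v[member]; outside <- v[!member]
    tt <- tryCatch({
      if (mode == "two.sample") stats::t.test(inside, outside)
      else stats::t.test(inside, mu = sm)
    }, error = function(e) NULL)
    if (is.null(tt)) {
      # degenerate: constant data; distinct constants => infinitely
      # separated groups, identical constants => no test
      ref <- if (mode == "two.sample") mean(outside) else sm
      if (isTRUE(all.equal(mean(inside), ref))) {
        tstat <- NA_real_; pval <- NA_real_; dfree <- NA_real_
      } else {
        tstat <- sign(mean(inside) - ref) * Inf
        pval <- .Machine$double.eps
        dfree <- NA_real_
      }
    } else {
      tstat <- unname(tt$statistic); pval <- tt$p.value
      dfree <- unname(tt$parameter)
    }
    data.frame(indicator = ind, cluster_mean = cm, state_mean = sm,
               delta = cm - sm, t = tstat, df = dfree, p = pval,
               stars = p_stars(pval),
               significant = !is.na(pval) & pval < alpha,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Full cluster profile of a LISA fit
#'
#' Packages the three conventional cluster reports: (1) membership,
#' population, and density per cluster type; (2) demographic means,
#' deltas against the state average, and Welch t-tests for selected
#' cluster types; (3) the RUCA urban/suburban/rural cross-tabulation per
#' cluster type.
#'
#' @param fit a [lisa()] fit (or a label vector).
#' @param tracts tract data frame aligned with the fit (needs `pop_total`,
#'   `area_sqmi`, `ruca`, and the indicator columns).
#' @param indicators columns for the demographic comparison; defaults to
#'   every prevalence column plus the raw demographic shares present.
#' @param compare_types cluster types to run the demographic comparison
#'   for (default `"HH"`, the type of substantive interest).
#' @param alpha significance level for flagging.
#' @return object of class `cluster_profile`: list with `membership`
#'   (data frame over HH/LL/LH/HL/NS/ISLAND), `comparisons` (named list of
#'   data frames), `ruca` (data frame of counts and percentages per
#'   cluster type), `alpha`.
#' @export
cluster_profile <- function(fit, tracts, indicators = NULL,
                            compare_types = "HH", alpha = 0.05) {
  labels <- .as_labels(fit)
  stopifnot(length(labels) == nrow(tracts))
  if (is.null(indicators)) {
    cand <- c(grep("^prev_", names(tracts), value = TRUE),
              intersect(c("pop_total", "pop_nonwhite", "hh_low_income"),
                        names(tracts)))
    indicators <- cand
  }
  types_all <- c("HH", "LL", "LH", "HL", "NS", "ISLAND")
  membership <- do.call(rbind, lapply(types_all, function(tp) {
    s <- cluster_population_summary(labels, tracts, tp)
    data.frame(cluster_type = tp, tracts = s$tracts,
               population = s$population, density = s$density,
               stringsAsFactors = FALSE)
  }))
  comparisons <- list()
  for (tp in compare_types) {
    if (sum(labels == tp) >= 2L)
      comparisons[[tp]] <- demographic_comparison(labels, tracts, tp,
                                                  indicators, alpha = alpha)
  }
  ruca_tab <- do.call(rbind, lapply(c("HH", "LL", "LH", "HL"), function(tp) {
    ct <- crosstab_ruca(labels, tracts$ruca, tp)
    data.frame(cluster_type = tp,
               rural_n = ct$counts[["rural"]],
               rural_pct = ct$percentages[["rural"]],
               suburban_n = ct$counts[["suburban"]],
               suburban_pct = ct$percentages[["suburban"]],
               urban_n = ct$counts[["urban"]],
               urban_pct = ct$percentages[["urban"]],
               stringsAsFactors = FALSE)
  }))
  structure(list(membership = membership, comparisons = comparisons,
                 ruca = ruca_tab, alpha = alpha),
            class = "cluster_profile")
}

#' @export
print.cluster_profile <- function(x, ...) {
  cat("Cluster membership and population:\n")
  m <- x$membership
  m$density <- round(m$density, 2)
  print(m, row.names = FALSE)
  cat("\nRUCA distribution (counts and % of cluster):\n")
  r <- x$ruca
  for (cc in grep("_pct$", names(r))) r[[cc]] <- round(r[[cc]], 1)
  print(r, row.names = FALSE)
  for (tp in names(x$comparisons)) {
    cat(sprintf("\n%s cluster vs state average (alpha = %g):\n", tp, x$alpha))
    d <- x$comparisons[[tp]]
    d$cluster_mean <- signif(d$cluster_mean, 4)
    d$state_mean <- signif(d$state_mean, 4)
    d$delta <- signif(d$delta, 4)
    d$t <- round(d$t, 2); d$p <- signif(d$p, 2)
    print(d[, c("indicator", "cluster_mean", "state_mean", "delta",
                "t", "p", "stars")], row.names = FALSE)
  }
  invisible(x)
}
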