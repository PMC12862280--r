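#' Planted bivariate cluster block
#'
#' Describes a rectangular block of lattice tracts whose flood and
#' inequality propensities are shifted upward, planting a joint
#' high-flood/high-inequality cluster the bivariate LISA should recover.
#' Effect sizes are on the standardized latent scale (units of one
#' background standard deviation).
#'
#' @param rows,cols length-2 integer vectors, inclusive row/column ranges
#'   of the block on the lattice.
#' @param flood upward shift of the flood propensity inside the block.
#' @param inequality upward shift of the deprivation propensities (nonwhite
#'   share and low-income share both rise; high-income share falls).
#' @return an object of class `planted_block`.
#' @export
planted_block <- function(rows, cols, flood = 2, inequality = 2) {
  stopifnot(length(rows) == 2L, length(cols) == 2L,
            rows[1] <= rows[2], cols[1] <= cols[2],
            is.numeric(flood), is.numeric(inequality))
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 flood = flood, inequality = inequality),
            class = "planted_block")
}

default_income_brackets <- function() {
  list(c(0, 25000), c(25000, 50000), c(50000, 75000),
       c(75000, 125000), c(125000, Inf))
}

#' Configuration for the synthetic tract generator
#'
#' Bundles and validates every knob of [synthesize_tracts()]. The defaults
#' are the package's reference study conditions: a 20-by-20 lattice of
#' one-square-mile tracts, moderate spatial autocorrelation
#' (`rho = 0.6`), one 6-by-6 planted block with a two-standard-deviation
#' shift in both flood and inequality propensities, 40 scored properties
#' per tract, and a base tract population of 4,000 that tapers from the
#' urban lattice center to the rural edge.
#'
#' @param n_rows,n_cols lattice dimensions (positive integers).
#' @param rho SAR autocorrelation strength in `[0, 0.99]`.
#' @param planted_blocks list of [planted_block()]s (possibly empty); each
#'   must lie inside the lattice.
#' @param income_brackets ordered list of `c(lower, upper)` household
#'   income bounds in dollars; the first bracket must top out at the
#'   low-income cut ($25,000) and the last must start at the high-income
#'   cut ($125,000) so the ICE Income extremes are bracket-exact.
#' @param n_properties_per_tract number of FloodFactor-scored properties
#'   per tract.
#' @param tract_population base population per tract before the
#'   urban-rural density taper.
#' @param cell_size tract side length (miles); land area is its square.
#' @param stochastic_counts if `FALSE` (default) counts are deterministic
#'   rounded transforms of the latent fields, which keeps
#'   parameter-recovery tests low-variance; if `TRUE` counts and property
#'   scores are drawn binomially/normally around the same targets.
#' @param seed integer master seed; every random draw flows from it.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_rows = 20, n_cols = 20, rho = 0.6,
                       planted_blocks = list(planted_block(c(4, 9), c(4, 9))),
                       income_brackets = default_income_brackets(),
                       n_properties_per_tract = 40,
                       tract_population = 4000,
                       cell_size = 1,
                       stochastic_counts = FALSE,
                       seed) {
  if (missing(seed)) stop("`seed` is required: the generator is fully seeded")
  stopifnot(n_rows >= 1, n_cols >= 1,
            n_rows == round(n_rows), n_cols == round(n_cols))
  if (!is.numeric(rho) || rho < 0 || rho > 0.99)
    stop("`rho` must lie in [0, 0.99] (strictly below 1: SAR inverse)")
  if (!is.list(planted_blocks)) stop("`planted_blocks` must be a list")
  for (b in planted_blocks) {
    if (!inherits(b, "planted_block")) stop("planted blocks must be built with planted_block()")
    if (b$rows[1] < 1 || b$rows[2] > n_rows || b$cols[1] < 1 || b$cols[2] > n_cols)
      stop("planted block falls outside the lattice")
  }
  if (length(income_brackets) < 3L) stop("need at least 3 income brackets")
  lowers <- vapply(income_brackets, `[`, numeric(1), 1L)
  uppers <- vapply(income_brackets, `[`, numeric(1), 2L)
  if (any(lowers >= uppers)) stop("income brackets must have lower < upper")
  if (any(uppers[-length(uppers)] != lowers[-1L]))
    stop("income brackets must be contiguous and ordered")
  if (uppers[1L] != 25000 || lowers[length(lowers)] != 125000)
    stop("first bracket must end at $25,000 and last start at $125,000 ",
         "(the ICE Income extreme cuts)")
  stopifnot(n_properties_per_tract >= 1, tract_population >= 100,
            cell_size > 0)
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 rho = rho, planted_blocks = planted_blocks,
                 income_brackets = income_brackets,
                 n_properties_per_tract = as.integer(n_properties_per_tract),
                 tract_population = as.integer(tract_population),
                 cell_size = cell_size,
                 stochastic_counts = isTRUE(stochastic_counts),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("sim_config: %dx%d lattice, rho = %g, %d planted block(s), seed %d\n",
              x$n_rows, x$n_cols, x$rho, length(x$planted_blocks), x$seed))
  invisible(x)
}

# clip latent propensities, warning once as required by the generator
# contract (out-of-range planted effects must not silently propagate)
.clip_latent <- function(f, limit = 6, what = "latent") {
  bad <- abs(f) > limit
  if (any(bad)) {
    warning(sum(bad), " ", what,
            " value(s) exceeded +/-", limit, " and were clipped")
    f <- pmin(pmax(f, -limit), limit)
  }
  f
}

# largest-remainder apportionment of `total` into shares `p` (sums to total)
.apportion <- function(total, p) {
  if (total <= 0) return(rep(0L, length(p)))
  p <- p / sum(p)
  raw <- total * p
  base <- floor(raw)
  left <- as.integer(round(total - sum(base)))
  if (left > 0) {
    idx <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[idx] <- base[idx] + 1
  }
  as.integer(base)
}

# concentric urban-to-rural gradient: normalized Chebyshev distance of each
# tract from the lattice center, in [0, 1]
.center_distance <- function(n_rows, n_cols) {
  ci <- (n_rows + 1) / 2; cj <- (n_cols + 1) / 2
  d <- outer(seq_len(n_rows), seq_len(n_cols),
             function(i, j) pmax(abs(i - ci), abs(j - cj)))
  dmax <- max(d)
  if (dmax == 0) d[] <- 0 else d <- d / dmax
  as.vector(t(d))  # row-major, matching make_lattice ids
}

#' Generate a synthetic tract table
#'
#' Builds a full synthetic study area from a [sim_config()]: a polygon
#' lattice, queen weights, four spatially autocorrelated latent fields
#' (flood, nonwhite-share, low-income, health propensities), and a tract
#' attribute table emulating the structure of census demographic counts,
#' per-property ordinal flood scores, chronic-condition prevalences, and
#' rural-urban commuting codes.
#'
#' Latent fields are SAR draws standardized to mean 0, variance 1;
#' planted blocks shift the flood and deprivation propensities. Counts are
#' deterministic rounded logistic transforms of the fields (binomial
#' sampling with `stochastic_counts = TRUE`); FloodFactor scores arise by
#' binning per-property latent values at the fixed decile edges of the
#' standard normal, so all ten levels occur at background settings;
#' RUCA codes grow 1 to 10 along concentric rings from the lattice center.
#' Identical configs (including the seed) give bit-identical output.
#'
#' @param config a [sim_config()].
#' @param verbose emit per-stage messages?
#' @return An object of class `tract_data`: a list with `tracts` (the
#'   attribute data frame, row order = lattice id order), `properties`
#'   (one row per scored property: `tract_id`, `ff`), `geometry`
#'   (a [tract_geometry()]), `weights` (row-standardized queen weights),
#'   and `config`.
#' @export
synthesize_tracts <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  geom <- make_lattice(cfg$n_rows, cfg$n_cols, cfg$cell_size)
  w <- queen_weights(geom, style = "W")
  n <- geom$n
  flood_log("generated %dx%d lattice (%d tracts)", cfg$n_rows, cfg$n_cols, n,
            verbose = verbose)

  # independent seeded substreams per latent field
  f_flood <- standardize(sar_field(w, cfg$rho, seed = stream_seed(cfg$seed, 101L)))
  f_race  <- standardize(sar_field(w, cfg$rho, seed = stream_seed(cfg$seed, 102L)))
  f_inc   <- standardize(sar_field(w, cfg$rho, seed = stream_seed(cfg$seed, 103L)))
  f_prev  <- standardize(sar_field(w, cfg$rho, seed = stream_seed(cfg$seed, 104L)))

  row_of <- rep(seq_len(cfg$n_rows), each = cfg$n_cols)
  col_of <- rep(seq_len(cfg$n_cols), times = cfg$n_rows)
  in_block <- rep(FALSE, n)
  for (b in cfg$planted_blocks) {
    m <- row_of >= b$rows[1] & row_of <= b$rows[2] &
         col_of >= b$cols[1] & col_of <= b$cols[2]
    in_block <- in_block | m
    f_flood[m] <- f_flood[m] + b$flood
    f_race[m]  <- f_race[m]  + b$inequality
    f_inc[m]   <- f_inc[m]   + b$inequality
  }
  f_flood <- .clip_latent(f_flood, what = "flood propensity")
  f_race  <- .clip_latent(f_race,  what = "nonwhite-share propensity")
  f_inc   <- .clip_latent(f_inc,   what = "low-income propensity")
  # deprivation feeds the health field: flood-sensitive chronic burden
  # tracks economic deprivation in the emulated inputs
  f_hlth <- 0.6 * f_inc + 0.8 * f_prev

  dist <- .center_distance(cfg$n_rows, cfg$n_cols)
  ruca <- pmax(1L, pmin(10L, as.integer(ceiling(10 * dist))))
  region <- paste0("Q", 1L + (row_of > cfg$n_rows / 2) * 2L +
                           (col_of > cfg$n_cols / 2))

  # density taper: urban center about 3x the rural edge
  pop <- as.integer(round(cfg$tract_population * (1.5 - dist)))
  hh <- as.integer(round(pop / 2.5))

  share_nonwhite <- stats::plogis(stats::qlogis(0.30) + 0.9 * f_race)
  share_low  <- stats::plogis(stats::qlogis(0.20) + 0.8 * f_inc)
  share_high <- stats::plogis(stats::qlogis(0.15) - 0.8 * f_inc)

  det <- !cfg$stochastic_counts
  draw_count <- function(size, prob, stream) {
    if (det) as.integer(round(size * prob))
    else with_seed(stream_seed(cfg$seed, stream),
                   as.integer(stats::rbinom(length(size), size, prob)))
  }
  pop_nonwhite <- draw_count(pop, share_nonwhite, 201L)
  pop_white    <- draw_count(pop - pop_nonwhite, 0.95, 202L)
  hh_low  <- draw_count(hh, share_low, 203L)
  hh_high <- draw_count(hh, share_high, 204L)
  # race-income cross counts for the combined ICE variant
  pop_nw_low <- draw_count(pop_nonwhite, share_low, 205L)
  pop_w_high <- draw_count(pop_white, share_high, 206L)

  nb <- length(cfg$income_brackets)
  mid_shares <- c(0.40, 0.35, 0.25)
  if (nb != 5L) mid_shares <- rep(1 / (nb - 2L), nb - 2L)
  brackets <- matrix(0L, n, nb)
  brackets[, 1L] <- hh_low
  brackets[, nb] <- hh_high
  middle <- hh - hh_low - hh_high
  middle[middle < 0L] <- 0L
  for (i in seq_len(n))
    brackets[i, 2:(nb - 1L)] <- .apportion(middle[i], mid_shares)
  colnames(brackets) <- sprintf("hh_inc_b%d", seq_len(nb))

  # per-property flood scores: decile binning of standard-normal scale
  m <- cfg$n_properties_per_tract
  spread <- stats::qnorm((seq_len(m) - 0.5) / m)
  edges <- stats::qnorm(seq_len(9L) / 10)
  prop_tract <- rep(geom$ids, each = m)
  v <- if (det) {
    as.vector(vapply(f_flood, function(f) (f + spread) / sqrt(2), numeric(m)))
  } else {
    with_seed(stream_seed(cfg$seed, 207L),
              (rep(f_flood, each = m) + stats::rnorm(n * m)) / sqrt(2))
  }
  ff <- findInterval(v, edges) + 1L
  properties <- data.frame(tract_id = prop_tract, ff = as.integer(ff),
                           stringsAsFactors = FALSE)

  prev_base <- c(asthma = 0.103, copd = 0.069, depression = 0.221,
                 diabetes = 0.109, kidney_disease = 0.031)
  prevs <- vapply(prev_base, function(b)
    stats::plogis(stats::qlogis(b) + 0.45 * f_hlth), numeric(n))
  colnames(prevs) <- paste0("prev_", names(prev_base))

  tracts <- data.frame(
    tract_id = geom$ids, row = row_of, col = col_of,
    region = region, ruca = ruca,
    area_sqmi = tract_areas(geom),
    pop_total = pop, hh_total = hh,
    pop_nonwhite = pop_nonwhite, pop_white = pop_white,
    hh_low_income = hh_low, hh_high_income = hh_high,
    pop_nonwhite_low_income = pop_nw_low,
    pop_white_high_income = pop_w_high,
    in_planted_block = in_block,
    stringsAsFactors = FALSE)
  tracts <- cbind(tracts, as.data.frame(brackets), as.data.frame(prevs))
  flood_log("synthesized %d tracts, %d properties", n, nrow(properties),
            verbose = verbose)

  structure(list(tracts = tracts, properties = properties,
                 geometry = geom, weights = w, config = cfg),
            class = "tract_data")
}

#' @export
print.tract_data <- function(x, ...) {
  cat(sprintf("tract_data: %d tracts, %d properties, %d planted tract(s)\n",
              nrow(x$tracts), nrow(x$properties), sum(x$tracts$in_planted_block)))
  print(x$config)
  invisible(x)
}

#' Write a tract data bundle to disk
#'
#' Writes the interchange triple: `tracts.geojson` (geometry plus tract
#' id), `tracts.csv` (attributes keyed by tract id), and `properties.csv`
#' (per-property flood scores).
#'
#' @param x a `tract_data` bundle from [synthesize_tracts()].
#' @param dir output directory (created if needed).
#' @return invisibly, the three file paths.
#' @export
write_tract_data <- function(x, dir) {
  stopifnot(inherits(x, "tract_data"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gj <- file.path(dir, "tracts.geojson")
  cs <- file.path(dir, "tracts.csv")
  pr <- file.path(dir, "properties.csv")
  write_geojson(x$geometry, gj,
                properties = x$tracts[, "area_sqmi", drop = FALSE])
  utils::write.csv(x$tracts, cs, row.names = FALSE)
  utils::write.csv(x$properties, pr, row.names = FALSE)
  invisible(c(geojson = gj, tracts = cs, properties = pr))
}
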