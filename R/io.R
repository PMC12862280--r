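#' Join tract geometry with an attribute table
#'
#' Reads polygon geometry from GeoJSON and tract attributes from CSV and
#' joins them on `tract_id`. Every GeoJSON feature must have exactly one
#' CSV row; the result preserves GeoJSON feature order. Duplicated ids on
#' either side, or CSV rows missing for some features, are errors that
#' name the offending ids.
#'
#' @param geojson_path path to a FeatureCollection of tract polygons
#'   (features carry a `tract_id` property).
#' @param csv_path path to an attribute CSV keyed by `tract_id`.
#' @return list with `tracts` (the joined data frame, feature order) and
#'   `geometry` (a [tract_geometry()]).
#' @export
read_tract_table <- function(geojson_path, csv_path) {
  gj <- read_geojson(geojson_path)
  attrs <- utils::read.csv(csv_path, stringsAsFactors = FALSE)
  if (!"tract_id" %in% names(attrs)) stop("CSV lacks a `tract_id` column")
  attrs$tract_id <- as.character(attrs$tract_id)
  ids <- gj$geometry$ids
  dup <- attrs$tract_id[duplicated(attrs$tract_id)]
  if (length(dup)) stop("duplicated tract ids in CSV: ",
                        paste(unique(dup), collapse = ", "))
  missing_ids <- setdiff(ids, attrs$tract_id)
  if (length(missing_ids))
    stop("CSV has no row for tract id(s): ",
         paste(missing_ids, collapse = ", "))
  extra <- setdiff(attrs$tract_id, ids)
  if (length(extra))
    warning(length(extra), " CSV row(s) without geometry dropped: ",
            paste(utils::head(extra, 5), collapse = ", "))
  tracts <- attrs[match(ids, attrs$tract_id), , drop = FALSE]
  rownames(tracts) <- NULL
  list(tracts = tracts, geometry = gj$geometry)
}

# read a run/sim configuration from JSON or YAML
read_config_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs needs the `yaml` package")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

# build a sim_config from a plain list (e.g. parsed from JSON/YAML)
as_sim_config <- function(x) {
  if (inherits(x, "sim_config")) return(x)
  blocks <- lapply(x$planted_blocks %||% list(), function(b)
    planted_block(unlist(b$rows), unlist(b$cols),
                  flood = b$flood %||% 2, inequality = b$inequality %||% 2))
  brackets <- if (!is.null(x$income_brackets))
    lapply(seq_len(nrow(as.matrix(x$income_brackets))), function(i) {
      r <- as.matrix(x$income_brackets)[i, ]
      c(r[1], if (is.na(r[2]) || r[2] < 0) Inf else r[2])
    }) else default_income_brackets()
  sim_config(
    n_rows = x$n_rows %||% 20, n_cols = x$n_cols %||% 20,
    rho = x$rho %||% 0.6,
    planted_blocks = if (is.null(x$planted_blocks))
      list(planted_block(c(4, 9), c(4, 9))) else blocks,
    income_brackets = brackets,
    n_properties_per_tract = x$n_properties_per_tract %||% 40,
    tract_population = x$tract_population %||% 4000,
    cell_size = x$cell_size %||% 1,
    stochastic_counts = x$stochastic_counts %||% FALSE,
    seed = x$seed)
}

#' Run the full study pipeline
#'
#' Orchestrates the complete workflow on synthetic or user-supplied data:
#' generate (or ingest) the tract table, compute every analysis index,
#' fit the univariate LISA of high flood risk, the bivariate LISA of flood
#' risk against each inequality and prevalence variable, the sensitivity
#' fits (Gini, IOD, and the per-level FF7-FF10 flood shares), and the
#' cluster profiles. All outputs are plain CSV/GeoJSON under `out_dir`,
#' plus a `manifest.json` recording the configuration, its hash, the seed,
#' and the package version: the manifest suffices to reproduce every
#' output byte-for-byte.
#'
#' @param config either a [sim_config()] (synthetic mode), a list with
#'   elements `geojson`, `tracts_csv`, `properties_csv` (file mode), or a
#'   path to a JSON/YAML file holding one of these (a top-level `synthetic`
#'   block selects synthetic mode).
#' @param out_dir output directory, created if needed.
#' @param pairs character matrix or data frame with columns `x`, `y`
#'   naming the bivariate variable pairs; defaults to high flood risk
#'   against the three ICE variants, the five prevalences, Gini and IOD,
#'   plus each FF-level share against (inverted) ICE Income.
#' @param permutations conditional permutations per fit.
#' @param seed master seed for the whole run (defaults to the sim config's
#'   seed in synthetic mode).
#' @param alpha significance levels (first is primary).
#' @param weights_style `"W"` (row-standardized, default) or `"B"`.
#' @param verbose per-stage log messages?
#' @return invisibly, a list with the result tables, fits, profile, paths,
#'   and manifest.
#' @export
run_all <- function(config, out_dir, pairs = NULL, permutations = 999,
                    seed = NULL, alpha = c(0.05, 0.01, 0.001),
                    weights_style = c("W", "B"), verbose = TRUE) {
  weights_style <- match.arg(weights_style)
  t0 <- proc.time()[["elapsed"]]
  if (is.character(config) && length(config) == 1L) {
    raw <- read_config_file(config)
    config <- if (!is.null(raw$synthetic)) as_sim_config(raw$synthetic) else raw
    if (!is.null(raw$permutations)) permutations <- raw$permutations
    if (!is.null(raw$seed)) seed <- raw$seed
  }

  # --- stage: ingest / generate -----------------------------------------
  stage <- "generate/ingest"
  res <- tryCatch({
    if (inherits(config, "sim_config")) {
      td <- synthesize_tracts(config, verbose = verbose)
      seed <- seed %||% config$seed
      list(tracts = td$tracts, properties = td$properties,
           geometry = td$geometry, weights = NULL, td = td)
    } else {
      if (is.null(config$geojson) || is.null(config$tracts_csv) ||
          is.null(config$properties_csv))
        stop("file mode needs `geojson`, `tracts_csv`, `properties_csv`")
      tt <- read_tract_table(config$geojson, config$tracts_csv)
      pr <- utils::read.csv(config$properties_csv, stringsAsFactors = FALSE)
      list(tracts = tt$tracts, properties = pr, geometry = tt$geometry,
           weights = NULL, td = NULL)
    }
  }, error = function(e) stop("stage [", stage, "] failed: ",
                              conditionMessage(e), call. = FALSE))
  if (is.null(seed)) stop("a `seed` is required (config or argument)")
  seed <- as.integer(seed)

  # --- stage: weights ----------------------------------------------------
  stage <- "spatial weights"
  w <- tryCatch({
    if (!is.null(res$td) && weights_style == "W") res$td$weights
    else queen_weights(res$geometry, style = weights_style)
  }, error = function(e) stop("stage [", stage, "] failed: ",
                              conditionMessage(e), call. = FALSE))
  flood_log("weights: %d tracts, %d islands", w$n, length(w$islands),
            verbose = verbose)

  # --- stage: indices ----------------------------------------------------
  stage <- "indices"
  tab <- tryCatch(
    compute_indices(if (!is.null(res$td)) res$td else res$tracts,
                    properties = res$properties, verbose = verbose),
    error = function(e) stop("stage [", stage, "] failed: ",
                             conditionMessage(e), call. = FALSE))

  if (is.null(pairs)) {
    ys <- intersect(c("ice_income", "ice_race", "ice_race_income",
                      grep("^prev_", names(tab), value = TRUE),
                      "gini", "iod"), names(tab))
    pairs <- data.frame(x = "p_flood_high", y = ys, stringsAsFactors = FALSE)
    for (lv in 7:10) {
      nm <- paste0("p_ff", lv)
      if (nm %in% names(tab) && "ice_income" %in% names(tab))
        pairs <- rbind(pairs, data.frame(x = nm, y = "ice_income"))
    }
  }
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  # pre-flight: every named variable must exist before any fit runs
  missing_vars <- setdiff(unique(c(pairs$x, pairs$y, "p_flood_high")),
                          names(tab))
  if (length(missing_vars))
    stop("stage [validate] failed: variables not in the assembled table: ",
         paste(missing_vars, collapse = ", "), call. = FALSE)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_csv_out <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    p
  }
  outputs <- character(0)
  outputs <- c(outputs, write_csv_out(tab, "tracts_indices.csv"))
  write_geojson(res$geometry, file.path(out_dir, "tracts.geojson"),
                properties = tab[, intersect(c("area_sqmi", "ruca"),
                                             names(tab)), drop = FALSE])
  write_gal(w, file.path(out_dir, "weights.gal"))

  # --- stage: LISA fits --------------------------------------------------
  stage <- "lisa"
  excl_total <- 0L
  # tracts with missing values are excluded from a fit (logged), never
  # imputed; the fit runs on the induced subgraph of complete tracts
  fit_one <- function(xv, yv = NULL) {
    x <- tab[[xv]]
    y <- if (is.null(yv)) NULL else tab[[yv]]
    ok <- !is.na(x) & (if (is.null(y)) TRUE else !is.na(y))
    if (!all(ok)) {
      flood_log("lisa %s ~ %s: %d tract(s) with missing data excluded",
                xv, yv %||% xv, sum(!ok), verbose = verbose)
      excl_total <<- excl_total + sum(!ok)
    }
    wfit <- if (all(ok)) w else subset_weights(w, ok)
    fit <- lisa(x[ok], y = if (is.null(y)) NULL else y[ok], weights = wfit,
                permutations = permutations,
                seed = stream_seed(seed, fnv_int(paste(xv, yv %||% xv))),
                alpha = alpha)
    fit$x_name <- xv
    fit$y_name <- yv %||% xv
    fit
  }
  fits <- list()
  uni <- tryCatch(fit_one("p_flood_high"),
                  error = function(e) stop("stage [", stage,
                                           " univariate] failed: ",
                                           conditionMessage(e), call. = FALSE))
  fits[["p_flood_high"]] <- uni
  outputs <- c(outputs, write_csv_out(as.data.frame(uni),
                                      "lisa_p_flood_high_univariate.csv"))
  for (r in seq_len(nrow(pairs))) {
    xv <- pairs$x[r]; yv <- pairs$y[r]
    key <- paste0(xv, "__", yv)
    fit <- tryCatch(fit_one(xv, yv),
                    error = function(e) stop("stage [", stage, " ", key,
                                             "] failed: ", conditionMessage(e),
                                             call. = FALSE))
    fits[[key]] <- fit
    outputs <- c(outputs,
                 write_csv_out(as.data.frame(fit),
                               paste0("lisa_", xv, "_", yv, ".csv")))
    flood_log("lisa %s ~ %s: global I = %.3f", xv, yv, fit$global,
              verbose = verbose)
  }

  # --- stage: profiling --------------------------------------------------
  stage <- "profiling"
  primary_key <- if ("ice_income" %in% pairs$y) "p_flood_high__ice_income"
                 else names(fits)[2L] %||% names(fits)[1L]
  tab_prof <- tab[match(fits[[primary_key]]$ids, tab$tract_id), , drop = FALSE]
  prof <- tryCatch(
    cluster_profile(fits[[primary_key]], tab_prof),
    error = function(e) stop("stage [", stage, "] failed: ",
                             conditionMessage(e), call. = FALSE))
  outputs <- c(outputs,
               write_csv_out(prof$membership, "profile_membership.csv"),
               write_csv_out(prof$ruca, "profile_ruca.csv"))
  if (length(prof$comparisons))
    outputs <- c(outputs, write_csv_out(prof$comparisons[[1L]],
                                        "profile_demographics.csv"))

  # --- manifest -----------------------------------------------------------
  cfg_json <- if (inherits(config, "sim_config"))
    jsonlite::toJSON(unclass(rapply(config, function(z)
      if (is.numeric(z) && any(is.infinite(z)))
        ifelse(is.infinite(z), "Inf", z) else z, how = "replace")),
      auto_unbox = TRUE, digits = NA, force = TRUE)
  else jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA, force = TRUE)
  manifest <- list(
    package = "floodlisa",
    version = as.character(utils::packageVersion("floodlisa")),
    seed = seed,
    permutations = as.integer(permutations),
    alpha = alpha,
    weights_style = weights_style,
    config_hash = fnv1a_hash(as.character(cfg_json)),
    config = jsonlite::fromJSON(as.character(cfg_json), simplifyVector = TRUE),
    n_tracts = nrow(tab),
    n_islands = length(w$islands),
    n_excluded_missing = excl_total,
    outputs = basename(outputs))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  flood_log("run-all complete in %.1fs: %d outputs in %s",
            proc.time()[["elapsed"]] - t0, length(outputs), out_dir,
            verbose = verbose)
  invisible(list(tracts = tab, weights = w, fits = fits, profile = prof,
                 outputs = outputs, manifest = manifest))
}

# small deterministic int from a string, for per-fit seed substreams
fnv_int <- function(x) {
  h <- fnv1a_hash(x)
  as.integer(strtoi(substr(h, 1, 7), base = 16L))
}
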