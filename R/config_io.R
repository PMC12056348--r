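# Occurrence classes: both species present, or a single-species (allotopic) site.
.occurrence_levels <- c("syntopy", "allotopy_horvathi", "allotopy_muralis")

#' Study configuration
#'
#' Assembles and validates the configuration shared by the whole pipeline:
#' simulation horizon, oviposition day, egg burial depth, the photoperiod
#' window bounding the reproductive season, the seasonal thermal-trait set,
#' the shade and retreat-depth grids, and the master RNG seed.
#'
#' Calendar convention: every simulated year has 365 days (no leap days), so
#' day-of-year indexing of photoperiod and the start day is uniform across
#' years. All temperatures at interfaces are degrees Celsius.
#'
#' @param start_year first simulated calendar year (label only).
#' @param n_years number of simulated years (>= 1).
#' @param start_doy day-of-year on which the egg is laid (1--365).
#' @param egg_depth burial depth of the egg, cm below ground.
#' @param repro_photoperiod_open daylength (h) opening the reproductive season
#'   on the ascending (spring) limb.
#' @param repro_photoperiod_close daylength (h) closing it on the descending
#'   (late-summer) limb.
#' @param season_set which seasonal thermal-trait set to use for a single run,
#'   `"spring"` or `"summer"`.
#' @param rng_seed master integer seed; every stochastic step in the package
#'   derives its stream from this single value.
#' @param shade_levels available shade fractions (subset of \[0, 0.9\]).
#' @param depth_grid substrate retreat depths, cm.
#' @param clutch_refractory_days minimum days between successive clutches.
#' @param survival_threshold survival probability below which the individual
#'   is considered dead (median-lifespan convention).
#' @return an object of class `study_config` (a validated named list).
#' @examples
#' cfg <- study_config()
#' cfg$n_years
#' @export
study_config <- function(start_year = 1995,
                         n_years = 16,
                         start_doy = 140,
                         egg_depth = 5,
                         repro_photoperiod_open = 12.6,
                         repro_photoperiod_close = 14.0,
                         season_set = "spring",
                         rng_seed = 1L,
                         shade_levels = seq(0, 0.9, by = 0.1),
                         depth_grid = c(0, 2.5, 5, 10, 20, 50, 100, 200),
                         clutch_refractory_days = 30,
                         survival_threshold = 0.5) {
  cfg <- list(
    start_year = as.integer(start_year),
    n_years = as.integer(n_years),
    start_doy = as.integer(start_doy),
    egg_depth = as.numeric(egg_depth),
    repro_photoperiod_open = as.numeric(repro_photoperiod_open),
    repro_photoperiod_close = as.numeric(repro_photoperiod_close),
    season_set = match.arg(season_set, c("spring", "summer")),
    rng_seed = as.integer(rng_seed),
    shade_levels = as.numeric(shade_levels),
    depth_grid = as.numeric(depth_grid),
    clutch_refractory_days = as.numeric(clutch_refractory_days),
    survival_threshold = as.numeric(survival_threshold)
  )
  validate_study_config(cfg)
  class(cfg) <- "study_config"
  cfg
}

validate_study_config <- function(cfg) {
  stopifnot(is.list(cfg))
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  if (!num1(cfg$n_years) || cfg$n_years < 1)
    stop("n_years must be >= 1", call. = FALSE)
  if (!num1(cfg$start_doy) || cfg$start_doy < 1 || cfg$start_doy > 365)
    stop("start_doy must lie in 1..365", call. = FALSE)
  if (!num1(cfg$egg_depth) || cfg$egg_depth < 0)
    stop("egg_depth must be >= 0 cm", call. = FALSE)
  if (any(cfg$shade_levels < 0) || any(cfg$shade_levels > 0.9))
    stop("shade_levels must lie within [0, 0.9]", call. = FALSE)
  if (length(cfg$depth_grid) < 1 || any(cfg$depth_grid < 0))
    stop("depth_grid must be non-empty and non-negative", call. = FALSE)
  if (!num1(cfg$survival_threshold) ||
      cfg$survival_threshold <= 0 || cfg$survival_threshold >= 1)
    stop("survival_threshold must lie in (0, 1)", call. = FALSE)
  invisible(cfg)
}

#' Load study sites
#'
#' Reads a site table (name, latitude, longitude, elevation, occurrence class)
#' from a CSV file, or returns the built-in fixture of the 15 study sites in
#' southern Slovenia arranged by increasing elevation: five syntopic sites,
#' five allotopic *I. horvathi* sites and five allotopic *P. muralis* sites.
#'
#' @param source `"builtin"` for the shipped fixture, or a path to a CSV file
#'   with header columns `name,lat,lon,elevation,occurrence` (UTF-8, comma
#'   separated, `.` decimal). Occurrence must be one of `syntopy`,
#'   `allotopy_horvathi`, `allotopy_muralis`.
#' @return a `data.frame` with one validated row per site.
#' @examples
#' sites <- load_sites()
#' table(sites$occurrence)
#' @export
load_sites <- function(source = "builtin") {
  path <- if (identical(source, "builtin")) {
    system.file("extdata", "sites.csv", package = "ectogradient", mustWork = TRUE)
  } else {
    source
  }
  if (!file.exists(path)) stop("site file not found: ", path, call. = FALSE)
  sites <- utils::read.csv(path, fileEncoding = "UTF-8",
                           stringsAsFactors = FALSE)
  if (nrow(sites) == 0) stop("no sites in ", path, call. = FALSE)
  required <- c("name", "lat", "lon", "elevation", "occurrence")
  missing <- setdiff(required, names(sites))
  if (length(missing))
    stop("site file missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  for (i in seq_len(nrow(sites))) {
    row <- sites[i, ]
    if (!is.finite(row$lat) || row$lat < -90 || row$lat > 90)
      stop(sprintf("site row %d (%s): lat out of [-90, 90]", i, row$name),
           call. = FALSE)
    if (!is.finite(row$elevation) || row$elevation < 0 || row$elevation > 3000)
      stop(sprintf("site row %d (%s): elevation out of [0, 3000]", i, row$name),
           call. = FALSE)
    if (!row$occurrence %in% .occurrence_levels)
      stop(sprintf(
        "site row %d (%s): unknown occurrence '%s' (allowed: %s)",
        i, row$name, row$occurrence,
        paste(.occurrence_levels, collapse = ", ")), call. = FALSE)
  }
  if (anyDuplicated(sites$name))
    stop("duplicate site names in site table", call. = FALSE)
  sites
}

#' Load a study configuration from YAML
#'
#' Keys must be a subset of the `study_config()` arguments; missing keys take
#' the defaults. Unknown keys are an error (no silent ignore).
#'
#' @param yaml_path path to a YAML file.
#' @return a `study_config` object.
#' @export
load_config <- function(yaml_path) {
  raw <- yaml::read_yaml(yaml_path)
  if (is.null(raw)) raw <- list()
  allowed <- names(formals(study_config))
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  numeric_keys <- setdiff(allowed, "season_set")
  for (k in intersect(names(raw), numeric_keys)) {
    if (!is.numeric(raw[[k]]))
      stop("config key '", k, "' must be numeric", call. = FALSE)
  }
  cfg <- do.call(study_config, raw)
  message("configuration (resolved): n_years=", cfg$n_years,
          ", start_doy=", cfg$start_doy, ", egg_depth=", cfg$egg_depth,
          " cm, photoperiod window=", cfg$repro_photoperiod_open, "-",
          cfg$repro_photoperiod_close, " h, season_set=", cfg$season_set,
          ", rng_seed=", cfg$rng_seed)
  cfg
}

#' Write and read life-history trait tables
#'
#' Plain CSV round trip for the per-site, per-species trait table produced by
#' [run_study()]. `read_traits(write_traits(x))` reproduces `x` exactly.
#'
#' @param table a trait `data.frame`.
#' @param csv_path output path.
#' @return `write_traits` returns `csv_path` invisibly; `read_traits` returns
#'   the `data.frame`.
#' @export
write_traits <- function(table, csv_path) {
  stopifnot(is.data.frame(table))
  utils::write.csv(table, csv_path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(csv_path)
}

#' @rdname write_traits
#' @export
read_traits <- function(csv_path) {
  utils::read.csv(csv_path, fileEncoding = "UTF-8", stringsAsFactors = FALSE)
}

# Derive a per-site, per-purpose RNG substream from the master seed.
# Keeps results bit-identical for equal configs while decorrelating sites.
derive_seed <- function(master, index) {
  as.integer((as.double(master) * 48271 + 7919 * as.double(index)) %%
               2147483563) + 1L
}
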