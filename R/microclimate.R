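# Synthetic hourly site microclimates along the elevational gradient.
#
# A parametric stochastic generator stands in for reanalysis-driven
# microclimate modelling: air temperature is a sum of an elevation lapse,
# seasonal and diurnal sinusoids and AR(1) noise; humidity has an elevation
# trend; snow is a boolean cold-season occupancy whose length grows with
# elevation; substrate temperatures follow a damped, lagged two-harmonic
# conduction model below a (snow-insulated) surface forcing.

#' Weather generator parameters
#'
#' Defaults encode the elevational structure of the study region: a mean
#' lapse of -0.0054 degC/m, humidity increasing at 0.015 %/m, and total
#' snow-free days over the simulation horizon declining at -1.053 d/m.
#' Solar radiation carries no elevation trend.
#'
#' @param sea_level_mean_T annual mean air temperature at sea level, degC.
#' @param lapse_rate elevational temperature lapse, degC per m (negative).
#' @param seasonal_amplitude amplitude of the annual temperature sinusoid, degC.
#' @param diurnal_amplitude_clear clear-sky amplitude of the diurnal
#'   temperature sinusoid, degC; clouds damp it by a factor `1 - 0.75*cloud`.
#' @param ar1_phi hourly AR(1) autocorrelation of the temperature noise, in \[0,1).
#' @param ar1_sigma stationary standard deviation of the AR(1) noise, degC.
#' @param rh_base mean relative humidity at sea level, percent.
#' @param rh_elev_slope humidity increase with elevation, percent per m.
#' @param rh_sigma stationary sd of the AR(1) humidity noise, percent (kept
#'   small enough that the \[0,100\] clamp is rarely active at the fixture
#'   elevations, so per-site mean humidity stays linear in elevation).
#' @param solar_clear_max clear-sky solar constant at full overhead sun, W/m^2.
#' @param snow_threshold_T daily-mean temperature below which the cold-season
#'   proxy treats a day as snow-accumulating, degC (used to anchor the snow
#'   window to the cold season).
#' @param snow_free_elev_slope change in total snow-free days over the whole
#'   horizon per metre of elevation (negative).
#' @param snow_days_sea_level expected snow-cover days per year at sea level.
#' @param snow_jitter_days half-range of the uniform per-year jitter applied
#'   to each snow-season boundary, days.
#' @param soil_damping_depth_diurnal damping depth of the diurnal harmonic, cm.
#' @param soil_damping_depth_annual damping depth of the annual harmonic, cm.
#' @return an object of class `weather_gen_params`.
#' @export
weather_gen_params <- function(sea_level_mean_T = 10.5,
                               lapse_rate = -0.0054,
                               seasonal_amplitude = 10,
                               diurnal_amplitude_clear = 8,
                               ar1_phi = 0.8,
                               ar1_sigma = 2.0,
                               rh_base = 70,
                               rh_elev_slope = 0.015,
                               rh_sigma = 4,
                               solar_clear_max = 900,
                               snow_threshold_T = 0,
                               snow_free_elev_slope = -1.053,
                               snow_days_sea_level = 5,
                               snow_jitter_days = 5,
                               soil_damping_depth_diurnal = 15,
                               soil_damping_depth_annual = 200) {
  gp <- as.list(environment())
  if (gp$lapse_rate >= 0) stop("lapse_rate must be negative", call. = FALSE)
  if (gp$ar1_phi < 0 || gp$ar1_phi >= 1)
    stop("ar1_phi must lie in [0, 1)", call. = FALSE)
  amps <- c(gp$seasonal_amplitude, gp$diurnal_amplitude_clear,
            gp$ar1_sigma, gp$rh_sigma)
  if (any(amps < 0)) stop("amplitudes must be >= 0", call. = FALSE)
  class(gp) <- "weather_gen_params"
  gp
}

#' Daylength from solar declination
#'
#' Standard no-refraction daylength: declination
#' `delta = 23.45 * sin(2*pi*(284 + doy)/365)` degrees and half-day hour angle
#' `H = acos(-tan(lat) tan(delta))`, giving `24*H/pi` hours of daylight.
#'
#' @param lat latitude, degrees north; polar latitudes (|lat| >= 66.5) are not
#'   supported.
#' @param doy day of year, 1-based (vectorised).
#' @return hours of daylight.
#' @examples
#' photoperiod(45.75, 172) # near-solstice maximum
#' @export
photoperiod <- function(lat, doy) {
  if (abs(lat) >= 66.5)
    stop("polar latitudes (|lat| >= 66.5) are unsupported", call. = FALSE)
  delta <- solar_declination(doy)
  lam <- lat * pi / 180
  cosH <- pmin(1, pmax(-1, -tan(lam) * tan(delta)))
  24 * acos(cosH) / pi
}

# Solar declination in radians for a 365-day year.
solar_declination <- function(doy) {
  23.45 * pi / 180 * sin(2 * pi * (284 + doy) / 365)
}

#' Instantaneous solar radiation
#'
#' Clear-sky half-wave model: radiation is `solar_clear_max * sin(elevation)`
#' when the sun is above the horizon and zero otherwise, attenuated by a
#' factor `1 - 0.75 * cloud_fraction`.
#'
#' @param lat latitude, degrees north.
#' @param doy day of year (vectorised).
#' @param hour local solar hour, 0--23 (vectorised).
#' @param cloud_fraction cloud cover in \[0,1\] (vectorised).
#' @param solar_clear_max clear-sky peak, W/m^2.
#' @return radiation, W/m^2.
#' @export
solar_series <- function(lat, doy, hour, cloud_fraction = 0,
                         solar_clear_max = 900) {
  stopifnot(all(cloud_fraction >= 0), all(cloud_fraction <= 1))
  delta <- solar_declination(doy)
  lam <- lat * pi / 180
  hour_angle <- (hour - 12) * pi / 12
  sin_alt <- sin(lam) * sin(delta) + cos(lam) * cos(delta) * cos(hour_angle)
  solar_clear_max * pmax(sin_alt, 0) * (1 - 0.75 * cloud_fraction)
}

#' Generate a site microclimate series
#'
#' Produces hourly air temperature at animal height, solar radiation, relative
#' humidity, a boolean snow flag and substrate temperatures on the configured
#' depth grid, over `cfg$n_years` x 365 x 24 hours.
#'
#' Air temperature is `sea_level_mean_T + lapse_rate*elevation` plus a
#' seasonal sinusoid (peak on day 200), a cloud-damped diurnal sinusoid (peak
#' at 14:00) and stationary AR(1) noise. Humidity is
#' `rh_base + rh_elev_slope*elevation` plus AR(1) noise, clamped to \[0,100\].
#' Snow occupies one window per year centred on the coldest day of the
#' seasonal cycle, with an expected length linear in elevation such that total
#' snow-free days over the horizon decline at `snow_free_elev_slope` days/m;
#' window boundaries get seed-driven uniform jitter. Substrate temperatures
#' are derived from the snow-insulated surface forcing by
#' [soil_temperature()].
#'
#' @param site one row of a site table (see [load_sites()]), or a list with
#'   `name`, `lat`, `elevation`.
#' @param gp a [weather_gen_params()] object.
#' @param cfg a [study_config()] object.
#' @param seed integer seed for this series; identical seed and config give a
#'   bit-identical series.
#' @return an object of class `microclimate_series`: a list with hourly
#'   vectors `air_T`, `solar`, `rh`, `snow`, `doy`, `hour`, `year`, a matrix
#'   `soil_T` (hours x depths), `depths`, and the site metadata.
#' @export
generate_site_weather <- function(site, gp = weather_gen_params(),
                                  cfg = study_config(), seed = cfg$rng_seed) {
  if (cfg$n_years < 1) stop("horizon must be at least 1 year", call. = FALSE)
  n_days <- cfg$n_years * 365L
  n_hours <- n_days * 24L
  doy <- rep(rep(1:365, each = 24L), cfg$n_years)
  hour <- rep(0:23, n_days)
  year <- rep(seq_len(cfg$n_years), each = 365L * 24L)
  day_index <- rep(seq_len(n_days), each = 24L)

  set.seed(seed)
  cloud_day <- rbeta(n_days, 2, 2)          # daily cloud fraction
  cloud <- cloud_day[day_index]

  base_T <- gp$sea_level_mean_T + gp$lapse_rate * site$elevation
  seasonal <- gp$seasonal_amplitude * cos(2 * pi * (doy - 200) / 365)
  diurnal <- gp$diurnal_amplitude_clear * (1 - 0.75 * cloud) *
    cos(2 * pi * (hour - 14) / 24)
  noise <- if (gp$ar1_sigma > 0) {
    innov <- rnorm(n_hours, 0, gp$ar1_sigma * sqrt(1 - gp$ar1_phi^2))
    as.numeric(stats::filter(innov, gp$ar1_phi, method = "recursive"))
  } else {
    rnorm(n_hours) * 0  # keep RNG stream alignment across sigma settings
  }
  air_T <- base_T + seasonal + diurnal + noise

  solar <- solar_series(site$lat, doy, hour, cloud, gp$solar_clear_max)

  rh_noise <- if (gp$rh_sigma > 0) {
    innov <- rnorm(n_hours, 0, gp$rh_sigma * sqrt(1 - gp$ar1_phi^2))
    as.numeric(stats::filter(innov, gp$ar1_phi, method = "recursive"))
  } else {
    rnorm(n_hours) * 0
  }
  rh <- pmin(100, pmax(0, gp$rh_base + gp$rh_elev_slope * site$elevation +
                         rh_noise))

  snow_day <- snow_season_flags(site$elevation, gp, cfg$n_years)
  snow <- snow_day[day_index]

  series <- list(
    site = site$name, lat = site$lat, elevation = site$elevation,
    occurrence = if (!is.null(site$occurrence)) site$occurrence else NA_character_,
    n_years = cfg$n_years,
    doy = doy, hour = hour, year = year,
    air_T = air_T, solar = solar, rh = rh, snow = snow,
    depths = cfg$depth_grid,
    gp = gp, seed = seed
  )
  class(series) <- "microclimate_series"
  series$.soil_dec <- soil_decomposition(series)
  series$soil_T <- vapply(cfg$depth_grid, function(z) soil_temperature(series, z),
                          numeric(n_hours))
  colnames(series$soil_T) <- paste0("d", cfg$depth_grid)
  series
}

# Boolean snow flag per simulated day. One snow window per year, centred on
# the coldest day of the seasonal temperature cycle (day 17 for a seasonal
# peak on day 200), whose expected length is linear in elevation. Jitter on
# each boundary is drawn from the active RNG stream.
snow_season_flags <- function(elevation, gp, n_years) {
  n_days <- n_years * 365L
  # snow_free_elev_slope is defined over the 16-year study horizon, so the
  # per-year snow season length is horizon-independent
  len <- gp$snow_days_sea_level - gp$snow_free_elev_slope * elevation / 16
  len <- max(0, len)
  flags <- logical(n_days)
  if (len == 0) {
    runif(2L * (n_years + 1L))  # keep stream alignment
    return(flags)
  }
  coldest <- 200 - 365 / 2 + 365  # day 382.5 in absolute days of year 1
  # one window per calendar winter, including the two part-winters at the
  # horizon edges, so total snow days stay linear in elevation
  for (y in seq_len(n_years + 1L)) {
    j <- round(runif(2, -gp$snow_jitter_days, gp$snow_jitter_days))
    centre <- (y - 2) * 365 + coldest
    a <- max(1, round(centre - len / 2 + j[1]))
    b <- min(n_days, round(centre + len / 2 + j[2]))
    if (b >= a && a <= n_days && b >= 1) flags[a:b] <- TRUE
  }
  flags
}

#' Substrate temperature at depth
#'
#' Damped, lagged conduction model. The surface forcing (air temperature, with
#' hours under snow replaced by an insulating 0 degC boundary) is decomposed
#' into a grand mean, a whole-horizon annual harmonic, the residual daily
#' means, a per-day diurnal first harmonic, and the intra-day residual. At
#' depth `z` each harmonic's amplitude is multiplied by `exp(-z/D)` and its
#' phase lagged by `z/D` radians, with `D` the annual or diurnal damping depth
#' respectively; the two non-harmonic residual terms are damped by the
#' matching `D` without a phase lag. At `z = 0` the reconstruction equals the
#' surface forcing exactly.
#'
#' @param series a `microclimate_series`.
#' @param depth depth below ground, cm (>= 0).
#' @return hourly substrate temperature, degC.
#' @export
soil_temperature <- function(series, depth) {
  if (depth < 0) stop("depth must be >= 0", call. = FALSE)
  dec <- soil_decomposition(series)
  Dd <- series$gp$soil_damping_depth_diurnal
  Da <- series$gp$soil_damping_depth_annual
  att_a <- exp(-depth / Da)
  att_d <- exp(-depth / Dd)
  n_days <- length(dec$daily_resid)
  t_hr <- rep(seq_len(n_days), each = 24L) - 1 + (0:23 + 0.5) / 24
  w_a <- 2 * pi / 365

  annual_z <- att_a * (dec$a_cos * cos(w_a * t_hr - depth / Da) +
                       dec$a_sin * sin(w_a * t_hr - depth / Da))
  daily_resid_z <- att_a * dec$daily_resid[dec$day_index]
  h <- series$hour
  w_d <- 2 * pi / 24
  diur_z <- att_d * (dec$d_cos[dec$day_index] * cos(w_d * h - depth / Dd) +
                     dec$d_sin[dec$day_index] * sin(w_d * h - depth / Dd))
  intra_z <- att_d * dec$intra_resid
  dec$mean + annual_z + daily_resid_z + diur_z + intra_z
}

# Orthogonal decomposition of the snow-insulated surface forcing; cached on
# the series object when precomputed by generate_site_weather.
soil_decomposition <- function(series) {
  if (!is.null(series$.soil_dec)) return(series$.soil_dec)
  forcing <- ifelse(series$snow, 0, series$air_T)
  n_hours <- length(forcing)
  n_days <- n_hours %/% 24L
  day_index <- rep(seq_len(n_days), each = 24L)
  fmat <- matrix(forcing, nrow = 24L)         # hours x days
  daily_mean <- colMeans(fmat)
  m <- mean(daily_mean)

  # Annual harmonic of the daily means over the whole horizon (whole periods,
  # so the cosine/sine regressors are orthogonal).
  t_day <- (seq_len(n_days) - 0.5)
  w_a <- 2 * pi / 365
  ca <- cos(w_a * t_day); sa <- sin(w_a * t_day)
  a_cos <- 2 * sum((daily_mean - m) * ca) / n_days
  a_sin <- 2 * sum((daily_mean - m) * sa) / n_days
  annual_daily <- a_cos * ca + a_sin * sa
  daily_resid <- daily_mean - m - annual_daily

  # Per-day diurnal first harmonic of the intra-day residual.
  h <- 0:23
  w_d <- 2 * pi / 24
  ch <- cos(w_d * h); sh <- sin(w_d * h)
  resid_mat <- sweep(fmat, 2, daily_mean)
  d_cos <- as.numeric(crossprod(resid_mat, ch)) / 12
  d_sin <- as.numeric(crossprod(resid_mat, sh)) / 12
  diur <- outer(ch, d_cos) + outer(sh, d_sin)
  intra_resid <- as.numeric(resid_mat - diur)

  # The hourly annual-harmonic evaluation at z = 0 must match the daily one
  # used in the decomposition; evaluate at mid-day resolution per hour.
  t_hr <- rep(seq_len(n_days), each = 24L) - 1 + (0:23 + 0.5) / 24
  # correction so that z = 0 reconstruction is exact: fold the (tiny)
  # difference between hourly and daily harmonic evaluation into intra_resid
  annual_hr <- a_cos * cos(w_a * t_hr) + a_sin * sin(w_a * t_hr)
  intra_resid <- intra_resid +
    (annual_daily[day_index] - annual_hr)

  list(mean = m, a_cos = a_cos, a_sin = a_sin,
       daily_resid = daily_resid, d_cos = d_cos, d_sin = d_sin,
       intra_resid = intra_resid, day_index = day_index)
}

#' Export a microclimate series to CSV
#'
#' One row per hour: `doy, hour, air_T, solar, rh, snow`, plus one substrate
#' temperature column per configured depth.
#'
#' @param series a `microclimate_series`.
#' @param csv_path output path.
#' @return `csv_path`, invisibly.
#' @export
write_microclimate <- function(series, csv_path) {
  df <- data.frame(doy = series$doy, hour = series$hour,
                   air_T = series$air_T, solar = series$solar,
                   rh = series$rh, snow = series$snow)
  soil <- as.data.frame(series$soil_T)
  names(soil) <- paste0("soil_T_", series$depths, "cm")
  utils::write.csv(cbind(df, soil), csv_path, row.names = FALSE)
  invisible(csv_path)
}

# Interpolate substrate temperature at an arbitrary depth from the series'
# precomputed depth grid (linear in depth between neighbouring grid points).
soil_at_depth <- function(series, depth) {
  depths <- series$depths
  if (depth <= min(depths)) return(series$soil_T[, which.min(depths)])
  if (depth >= max(depths)) return(series$soil_T[, which.max(depths)])
  hit <- which(depths == depth)
  if (length(hit)) return(series$soil_T[, hit[1]])
  lo <- max(which(depths < depth)); hi <- min(which(depths > depth))
  wt <- (depth - depths[lo]) / (depths[hi] - depths[lo])
  (1 - wt) * series$soil_T[, lo] + wt * series$soil_T[, hi]
}
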