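# Operative temperatures across microhabitats (shade levels, retreat depths)
# and the hourly behavioural decision rule: emerge, bask, forage, shelter.

.sigma_sb <- 5.670374419e-8  # Stefan-Boltzmann, W m^-2 K^-4
.emissivity <- 0.95

# state codes used in the vectorised hourly decision
.state_levels <- c("nocturnal_retreat", "inactive_cold", "basking",
                   "foraging", "shelter_heat")

#' Species thermal-behaviour parameters
#'
#' Seasonal thermal thresholds driving the hourly activity decision:
#' the emergence threshold, the voluntary foraging band, the preferred body
#' temperature targeted while active, and the critical thermal limits bounding
#' retreat selection. Seasonal values (`spring`, `summer`) differ only in the
#' foraging band and preferred temperature.
#'
#' @param T_emerge minimum body temperature for leaving the retreat, degC.
#' @param T_forage_min named numeric (`spring`, `summer`): voluntary thermal
#'   minimum for foraging, degC.
#' @param T_forage_max named numeric: voluntary thermal maximum, degC.
#' @param T_pref named numeric: preferred body temperature, degC.
#' @param CT_min,CT_max critical thermal limits, degC.
#' @param absorptivity solar absorptivity of the animal surface.
#' @param char_dim characteristic dimension, m.
#' @param wind_default wind speed used in the convective term, m/s.
#' @return an object of class `behavior_params`.
#' @export
behavior_params <- function(T_emerge,
                            T_forage_min, T_forage_max, T_pref,
                            CT_min, CT_max,
                            absorptivity = 0.9, char_dim = 0.06,
                            wind_default = 1.0) {
  bp <- list(T_emerge = T_emerge,
             T_forage_min = T_forage_min, T_forage_max = T_forage_max,
             T_pref = T_pref, CT_min = CT_min, CT_max = CT_max,
             absorptivity = absorptivity, char_dim = char_dim,
             wind_default = wind_default)
  for (s in c("spring", "summer")) {
    ok <- bp$CT_min < bp$T_emerge &&
      bp$T_emerge <= bp$T_forage_min[[s]] &&
      bp$T_forage_min[[s]] < bp$T_pref[[s]] &&
      bp$T_pref[[s]] < bp$T_forage_max[[s]] &&
      bp$T_forage_max[[s]] < bp$CT_max
    if (!ok)
      stop("thermal thresholds must satisfy CT_min < T_emerge <= ",
           "T_forage_min < T_pref < T_forage_max < CT_max (season ", s, ")",
           call. = FALSE)
  }
  class(bp) <- "behavior_params"
  bp
}

# Convective heat transfer coefficient, W m^-2 K^-1, forced convection over a
# small bluff body of characteristic dimension d (m) at wind speed u (m/s).
convective_coefficient <- function(wind, char_dim) {
  6.2 * wind^0.6 * char_dim^(-0.4)
}

#' Operative (steady-state) temperature in a surface microhabitat
#'
#' Linearised steady-state energy balance for a small ectotherm:
#' `T_e = T_air + a*(1-shade)*S / (h_c + 4*sigma*eps*T_airK^3)`, where `a` is
#' solar absorptivity, `S` solar radiation, `h_c` the convective coefficient
#' at the default wind speed and the fourth-power radiative exchange is
#' linearised around air temperature. Equals air temperature when `S = 0`;
#' strictly decreasing in shade when `S > 0`. Evaporative and metabolic terms
#' are neglected (small for a ~5 g lizard at this resolution).
#'
#' @param air_T air temperature, degC (vectorised).
#' @param solar solar radiation, W/m^2 (vectorised).
#' @param shade shade fraction in \[0, 0.9\].
#' @param bp a [behavior_params()] object.
#' @return operative temperature, degC.
#' @export
operative_temperature <- function(air_T, solar, shade, bp) {
  if (any(shade < 0) || any(shade > 0.9))
    stop("shade must lie in [0, 0.9]", call. = FALSE)
  h_c <- convective_coefficient(bp$wind_default, bp$char_dim)
  rad <- 4 * .sigma_sb * .emissivity * (air_T + 273.15)^3
  air_T + bp$absorptivity * (1 - shade) * solar / (h_c + rad)
}

#' Enumerate microhabitat body-temperature options for one hour
#'
#' Surface options are the operative temperatures at each configured shade
#' level (suppressed entirely when snow is present); retreat options are the
#' substrate temperatures at each configured depth. Body temperature is
#' assumed equal to the selected option (steady-state, small-body limit).
#'
#' @param hour_env list with `air_T`, `solar`, `snow` and `soil_T` (vector of
#'   substrate temperatures on the depth grid).
#' @param cfg a [study_config()] (supplies `shade_levels` and `depth_grid`).
#' @param bp a [behavior_params()].
#' @return data.frame with columns `type` ("surface"/"retreat"), `value`
#'   (shade fraction or depth cm) and `T_option` (degC).
#' @export
enumerate_microhabitats <- function(hour_env, cfg, bp) {
  if (length(cfg$depth_grid) == 0) stop("empty depth grid", call. = FALSE)
  out <- data.frame(type = character(0), value = numeric(0),
                    T_option = numeric(0))
  if (!isTRUE(hour_env$snow)) {
    te <- operative_temperature(hour_env$air_T, hour_env$solar,
                                cfg$shade_levels, bp)
    out <- rbind(out, data.frame(type = "surface", value = cfg$shade_levels,
                                 T_option = te))
  }
  out <- rbind(out, data.frame(type = "retreat", value = cfg$depth_grid,
                               T_option = hour_env$soil_T))
  out
}

# Distance of temperatures to the closed interval [lo, hi]; 0 inside.
.band_dist <- function(x, lo, hi) pmax(lo - x, 0) + pmax(x - hi, 0)

#' Select a microhabitat and behavioural state for one hour
#'
#' Decision tree: (1) at night the animal is in a nocturnal retreat at the
#' depth whose temperature is closest to the safe band `[CT_min, CT_max]`
#' (shallowest wins ties); (2) by day, if no surface option reaches the
#' emergence threshold the animal stays inactive in a retreat; (3) otherwise
#' it picks, among surface options at or above `T_emerge`, the shade level
#' whose operative temperature is closest to the seasonal preferred body
#' temperature -- classed as foraging if the result lies within the voluntary
#' foraging band and basking if it lies in `[T_emerge, T_forage_min)`; if even
#' the coolest eligible option exceeds `T_forage_max` the animal shelters at
#' the shallowest depth whose temperature lies within `[CT_min, T_forage_max]`.
#' If no microhabitat anywhere lies within the critical thermal limits, the
#' decision is recorded with a `lethal_exposure` flag.
#'
#' @param options data.frame from [enumerate_microhabitats()].
#' @param bp a [behavior_params()].
#' @param season `"spring"` or `"summer"`.
#' @param is_day logical; diurnal activity only.
#' @return list with `state`, `T_body`, `microhabitat` (list with `type`,
#'   `value`), `feeding`, `lethal_exposure`.
#' @export
select_microhabitat <- function(options, bp, season, is_day) {
  if (nrow(options) == 0) stop("no microhabitat options", call. = FALSE)
  surf <- options[options$type == "surface", , drop = FALSE]
  retr <- options[options$type == "retreat", , drop = FALSE]
  tf_min <- bp$T_forage_min[[season]]
  tf_max <- bp$T_forage_max[[season]]
  t_pref <- bp$T_pref[[season]]

  pick_retreat <- function(band_hi = bp$CT_max) {
    d <- .band_dist(retr$T_option, bp$CT_min, band_hi)
    i <- which.min(d)  # ties: first = shallowest (grid ordered by depth)
    list(idx = i, T = retr$T_option[i], value = retr$value[i],
         lethal = d[i] > 0)
  }

  mk <- function(state, T_body, type, value, lethal = FALSE) {
    list(state = state, T_body = T_body,
         microhabitat = list(type = type, value = value),
         feeding = identical(state, "foraging"),
         lethal_exposure = lethal)
  }

  if (!is_day) {
    r <- pick_retreat()
    return(mk("nocturnal_retreat", r$T, "retreat", r$value, r$lethal))
  }
  eligible <- surf[surf$T_option >= bp$T_emerge, , drop = FALSE]
  if (nrow(eligible) == 0) {
    r <- pick_retreat()
    return(mk("inactive_cold", r$T, "retreat", r$value, r$lethal))
  }
  j <- which.min(abs(eligible$T_option - t_pref))
  T_b <- eligible$T_option[j]
  if (T_b > tf_max || T_b > bp$CT_max) {
    # even the best-placed option is too hot: shelter from the heat
    ok <- which(retr$T_option >= bp$CT_min & retr$T_option <= tf_max)
    if (length(ok)) {
      i <- ok[1]  # shallowest admissible depth
      return(mk("shelter_heat", retr$T_option[i], "retreat", retr$value[i]))
    }
    r <- pick_retreat()
    return(mk("shelter_heat", r$T, "retreat", r$value, r$lethal))
  }
  state <- if (T_b >= tf_min) "foraging" else "basking"
  mk(state, T_b, "surface", eligible$value[j])
}

#' Seasonal parameter set for a day of year
#'
#' The study design runs whole simulations under a fixed seasonal trait set
#' (`spring_run` or `summer_run`), mirroring the two-parameter-set design;
#' `switching` is an extension that uses spring values before the summer
#' solstice (day 172) and summer values after.
#'
#' @param doy day of year (vectorised).
#' @param season_mode `"spring_run"`, `"summer_run"` or `"switching"`.
#' @return character vector, `"spring"` or `"summer"`.
#' @export
season_of <- function(doy, season_mode = c("spring_run", "summer_run",
                                           "switching")) {
  season_mode <- match.arg(season_mode)
  switch(season_mode,
         spring_run = rep("spring", length(doy)),
         summer_run = rep("summer", length(doy)),
         switching = ifelse(doy < 172, "spring", "summer"))
}

# Vectorised hourly behavioural decision over a whole microclimate series.
# Returns integer state codes (index into .state_levels), body temperature,
# feeding flag and lethal-exposure flag for every hour. Must agree with
# select_microhabitat() hour by hour (property-tested).
decide_hours <- function(series, bp, cfg, season_mode = "spring_run") {
  n <- length(series$air_T)
  season <- season_of(series$doy, season_mode)
  t_pref <- ifelse(season == "spring", bp$T_pref[["spring"]],
                   bp$T_pref[["summer"]])
  tf_min <- ifelse(season == "spring", bp$T_forage_min[["spring"]],
                   bp$T_forage_min[["summer"]])
  tf_max <- ifelse(season == "spring", bp$T_forage_max[["spring"]],
                   bp$T_forage_max[["summer"]])
  is_day <- series$solar > 0

  h_c <- convective_coefficient(bp$wind_default, bp$char_dim)
  denom <- h_c + 4 * .sigma_sb * .emissivity * (series$air_T + 273.15)^3
  gain <- bp$absorptivity * series$solar / denom      # full-sun excess
  shades <- cfg$shade_levels
  # operative temperature for every shade level: n x n_shade
  te <- series$air_T + outer(gain, 1 - shades)
  te[series$snow, ] <- NA_real_                        # snow gates the surface

  elig <- !is.na(te) & te >= bp$T_emerge
  dist <- abs(te - t_pref)
  dist[!elig] <- Inf
  best_col <- max.col(-dist, ties.method = "first")
  any_elig <- rowSums(elig) > 0
  best_te <- te[cbind(seq_len(n), best_col)]

  soil <- series$soil_T                                # n x n_depth
  safe_d <- .band_dist(soil, bp$CT_min, bp$CT_max)
  ret_col <- max.col(-safe_d, ties.method = "first")
  ret_T <- soil[cbind(seq_len(n), ret_col)]
  ret_lethal <- safe_d[cbind(seq_len(n), ret_col)] > 0

  # shallowest depth admissible for heat sheltering
  heat_ok <- soil >= bp$CT_min & sweep(soil, 1, tf_max, "<=")
  has_heat <- rowSums(heat_ok) > 0
  heat_col <- max.col(heat_ok, ties.method = "first")
  heat_T <- soil[cbind(seq_len(n), heat_col)]

  state <- integer(n)
  T_body <- numeric(n)
  lethal <- logical(n)

  night <- !is_day
  state[night] <- 1L
  T_body[night] <- ret_T[night]
  lethal[night] <- ret_lethal[night]

  cold <- is_day & !any_elig
  state[cold] <- 2L
  T_body[cold] <- ret_T[cold]
  lethal[cold] <- ret_lethal[cold]

  act <- is_day & any_elig
  hot <- act & best_te > tf_max
  forage <- act & !hot & best_te >= tf_min
  bask <- act & !hot & best_te < tf_min
  state[forage] <- 4L
  state[bask] <- 3L
  T_body[forage | bask] <- best_te[forage | bask]

  hs <- hot & has_heat
  state[hs] <- 5L
  T_body[hs] <- heat_T[hs]
  hf <- hot & !has_heat
  state[hf] <- 5L
  T_body[hf] <- ret_T[hf]
  lethal[hf] <- ret_lethal[hf]

  list(state = state, T_body = T_body,
       feeding = state == 4L, lethal_exposure = lethal,
       season = season)
}
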