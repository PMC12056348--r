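test_that("operative temperature follows the linearised energy balance", {
  bp <- toy_behavior()
  # no radiative load: equals air temperature exactly
  expect_equal(operative_temperature(20, 0, 0, bp), 20)
  # monotone decreasing in shade
  expect_lt(operative_temperature(20, 800, 0.9, bp),
            operative_temperature(20, 800, 0, bp))
  # independent hand evaluation of the stated formula
  h_c <- 6.2 * bp$wind_default^0.6 * bp$char_dim^(-0.4)
  rad <- 4 * 5.670374419e-8 * 0.95 * (20 + 273.15)^3
  expect_equal(operative_temperature(20, 800, 0, bp),
               20 + 0.9 * 800 / (h_c + rad), tolerance = 1e-12)
  expect_error(operative_temperature(20, 800, 1.0, bp), "shade")
})

test_that("thermal threshold ordering is enforced", {
  expect_error(behavior_params(
    T_emerge = 25,
    T_forage_min = c(spring = 18.2, summer = 26.3),
    T_forage_max = c(spring = 32.8, summer = 35.5),
    T_pref = c(spring = 26.9, summer = 31.2),
    CT_min = 5.1, CT_max = 43.0), "thermal thresholds")
})

test_that("microhabitat enumeration gates surfaces under snow", {
  bp <- toy_behavior()
  cfg <- short_config()
  env <- list(air_T = 15, solar = 600, snow = FALSE,
              soil_T = rep(12, length(cfg$depth_grid)))
  opts <- enumerate_microhabitats(env, cfg, bp)
  expect_equal(sum(opts$type == "surface"), length(cfg$shade_levels))
  expect_equal(sum(opts$type == "retreat"), length(cfg$depth_grid))

  env$snow <- TRUE
  opts_snow <- enumerate_microhabitats(env, cfg, bp)
  expect_equal(sum(opts_snow$type == "surface"), 0)
  expect_equal(sum(opts_snow$type == "retreat"), length(cfg$depth_grid))

  # uniform soil column: all retreat options equal
  expect_true(all(opts$T_option[opts$type == "retreat"] == 12))

  expect_error(enumerate_microhabitats(env, short_config(depth_grid = numeric(0)), bp))
})

test_that("hourly selection implements the decision tree", {
  bp <- toy_behavior()
  cfg <- short_config()

  # midday with a shade gradient spanning T_pref: forages at the achievable
  # operative temperature closest to T_pref
  env <- list(air_T = 22, solar = 700, snow = FALSE,
              soil_T = rep(15, length(cfg$depth_grid)))
  opts <- enumerate_microhabitats(env, cfg, bp)
  dec <- select_microhabitat(opts, bp, "spring", is_day = TRUE)
  expect_equal(dec$state, "foraging")
  expect_true(dec$feeding)
  # exhaustive check: chosen T_body is the achievable minimiser of |T - T_pref|
  eligible <- opts$T_option[opts$type == "surface" &
                              opts$T_option >= bp$T_emerge]
  expect_equal(dec$T_body, eligible[which.min(abs(eligible - 26.9))])

  # cold day below the emergence threshold: inactive in a retreat
  env_cold <- list(air_T = 10, solar = 150, snow = FALSE,
                   soil_T = rep(8, length(cfg$depth_grid)))
  opts_cold <- enumerate_microhabitats(env_cold, cfg, bp)
  if (max(opts_cold$T_option[opts_cold$type == "surface"]) < bp$T_emerge) {
    dec_cold <- select_microhabitat(opts_cold, bp, "spring", TRUE)
    expect_equal(dec_cold$state, "inactive_cold")
    expect_false(dec_cold$feeding)
  }

  # night: nocturnal retreat, never feeding
  dec_night <- select_microhabitat(opts, bp, "spring", is_day = FALSE)
  expect_equal(dec_night$state, "nocturnal_retreat")
  expect_false(dec_night$feeding)

  # basking band: eligible but below the foraging minimum
  env_bask <- list(air_T = 17, solar = 100, snow = FALSE,
                   soil_T = rep(12, length(cfg$depth_grid)))
  opts_bask <- enumerate_microhabitats(env_bask, cfg, bp)
  te <- opts_bask$T_option[opts_bask$type == "surface"]
  if (any(te >= bp$T_emerge) && max(te) < bp$T_forage_min[["spring"]]) {
    dec_bask <- select_microhabitat(opts_bask, bp, "spring", TRUE)
    expect_equal(dec_bask$state, "basking")
  }

  # scorching surface everywhere: shelter from the heat below ground
  env_hot <- list(air_T = 40, solar = 1000, snow = FALSE,
                  soil_T = c(39, 35, 30, 25, 20, 18, 15, 14))
  opts_hot <- enumerate_microhabitats(env_hot, cfg, bp)
  if (min(opts_hot$T_option[opts_hot$type == "surface"]) >
      bp$T_forage_max[["spring"]]) {
    dec_hot <- select_microhabitat(opts_hot, bp, "spring", TRUE)
    expect_equal(dec_hot$state, "shelter_heat")
    expect_lte(dec_hot$T_body, bp$T_forage_max[["spring"]])
    expect_gte(dec_hot$T_body, bp$CT_min)
  }
})

test_that("selection stays within critical limits whenever possible", {
  bp <- toy_behavior()
  cfg <- short_config()
  set.seed(31)
  for (i in 1:200) {
    env <- list(air_T = runif(1, -10, 45), solar = runif(1, 0, 1000),
                snow = runif(1) < 0.2,
                soil_T = runif(length(cfg$depth_grid), -5, 45))
    opts <- enumerate_microhabitats(env, cfg, bp)
    dec <- select_microhabitat(opts, bp, "summer", is_day = runif(1) < 0.6)
    any_safe <- any(opts$T_option >= bp$CT_min & opts$T_option <= bp$CT_max)
    if (any_safe && !dec$lethal_exposure) {
      expect_gte(dec$T_body, bp$CT_min)
      expect_lte(dec$T_body, bp$CT_max)
    }
    # foraging/basking body temperatures respect their bands
    if (dec$state == "foraging") {
      expect_gte(dec$T_body, bp$T_forage_min[["summer"]])
      expect_lte(dec$T_body, bp$T_forage_max[["summer"]])
    }
    if (dec$state == "basking") {
      expect_gte(dec$T_body, bp$T_emerge)
      expect_lt(dec$T_body, bp$T_forage_min[["summer"]])
    }
  }
})

test_that("vectorised decisions match the scalar selector hour by hour", {
  bp <- toy_behavior()
  cfg <- short_config()
  m <- generate_site_weather(first_site(), weather_gen_params(), cfg, seed = 13)
  dec <- ectogradient:::decide_hours(m, bp, cfg, "spring_run")
  set.seed(99)
  hours <- sample(length(m$air_T), 300)
  states <- c("nocturnal_retreat", "inactive_cold", "basking", "foraging",
              "shelter_heat")
  for (i in hours) {
    env <- list(air_T = m$air_T[i], solar = m$solar[i], snow = m$snow[i],
                soil_T = m$soil_T[i, ])
    opts <- enumerate_microhabitats(env, cfg, bp)
    ref <- select_microhabitat(opts, bp, "spring", is_day = m$solar[i] > 0)
    expect_equal(states[dec$state[i]], ref$state)
    expect_equal(dec$T_body[i], ref$T_body, tolerance = 1e-9)
    expect_equal(dec$feeding[i], ref$feeding)
  }
})

test_that("lower emergence thresholds never reduce activity", {
  cfg <- short_config()
  m <- generate_site_weather(first_site(), weather_gen_params(), cfg, seed = 17)
  mk_bp <- function(t_emerge) behavior_params(
    T_emerge = t_emerge,
    T_forage_min = c(spring = 18.2, summer = 26.3),
    T_forage_max = c(spring = 32.8, summer = 35.5),
    T_pref = c(spring = 26.9, summer = 31.2),
    CT_min = 5.1, CT_max = 43.0)
  active_hours <- function(t_emerge) {
    d <- ectogradient:::decide_hours(m, mk_bp(t_emerge), cfg, "spring_run")
    sum(d$state %in% c(3L, 4L))
  }
  a <- vapply(c(17.8, 16.5, 15.6, 14.0), active_hours, numeric(1))
  expect_true(all(diff(a) >= 0))
})

test_that("seasonal trait sets follow the run mode", {
  expect_equal(unique(season_of(1:365, "summer_run")), "summer")
  expect_equal(unique(season_of(1:365, "spring_run")), "spring")
  expect_equal(season_of(100, "switching"), "spring")
  expect_equal(season_of(200, "switching"), "summer")
})
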