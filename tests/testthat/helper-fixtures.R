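# Shared fixtures: a short-horizon configuration and a fast toy DEB parameter
# set keep the module tests well under a minute.

short_config <- function(n_years = 2, seed = 11L, ...) {
  study_config(n_years = n_years, rng_seed = seed, ...)
}

# Small, fast-maturing parameter set for integrator-level tests.
toy_deb <- function(...) {
  args <- utils::modifyList(
    list(p_Am = 250, v = 0.02, kappa = 0.8, p_M = 130, E_G = 7800,
         k_J = 0.002, E_Hb = 60, E_Hp = 2500, T_A = 9000,
         h_a = 1e-9, s_G = 0.01, del_M = 0.22),
    list(...))
  do.call(deb_params, args)
}

toy_behavior <- function() {
  behavior_params(
    T_emerge = 17.8,
    T_forage_min = c(spring = 18.2, summer = 26.3),
    T_forage_max = c(spring = 32.8, summer = 35.5),
    T_pref = c(spring = 26.9, summer = 31.2),
    CT_min = 5.1, CT_max = 43.0)
}

first_site <- function() load_sites()[1, ]

# independent closed-form daylength oracle (declination formula, coded apart
# from the implementation)
daylength_oracle <- function(lat, doy) {
  delta <- 23.45 * pi / 180 * sin(2 * pi * (284 + doy) / 365)
  H <- acos(pmin(1, pmax(-1, -tan(lat * pi / 180) * tan(delta))))
  24 * H / pi
}
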