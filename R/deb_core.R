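# Standard Dynamic Energy Budget model: kappa-rule reserve dynamics,
# single-Arrhenius temperature correction, embryo development, Weibull/Gompertz
# ageing, and conversion of the reproduction buffer into clutches.

# Composition constants used only to convert structure+reserve to wet weight:
# molar weight of reserve / chemical potential of reserve, and structure density.
.w_E_over_mu_E <- 23.9 / 550e3   # g/J
.d_V <- 1                        # g/cm^3

#' Core DEB parameters
#'
#' Parameters of the standard DEB model for one species. Defaults are a
#' generic small-lacertid starting point; species-calibrated sets are provided
#' by [species_params()].
#'
#' @param p_Am maximum surface-specific assimilation rate, J/cm^2/d.
#' @param v energy conductance, cm/d.
#' @param kappa fraction of mobilised reserve allocated to soma, in (0,1).
#' @param p_M volume-specific somatic maintenance, J/cm^3/d.
#' @param E_G volume-specific cost of structure, J/cm^3.
#' @param k_J maturity maintenance rate coefficient, 1/d.
#' @param E_Hb maturity at birth (hatching), J.
#' @param E_Hp maturity at puberty, J.
#' @param T_A Arrhenius temperature, K.
#' @param T_ref reference temperature, K (rates are specified at `T_ref`).
#' @param h_a Weibull ageing acceleration, 1/d^2.
#' @param s_G Gompertz stress coefficient, dimensionless.
#' @param del_M shape coefficient converting structural length to
#'   snout--vent length (SVL = structural length / del_M).
#' @param kap_R reproduction efficiency, in (0,1].
#' @param E_0 initial egg energy, J. If `NULL`, computed by bisection so the
#'   hatchling starts with full reserve density (e at birth = 1) and cached.
#' @return an object of class `deb_params`.
#' @export
deb_params <- function(p_Am = 250, v = 0.02, kappa = 0.8, p_M = 130,
                       E_G = 7800, k_J = 0.002, E_Hb = 60, E_Hp = 2500,
                       T_A = 9000, T_ref = 293.15, h_a = 1e-10, s_G = 0.01,
                       del_M = 0.22, kap_R = 0.95, E_0 = NULL) {
  p <- list(p_Am = p_Am, v = v, kappa = kappa, p_M = p_M, E_G = E_G,
            k_J = k_J, E_Hb = E_Hb, E_Hp = E_Hp, T_A = T_A, T_ref = T_ref,
            h_a = h_a, s_G = s_G, del_M = del_M, kap_R = kap_R, E_0 = E_0)
  validate_deb_params(p)
  class(p) <- "deb_params"
  if (is.null(p$E_0)) p$E_0 <- initial_egg_energy(p)
  p
}

validate_deb_params <- function(p) {
  if (!(p$kappa > 0 && p$kappa < 1))
    stop("kappa must lie in (0, 1)", call. = FALSE)
  if (!(p$kap_R > 0 && p$kap_R <= 1))
    stop("kap_R must lie in (0, 1]", call. = FALSE)
  if (!(p$E_Hb < p$E_Hp))
    stop("E_Hb must be smaller than E_Hp", call. = FALSE)
  rates <- c(p$p_Am, p$v, p$p_M, p$E_G, p$k_J, p$T_A, p$T_ref)
  if (any(rates <= 0)) stop("all rates must be > 0", call. = FALSE)
  if (p$h_a < 0 || p$s_G < 0 || p$del_M <= 0)
    stop("h_a, s_G must be >= 0 and del_M > 0", call. = FALSE)
  invisible(p)
}

# Reserve capacity and ultimate structural length (f = 1), cm.
deb_E_m <- function(p) p$p_Am / p$v
deb_L_i <- function(p) p$kappa * p$p_Am / p$p_M

# von Bertalanffy growth rate at f = 1 and T_ref, 1/d.
deb_r_B <- function(p) p$p_M / (3 * (deb_E_m(p) * p$kappa + p$E_G))

#' Arrhenius temperature correction
#'
#' Single-Arrhenius rate multiplier
#' `TC = exp(T_A/T_ref - T_A/T_K)` with `T_K = T_body + 273.15`. Equals 1 at
#' the reference temperature and increases strictly with body temperature.
#'
#' @param T_body body temperature, degC (vectorised).
#' @param p a `deb_params` object.
#' @return dimensionless rate multiplier.
#' @examples
#' arrhenius_tc(20, deb_params(E_0 = 5000)) # 1 at T_ref = 293.15 K
#' @export
arrhenius_tc <- function(T_body, p) {
  exp(p$T_A / p$T_ref - p$T_A / (T_body + 273.15))
}

#' Initial DEB state
#'
#' @param p a `deb_params` object.
#' @param stage `"embryo"` starts from the egg (`E = E_0`, negligible
#'   structure, zero maturity); `"hatchling"` is a convenience for tests.
#' @return an object of class `deb_state`: reserve `E` (J), structure `V`
#'   (cm^3), maturity `E_H` (J), reproduction buffer `E_R` (J), ageing
#'   acceleration `q` (1/d^2), hazard `h` (1/d), survival `S`, `stage`, and
#'   `age` (d).
#' @export
deb_state <- function(p, stage = c("embryo", "hatchling")) {
  stage <- match.arg(stage)
  s <- list(E = p$E_0, V = 1e-6, E_H = 0, E_R = 0,
            q = 0, h = 0, S = 1, stage = "embryo", age = 0, dead = FALSE)
  class(s) <- "deb_state"
  if (stage == "hatchling") {
    emb <- simulate_embryo(p, rep(p$T_ref - 273.15, 24 * 730), dt = 0.05)
    s <- emb$hatchling
  }
  s
}

#' Energy fluxes of the standard DEB model
#'
#' Computes assimilation `p_A`, mobilisation `p_C`, somatic maintenance `p_S`,
#' maturity maintenance `p_J`, growth `p_G` and maturation/reproduction `p_R`
#' (all J/d) for a state, parameter set, scaled functional response and
#' temperature correction factor. Embryos do not assimilate (`p_A = 0`).
#'
#' The kappa-rule partition: `p_G = kappa*p_C - p_S` and
#' `p_R = (1-kappa)*p_C - p_J`, with mobilisation
#' `p_C = E * (TC*E_G*v*L^2/V + TC*p_M) / (E_G + kappa*E/V)`, `L = V^(1/3)`
#' (volume-specific maintenance in the numerator).
#'
#' @param s a `deb_state`.
#' @param p a `deb_params`.
#' @param f scaled functional response in \[0,1\].
#' @param TC Arrhenius correction factor (see [arrhenius_tc()]).
#' @return named numeric vector of the six fluxes.
#' @export
deb_fluxes <- function(s, p, f, TC) {
  if (s$V <= 0) stop("state has no structure; initialise via the embryo",
                     call. = FALSE)
  if (s$stage == "embryo") f <- 0
  L <- s$V^(1 / 3)
  p_A <- if (s$stage == "embryo") 0 else TC * p$p_Am * f * L^2
  p_S <- TC * p$p_M * s$V
  p_J <- TC * p$k_J * s$E_H
  # mobilisation: volume-specific maintenance TC*p_M in the numerator
  p_C <- s$E * (TC * p$E_G * p$v * L^2 / s$V + TC * p$p_M) /
    (p$E_G + p$kappa * s$E / s$V)
  p_G <- p$kappa * p_C - p_S
  p_R <- (1 - p$kappa) * p_C - p_J
  c(p_A = p_A, p_C = p_C, p_S = p_S, p_J = p_J, p_G = p_G, p_R = p_R)
}

# Pack the parameters used by the inner integrator into a plain numeric
# vector (classed-list access is too slow for the hot loop):
# 1 p_Am, 2 v, 3 kappa, 4 p_M, 5 E_G, 6 k_J, 7 E_Hp, 8 kap_R, 9 h_a, 10 s_G,
# 11 E_m, 12 V_i.
.deb_pack <- function(p) {
  c(p$p_Am, p$v, p$kappa, p$p_M, p$E_G, p$k_J, p$E_Hp, p$kap_R,
    p$h_a, p$s_G, deb_E_m(p), deb_L_i(p)^3)
}

# Fast internal single step on a plain numeric state vector
# y = c(E, V, E_H, E_R, q, h, S, age); returns the updated vector plus a
# death flag (9th element). Starvation: maintenance deficits are paid from
# the reproduction buffer, then by diverting the maturation stream; unpayable
# maintenance kills. Maturity is never drained. Structure never shrinks.
.deb_step_num <- function(y, pv, TC, f, dt, embryo) {
  E <- y[1]; V <- y[2]; E_H <- y[3]; E_R <- y[4]
  q <- y[5]; h <- y[6]; S <- y[7]
  L <- V^(1 / 3)
  p_S <- TC * pv[4] * V
  p_J <- TC * pv[6] * E_H
  p_C <- E * (TC * pv[5] * pv[2] * L^2 / V + TC * pv[4]) /
    (pv[5] + pv[3] * E / V)
  p_A <- if (embryo) 0 else TC * pv[1] * f * L^2
  p_G <- pv[3] * p_C - p_S
  p_R <- (1 - pv[3]) * p_C - p_J

  # Starvation priority: somatic maintenance is paid first from the kappa
  # stream, then from the reproduction buffer, then by diverting the
  # maturation/reproduction stream; if still unpayable, the individual dies.
  # A maturity-maintenance shortfall is paid from the buffer when possible
  # and otherwise forgone (the rejuvenation case, without tracking the
  # maturity decline). Maturity is never drained; structure never shrinks.
  dead <- FALSE
  if (p_G < 0) {
    need <- -p_G; p_G <- 0
    from_R <- min(need, E_R / dt)
    E_R <- E_R - from_R * dt
    need <- need - from_R
    if (need > 0 && p_R > 0) {
      divert <- min(need, p_R)
      p_R <- p_R - divert
      need <- need - divert
    }
    if (need > 1e-12 * p_S) dead <- TRUE
  }
  if (p_R < 0) {
    need <- -p_R; p_R <- 0
    from_R <- min(need, E_R / dt)
    E_R <- E_R - from_R * dt
  }
  E <- E + (p_A - p_C) * dt
  V <- V + p_G / pv[5] * dt
  if (E_H < pv[7]) E_H <- E_H + p_R * dt else E_R <- E_R + pv[8] * p_R * dt
  if (E < 0) { E <- 0; dead <- TRUE }

  # ageing (no ageing before birth)
  if (!embryo && pv[9] > 0) {
    e <- E / (V * pv[11])
    r <- p_G / (pv[5] * V)
    dq <- (q * (V / pv[12]) * pv[10] + pv[9]) * max(e * (TC * pv[2] / L - r), 0) -
      r * q
    dh <- q - r * h
    q <- max(q + dq * dt, 0)
    h <- max(h + dh * dt, 0)
    S <- S * exp(-h * dt)
  }
  c(E, V, E_H, E_R, q, h, S, y[8] + dt, if (dead) 1 else 0)
}

#' Advance a DEB state by one time step
#'
#' Euler integration with automatic sub-stepping: when the relative change of
#' reserve or structure within the step exceeds 1%, the step is subdivided.
#' Stage transitions (embryo to juvenile at `E_Hb`, juvenile to adult at
#' `E_Hp`) are applied when maturity crosses the thresholds. Maintenance
#' shortfalls drain the reproduction buffer first, then kill (starvation,
#' `S = 0`). Maturity is never drained and structure never shrinks.
#'
#' @param s a `deb_state`.
#' @param p a `deb_params`.
#' @param T_body body temperature, degC.
#' @param f scaled functional response in \[0,1\].
#' @param dt step, days (<= 1/24 recommended for environmental coupling; the
#'   integrator sub-steps internally when needed).
#' @return the updated `deb_state`.
#' @export
deb_step <- function(s, p, T_body, f, dt) {
  if (anyNA(c(s$E, s$V, s$E_H, s$E_R, s$q, s$h, s$S)))
    stop("NaN in DEB state: ", paste(unlist(s[1:7]), collapse = ", "),
         call. = FALSE)
  TC <- arrhenius_tc(T_body, p)
  pv <- .deb_pack(p)
  y <- c(s$E, s$V, s$E_H, s$E_R, s$q, s$h, s$S, s$age)
  embryo <- s$stage == "embryo"
  n_sub <- 1L
  repeat {
    h_dt <- dt / n_sub
    y_try <- .deb_step_num(y, pv, TC, f, h_dt, embryo)
    rel <- max(abs(y_try[1] - y[1]) / max(y[1], 1e-12),
               abs(y_try[2] - y[2]) / max(y[2], 1e-12))
    if (rel <= 0.01 || n_sub >= 1024L) break
    n_sub <- n_sub * 2L
  }
  if (n_sub > 1L) {
    for (i in seq_len(n_sub)) {
      y <- .deb_step_num(y, pv, TC, f, dt / n_sub, embryo)
      if (y[9] > 0) break
    }
  } else {
    y <- y_try
  }
  s$E <- y[1]; s$V <- y[2]; s$E_H <- y[3]; s$E_R <- y[4]
  s$q <- y[5]; s$h <- y[6]; s$S <- y[7]; s$age <- y[8]
  if (y[9] > 0) { s$dead <- TRUE; s$S <- 0 }
  if (s$stage == "embryo" && s$E_H >= p$E_Hb) s$stage <- "juvenile"
  if (s$stage == "juvenile" && s$E_H >= p$E_Hp) s$stage <- "adult"
  s
}

#' Simulate embryonic development on a substrate temperature series
#'
#' The embryo (`E = E_0`, negligible structure, zero maturity) is stepped
#' hourly on the supplied substrate temperatures until maturity reaches
#' `E_Hb` (hatching). Fails if the egg has not hatched within two simulated
#' years (arrested development under cold microclimates) or runs out of
#' reserve.
#'
#' @param p a `deb_params`.
#' @param soil_T_series hourly substrate temperature at egg depth, degC.
#' @param dt integration step in days (default hourly).
#' @return list with `hatch_day` (days since oviposition, fractional),
#'   `hatchling` (the `deb_state` at hatching) and `viable`.
#' @export
simulate_embryo <- function(p, soil_T_series, dt = 1 / 24) {
  guard_days <- 2 * 365
  pv <- .deb_pack(p)
  y <- c(p$E_0, 1e-6, 0, 0, 0, 0, 1, 0)
  t <- 0
  n <- length(soil_T_series)
  if (n < 24)
    stop("substrate series too short for embryonic development", call. = FALSE)
  steps_per_hour <- max(1L, as.integer(round(1 / (24 * dt))))
  dt <- 1 / 24 / steps_per_hour
  # hatch must occur within the guard window and the available series;
  # running out of either means a non-viable egg under this microclimate
  for (i in seq_len(min(n, guard_days * 24L))) {
    TC <- exp(p$T_A / p$T_ref - p$T_A / (soil_T_series[i] + 273.15))
    for (k in seq_len(steps_per_hour)) {
      y <- .deb_step_num(y, pv, TC, 0, dt, TRUE)
      t <- t + dt
      if (y[3] >= p$E_Hb) {
        s <- structure(list(E = y[1], V = y[2], E_H = y[3], E_R = 0,
                            q = 0, h = 0, S = 1, stage = "juvenile",
                            age = 0, dead = FALSE),
                       class = "deb_state")
        return(list(hatch_day = t, hatchling = s, viable = TRUE))
      }
      if (y[9] > 0)
        return(list(hatch_day = NA_real_, hatchling = NULL, viable = FALSE))
    }
  }
  list(hatch_day = NA_real_, hatchling = NULL, viable = FALSE)
}

# Embryonic development at constant temperature: fast inner integrator used
# by the egg-energy bisection and by zero-variate predictions. Returns the
# hatch time (d) and the state vector at hatching, or viable = FALSE.
.embryo_const_T <- function(p, temp, dt = 0.25, E_0 = p$E_0,
                            guard_days = 2 * 365) {
  TC <- exp(p$T_A / p$T_ref - p$T_A / (temp + 273.15))
  pv <- .deb_pack(p)
  y <- c(E_0, 1e-6, 0, 0, 0, 0, 1, 0)
  t <- 0
  while (t < guard_days) {
    y <- .deb_step_num(y, pv, TC, 0, dt, TRUE)
    t <- t + dt
    if (y[3] >= p$E_Hb) return(list(hatch_day = t, y = y, viable = TRUE))
    if (y[9] > 0) return(list(viable = FALSE))
  }
  list(viable = FALSE)
}

# Initial egg energy by bisection: the smallest E_0 such that the hatchling's
# scaled reserve density e_b = E_b/(V_b*E_m) equals 1 at the reference
# temperature (standard initial-scaled-reserve condition). A warm-start guess
# narrows the initial bracket (used inside the estimation loop).
initial_egg_energy <- function(p, dt = 0.02, tol = 1e-3, guess = NULL) {
  T_ref_C <- p$T_ref - 273.15
  E_m <- deb_E_m(p)
  e_b <- function(E_0) {
    emb <- .embryo_const_T(p, T_ref_C, dt = min(dt, 0.25), E_0 = E_0)
    if (!emb$viable) return(-1)
    emb$y[1] / (emb$y[2] * E_m)
  }
  lo <- p$E_Hb                     # too small: cannot even build maturity
  hi <- p$E_Hb * 4 + 1
  if (!is.null(guess) && is.finite(guess) && guess > lo) {
    glo <- guess / 1.4; ghi <- guess * 1.4
    if (glo > lo && e_b(glo) < 1 && e_b(ghi) >= 1) {
      lo <- glo; hi <- ghi
    }
  }
  while (e_b(hi) < 1) {
    hi <- hi * 2
    if (hi > 1e9) stop("no viable initial egg energy found", call. = FALSE)
  }
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    if (e_b(mid) < 1) lo <- mid else hi <- mid
    if ((hi - lo) / hi < tol) break
  }
  hi
}

#' Convert the reproduction buffer into a clutch
#'
#' Within the reproductive window, an adult with at least one egg's worth of
#' buffer lays `min(round(a + b*SVL), cap, floor(kap_R*E_R/E_0))` eggs, where
#' SVL (mm) is the current snout--vent length and the linear clutch-size rule
#' `(a, b)` and cap are species-specific. Rounding is half-away-from-zero.
#' Each egg costs `E_0/kap_R` from the buffer (reproduction efficiency applied
#' once at conversion). Outside the window, or with insufficient buffer, no
#' eggs are laid and the state is unchanged.
#'
#' @param s an adult `deb_state`.
#' @param p a `deb_params`.
#' @param rule list with `a`, `b` (clutch size vs SVL in mm) and `cap`
#'   (maximum eggs per clutch).
#' @param in_window is the day within the photoperiod-bounded reproductive
#'   season?
#' @return list with `eggs` (integer) and `state` (updated `deb_state`).
#' @export
clutch_from_buffer <- function(s, p, rule, in_window) {
  if (s$stage != "adult" || !in_window || s$E_R < p$E_0)
    return(list(eggs = 0L, state = s))
  svl <- 10 * s$V^(1 / 3) / p$del_M
  candidate <- floor(rule$a + rule$b * svl + 0.5)  # round half away from zero
  affordable <- floor(p$kap_R * s$E_R / p$E_0)
  eggs <- max(0L, min(candidate, rule$cap, affordable))
  if (eggs > 0) s$E_R <- s$E_R - eggs * p$E_0 / p$kap_R
  list(eggs = as.integer(eggs), state = s)
}
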