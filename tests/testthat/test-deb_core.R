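test_that("Arrhenius correction is 1 at T_ref, monotone, and matches direct evaluation", {
  p <- toy_deb()
  expect_equal(arrhenius_tc(20, p), 1, tolerance = 1e-12)
  p9 <- toy_deb(T_A = 9000)
  expect_equal(arrhenius_tc(30, p9), exp(9000 / 293.15 - 9000 / 303.15),
               tolerance = 1e-12)
  expect_lt(arrhenius_tc(25, p), arrhenius_tc(35, p))
  tc <- arrhenius_tc(seq(-20, 60, by = 5), p)
  expect_true(all(diff(tc) > 0))
})

test_that("parameter invariants are enforced", {
  expect_error(toy_deb(kappa = 1.2), "kappa")
  expect_error(toy_deb(kap_R = 0), "kap_R")
  expect_error(toy_deb(E_Hb = 3000, E_Hp = 2500), "E_Hb")
  expect_error(toy_deb(p_M = -1), "rates")
})

test_that("fluxes satisfy the kappa-rule balance and ultimate-size fixed point", {
  p <- toy_deb()
  hatch <- simulate_embryo(p, rep(20, 24 * 730))
  s <- hatch$hatchling

  # conservation: p_C = p_G + p_S + p_J + p_R for arbitrary valid states
  for (scale in c(1, 2.5, 6)) {
    s2 <- s
    s2$V <- s$V * scale
    s2$E <- s$E * scale * 0.8
    s2$E_H <- min(p$E_Hp, s$E_H * scale)
    fl <- deb_fluxes(s2, p, 1, 1.3)
    expect_equal(fl[["p_C"]],
                 fl[["p_G"]] + fl[["p_S"]] + fl[["p_J"]] + fl[["p_R"]],
                 tolerance = 1e-9)
  }

  # at ultimate size with e = 1: kappa*p_C equals somatic maintenance exactly
  L_i <- p$kappa * p$p_Am / p$p_M
  s_i <- s
  s_i$V <- L_i^3
  s_i$E <- s_i$V * p$p_Am / p$v
  s_i$E_H <- p$E_Hp
  s_i$stage <- "adult"
  fl <- deb_fluxes(s_i, p, 1, 1)
  expect_equal(p$kappa * fl[["p_C"]], fl[["p_S"]], tolerance = 1e-12)
  expect_equal(fl[["p_G"]], 0, tolerance = 1e-9 * fl[["p_S"]])

  expect_error(deb_fluxes(list(V = 0, stage = "juvenile"), p, 1, 1),
               "structure")
})

test_that("growth at constant T_ref and f = 1 follows the von Bertalanffy form", {
  p <- toy_deb()
  hatch <- simulate_embryo(p, rep(20, 24 * 730))
  s <- hatch$hatchling
  L_b <- s$V^(1 / 3)
  L_i <- p$kappa * p$p_Am / p$p_M
  r_B <- p$p_M / (3 * (p$p_Am / p$v * p$kappa + p$E_G))
  for (i in 1:(365 * 24)) s <- deb_step(s, p, 20, 1, 1 / 24)
  L_expected <- L_i - (L_i - L_b) * exp(-r_B * 365)
  expect_equal(s$V^(1 / 3), L_expected, tolerance = 0.01)
})

test_that("ultimate length equals kappa*p_Am/p_M over random parameter draws", {
  set.seed(402)
  for (rep in 1:5) {
    p <- deb_params(p_Am = runif(1, 150, 400), v = runif(1, 0.01, 0.04),
                    kappa = runif(1, 0.6, 0.9), p_M = runif(1, 60, 200),
                    E_G = runif(1, 7000, 8500), E_Hb = runif(1, 40, 120),
                    E_Hp = runif(1, 2000, 5000), h_a = 0)
    hatch <- simulate_embryo(p, rep(20, 24 * 730))
    expect_true(hatch$viable)
    s <- hatch$hatchling
    # integrate long enough to approach the asymptote
    t_end <- ceiling(8 / (p$p_M / (3 * (p$p_Am / p$v * p$kappa + p$E_G))))
    y <- c(s$E, s$V, s$E_H, s$E_R, 0, 0, 1, 0)
    pv <- ectogradient:::.deb_pack(p)
    for (i in seq_len(t_end)) y <- ectogradient:::.deb_step_num(y, pv, 1, 1, 1, FALSE)
    L_i <- p$kappa * p$p_Am / p$p_M
    expect_equal(y[2]^(1 / 3), L_i, tolerance = 0.005)
  }
})

test_that("energy bookkeeping conserves assimilated energy", {
  # over any interval: assimilation = change in reserve + mobilised energy
  p <- toy_deb()
  hatch <- simulate_embryo(p, rep(20, 24 * 730))
  s <- hatch$hatchling
  y <- c(s$E, s$V, s$E_H, s$E_R, 0, 0, 1, 0)
  pv <- ectogradient:::.deb_pack(p)
  dt <- 1 / 24
  assimilated <- 0
  mobilised <- 0
  for (i in 1:2000) {
    L <- y[2]^(1 / 3)
    p_A <- p$p_Am * 1 * L^2
    p_C <- y[1] * (p$E_G * p$v * L^2 / y[2] + p$p_M) /
      (p$E_G + p$kappa * y[1] / y[2])
    assimilated <- assimilated + p_A * dt
    mobilised <- mobilised + p_C * dt
    y <- ectogradient:::.deb_step_num(y, pv, 1, 1, dt, FALSE)
  }
  dE <- y[1] - s$E
  expect_equal(assimilated, dE + mobilised, tolerance = 1e-8 * assimilated)
})

test_that("maturity never decreases and survival is non-increasing", {
  p <- toy_deb(h_a = 1e-8)
  hatch <- simulate_embryo(p, rep(20, 24 * 730))
  s <- hatch$hatchling
  E_H_prev <- s$E_H
  S_prev <- s$S
  set.seed(7)
  temps <- runif(3000, 5, 35)
  fs <- rbinom(3000, 1, 0.4)
  for (i in seq_along(temps)) {
    s <- deb_step(s, p, temps[i], fs[i], 1 / 24)
    expect_gte(s$E_H, E_H_prev)
    expect_lte(s$S, S_prev + 1e-15)
    E_H_prev <- s$E_H
    S_prev <- s$S
    if (s$dead) break
  }
})

test_that("no ageing means permanent survival; starvation kills in finite time", {
  p0 <- toy_deb(h_a = 0)
  hatch <- simulate_embryo(p0, rep(20, 24 * 730))
  s <- hatch$hatchling
  for (i in 1:5000) s <- deb_step(s, p0, 20, 1, 1 / 24)
  expect_equal(s$S, 1)

  # f = 0 forever from the juvenile stage: reserve declines monotonically
  # and death occurs in finite time
  s <- hatch$hatchling
  E_prev <- s$E
  died <- FALSE
  for (i in 1:(5 * 365)) {
    s <- deb_step(s, p0, 20, 0, 1)
    expect_lte(s$E, E_prev)
    E_prev <- s$E
    if (s$dead) { died <- TRUE; break }
  }
  expect_true(died)
})

test_that("embryo development responds to temperature and arrests in the cold", {
  p <- toy_deb()
  warm <- simulate_embryo(p, rep(25, 24 * 730))
  cool <- simulate_embryo(p, rep(20, 24 * 730))
  expect_true(warm$viable && cool$viable)
  expect_lt(warm$hatch_day, cool$hatch_day)

  # hatchling reserve density equals 1 (initial-scaled-reserve condition)
  e_b <- cool$hatchling$E / (cool$hatchling$V * p$p_Am / p$v)
  expect_equal(e_b, 1, tolerance = 0.01)

  # development time at T_ref matches a fine-step integrator within 1%
  fine <- ectogradient:::.embryo_const_T(p, 20, dt = 1e-3)
  expect_equal(cool$hatch_day, fine$hatch_day, tolerance = 0.01)

  # effectively arrested development hits the guard
  cold <- simulate_embryo(p, rep(-5, 24 * 730))
  expect_false(cold$viable)
})

test_that("clutch conversion caps, rounds and decrements the buffer correctly", {
  p <- toy_deb()
  rule <- list(a = -2.0, b = 0.12, cap = 5)
  hatch <- simulate_embryo(p, rep(20, 24 * 730))
  s <- hatch$hatchling
  s$stage <- "adult"
  s$V <- 1.4^3                       # large adult, SVL ~ 64 mm
  s$E_R <- 100 * p$E_0

  # saturated buffer and large SVL: the species cap binds
  out <- clutch_from_buffer(s, p, rule, in_window = TRUE)
  expect_identical(out$eggs, 5L)
  expect_equal(out$state$E_R, s$E_R - 5 * p$E_0 / p$kap_R)

  # insufficient buffer
  s2 <- s; s2$E_R <- 0.5 * p$E_0
  expect_identical(clutch_from_buffer(s2, p, rule, TRUE)$eggs, 0L)

  # outside the window: no eggs, state unchanged
  out3 <- clutch_from_buffer(s, p, rule, in_window = FALSE)
  expect_identical(out3$eggs, 0L)
  expect_identical(out3$state, s)

  # rounding convention: candidate 3.4 rounds to 3 (half away from zero)
  svl_target <- (3.4 + 2.0) / 0.12             # a + b*SVL = 3.4
  s4 <- s
  s4$V <- (svl_target * p$del_M / 10)^3
  s4$E_R <- 4.5 * p$E_0
  expect_identical(clutch_from_buffer(s4, p, rule, TRUE)$eggs, 3L)
  # brute-force check of round-half-away-from-zero on a grid
  for (x in c(0.4, 0.5, 1.49, 1.5, 2.5, 3.4)) {
    expect_equal(floor(x + 0.5), round(x + 1e-9))
  }
})
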