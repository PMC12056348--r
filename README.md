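# ectogradient

Mechanistic life-history modelling for two elevationally segregated lacertid
lizards — the lowland wall lizard *Podarcis muralis* and the highland
Horvath's rock lizard *Iberolacerta horvathi* — across 15 study sites
(238–1279 m a.s.l.) in the northern Dinarides where the species occur
together (syntopy) or alone (allotopy). The package asks how the abiotic
gradient alone shapes life-history outcomes, for ecophysiologists and
macroecologists studying coexistence along climatic gradients.

The pipeline chains four mechanistic stages:

1. **Synthetic microclimate** — hourly air temperature, solar radiation,
   humidity, snow cover and substrate temperatures with the elevational
   structure of the region (lapse β = −0.0054 °C/m, humidity +0.015 %/m,
   snow-free days −1.053 d/m over the 16-year horizon, no solar trend).
2. **Behavioural thermoregulation** — operative temperatures
   `T_e = T_air + a(1−s)·S/(h_c + 4σεT³)` over shade levels 0–90 % and
   retreat depths 0–200 cm; hourly decisions (bask / forage / shelter /
   retreat) against the species' seasonal thermal thresholds
   (T_emerge 17.8 vs 15.6 °C, seasonal voluntary bands and preferred
   temperatures, critical limits 5.1/43.0 and 5.7/42.2 °C).
3. **Standard DEB life cycle** — reserve/structure/maturity/reproduction-
   buffer dynamics under the κ-rule with single-Arrhenius temperature
   correction; egg buried at 5 cm on day 140; feeding only while foraging;
   clutches of up to 5 eggs inside the photoperiod window (daylength
   12.6 h → 14 h); Weibull–Gompertz ageing. Parameters are estimated from
   zero-variate life-history data by the covariation method (weighted
   symmetric loss, MRE/SMSE).
4. **Statistics** — OLS of the six life-history traits (egg development
   time, lifespan, reproductive years, yearly basking and foraging hours,
   yearly fecundity) on `elevation × species × location type`, simplified by
   AICc (ΔAICc > 2 keeps the simpler model), Tukey–Kramer post hoc contrasts
   on location type, Shapiro–Wilk and Breusch–Pagan diagnostics.

The methods vignette (`vignettes/methods.Rmd`) documents the model,
its assumptions, parameter provenance and limitations.

## Worked example

```r
library(ectogradient)

sites <- load_sites()                      # the 15-site study table
cfg   <- study_config(rng_seed = 4L)       # 16-year horizon, day-140 oviposition
gp    <- weather_gen_params()

# one individual per species at the lowest site (Bilpa, 238 m)
m  <- generate_site_weather(sites[1, ], gp, cfg, seed = 41)
for (spn in c("P_muralis", "I_horvathi")) {
  sp <- species_params(spn)
  tr <- run_individual(sites[1, ], m, sp$deb, sp$behavior, sp$clutch, cfg)$traits
  print(tr[, c("species", "egg_dev_days", "lifespan_years",
               "reproductive_years", "yearly_fecundity")])
}
```

At the lowest site this prints an egg development time of 158 days, an
8.7-year lifespan, 7 reproductive years and a mean fecundity of 3.1 eggs per
reproductive year for *P. muralis*, against 243 days, 7.4 years,
4 reproductive years and 1.2 eggs for *I. horvathi* — the wall lizard
matures earlier, lives slightly longer and reproduces more, while the rock
lizard spends roughly nine times as many hours basking (≈455 vs ≈55 h/yr).
At the highest site (Orlovica, 1279 m) the same simulations lengthen egg
development to 421/447 days, lengthen lifespans to 9.7/8.6 years and cut
fecundity to 2.2/1.0 — activity and reproductive output fall with elevation
while development slows, and the decline is steeper for the lowland species.

The microclimate stage can be checked directly against its configured
structure:

```r
mc <- compare_microclimate(sites, gp, study_config(rng_seed = 2L))
mc$fits$mean_T$fit$beta[["elevation"]]    # -0.005404  (configured -0.0054)
mc$fits$mean_rh$fit$beta[["elevation"]]   #  0.014952  (configured  0.015)
mc$fits$mean_solar$fit$p[["elevation"]]   #  0.66      (no solar trend)
```

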