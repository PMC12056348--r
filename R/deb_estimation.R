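# Covariation-method parameter estimation: forward predictions of zero-variate
# life-history data, weighted symmetric loss, Nelder-Mead search in
# transformed parameter space, and MRE/SMSE goodness-of-fit.

.zero_variate_keys <- c("age_at_birth_d", "age_at_puberty_d", "lifespan_d",
                        "SVL_at_birth_mm", "SVL_at_puberty_mm", "SVL_max_mm",
                        "wet_weight_max_g",
                        "max_reproduction_rate_eggs_per_yr")

#' Assemble a zero-variate data table
#'
#' @param key datum name, one of `age_at_birth_d`, `age_at_puberty_d`,
#'   `lifespan_d`, `SVL_at_birth_mm`, `SVL_at_puberty_mm`, `SVL_max_mm`,
#'   `wet_weight_max_g`, `max_reproduction_rate_eggs_per_yr`.
#' @param value observed value, in the key's units (> 0).
#' @param temperature temperature at which the datum applies, degC.
#' @param weight non-negative weight.
#' @return a `data.frame` of class `zero_variate_data`.
#' @export
zero_variate_data <- function(key, value, temperature = 20, weight = 1) {
  bad <- setdiff(key, .zero_variate_keys)
  if (length(bad))
    stop("unknown zero-variate keys: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (any(value <= 0)) stop("datum values must be > 0", call. = FALSE)
  if (any(weight < 0)) stop("weights must be >= 0", call. = FALSE)
  d <- data.frame(key = key, value = value,
                  temperature = rep_len(temperature, length(key)),
                  weight = rep_len(weight, length(key)),
                  stringsAsFactors = FALSE)
  class(d) <- c("zero_variate_data", "data.frame")
  d
}

#' Forward-predict zero-variate quantities from DEB parameters
#'
#' Each quantity is computed by forward simulation at its datum temperature
#' with `f = 1`: an embryo run for birth quantities; a juvenile/adult run for
#' age at puberty, lifespan (first time survival drops below 0.5) and size at
#' puberty; closed forms for ultimate size and weight
#' (`L_i = kappa*p_Am/p_M`); and the reproduction-buffer flux at ultimate size
#' for the maximum reproduction rate.
#'
#' @param p a [deb_params()].
#' @param keys character vector of datum keys.
#' @param temperatures matching temperatures, degC.
#' @param control list of integration steps: `dt_embryo`, `dt` (days).
#' @return named numeric vector of predictions; `NA` for a non-viable
#'   parameter set (no hatch, or no puberty within 50 years).
#' @export
predict_zero_variate <- function(p, keys, temperatures,
                                 control = list(dt_embryo = 0.1, dt = 0.25, dt_adult = 1)) {
  stopifnot(length(keys) == length(temperatures))
  preds <- setNames(rep(NA_real_, length(keys)), keys)
  pv <- .deb_pack(p)
  L_i <- deb_L_i(p)
  E_m <- deb_E_m(p)
  svl <- function(V) 10 * V^(1 / 3) / p$del_M

  for (temp in unique(temperatures)) {
    sel <- temperatures == temp
    need <- keys[sel]
    TC <- arrhenius_tc(temp, p)

    emb <- NULL
    if (any(need %in% c("age_at_birth_d", "SVL_at_birth_mm",
                        "age_at_puberty_d", "SVL_at_puberty_mm",
                        "lifespan_d"))) {
      emb <- .embryo_const_T(p, temp, dt = control$dt_embryo)
      if (!emb$viable) next
      if ("age_at_birth_d" %in% need)
        preds[which(sel & keys == "age_at_birth_d")] <- emb$hatch_day
      if ("SVL_at_birth_mm" %in% need)
        preds[which(sel & keys == "SVL_at_birth_mm")] <- svl(emb$y[2])
    }

    if (any(need %in% c("age_at_puberty_d", "SVL_at_puberty_mm",
                        "lifespan_d"))) {
      y <- c(emb$y[1], emb$y[2], emb$y[3], 0, 0, 0, 1, 0)
      dt <- control$dt
      dt_adult <- if (!is.null(control$dt_adult)) control$dt_adult else 1
      t <- 0
      puberty_t <- NA_real_
      puberty_V <- NA_real_
      lifespan_t <- NA_real_
      guard <- 50 * 365
      while (t < guard) {
        step <- if (is.na(puberty_t)) dt else dt_adult
        y <- .deb_step_num(y, pv, TC, 1, step, FALSE)
        t <- t + step
        if (is.na(puberty_t) && y[3] >= p$E_Hp) {
          puberty_t <- t
          puberty_V <- y[2]
        }
        if (y[9] > 0) { lifespan_t <- t; break }
        if (y[7] < 0.5) { lifespan_t <- t; break }
      }
      if ("age_at_puberty_d" %in% need)
        preds[which(sel & keys == "age_at_puberty_d")] <- puberty_t
      if ("SVL_at_puberty_mm" %in% need && !is.na(puberty_V))
        preds[which(sel & keys == "SVL_at_puberty_mm")] <- svl(puberty_V)
      if ("lifespan_d" %in% need)
        preds[which(sel & keys == "lifespan_d")] <- lifespan_t
    }

    if ("SVL_max_mm" %in% need)
      preds[which(sel & keys == "SVL_max_mm")] <- 10 * L_i / p$del_M
    if ("wet_weight_max_g" %in% need)
      preds[which(sel & keys == "wet_weight_max_g")] <-
        .d_V * L_i^3 * (1 + E_m * .w_E_over_mu_E / .d_V)
    if ("max_reproduction_rate_eggs_per_yr" %in% need) {
      V_i <- L_i^3
      p_C_i <- TC * (p$p_Am * L_i^2)  # at e = 1, L = L_i: p_C = p_Am L^2
      p_R_i <- (1 - p$kappa) * p_C_i - TC * p$k_J * p$E_Hp
      preds[which(sel & keys == "max_reproduction_rate_eggs_per_yr")] <-
        max(0, 365 * p$kap_R * p_R_i / p$E_0)
    }
  }
  preds
}

#' Symmetric weighted loss of a DEB parameterisation
#'
#' `loss = sum_i w_i (pred_i - obs_i)^2 / (pred_i^2 + obs_i^2)`: zero iff all
#' positively weighted predictions equal their observations, and invariant to
#' a joint rescaling of a prediction/observation pair.
#'
#' @param p a [deb_params()].
#' @param data a [zero_variate_data()] table.
#' @param control integration control, see [predict_zero_variate()].
#' @return scalar loss; `Inf` for non-viable parameter sets.
#' @export
loss_fn <- function(p, data, control = list(dt_embryo = 0.1, dt = 0.25, dt_adult = 1)) {
  if (all(data$weight == 0)) stop("all weights are zero", call. = FALSE)
  preds <- predict_zero_variate(p, data$key, data$temperature, control)
  if (anyNA(preds)) return(Inf)
  sum(data$weight * (preds - data$value)^2 / (preds^2 + data$value^2))
}

#' Mean relative error and symmetric mean squared error
#'
#' `MRE = (sum w_i |pred_i - obs_i| / obs_i) / sum w_i` and
#' `SMSE = (sum w_i (pred_i - obs_i)^2 / (pred_i^2 + obs_i^2)) / sum w_i`.
#'
#' @param preds numeric predictions.
#' @param data a [zero_variate_data()] table aligned with `preds`.
#' @return named vector `c(mre, smse)`.
#' @export
goodness_of_fit <- function(preds, data) {
  stopifnot(length(preds) == nrow(data))
  if (any(data$value == 0))
    stop("zero observations are not admissible (choose units without zeros)",
         call. = FALSE)
  w <- data$weight
  mre <- sum(w * abs(preds - data$value) / data$value) / sum(w)
  smse <- sum(w * (preds - data$value)^2 / (preds^2 + data$value^2)) / sum(w)
  c(mre = mre, smse = smse)
}

# Parameter transforms for unconstrained search: log for positive rates,
# logit for kappa.
.free_defaults <- c("kappa", "p_Am", "v", "p_M", "E_Hb", "E_Hp", "h_a")

.to_search <- function(p, free) {
  vapply(free, function(nm) {
    x <- p[[nm]]
    if (nm == "kappa") log(x / (1 - x)) else log(x)
  }, numeric(1))
}

.from_search <- function(theta, p, free) {
  for (i in seq_along(free)) {
    nm <- free[i]
    p[[nm]] <- if (nm == "kappa") 1 / (1 + exp(-theta[i])) else exp(theta[i])
  }
  p
}

#' Estimate DEB parameters by the covariation method
#'
#' Nelder-Mead minimisation of the weighted symmetric loss in log-parameter
#' space (logit for `kappa`), starting from `init`. Proposals violating the
#' parameter invariants (e.g. `E_Hb >= E_Hp`) or producing non-viable life
#' cycles are rejected with infinite loss. The initial egg energy `E_0` is
#' recomputed for every candidate parameter set. Deterministic for a fixed
#' `init` and `seed`.
#'
#' @param data a [zero_variate_data()] table.
#' @param init a [deb_params()] starting point.
#' @param free names of free parameters (default `kappa, p_Am, v, p_M, E_Hb,
#'   E_Hp, h_a`; the rest stay fixed).
#' @param seed integer seed (the search itself is deterministic; the seed
#'   fixes any downstream use).
#' @param max_iter maximum Nelder-Mead iterations.
#' @param control integration control, see [predict_zero_variate()].
#' @return list of class `estimation_result`: `params`, `loss`, `mre`,
#'   `smse`, `converged`, `n_iter`, and the per-datum `predictions`.
#' @export
estimate <- function(data, init, free = .free_defaults, seed = 1L,
                     max_iter = 400,
                     control = list(dt_embryo = 0.1, dt = 0.25, dt_adult = 1)) {
  set.seed(seed)
  theta0 <- .to_search(init, free)
  last_E0 <- init$E_0
  obj <- function(theta) {
    if (any(!is.finite(theta)) || any(abs(theta - theta0) > 12)) return(1e12)
    pc <- .from_search(theta, init, free)
    ok <- tryCatch({ validate_deb_params(pc); TRUE },
                   error = function(e) FALSE)
    if (!ok) return(1e12)
    pc$E_0 <- tryCatch(initial_egg_energy(pc, dt = control$dt_embryo,
                                          guess = last_E0),
                       error = function(e) NA_real_)
    if (is.na(pc$E_0)) return(1e12)
    last_E0 <<- pc$E_0
    l <- loss_fn(pc, data, control)
    if (!is.finite(l)) 1e12 else l
  }
  init_loss <- obj(theta0)
  if (max_iter == 0) {
    gof <- estimation_gof(init, data, control)
    return(structure(list(params = init, loss = init_loss,
                          mre = gof["mre"], smse = gof["smse"],
                          converged = FALSE, n_iter = 0L,
                          predictions = gof_predictions(init, data, control)),
                     class = "estimation_result"))
  }
  opt <- stats::optim(theta0, obj, method = "Nelder-Mead",
                      control = list(maxit = max_iter, reltol = 1e-10))
  best <- .from_search(opt$par, init, free)
  best$E_0 <- initial_egg_energy(best, dt = control$dt_embryo)
  gof <- estimation_gof(best, data, control)
  structure(list(
    params = best, loss = opt$value,
    mre = unname(gof["mre"]), smse = unname(gof["smse"]),
    converged = opt$convergence == 0 && opt$value < init_loss + 1e-12,
    n_iter = opt$counts[["function"]],
    predictions = gof_predictions(best, data, control)
  ), class = "estimation_result")
}

estimation_gof <- function(p, data, control) {
  preds <- predict_zero_variate(p, data$key, data$temperature, control)
  goodness_of_fit(preds, data)
}

gof_predictions <- function(p, data, control) {
  preds <- predict_zero_variate(p, data$key, data$temperature, control)
  data.frame(key = data$key, observed = data$value, predicted = unname(preds),
             relative_error = unname(abs(preds - data$value) / data$value),
             stringsAsFactors = FALSE)
}

#' Write a fit report to JSON
#'
#' @param result an `estimation_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(result, path) {
  out <- list(
    params = result$params[!vapply(result$params, is.null, logical(1))],
    loss = result$loss, mre = result$mre, smse = result$smse,
    converged = result$converged, n_iter = result$n_iter,
    predictions = result$predictions
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read pseudo-data from CSV
#'
#' Columns: `key,value,units,temperature_C,weight` (units column is carried
#' through unchecked).
#'
#' @param path CSV path.
#' @return a [zero_variate_data()] table.
#' @export
read_pseudo_data <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  zero_variate_data(df$key, df$value, df$temperature_C, df$weight)
}
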