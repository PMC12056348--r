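# Statistical comparison stage: OLS with treatment coding and fixed reference
# levels, AICc-based model simplification (delta AICc > 2 rule), Tukey-Kramer
# pairwise post hoc contrasts, and residual diagnostics.

# Fixed reference levels for treatment coding (documented convention).
.ref_levels <- list(
  species = "I_horvathi",
  occurrence = "allotopy_horvathi"
)

#' Build a treatment-coded design matrix
#'
#' Continuous terms enter as given; categorical terms are dummy (treatment)
#' coded against fixed, documented reference levels (species: `I_horvathi`;
#' occurrence: `allotopy_horvathi`; otherwise the first sorted level).
#' Interaction terms (`a:b`) are elementwise products of the coded columns.
#' Column order is deterministic. Rows with `NA` in the response or any term
#' are dropped listwise beforehand by [fit_trait_model()].
#'
#' @param table a `data.frame`.
#' @param formula_terms character vector of term labels, e.g.
#'   `c("elevation", "occurrence", "elevation:occurrence")`.
#' @return list with `X` (numeric matrix incl. intercept), `terms`
#'   (coefficient names) and `factor_info` (levels per categorical term).
#' @export
design_matrix <- function(table, formula_terms) {
  n <- nrow(table)
  cols <- list(`(Intercept)` = rep(1, n))
  factor_info <- list()

  code_main <- function(v) {
    if (!v %in% names(table)) stop("unknown term name: ", v, call. = FALSE)
    x <- table[[v]]
    if (is.numeric(x)) {
      out <- list(); out[[v]] <- x
      return(out)
    }
    lev <- sort(unique(as.character(x)))
    ref <- .ref_levels[[v]]
    if (!is.null(ref) && ref %in% lev) lev <- c(ref, setdiff(lev, ref))
    if (length(lev) < 2)
      stop("categorical term '", v, "' has fewer than 2 levels", call. = FALSE)
    factor_info[[v]] <<- lev
    out <- list()
    for (l in lev[-1]) out[[paste0(v, l)]] <- as.numeric(x == l)
    out
  }

  for (term in formula_terms) {
    parts <- strsplit(term, ":", fixed = TRUE)[[1]]
    coded <- lapply(parts, code_main)
    grid <- coded[[1]]
    if (length(coded) > 1) {
      for (j in 2:length(coded)) {
        new <- list()
        for (a in names(grid)) for (b in names(coded[[j]]))
          new[[paste0(a, ":", b)]] <- grid[[a]] * coded[[j]][[b]]
        grid <- new
      }
    }
    for (nm in names(grid)) cols[[nm]] <- grid[[nm]]
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  # rank-deficiency check with an informative column name
  zerovar <- apply(X[, -1, drop = FALSE], 2, function(c) var(c) == 0)
  if (any(zerovar))
    stop("rank deficiency: constant column(s) ",
         paste(names(which(zerovar)), collapse = ", "), call. = FALSE)
  list(X = X, terms = colnames(X), factor_info = factor_info)
}

#' Fit an ordinary least squares regression
#'
#' QR-based least squares with classical standard errors, two-sided t-tests,
#' and the small-sample corrected information criterion
#' `AICc = n*log(rss/n) + 2k + 2k(k+1)/(n-k-1)`, where `k` counts the
#' coefficients plus the error variance.
#'
#' @param y response vector.
#' @param X design matrix (including the intercept column).
#' @return object of class `ols_fit`: `terms`, `beta`, `se`, `t`, `p`, `n`,
#'   `k`, `rss`, `aicc`, `sigma2`, `df_residual`, `XtX_inv`, `residuals`,
#'   `fitted`.
#' @export
fit_ols <- function(y, X) {
  X <- as.matrix(X)
  n <- length(y)
  k_coef <- ncol(X)
  if (n <= k_coef)
    stop("need more observations than coefficients", call. = FALSE)
  qrX <- qr(X)
  if (qrX$rank < k_coef)
    stop("rank-deficient design matrix (singular X'X)", call. = FALSE)
  beta <- qr.coef(qrX, y)
  fitted <- as.numeric(X %*% beta)
  res <- y - fitted
  rss <- sum(res^2)
  df <- n - k_coef
  sigma2 <- rss / df
  XtX_inv <- chol2inv(qr.R(qrX))
  se <- setNames(sqrt(pmax(diag(XtX_inv) * sigma2, 0)), colnames(X))
  tval <- beta / se
  pval <- 2 * pt(-abs(tval), df)
  k <- k_coef + 1  # error variance counts as a parameter
  aicc <- n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
  structure(list(
    terms = colnames(X), beta = beta, se = se, t = tval, p = pval,
    n = n, k = k, rss = rss, aicc = aicc, sigma2 = sigma2,
    df_residual = df, XtX_inv = XtX_inv, residuals = res, fitted = fitted
  ), class = "ols_fit")
}

#' Choose between nested models by the corrected information criterion
#'
#' The fuller model is retained only when it improves AICc by more than 2
#' (`aicc(reduced) - aicc(full) > 2`); otherwise the simpler model is chosen,
#' including on exact ties.
#'
#' @param full,reduced `ols_fit` objects fitted to the same response.
#' @return list with `chosen` (`"full"` or `"reduced"`), `model`, and
#'   `delta_aicc` (`aicc(reduced) - aicc(full)`).
#' @export
select_model <- function(full, reduced) {
  if (full$n != reduced$n)
    stop("models must be fitted to the same observations", call. = FALSE)
  if (length(reduced$terms) > length(full$terms)) {
    tmp <- full; full <- reduced; reduced <- tmp
  }
  delta <- reduced$aicc - full$aicc
  if (delta > 2) {
    list(chosen = "full", model = full, delta_aicc = delta)
  } else {
    list(chosen = "reduced", model = reduced, delta_aicc = delta)
  }
}

#' Tukey-Kramer pairwise contrasts of a factor's adjusted means
#'
#' All pairwise differences between the factor's level effects, with standard
#' errors from the fitted covariance and p-values from the studentized range
#' distribution (`ptukey`) on the model's residual degrees of freedom. The
#' factor must enter the model additively (its dummies present, no
#' interactions involving it).
#'
#' @param fit an `ols_fit`.
#' @param factor_name the categorical term name.
#' @param levels character vector of the factor's levels in coding order
#'   (reference first), as returned in `design_matrix()$factor_info`.
#' @return `data.frame` with one row per unordered level pair: `level_i`,
#'   `level_j`, `estimate`, `se`, `q`, `adjusted_p`.
#' @export
tukey_pairwise <- function(fit, factor_name, levels) {
  dummy_names <- paste0(factor_name, levels[-1])
  if (!all(dummy_names %in% fit$terms))
    stop("factor '", factor_name, "' is not in the model", call. = FALSE)
  if (any(grepl(":", fit$terms, fixed = TRUE) &
          grepl(factor_name, fit$terms, fixed = TRUE)))
    stop("Tukey contrasts require the factor to enter additively",
         call. = FALSE)
  k <- length(levels)
  idx <- setNames(match(dummy_names, fit$terms), levels[-1])
  effect <- c(setNames(0, levels[1]), fit$beta[idx])

  rows <- list()
  for (i in 1:(k - 1)) for (j in (i + 1):k) {
    ci <- rep(0, length(fit$terms))
    if (i > 1) ci[idx[levels[i]]] <- 1
    cj <- rep(0, length(fit$terms))
    if (j > 1) cj[idx[levels[j]]] <- 1
    cc <- cj - ci
    est <- sum(cc * fit$beta)
    se <- sqrt(drop(t(cc) %*% fit$XtX_inv %*% cc) * fit$sigma2)
    q <- abs(est) * sqrt(2) / se
    p <- 1 - ptukey(q, nmeans = k, df = fit$df_residual)
    rows[[length(rows) + 1]] <- data.frame(
      level_i = levels[i], level_j = levels[j],
      estimate = est, se = se, q = q, adjusted_p = p,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Residual diagnostics
#'
#' Shapiro-Wilk normality test on the residuals, a Breusch-Pagan
#' heteroscedasticity test against the model's regressors, and QQ-plot
#' coordinates (theoretical vs sample quantiles) for visual checking.
#' Skipped with a warning when fewer than 8 observations are available.
#'
#' @param fit an `ols_fit`.
#' @param y response vector used in the fit.
#' @param X design matrix used in the fit.
#' @return list with `shapiro_p`, `bp_p`, `qq` (data.frame `theoretical`,
#'   `sample`), or `NULL` (with a warning) when `n < 8`.
#' @export
diagnostics <- function(fit, y, X) {
  if (fit$n < 8) {
    warning("fewer than 8 observations: diagnostics skipped")
    return(NULL)
  }
  res <- fit$residuals
  sw <- shapiro.test(res)
  Xr <- as.matrix(X)[, -1, drop = FALSE]  # regressors without intercept
  m <- stats::lm(y ~ Xr)
  bp <- lmtest::bptest(m)
  qq <- qqnorm(res, plot.it = FALSE)
  ord <- order(qq$x)
  list(shapiro_p = sw$p.value,
       bp_stat = unname(bp$statistic), bp_p = bp$p.value,
       qq = data.frame(theoretical = qq$x[ord], sample = qq$y[ord]))
}

#' Fit, simplify and test one response of the trait (or microclimate) table
#'
#' Reproduces the statistical protocol of the study for a single response:
#' fit the full model with all pairwise interactions among the supplied
#' predictors and the additive model, keep the fuller model only if it
#' improves AICc by more than 2, then run Tukey-Kramer post hoc contrasts on
#' the occurrence (location-type) factor when it enters the chosen model
#' additively, plus residual diagnostics.
#'
#' @param table data (e.g. from [run_study()]).
#' @param response response column name.
#' @param predictors character vector of predictor columns (continuous or
#'   categorical), e.g. `c("elevation", "species", "occurrence")`.
#' @param interactions logical: offer the pairwise-interaction model.
#' @return list of class `trait_comparison`: `response`, `chosen_formula`,
#'   `fit`, `delta_aicc`, `contrasts` (per categorical predictor),
#'   `diagnostics`, `n_dropped`.
#' @export
fit_trait_model <- function(table, response, predictors, interactions = TRUE) {
  cols <- c(response, predictors)
  keep <- stats::complete.cases(table[, cols])
  n_dropped <- sum(!keep)
  tab <- table[keep, , drop = FALSE]
  y <- tab[[response]]

  additive <- predictors
  dm_red <- design_matrix(tab, additive)
  fit_red <- fit_ols(y, dm_red$X)
  chosen <- fit_red
  dm_chosen <- dm_red
  delta <- NA_real_
  formula_str <- paste(response, "~", paste(predictors, collapse = " + "))

  if (interactions && length(predictors) > 1) {
    pairs <- utils::combn(predictors, 2, FUN = function(v)
      paste(v, collapse = ":"))
    full_terms <- c(additive, pairs)
    ok <- tryCatch({
      dm_full <- design_matrix(tab, full_terms)
      fit_full <- fit_ols(y, dm_full$X)
      TRUE
    }, error = function(e) FALSE)
    if (ok) {
      sel <- select_model(fit_full, fit_red)
      delta <- sel$delta_aicc
      if (sel$chosen == "full") {
        chosen <- fit_full
        dm_chosen <- dm_full
        formula_str <- paste(response, "~",
                             paste(full_terms, collapse = " + "))
      }
    }
  }

  contrasts <- list()
  for (v in names(dm_chosen$factor_info)) {
    has_int <- any(grepl(":", chosen$terms, fixed = TRUE) &
                     grepl(v, chosen$terms, fixed = TRUE))
    if (!has_int)
      contrasts[[v]] <- tukey_pairwise(chosen, v, dm_chosen$factor_info[[v]])
  }
  diag <- tryCatch(diagnostics(chosen, y, dm_chosen$X),
                   warning = function(w) NULL)

  structure(list(response = response, chosen_formula = formula_str,
                 fit = chosen, delta_aicc = delta, contrasts = contrasts,
                 diagnostics = diag, n_dropped = n_dropped,
                 design = dm_chosen),
            class = "trait_comparison")
}

#' Compare all six life-history traits across elevation, species and
#' location type
#'
#' Runs [fit_trait_model()] for every trait column of a [run_study()] table,
#' separately per seasonal trait set, with predictors
#' `elevation * species * occurrence` simplified by AICc.
#'
#' @param traits trait table from [run_study()].
#' @param season_set which season's rows to analyse (`"spring"`/`"summer"`).
#' @return named list of `trait_comparison` objects.
#' @export
compare_traits <- function(traits, season_set = "spring") {
  tab <- traits[traits$season_set == season_set, , drop = FALSE]
  responses <- c("egg_dev_days", "lifespan_years", "reproductive_years",
                 "yearly_bask_h", "yearly_forage_h", "yearly_fecundity")
  out <- lapply(responses, function(r)
    tryCatch(fit_trait_model(tab, r, c("elevation", "species", "occurrence")),
             error = function(e) structure(list(response = r,
                                                error = conditionMessage(e)),
                                           class = "trait_comparison")))
  names(out) <- responses
  out
}

#' Summarise per-site microclimate and regress on elevation and location type
#'
#' Computes per-site means of air temperature, relative humidity, solar
#' radiation and the total number of snow-free days over the horizon from the
#' generated series, then fits `mean ~ elevation + occurrence` for each.
#'
#' @param sites site table.
#' @param gp a [weather_gen_params()].
#' @param cfg a [study_config()].
#' @return list with `site_means` (data.frame) and `fits` (named list of
#'   `trait_comparison`-like results for `mean_T`, `mean_rh`, `mean_solar`,
#'   `snow_free_days`).
#' @export
compare_microclimate <- function(sites, gp = weather_gen_params(),
                                 cfg = study_config()) {
  rows <- lapply(seq_len(nrow(sites)), function(i) {
    m <- generate_site_weather(sites[i, ], gp, cfg,
                               seed = derive_seed(cfg$rng_seed, i))
    data.frame(site = sites[i, ]$name, elevation = sites[i, ]$elevation,
               occurrence = sites[i, ]$occurrence,
               mean_T = mean(m$air_T), mean_rh = mean(m$rh),
               mean_solar = mean(m$solar),
               snow_free_days = sum(!m$snow) / 24,
               stringsAsFactors = FALSE)
  })
  site_means <- do.call(rbind, rows)
  fits <- lapply(c(mean_T = "mean_T", mean_rh = "mean_rh",
                   mean_solar = "mean_solar",
                   snow_free_days = "snow_free_days"),
                 function(r) fit_trait_model(site_means, r,
                                             c("elevation", "occurrence"),
                                             interactions = FALSE))
  list(site_means = site_means, fits = fits)
}

#' Write a statistics report to JSON
#'
#' Per response: chosen formula, coefficient table, delta-AICc, contrasts and
#' diagnostic p-values.
#'
#' @param comparisons named list from [compare_traits()] /
#'   [compare_microclimate()]`$fits`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stats_report <- function(comparisons, path) {
  report <- lapply(comparisons, function(cmp) {
    if (!is.null(cmp$error)) return(list(error = cmp$error))
    list(
      formula = cmp$chosen_formula,
      delta_aicc = cmp$delta_aicc,
      coefficients = data.frame(term = cmp$fit$terms,
                                beta = unname(cmp$fit$beta),
                                se = unname(cmp$fit$se),
                                t = unname(cmp$fit$t),
                                p = unname(cmp$fit$p)),
      aicc = cmp$fit$aicc,
      contrasts = cmp$contrasts,
      shapiro_p = if (!is.null(cmp$diagnostics)) cmp$diagnostics$shapiro_p,
      bp_p = if (!is.null(cmp$diagnostics)) cmp$diagnostics$bp_p
    )
  })
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
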