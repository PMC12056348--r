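make_toy_table <- function(n = 30, seed = 1) {
  set.seed(seed)
  data.frame(
    y = rnorm(n),
    elevation = runif(n, 200, 1300),
    species = rep(c("I_horvathi", "P_muralis"), length.out = n),
    occurrence = rep(c("syntopy", "allotopy_horvathi", "allotopy_muralis"),
                     length.out = n),
    stringsAsFactors = FALSE
  )
}

test_that("design matrices use treatment coding with fixed references", {
  tab <- make_toy_table()
  dm <- design_matrix(tab, c("elevation", "occurrence"))
  # intercept + 1 continuous + 2 dummies
  expect_equal(ncol(dm$X), 4)
  expect_equal(dm$factor_info$occurrence[1], "allotopy_horvathi")
  dm2 <- design_matrix(tab, c("elevation", "species", "occurrence"))
  expect_equal(dm2$factor_info$species[1], "I_horvathi")

  # full three-way interaction of continuous x 2-level x 3-level: 12 columns
  dm3 <- design_matrix(tab, c("elevation", "species", "occurrence",
                              "elevation:species", "elevation:occurrence",
                              "species:occurrence",
                              "elevation:species:occurrence"))
  expect_equal(ncol(dm3$X), 12)

  expect_error(design_matrix(tab, "altitude"), "unknown term")
  tab$flat <- 1
  expect_error(design_matrix(tab, c("elevation", "flat")), "rank deficiency")
})

test_that("fit_ols matches the normal-equations oracle", {
  # exact interpolation
  X <- cbind(1, 0:2)
  fit <- fit_ols(c(0, 1, 2), X)
  expect_equal(unname(fit$beta), c(0, 1), tolerance = 1e-12)
  expect_lt(fit$rss, 1e-20)

  # random instances against the independent linear-algebra oracle
  set.seed(14)
  for (i in 1:10) {
    n <- 25
    X <- cbind(1, matrix(rnorm(n * 3), n))
    colnames(X) <- c("(Intercept)", "x1", "x2", "x3")
    y <- rnorm(n)
    fit <- fit_ols(y, X)
    beta_oracle <- solve(t(X) %*% X) %*% t(X) %*% y
    expect_equal(unname(fit$beta), as.numeric(beta_oracle), tolerance = 1e-10)
    # SEs and p-values agree with lm
    lm_fit <- summary(lm(y ~ X - 1))
    expect_equal(unname(fit$se), unname(lm_fit$coefficients[, 2]),
                 tolerance = 1e-10)
    expect_equal(unname(fit$p), unname(lm_fit$coefficients[, 4]),
                 tolerance = 1e-10)
  }

  expect_error(fit_ols(rnorm(3), cbind(1, rnorm(3), rnorm(3), rnorm(3))),
               "observations")
  expect_error(fit_ols(rnorm(10), cbind(1, 1:10, 2 * (1:10))),
               "rank-deficient")
})

test_that("AICc uses the stated small-sample correction", {
  set.seed(3)
  n <- 20
  X <- cbind(1, rnorm(n))
  y <- rnorm(n)
  fit <- fit_ols(y, X)
  k <- ncol(X) + 1
  aic_part <- n * log(fit$rss / n) + 2 * k
  expect_equal(fit$aicc, aic_part + 2 * k * (k + 1) / (n - k - 1),
               tolerance = 1e-12)
  # the correction vanishes as n grows
  n2 <- 5000
  X2 <- cbind(1, rnorm(n2)); y2 <- rnorm(n2)
  fit2 <- fit_ols(y2, X2)
  k2 <- 3
  expect_lt(fit2$aicc - (n2 * log(fit2$rss / n2) + 2 * k2), 0.01)
})

test_that("model selection applies the delta-AICc > 2 simplicity rule", {
  fake <- function(aicc, terms) structure(
    list(aicc = aicc, n = 30, terms = terms), class = "ols_fit")
  full <- fake(100, c("(Intercept)", "a", "b", "c"))
  red <- fake(105, c("(Intercept)", "a"))
  sel <- select_model(full, red)
  expect_equal(sel$chosen, "full")
  expect_equal(sel$delta_aicc, 5)

  red2 <- fake(101.9, c("(Intercept)", "a"))
  expect_equal(select_model(full, red2)$chosen, "reduced")

  # exact tie: simpler model wins; argument order must not matter
  red3 <- fake(100, c("(Intercept)", "a"))
  expect_equal(select_model(full, red3)$chosen, "reduced")
  expect_equal(select_model(red3, full)$chosen, "reduced")
  expect_identical(select_model(full, red)$model$terms,
                   select_model(red, full)$model$terms)

  bad <- fake(90, "a"); bad$n <- 10
  expect_error(select_model(full, bad), "same observations")
})

test_that("Tukey-Kramer contrasts match the studentized-range oracle", {
  # balanced one-way layout, checked against stats::TukeyHSD
  set.seed(21)
  g <- rep(c("allotopy_horvathi", "allotopy_muralis", "syntopy"), each = 8)
  y <- rnorm(24) + rep(c(0, 0.8, 1.6), each = 8)
  tab <- data.frame(y = y, occurrence = g, stringsAsFactors = FALSE)
  dm <- design_matrix(tab, "occurrence")
  fit <- fit_ols(y, dm$X)
  res <- tukey_pairwise(fit, "occurrence", dm$factor_info$occurrence)
  expect_equal(nrow(res), 3)

  hsd <- TukeyHSD(aov(y ~ factor(g)))[[1]]
  # align pairs (TukeyHSD labels rows "B-A")
  for (r in seq_len(nrow(res))) {
    lab <- paste0(res$level_j[r], "-", res$level_i[r])
    alt <- paste0(res$level_i[r], "-", res$level_j[r])
    row <- if (lab %in% rownames(hsd)) hsd[lab, ] else -hsd[alt, c(1, 2, 3, 4)]
    expect_equal(res$estimate[r], unname(row[1]), tolerance = 1e-9)
    expect_equal(res$adjusted_p[r], unname(abs(row[4])), tolerance = 1e-9)
  }

  # direct q-statistic brute force
  q_oracle <- abs(res$estimate[1]) * sqrt(2) / res$se[1]
  expect_equal(res$q[1], q_oracle, tolerance = 1e-12)
  expect_equal(res$adjusted_p[1],
               1 - ptukey(q_oracle, nmeans = 3, df = fit$df_residual),
               tolerance = 1e-12)

  # zero-noise identical group means: all estimates 0
  y0 <- rep(5, 24) + rep(c(0, 0, 0), each = 8) + rnorm(24, 0, 1e-8)
  fit0 <- fit_ols(y0, dm$X)
  res0 <- tukey_pairwise(fit0, "occurrence", dm$factor_info$occurrence)
  expect_true(all(abs(res0$estimate) < 1e-6))

  # 2-level factor: single contrast, adjusted p equals the unadjusted t test
  tab2 <- data.frame(y = rnorm(20), species = rep(c("I_horvathi", "P_muralis"), 10),
                     stringsAsFactors = FALSE)
  dm2 <- design_matrix(tab2, "species")
  fit2 <- fit_ols(tab2$y, dm2$X)
  res2 <- tukey_pairwise(fit2, "species", dm2$factor_info$species)
  expect_equal(nrow(res2), 1)
  expect_equal(res2$adjusted_p, unname(fit2$p[2]), tolerance = 1e-9)

  expect_error(tukey_pairwise(fit2, "occurrence",
                              c("allotopy_horvathi", "syntopy")),
               "not in the model")
})

test_that("diagnostics flag constructed violations and pass clean residuals", {
  # calibration: standard-normal residuals rarely flagged
  passes <- 0
  for (s in 1:40) {
    set.seed(s)
    n <- 200
    X <- cbind(1, rnorm(n))
    y <- X %*% c(1, 2) + rnorm(n)
    fit <- fit_ols(as.numeric(y), X)
    d <- diagnostics(fit, as.numeric(y), X)
    if (d$shapiro_p > 0.01) passes <- passes + 1
  }
  expect_gte(passes, 38)  # >= 95%

  # heteroscedastic construction is flagged
  set.seed(5)
  n <- 200
  x <- runif(n, 1, 3)
  y <- 1 + 2 * x + rnorm(n, sd = x^2)
  X <- cbind(1, x)
  fit <- fit_ols(y, X)
  d <- diagnostics(fit, y, X)
  expect_lt(d$bp_p, 0.05)

  # QQ coordinates sorted ascending in both axes
  expect_true(all(diff(d$qq$theoretical) >= 0))
  expect_true(all(diff(d$qq$sample) >= 0))

  # small samples skipped with a warning
  Xs <- cbind(1, rnorm(6)); ys <- rnorm(6)
  fits <- fit_ols(ys, Xs)
  expect_warning(out <- diagnostics(fits, ys, Xs), "skipped")
  expect_null(out)
})

test_that("trait-model pipeline selects, tests and reports", {
  set.seed(8)
  tab <- make_toy_table(60)
  tab$y <- 2 + 0.003 * tab$elevation +
    ifelse(tab$species == "P_muralis", 1.5, 0) + rnorm(60, 0, 0.5)
  cmp <- fit_trait_model(tab, "y", c("elevation", "species", "occurrence"))
  expect_s3_class(cmp, "trait_comparison")
  expect_true(cmp$fit$beta[["elevation"]] > 0)
  expect_true("occurrence" %in% names(cmp$contrasts))
  expect_equal(nrow(cmp$contrasts$occurrence), 3)
  tmp <- withr::local_tempfile(fileext = ".json")
  write_stats_report(list(y = cmp), tmp)
  expect_true(jsonlite::validate(readLines(tmp, warn = FALSE) |>
                                   paste(collapse = "\n")))
})
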