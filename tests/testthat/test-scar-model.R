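sim_table <- function(...) {
  tab <- simulate_glmm_table(...)
  scale_predictors(tab, predictors = c(uv = "uv", bv = "bv",
                                       lls = "lls", lat = "lat"))
}

test_that("scaling centers pooled columns and round-trips its scaler", {
  df <- data.frame(uv_mv = c(0, 2, 4, 1), bv_mv = c(1, 3, 2, 5),
                   lls_pct = c(2, 1, 0, 4), lat_ms = c(-5, 5, 0, 10),
                   scar_label = c(0, 1, 0, 1), subject_id = c(1, 1, 2, 2))
  mt <- scale_predictors(df)
  for (nm in c("uv", "bv", "lls", "lat")) {
    expect_equal(mean(mt[[nm]]), 0, tolerance = 1e-8)
    expect_equal(sd(mt[[nm]]), 1, tolerance = 1e-8)
  }
  # hand z-score with the n-1 SD convention: {0, 2} -> +/- 1/sqrt(2) * 2/...
  d2 <- data.frame(uv_mv = c(0, 2), bv_mv = c(0, 1), lls_pct = c(0, 1),
                   lat_ms = c(0, 1), scar_label = c(0, 1), subject_id = c(1, 2))
  m2 <- scale_predictors(d2)
  expect_equal(m2$uv, c(-1, 1) / sqrt(2), tolerance = 1e-12)
  # re-applying the stored scaler reproduces the columns bit-identically
  m3 <- scale_predictors(df, scaler = attr(mt, "scaler"))
  expect_identical(m3$uv, mt$uv)
  # constant predictor is refused
  dfc <- df
  dfc$bv_mv <- 3
  expect_error(scale_predictors(dfc), "zero-variance")
})

test_that("the mixed fit matches plain logistic regression when clusters carry no effect", {
  tab <- simulate_glmm_table(beta = c(uv = -1.5, bv = 0.8), beta0 = -0.5,
                             sigma_u = 0, n_subjects = 10,
                             points_per_subject = 150, seed = 3)
  mt <- scale_predictors(tab, predictors = c(uv = "uv", bv = "bv"))
  fit <- fit_scar_glmm(mt, predictors = c("uv", "bv"))
  oracle <- glm(scar ~ uv + bv, data = mt, family = binomial())
  expect_equal(unname(fit$fixed[c("uv", "bv")]),
               unname(coef(oracle)[c("uv", "bv")]), tolerance = 2e-3)
  expect_lt(fit$random_intercept_sd, 0.15)
  # single-class outcome is refused
  mt1 <- mt
  mt1$scar <- 1L
  expect_error(fit_scar_glmm(mt1), "both outcome classes")
})

test_that("null data yield near-unit odds ratios", {
  mt <- sim_table(beta = c(uv = 0, bv = 0, lls = 0, lat = 0), beta0 = 0,
                  sigma_u = 0.3, seed = 5)
  fit <- fit_scar_glmm(mt)
  expect_true(all(abs(log(fit$odds_ratios)) < 0.25))
})

test_that("AIC backward selection drops a pure-noise predictor", {
  drops <- vapply(1:10, function(r) {
    tab <- simulate_glmm_table(beta = c(uv = -2, bv = -1, lls = -0.8, lat = 0),
                               seed = 100 + r)
    mt <- scale_predictors(tab, predictors = c(uv = "uv", bv = "bv",
                                               lls = "lls", lat = "lat"))
    sel <- backward_select_aic(mt)
    !("lat" %in% sel$predictors)
  }, logical(1))
  expect_gte(sum(drops), 6)
  # all-noise predictors can shrink to the intercept-only model
  tabn <- simulate_glmm_table(beta = c(uv = 0, bv = 0), beta0 = 0,
                              sigma_u = 0.2, seed = 11)
  mtn <- scale_predictors(tabn, predictors = c(uv = "uv", bv = "bv"))
  seln <- backward_select_aic(mtn, predictors = c("uv", "bv"))
  expect_lte(length(seln$predictors), 1)
})

test_that("bootstrap odds-ratio intervals are deterministic and sane", {
  mt <- sim_table(seed = 9)
  b1 <- bootstrap_or_ci(mt, n_boot = 12, seed = 42)
  b2 <- bootstrap_or_ci(mt, n_boot = 12, seed = 42)
  expect_identical(b1$or_ci, b2$or_ci)
  expect_true(all(b1$or_ci$lower <= b1$or_ci$or + 1e-9))
  expect_true(all(b1$or_ci$upper >= b1$or_ci$or - 1e-9))
  expect_true(all(b1$or_ci$lower > 0))
})

test_that("predicted probabilities use the mean random intercept and scaler", {
  mt <- sim_table(seed = 13)
  fit <- fit_scar_glmm(mt)
  # all predictors at the training means -> plogis(intercept)
  mu <- data.frame(uv = fit$scaler$uv[["mean"]], bv = fit$scaler$bv[["mean"]],
                   lls = fit$scaler$lls[["mean"]], lat = fit$scaler$lat[["mean"]])
  expect_equal(predict_probability(fit, mu),
               plogis(unname(fit$fixed[["(Intercept)"]])), tolerance = 1e-12)
  # lowering UV (fitted OR < 1) raises the predicted probability
  lo <- mu; lo$uv <- lo$uv - 1
  expect_gt(predict_probability(fit, lo), predict_probability(fit, mu))
  expect_error(predict_probability(fit, mu[, -1]), "missing predictor")
  # hand-computed logistic: b0 = 0, b_uv = -2, z = 1 -> 0.1192
  toy <- fit
  toy$fixed <- c("(Intercept)" = 0, uv = -2, bv = 0, lls = 0, lat = 0)
  z1 <- mu
  z1$uv <- fit$scaler$uv[["mean"]] + fit$scaler$uv[["sd"]]
  expect_equal(predict_probability(toy, z1), plogis(-2), tolerance = 1e-12)
})

test_that("the C-statistic equals brute-force concordance and is rank-invariant", {
  expect_equal(c_statistic(c(1, 1, 0, 0), c(0.9, 0.4, 0.5, 0.1)), 0.75)
  expect_equal(c_statistic(c(1, 0), c(0.9, 0.1)), 1)
  expect_equal(c_statistic(c(1, 0, 1, 0), rep(0.5, 4)), 0.5)
  expect_warning(cna <- c_statistic(c(1, 1), c(0.2, 0.3)), "single outcome")
  expect_true(is.na(cna))
  set.seed(17)
  for (i in 1:20) {
    n <- sample(10:80, 1)
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    p <- round(runif(n), 2)  # rounding forces ties
    expect_identical(c_statistic(y, p), brute_force_auc(y, p))
    # strictly monotone transform leaves the AUC unchanged
    expect_identical(c_statistic(y, qlogis(pmin(pmax(p, 0.01), 0.99))),
                     c_statistic(y, pmin(pmax(p, 0.01), 0.99)))
  }
})

test_that("within-subject C weights subjects by their point counts", {
  # subject A: perfectly concordant with 10 points; B: C = 0.5 with 30
  y <- c(rep(c(1, 0), 5), rep(c(1, 0), 15))
  p <- c(ifelse(y[1:10] == 1, 0.9, 0.1), rep(0.5, 30))
  s <- rep(c("A", "B"), c(10, 30))
  w <- within_subject_c(y, p, s)
  expect_equal(w$weighted_c, 0.25 * 1 + 0.75 * 0.5)
  # single-class subjects are excluded and listed
  y2 <- c(y, rep(1, 5))
  p2 <- c(p, runif(5))
  s2 <- c(s, rep("C", 5))
  w2 <- within_subject_c(y2, p2, s2)
  expect_identical(w2$excluded_subjects, "C")
  expect_equal(w2$weighted_c, w$weighted_c)
  # one contributing subject -> its own C
  w1 <- within_subject_c(y[1:10], p[1:10], s[1:10])
  expect_equal(w1$weighted_c, 1)
})

test_that("calibration slope is ~1 for self-generated outcomes", {
  mt <- sim_table(seed = 21)
  fit <- fit_scar_glmm(mt)
  lp <- linear_predictor(fit, mt)
  set.seed(22)
  idx <- sample.int(nrow(mt), 4000, replace = TRUE)
  y_new <- rbinom(4000, 1, plogis(lp[idx]))
  cs <- calibration_slope(lp[idx], y_new, mt$subject[idx], method = "fixed")
  expect_equal(cs$slope, 1, tolerance = 0.06)
})

test_that("internal validation report is complete and deterministic", {
  mt <- sim_table(seed = 31)
  v1 <- internal_validation(mt, n_boot = 10, seed = 77, slope_method = "fixed")
  v2 <- internal_validation(mt, n_boot = 10, seed = 77, slope_method = "fixed")
  expect_identical(v1$optimism_corrected_c, v2$optimism_corrected_c)
  expect_identical(v1$optimism_corrected_slope, v2$optimism_corrected_slope)
  expect_true(v1$c_statistic >= 0 && v1$c_statistic <= 1)
  expect_lte(v1$optimism_corrected_c, v1$c_statistic + 1e-9)
  expect_length(v1$c_ci, 2)
  expect_length(v1$slope_ci, 2)
  expect_true(is.finite(v1$sensitivity_pct) && is.finite(v1$specificity_pct))
  expect_equal(v1$n_boot_used + v1$n_boot_dropped, v1$n_boot)
})
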