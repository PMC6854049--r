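#' Scale and center the EMM predictors
#'
#' Builds the model table: z-scored predictors (pooled over all points,
#' sample SD with n-1 denominator), the binary scar outcome and the
#' subject cluster.  The scaler (per-predictor mean and SD) is stored so
#' new data can be placed on the training scale.
#'
#' @param df data.frame of matched points.
#' @param predictors named character vector mapping short predictor names
#'   to raw column names.
#' @param outcome,cluster column names of the scar label and subject id.
#' @param scaler optional stored scaler to re-apply instead of estimating.
#' @return data.frame of class `model_table` with columns `uv`, `bv`,
#'   `lls`, `lat` (or the supplied names), `scar`, `subject`; attribute
#'   `scaler`.
#' @export
scale_predictors <- function(df,
                             predictors = c(uv = "uv_mv", bv = "bv_mv",
                                            lls = "lls_pct", lat = "lat_ms"),
                             outcome = "scar_label", cluster = "subject_id",
                             scaler = NULL) {
  y <- df[[outcome]]
  if (is.null(y) || anyNA(y) || !all(y %in% c(0, 1)))
    stop("outcome must be binary 0/1 without missing values")
  out <- data.frame(row.names = seq_len(nrow(df)))
  if (is.null(scaler)) {
    scaler <- list()
    for (nm in names(predictors)) {
      x <- df[[predictors[[nm]]]]
      if (any(!is.finite(x))) stop(sprintf("predictor %s has non-finite values", nm))
      s <- stats::sd(x)
      if (s < 1e-12) stop(sprintf("zero-variance predictor: %s", nm))
      scaler[[nm]] <- c(mean = mean(x), sd = s, raw = NA)
      attr(scaler[[nm]], "raw_col") <- predictors[[nm]]
    }
  }
  for (nm in names(predictors)) {
    x <- df[[predictors[[nm]]]]
    out[[nm]] <- (x - scaler[[nm]][["mean"]]) / scaler[[nm]][["sd"]]
  }
  out$scar <- as.integer(y)
  out$subject <- factor(df[[cluster]])
  if (nlevels(out$subject) < 2) stop("at least 2 subject clusters required")
  attr(out, "scaler") <- scaler
  class(out) <- c("model_table", "data.frame")
  out
}

# shared quiet glmer wrapper; collects convergence messages
glmm_fit_quiet <- function(formula, data, nagq = 1, fast = FALSE) {
  msgs <- character()
  ctrl <- lme4::glmerControl(calc.derivs = !fast,
                             check.conv.singular = lme4::.makeCC(action = "ignore", tol = 1e-4))
  fit <- withCallingHandlers(
    lme4::glmer(formula, data = data, family = stats::binomial(),
                nAGQ = nagq, control = ctrl),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      msgs <<- c(msgs, conditionMessage(m))
      invokeRestart("muffleMessage")
    })
  attr(fit, "fit_messages") <- msgs
  fit
}

#' Fit the random-intercept logistic scar model
#'
#' Maximizes the marginal likelihood of
#' `logit P(scar = 1 | x, subject j) = b0 + b'x + u_j`, `u_j ~ N(0, s_u^2)`
#' over the scaled predictors, integrating the random intercept by adaptive
#' Gauss-Hermite quadrature (`nagq` nodes) or the Laplace approximation
#' (`nagq = 1`).
#'
#' @param table `model_table` from [scale_predictors()].
#' @param predictors predictor subset to include (default all four).
#' @param nagq adaptive quadrature nodes (1 = Laplace).
#' @return object of class `scar_glmm` with `fixed` (log-odds per SD),
#'   `odds_ratios`, `random_intercept_sd`, `aic`, `converged`, the stored
#'   `scaler` and the underlying `lme4` fit.
#' @export
fit_scar_glmm <- function(table, predictors = c("uv", "bv", "lls", "lat"),
                          nagq = 1) {
  if (length(unique(table$scar)) < 2)
    stop("both outcome classes must be present")
  if (nlevels(droplevels(table$subject)) < 2)
    stop("at least 2 subject clusters required")
  rhs <- if (length(predictors)) paste(predictors, collapse = " + ") else "1"
  fo <- stats::as.formula(paste("scar ~", rhs, "+ (1 | subject)"))
  fit <- glmm_fit_quiet(fo, table, nagq = nagq)
  msgs <- attr(fit, "fit_messages")
  fe <- lme4::fixef(fit)
  structure(list(
    fixed = fe,
    odds_ratios = exp(fe[setdiff(names(fe), "(Intercept)")]),
    random_intercept_sd = sqrt(unname(lme4::VarCorr(fit)$subject[1])),
    aic = stats::AIC(fit),
    converged = !any(grepl("failed to converge|unable to evaluate",
                           msgs, ignore.case = TRUE)),
    messages = msgs,
    predictors = predictors,
    scaler = attr(table, "scaler"),
    model = fit), class = "scar_glmm")
}

#' @export
print.scar_glmm <- function(x, ...) {
  cat("random-intercept logistic scar model\n")
  cat(sprintf("  predictors: %s\n", paste(x$predictors, collapse = ", ")))
  if (length(x$odds_ratios)) {
    cat("  odds ratios (per SD):\n")
    for (nm in names(x$odds_ratios))
      cat(sprintf("    %-4s %.3f\n", nm, x$odds_ratios[[nm]]))
  }
  cat(sprintf("  random intercept SD %.3f, AIC %.1f, converged: %s\n",
              x$random_intercept_sd, x$aic, x$converged))
  invisible(x)
}

#' Backward predictor selection by AIC
#'
#' Starting from the full predictor set, repeatedly removes the predictor
#' whose removal lowers the AIC most, until no removal lowers it.  Ties
#' break deterministically by the fixed predictor order.
#'
#' @param table `model_table`.
#' @param predictors starting predictor set (default UV, BV, LLS, LAT).
#' @param nagq quadrature nodes.
#' @return list with `predictors` (selected set), `fit` (`scar_glmm`) and
#'   `trace` (data.frame of steps).
#' @export
backward_select_aic <- function(table, predictors = c("uv", "bv", "lls", "lat"),
                                nagq = 1) {
  current <- predictors
  fit <- fit_scar_glmm(table, current, nagq = nagq)
  trace <- data.frame(step = 0L, dropped = "", aic = fit$aic)
  step <- 0L
  while (length(current) > 0) {
    cand <- lapply(seq_along(current), function(i)
      fit_scar_glmm(table, current[-i], nagq = nagq))
    aics <- vapply(cand, function(f) f$aic, 0)
    best <- which.min(aics)  # which.min takes the first = fixed-order tie-break
    if (aics[best] >= fit$aic) break
    step <- step + 1L
    trace <- rbind(trace, data.frame(step = step, dropped = current[best],
                                     aic = aics[best]))
    fit <- cand[[best]]
    current <- current[-best]
  }
  list(predictors = current, fit = fit, trace = trace)
}

# resample row indices keeping both classes and >= 2 clusters
resample_rows_valid <- function(table, max_attempts = 10) {
  n <- nrow(table)
  for (a in seq_len(max_attempts)) {
    idx <- sample.int(n, n, replace = TRUE)
    if (length(unique(table$scar[idx])) == 2 &&
        length(unique(table$subject[idx])) >= 2) return(idx)
  }
  NULL
}

#' Bootstrap percentile confidence intervals for the odds ratios
#'
#' Resamples individual points with replacement, refits the model, and
#' returns per-predictor 2.5/97.5 percentile intervals of the odds
#' ratios.  Replicates that fail to converge (or lose a class despite up
#' to 10 redraws) are dropped and counted.
#'
#' @param table `model_table`.
#' @param predictors predictor set of the final model.
#' @param n_boot bootstrap replicates (default 500).
#' @param seed RNG seed.
#' @param nagq quadrature nodes.
#' @return list with `or_ci` (data.frame: predictor, or, lower, upper),
#'   `n_used`, `n_dropped` (a warning is attached when > 20% dropped).
#' @export
bootstrap_or_ci <- function(table, predictors = c("uv", "bv", "lls", "lat"),
                            n_boot = 500, seed = 1, nagq = 1) {
  base <- fit_scar_glmm(table, predictors, nagq = nagq)
  set.seed(seed)
  ors <- matrix(NA_real_, n_boot, length(predictors),
                dimnames = list(NULL, predictors))
  dropped <- 0L
  for (b in seq_len(n_boot)) {
    idx <- resample_rows_valid(table)
    if (is.null(idx)) { dropped <- dropped + 1L; next }
    fb <- tryCatch(fit_scar_glmm(table[idx, , drop = FALSE], predictors,
                                 nagq = nagq),
                   error = function(e) NULL)
    if (is.null(fb) || !fb$converged) { dropped <- dropped + 1L; next }
    ors[b, ] <- fb$odds_ratios[predictors]
  }
  used <- !is.na(ors[, 1])
  ci <- if (any(used))
    t(apply(ors[used, , drop = FALSE], 2, stats::quantile,
            probs = c(0.025, 0.975)))
  else matrix(NA_real_, length(predictors), 2)
  out <- list(or_ci = data.frame(predictor = predictors,
                                 or = unname(base$odds_ratios[predictors]),
                                 lower = ci[, 1], upper = ci[, 2],
                                 row.names = NULL),
              n_used = sum(used), n_dropped = dropped)
  if (dropped > 0.2 * n_boot)
    out$warning <- sprintf("%d of %d bootstrap replicates failed", dropped, n_boot)
  out
}

#' Linear predictor of a fitted scar model on a model table
#' @param fit `scar_glmm`.
#' @param table `model_table` on the same scale.
#' @return fixed-effects linear predictor (mean random intercept = 0).
#' @export
linear_predictor <- function(fit, table) {
  lp <- rep(fit$fixed[["(Intercept)"]], nrow(table))
  for (nm in fit$predictors) lp <- lp + fit$fixed[[nm]] * table[[nm]]
  lp
}

#' Predicted scar probability for new raw measurements
#'
#' Applies the stored scaler to the raw EMM values and evaluates
#' `plogis(b0 + b'z)` with the random intercept at its distributional
#' mean (0), since the cluster effect of a new subject is unknown.
#'
#' @param fit `scar_glmm`.
#' @param newdata data.frame with the raw predictor columns the scaler was
#'   trained on (e.g. `uv_mv`, `bv_mv`, `lls_pct`, `lat_ms`).
#' @return predicted probabilities.
#' @export
predict_probability <- function(fit, newdata) {
  lp <- rep(fit$fixed[["(Intercept)"]], nrow(newdata))
  for (nm in fit$predictors) {
    sc <- fit$scaler[[nm]]
    col <- attr(sc, "raw_col")
    if (is.null(col) || is.null(newdata[[col]])) col <- nm
    x <- newdata[[col]]
    if (is.null(x)) stop(sprintf("missing predictor column for %s", nm))
    lp <- lp + fit$fixed[[nm]] * (x - sc[["mean"]]) / sc[["sd"]]
  }
  stats::plogis(lp)
}

#' Concordance statistic (area under the ROC curve)
#'
#' Probability that a randomly chosen scar point receives a higher
#' predicted probability than a randomly chosen non-scar point, ties
#' counted one half; computed by the rank (Wilcoxon) identity.
#'
#' @param labels binary outcomes.
#' @param probabilities predicted probabilities (any monotone score).
#' @return C-statistic in \[0, 1\]; `NA` with a warning for single-class
#'   input.
#' @export
c_statistic <- function(labels, probabilities) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    warning("C-statistic undefined with a single outcome class")
    return(NA_real_)
  }
  r <- rank(probabilities)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Within-subject C-statistic
#'
#' Mean of the per-subject C-statistics over subjects with both outcome
#' classes, weighted by each contributing subject's EMM point count.
#'
#' @param labels,probabilities,subjects point-level data.
#' @return list with `weighted_c`, `per_subject` (data.frame with subject,
#'   n, c) and `excluded_subjects` (single-class subjects).
#' @export
within_subject_c <- function(labels, probabilities, subjects) {
  per <- lapply(split(seq_along(labels), subjects), function(ix) {
    has_both <- length(unique(labels[ix])) == 2
    data.frame(n = length(ix),
               c = if (has_both)
                 c_statistic(labels[ix], probabilities[ix]) else NA_real_)
  })
  df <- do.call(rbind, per)
  df$subject <- rownames(df)
  rownames(df) <- NULL
  ok <- !is.na(df$c)
  if (!any(ok)) {
    warning("no subject has both outcome classes")
    return(list(weighted_c = NA_real_, per_subject = df,
                excluded_subjects = df$subject))
  }
  w <- df$n[ok] / sum(df$n[ok])
  list(weighted_c = sum(w * df$c[ok]),
       per_subject = df[, c("subject", "n", "c")],
       excluded_subjects = df$subject[!ok])
}

#' Calibration slope of a linear predictor
#'
#' Refits `logit P(y) = a + b*LP + u0_j + u1_j*LP` (random intercept and
#' random slope per subject) and returns the fixed-effect slope `b`; a
#' slope of 1 indicates good calibration.  Falls back to a fixed-effects
#' logistic slope with a warning when the mixed fit fails.
#'
#' @param lp linear predictor values.
#' @param labels binary outcomes.
#' @param subjects cluster ids.
#' @param method `"mixed"` (random slope + intercept) or `"fixed"` (plain
#'   logistic).
#' @return list with `slope`, `method_used`, `converged`.
#' @export
calibration_slope <- function(lp, labels, subjects,
                              method = c("mixed", "fixed")) {
  method <- match.arg(method)
  dat <- data.frame(y = as.integer(labels), lp = lp, subject = factor(subjects))
  if (method == "mixed" && nlevels(dat$subject) >= 2) {
    fit <- tryCatch(glmm_fit_quiet(y ~ lp + (1 + lp | subject), dat,
                                   nagq = 1, fast = TRUE),
                    error = function(e) NULL)
    if (!is.null(fit)) {
      msgs <- attr(fit, "fit_messages")
      conv <- !any(grepl("failed to converge", msgs, ignore.case = TRUE))
      if (conv)
        return(list(slope = unname(lme4::fixef(fit)[["lp"]]),
                    method_used = "mixed", converged = TRUE))
    }
    warning("random-slope calibration model did not converge; using fixed-effects slope")
  }
  gf <- suppressWarnings(stats::glm(y ~ lp, data = dat,
                                    family = stats::binomial()))
  list(slope = unname(stats::coef(gf)[["lp"]]),
       method_used = "fixed", converged = gf$converged)
}

#' Bootstrap internal validation with optimism correction
#'
#' Harrell-style validation of the final model: for each replicate,
#' individual points are resampled with replacement, the model is refitted
#' on the replicate, and the C-statistic and calibration slope are
#' evaluated both on the replicate and on the original data; the mean
#' difference is the optimism, subtracted from the apparent performance.
#' Point-level (not cluster-level) resampling reflects the small number of
#' subjects.  Sensitivity and specificity are computed on the original
#' data at `prob_threshold`.
#'
#' @param table `model_table`.
#' @param predictors final predictor set.
#' @param n_boot replicates (default 500).
#' @param seed RNG seed.
#' @param prob_threshold operating point for sensitivity/specificity.
#' @param nagq quadrature nodes.
#' @param slope_method `"mixed"` or `"fixed"` for the apparent and
#'   replicate calibration slopes.
#' @return object of class `validation_report`.
#' @export
internal_validation <- function(table, predictors = c("uv", "bv", "lls", "lat"),
                                n_boot = 500, seed = 1, prob_threshold = 0.5,
                                nagq = 1, slope_method = "mixed") {
  fit <- fit_scar_glmm(table, predictors, nagq = nagq)
  y <- table$scar
  lp0 <- linear_predictor(fit, table)
  p0 <- stats::plogis(lp0)
  app_c <- c_statistic(y, p0)
  wsc <- within_subject_c(y, p0, table$subject)
  app_slope <- calibration_slope(lp0, y, table$subject, method = slope_method)

  set.seed(seed)
  opt_c <- opt_slope <- app_c_b <- app_slope_b <- rep(NA_real_, n_boot)
  dropped <- 0L
  for (b in seq_len(n_boot)) {
    idx <- resample_rows_valid(table)
    if (is.null(idx)) { dropped <- dropped + 1L; next }
    tb <- table[idx, , drop = FALSE]
    attr(tb, "scaler") <- attr(table, "scaler")
    fb <- tryCatch(fit_scar_glmm(tb, predictors, nagq = nagq),
                   error = function(e) NULL)
    if (is.null(fb) || !fb$converged) { dropped <- dropped + 1L; next }
    lp_bb <- linear_predictor(fb, tb)
    lp_bo <- linear_predictor(fb, table)
    c_bb <- c_statistic(tb$scar, stats::plogis(lp_bb))
    c_bo <- c_statistic(y, stats::plogis(lp_bo))
    s_bb <- calibration_slope(lp_bb, tb$scar, tb$subject, method = slope_method)
    s_bo <- calibration_slope(lp_bo, y, table$subject, method = slope_method)
    opt_c[b] <- c_bb - c_bo
    opt_slope[b] <- s_bb$slope - s_bo$slope
    # sampling variability of the apparent metrics (base model, resampled rows)
    app_c_b[b] <- c_statistic(y[idx], p0[idx])
    app_slope_b[b] <- calibration_slope(lp0[idx], y[idx], table$subject[idx],
                                        method = "fixed")$slope
  }
  used <- !is.na(opt_c)
  structure(list(
    c_statistic = app_c,
    c_ci = unname(stats::quantile(app_c_b[used], c(0.025, 0.975))),
    within_subject_c = wsc,
    calibration_slope = app_slope$slope,
    slope_ci = unname(stats::quantile(app_slope_b[used], c(0.025, 0.975))),
    optimism_c = mean(opt_c[used]),
    optimism_slope = mean(opt_slope[used]),
    optimism_corrected_c = app_c - mean(opt_c[used]),
    optimism_corrected_slope = app_slope$slope - mean(opt_slope[used]),
    sensitivity_pct = 100 * mean(p0[y == 1] >= prob_threshold),
    specificity_pct = 100 * mean(p0[y == 0] < prob_threshold),
    prob_threshold = prob_threshold,
    n_boot = n_boot, n_boot_used = sum(used), n_boot_dropped = dropped,
    fit = fit), class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("internal validation (point-level bootstrap)\n")
  cat(sprintf("  C-statistic           %.3f [%.3f-%.3f]\n",
              x$c_statistic, x$c_ci[1], x$c_ci[2]))
  cat(sprintf("  within-subject C      %.3f\n", x$within_subject_c$weighted_c))
  cat(sprintf("  calibration slope     %.3f [%.3f-%.3f]\n",
              x$calibration_slope, x$slope_ci[1], x$slope_ci[2]))
  cat(sprintf("  optimism-corrected C  %.3f, slope %.3f (n_boot = %d, used %d)\n",
              x$optimism_corrected_c, x$optimism_corrected_slope,
              x$n_boot, x$n_boot_used))
  cat(sprintf("  sens/spec at p >= %.2f: %.1f%% / %.1f%%\n",
              x$prob_threshold, x$sensitivity_pct, x$specificity_pct))
  invisible(x)
}
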