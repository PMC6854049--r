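test_that("peak features take the first attainment of the minimum", {
  pk <- peak_features(c(0, 100, 200, 300), c(0, -10, -26, -20))
  expect_equal(pk$strain_max_pct, -26)
  expect_equal(pk$ttp_max_ms, 200)
  # tie resolved to the earliest time
  pk2 <- peak_features(c(0, 100, 200, 300), c(0, -26, -26, -20))
  expect_equal(pk2$ttp_max_ms, 100)
  # flat zero curve
  pk0 <- peak_features(c(0, 100, 200), c(0, 0, 0))
  expect_equal(pk0$strain_max_pct, 0)
  expect_equal(pk0$ttp_max_ms, 0)
  expect_error(peak_features(c(0, 100), c(0, -1)), "3 samples")
  expect_error(peak_features(c(0, 100, 50), c(0, -1, -2)), "increasing")
})

test_that("tangent onset is exact on an ideal ramp and equivariant", {
  t <- seq(0, 400, by = 25)
  s <- ifelse(t < 100, 0, -(t - 100) * 0.1)
  expect_equal(onset_time(t, s), 100, tolerance = 1e-9)
  # +50 ms time shift moves the onset by +50 ms
  expect_equal(onset_time(t + 50, s), 150, tolerance = 1e-9)
  # amplitude scaling leaves timing untouched, scales the peak
  expect_equal(onset_time(t, 3 * s), 100, tolerance = 1e-9)
  pk <- peak_features(t, 3 * s)
  expect_equal(pk$strain_max_pct, 3 * min(s))
  expect_equal(pk$ttp_max_ms, peak_features(t, s)$ttp_max_ms)
  # flat / non-shortening curves have no onset
  expect_true(is.na(onset_time(t, rep(0, length(t)))))
  expect_true(is.na(onset_time(t, seq(0, -1, length.out = length(t)) * -5)))
})

test_that("onset does not precede the peak and stays within the window", {
  set.seed(8)
  for (i in 1:25) {
    t0 <- sample(seq(50, 250, by = 25), 1)
    tp <- t0 + sample(seq(75, 300, by = 25), 1)
    t <- seq(0, 700, by = 25)
    s <- emmscar:::strain_curve_eval(t, runif(1, -35, -8), t0, tp)
    on <- onset_time(t, s)
    pk <- peak_features(t, s)
    expect_true(on >= t[1] && on <= pk$ttp_max_ms)
  }
})

test_that("akinetic filter splits at the -7.5% rule and is idempotent", {
  feats <- data.frame(subject_id = 1, slice_index = 1, sector_index = 0:3,
                      strain_max_pct = c(-26, -5, -7.5, -7.4),
                      ttp_max_ms = 300, t_onset_ms = 100)
  fl <- akinetic_filter(feats)
  expect_equal(fl$included$sector_index, c(0L, 2L))   # -7.5 exactly is kept
  expect_equal(fl$akinetic$sector_index, c(1L, 3L))
  again <- akinetic_filter(fl$included)
  expect_identical(nrow(again$akinetic), 0L)
  expect_identical(again$included$sector_index, fl$included$sector_index)
})

test_that("generator round-trip recovers peak and onset from the frame grid", {
  cfg <- small_config()
  sub <- simulate_subject(cfg, 2)
  ft <- strain_feature_table(sub$strain$curves,
                             threshold_pct = cfg$akinetic_threshold_pct)
  m <- merge(ft, sub$strain$truth,
             by = c("subject_id", "slice_index", "sector_index"))
  expect_equal(m$strain_max_pct, m$amplitude_pct, tolerance = 1e-9)
  ok <- !m$akinetic.x
  expect_equal(m$ttp_max_ms[ok], m$tp_ms[ok], tolerance = 1e-9)
  frame <- diff(sort(unique(sub$strain$curves$time_ms)))[1]
  expect_lt(max(abs(m$t_onset_ms[ok] - m$t0_ms[ok])), frame)
  # noiseless curves: filter agrees with the generator's akinetic truth
  expect_identical(m$akinetic.x, m$akinetic.y)
})

test_that("akinetic LV fraction and strain medians track the configuration", {
  cfg <- lv_config(n_theta = 24, n_phi = 36)
  feats <- lapply(1:6, function(i) {
    sub <- simulate_subject(cfg, i)
    ft <- strain_feature_table(sub$strain$curves)
    tr <- sub$strain$truth
    merge(ft, tr, by = c("subject_id", "slice_index", "sector_index"))
  })
  m <- do.call(rbind, feats)
  akin_pct <- 100 * mean(m$akinetic.x)
  expect_gt(akin_pct, 5)    # observed condition: 13.2 +/- 6.9% of the LV
  expect_lt(akin_pct, 22)
  incl <- !m$akinetic.x
  expect_equal(median(m$strain_max_pct[incl & !m$scar]), -26.0, tolerance = 0.08)
  expect_equal(median(m$strain_max_pct[incl & m$scar]), -15.7, tolerance = 0.15)
})

test_that("curves with too many missing frames are flagged invalid", {
  t <- seq(0, 800, length.out = 30)
  s <- emmscar:::strain_curve_eval(t, -20, 100, 350)
  s[1:9] <- NA  # 30% missing
  cu <- data.frame(subject_id = 1, slice_index = 1, sector_index = 0,
                   time_ms = t, strain_pct = s)
  ft <- strain_feature_table(cu)
  expect_false(ft$valid[1])
  expect_true(is.na(ft$strain_max_pct[1]))
})
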