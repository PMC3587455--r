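test_that("eval_stats matches the hand-computed worked example", {
  # M = (2,2,3), O = (1,8,3): ratios 2, 0.25, 1 -> FAC2 2/3;
  # MB = -5/3; NMB = -5/12; RMSE = sqrt(37/3); r = -0.5/(sd_m sd_o)
  st <- eval_stats(c(2, 2, 3), c(1, 8, 3))
  expect_equal(st$n, 3)
  expect_equal(st$fac2, 2 / 3)
  expect_equal(st$mb, -1.667, tolerance = 1e-3)
  expect_equal(st$nmb, -0.4167, tolerance = 1e-3)
  expect_equal(st$rmse, 3.512, tolerance = 1e-3)
  expect_equal(st$r, -0.240, tolerance = 1e-2)
})

test_that("eval_stats degenerate and convention cases", {
  # identical series: perfect scores, r undefined (zero variance)
  same <- eval_stats(c(3, 3, 3), c(3, 3, 3))
  expect_equal(same$fac2, 1)
  expect_equal(same$mb, 0)
  expect_equal(same$rmse, 0)
  expect_true(is.na(same$r))
  # zero-observation convention: (0,0) inside, (M>0, 0) outside
  z <- eval_stats(c(0, 1, 5), c(0, 0, 5))
  expect_equal(z$fac2, 2 / 3)
  # pairs with missing values are dropped before any statistic
  miss <- eval_stats(c(1, NA, 3, 4), c(1, 2, NA, 4))
  expect_equal(miss$n, 2)
  expect_equal(miss$mb, 0)
  expect_error(eval_stats(1, 1), "at least 2")
})

test_that("eval_stats translation and scaling properties", {
  set.seed(14)
  m <- runif(50, 10, 60); o <- runif(50, 10, 60)
  base <- eval_stats(m, o)
  shift <- eval_stats(m + 4.2, o)
  expect_equal(shift$mb, base$mb + 4.2, tolerance = 1e-12)
  expect_equal(shift$r, base$r, tolerance = 1e-12)
  # FAC2 invariant under a common positive rescaling
  scaled <- eval_stats(3.7 * m, 3.7 * o)
  expect_equal(scaled$fac2, base$fac2)
  expect_equal(scaled$nmb, base$nmb, tolerance = 1e-12)
})

test_that("pooled NMB is the observation-weighted combination of site NMBs", {
  set.seed(15)
  m1 <- runif(30, 5, 50); o1 <- runif(30, 5, 50)
  m2 <- runif(40, 5, 50); o2 <- runif(40, 5, 50)
  pooled <- eval_stats(c(m1, m2), c(o1, o2))$nmb
  n1 <- eval_stats(m1, o1)$nmb; n2 <- eval_stats(m2, o2)$nmb
  w1 <- sum(o1) / (sum(o1) + sum(o2))
  expect_equal(pooled, w1 * n1 + (1 - w1) * n2, tolerance = 1e-12)
})

test_that("parameter recovery: statistics converge as observation noise vanishes", {
  set.seed(16)
  ts <- as.POSIXct("2006-01-02", tz = "UTC") + 3600 * (0:335)
  truth <- 30 + 10 * sin(2 * pi * (0:335) / 24) + runif(336, 0, 5)
  for (noise in c(0.2, 0.02, 0)) {
    obs <- truth * exp(rnorm(336, 0, noise))
    st <- eval_stats(truth, obs)
    if (noise == 0) {
      expect_equal(st$fac2, 1)
      expect_equal(st$mb, 0)
      expect_equal(st$r, 1)
    }
  }
  st_small <- eval_stats(truth, truth * exp(rnorm(336, 0, 0.01)))
  expect_gt(st_small$r, 0.99)
  expect_lt(abs(st_small$mb), 0.5)
})

test_that("temporal means recover structure with the right bin counts", {
  ts <- as.POSIXct("2006-01-02", tz = "UTC") + 3600 * (0:335)  # two weeks
  const <- temporal_means(ts, rep(5, 336), "hour_of_day")
  expect_equal(const$mean, rep(5, 24))
  expect_equal(const$ci_halfwidth, rep(0, 24))
  expect_equal(nrow(temporal_means(ts, rnorm(336), "hour_of_week")), 168)
  expect_equal(nrow(temporal_means(ts, rnorm(336), "day_of_week")), 7)
  # a pure 24 h sinusoid is recovered at the bin centres
  h <- as.POSIXlt(ts, tz = "UTC")$hour
  v <- 10 + 4 * sin(2 * pi * h / 24)
  prof <- temporal_means(ts, v, "hour_of_day")
  expect_equal(prof$mean, 10 + 4 * sin(2 * pi * (0:23) / 24),
               tolerance = 1e-9)
  expect_error(temporal_means(ts, v, "fortnight"), "unknown mode")
})

test_that("residual profiles localise an injected bias", {
  ts <- as.POSIXct("2006-01-02", tz = "UTC") + 3600 * (0:335)
  o <- rep(20, 336)
  expect_equal(residual_profile(ts, o, o, "hour_of_day")$mean, rep(0, 24))
  expect_equal(residual_profile(ts, o + 2, o, "hour_of_day")$mean, rep(2, 24))
  # morning-only bias appears only in morning bins
  h <- as.POSIXlt(ts, tz = "UTC")$hour
  m <- o + ifelse(h %in% 7:9, 6, 0)
  prof <- residual_profile(ts, m, o, "hour_of_day")
  expect_equal(prof$mean[8:10], rep(6, 3))
  expect_equal(prof$mean[-(8:10)], rep(0, 21))
})

test_that("constrained-NOx NO2 model is self-consistent and monotone in f_no2", {
  set.seed(17)
  n <- 336
  nox_obs <- pmax(20 + 80 * runif(n) + 30 * sin(2 * pi * (1:n) / 24), 1)
  o3_bg <- pmax(25 + 8 * sin(2 * pi * (1:n) / 24 + 1), 2)
  rates <- rate_params(k1 = 4.5e-4, j = 5e-3)
  tof <- runif(n, 5, 60)
  fwd <- constrained_no2_eval(nox_obs, f_no2 = 0.20, o3_bg, rates, tof)
  # observations generated by the forward model recover R^2 = 1
  self <- constrained_no2_eval(nox_obs, 0.20, o3_bg, rates, tof,
                               observed_no2 = fwd$modelled_no2)
  expect_equal(self$r_squared, 1, tolerance = 1e-9)
  expect_equal(self$mean_modelled, self$mean_observed, tolerance = 1e-9)
  # mean modelled NO2 strictly increases with the primary NO2 fraction
  means <- vapply(seq(0.16, 0.26, by = 0.02), function(f) {
    constrained_no2_eval(nox_obs, f, o3_bg, rates, tof)$mean_modelled
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("constrained mode handles backgrounds and degenerate inputs", {
  rates <- rate_params(k1 = 4e-4, j = 5e-3)
  # degenerate: no tof, no primary NO2, no background NO2 -> all-zero NO2
  out <- constrained_no2_eval(rep(50, 24), 0, rep(0, 24), rates, tof = 0,
                              observed_no2 = rep(0, 24))
  expect_equal(out$modelled_no2, rep(0, 24))
  expect_true(is.na(out$r_squared))   # flagged, not an error
  # "total" mode attributes only the above-background share to the road
  tot <- constrained_no2_eval(rep(100, 24), 0.2, rep(30, 24), rates, tof = 0,
                              background_no = 10, background_no2 = 20)
  expect_equal(tot$modelled_no2, rep(20 + 0.2 * 70, 24))
  inc <- constrained_no2_eval(rep(100, 24), 0.2, rep(30, 24), rates, tof = 0,
                              background_no = 10, background_no2 = 20,
                              mode = "increment")
  expect_equal(inc$modelled_no2, rep(20 + 0.2 * 100, 24))
  expect_error(constrained_no2_eval(rep(1, 5), 0.2, rep(1, 3), rates, 0),
               "misaligned")
})
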