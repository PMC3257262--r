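test_that("noiseless decays are fitted exactly", {
  t <- default_cpmg_delays()
  expect_equal(length(t), 10)
  expect_equal(t[1], 0.010)
  expect_equal(t[10], 0.190)
  fit <- fit_r2(t, 10 * exp(-5 * t))
  expect_equal(fit$status, "ok")
  expect_equal(fit$r2, 5, tolerance = 1e-8)
  expect_equal(fit$i0, 10, tolerance = 1e-8)
  expect_lt(fit$r2_err, 1e-6)
})

test_that("a two-point noiseless decay equals the log-ratio closed form", {
  t <- c(0.01, 0.11)
  y <- 8 * exp(-4.2 * t)
  fit <- fit_r2(t, y)
  expect_equal(fit$status, "ok")
  expect_equal(fit$r2, log(y[1] / y[2]) / (t[2] - t[1]), tolerance = 1e-8)
  expect_true(is.na(fit$r2_err))  # no residual degrees of freedom
})

test_that("R2 is invariant to uniform intensity rescaling", {
  t <- default_cpmg_delays()
  set.seed(14)
  y <- 10 * exp(-6 * t) * (1 + rnorm(10, 0, 0.02))
  f1 <- fit_r2(t, y)
  f2 <- fit_r2(t, 1e3 * y)
  expect_equal(f2$r2, f1$r2, tolerance = 1e-6)
  expect_equal(f2$i0, 1e3 * f1$i0, tolerance = 1e-6)
})

test_that("Monte-Carlo recovery at 2% noise is unbiased with calibrated errors", {
  t <- default_cpmg_delays()
  set.seed(77)
  r2_true <- 5
  est <- se <- numeric(200)
  for (i in 1:200) {
    y <- 10 * exp(-r2_true * t) + rnorm(10, 0, 0.02 * 10)
    f <- fit_r2(t, y)
    est[i] <- f$r2; se[i] <- f$r2_err
  }
  expect_lt(abs(mean(est) - r2_true) / r2_true, 0.02)
  # reported covariance SEs agree with the empirical scatter
  expect_gt(sd(est) / mean(se), 0.7)
  expect_lt(sd(est) / mean(se), 1.4)
  # 1-SE interval coverage near the nominal 68%
  cover <- mean(abs(est - r2_true) < se)
  expect_gt(cover, 0.58)
  expect_lt(cover, 0.78)
})

test_that("pathological decays produce failure records, not exceptions", {
  t <- default_cpmg_delays()
  grow <- fit_r2(t, 2 * exp(+3 * t))
  expect_equal(grow$status, "failed")
  expect_match(grow$reason, "non-decaying")
  flat0 <- fit_r2(t, rep(-1, 10))
  expect_equal(flat0$status, "failed")
  # batch fitting carries failures through
  mat <- rbind(`2` = 10 * exp(-4 * t), `3` = 2 * exp(+3 * t))
  series <- relaxation_series(toy_condition(), t, mat)
  prof <- fit_r2_profile(series)
  expect_equal(prof$status, c("ok", "failed"))
  expect_equal(prof$r2[1], 4, tolerance = 1e-7)
})

test_that("exchange detection matches the worked geometries", {
  t <- default_cpmg_delays()
  mk_profile <- function(r2_map) {
    structure(data.frame(position = as.integer(names(r2_map)),
                         r2 = as.numeric(r2_map), status = "ok"),
              class = c("r2_profile", "data.frame"))
  }
  # flat profile: no segments
  flat <- mk_profile(setNames(rep(3, 20), 1:20))
  expect_equal(nrow(detect_exchange_segments(flat)), 0)
  # planted block exactly recovered
  r2 <- setNames(rep(3, 40), 1:40)
  r2[15:24] <- 15
  seg <- detect_exchange_segments(mk_profile(r2), k_sigma = 1, min_len = 3)
  expect_equal(nrow(seg), 1)
  expect_equal(c(seg$start, seg$end), c(15, 24))
  expect_equal(seg$label, "exchange")
  # too few residues for the spread statistics
  expect_error(detect_exchange_segments(mk_profile(setNames(1:4, 1:4))),
               "at least 5")
})

test_that("exchange detection is a pure function of the profile", {
  set.seed(55)
  r2 <- c(rep(3, 30) + rnorm(30, 0, 0.1), rep(14, 6))
  pos <- c(1:30, 41:46)
  prof <- structure(data.frame(position = pos, r2 = r2, status = "ok"),
                    class = c("r2_profile", "data.frame"))
  perm <- sample(nrow(prof))
  prof_perm <- prof[perm, ]
  expect_equal(detect_exchange_segments(prof),
               detect_exchange_segments(prof_perm),
               ignore_attr = TRUE)
})

test_that("exchange segments equal the exhaustive threshold-scan oracle", {
  set.seed(123)
  for (i in 1:20) {
    n <- sample(15:50, 1)
    pos <- sort(sample(1:70, n))
    r2 <- exp(rnorm(n, log(4), 0.5))
    boost <- sample(n, sample(3:8, 1))
    r2[boost] <- r2[boost] + 10
    prof <- structure(data.frame(position = pos, r2 = r2, status = "ok"),
                      class = c("r2_profile", "data.frame"))
    ml <- sample(1:3, 1)
    got <- detect_exchange_segments(prof, k_sigma = 1, min_len = ml)
    want <- oracle_exchange_segments(pos, r2, 1, ml)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
  }
})

test_that("profile summaries report the converged-fit statistics", {
  vals <- c(2.61, 15.02, rep((73 - 2.61 - 15.02) / 8, 8))
  prof <- data.frame(position = 1:10, r2 = vals, status = "ok")
  s <- r2_summary(prof)
  expect_equal(s$min, 2.61)
  expect_equal(s$max, 15.02)
  expect_equal(s$mean, 7.3)
  expect_equal(s$n, 10)
})
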