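test_that("trimming finds the stated thresholds", {
  # ramp whose first sample above 0.02 m/s falls at t = 0.10 s exactly
  t <- seq(0, 3, by = 0.01)
  v <- pmax(0, pmin(2.05 * (t - 0.09), 0.2))
  v <- pmin(v, pmax(0, 0.4 * (1.9 - t)))
  x <- cumsum(c(0, diff(t)) * v)
  x <- x * 0.25 / max(x)
  rec <- make_record(t, v, x = x, L = 0.25)
  tr <- trim_trial(rec)
  expect_equal(tr$meta$trim_start, 0.10)
  expect_equal(tr$t[1], 0)
  expect_true(abs(tr$x[length(tr$t)] - 0.25) <= 0.009)
  expect_lt(abs(tr$xd[length(tr$t)]), 0.10)

  # stationary record is untrimmable
  rec0 <- make_record(t, numeric(length(t)), x = numeric(length(t)), L = 0.25)
  expect_error(trim_trial(rec0), class = "cupshaper_untrimmable")
})

test_that("trimming a simulated trial agrees with a brute-force scan", {
  p <- default_params()
  rec <- simulate_trial("RB", p, impedance_params(150, 5), D = 1.0, L = 0.25)
  tr <- trim_trial(rec)
  # independent literal scan of the stated conditions
  i0 <- NA
  for (i in seq_along(rec$t)) if (abs(rec$xd[i]) > 0.02) { i0 <- i; break }
  j <- NA
  for (i in (i0 + 1):length(rec$t)) {
    if (abs(rec$x[i] - 0.25) <= (0.041 - 0.023) / 2 && abs(rec$xd[i]) < 0.10) {
      j <- i; break
    }
  }
  expect_equal(tr$meta$trim_start, rec$t[i0])
  expect_equal(tr$meta$trim_end, rec$t[j])
  expect_equal(tr$meta$movement_duration, rec$t[j] - rec$t[i0])
})

test_that("peak metrics identify the two dominant velocity peaks", {
  # constructed two-lobe profile with maxima 0.5 and 0.4
  t <- seq(0, 2, by = 0.005)
  v <- 0.5 * exp(-((t - 0.5) / 0.15)^2) + 0.4 * exp(-((t - 1.4) / 0.15)^2)
  pk <- peak_metrics(v, t = t)
  expect_true(pk$defined)
  expect_equal(pk$ratio, 1.25, tolerance = 1e-3)
  expect_equal(pk$t_peak1, 0.5, tolerance = 0.01)
  expect_lt(pk$interpeak_min, 0.05)

  # single-peak minimum-jerk trial: undefined, flagged rather than thrown
  nom <- min_jerk(1, 0.25)
  pk1 <- peak_metrics(nom$v, t = nom$t)
  expect_false(pk1$defined)
  expect_true(is.na(pk1$ratio))

  # mirror-symmetric profile has ratio exactly 1
  vs <- c(v, rev(v))
  pks <- peak_metrics(vs)
  expect_identical(pks$ratio, 1)
})

test_that("residual ball angle matches the small-angle closed form", {
  p <- default_params()
  expect_identical(residual_ball_angle(0, 0, p), 0)
  # released at 0.1 rad from rest: maximum is the release angle
  expect_equal(residual_ball_angle(0.1, 0, p), 0.1 * 180 / pi,
               tolerance = 1e-6)
  # kicked from the bottom: amplitude phid/omega in the small-angle limit
  omega <- sqrt(p$g / p$l)
  got <- residual_ball_angle(0, 0.44294, p)
  expect_equal(got, 5.7296, tolerance = 0.01 * 5.7296)

  # nonlinear amplitude exceeds the closed form, monotonically in amplitude
  amps <- c(0.2, 0.5, 1.0, 1.8)
  excess <- vapply(amps, function(a) {
    residual_ball_angle(0, a * omega, p) / (a * 180 / pi)
  }, numeric(1))
  expect_lt(abs(excess[1] - 1), 0.01)
  expect_true(all(diff(excess) > 0))
  expect_gt(excess[4], 1.1)
})

test_that("VAF follows its defining formula and invariances", {
  v <- sin(seq(0, 5, by = 0.01))
  expect_equal(vaf(v, v), 100)
  expect_equal(vaf(v, rep(0.3, length(v))), 0)
  expect_equal(vaf(v, v + 0.05), 100, tolerance = 1e-12)
  for (b in c(-2, 0.1, 7)) expect_equal(vaf(v + b, v), 100, tolerance = 1e-12)
  expect_lt(vaf(v, 0.5 * v), 100)
  expect_error(vaf(rep(1, 10), v[1:10]), class = "cupshaper_undefined")
})

test_that("RMSE objective is range-normalized, weighted, and literal", {
  # hand-evaluated 2-sample toy: obs x = (0,1), sim x = (0,0)
  obs <- make_record(c(0, 1), c(0, 0), x = c(0, 1), L = 1)
  sim <- make_record(c(0, 1), c(0, 0), x = c(0, 0), L = 1)
  cfg1 <- objective_config(weights = c(x = 1))
  expect_equal(rmse_objective(obs, sim, cfg1), 1)
  # sim == obs is a perfect score
  expect_equal(rmse_objective(obs, obs, cfg1), 0)

  # scaling law: all weights x4 doubles the total
  p <- default_params()
  a <- trim_trial(simulate_trial("RB", p, impedance_params(150, 5), D = 1))
  b <- trim_trial(simulate_trial("RB", p, impedance_params(180, 6), D = 1))
  w1 <- objective_config(c(x = 1, xd = 1, phi = 1, phid = 1))
  w4 <- objective_config(c(x = 4, xd = 4, phi = 4, phid = 4))
  expect_equal(rmse_objective(a, b, w4), 2 * rmse_objective(a, b, w1),
               tolerance = 1e-12)

  # a zero-range observed variable is skipped with a warning
  cfg_phi <- objective_config(weights = c(x = 1, phi = 1))
  expect_warning(val <- rmse_objective(obs, sim, cfg_phi), "zero observed range")
  expect_equal(val, 1)
})
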