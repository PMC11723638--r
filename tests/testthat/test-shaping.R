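test_that("ZV impulses match printed and independently evaluated values", {
  # undamped pendulum mode of the experiment: equal halves, t2 = Td/2 = 0.71 s
  zv <- zv_impulses(pendulum_mode(default_params()))
  expect_equal(zv$amplitudes, c(0.5, 0.5), tolerance = 1e-12)
  expect_equal(zv$times[2], 0.71, tolerance = 5e-3)
  expect_equal(zv$times[2], 0.7092517, tolerance = 1e-6)

  # damped mode (rigid-body lump, K=100, B=10, M=3): frozen high-precision values
  zd <- zv_impulses(mode_spec(omega_n = sqrt(100 / 3),
                              zeta = 10 / (2 * sqrt(300))))
  expect_equal(zd$amplitudes, c(0.72055693, 0.27944307), tolerance = 1e-7)
  expect_equal(zd$times[2], 0.56833550, tolerance = 1e-7)

  # normalization across a range of modes
  for (z in seq(0, 0.9, by = 0.15)) {
    tr <- zv_impulses(mode_spec(omega_n = 3 + 5 * z, zeta = z))
    expect_equal(sum(tr$amplitudes), 1, tolerance = 1e-12)
    expect_true(all(tr$amplitudes > 0))
  }
  expect_error(zv_impulses(mode_spec(omega_n = 2, zeta = 1.2)),
               class = "cupshaper_degenerate_mode")
})

test_that("impulse-train convolution follows its definition", {
  a <- impulse_train(c(0.5, 0.5), c(0, 0.71))
  b <- impulse_train(c(0.5, 0.5), c(0, 0.30))
  ab <- convolve_trains(a, b)
  expect_equal(ab$amplitudes, rep(0.25, 4))
  expect_equal(ab$times, c(0, 0.30, 0.71, 1.01))
  # identity element
  delta <- impulse_train(1, 0)
  expect_equal(convolve_trains(a, delta)$amplitudes, a$amplitudes)
  expect_equal(convolve_trains(a, delta)$times, a$times)
  # two two-impulse trains give four impulses; coincident times merge
  expect_length(ab$amplitudes, 4)
  sq <- convolve_trains(a, a)
  expect_equal(sq$amplitudes, c(0.25, 0.5, 0.25))
  expect_equal(sq$times, c(0, 0.71, 1.42))
  expect_equal(sum(sq$amplitudes), 1, tolerance = 1e-12)
})

test_that("minimum-jerk profile has exact boundary values and area", {
  nom <- min_jerk(D = 1, L = 0.25)
  expect_equal(nom$f_pos(1), 0.25, tolerance = 1e-15)
  expect_equal(nom$f_vel(c(0, 1)), c(0, 0))
  expect_equal(nom$f_acc(c(0, 1)), c(0, 0))
  # peak velocity 1.875*L/D at mid-movement
  expect_equal(max(nom$v), 1.875 * 0.25, tolerance = 1e-9)
  expect_equal(nom$t[which.max(nom$v)], 0.5, tolerance = 1e-3)
  expect_equal(trapz(nom$t, nom$v), 0.25, tolerance = 1e-10)
})

test_that("shaping superposes shifted nominals and preserves displacement", {
  nom <- min_jerk(0.49, 0.25)
  # single impulse: shaped command is the nominal
  id <- shape_command(nom, impulse_train(1, 0))
  expect_equal(id$x0_dot, nom$f_vel(id$t), tolerance = 1e-12)
  expect_equal(id$duration, 0.49)

  # ZV zeta=0 with total duration 1.20 s < natural period: two equal peaks
  # separated by an exactly zero plateau
  zv <- zv_impulses(pendulum_mode(default_params()))
  cmd <- shape_command(min_jerk(1.20 - zv$times[2], 0.25), zv)
  expect_equal(cmd$duration, 1.20, tolerance = 1e-9)
  pk <- peak_metrics(cmd)
  expect_true(pk$defined)
  expect_equal(pk$ratio, 1, tolerance = 1e-9)
  expect_identical(pk$interpeak_min, 0)
  expect_equal(cmd$x0[length(cmd$x0)], 0.25, tolerance = 1e-9)

  # displacement preserved for an arbitrary valid train
  tr3 <- impulse_train(c(0.2, 0.5, 0.3), c(0, 0.3, 0.8))
  cmd3 <- shape_command(min_jerk(0.7, 0.25), tr3)
  expect_equal(cmd3$f_pos(cmd3$duration + 1), 0.25, tolerance = 1e-12)
  expect_equal(trapz(cmd3$t, cmd3$x0_dot), 0.25, tolerance = 1e-6)
})

test_that("duration sweep reproduces the canonical two-peak structure", {
  p <- default_params()
  mode <- pendulum_mode(p)
  Tn <- 2 * pi / mode$omega_n
  cmds <- duration_sweep(mode, L = 0.25, n = 22, range = c(0.75, 1.5))
  expect_length(cmds, 22)
  totals <- vapply(cmds, `[[`, numeric(1), "duration")
  expect_equal(totals[1], 0.75 * Tn, tolerance = 1e-9)
  expect_equal(totals[22], 1.5 * Tn, tolerance = 1e-9)

  mins <- rep(NA_real_, 22)
  for (i in seq_along(cmds)) {
    expect_equal(cmds[[i]]$x0[length(cmds[[i]]$x0)], 0.25, tolerance = 1e-9)
    pk <- peak_metrics(cmds[[i]])
    if (pk$defined) {
      expect_equal(pk$ratio, 1, tolerance = 1e-6)
      mins[i] <- pk$interpeak_min
    }
    # zeta = 0: velocity profile is mirror-symmetric about mid-movement
    v_rev <- cmds[[i]]$f_vel(cmds[[i]]$duration - cmds[[i]]$t)
    expect_lt(max(abs(cmds[[i]]$x0_dot - v_rev)), 1e-9)
  }
  # two distinct peaks exist for all sufficiently short durations; the very
  # longest commands merge into a single broad peak
  short <- totals < Tn - 1e-9
  expect_true(all(!is.na(mins[short])))
  expect_true(all(mins[short] == 0))
  defined <- which(!is.na(mins))
  expect_true(all(diff(defined) == 1)) # bimodal commands form a prefix
  expect_gte(sum(!short & !is.na(mins)), 5)
  above <- mins[defined][totals[defined] > Tn + 1e-6]
  expect_true(all(above > 0))
  expect_true(all(diff(mins[defined]) >= -1e-12))
})
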