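test_that("model trains match their per-model contracts", {
  p <- default_params()
  imp <- default_imp()
  # NI: identical to the bare-pendulum ZV shaper (zeta = 0, Td = 1.4185 s)
  ni <- model_train("NI", p, imp)
  zv <- zv_impulses(pendulum_mode(p))
  expect_equal(ni$amplitudes, zv$amplitudes)
  expect_equal(ni$times, zv$times)
  expect_equal(ni$times[2], 1.418503 / 2, tolerance = 1e-6)
  # MM: convolved two-mode shaper with four impulses
  expect_length(model_train("MM", p, imp)$amplitudes, 4)
  # RB with K = 0 is degenerate
  expect_error(plan_trial("RB", p, impedance_params(0, 0), D = 1, L = 0.25),
               class = "cupshaper_degenerate_mode")
})

test_that("rigid-body mode implements its closed forms", {
  p <- default_params()
  rb <- rb_mode(p, impedance_params(100, 10))
  expect_equal(rb$omega_n, 5.773502692, tolerance = 1e-9)
  expect_equal(rb$zeta, 0.288675135, tolerance = 1e-8)
  expect_equal(rb$T_d, 1.136670990, tolerance = 1e-9)
  # no damping
  rb0 <- rb_mode(p, impedance_params(100, 0))
  expect_equal(rb0$zeta, 0)
  expect_equal(rb0$T_d, 2 * pi / rb0$omega_n, tolerance = 1e-12)
  # omega scales as sqrt(K)
  expect_equal(rb_mode(p, impedance_params(200, 0))$omega_n,
               sqrt(2) * rb0$omega_n, tolerance = 1e-12)
})

test_that("effective mass-spring-damper round-trips its mode", {
  eff <- effective_system(mode_spec(omega_n = 2, zeta = 0.1), mass = 1.9)
  expect_equal(eff$K_eff, 7.6, tolerance = 1e-12)
  expect_equal(eff$B_eff, 0.76, tolerance = 1e-12)
  expect_equal(effective_system(mode_spec(omega_n = 3, zeta = 0), 2)$B_eff, 0)
  # invert K_eff, B_eff back to the mode
  omega <- sqrt(eff$K_eff / eff$mass)
  zeta <- eff$B_eff / (2 * eff$mass * omega)
  expect_equal(omega, eff$mode$omega_n, tolerance = 1e-12)
  expect_equal(zeta, eff$mode$zeta, tolerance = 1e-12)
})

test_that("feedforward formulas evaluate samplewise per model", {
  p <- default_params()
  des <- list(xdd = c(0, 1, -2), phi = c(0, 0, 0))
  expect_equal(feedforward_force("RB", p, list(xdd = numeric(3))), numeric(3))
  expect_equal(feedforward_force("MM", p, des), p$m_c * des$xdd)
  expect_equal(feedforward_force("SM", p, des), p$m_c * des$xdd)
  expect_equal(feedforward_force("FM", p, des), p$m_p * des$xdd)
  expect_equal(feedforward_force("RB", p, des), (p$m_c + p$m_p) * des$xdd)
  expect_error(feedforward_force("NI", p, list(xdd = 1:3, phi = NULL)),
               class = "cupshaper_contract")
})

test_that("NI feedforward satisfies the impulse balance", {
  p <- default_params()
  plan <- plan_trial("NI", p, default_imp(), D = 1.20 - 0.7092517, L = 0.25)
  lhs <- trapz(plan$t, plan$F_ff)
  rhs <- p$m_c * plan$command$f_vel(max(plan$t)) -
    p$m_p * p$g * trapz(plan$t, plan$desired$phi)
  expect_equal(lhs, rhs, tolerance = 1e-6)
})

test_that("exact-model planning cancels the modes it targets", {
  p <- default_params()
  imp <- default_imp()

  # MM: desired-trajectory command + feedforward on the coupled linear plant
  plan <- plan_trial("MM", p, imp, D = 0.8, L = 0.25, horizon = 4)
  tr <- simulate_coupled(p, imp,
                         list(x0 = plan$f_xdes, x0_dot = plan$f_vdes),
                         F_ff = plan$f_Fff, linear = TRUE, duration = 4)
  expect_lt(max(abs(tr$phi[tr$t > plan$command$duration])), 1e-4)

  # the convolved train alone cancels both modes through the impedance path
  tr2 <- simulate_coupled(p, imp, plan$command, linear = TRUE, duration = 4)
  expect_lt(max(abs(tr2$phi[tr2$t > plan$command$duration])), 1e-4)

  # NI applied to the uncoupled (kinematically driven) linear pendulum
  plan_ni <- plan_trial("NI", p, imp, D = 0.6, L = 0.25, horizon = 4)
  after <- plan_ni$t > plan_ni$command$duration
  expect_lt(max(abs(plan_ni$desired$phi[after])), 1e-6)
  pk <- peak_metrics(plan_ni$command)
  expect_equal(pk$ratio, 1, tolerance = 1e-6)
})

test_that("single-mode planning suppresses its targeted mode of the coupled plant", {
  p <- default_params()
  imp <- default_imp()
  m <- coupled_linear_matrix(p, imp)
  md <- modal_decomposition(m)
  ev <- eigen(m$A)
  modal_amp <- function(tr, t_end, target_omega) {
    i <- which.min(abs(tr$t - t_end))
    s <- c(tr$x[i] - 0.25, tr$x_dot[i], tr$phi[i], tr$phi_dot[i])
    z <- solve(ev$vectors, s)
    sel <- which(abs(Mod(ev$values) - target_omega) < 1e-6 & Im(ev$values) > 0)
    Mod(z[sel])
  }
  nom <- min_jerk(0.9, 0.25)
  un <- simulate_coupled(p, imp, list(x0 = nom$f_pos, x0_dot = nom$f_vel),
                         linear = TRUE, duration = 5)
  for (kind in c("SM", "FM")) {
    target <- if (kind == "SM") md$slow$omega_n else md$fast$omega_n
    plan <- plan_trial(kind, p, imp, D = 0.9, L = 0.25, horizon = 5)
    sh <- simulate_coupled(p, imp, plan$command, linear = TRUE, duration = 5)
    ratio <- modal_amp(sh, plan$command$duration, target) /
      modal_amp(un, 0.9, target)
    expect_lt(ratio, 0.05)
  }
})

test_that("rigid-body planning on the nonlinear plant gives peak ratio > 1", {
  p <- default_params()
  imp <- impedance_params(150, 5)
  D <- 1.3 - max(model_train("RB", p, imp)$times)
  rec <- simulate_trial("RB", p, imp, D = D, L = 0.25)
  pk <- peak_metrics(trim_trial(rec))
  expect_true(pk$defined)
  expect_gt(pk$ratio, 1)
})
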