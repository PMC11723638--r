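test_that("equilibrium and momentum-conservation trajectories are exact", {
  p <- default_params()
  for (sim in list(simulate_nonlinear, simulate_linearized)) {
    tr <- sim(p, 0, state(), duration = 1)
    expect_true(all(abs(tr$x) == 0) && all(abs(tr$phi) == 0))
    expect_true(all(tr$F_ball == 0))
  }
  # pure translation: no coupling at phi = 0, x advances linearly
  tr <- simulate_nonlinear(p, 0, state(x_dot = 0.1), duration = 2)
  expect_equal(tr$x, 0.1 * tr$t, tolerance = 1e-12)
  expect_true(all(tr$phi == 0))
})

test_that("free oscillation period matches the closed-form linearized value", {
  p <- default_params()
  # cart free, ball released at small angle: period 2*pi*sqrt(l*m_c/(g*(m_c+m_p)))
  T_ref <- 2 * pi * sqrt(p$l * p$m_c / (p$g * (p$m_c + p$m_p)))
  expect_equal(T_ref, 1.128877, tolerance = 1e-6)
  tr <- simulate_nonlinear(p, 0, state(phi = 0.05), duration = 6)
  cross <- which(diff(sign(tr$phi)) != 0)
  T_meas <- 2 * mean(diff(tr$t[cross]))
  expect_equal(T_meas, T_ref, tolerance = 2e-3)
})

test_that("linearized and nonlinear trajectories converge as phi0 -> 0", {
  p <- default_params()
  errs <- vapply(c(0.01, 0.02, 0.04), function(phi0) {
    trn <- simulate_nonlinear(p, 0, state(phi = phi0), duration = 1.2)
    trl <- simulate_linearized(p, 0, state(phi = phi0), duration = 1.2)
    max(abs(trn$phi - trl$phi))
  }, numeric(1))
  expect_lt(errs[1], 1e-3)
  # cubic scaling: doubling phi0 multiplies the gap by about 8
  expect_gt(errs[2] / errs[1], 4)
  expect_gt(errs[3] / errs[2], 4)
  expect_lt(errs[3] / errs[2], 16)
})

test_that("constant force from rest gives the reduced-form initial acceleration", {
  p <- default_params()
  tr <- simulate_linearized(p, 3, state(), duration = 0.5)
  # algebraic elimination: m_c*xdd = m_p*g*phi + F, so xdd(0) = F/m_c
  expect_equal(tr$x_ddot[1], 3 / p$m_c, tolerance = 1e-12)
  trn <- simulate_nonlinear(p, 3, state(), duration = 0.5)
  expect_equal(trn$x_ddot[1], 3 / p$m_c, tolerance = 1e-12)
})

test_that("coupled linear matrix has the documented structure and spectrum", {
  p <- default_params()
  m0 <- coupled_linear_matrix(p, impedance_params(0, 0))
  ev <- eigen(m0$A, only.values = TRUE)$values
  # K = B = 0: double zero plus an imaginary pair at sqrt(g*(mc+mp)/(l*mc))
  w_ref <- sqrt(p$g * (p$m_c + p$m_p) / (p$l * p$m_c))
  expect_equal(w_ref, 5.565873, tolerance = 1e-6)
  expect_equal(sort(Mod(ev)), sort(c(0, 0, w_ref, w_ref)), tolerance = 1e-9)
  # symbolic row check for the phi_ddot equation
  imp <- impedance_params(123, 4.5)
  m <- coupled_linear_matrix(p, imp)
  row_ref <- c(imp$K / (p$l * p$m_c), imp$B / (p$l * p$m_c),
               -(p$g / p$l + p$g * p$m_p / (p$l * p$m_c)), 0)
  expect_equal(unname(m$A[4, ]), row_ref, tolerance = 1e-12)
  expect_equal(unname(m$B_in[4, ]), -row_ref[c(1, 2, 1)] / c(1, 1, imp$K),
               tolerance = 1e-12)
})

test_that("coupled linear simulation matches the matrix-exponential solution", {
  p <- default_params()
  imp <- default_imp()
  m <- coupled_linear_matrix(p, imp)
  s0 <- c(0.1, 0, 0.2, 0)
  zero_cmd <- list(x0 = function(t) 0 * t, x0_dot = function(t) 0 * t)
  tr <- simulate_coupled(p, imp, zero_cmd, linear = TRUE,
                         initial = state(0.1, 0, 0.2, 0), duration = 0.5)
  ref <- as.numeric(Matrix::expm(m$A * 0.5) %*% s0)
  got <- c(tr$x[length(tr$t)], tr$x_dot[length(tr$t)],
           tr$phi[length(tr$t)], tr$phi_dot[length(tr$t)])
  expect_equal(got, ref, tolerance = 1e-6)
})

test_that("modal decomposition orders, recovers, and signals degeneracy", {
  p <- default_params()
  md <- modal_decomposition(coupled_linear_matrix(p, default_imp()))
  expect_lt(md$slow$omega_n, md$fast$omega_n)
  expect_true(md$slow$zeta >= 0 && md$slow$zeta < 1)

  # decoupled sanity fixture: two independent mass-spring-dampers
  msd_block <- function(omega, zeta)
    matrix(c(0, 1, -omega^2, -2 * zeta * omega), 2, 2, byrow = TRUE)
  A <- as.matrix(Matrix::bdiag(msd_block(2, 0.1), msd_block(7, 0.3)))
  md2 <- modal_decomposition(A)
  expect_equal(md2$slow$omega_n, 2, tolerance = 1e-12)
  expect_equal(md2$slow$zeta, 0.1, tolerance = 1e-12)
  expect_equal(md2$fast$omega_n, 7, tolerance = 1e-12)
  expect_equal(md2$fast$zeta, 0.3, tolerance = 1e-12)

  # no dissipation: both modes undamped
  md3 <- modal_decomposition(coupled_linear_matrix(p, impedance_params(100, 0)))
  expect_equal(md3$slow$zeta, 0, tolerance = 1e-9)
  expect_equal(md3$fast$zeta, 0, tolerance = 1e-9)

  # overdamped / real spectrum signals instead of continuing
  A_over <- as.matrix(Matrix::bdiag(msd_block(2, 1.5), msd_block(7, 0.3)))
  expect_error(modal_decomposition(A_over), class = "cupshaper_degenerate_mode")
})

test_that("pendulum-like mode approaches sqrt(g/l) as hand stiffness grows", {
  p <- default_params()
  w_pend <- sqrt(p$g / p$l)
  freqs <- vapply(c(100, 300, 1000, 3000, 10000), function(K) {
    modal_decomposition(coupled_linear_matrix(p, impedance_params(K, 10)))$slow$omega_n
  }, numeric(1))
  expect_true(all(diff(freqs) > 0))
  expect_true(all(freqs < w_pend))
  expect_lt(w_pend - freqs[length(freqs)], 0.02)
})

test_that("energy is conserved and the integrator is step-stable", {
  p <- default_params()
  tr <- simulate_nonlinear(p, 0, state(phi = 0.3, x_dot = 0.2),
                           duration = 10, step = 1e-3)
  E <- mechanical_energy(tr, p)
  expect_lt(max(abs(E - E[1])) / E[1], 1e-6)

  end_state <- function(step) {
    tr <- simulate_nonlinear(p, 0, state(phi = 0.3), duration = 2, step = step)
    n <- length(tr$t)
    c(tr$x[n], tr$x_dot[n], tr$phi[n], tr$phi_dot[n])
  }
  expect_lt(max(abs(end_state(1 / 1200) - end_state(1 / 2400))), 1e-8)
})

test_that("integration blow-up raises a classed failure naming the time", {
  p <- default_params()
  err <- expect_error(
    simulate_nonlinear(p, function(t) exp(300 * t), state(), duration = 3),
    class = "cupshaper_integration_failure")
  expect_match(conditionMessage(err), "t = ")
})
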