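# Core dynamics: integration of the cart-pendulum plant (nonlinear and
# linearized), the hand-impedance coupled system, and the modal structure of
# the coupled 4th-order linear system.

new_state_trajectory <- function(t, out, step, linear) {
  structure(list(
    t = t, x = out$x, x_dot = out$xd, phi = out$phi, phi_dot = out$phid,
    x_ddot = out$xdd, phi_ddot = out$phidd, F = out$F, F_ball = out$F_ball,
    step = step, linear = linear
  ), class = "state_trajectory")
}

check_blowup <- function(out, step) {
  if (out$blowup >= 0)
    cs_abort(sprintf("integration failure: state became non-finite at t = %.4f s",
                     out$blowup * step),
             "cupshaper_integration_failure")
  invisible(out)
}

check_sim_args <- function(duration, step) {
  if (!is.finite(duration) || duration <= 0)
    cs_abort("duration must be > 0", "cupshaper_contract")
  if (!is.finite(step) || step <= 0)
    cs_abort("step must be > 0", "cupshaper_contract")
  n <- as.integer(round(duration / step))
  max(n, 1L)
}

#' Simulate the nonlinear cart-pendulum under an applied force
#'
#' Integrates the full nonlinear equations of motion of the cart-pendulum
#' with a prescribed horizontal force on the cart, using fixed-step RK4.
#' Accelerations and the ball reaction force `F_ball` are recomputed from the
#' equations of motion at every output sample (not finite-differenced).
#'
#' @param params a [system_params()] object.
#' @param force_profile force on the cup in N: a (vectorized) function of
#'   time, or a scalar for a constant force.
#' @param initial initial [state()].
#' @param duration horizon in s.
#' @param step integration/output step in s (default 1/1200).
#' @return A `state_trajectory`: uniform time grid plus `x`, `x_dot`,
#'   `x_ddot`, `phi`, `phi_dot`, `phi_ddot`, `F`, `F_ball`.
#' @export
simulate_nonlinear <- function(params, force_profile = 0, initial = state(),
                               duration, step = 1 / 1200) {
  n <- check_sim_args(duration, step)
  f <- as_profile_fun(force_profile, "force_profile")
  Fh <- f(half_grid(n, step))
  out <- rk4_forced_plant_cpp(unname(initial), Fh, step, n,
                              params$m_c, params$m_p, params$l, params$g,
                              FALSE)
  check_blowup(out, step)
  new_state_trajectory((0:n) * step, out, step, linear = FALSE)
}

#' Simulate the linearized cart-pendulum under an applied force
#'
#' Same contract as [simulate_nonlinear()] for the small-angle linearization
#' about the downward equilibrium.
#'
#' @inheritParams simulate_nonlinear
#' @return A `state_trajectory`.
#' @export
simulate_linearized <- function(params, force_profile = 0, initial = state(),
                                duration, step = 1 / 1200) {
  n <- check_sim_args(duration, step)
  f <- as_profile_fun(force_profile, "force_profile")
  Fh <- f(half_grid(n, step))
  out <- rk4_forced_plant_cpp(unname(initial), Fh, step, n,
                              params$m_c, params$m_p, params$l, params$g,
                              TRUE)
  check_blowup(out, step)
  new_state_trajectory((0:n) * step, out, step, linear = TRUE)
}

# Extract (position, velocity) command functions from a shaped command or a
# bare list of functions.
command_funs <- function(command) {
  if (inherits(command, "shaped_command"))
    return(list(pos = command$f_pos, vel = command$f_vel, acc = command$f_acc))
  if (is.list(command) && is.function(command$x0) && is.function(command$x0_dot))
    return(list(pos = command$x0, vel = command$x0_dot,
                acc = if (is.function(command$x0_ddot)) command$x0_ddot else NULL))
  cs_abort("command must be a shaped_command or list(x0=, x0_dot=) of functions",
           "cupshaper_contract")
}

#' Simulate the hand-impedance coupled cart-pendulum
#'
#' The applied force is generated by the hand model
#' `F = F_ff + B*(x0_dot - x_dot) + K*(x0 - x)` where `(x0, x0_dot)` is the
#' shaped command trajectory.  With `linear = TRUE` the plant is the
#' small-angle linearization; otherwise the full nonlinear equations are
#' integrated.
#'
#' @param params a [system_params()] object.
#' @param imp an [impedance_params()] object.
#' @param command a [shape_command()] result, or a list with vectorized
#'   functions `x0` and `x0_dot`.
#' @param F_ff feedforward force in N: function of time, scalar, or NULL for
#'   zero.
#' @param linear logical; integrate the linearized plant (default FALSE).
#' @param initial initial [state()].
#' @param duration horizon in s (default: command duration + 1 s).
#' @param step integration/output step in s.
#' @return A `state_trajectory`; `F` holds the realized impedance force.
#' @export
simulate_coupled <- function(params, imp, command, F_ff = NULL,
                             linear = FALSE, initial = state(),
                             duration = NULL, step = 1 / 1200) {
  cf <- command_funs(command)
  if (is.null(duration)) {
    if (!inherits(command, "shaped_command"))
      cs_abort("duration is required unless command is a shaped_command",
               "cupshaper_contract")
    duration <- command$duration + 1
  }
  n <- check_sim_args(duration, step)
  th <- half_grid(n, step)
  ff <- if (is.null(F_ff)) function(t) numeric(length(t)) else
    as_profile_fun(F_ff, "F_ff")
  out <- rk4_coupled_cpp(unname(initial), cf$pos(th), cf$vel(th), ff(th),
                         step, n, params$m_c, params$m_p, params$l, params$g,
                         imp$K, imp$B, linear)
  check_blowup(out, step)
  new_state_trajectory((0:n) * step, out, step, linear = linear)
}

#' State matrix of the coupled linear hand-object system
#'
#' Algebraic reduction of the linearized cart-pendulum coupled to the hand
#' impedance to explicit first-order form with state `(x, x_dot, phi,
#' phi_dot)`:
#' \deqn{\ddot x = (m_p g \phi - B\dot x - K x)/m_c + (K x_0 + B\dot x_0 + F_{ff})/m_c}
#' \deqn{\ddot\phi = -(g/l)\phi - \ddot x / l}
#'
#' @param params a [system_params()] object.
#' @param imp an [impedance_params()] object.
#' @return A list with the 4x4 state matrix `A`, the 4x3 input matrix `B_in`
#'   mapping inputs `(x0, x0_dot, F_ff)`, and the parameter objects.
#' @export
coupled_linear_matrix <- function(params, imp) {
  mc <- params$m_c; mp <- params$m_p; l <- params$l; g <- params$g
  K <- imp$K; B <- imp$B
  A <- matrix(0, 4, 4)
  A[1, 2] <- 1
  A[2, ] <- c(-K / mc, -B / mc, mp * g / mc, 0)
  A[3, 4] <- 1
  A[4, ] <- c(K / (mc * l), B / (mc * l), -g * (mc + mp) / (l * mc), 0)
  B_in <- matrix(0, 4, 3)
  B_in[2, ] <- c(K / mc, B / mc, 1 / mc)
  B_in[4, ] <- -B_in[2, ] / l
  dimnames(A) <- list(c("x", "x_dot", "phi", "phi_dot"),
                      c("x", "x_dot", "phi", "phi_dot"))
  dimnames(B_in) <- list(rownames(A), c("x0", "x0_dot", "F_ff"))
  structure(list(A = A, B_in = B_in, params = params, imp = imp),
            class = "coupled_system_matrix")
}

#' Modal decomposition of the coupled linear system
#'
#' Extracts the two underdamped oscillatory modes of the 4th-order coupled
#' system.  For an eigenvalue pair \eqn{\lambda = -\sigma \pm i\omega_d} the
#' mode has `omega_n = |lambda|`, `zeta = sigma/|lambda|` and
#' `T_d = 2*pi/omega_d`.  The "slow" mode is the pair with the smaller
#' natural frequency.
#'
#' @param m a [coupled_linear_matrix()] result or a plain 4x4 matrix.
#' @return A list with [mode_spec()] entries `slow` and `fast`.  If the
#'   matrix does not have two distinct complex-conjugate (underdamped)
#'   eigenvalue pairs a `cupshaper_degenerate_mode` error is raised.
#' @export
modal_decomposition <- function(m) {
  A <- if (inherits(m, "coupled_system_matrix")) m$A else m
  if (!is.matrix(A) || nrow(A) != ncol(A))
    cs_abort("modal_decomposition needs a square matrix", "cupshaper_contract")
  ev <- eigen(A, only.values = TRUE)$values
  scale <- max(Mod(ev), 1)
  up <- ev[Im(ev) > 1e-9 * scale]
  if (length(up) != 2)
    cs_abort(sprintf(
      "degenerate modes: expected two underdamped eigenvalue pairs, found %d",
      length(up)), "cupshaper_degenerate_mode")
  if (Mod(up[1] - up[2]) <= 1e-9 * scale)
    cs_abort("degenerate modes: repeated eigenvalue pair",
             "cupshaper_degenerate_mode")
  modes <- lapply(up, function(lam) {
    omega_n <- Mod(lam)
    zeta <- -Re(lam) / omega_n
    if (zeta < 0) {
      if (zeta > -1e-12) zeta <- 0
      else cs_abort("unstable eigenvalue pair (negative damping)",
                    "cupshaper_degenerate_mode")
    }
    mode_spec(omega_n = omega_n, zeta = zeta)
  })
  ord <- order(vapply(modes, `[[`, numeric(1), "omega_n"))
  list(slow = modes[[ord[1]]], fast = modes[[ord[2]]])
}

#' Total mechanical energy along a trajectory
#'
#' Kinetic plus potential energy of the cart-pendulum (potential zero at the
#' hanging rest configuration).  With no applied force the nonlinear system
#' conserves this quantity; used as an integrator audit.
#'
#' @param traj a `state_trajectory` from [simulate_nonlinear()].
#' @param params a [system_params()] object.
#' @return Numeric vector of energies (J), one per sample.
#' @export
mechanical_energy <- function(traj, params) {
  mc <- params$m_c; mp <- params$m_p; l <- params$l; g <- params$g
  0.5 * (mc + mp) * traj$x_dot^2 +
    mp * l * traj$x_dot * traj$phi_dot * cos(traj$phi) +
    0.5 * mp * l^2 * traj$phi_dot^2 +
    mp * g * l * (1 - cos(traj$phi))
}

#' @export
print.state_trajectory <- function(x, ...) {
  cat(sprintf("state trajectory: %d samples, step %.6g s (%s plant)\n",
              length(x$t), x$step, if (x$linear) "linearized" else "nonlinear"))
  invisible(x)
}
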