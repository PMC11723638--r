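# The five candidate internal models.  Each model plans a shaped command for
# the transport movement, forward-simulates its own (hypothesized) dynamics
# to obtain desired kinematics, and derives a feedforward force profile from
# those desired kinematics.

#' Internal model kinds
#'
#' The closed set of candidate internal models:
#' * `"MM"` multi-mode: exact 4th-order coupled hand-object model, both
#'   oscillatory modes cancelled by a convolved four-impulse shaper.
#' * `"SM"` slow-mode: effective mass-spring-damper of the slower coupled
#'   mode (modal mass = cup mass).
#' * `"FM"` fast-mode: effective mass-spring-damper of the faster coupled
#'   mode (modal mass = ball mass).
#' * `"RB"` rigid-body: cup and ball lumped into one mass on the hand
#'   spring-damper; no ball dynamics.
#' * `"NI"` no-impedance: bare cart-pendulum without hand impedance; shaper
#'   built on the pendulum mode `sqrt(g/l)`.
#'
#' @return Character vector of the five kind codes.
#' @export
model_kinds <- function() c("MM", "SM", "FM", "RB", "NI")

#' Rigid-body mode of the lumped hand-object system
#'
#' Treating cup plus ball as a single mass `M = m_c + m_p` on the hand
#' spring-damper gives `omega = sqrt(K/M)`, `zeta = B/(2*sqrt(K*M))` and
#' `T_d = 2*pi/(omega*sqrt(1-zeta^2))`.
#'
#' @param params a [system_params()] object.
#' @param imp an [impedance_params()] object; requires `K > 0` and an
#'   underdamped result.
#' @return A [mode_spec()].
#' @export
rb_mode <- function(params, imp) {
  M <- params$m_c + params$m_p
  if (imp$K <= 0)
    cs_abort("rigid-body mode undefined for K = 0", "cupshaper_degenerate_mode")
  omega <- sqrt(imp$K / M)
  zeta <- imp$B / (2 * sqrt(imp$K * M))
  if (zeta >= 1)
    cs_abort("rigid-body mode overdamped (zeta >= 1)",
             "cupshaper_degenerate_mode")
  mode_spec(omega_n = omega, zeta = zeta)
}

#' Effective mass-spring-damper of a single mode
#'
#' Represents one vibratory mode of the coupled system as an equivalent
#' mass-spring-damper: `K_eff = mass*omega_n^2`, `B_eff =
#' 2*mass*zeta*omega_n`.
#'
#' @param mode a [mode_spec()].
#' @param mass effective modal mass in kg (> 0).
#' @return An object of class `effective_system` with fields `mass`, `K_eff`,
#'   `B_eff`, `mode`.
#' @export
effective_system <- function(mode, mass) {
  if (!is.finite(mass) || mass <= 0)
    cs_abort("mass must be > 0", "cupshaper_contract")
  structure(list(mass = mass,
                 K_eff = mass * mode$omega_n^2,
                 B_eff = 2 * mass * mode$zeta * mode$omega_n,
                 mode = mode),
            class = "effective_system")
}

#' Impulse train of an internal model
#'
#' Builds the shaper train each internal model prescribes: a convolved
#' four-impulse train for `MM`, single-mode ZV trains for the others.
#'
#' @param kind one of [model_kinds()].
#' @param params a [system_params()] object.
#' @param imp an [impedance_params()] object.
#' @return An [impulse_train()].
#' @export
model_train <- function(kind, params, imp) {
  kind <- match.arg(kind, model_kinds())
  if (kind %in% c("MM", "SM", "FM")) {
    modes <- modal_decomposition(coupled_linear_matrix(params, imp))
    return(switch(kind,
      MM = convolve_trains(zv_impulses(modes$slow), zv_impulses(modes$fast)),
      SM = zv_impulses(modes$slow),
      FM = zv_impulses(modes$fast)))
  }
  switch(kind,
    RB = zv_impulses(rb_mode(params, imp)),
    NI = zv_impulses(pendulum_mode(params)))
}

#' Feedforward force from desired kinematics
#'
#' Evaluates the model-specific feedforward formula samplewise:
#' * MM, NI: `F_ff = m_c * xdd_des - m_p * g * phi_des`
#' * SM: `F_ff = m_c * xdd_des`
#' * FM: `F_ff = m_p * xdd_des`
#' * RB: `F_ff = (m_c + m_p) * xdd_des`
#'
#' @param kind one of [model_kinds()].
#' @param params a [system_params()] object.
#' @param desired list with `xdd` and, for MM/NI, `phi`.
#' @return Numeric force vector in N.
#' @export
feedforward_force <- function(kind, params, desired) {
  kind <- match.arg(kind, model_kinds())
  if (kind %in% c("MM", "NI")) {
    if (is.null(desired$phi))
      cs_abort(sprintf("model %s requires desired ball angle phi", kind),
               "cupshaper_contract")
    return(params$m_c * desired$xdd - params$m_p * params$g * desired$phi)
  }
  mass <- switch(kind, SM = params$m_c, FM = params$m_p,
                 RB = params$m_c + params$m_p)
  mass * desired$xdd
}

#' Plan a transport movement under an internal model
#'
#' Full planning pipeline of one internal model: build the model's impulse
#' train, shape a minimum-jerk nominal of duration `D` and displacement `L`,
#' forward-simulate the internal model driven by the shaped command (with
#' zero feedforward, responding through its own impedance/mode coupling) to
#' obtain desired kinematics, and compute the feedforward force from those
#' desired kinematics.
#'
#' @param kind one of [model_kinds()].
#' @param params a [system_params()] object.
#' @param imp an [impedance_params()] object.
#' @param D nominal (minimum-jerk) duration in s.
#' @param L displacement in m.
#' @param horizon horizon over which desired kinematics and feedforward are
#'   generated, in s.  Default: command duration plus one period of the
#'   planned mode (settling tail).
#' @param step integration step in s.
#' @param train optional [impulse_train()] override (e.g. jittered impulse
#'   times); default is [model_train()] for `kind`.
#' @return An object of class `planned_trial`: the `command`
#'   (`shaped_command`), `desired` kinematics (`x`, `xd`, `xdd` and, for
#'   MM/NI, `phi`, `phid`, `phidd` on grid `t`), the feedforward samples
#'   `F_ff` with interpolator `f_Fff`, the `train`, and bookkeeping fields.
#' @export
plan_trial <- function(kind, params, imp, D, L, horizon = NULL,
                       step = 1 / 1200, train = NULL) {
  kind <- match.arg(kind, model_kinds())
  if (!is.finite(D) || D <= 0)
    cs_abort("nominal duration must be > 0", "cupshaper_contract")
  modes <- if (kind %in% c("MM", "SM", "FM"))
    modal_decomposition(coupled_linear_matrix(params, imp)) else NULL
  if (is.null(train)) {
    train <- switch(kind,
      MM = convolve_trains(zv_impulses(modes$slow), zv_impulses(modes$fast)),
      SM = zv_impulses(modes$slow),
      FM = zv_impulses(modes$fast),
      RB = zv_impulses(rb_mode(params, imp)),
      NI = zv_impulses(pendulum_mode(params)))
  }
  command <- shape_command(min_jerk(D, L, step), train, step)
  tail_mode <- switch(kind,
    MM = modes$slow, SM = modes$slow, FM = modes$fast,
    RB = rb_mode(params, imp), NI = pendulum_mode(params))
  if (is.null(horizon))
    horizon <- command$duration + 2 * pi / tail_mode$omega_n
  n <- max(1L, as.integer(ceiling(horizon / step - 1e-9)))
  t <- (0:n) * step
  th <- half_grid(n, step)
  x0h <- command$f_pos(th)
  v0h <- command$f_vel(th)
  desired <- switch(kind,
    MM = {
      out <- rk4_coupled_cpp(rep(0, 4), x0h, v0h, numeric(length(th)),
                             step, n, params$m_c, params$m_p, params$l,
                             params$g, imp$K, imp$B, TRUE)
      check_blowup(out, step)
      list(t = t, x = out$x, xd = out$xd, xdd = out$xdd,
           phi = out$phi, phid = out$phid, phidd = out$phidd)
    },
    SM = msd_desired(effective_system(modes$slow, params$m_c), x0h, v0h,
                     step, n, t),
    FM = msd_desired(effective_system(modes$fast, params$m_p), x0h, v0h,
                     step, n, t),
    RB = msd_desired(
      structure(list(mass = params$m_c + params$m_p, K_eff = imp$K,
                     B_eff = imp$B), class = "effective_system"),
      x0h, v0h, step, n, t),
    NI = {
      a0h <- command$f_acc(th)
      out <- rk4_pendulum_cpp(c(0, 0), a0h, step, n, params$l, params$g, TRUE)
      check_blowup(out, step)
      list(t = t, x = command$f_pos(t), xd = command$f_vel(t),
           xdd = command$f_acc(t),
           phi = out$phi, phid = out$phid, phidd = out$phidd)
    })
  F_ff <- feedforward_force(kind, params, desired)
  # evaluators of the desired cup trajectory; for NI the cart is commanded
  # directly so the closed-form command closures are exact
  if (kind == "NI") {
    f_xdes <- command$f_pos
    f_vdes <- command$f_vel
  } else {
    f_xdes <- ugrid_fun(desired$x, step)
    f_vdes <- ugrid_fun(desired$xd, step)
  }
  structure(list(kind = kind, command = command, desired = desired,
                 F_ff = F_ff, f_Fff = ugrid_fun(F_ff, step),
                 f_xdes = f_xdes, f_vdes = f_vdes,
                 t = t, train = train, modes = modes, params = params,
                 imp = imp, horizon = n * step, step = step),
            class = "planned_trial")
}

msd_desired <- function(eff, x0h, v0h, step, n, t) {
  out <- rk4_msd_cpp(c(0, 0), x0h, v0h, step, n, eff$mass, eff$K_eff,
                     eff$B_eff)
  if (out$blowup >= 0)
    cs_abort("integration failure in desired kinematics",
             "cupshaper_integration_failure")
  list(t = t, x = out$x, xd = out$xd, xdd = out$xdd,
       phi = NULL, phid = NULL, phidd = NULL)
}

#' @export
print.planned_trial <- function(x, ...) {
  cat(sprintf(
    "planned trial [%s]: D = %.4g s, L = %g m, %d impulses, horizon %.4g s\n",
    x$kind, x$command$D_nominal, x$command$L,
    length(x$train$amplitudes), x$horizon))
  invisible(x)
}
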