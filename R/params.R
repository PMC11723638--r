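#' Physical parameters of the cart-pendulum object
#'
#' The "cup with a ball rolling inside" is modelled as a cart of mass `m_c`
#' carrying a pendulum of mass `m_p` and length `l`.  The defaults are the
#' values rendered by the experimental apparatus the package emulates.
#'
#' @param m_c cart (cup) mass in kg.
#' @param m_p pendulum (ball) mass in kg.
#' @param l pendulum length in m.
#' @param g gravitational acceleration in m/s^2.
#' @return An object of class `system_params`.
#' @examples
#' p <- system_params()
#' pendulum_period(p) # about 1.42 s
#' @export
system_params <- function(m_c = 1.9, m_p = 1.1, l = 0.5, g = 9.81) {
  v <- c(m_c, m_p, l, g)
  if (!all(is.finite(v)) || any(v <= 0))
    cs_abort("system parameters must be finite and strictly positive",
             "cupshaper_contract")
  structure(list(m_c = m_c, m_p = m_p, l = l, g = g), class = "system_params")
}

#' Hand impedance parameters
#'
#' Stiffness and damping of the spring-damper element coupling the commanded
#' hand trajectory to the object.
#'
#' @param K stiffness in N/m (>= 0).
#' @param B damping in Ns/m (>= 0).
#' @return An object of class `impedance_params`.
#' @export
impedance_params <- function(K = 100, B = 10) {
  if (!is.finite(K) || !is.finite(B) || K < 0 || B < 0)
    cs_abort("impedance parameters must be finite and non-negative",
             "cupshaper_contract")
  structure(list(K = K, B = B), class = "impedance_params")
}

#' Oscillatory mode specification
#'
#' An underdamped second-order mode described by its undamped natural
#' frequency, damping ratio and damped natural period
#' `T_d = 2*pi / (omega_n * sqrt(1 - zeta^2))`.  Either `omega_n` or `T_d`
#' must be given; if both are given they must be consistent.
#'
#' @param omega_n undamped natural frequency in rad/s (> 0).
#' @param zeta damping ratio, `0 <= zeta < 1`.
#' @param T_d damped natural period in s.
#' @return An object of class `mode_spec` with fields `omega_n`, `zeta`,
#'   `T_d`.
#' @export
mode_spec <- function(omega_n = NULL, zeta = 0, T_d = NULL) {
  if (!is.finite(zeta) || zeta < 0)
    cs_abort("damping ratio must be finite and >= 0", "cupshaper_contract")
  if (zeta >= 1)
    cs_abort("mode is not underdamped (zeta >= 1)", "cupshaper_degenerate_mode")
  if (is.null(omega_n) && is.null(T_d))
    cs_abort("one of omega_n or T_d is required", "cupshaper_contract")
  if (is.null(omega_n)) omega_n <- 2 * pi / (T_d * sqrt(1 - zeta^2))
  if (!is.finite(omega_n) || omega_n <= 0)
    cs_abort("natural frequency must be finite and > 0", "cupshaper_contract")
  T_d_ref <- 2 * pi / (omega_n * sqrt(1 - zeta^2))
  if (!is.null(T_d) && abs(T_d - T_d_ref) > 1e-9 * T_d_ref)
    cs_abort("inconsistent omega_n / zeta / T_d", "cupshaper_contract")
  structure(list(omega_n = omega_n, zeta = zeta, T_d = T_d_ref),
            class = "mode_spec")
}

#' Bare pendulum mode and natural period
#'
#' The undamped oscillation of the ball when the cup is held fixed (or
#' position-commanded): frequency `sqrt(g/l)`, period `2*pi*sqrt(l/g)`.
#'
#' @param params a [system_params()] object.
#' @return `pendulum_mode()` returns a [mode_spec()]; `pendulum_period()` the
#'   period in seconds.
#' @export
pendulum_mode <- function(params = system_params()) {
  mode_spec(omega_n = sqrt(params$g / params$l), zeta = 0)
}

#' @rdname pendulum_mode
#' @export
pendulum_period <- function(params = system_params()) {
  2 * pi * sqrt(params$l / params$g)
}

#' Initial state of the cart-pendulum
#'
#' @param x cup position (m).
#' @param x_dot cup velocity (m/s).
#' @param phi ball angle (rad, 0 at the bottom of the cup, positive
#'   counterclockwise).
#' @param phi_dot ball angular velocity (rad/s).
#' @return A named numeric vector of length 4.
#' @export
state <- function(x = 0, x_dot = 0, phi = 0, phi_dot = 0) {
  s <- c(x = x, x_dot = x_dot, phi = phi, phi_dot = phi_dot)
  if (!all(is.finite(s)))
    cs_abort("state must be finite", "cupshaper_contract")
  s
}

#' @export
print.system_params <- function(x, ...) {
  cat(sprintf("cart-pendulum parameters: m_c = %g kg, m_p = %g kg, l = %g m, g = %g m/s^2\n",
              x$m_c, x$m_p, x$l, x$g))
  invisible(x)
}

#' @export
print.impedance_params <- function(x, ...) {
  cat(sprintf("hand impedance: K = %g N/m, B = %g Ns/m\n", x$K, x$B))
  invisible(x)
}

#' @export
print.mode_spec <- function(x, ...) {
  cat(sprintf("mode: omega_n = %.5g rad/s, zeta = %.5g, T_d = %.5g s\n",
              x$omega_n, x$zeta, x$T_d))
  invisible(x)
}
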