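# Input shaping: ZV impulse trains, convolved multi-mode trains, minimum-jerk
# nominal profiles, and shaped command trajectories.

#' Impulse train
#'
#' A set of shaper impulses (amplitudes, times).  Amplitudes must be strictly
#' positive and sum to one; times nondecreasing with the first at zero.
#'
#' @param amplitudes impulse amplitudes (dimensionless).
#' @param times impulse times in s.
#' @return An object of class `impulse_train`.
#' @export
impulse_train <- function(amplitudes, times) {
  if (length(amplitudes) != length(times) || length(amplitudes) < 1)
    cs_abort("amplitudes and times must be equal-length, non-empty",
             "cupshaper_contract")
  if (any(!is.finite(amplitudes)) || any(!is.finite(times)))
    cs_abort("impulse train must be finite", "cupshaper_contract")
  if (any(amplitudes <= 0))
    cs_abort("impulse amplitudes must be > 0", "cupshaper_contract")
  if (abs(sum(amplitudes) - 1) > 1e-9)
    cs_abort("impulse amplitudes must sum to 1", "cupshaper_contract")
  if (is.unsorted(times) || abs(times[1]) > 1e-12)
    cs_abort("impulse times must be nondecreasing and start at 0",
             "cupshaper_contract")
  times[1] <- 0
  structure(list(amplitudes = amplitudes, times = times),
            class = "impulse_train")
}

#' Zero-vibration (ZV) shaper for a single underdamped mode
#'
#' The minimal two-impulse shaper: with `C = exp(-zeta*pi/sqrt(1-zeta^2))`,
#' amplitudes `A1 = 1/(1+C)`, `A2 = C/(1+C)` at times `0` and `T_d/2`.  For
#' an undamped mode both amplitudes are 0.5 and the second impulse falls at
#' half the natural period.
#'
#' @param mode a [mode_spec()] (requires `0 <= zeta < 1`).
#' @return An [impulse_train()] with two impulses.
#' @export
zv_impulses <- function(mode) {
  if (!inherits(mode, "mode_spec"))
    cs_abort("mode must be a mode_spec", "cupshaper_contract")
  if (mode$zeta >= 1)
    cs_abort("ZV shaper undefined for zeta >= 1", "cupshaper_degenerate_mode")
  C <- exp(-mode$zeta * pi / sqrt(1 - mode$zeta^2))
  impulse_train(c(1, C) / (1 + C), c(0, mode$T_d / 2))
}

#' Convolve two impulse trains
#'
#' The multi-mode (convolved) shaper: amplitudes are all pairwise products
#' and times all pairwise sums, sorted; coincident times are merged by
#' summing amplitudes.  Unit amplitude sum is preserved.
#'
#' @param a,b [impulse_train()] objects.
#' @return An [impulse_train()].
#' @export
convolve_trains <- function(a, b) {
  amp <- as.vector(outer(a$amplitudes, b$amplitudes))
  tt <- as.vector(outer(a$times, b$times, `+`))
  ord <- order(tt)
  amp <- amp[ord]; tt <- tt[ord]
  # merge duplicates (within 1e-12 s) by amplitude summation
  keep_amp <- numeric(0); keep_t <- numeric(0)
  for (i in seq_along(tt)) {
    if (length(keep_t) && tt[i] - keep_t[length(keep_t)] <= 1e-12) {
      keep_amp[length(keep_amp)] <- keep_amp[length(keep_amp)] + amp[i]
    } else {
      keep_t <- c(keep_t, tt[i]); keep_amp <- c(keep_amp, amp[i])
    }
  }
  impulse_train(keep_amp, keep_t)
}

# closed-form minimum-jerk basis, clamped outside [0, D]
mj_funs <- function(D, L) {
  list(
    pos = function(t) {
      tau <- pmin(pmax(t / D, 0), 1)
      L * (10 * tau^3 - 15 * tau^4 + 6 * tau^5)
    },
    vel = function(t) {
      tau <- t / D
      v <- (L / D) * (30 * tau^2 - 60 * tau^3 + 30 * tau^4)
      v[tau < 0 | tau > 1] <- 0
      v
    },
    acc = function(t) {
      tau <- t / D
      a <- (L / D^2) * (60 * tau - 180 * tau^2 + 120 * tau^3)
      a[tau < 0 | tau > 1] <- 0
      a
    }
  )
}

#' Minimum-jerk nominal profile
#'
#' Point-to-point quintic `x(tau) = L*(10 tau^3 - 15 tau^4 + 6 tau^5)` with
#' `tau = t/D`; velocity and acceleration are its exact derivatives, zero at
#' both ends.  Outside `[0, D]` the profile is held at its boundary values.
#'
#' @param D movement duration in s (> 0).
#' @param L displacement in m.
#' @param step sampling step for the stored grid in s.
#' @return An object of class `nominal_profile` with sampled arrays `t`, `x`,
#'   `v`, `a` and exact evaluators `f_pos`, `f_vel`, `f_acc`.
#' @export
min_jerk <- function(D, L, step = 1 / 1200) {
  if (!is.finite(D) || D <= 0)
    cs_abort("duration must be > 0", "cupshaper_contract")
  f <- mj_funs(D, L)
  n <- max(1L, as.integer(ceiling(D / step - 1e-9)))
  t <- (0:n) * step
  structure(list(D = D, L = L, step = step,
                 t = t, x = f$pos(t), v = f$vel(t), a = f$acc(t),
                 f_pos = f$pos, f_vel = f$vel, f_acc = f$acc),
            class = "nominal_profile")
}

#' Shape a nominal profile with an impulse train
#'
#' Superposition of time-shifted copies of the nominal profile:
#' `x0(t) = sum_i A_i * x_nom(t - t_i)` (identically for velocity and
#' acceleration).  Impulse times are applied exactly through the closed-form
#' nominal evaluators, so no grid snapping occurs.  The total movement
#' duration is `D + max(times)` and the commanded displacement is preserved
#' because the amplitudes sum to one.
#'
#' @param nominal a [min_jerk()] profile.
#' @param train an [impulse_train()].
#' @param step sampling step of the stored command grid in s.
#' @return An object of class `shaped_command`: grid arrays `t`, `x0`,
#'   `x0_dot`, `x0_ddot`, total `duration`, and exact evaluators `f_pos`,
#'   `f_vel`, `f_acc`.
#' @export
shape_command <- function(nominal, train, step = nominal$step) {
  if (!inherits(nominal, "nominal_profile"))
    cs_abort("nominal must be a nominal_profile", "cupshaper_contract")
  if (!inherits(train, "impulse_train"))
    cs_abort("train must be an impulse_train", "cupshaper_contract")
  A <- train$amplitudes; ti <- train$times
  shift_sum <- function(f) {
    force(f)
    function(t) {
      out <- numeric(length(t))
      for (i in seq_along(A)) out <- out + A[i] * f(t - ti[i])
      out
    }
  }
  f_pos <- shift_sum(nominal$f_pos)
  f_vel <- shift_sum(nominal$f_vel)
  f_acc <- shift_sum(nominal$f_acc)
  total <- nominal$D + max(ti)
  n <- max(1L, as.integer(ceiling(total / step - 1e-9)))
  t <- (0:n) * step
  structure(list(t = t, x0 = f_pos(t), x0_dot = f_vel(t), x0_ddot = f_acc(t),
                 duration = total, D_nominal = nominal$D, L = nominal$L,
                 train = train, step = step,
                 f_pos = f_pos, f_vel = f_vel, f_acc = f_acc),
            class = "shaped_command")
}

#' Sweep of shaped commands over movement durations
#'
#' Builds ZV-shaped minimum-jerk commands whose *total* shaped durations are
#' evenly spaced over the given multiples of the mode's undamped natural
#' period (`2*pi/omega_n`).
#'
#' @param mode a [mode_spec()] to build the ZV shaper from.
#' @param L displacement in m.
#' @param n number of durations (>= 2).
#' @param range multiples of the natural period, inclusive endpoints.
#' @param step sampling step in s.
#' @return A list of `shaped_command` objects of length `n`.
#' @export
duration_sweep <- function(mode, L, n = 22, range = c(0.75, 1.5),
                           step = 1 / 1200) {
  if (n < 2) cs_abort("n must be >= 2", "cupshaper_contract")
  Tn <- 2 * pi / mode$omega_n
  train <- zv_impulses(mode)
  t_last <- max(train$times)
  totals <- seq(range[1] * Tn, range[2] * Tn, length.out = n)
  lapply(totals, function(total) {
    D <- total - t_last
    if (D <= 0)
      cs_abort("total duration shorter than the shaper itself",
               "cupshaper_contract")
    shape_command(min_jerk(D, L, step), train, step)
  })
}

#' @export
print.impulse_train <- function(x, ...) {
  cat(sprintf("impulse train (%d impulses):\n", length(x$amplitudes)))
  cat(sprintf("  A = %s\n", paste(signif(x$amplitudes, 5), collapse = ", ")))
  cat(sprintf("  t = %s s\n", paste(signif(x$times, 5), collapse = ", ")))
  invisible(x)
}

#' @export
print.shaped_command <- function(x, ...) {
  cat(sprintf(
    "shaped command: L = %g m, nominal D = %.4g s, total duration = %.4g s, %d impulses\n",
    x$L, x$D_nominal, x$duration, length(x$train$amplitudes)))
  invisible(x)
}
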