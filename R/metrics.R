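# Per-trial performance measures: trimming, velocity peak structure,
# residual ball angle, variance accounted for, and the weighted normalized
# RMSE fitting objective.

#' Trim a trial to the task-relevant movement
#'
#' The movement starts at the first sample where the cup speed exceeds
#' `start_thresh` and ends at the first subsequent sample where the cup is
#' completely inside the target region (`|x - L| <= (region_width -
#' cup_width)/2`) with speed below `end_thresh`.  Time is rebased to zero at
#' the trim start.
#'
#' @param record a `trial_record`.
#' @param start_thresh start speed threshold in m/s.
#' @param end_thresh end speed threshold in m/s.
#' @param L target displacement in m (default from metadata).
#' @param region_width,cup_width target region and cup widths in m.
#' @return A trimmed `trial_record`; metadata gains `trimmed`, `trim_start`,
#'   `trim_end` (times in the untrimmed record) and `movement_duration`.
#'   Raises a `cupshaper_untrimmable` error if no qualifying start or end
#'   sample exists.
#' @export
trim_trial <- function(record, start_thresh = 0.02, end_thresh = 0.10,
                       L = record$meta$displacement, region_width = 0.041,
                       cup_width = 0.023) {
  v <- abs(record$xd)
  i0 <- which(v > start_thresh)[1]
  if (is.na(i0))
    cs_abort("untrimmable trial: cup speed never exceeds the start threshold",
             "cupshaper_untrimmable")
  half_gap <- (region_width - cup_width) / 2
  ok <- abs(record$x - L) <= half_gap & v < end_thresh
  j <- which(ok & seq_along(ok) > i0)[1]
  if (is.na(j))
    cs_abort("untrimmable trial: cup never settles inside the target region",
             "cupshaper_untrimmable")
  idx <- i0:j
  meta <- record$meta
  meta$trimmed <- TRUE
  meta$trim_start <- record$t[i0]
  meta$trim_end <- record$t[j]
  meta$movement_duration <- record$t[j] - record$t[i0]
  trial_record(t = record$t[idx] - record$t[i0], F = record$F[idx],
               x = record$x[idx], xd = record$xd[idx], xdd = record$xdd[idx],
               phi = record$phi[idx], phid = record$phid[idx],
               phidd = record$phidd[idx],
               subject = record$subject, block = record$block,
               trial = record$trial, rate = record$rate, meta = meta)
}

# local maxima of v (plateaus count once, at their first sample) with
# topographic prominence
find_peaks <- function(v) {
  n <- length(v)
  idx <- integer(0)
  i <- 2L
  while (i < n) {
    if (v[i] > v[i - 1]) {
      j <- i
      while (j < n && v[j + 1] == v[i]) j <- j + 1L
      if (j < n && v[j + 1] < v[i]) idx <- c(idx, i)
      i <- j + 1L
    } else i <- i + 1L
  }
  if (!length(idx)) return(data.frame(idx = integer(0), prom = numeric(0)))
  prom <- vapply(idx, function(p) {
    left <- v[seq_len(p - 1)]
    higher_l <- which(left > v[p])
    lmin <- min(v[(if (length(higher_l)) max(higher_l) else 1):p])
    right <- v[p:n]
    higher_r <- which(right > v[p])
    rmin <- min(v[p:(p - 1 + (if (length(higher_r)) min(higher_r) else n - p + 1))])
    v[p] - max(lmin, rmin)
  }, numeric(1))
  data.frame(idx = idx, prom = prom)
}

#' Velocity peak metrics of a trimmed trial
#'
#' Detects local maxima of the cup velocity with prominence at least
#' `prominence_frac` of the global maximum, takes the two largest, and in
#' time order reports `peak1` (earlier), `peak2` (later), their ratio
#' `peak1/peak2`, and the minimum velocity strictly between them.  With
#' fewer than two qualifying peaks the ratio and inter-peak minimum are
#' flagged undefined (`defined = FALSE`, values `NA`), not an error.
#'
#' @param x a trimmed `trial_record`, a `shaped_command`, or a numeric
#'   velocity vector.
#' @param t time grid (only for the numeric method).
#' @param prominence_frac prominence threshold as a fraction of the global
#'   maximum velocity.
#' @param ... passed to methods.
#' @return A list: `peak1`, `peak2`, `ratio`, `interpeak_min`, `t_peak1`,
#'   `t_peak2`, `defined`.
#' @export
peak_metrics <- function(x, ...) UseMethod("peak_metrics")

#' @rdname peak_metrics
#' @export
peak_metrics.default <- function(x, t = seq_along(x), prominence_frac = 0.05,
                                 ...) {
  v <- as.numeric(x)
  undef <- list(peak1 = NA_real_, peak2 = NA_real_, ratio = NA_real_,
                interpeak_min = NA_real_, t_peak1 = NA_real_,
                t_peak2 = NA_real_, defined = FALSE)
  pk <- find_peaks(v)
  pk <- pk[pk$prom >= prominence_frac * max(v), , drop = FALSE]
  if (nrow(pk) < 2) return(undef)
  top <- pk[order(-v[pk$idx], pk$idx)[1:2], "idx"]
  i1 <- min(top); i2 <- max(top)
  between <- v[(i1 + 1):(i2 - 1)]
  # refine peak height and time by a three-point parabola so that sampled
  # maxima of smooth profiles are not biased by the grid
  refine <- function(i) {
    if (i <= 1L || i >= length(v)) return(c(v[i], t[i]))
    d2 <- v[i - 1] - 2 * v[i] + v[i + 1]
    if (d2 >= 0) return(c(v[i], t[i]))
    delta <- 0.5 * (v[i - 1] - v[i + 1]) / d2
    c(v[i] - 0.25 * (v[i - 1] - v[i + 1]) * delta,
      t[i] + delta * (t[2] - t[1]))
  }
  r1 <- refine(i1); r2 <- refine(i2)
  list(peak1 = r1[1], peak2 = r2[1], ratio = r1[1] / r2[1],
       interpeak_min = min(between), t_peak1 = r1[2], t_peak2 = r2[2],
       defined = TRUE)
}

#' @rdname peak_metrics
#' @export
peak_metrics.trial_record <- function(x, prominence_frac = 0.05, ...) {
  peak_metrics.default(x$xd, t = x$t, prominence_frac = prominence_frac)
}

#' @rdname peak_metrics
#' @export
peak_metrics.shaped_command <- function(x, prominence_frac = 0.05, ...) {
  peak_metrics.default(x$x0_dot, t = x$t, prominence_frac = prominence_frac)
}

#' Residual ball angle
#'
#' Initializes a free undamped (nonlinear) pendulum with the end-of-movement
#' ball state and forward-simulates it for one natural period
#' `2*pi*sqrt(l/g)`; the maximum absolute angle attained is the residual
#' ball angle, reported in degrees.
#'
#' @param phi_f ball angle at movement end (rad).
#' @param phi_dot_f ball angular velocity at movement end (rad/s).
#' @param params a [system_params()] object.
#' @param step integration step in s.
#' @return Residual ball angle in degrees.
#' @export
residual_ball_angle <- function(phi_f, phi_dot_f, params = system_params(),
                                step = 1e-3) {
  if (!is.finite(phi_f) || !is.finite(phi_dot_f))
    cs_abort("ball end state must be finite", "cupshaper_contract")
  Tn <- pendulum_period(params)
  n <- as.integer(ceiling(Tn / step))
  out <- rk4_pendulum_cpp(c(phi_f, phi_dot_f), numeric(2L * n + 1L), step, n,
                          params$l, params$g, FALSE)
  check_blowup(out, step)
  max(abs(out$phi)) * 180 / pi
}

#' Variance accounted for (VAF)
#'
#' Percentage of the observed signal's variance explained by the simulated
#' signal after mean removal:
#' `100 * max(1 - sum((v - vhat - mean(v) + mean(vhat))^2) /
#' sum((v - mean(v))^2), 0)`.  Invariant to constant offsets of either
#' signal; clamped at zero.
#'
#' @param v_obs observed signal (non-constant).
#' @param v_sim simulated signal, same length.
#' @return VAF in percent.
#' @export
vaf <- function(v_obs, v_sim) {
  if (length(v_obs) != length(v_sim))
    cs_abort("signals must have equal length", "cupshaper_contract")
  denom <- sum((v_obs - mean(v_obs))^2)
  if (denom == 0)
    cs_abort("VAF undefined for a constant observed signal",
             "cupshaper_undefined")
  resid <- v_obs - v_sim - mean(v_obs) + mean(v_sim)
  100 * max(1 - sum(resid^2) / denom, 0)
}

#' Objective configuration for trial fitting
#'
#' Kinematic variables entering the fitting objective and their weights.
#' Variable names refer to trial-record columns.
#'
#' @param weights named positive numeric vector of variable weights.
#' @return An object of class `objective_config`.
#' @export
objective_config <- function(weights = c(x = 1, xd = 1, phi = 1, phid = 1)) {
  if (is.null(names(weights)) || any(!nzchar(names(weights))) ||
      any(!is.finite(weights)) || any(weights <= 0))
    cs_abort("weights must be a named vector of positive numbers",
             "cupshaper_contract")
  structure(list(weights = weights), class = "objective_config")
}

#' Weighted range-normalized RMSE objective
#'
#' For each configured variable the error is
#' `RMSE_x = w_x * sqrt(sum((x - xhat)^2)) / (max(x) - min(x))`, evaluated
#' after linearly resampling the simulated record onto the observed time
#' grid; the total objective is `sum_x RMSE_x / sum_x sqrt(w_x)`.  A
#' variable whose observed range is zero is skipped with a warning.
#'
#' @param obs observed (trimmed) `trial_record`.
#' @param sim simulated (trimmed) `trial_record`.
#' @param cfg an [objective_config()].
#' @return Scalar objective value.
#' @export
rmse_objective <- function(obs, sim, cfg = objective_config()) {
  w <- cfg$weights
  total <- 0
  denom <- 0
  for (vn in names(w)) {
    vo <- obs[[vn]]
    rng <- max(vo) - min(vo)
    if (rng == 0) {
      warning(sprintf("variable %s has zero observed range; skipped", vn))
      next
    }
    vs <- approx(sim$t, sim[[vn]], xout = obs$t, rule = 2)$y
    total <- total + w[[vn]] * sqrt(sum((vo - vs)^2)) / rng
    denom <- denom + sqrt(w[[vn]])
  }
  if (denom == 0)
    cs_abort("no usable variables in objective", "cupshaper_undefined")
  total / denom
}

#' Metrics row for one trial
#'
#' Convenience wrapper: trims the record (unless already trimmed) and
#' collects movement duration, peak metrics and residual ball angle.
#'
#' @param record a `trial_record`.
#' @param params a [system_params()] object.
#' @param ... passed to [trim_trial()].
#' @return A one-row `data.frame`.
#' @export
trial_metrics <- function(record, params = system_params(), ...) {
  tr <- if (isTRUE(record$meta$trimmed)) record else trim_trial(record, ...)
  pk <- peak_metrics(tr)
  nlast <- length(tr$t)
  data.frame(subject = tr$subject, block = tr$block, trial = tr$trial,
             movement_duration = tr$t[nlast],
             peak1 = pk$peak1, peak2 = pk$peak2, peak_ratio = pk$ratio,
             interpeak_min = pk$interpeak_min,
             residual_angle_deg = residual_ball_angle(tr$phi[nlast],
                                                      tr$phid[nlast], params),
             peaks_defined = pk$defined,
             stringsAsFactors = FALSE)
}

#' Metrics table for a set of trials
#'
#' @param records list of `trial_record`s.
#' @param params a [system_params()] object.
#' @param ... passed to [trial_metrics()].
#' @return A `data.frame` with one row per trial; untrimmable trials are
#'   dropped with a warning.
#' @export
metrics_table <- function(records, params = system_params(), ...) {
  rows <- lapply(records, function(r) {
    tryCatch(trial_metrics(r, params, ...),
             cupshaper_untrimmable = function(e) {
               warning(sprintf("trial %s/%s/%g untrimmable; dropped",
                               r$subject, r$block, r$trial))
               NULL
             })
  })
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}
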