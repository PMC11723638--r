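# End-to-end trial generation: plan under an internal model, execute on the
# coupled nonlinear plant, package as a 120 Hz trial record, and round-trip
# records through a plain-text CSV dialect.

trial_columns <- c("t", "F", "x", "xd", "xdd", "phi", "phid", "phidd")

#' Construct a trial record
#'
#' A trial record holds the sampled kinematics and applied force of one
#' transport movement (observed or simulated) on a uniform time grid, plus
#' metadata.
#'
#' @param t,F,x,xd,xdd,phi,phid,phidd equal-length numeric columns: time (s),
#'   applied force (N), cup position/velocity/acceleration, ball
#'   angle/velocity/acceleration.
#' @param subject,block subject and block identifiers (coerced to character).
#' @param trial trial index.
#' @param rate sample rate in Hz.
#' @param meta named list of additional metadata (must include
#'   `displacement`; `nominal_duration` recommended).
#' @return An object of class `trial_record`.
#' @export
trial_record <- function(t, F, x, xd, xdd, phi, phid, phidd,
                         subject = "sim", block = "0", trial = 1,
                         rate = 120, meta = list()) {
  cols <- list(t = t, F = F, x = x, xd = xd, xdd = xdd,
               phi = phi, phid = phid, phidd = phidd)
  n <- length(t)
  if (n < 2 || !all(vapply(cols, length, integer(1)) == n))
    cs_abort("trial columns must have equal length >= 2", "cupshaper_contract")
  dt <- diff(t)
  if (any(dt <= 0) || diff(range(dt)) > 1e-9 * max(dt))
    cs_abort("time grid must be uniform and strictly increasing",
             "cupshaper_contract")
  if (is.null(meta$displacement) || !is.finite(meta$displacement) ||
      meta$displacement < 0)
    cs_abort("meta$displacement (m) is required and must be >= 0",
             "cupshaper_contract")
  structure(c(cols, list(subject = as.character(subject),
                         block = as.character(block),
                         trial = as.numeric(trial), rate = as.numeric(rate),
                         meta = meta)),
            class = "trial_record")
}

#' Simulate one trial under an internal model
#'
#' Plans the movement with [plan_trial()], then executes the shaped command
#' and feedforward force on the coupled *nonlinear* plant, sampling the
#' result at `rate` Hz.  The record is untrimmed; a settling tail is always
#' simulated after the command ends.
#'
#' @param kind one of [model_kinds()].
#' @param params a [system_params()] object.
#' @param imp an [impedance_params()] object.
#' @param D nominal (minimum-jerk) duration in s.
#' @param L displacement in m (0 gives a stationary trial).
#' @param extra_T extra horizon padding in s (>= 0); used by the fitter to
#'   lengthen candidate trials before re-trimming.
#' @param rate output sample rate in Hz; the integration step must divide
#'   `1/rate`.
#' @param settle settling tail after command end in s.
#' @param step integration step in s.
#' @param subject,block,trial identifiers stored in the record.
#' @param train optional impulse-train override passed to [plan_trial()].
#' @return A `trial_record` sampled at `rate` Hz.
#' @export
simulate_trial <- function(kind, params = system_params(),
                           imp = impedance_params(), D, L = 0.25,
                           extra_T = 0, rate = 120, settle = 1.5,
                           step = 1 / 1200, subject = "sim", block = "0",
                           trial = 1, train = NULL) {
  if (!is.finite(extra_T) || extra_T < 0)
    cs_abort("extra_T must be >= 0", "cupshaper_contract")
  k <- 1 / (rate * step)
  if (abs(k - round(k)) > 1e-9)
    cs_abort("integration step must divide the output sample interval 1/rate",
             "cupshaper_contract")
  k <- as.integer(round(k))
  kind <- match.arg(kind, model_kinds())
  if (is.null(train)) train <- model_train(kind, params, imp)
  total_cmd <- D + max(train$times)
  n_out <- as.integer(ceiling((total_cmd + extra_T + settle) * rate - 1e-9))
  horizon <- n_out / rate
  plan <- plan_trial(kind, params, imp, D, L, horizon = horizon, step = step,
                     train = train)
  n <- n_out * k
  # Execution: the feedforward force is applied together with the hand
  # impedance restoring toward the *desired* trajectory.  F_ff is the total
  # model-predicted force along the desired kinematics, so referencing the
  # spring-damper to (x_des, xd_des) makes a perfect internal model track
  # its desired trajectory exactly; for NI x_des coincides with the shaped
  # command x0.
  if (kind == "NI") {
    th <- half_grid(n, step)
    xh <- plan$f_xdes(th)
    vh <- plan$f_vdes(th)
  } else {
    xh <- grid_to_half(plan$desired$x)
    vh <- grid_to_half(plan$desired$xd)
  }
  out <- rk4_coupled_cpp(rep(0, 4), xh, vh, grid_to_half(plan$F_ff), step, n,
                         params$m_c, params$m_p, params$l, params$g,
                         imp$K, imp$B, FALSE)
  check_blowup(out, step)
  idx <- seq(1L, n + 1L, by = k)
  trial_record(
    t = (idx - 1L) * step, F = out$F[idx], x = out$x[idx], xd = out$xd[idx],
    xdd = out$xdd[idx], phi = out$phi[idx], phid = out$phid[idx],
    phidd = out$phidd[idx],
    subject = subject, block = block, trial = trial, rate = rate,
    meta = list(displacement = L, nominal_duration = D,
                command_duration = total_cmd, kind = kind,
                K = imp$K, B = imp$B, extra_T = extra_T, settle = settle,
                provenance = "simulate_trial"))
}

#' Write / read a trial record as delimited text
#'
#' One row per sample with named columns
#' `t,F,x,xd,xdd,phi,phid,phidd`; metadata as `# key: value` header lines.
#' The round trip is lossless (values written with 17 significant digits);
#' columns are matched by name, so column order is free.
#'
#' @param record a `trial_record`.
#' @param path file path.
#' @return `write_trial()` returns `path` invisibly; `read_trial()` returns a
#'   `trial_record`.
#' @export
write_trial <- function(record, path) {
  if (!inherits(record, "trial_record"))
    cs_abort("record must be a trial_record", "cupshaper_contract")
  meta <- c(list(subject = record$subject, block = record$block,
                 trial = record$trial, rate = record$rate), record$meta)
  fmt <- function(v) if (is.numeric(v)) sprintf("%.17g", v) else as.character(v)
  hdr <- vapply(names(meta), function(k) sprintf("# %s: %s", k, fmt(meta[[k]])),
                character(1))
  body <- do.call(paste, c(lapply(trial_columns,
                                  function(cn) sprintf("%.17g", record[[cn]])),
                           sep = ","))
  writeLines(c(hdr, paste(trial_columns, collapse = ","), body), path)
  invisible(path)
}

#' @rdname write_trial
#' @export
read_trial <- function(path) {
  lines <- readLines(path)
  is_hdr <- grepl("^#", lines)
  if (all(is_hdr))
    cs_abort(sprintf("malformed trial file %s: no data section", path),
             "cupshaper_parse_error")
  meta <- list()
  for (i in which(is_hdr)) {
    m <- regmatches(lines[i], regexec("^#\\s*([^:]+):\\s*(.*)$", lines[i]))[[1]]
    if (length(m) != 3)
      cs_abort(sprintf("malformed header at line %d of %s", i, path),
               "cupshaper_parse_error")
    key <- trimws(m[2]); val <- trimws(m[3])
    num <- suppressWarnings(as.numeric(val))
    meta[[key]] <- if (!is.na(num)) num else val
  }
  df <- read.csv(text = paste(lines[!is_hdr], collapse = "\n"),
                 check.names = FALSE)
  missing <- setdiff(trial_columns, names(df))
  if (length(missing))
    cs_abort(sprintf("trial file %s is missing column(s): %s", path,
                     paste(missing, collapse = ", ")),
             "cupshaper_parse_error")
  t <- df$t
  dt <- diff(t)
  if (any(dt <= 0) || diff(range(dt)) > 1e-9 * max(dt))
    cs_abort(sprintf("trial file %s: non-uniform time grid", path),
             "cupshaper_parse_error")
  ids <- c("subject", "block", "trial", "rate")
  extra <- meta[setdiff(names(meta), ids)]
  trial_record(t = df$t, F = df$F, x = df$x, xd = df$xd, xdd = df$xdd,
               phi = df$phi, phid = df$phid, phidd = df$phidd,
               subject = if (is.null(meta$subject)) "NA" else meta$subject,
               block = if (is.null(meta$block)) "NA" else meta$block,
               trial = if (is.null(meta$trial)) NA_real_ else meta$trial,
               rate = if (is.null(meta$rate)) 1 / stats::median(dt) else meta$rate,
               meta = extra)
}

#' Newton-consistency residual of a trial record
#'
#' Restates the cart equation of motion on the record:
#' `(m_c+m_p)*xdd - m_p*l*(phid^2*sin(phi) - phidd*cos(phi)) - F`, which is
#' zero (to integration tolerance) for every simulated record.
#'
#' @param record a `trial_record`.
#' @param params a [system_params()] object.
#' @return Numeric residual vector in N.
#' @export
newton_residual <- function(record, params) {
  (params$m_c + params$m_p) * record$xdd -
    params$m_p * params$l *
      (record$phid^2 * sin(record$phi) - record$phidd * cos(record$phi)) -
    record$F
}

#' @export
print.trial_record <- function(x, ...) {
  cat(sprintf(
    "trial record %s/block %s/#%g: %d samples at %g Hz, L = %g m%s\n",
    x$subject, x$block, x$trial, length(x$t), x$rate, x$meta$displacement,
    if (isTRUE(x$meta$trimmed)) " (trimmed)" else ""))
  invisible(x)
}
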