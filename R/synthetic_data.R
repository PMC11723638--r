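# Synthetic surrogate dataset generator.  Stands in for the human dataset:
# variability is injected at the command level (impedance draws, impulse-time
# and duration jitter) plus additive measurement noise, while the executed
# plant stays deterministic.

#' Configuration of the synthetic-trial generator
#'
#' Defaults emulate the testing blocks of the transport experiment the
#' package models: 0.25 m displacement, nominal total movement durations of
#' 1.40 s ("block 3") and 1.20 s ("block 4"), 50 trials per block, and the
#' rigid-body internal model (the best-fitting model) as generating
#' controller.
#'
#' @param kind generating internal model, one of [model_kinds()].
#' @param K_mean,B_mean population-mean hand stiffness (N/m) and damping
#'   (Ns/m).
#' @param subject_sigma log-normal spread (sdlog) of per-subject mean
#'   impedance around the population mean.
#' @param imp_sigma log-normal spread (sdlog) of per-trial impedance around
#'   the subject mean.
#' @param time_jitter SD (s) of Gaussian jitter on impulse times after the
#'   first.
#' @param duration_jitter SD (s) of Gaussian jitter on the total movement
#'   duration.
#' @param noise_xd,noise_phi SD of white measurement noise added to the cup
#'   velocity (m/s) and ball angle (rad) after simulation.
#' @param L displacement in m.
#' @param durations named numeric vector of nominal total movement durations
#'   per block (s).
#' @param trials_per_block trials per block.
#' @param seed root seed; all randomness is derived from it by counter, so a
#'   dataset is reproducible and order-independent.
#' @param K_duration_coupling optional `c(a, b)`: per-trial stiffness mean
#'   follows `K(D) = a * exp(-b * D)` of the jittered duration, emulating
#'   stiffer hands for faster movements.  `NULL` (default) disables it.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(kind = "RB", K_mean = 150, B_mean = 5,
                             subject_sigma = 0.15, imp_sigma = 0.10,
                             time_jitter = 0.01, duration_jitter = 0.05,
                             noise_xd = 0.005, noise_phi = 0.002, L = 0.25,
                             durations = c("3" = 1.40, "4" = 1.20),
                             trials_per_block = 50, seed = 1,
                             K_duration_coupling = NULL) {
  kind <- match.arg(kind, model_kinds())
  sig <- c(subject_sigma, imp_sigma, time_jitter, duration_jitter,
           noise_xd, noise_phi)
  if (any(!is.finite(sig)) || any(sig < 0))
    cs_abort("all spread parameters must be finite and >= 0",
             "cupshaper_contract")
  if (any(durations <= 0) || is.null(names(durations)))
    cs_abort("durations must be a named vector of positive times",
             "cupshaper_contract")
  structure(list(kind = kind, K_mean = K_mean, B_mean = B_mean,
                 subject_sigma = subject_sigma, imp_sigma = imp_sigma,
                 time_jitter = time_jitter,
                 duration_jitter = duration_jitter, noise_xd = noise_xd,
                 noise_phi = noise_phi, L = L, durations = durations,
                 trials_per_block = trials_per_block, seed = seed,
                 K_duration_coupling = K_duration_coupling),
            class = "generator_config")
}

# deterministic per-entity seeds derived from the root seed by counter
subject_seed <- function(cfg, s_idx)
  (cfg$seed + 1000003 * s_idx) %% .Machine$integer.max
trial_seed <- function(cfg, s_idx, b_idx, index)
  (cfg$seed + 1000003 * s_idx + 10007 * b_idx + index) %% .Machine$integer.max

subject_means <- function(cfg, s_idx) {
  with_seed(subject_seed(cfg, s_idx), {
    z <- rnorm(2, 0, cfg$subject_sigma)
    list(K = cfg$K_mean * exp(z[1]), B = cfg$B_mean * exp(z[2]))
  })
}

#' Generate one synthetic trial
#'
#' Draws per-trial impedance and duration from the configured distributions,
#' jitters the internal model's impulse times, simulates the trial on the
#' coupled nonlinear plant, and adds measurement noise to the cup velocity
#' and ball angle.  The true generating parameters are recorded in the
#' metadata, so the trial re-simulates exactly with all spreads set to zero.
#'
#' @param cfg a [generator_config()].
#' @param subject subject index (integer) or id string `"S<k>"`.
#' @param block block name; must be one of `names(cfg$durations)`.
#' @param index trial index within the block.
#' @param params a [system_params()] object.
#' @return A `trial_record` with provenance metadata (`true_K`, `true_B`,
#'   `true_D_total`, impulse times, noise SDs).
#' @export
generate_trial <- function(cfg, subject = 1, block = names(cfg$durations)[1],
                           index = 1, params = system_params()) {
  block <- as.character(block)
  if (!block %in% names(cfg$durations))
    cs_abort(sprintf("unknown block '%s'", block), "cupshaper_contract")
  s_idx <- if (is.character(subject))
    as.integer(sub("^S", "", subject)) else as.integer(subject)
  b_idx <- match(block, names(cfg$durations))
  sm <- subject_means(cfg, s_idx)
  with_seed(trial_seed(cfg, s_idx, b_idx, index), {
    D_total <- cfg$durations[[block]] + rnorm(1, 0, cfg$duration_jitter)
    K_center <- if (is.null(cfg$K_duration_coupling)) sm$K else
      cfg$K_duration_coupling[1] * exp(-cfg$K_duration_coupling[2] * D_total)
    K <- K_center * exp(rnorm(1, 0, cfg$imp_sigma))
    B <- sm$B * exp(rnorm(1, 0, cfg$imp_sigma))
    imp <- impedance_params(K, B)
    train <- model_train(cfg$kind, params, imp)
    times <- train$times
    if (length(times) > 1 && cfg$time_jitter > 0) {
      times[-1] <- times[-1] + rnorm(length(times) - 1, 0, cfg$time_jitter)
      times <- sort(pmax(times, 0))
      times[1] <- 0
      train <- impulse_train(train$amplitudes, times)
    }
    D_mj <- D_total - max(train$times)
    if (D_mj <= 0.1)
      cs_abort("jittered duration left no room for the nominal profile",
               "cupshaper_contract")
    rec <- simulate_trial(cfg$kind, params, imp, D = D_mj, L = cfg$L,
                          subject = sprintf("S%d", s_idx), block = block,
                          trial = index, train = train)
    n <- length(rec$t)
    if (cfg$noise_xd > 0) rec$xd <- rec$xd + rnorm(n, 0, cfg$noise_xd)
    if (cfg$noise_phi > 0) rec$phi <- rec$phi + rnorm(n, 0, cfg$noise_phi)
    rec$meta <- c(rec$meta, list(
      true_K = K, true_B = B, true_D_total = D_total, true_D_mj = D_mj,
      impulse_times = paste(sprintf("%.17g", train$times), collapse = ";"),
      impulse_amplitudes = paste(sprintf("%.17g", train$amplitudes),
                                 collapse = ";"),
      noise_xd = cfg$noise_xd, noise_phi = cfg$noise_phi,
      generator_seed = cfg$seed))
    rec$meta$provenance <- "generate_trial"
    rec
  })
}

#' Generate a full synthetic dataset
#'
#' Writes the directory layout `<dir>/<subject>/<block>/trial_<n>.csv` plus
#' a `truth.csv` table of per-trial generating parameters for recovery
#' scoring.  With the same configuration (including seed) the dataset is
#' byte-identical across runs.
#'
#' @param cfg a [generator_config()].
#' @param n_subjects number of subjects.
#' @param trials_per_block trials per block (default from `cfg`).
#' @param dir output directory (created if missing).  `NULL` skips writing
#'   and returns the records in memory.
#' @param params a [system_params()] object.
#' @return Invisibly, a list with `records` (list of `trial_record`s),
#'   `truth` (`data.frame`), and `files` (paths, or `NULL`).
#' @export
generate_dataset <- function(cfg, n_subjects, trials_per_block =
                               cfg$trials_per_block, dir = NULL,
                             params = system_params()) {
  records <- list(); truth <- list(); files <- character(0)
  for (s in seq_len(n_subjects)) {
    for (block in names(cfg$durations)) {
      for (i in seq_len(trials_per_block)) {
        rec <- generate_trial(cfg, s, block, i, params)
        records[[length(records) + 1L]] <- rec
        truth[[length(truth) + 1L]] <- data.frame(
          subject = rec$subject, block = block, trial = i,
          kind = cfg$kind, true_K = rec$meta$true_K,
          true_B = rec$meta$true_B, true_D_total = rec$meta$true_D_total,
          stringsAsFactors = FALSE)
        if (!is.null(dir)) {
          d <- file.path(dir, rec$subject, block)
          dir.create(d, recursive = TRUE, showWarnings = FALSE)
          path <- file.path(d, sprintf("trial_%d.csv", i))
          write_trial(rec, path)
          files <- c(files, path)
        }
      }
    }
  }
  truth <- do.call(rbind, truth)
  if (!is.null(dir))
    write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(list(records = records, truth = truth,
                 files = if (length(files)) files else NULL))
}
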