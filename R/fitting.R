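# Per-trial model fitting: CRS2 (controlled random search with local
# mutation) global optimization over (K, B, extra duration T).

#' Bounds and initial values for trial fitting
#'
#' @param K stiffness range in N/m.
#' @param B damping range in Ns/m.
#' @param T extra-duration range in ms.
#' @param init_K,init_B initial stiffness/damping seeded into the optimizer
#'   population.
#' @return An object of class `fit_bounds`.
#' @export
fit_bounds <- function(K = c(0, 1000), B = c(0, 100), T = c(0, 1000),
                       init_K = 100, init_B = 10) {
  chk <- function(r, nm) {
    if (length(r) != 2 || !all(is.finite(r)) || r[1] >= r[2] || r[1] < 0)
      cs_abort(sprintf("invalid %s range", nm), "cupshaper_contract")
  }
  chk(K, "K"); chk(B, "B"); chk(T, "T")
  structure(list(K = K, B = B, T = T, init_K = init_K, init_B = init_B),
            class = "fit_bounds")
}

#' Controlled random search (CRS2) with local mutation
#'
#' Population-based derivative-free global minimizer.  A population of
#' `10*(n+1)` points is drawn uniformly in the bounds; each iteration
#' reflects a random simplex (anchored at the current best point) through
#' its last vertex; if the reflected point is rejected (out of bounds or
#' worse than the current worst), a locally mutated point between the best
#' point and the reflection is tried instead.  The search stops at the
#' evaluation budget or when the population objective spread falls below
#' `ftol_rel` relative to the best value.
#'
#' @param fn objective: function of a numeric vector, returning a scalar.
#' @param lower,upper finite bound vectors.
#' @param budget maximum number of objective evaluations (>= population
#'   size).
#' @param seed integer seed; the search is deterministic given the seed.
#' @param ftol_rel relative objective-spread stopping tolerance.
#' @param init optional point included in the initial population.
#' @return A list: `par`, `value`, `evals`, and `history` (best-so-far value
#'   after each evaluation).
#' @export
crs2_minimize <- function(fn, lower, upper, budget = 3000, seed = NULL,
                          ftol_rel = 1e-6, init = NULL) {
  n <- length(lower)
  if (length(upper) != n || any(!is.finite(lower)) || any(!is.finite(upper)) ||
      any(lower >= upper))
    cs_abort("bounds must be finite with lower < upper", "cupshaper_contract")
  N <- 10L * (n + 1L)
  if (budget < N)
    cs_abort(sprintf("budget (%d) below population size (%d)", budget, N),
             "cupshaper_contract")
  with_seed(seed, {
    pop <- matrix(runif(N * n, rep(lower, each = N), rep(upper, each = N)),
                  nrow = N)
    if (!is.null(init))
      pop[1, ] <- pmin(pmax(init, lower), upper)
    f <- apply(pop, 1, fn)
    evals <- N
    history <- cummin(f)
    while (evals < budget) {
      ib <- which.min(f); iw <- which.max(f)
      fb <- f[ib]; fw <- f[iw]
      if (fw - fb <= ftol_rel * max(abs(fb), 1e-12)) break
      others <- sample(setdiff(seq_len(N), ib), n)
      simplex <- rbind(pop[ib, ], pop[others, , drop = FALSE])
      centroid <- colMeans(simplex[1:n, , drop = FALSE])
      trial <- 2 * centroid - simplex[n + 1, ]
      accepted <- FALSE
      if (all(trial >= lower) && all(trial <= upper)) {
        ft <- fn(trial); evals <- evals + 1L
        history <- c(history, min(history[length(history)], ft))
        if (ft < fw) {
          pop[iw, ] <- trial; f[iw] <- ft; accepted <- TRUE
        }
      }
      if (!accepted && evals < budget) {
        omega <- runif(n)
        mut <- pmin(pmax((1 + omega) * pop[ib, ] - omega * trial, lower),
                    upper)
        fm <- fn(mut); evals <- evals + 1L
        history <- c(history, min(history[length(history)], fm))
        if (fm < fw) {
          pop[iw, ] <- mut; f[iw] <- fm
        }
      }
    }
    ib <- which.min(f)
    list(par = pop[ib, ], value = f[ib], evals = evals, history = history)
  })
}

#' Fit one internal model to one trial
#'
#' Minimizes the weighted range-normalized RMSE between the observed trimmed
#' trial and candidate simulated trials over stiffness `K`, damping `B` and
#' extra duration `T` (ms).  Each candidate is simulated from rest with
#' nominal duration `D_obs + T` and horizon padding `T`, then trimmed at the
#' same velocity thresholds as the data before comparison.  Candidates that
#' fail to simulate or trim receive a large penalty.
#'
#' @param obs trimmed `trial_record` (see [trim_trial()]).
#' @param kind one of [model_kinds()].
#' @param params a [system_params()] object.
#' @param bounds a [fit_bounds()].
#' @param cfg an [objective_config()].
#' @param budget objective-evaluation budget.
#' @param seed integer seed for the optimizer.
#' @param L displacement in m (default from `obs` metadata).
#' @param step integration step for candidate simulations in s.
#' @return An object of class `fit_result`: best `K`, `B`, `T` (ms),
#'   `objective`, `vaf` (% of cup velocity), peak metrics of the best
#'   simulated trial, `evals`, `seed`.  Raises `cupshaper_fit_failure` if
#'   every candidate failed.
#' @export
fit_trial <- function(obs, kind, params = system_params(),
                      bounds = fit_bounds(), cfg = objective_config(),
                      budget = 3000, seed = 1,
                      L = obs$meta$displacement, step = 1 / 1200) {
  kind <- match.arg(kind, model_kinds())
  if (!isTRUE(obs$meta$trimmed))
    cs_abort("obs must be a trimmed trial_record", "cupshaper_contract")
  D_obs <- obs$t[length(obs$t)]
  penalty <- 1e6
  # Candidate nominal duration: the trimmed observed duration minus the
  # duration parameter T.  The trimmed duration of a shaped movement always
  # exceeds its minimum-jerk nominal duration (by the shaper delay plus the
  # settling overhead consumed by the velocity thresholds), so T spans that
  # overhead; candidates are simulated from rest and re-trimmed exactly like
  # the data.
  sim_candidate <- function(p) {
    K <- p[1]; B <- p[2]; T_s <- p[3] / 1000
    D_cand <- D_obs - T_s
    if (D_cand <= 0.05)
      cs_abort("candidate duration collapsed", "cupshaper_contract")
    rec <- simulate_trial(kind, params, impedance_params(K, B),
                          D = D_cand, L = L, step = step)
    trim_trial(rec)
  }
  objective <- function(p) {
    tryCatch(rmse_objective(obs, sim_candidate(p), cfg),
             cupshaper_error = function(e) penalty,
             error = function(e) penalty)
  }
  lower <- c(bounds$K[1], bounds$B[1], bounds$T[1])
  upper <- c(bounds$K[2], bounds$B[2], bounds$T[2])
  init <- c(bounds$init_K, bounds$init_B, mean(bounds$T))
  opt <- crs2_minimize(objective, lower, upper, budget = budget, seed = seed,
                       init = init)
  if (opt$value >= penalty)
    cs_abort(sprintf(
      "fit failure: all %d candidates failed simulation or trimming (model %s)",
      opt$evals, kind), "cupshaper_fit_failure")
  best_sim <- sim_candidate(opt$par)
  v_sim <- approx(best_sim$t, best_sim$xd, xout = obs$t, rule = 2)$y
  pk <- peak_metrics(best_sim)
  structure(list(kind = kind, K = opt$par[1], B = opt$par[2], T = opt$par[3],
                 objective = opt$value, vaf = vaf(obs$xd, v_sim),
                 sim_peak_ratio = pk$ratio,
                 sim_interpeak_min = pk$interpeak_min,
                 sim_movement_duration = best_sim$t[length(best_sim$t)],
                 evals = opt$evals, seed = seed, history = opt$history),
            class = "fit_result")
}

#' Fit several models to several trials
#'
#' Maps [fit_trial()] over trials and model kinds with per-(trial, model)
#' seeds derived from `seed` by counter, so results do not depend on
#' evaluation order.  Per-fit failures are recorded, not fatal.
#'
#' @param trials list of trimmed `trial_record`s (untrimmed records are
#'   trimmed on the fly).
#' @param kinds character vector of model kinds.
#' @param params a [system_params()] object.
#' @param bounds a [fit_bounds()].
#' @param cfg an [objective_config()].
#' @param budget per-fit evaluation budget.
#' @param seed root seed.
#' @param step integration step in s.
#' @return A `data.frame` with one row per successful trial x kind fit;
#'   failures are attached as the `data.frame` attribute `"failures"`.
#' @export
fit_dataset <- function(trials, kinds = model_kinds(),
                        params = system_params(), bounds = fit_bounds(),
                        cfg = objective_config(), budget = 3000, seed = 1,
                        step = 1 / 1200) {
  rows <- list(); fails <- list()
  counter <- 0L
  for (ti in seq_along(trials)) {
    obs <- trials[[ti]]
    for (kind in kinds) {
      counter <- counter + 1L
      sub_seed <- (seed + 7919L * counter) %% .Machine$integer.max
      res <- tryCatch({
        ob <- if (isTRUE(obs$meta$trimmed)) obs else trim_trial(obs)
        fit_trial(ob, kind, params, bounds, cfg, budget = budget,
                  seed = sub_seed, step = step)
      }, cupshaper_error = function(e) e, error = function(e) e)
      if (inherits(res, "fit_result")) {
        rows[[length(rows) + 1L]] <- data.frame(
          subject = obs$subject, block = obs$block, trial = obs$trial,
          kind = kind, K = res$K, B = res$B, T = res$T,
          objective = res$objective, vaf = res$vaf,
          sim_peak_ratio = res$sim_peak_ratio,
          sim_interpeak_min = res$sim_interpeak_min,
          sim_movement_duration = res$sim_movement_duration,
          movement_duration = obs$t[length(obs$t)],
          evals = res$evals, seed = sub_seed, stringsAsFactors = FALSE)
      } else {
        fails[[length(fails) + 1L]] <- data.frame(
          subject = obs$subject, block = obs$block, trial = obs$trial,
          kind = kind, error = conditionMessage(res),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(subject = character(0), block = character(0),
               trial = numeric(0), kind = character(0))
  attr(out, "failures") <- if (length(fails)) do.call(rbind, fails) else
    data.frame(subject = character(0), kind = character(0),
               error = character(0))
  out
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf(
    "fit [%s]: K = %.4g N/m, B = %.4g Ns/m, T = %.4g ms, objective = %.5g, VAF = %.2f%% (%d evals)\n",
    x$kind, x$K, x$B, x$T, x$objective, x$vaf, x$evals))
  invisible(x)
}
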