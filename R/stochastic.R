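#' Periodic pathogen-encounter schedule
#'
#' The host encounters the pathogen periodically across its lifetime: at
#' `t = 0, period, 2 * period, ...` for every multiple strictly below `T`,
#' `inoculum` bacteria are added before that step's reactions. The default
#' study condition (period 200, lifetime 1000) gives five encounters.
#'
#' @param period encounter period in steps (`>= 1`).
#' @param T host lifetime in steps (`>= 1`).
#' @param inoculum bacteria added per encounter (`>= 1`).
#' @return An object of class `encounter_schedule` with elements `times`
#'   (integer event times), `inoculum`, `period`, `T`.
#' @examples
#' length(encounter_schedule(200, 1000)$times) # 5
#' @export
encounter_schedule <- function(period, T, inoculum = 1) {
  if (period < 1 || T < 1) {
    stop("invalid config: period and T must be >= 1", call. = FALSE)
  }
  if (inoculum < 1) stop("invalid config: inoculum must be >= 1", call. = FALSE)
  times <- as.integer(period) * (0:((T - 1) %/% period))
  structure(list(times = as.integer(times), inoculum = as.integer(inoculum),
                 period = period, T = as.integer(T)),
            class = "encounter_schedule")
}

#' Advance one discrete stochastic step (reference implementation)
#'
#' The simulator is a discrete-time Gillespie-like scheme in which at most two
#' reactions fire per step: one from the bacterial set (proliferation or
#' elimination) and one from the immune set, each chosen with probability
#' proportional to its propensity within its set. If a set's total propensity
#' is zero, no reaction fires from that set. Both sets are evaluated on the
#' step's starting state and the two selected state changes are applied
#' jointly; the time index advances by one regardless.
#'
#' This R implementation over [build_network()] channels is the reference
#' surface; [simulate_trajectory()] and [run_ensemble()] use an equivalent
#' compiled engine. Uses R's RNG (seed with [set.seed()]); the bacterial draw
#' consumes the stream before the immune draw.
#'
#' @param state a [system_state()] (or named count vector with attribute `t`).
#' @param network a [build_network()] result.
#' @param params a [model_params()] object.
#' @return The updated state with attribute `t` incremented.
#' @export
step_state <- function(state, network, params) {
  a_b <- propensity_vector(state, network$bacterial_channels, params)
  a_i <- propensity_vector(state, network$immune_channels, params)
  s <- state
  if (sum(a_b) > 0) {
    j <- pick_channel(a_b)
    s <- s + network$bacterial_channels[[j]]$delta
  }
  if (sum(a_i) > 0) {
    j <- pick_channel(a_i)
    s <- s + network$immune_channels[[j]]$delta
  }
  t0 <- attr(state, "t")
  attributes(s) <- attributes(state)
  attr(s, "t") <- (if (is.null(t0)) 0L else t0) + 1L
  s
}

# inverse-CDF selection from unnormalized weights, one uniform draw
pick_channel <- function(a) {
  u <- runif(1) * sum(a)
  findInterval(u, cumsum(a), left.open = TRUE) + 1L
}

#' Simulate one stochastic trajectory
#'
#' Runs the discrete-time two-reaction-set scheme for `T` steps, applying any
#' scheduled encounter (B increased by the inoculum) before the reactions of
#' that step, and records the full state at every integer time from 0 to `T`
#' (the recorded state at an encounter time includes the inoculum).
#' Identical `(params, schedule, seed)` give bit-identical trajectories.
#'
#' @param params a [model_params()] object.
#' @param schedule an [encounter_schedule()].
#' @param T lifetime in steps; defaults to `schedule$T`.
#' @param init initial state, default [default_init()].
#' @param seed integer seed for this trajectory.
#' @return A data frame with columns `t`, `B`, `R`, `N`, `P`, `S`, `A`
#'   (`T + 1` rows) carrying `params`, `schedule` and `seed` as attributes.
#' @export
simulate_trajectory <- function(params, schedule, T = schedule$T,
                                init = default_init(), seed = 1L) {
  stopifnot(inherits(params, "circuit_params"))
  if (any(init < 0)) stop("init counts must be >= 0", call. = FALSE)
  m <- sim_trajectory_cpp(params_to_vec(params), as.integer(T),
                          schedule$times, schedule$inoculum,
                          as.numeric(init), as.double(seed))
  out <- data.frame(t = 0:T, m)
  names(out) <- c("t", species_order())
  attr(out, "params") <- params
  attr(out, "schedule") <- schedule
  attr(out, "seed") <- seed
  attr(out, "engine") <- "stochastic"
  out
}

#' Run a replicate ensemble
#'
#' Repeats [simulate_trajectory()] `n_reps` times; replicate `r` uses an
#' independent random stream derived deterministically from
#' `(base_seed, rep_offset + r)`, so ensembles can be produced in chunks (via
#' `rep_offset`) that are bit-identical to a single serial run.
#'
#' @param params a [model_params()] object.
#' @param schedule an [encounter_schedule()].
#' @param n_reps number of replicate simulations (`>= 1`). Full-scale study
#'   runs use 10,000.
#' @param base_seed integer root seed of the ensemble.
#' @param T lifetime in steps; defaults to `schedule$T`.
#' @param init initial state.
#' @param rep_offset index of the first replicate within the ensemble's
#'   seed sequence (for chunked execution).
#' @param keep_bacteria also record the bacteria matrix.
#' @return An object of class `amp_ensemble`: a list with `amp` (and
#'   optionally `bacteria`) as `n_reps x (T + 1)` matrices, plus metadata.
#' @export
run_ensemble <- function(params, schedule, n_reps, base_seed,
                         T = schedule$T, init = default_init(),
                         rep_offset = 0L, keep_bacteria = TRUE) {
  stopifnot(inherits(params, "circuit_params"))
  if (n_reps < 1) stop("invalid config: n_reps must be >= 1", call. = FALSE)
  if (any(init < 0)) stop("init counts must be >= 0", call. = FALSE)
  res <- sim_ensemble_cpp(params_to_vec(params), as.integer(T),
                          schedule$times, schedule$inoculum,
                          as.numeric(init), as.integer(n_reps),
                          as.double(base_seed), as.integer(rep_offset),
                          keep_bacteria)
  structure(list(amp = res$amp, bacteria = res$bacteria,
                 n_reps = as.integer(n_reps), T = as.integer(T),
                 base_seed = base_seed, params = params, schedule = schedule),
            class = "amp_ensemble")
}

#' @export
print.amp_ensemble <- function(x, ...) {
  cat("<amp_ensemble> ", x$n_reps, " replicates x ", x$T + 1,
      " time points (", x$params$topology, ", base_seed = ", x$base_seed,
      ")\n", sep = "")
  invisible(x)
}
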