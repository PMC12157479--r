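#' Fitness from bacterial load alone
#'
#' `exp(-mean_B)`: host fitness falls with the lifetime-average bacterial
#' load; the scenario where pathogen virulence far outweighs immunopathology.
#'
#' @param mean_B lifetime-average bacterial load (`>= 0`).
#' @return Fitness in (0, 1].
#' @export
fitness_load <- function(mean_B) {
  if (any(mean_B < 0)) stop("invalid input: mean_B must be >= 0", call. = FALSE)
  exp(-mean_B)
}

#' Fitness from bacterial load and AMP cost
#'
#' `exp(-(mean_B + mean_A))`: the host must fight off infection while
#' minimizing AMP expression, whose overproduction is immunopathologic. This
#' is the fitness used in the evolutionary simulations.
#'
#' @param mean_B,mean_A lifetime-average bacterial load and AMP level
#'   (both `>= 0`).
#' @return Fitness in (0, 1].
#' @export
fitness_combined <- function(mean_B, mean_A) {
  if (any(mean_B < 0) || any(mean_A < 0)) {
    stop("invalid input: lifetime means must be >= 0", call. = FALSE)
  }
  exp(-(mean_B + mean_A))
}

evolving_names <- function() c("beta1", "beta2", "beta5", "lam", "beta3", "beta4")

default_bounds <- function() {
  list(lower = c(beta1 = 1, beta2 = 1, beta5 = 1, lam = 0.1,
                 beta3 = 1, beta4 = 1),
       upper = c(beta1 = 10, beta2 = 10, beta5 = 10, lam = 1,
                 beta3 = 10, beta4 = 10))
}

#' Evolutionary-simulation configuration
#'
#' @param generations mutation-selection generations (full scale: 5,000).
#' @param fitness `"combined"` (load + AMP cost; the default used for the
#'   evolutionary study) or `"load"`.
#' @param engine `"stochastic"` or `"ode"` fitness evaluation.
#' @param n_eval replicate simulations per stochastic fitness evaluation.
#' @param T,period,inoculum lifetime and encounter schedule.
#' @param k0,Zn,Zs,kappa_kill,delta_pirk,c_cactus,amp_form fixed (non-evolving)
#'   circuit context.
#' @param use_crn reuse one random stream for every fitness evaluation
#'   (common random numbers): re-evaluating identical parameters then returns
#'   an identical estimate.
#' @param re_evaluate_incumbent re-estimate the incumbent's fitness each
#'   generation instead of caching it.
#' @param noise_reps ensemble size for the start/end noise estimates.
#' @param noise_margin relative margin above which the final noise counts as
#'   increased.
#' @param mutable subset of parameter names allowed to mutate (all six by
#'   default).
#' @param fitness_fn optional override: a `function(param_vector) -> fitness`
#'   replacing simulation entirely (used for algorithm checks).
#' @return A list of class `evolve_config`.
#' @export
evolve_config <- function(generations = 5000,
                          fitness = c("combined", "load"),
                          engine = c("stochastic", "ode"),
                          n_eval = 100, T = 1000, period = 200, inoculum = 1,
                          k0 = 0.1, Zn = 1, Zs = 1,
                          kappa_kill = 1, delta_pirk = 1, c_cactus = 1,
                          amp_form = "competitive",
                          use_crn = FALSE, re_evaluate_incumbent = FALSE,
                          noise_reps = 1000, noise_margin = 0.05,
                          mutable = evolving_names(), fitness_fn = NULL) {
  fitness <- match.arg(fitness)
  engine <- match.arg(engine)
  if (generations < 0) stop("invalid config: generations < 0", call. = FALSE)
  if (n_eval < 1) stop("invalid config: n_eval must be >= 1", call. = FALSE)
  if (!all(mutable %in% evolving_names())) {
    stop("invalid config: unknown mutable parameter", call. = FALSE)
  }
  structure(list(generations = generations, fitness = fitness,
                 engine = engine, n_eval = n_eval, T = T, period = period,
                 inoculum = inoculum, k0 = k0, Zn = Zn, Zs = Zs,
                 kappa_kill = kappa_kill, delta_pirk = delta_pirk,
                 c_cactus = c_cactus, amp_form = amp_form,
                 use_crn = use_crn,
                 re_evaluate_incumbent = re_evaluate_incumbent,
                 noise_reps = noise_reps, noise_margin = noise_margin,
                 mutable = mutable, fitness_fn = fitness_fn),
            class = "evolve_config")
}

build_evolved_params <- function(values, topology, config) {
  model_params(topology, k0 = config$k0,
               beta1 = values[["beta1"]], beta2 = values[["beta2"]],
               beta3 = values[["beta3"]], beta4 = values[["beta4"]],
               beta5 = values[["beta5"]], lam = values[["lam"]],
               Zn = config$Zn, Zs = config$Zs,
               kappa_kill = config$kappa_kill,
               delta_pirk = config$delta_pirk, c_cactus = config$c_cactus,
               amp_form = config$amp_form)
}

#' Estimate fitness of a parameter set
#'
#' Stochastic mode: runs `n_eval` seeded replicate simulations, computes each
#' replicate's lifetime means of A and B (over the `T + 1` recorded time
#' points), applies the fitness function per replicate and returns the
#' average. Deterministic mode: one ODE run, fitness of its lifetime means.
#'
#' @param values named vector of the six evolving parameters.
#' @param topology `"IMD"` or `"TOLL"`.
#' @param config an [evolve_config()].
#' @param seed stream seed for the stochastic evaluation.
#' @return Scalar fitness estimate in (0, 1].
#' @export
evaluate_fitness <- function(values, topology, config = evolve_config(),
                             seed = 1L) {
  if (!is.null(config$fitness_fn)) return(config$fitness_fn(values))
  params <- build_evolved_params(values, topology, config)
  schedule <- encounter_schedule(config$period, config$T, config$inoculum)
  if (config$engine == "ode") {
    sol <- solve_deterministic(params, schedule)
    mB <- mean(pmax(sol$B, 0))
    mA <- mean(pmax(sol$A, 0))
    return(if (config$fitness == "load") fitness_load(mB)
           else fitness_combined(mB, mA))
  }
  ens <- run_ensemble(params, schedule, n_reps = config$n_eval,
                      base_seed = seed, keep_bacteria = TRUE)
  mB <- rowMeans(ens$bacteria)
  mA <- rowMeans(ens$amp)
  f <- if (config$fitness == "load") fitness_load(mB)
       else fitness_combined(mB, mA)
  mean(f)
}

#' Propose a single mutation
#'
#' Picks one of the mutable parameters uniformly at random and adds or
#' subtracts one step with equal probability (step 1 for the five production
#' rates, 0.1 for the degradation rate `lam`). A proposal that leaves the
#' bounds (`lam` in [0.1, 1], others in [1, 10]) is marked out-of-bounds and
#' the generation counts as rejected; values are never clamped. Uses R's RNG.
#'
#' @param values named vector of the six evolving parameters.
#' @param mutable which parameters may mutate.
#' @param bounds list with named `lower`/`upper` vectors.
#' @return List with `candidate` (the mutated vector, unchanged if
#'   out-of-bounds), `param`, `direction` (+1/-1), `step` and `in_bounds`.
#' @export
propose_mutation <- function(values, mutable = evolving_names(),
                             bounds = default_bounds()) {
  par <- mutable[sample.int(length(mutable), 1)]
  dir <- if (runif(1) < 0.5) -1 else 1
  step <- if (par == "lam") 0.1 else 1
  cand <- values
  cand[[par]] <- cand[[par]] + dir * step
  eps <- 1e-9 # lam arithmetic in 0.1 steps is inexact in binary
  in_bounds <- cand[[par]] >= bounds$lower[[par]] - eps &&
    cand[[par]] <= bounds$upper[[par]] + eps
  list(candidate = if (in_bounds) cand else values,
       param = par, direction = dir, step = step, in_bounds = in_bounds)
}

init_evolving <- function() {
  v <- c(beta1 = 0, beta2 = 0, beta5 = 0, lam = 0,
         beta3 = 0, beta4 = 0)
  for (nm in c("beta1", "beta2", "beta5", "beta3", "beta4")) {
    v[[nm]] <- sample(1:10, 1)
  }
  v[["lam"]] <- sample(seq(0.1, 1, by = 0.1), 1)
  v
}

#' Greedy evolutionary simulation of one lineage
#'
#' Starts from uniformly random parameter values on the allowed grids and,
#' for each generation, proposes a single mutation, estimates the mutant's
#' fitness, and accepts it only if the estimate strictly exceeds the
#' incumbent's (cached) fitness. Out-of-bounds proposals are rejected without
#' evaluation. After the run, AMP noise of the initial and final parameter
#' sets is estimated on a fixed-size ensemble to flag lineages whose noise
#' increased across generations.
#'
#' @param topology `"IMD"` or `"TOLL"`.
#' @param config an [evolve_config()].
#' @param seed integer seed governing initialization, proposals and all
#'   fitness-evaluation streams.
#' @return List of class `evolution_record`: `initial`/`final` parameter
#'   vectors, `initial_fitness`/`final_fitness`, a per-generation `trace`
#'   data frame (proposed parameter, direction, candidate fitness, accepted
#'   flag), `initial_noise`, `final_noise`, `noise_increased`, `seed`.
#' @export
evolve <- function(topology = c("IMD", "TOLL"), config = evolve_config(),
                   seed = 1L) {
  topology <- match.arg(topology)
  stopifnot(inherits(config, "evolve_config"))
  bounds <- default_bounds()
  set.seed(seed)
  current <- init_evolving()
  eval_seed <- function(gen) {
    if (config$use_crn) derive_seed(seed, 0) else derive_seed(seed, gen)
  }
  current_fit <- evaluate_fitness(current, topology, config, eval_seed(0))
  initial <- current
  initial_fit <- current_fit
  g <- config$generations
  trace <- data.frame(generation = seq_len(g),
                      param = character(g), direction = integer(g),
                      in_bounds = logical(g),
                      candidate_fitness = rep(NA_real_, g),
                      accepted = logical(g), fitness = rep(NA_real_, g),
                      stringsAsFactors = FALSE)
  for (gen in seq_len(g)) {
    prop <- propose_mutation(current, config$mutable, bounds)
    trace$param[gen] <- prop$param
    trace$direction[gen] <- prop$direction
    trace$in_bounds[gen] <- prop$in_bounds
    if (prop$in_bounds) {
      if (config$re_evaluate_incumbent) {
        current_fit <- evaluate_fitness(current, topology, config,
                                        eval_seed(gen))
      }
      cand_fit <- evaluate_fitness(prop$candidate, topology, config,
                                   eval_seed(gen))
      trace$candidate_fitness[gen] <- cand_fit
      if (cand_fit > current_fit) { # strict: ties reject
        current <- prop$candidate
        current_fit <- cand_fit
        trace$accepted[gen] <- TRUE
      }
    }
    trace$fitness[gen] <- current_fit
  }
  noise_for <- function(values, tag) {
    if (!is.null(config$fitness_fn) || config$noise_reps < 2) return(NA_real_)
    params <- build_evolved_params(values, topology, config)
    schedule <- encounter_schedule(config$period, config$T, config$inoculum)
    ens <- run_ensemble(params, schedule, n_reps = config$noise_reps,
                        base_seed = derive_seed(seed, 1000000 + tag),
                        keep_bacteria = FALSE)
    noise_score(ens$amp)
  }
  n0 <- noise_for(initial, 0)
  n1 <- noise_for(current, 1)
  structure(list(topology = topology, seed = seed,
                 initial = initial, final = current,
                 initial_fitness = initial_fit, final_fitness = current_fit,
                 trace = trace,
                 initial_noise = n0, final_noise = n1,
                 noise_increased = isTRUE(n1 > n0 * (1 + config$noise_margin))),
            class = "evolution_record")
}

#' Batch of independent evolutionary replicates
#'
#' Runs [evolve()] `n_replicates` times with child seeds derived from
#' `base_seed` and collects one row per replicate.
#'
#' @param n_replicates number of lineages (full scale: 500).
#' @param topology `"IMD"` or `"TOLL"`.
#' @param config an [evolve_config()].
#' @param base_seed root seed.
#' @return Data frame: per replicate the final six parameters, final fitness,
#'   initial/final noise, the `noise_increased` flag and the
#'   [classify_outcome()] category.
#' @export
run_evolution_batch <- function(n_replicates, topology = c("IMD", "TOLL"),
                                config = evolve_config(), base_seed = 1L) {
  topology <- match.arg(topology)
  if (n_replicates < 1) {
    stop("invalid config: n_replicates must be >= 1", call. = FALSE)
  }
  rows <- lapply(seq_len(n_replicates), function(r) {
    rec <- evolve(topology, config, seed = derive_seed(base_seed, r))
    data.frame(replicate = r, topology = topology,
               t(rec$final),
               final_fitness = rec$final_fitness,
               initial_noise = rec$initial_noise,
               final_noise = rec$final_noise,
               noise_increased = rec$noise_increased,
               outcome = classify_outcome(rec$final),
               seed = rec$seed,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify an evolved NFL configuration
#'
#' Labels a final parameter set by which NFL production rates exceed a
#' threshold (default 5, the midpoint of the allowed range; strict
#' inequality): both, only the downstream (`beta4`), only the upstream
#' (`beta3`), or neither.
#'
#' @param values named vector containing `beta3` and `beta4`.
#' @param threshold strength threshold.
#' @return One of `"both-strong"`, `"downstream-biased"`,
#'   `"upstream-biased"`, `"both-weak"`.
#' @export
classify_outcome <- function(values, threshold = 5) {
  up <- values[["beta3"]] > threshold
  down <- values[["beta4"]] > threshold
  if (up && down) "both-strong"
  else if (down) "downstream-biased"
  else if (up) "upstream-biased"
  else "both-weak"
}
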