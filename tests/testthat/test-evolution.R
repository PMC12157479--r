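test_that("fitness functions follow the exponential load/cost forms", {
  expect_equal(fitness_load(0), 1)
  expect_equal(fitness_load(1), exp(-1))
  expect_equal(fitness_combined(0, 0), 1)
  expect_equal(fitness_combined(1, 1), exp(-2))
  expect_equal(fitness_combined(2.5, 0), fitness_load(2.5))
  x <- seq(0, 10, 0.5)
  expect_true(all(diff(fitness_load(x)) < 0))
  expect_true(all(fitness_load(x) > 0 & fitness_load(x) <= 1))
  expect_error(fitness_load(-0.1), "invalid input")
  expect_error(fitness_combined(1, -1), "invalid input")
})

test_that("mutations pick one parameter, step symmetrically, respect bounds", {
  v <- c(beta1 = 5, beta2 = 5, beta5 = 5, lam = 0.5, beta3 = 5, beta4 = 5)
  set.seed(300)
  n <- 100000
  par <- character(n)
  dir <- integer(n)
  step_ok <- logical(n)
  for (i in seq_len(n)) {
    pr <- propose_mutation(v)
    par[i] <- pr$param
    dir[i] <- pr$direction
    want <- if (pr$param == "lam") 0.1 else 1
    step_ok[i] <- isTRUE(all.equal(abs(pr$candidate[[pr$param]] -
                                         v[[pr$param]]), want))
  }
  expect_true(all(step_ok))
  freq <- table(par) / n
  se6 <- sqrt((1 / 6) * (5 / 6) / n)
  expect_true(all(abs(freq - 1 / 6) < 3 * se6))
  se2 <- sqrt(0.25 / n)
  expect_lt(abs(mean(dir == 1) - 0.5), 3 * se2)
})

test_that("out-of-bounds proposals are rejected, never clamped", {
  hi <- c(beta1 = 10, beta2 = 10, beta5 = 10, lam = 1, beta3 = 10, beta4 = 10)
  lo <- c(beta1 = 1, beta2 = 1, beta5 = 1, lam = 0.1, beta3 = 1, beta4 = 1)
  set.seed(301)
  for (i in 1:400) {
    for (v in list(hi, lo)) {
      pr <- propose_mutation(v)
      if (!pr$in_bounds) expect_identical(pr$candidate, v)
      expect_true(all(pr$candidate >= lo - 1e-9 & pr$candidate <= hi + 1e-9))
    }
  }
})

test_that("fitness evaluation matches the closed form on a frozen circuit", {
  # all rates 0, k0 = 0: B jumps by 1 at each of the 5 encounters and no
  # reaction ever fires, so the lifetime mean of B over t = 0..1000 is
  # (200*(1+2+3+4) + 201*5)/1001 and A stays 0
  cfg <- evolve_config(generations = 0, n_eval = 4, T = 1000,
                       k0 = 0, noise_reps = 0)
  cfg$kappa_kill <- 0
  v <- c(beta1 = 0, beta2 = 0, beta5 = 0, lam = 0, beta3 = 0, beta4 = 0)
  f <- evaluate_fitness(v, "IMD", cfg, seed = 5)
  expect_equal(f, exp(-3005 / 1001))
  # identical seed, identical estimate
  expect_identical(f, evaluate_fitness(v, "IMD", cfg, seed = 5))
})

test_that("deterministic-mode fitness of the empty system is 1", {
  cfg <- evolve_config(generations = 0, engine = "ode", T = 50,
                       k0 = 0, noise_reps = 0)
  cfg$kappa_kill <- 0
  cfg$inoculum <- 1
  v <- c(beta1 = 0, beta2 = 0, beta5 = 0, lam = 0.2, beta3 = 0, beta4 = 0)
  # one inoculation at t = 0 with k0 = 0 and no killing: mean B = 1
  expect_equal(evaluate_fitness(v, "IMD", cfg), exp(-1), tolerance = 1e-6)
})

test_that("the hill climber maximizes an injected deterministic fitness", {
  cfg <- evolve_config(generations = 40, noise_reps = 0, mutable = "beta1",
                       fitness_fn = function(v) -(v[["beta1"]] - 7)^2)
  for (seed in 1:5) {
    rec <- evolve("IMD", cfg, seed = seed)
    expect_equal(unname(rec$final[["beta1"]]), 7)
    acc <- rec$trace$candidate_fitness[rec$trace$accepted]
    if (length(acc) > 1) expect_true(all(diff(acc) > 0))
    # the incumbent's recorded fitness never decreases
    expect_true(all(diff(rec$trace$fitness) >= 0))
  }
})

test_that("zero generations return the initial parameters unchanged", {
  cfg <- evolve_config(generations = 0, n_eval = 2, T = 50, noise_reps = 0)
  rec <- evolve("TOLL", cfg, seed = 17)
  expect_identical(rec$final, rec$initial)
  expect_equal(nrow(rec$trace), 0)
})

test_that("stochastic evolution keeps bounds and a strictly increasing record", {
  cfg <- evolve_config(generations = 60, n_eval = 5, T = 150, noise_reps = 50)
  rec <- evolve("IMD", cfg, seed = 23)
  lo <- c(beta1 = 1, beta2 = 1, beta5 = 1, lam = 0.1, beta3 = 1, beta4 = 1)
  hi <- c(beta1 = 10, beta2 = 10, beta5 = 10, lam = 1, beta3 = 10, beta4 = 10)
  # replay the accepted proposals to check bounds at every generation
  v <- rec$initial
  for (g in seq_len(nrow(rec$trace))) {
    if (rec$trace$accepted[g]) {
      step <- if (rec$trace$param[g] == "lam") 0.1 else 1
      v[[rec$trace$param[g]]] <- v[[rec$trace$param[g]]] +
        rec$trace$direction[g] * step
    }
    expect_true(all(v >= lo - 1e-9 & v <= hi + 1e-9))
  }
  expect_equal(unname(v), unname(rec$final))
  acc <- rec$trace$candidate_fitness[rec$trace$accepted]
  if (length(acc) > 1) expect_true(all(diff(acc) > 0))
  expect_true(is.finite(rec$initial_noise) && is.finite(rec$final_noise))
})

test_that("common random numbers make re-evaluation exactly reproducible", {
  cfg <- evolve_config(generations = 0, n_eval = 6, T = 100, noise_reps = 0,
                       use_crn = TRUE)
  v <- c(beta1 = 3, beta2 = 4, beta5 = 2, lam = 0.2, beta3 = 2, beta4 = 6)
  f1 <- evaluate_fitness(v, "TOLL", cfg, seed = 88)
  f2 <- evaluate_fitness(v, "TOLL", cfg, seed = 88)
  expect_identical(f1, f2)
})

test_that("evolution batches are reproducible row tables", {
  cfg <- evolve_config(generations = 15, n_eval = 3, T = 100, noise_reps = 0)
  tab1 <- run_evolution_batch(3, "IMD", cfg, base_seed = 9)
  tab2 <- run_evolution_batch(3, "IMD", cfg, base_seed = 9)
  expect_identical(tab1, tab2)
  expect_equal(nrow(tab1), 3)
  expect_true(all(c("beta3", "beta4", "final_fitness", "outcome") %in%
                    names(tab1)))
})

test_that("outcome classification thresholds NFL strengths strictly", {
  expect_equal(classify_outcome(c(beta3 = 1, beta4 = 10)), "downstream-biased")
  expect_equal(classify_outcome(c(beta3 = 10, beta4 = 1)), "upstream-biased")
  expect_equal(classify_outcome(c(beta3 = 10, beta4 = 10)), "both-strong")
  expect_equal(classify_outcome(c(beta3 = 5, beta4 = 5)), "both-weak")
})

test_that("removing the AMP cost does not lower evolved AMP expression", {
  # under load-only fitness AMP is free, so lifetime AMP of the evolved
  # parameters should not be systematically below the cost-penalized runs
  amp_of <- function(fit) {
    cfg <- evolve_config(generations = 80, n_eval = 8, T = 200,
                         noise_reps = 0, fitness = fit)
    sch <- encounter_schedule(200, 200)
    mean(vapply(1:6, function(s) {
      rec <- evolve("IMD", cfg, seed = 500 + s)
      p <- ampnoise:::build_evolved_params(rec$final, "IMD", cfg)
      mean(run_ensemble(p, sch, 60, base_seed = 999, keep_bacteria = FALSE)$amp)
    }, numeric(1)))
  }
  expect_gte(amp_of("load"), 0.8 * amp_of("combined"))
})
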