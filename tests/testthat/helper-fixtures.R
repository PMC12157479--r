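# shared fixtures: small parameter sets and random valid states

tiny_params <- function(topology = "IMD", ...) {
  args <- list(topology = topology, k0 = 0.1, beta1 = 2, beta2 = 3,
               beta3 = 1, beta4 = 2, beta5 = 4, lam = 0.2)
  over <- list(...)
  args[names(over)] <- over
  do.call(model_params, args)
}

random_params <- function(topology = sample(c("IMD", "TOLL"), 1)) {
  model_params(topology,
               k0 = sample(c(0.1, 0.5), 1),
               beta1 = sample(1:10, 1), beta2 = sample(1:10, 1),
               beta3 = sample(c(0, 1, 10), 1), beta4 = sample(c(0, 1, 10), 1),
               beta5 = sample(1:10, 1), lam = sample(seq(0.1, 1, 0.1), 1))
}

random_state <- function(max_count = 20) {
  do.call(system_state, as.list(setNames(sample(0:max_count, 6, TRUE),
                                         species_order())))
}

# propensity vectors straight from the compiled engine, for cross-checks
# against the R channel objects
cpp_propensities <- function(state, params) {
  ampnoise:::propensities_cpp(ampnoise:::params_to_vec(params),
                              as.numeric(state))
}
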