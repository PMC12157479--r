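#' Construct the parameter set of one immune-circuit variant
#'
#' Bundles every rate constant and binding energy of an Imd- or Toll-like
#' circuit. The six species are bacteria (B), receptors (R), active NF-kB (N),
#' the upstream negative-feedback protein Pirk (P), the downstream
#' negative-feedback protein (S; Repressosome for `"IMD"`, Cactus for
#' `"TOLL"`), and antimicrobial peptides (A).
#'
#' @param topology `"IMD"` or `"TOLL"`. The two variants differ only in how S
#'   acts: the Repressosome competes with NF-kB for the AMP promoter, Cactus
#'   removes active NF-kB before it reaches the nucleus.
#' @param k0 bacterial proliferation rate.
#' @param beta1 receptor production rate (the strength of the positive
#'   feedback loop, since receptors are induced by NF-kB).
#' @param beta2 NF-kB activation rate (per receptor-bacterium encounter).
#' @param beta3 Pirk (upstream NFL) production rate.
#' @param beta4 downstream-NFL production rate.
#' @param beta5 AMP production rate.
#' @param lam degradation rate applied to all immune proteins (R, N, P, S, A).
#' @param Zn,Zs binding energies of NF-kB and of the Repressosome at the AMP
#'   promoter; smaller values mean stronger binding. Both must be positive.
#' @param kappa_kill AMP-mediated bacterial killing constant.
#' @param delta_pirk Pirk-mediated receptor removal constant.
#' @param c_cactus Cactus-mediated NF-kB removal constant (Toll only).
#' @param amp_form form of the Imd AMP production rate (see
#'   [amp_production_rate()]): `"competitive"` (default), `"occupancy"`
#'   (occupancy-only, bounded by `beta5`) or `"leaky"` (occupancy with a
#'   `+1` leak term in the denominator).
#'
#' @return An object of class `circuit_params`.
#' @examples
#' p <- model_params("IMD", beta3 = 10, beta4 = 10)
#' p$beta4
#' @export
model_params <- function(topology = c("IMD", "TOLL"),
                         k0 = 0.1,
                         beta1 = 1, beta2 = 1, beta3 = 0, beta4 = 0, beta5 = 1,
                         lam = 0.1,
                         Zn = 1, Zs = 1,
                         kappa_kill = 1, delta_pirk = 1, c_cactus = 1,
                         amp_form = c("competitive", "occupancy", "leaky")) {
  topology <- match.arg(topology)
  amp_form <- match.arg(amp_form)
  p <- list(
    topology = topology,
    k0 = k0, beta1 = beta1, beta2 = beta2, beta3 = beta3, beta4 = beta4,
    beta5 = beta5, lam = lam, Zn = Zn, Zs = Zs,
    kappa_kill = kappa_kill, delta_pirk = delta_pirk, c_cactus = c_cactus,
    amp_form = amp_form
  )
  rates <- unlist(p[c("k0", "beta1", "beta2", "beta3", "beta4", "beta5",
                      "lam", "kappa_kill", "delta_pirk", "c_cactus")])
  if (any(!is.finite(rates)) || any(rates < 0)) {
    stop("all rate constants must be finite and >= 0", call. = FALSE)
  }
  if (!is.finite(Zn) || Zn <= 0 || !is.finite(Zs) || Zs <= 0) {
    stop("binding energies Zn and Zs must be > 0", call. = FALSE)
  }
  structure(p, class = "circuit_params")
}

#' @export
print.circuit_params <- function(x, ...) {
  cat("<circuit_params> ", x$topology, " topology (amp_form = ",
      x$amp_form, ")\n", sep = "")
  r <- unlist(x[c("k0", "beta1", "beta2", "beta3", "beta4", "beta5", "lam",
                  "Zn", "Zs", "kappa_kill", "delta_pirk", "c_cactus")])
  print(r)
  invisible(x)
}

#' Construct a system state
#'
#' A named count vector in the canonical species order, with the time index
#' stored in attribute `"t"`. Counts are integer-valued in the stochastic
#' engine and real-valued in the ODE engine.
#'
#' @param B,R,N,P,S,A species counts, all `>= 0`.
#' @param t integer time index, `>= 0`.
#' @return Named numeric vector of length 6 with class `system_state`.
#' @export
system_state <- function(B = 0, R = 0, N = 0, P = 0, S = 0, A = 0, t = 0) {
  s <- c(B = B, R = R, N = N, P = P, S = S, A = A)
  if (any(!is.finite(s)) || any(s < 0)) {
    stop("species counts must be finite and >= 0", call. = FALSE)
  }
  if (t < 0) stop("time index must be >= 0", call. = FALSE)
  structure(s, t = as.integer(t), class = c("system_state", "numeric"))
}

#' Default initial condition
#'
#' All species absent except a single seed receptor. With receptor production
#' strictly proportional to NF-kB and NF-kB activation proportional to
#' receptor x bacteria, an all-zero start is absorbing; one receptor breaks
#' the deadlock minimally.
#'
#' @param R0 initial receptor count.
#' @return A [system_state()].
#' @export
default_init <- function(R0 = 1) system_state(R = R0)

#' AMP production propensity
#'
#' In the Toll-like model Cactus does not act at the promoter (it removes
#' active NF-kB through a separate channel), so the rate is simply
#' `beta5 * N / Zn`. In the Imd-like model the Repressosome competes with
#' NF-kB for the AMP promoter, and the competition factor
#' `(N/Zn) / (N/Zn + S/Zs)` (defined as 0 when both species are absent)
#' depends only on the Repressosome-to-NF-kB ratio when `Zn = Zs`. Three
#' functional forms are available through `params$amp_form`:
#'
#' * `"competitive"` (default): `beta5 * (N/Zn) * (N/Zn)/(N/Zn + S/Zs)` --
#'   the Toll rate attenuated by the competition factor. With no Repressosome
#'   present this reduces exactly to the Toll rate, so the two topologies
#'   differ only through the downstream NFL.
#' * `"occupancy"`: `beta5 * (N/Zn)/(N/Zn + S/Zs)`, occupancy-only and
#'   bounded by `beta5`.
#' * `"leaky"`: `beta5 * (N/Zn)/(1 + N/Zn + S/Zs)`, occupancy with a leak
#'   term.
#'
#' @param N active NF-kB count (`>= 0`).
#' @param S downstream-NFL protein count (`>= 0`).
#' @param params a [model_params()] object.
#' @param topology optional override of `params$topology`.
#' @return Nonnegative production rate (vectorized over `N`, `S`).
#' @export
amp_production_rate <- function(N, S, params, topology = params$topology) {
  if (any(N < 0) || any(S < 0)) {
    stop("N and S must be >= 0", call. = FALSE)
  }
  if (params$Zn <= 0 || params$Zs <= 0) {
    stop("binding energies Zn and Zs must be > 0", call. = FALSE)
  }
  if (topology == "TOLL") {
    return(params$beta5 * N / params$Zn)
  }
  x <- N / params$Zn
  y <- S / params$Zs
  # the ratio forms are 0 when the total promoter weight vanishes; the 1e-9
  # floor only matters for real-valued (ODE) states, where the ratio's
  # Jacobian grows like 1/(x + y) and would otherwise stall the stiff solver
  # as both species decay to zero -- integer counts are never below 1/Z
  switch(params$amp_form,
         leaky = params$beta5 * x / (1 + x + y),
         occupancy = ifelse(x + y > 1e-9, params$beta5 * x / (x + y), 0),
         competitive = ifelse(x + y > 1e-9, params$beta5 * x * x / (x + y), 0))
}

new_channel <- function(id, set, delta, propensity) {
  stopifnot(set %in% c("BACTERIAL", "IMMUNE"))
  list(id = id, set = set, delta = delta, propensity = propensity)
}

delta_vec <- function(...) {
  z <- setNames(numeric(6), species_order())
  m <- c(...)
  z[names(m)] <- m
  z
}

#' Build the reaction network of a circuit variant
#'
#' Returns the full channel list: a bacterial set (proliferation and
#' AMP-mediated elimination; exactly one bacterial reaction can fire per
#' step) and an immune set (production of R, N, P, S and A, Pirk-mediated
#' receptor removal, first-order degradation of every immune protein, and for
#' the Toll-like model Cactus-mediated NF-kB removal). Every decrement
#' channel's propensity is proportional to the decremented species, so firing
#' a channel with positive propensity can never drive a count negative.
#'
#' @param params a [model_params()] object.
#' @return An object of class `reaction_network` with elements
#'   `bacterial_channels`, `immune_channels` and `topology`.
#' @export
build_network <- function(params) {
  stopifnot(inherits(params, "circuit_params"))
  bact <- list(
    new_channel("proliferation", "BACTERIAL", delta_vec(B = 1),
                function(s, p) p$k0 * s[["B"]]),
    new_channel("elimination", "BACTERIAL", delta_vec(B = -1),
                function(s, p) p$kappa_kill * s[["A"]] * s[["B"]])
  )
  imm <- list(
    new_channel("receptor_production", "IMMUNE", delta_vec(R = 1),
                function(s, p) p$beta1 * s[["N"]]),
    new_channel("nfkb_activation", "IMMUNE", delta_vec(N = 1),
                function(s, p) p$beta2 * s[["R"]] * s[["B"]]),
    new_channel("pirk_production", "IMMUNE", delta_vec(P = 1),
                function(s, p) p$beta3 * s[["N"]]),
    new_channel("downstream_nfl_production", "IMMUNE", delta_vec(S = 1),
                function(s, p) p$beta4 * s[["N"]]),
    new_channel("amp_production", "IMMUNE", delta_vec(A = 1),
                function(s, p) amp_production_rate(s[["N"]], s[["S"]], p)),
    new_channel("pirk_receptor_removal", "IMMUNE", delta_vec(R = -1),
                function(s, p) p$delta_pirk * s[["P"]] * s[["R"]]),
    new_channel("deg_R", "IMMUNE", delta_vec(R = -1),
                function(s, p) p$lam * s[["R"]]),
    new_channel("deg_N", "IMMUNE", delta_vec(N = -1),
                function(s, p) p$lam * s[["N"]]),
    new_channel("deg_P", "IMMUNE", delta_vec(P = -1),
                function(s, p) p$lam * s[["P"]]),
    new_channel("deg_S", "IMMUNE", delta_vec(S = -1),
                function(s, p) p$lam * s[["S"]]),
    new_channel("deg_A", "IMMUNE", delta_vec(A = -1),
                function(s, p) p$lam * s[["A"]])
  )
  if (params$topology == "TOLL") {
    imm <- c(imm, list(
      new_channel("cactus_nfkb_removal", "IMMUNE", delta_vec(N = -1),
                  function(s, p) p$c_cactus * s[["S"]] * s[["N"]])
    ))
  }
  structure(list(bacterial_channels = bact, immune_channels = imm,
                 topology = params$topology),
            class = "reaction_network")
}

#' Evaluate channel propensities at a state
#'
#' @param state named count vector (see [system_state()]).
#' @param channels a list of channels from [build_network()].
#' @param params a [model_params()] object.
#' @return Numeric vector of nonnegative rates, one per channel, named by
#'   channel id.
#' @export
propensity_vector <- function(state, channels, params) {
  if (any(state < 0)) stop("invalid state: negative species count", call. = FALSE)
  a <- vapply(channels, function(ch) ch$propensity(state, params), numeric(1))
  names(a) <- vapply(channels, `[[`, character(1), "id")
  if (any(!is.finite(a)) || any(a < 0)) {
    stop("propensities must be finite and >= 0", call. = FALSE)
  }
  a
}

# flat numeric encoding consumed by the C++ engine; order is fixed and must
# match the enum in src/engine.cpp
params_to_vec <- function(params) {
  c(params$k0, params$beta1, params$beta2, params$beta3, params$beta4,
    params$beta5, params$lam, params$Zn, params$Zs,
    params$kappa_kill, params$delta_pirk, params$c_cactus,
    if (params$topology == "TOLL") 1 else 0,
    switch(params$amp_form, competitive = 0, occupancy = 1, leaky = 2))
}
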