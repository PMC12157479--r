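#' Deterministic right-hand side of a circuit variant
#'
#' Mass-action ODE counterpart of the stochastic reaction network:
#' \deqn{dB/dt = k_0 B - \kappa A B}
#' \deqn{dR/dt = \beta_1 N - \delta P R - \lambda R}
#' \deqn{dN/dt = \beta_2 R B - \lambda N \;(-\; c S N \textrm{ for Toll})}
#' \deqn{dP/dt = \beta_3 N - \lambda P}
#' \deqn{dS/dt = \beta_4 N - \lambda S}
#' \deqn{dA/dt = \mathrm{amp\_production\_rate}(N, S) - \lambda A}
#'
#' @param state real-valued named state vector (species order of
#'   [species_order()]).
#' @param params a [model_params()] object.
#' @param topology optional override of `params$topology`.
#' @return Named derivative vector.
#' @export
circuit_rhs <- function(state, params, topology = params$topology) {
  B <- state[["B"]]; R <- state[["R"]]; N <- state[["N"]]
  P <- state[["P"]]; S <- state[["S"]]; A <- state[["A"]]
  dN <- params$beta2 * R * B - params$lam * N
  if (topology == "TOLL") dN <- dN - params$c_cactus * S * N
  c(B = params$k0 * B - params$kappa_kill * A * B,
    R = params$beta1 * N - params$delta_pirk * P * R - params$lam * R,
    N = dN,
    P = params$beta3 * N - params$lam * P,
    S = params$beta4 * N - params$lam * S,
    A = amp_production_rate(max(N, 0), max(S, 0), params, topology) -
      params$lam * A)
}

#' Solve the noise-free (deterministic) model
#'
#' Integrates the ODE counterpart with a stiff-capable multistep method
#' (BDF via [deSolve::ode()]) piecewise between pathogen encounters. Each
#' encounter is an impulsive state jump `B <- B + inoculum` applied at the
#' event time, after which the solver restarts; the recorded state at an
#' event time includes the jump, mirroring the stochastic engine.
#'
#' Species below an extinction cutoff of `1e-9` are treated as absent when
#' evaluating the vector field, so a cleared infection (or a fully decayed
#' immune response) cannot re-ignite from sub-tolerance numerical residuals;
#' in the stochastic model the corresponding zero-count states are absorbing.
#' Recorded values are floored at 0 (raw solver output may undershoot on the
#' order of the tolerances).
#'
#' @param params a [model_params()] object.
#' @param schedule an [encounter_schedule()].
#' @param T lifetime; defaults to `schedule$T`.
#' @param init initial state (real-valued allowed).
#' @param atol,rtol absolute and relative solver tolerances
#'   (defaults `1e-6` and `1e-8`).
#' @return A data frame on the integer time grid `t = 0 ... T` with species
#'   columns, `engine = "ode"` and the tolerances as attributes.
#' @export
solve_deterministic <- function(params, schedule, T = schedule$T,
                                init = default_init(),
                                atol = 1e-6, rtol = 1e-8) {
  stopifnot(inherits(params, "circuit_params"))
  if (atol <= 0 || rtol <= 0) {
    stop("atol and rtol must be > 0", call. = FALSE)
  }
  event_times <- if (is.null(schedule$times)) integer(0) else schedule$times
  inoculum <- if (is.null(schedule$inoculum)) 0L else schedule$inoculum
  # evaluate the vector field on a regularized state: (i) clamped to >= 0,
  # since the solver may undershoot zero within tolerance and terms like
  # k0*B would amplify a tiny negative excursion exponentially; (ii) species
  # below the extinction cutoff treated as absent, mirroring the stochastic
  # model where extinction is absorbing -- otherwise a sub-tolerance residual
  # (e.g. B ~ 1e-12 after clearance) regrows exponentially and the solution
  # becomes sensitive to integration error
  cutoff <- 1e-9
  deriv <- function(t, y, parms) {
    y <- pmax(y, 0)
    y[y < cutoff] <- 0
    list(unname(circuit_rhs(y, parms)))
  }

  bounds <- sort(unique(c(0L, event_times[event_times < T], as.integer(T))))
  n_seg <- length(bounds) - 1
  state <- setNames(as.numeric(init), species_order())
  rows <- vector("list", n_seg)
  for (i in seq_len(n_seg)) {
    t0 <- bounds[i]
    t1 <- bounds[i + 1]
    if (t0 %in% event_times) state[["B"]] <- state[["B"]] + inoculum
    sol <- deSolve::ode(y = state, times = as.numeric(t0:t1), func = deriv,
                        parms = params, method = "bdf",
                        atol = atol, rtol = rtol, maxsteps = 20000)
    if (attr(sol, "istate")[1] < 0) {
      stop("ODE solver failed; last successful time ",
           max(sol[, "time"]), call. = FALSE)
    }
    # a segment's endpoint is re-recorded (post-jump) by the next segment
    rows[[i]] <- if (i == n_seg) sol else sol[-nrow(sol), , drop = FALSE]
    state <- sol[nrow(sol), species_order()]
  }
  m <- do.call(rbind, rows)
  # counts are nonnegative; the solver may undershoot zero on the order of
  # its tolerances, so recorded values are floored at 0
  out <- data.frame(t = m[, "time"],
                    pmax(m[, species_order(), drop = FALSE], 0))
  rownames(out) <- NULL
  attr(out, "params") <- params
  attr(out, "schedule") <- schedule
  attr(out, "engine") <- "ode"
  attr(out, "atol") <- atol
  attr(out, "rtol") <- rtol
  out
}
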