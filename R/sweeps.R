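#' The four NFL-activity regimes
#'
#' The production rates of the two negative feedback loops are either highly
#' expressed (10) or knocked down (0), giving four regimes: both knocked
#' down, upstream (Pirk) only, downstream (Repressosome/Cactus) only, and
#' both active.
#'
#' @return Data frame with columns `label`, `beta3`, `beta4` (4 rows).
#' @export
regime_table <- function() {
  data.frame(
    label = c("both_knocked_down", "upstream_active",
              "downstream_active", "both_active"),
    beta3 = c(0, 10, 0, 10),
    beta4 = c(0, 0, 10, 10),
    stringsAsFactors = FALSE
  )
}

as_regime <- function(regime) {
  if (is.character(regime)) {
    tab <- regime_table()
    i <- match(regime, tab$label)
    if (is.na(i)) {
      stop("unknown regime label: ", regime, "; see regime_table()",
           call. = FALSE)
    }
    return(as.list(tab[i, ]))
  }
  stopifnot(is.list(regime), all(c("label", "beta3", "beta4") %in% names(regime)))
  regime
}

#' Specify a background-parameter noise sweep
#'
#' Describes one sweep: a topology, an NFL regime, the grid of background
#' parameter levels (`beta1`, `beta2`, `beta5` from 1 to 10 and `lam` from
#' 0.1 to 1 at full scale), the encounter schedule and the ensemble size.
#'
#' @param topology `"IMD"` or `"TOLL"`.
#' @param regime a label from [regime_table()] or a
#'   `list(label =, beta3 =, beta4 =)` for custom NFL strengths.
#' @param beta1_levels,beta2_levels,beta5_levels,lam_levels background grids.
#' @param k0 bacterial proliferation rate.
#' @param Zn,Zs binding energies (1 except in the Zs sensitivity analysis).
#' @param n_reps replicates per grid point (full scale: 10,000).
#' @param T lifetime in steps (full scale: 1,000).
#' @param period encounter period (full scale: 200).
#' @param inoculum bacteria per encounter.
#' @param base_seed root seed; each grid point derives its own stream.
#' @param amp_form see [model_params()].
#' @return An object of class `sweep_spec`.
#' @export
sweep_spec <- function(topology = c("IMD", "TOLL"),
                       regime = "both_knocked_down",
                       beta1_levels = 1:10, beta2_levels = 1:10,
                       beta5_levels = 1:10,
                       lam_levels = seq(0.1, 1, by = 0.1),
                       k0 = 0.1, Zn = 1, Zs = 1,
                       n_reps = 10000, T = 1000, period = 200, inoculum = 1,
                       base_seed = 1L, amp_form = "competitive") {
  topology <- match.arg(topology)
  lv <- list(beta1_levels, beta2_levels, beta5_levels, lam_levels)
  if (any(vapply(lv, length, 1L) == 0)) {
    stop("invalid config: empty grid level list", call. = FALSE)
  }
  structure(list(topology = topology, regime = as_regime(regime),
                 beta1_levels = beta1_levels, beta2_levels = beta2_levels,
                 beta5_levels = beta5_levels, lam_levels = lam_levels,
                 k0 = k0, Zn = Zn, Zs = Zs,
                 n_reps = n_reps, T = T, period = period, inoculum = inoculum,
                 base_seed = base_seed, amp_form = amp_form),
            class = "sweep_spec")
}

#' Background-parameter grid of a sweep
#'
#' Cartesian product of the four background-parameter level lists in a fixed,
#' stable order (`beta1` varying fastest, then `beta2`, `beta5`, `lam`). The
#' full-scale grid has 10^4 = 10,000 parameter sets per regime.
#'
#' @param spec a [sweep_spec()].
#' @return Data frame with columns `grid_index`, `beta1`, `beta2`, `beta5`,
#'   `lam`.
#' @export
background_grid <- function(spec) {
  stopifnot(inherits(spec, "sweep_spec"))
  g <- expand.grid(beta1 = spec$beta1_levels, beta2 = spec$beta2_levels,
                   beta5 = spec$beta5_levels, lam = spec$lam_levels,
                   KEEP.OUT.ATTRS = FALSE)
  cbind(grid_index = seq_len(nrow(g)), g)
}

#' Run a noise sweep over the background grid
#'
#' For every grid point, builds the circuit parameters (regime fixing `beta3`
#' and `beta4`), runs a replicate ensemble with a grid-point-specific seed
#' derived from `(base_seed, grid_index)`, and records the noise score and
#' average AMP expression. Because seeds are per-point, running a subset via
#' `indices` (chunked or resumed execution) reproduces exactly the same rows
#' as a full serial run.
#'
#' @param spec a [sweep_spec()].
#' @param indices optional subset of grid indices to run.
#' @param progress print a progress message every `progress` grid points
#'   (0 = silent).
#' @return Data frame: one row per grid point with the background parameters,
#'   regime columns, `noise`, `avg_amp` and bookkeeping columns.
#' @export
run_noise_sweep <- function(spec, indices = NULL, progress = 0) {
  stopifnot(inherits(spec, "sweep_spec"))
  grid <- background_grid(spec)
  if (!is.null(indices)) grid <- grid[grid$grid_index %in% indices, , drop = FALSE]
  schedule <- encounter_schedule(spec$period, spec$T, spec$inoculum)
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    gp <- grid[i, ]
    params <- model_params(spec$topology, k0 = spec$k0,
                           beta1 = gp$beta1, beta2 = gp$beta2,
                           beta3 = spec$regime$beta3,
                           beta4 = spec$regime$beta4,
                           beta5 = gp$beta5, lam = gp$lam,
                           Zn = spec$Zn, Zs = spec$Zs,
                           amp_form = spec$amp_form)
    seed_i <- derive_seed(spec$base_seed, gp$grid_index)
    ens <- run_ensemble(params, schedule, n_reps = spec$n_reps,
                        base_seed = seed_i, keep_bacteria = FALSE)
    rows[[i]] <- data.frame(
      grid_index = gp$grid_index, topology = spec$topology,
      regime = spec$regime$label,
      beta1 = gp$beta1, beta2 = gp$beta2, beta5 = gp$beta5, lam = gp$lam,
      beta3 = spec$regime$beta3, beta4 = spec$regime$beta4,
      Zn = spec$Zn, Zs = spec$Zs, k0 = spec$k0,
      noise = noise_score(ens$amp), avg_amp = mean_amp(ens$amp),
      n_reps = spec$n_reps, T = spec$T, seed = seed_i,
      stringsAsFactors = FALSE)
    if (progress > 0 && i %% progress == 0) {
      message("sweep ", spec$regime$label, ": ", i, "/", nrow(grid),
              " grid points done")
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Scaled-down sweep fixture
#'
#' A small sweep for desk-scale runs and tests: `k` evenly spaced levels per
#' background parameter (always including the endpoints of the full ranges,
#' 1..10 for the rates and 0.1..1 for `lam`), with a reduced ensemble size
#' and lifetime. Grid size is `k^4`.
#'
#' @param k levels per background parameter (`>= 2`).
#' @param n_reps replicates per grid point.
#' @param T lifetime in steps.
#' @param topology,regime,k0,Zn,Zs,base_seed,... passed to [sweep_spec()].
#' @return A [sweep_spec()].
#' @export
fixture_grid <- function(k = 3, n_reps = 200, T = 500,
                         topology = "IMD", regime = "both_knocked_down",
                         k0 = 0.1, Zn = 1, Zs = 1, base_seed = 20240222L,
                         ...) {
  if (k < 2) stop("invalid config: k must be >= 2", call. = FALSE)
  sweep_spec(topology = topology, regime = regime,
             beta1_levels = seq(1, 10, length.out = k),
             beta2_levels = seq(1, 10, length.out = k),
             beta5_levels = seq(1, 10, length.out = k),
             lam_levels = seq(0.1, 1, length.out = k),
             k0 = k0, Zn = Zn, Zs = Zs,
             n_reps = n_reps, T = T, base_seed = base_seed, ...)
}
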