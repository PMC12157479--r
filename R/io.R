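#' Write circuit parameters to a plain-text config file
#'
#' Flat key-value YAML section; round-trips through [read_params()].
#'
#' @param params a [model_params()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "circuit_params"))
  yaml::write_yaml(unclass(params), path)
  invisible(path)
}

#' Read circuit parameters from a plain-text config file
#'
#' @param path a file written by [write_params()] (or hand-edited with the
#'   same keys).
#' @return A validated [model_params()] object.
#' @export
read_params <- function(path) {
  kv <- yaml::read_yaml(path)
  do.call(model_params, kv)
}

meta_sidecar <- function(path, meta) {
  side <- paste0(path, ".meta.json")
  jsonlite::write_json(meta, side, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(side)
}

schedule_meta <- function(schedule) {
  list(period = schedule$period, T = schedule$T,
       inoculum = schedule$inoculum, times = schedule$times)
}

#' Write a trajectory as long-format CSV
#'
#' One row per (t, species) pair, species in the canonical order; parameters,
#' seed, topology and schedule go into a JSON sidecar at
#' `<path>.meta.json`. Output bytes are a pure function of the trajectory,
#' so identical seeded runs give byte-identical files.
#'
#' @param traj a [simulate_trajectory()] or [solve_deterministic()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  long <- data.frame(
    t = rep(traj$t, times = 6),
    species = rep(species_order(), each = nrow(traj)),
    count = unlist(traj[species_order()], use.names = FALSE))
  write.csv(long, path, row.names = FALSE, quote = FALSE)
  params <- attr(traj, "params")
  meta_sidecar(path, list(
    engine = attr(traj, "engine"), seed = attr(traj, "seed"),
    params = if (is.null(params)) NULL else unclass(params),
    schedule = schedule_meta(attr(traj, "schedule"))))
  invisible(path)
}

#' Write an ensemble as long-format CSV
#'
#' One row per (replicate, t, species) with species `A` (and `B` when the
#' bacteria matrix was kept); metadata in a JSON sidecar.
#'
#' @param ensemble a [run_ensemble()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_ensemble_csv <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "amp_ensemble"))
  nt <- ensemble$T + 1
  nr <- ensemble$n_reps
  block <- function(m, sp) data.frame(
    replicate = rep(seq_len(nr), times = nt),
    t = rep(0:ensemble$T, each = nr),
    species = sp,
    count = as.vector(m))
  long <- block(ensemble$amp, "A")
  if (!is.null(ensemble$bacteria)) {
    long <- rbind(long, block(ensemble$bacteria, "B"))
  }
  write.csv(long, path, row.names = FALSE, quote = FALSE)
  meta_sidecar(path, list(
    engine = "stochastic", base_seed = ensemble$base_seed,
    n_reps = ensemble$n_reps, T = ensemble$T,
    params = unclass(ensemble$params),
    schedule = schedule_meta(ensemble$schedule)))
  invisible(path)
}
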