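#' Coefficient of variation of AMP counts at one time point
#'
#' CV across the replicate ensemble at a single time point, using the
#' population standard deviation. When the replicate column is identically
#' zero (mean and standard deviation both zero) the CV is defined as 0.
#'
#' @param values nonnegative replicate AMP counts at one time point
#'   (length `>= 2`).
#' @return `sd / mean`, or 0 when both vanish.
#' @export
cv_at_time <- function(values) {
  if (length(values) == 0) stop("invalid input: empty vector", call. = FALSE)
  if (length(values) < 2) {
    stop("invalid input: need >= 2 replicates", call. = FALSE)
  }
  mu <- mean(values)
  if (mu == 0) return(0)
  sigma <- sqrt(mean((values - mu)^2)) # population sd
  sigma / mu
}

#' Time-averaged AMP expression noise
#'
#' The circuit's noise score: the arithmetic mean, over all recorded time
#' points, of the per-time-point coefficient of variation across replicates.
#'
#' @param amp_matrix replicate x time matrix of AMP counts (`>= 2` rows).
#' @return Nonnegative noise score.
#' @export
noise_score <- function(amp_matrix) {
  amp_matrix <- as.matrix(amp_matrix)
  if (nrow(amp_matrix) < 2) {
    stop("invalid input: need >= 2 replicates", call. = FALSE)
  }
  mu <- colMeans(amp_matrix)
  sigma <- sqrt(pmax(colMeans(amp_matrix^2) - mu^2, 0))
  cv <- ifelse(mu > 0, sigma / mu, 0)
  mean(cv)
}

#' Time-averaged mean AMP expression
#'
#' Mean over time of the per-time replicate means, i.e. the grand mean of the
#' replicate x time matrix.
#'
#' @inheritParams noise_score
#' @return Nonnegative average AMP level.
#' @export
mean_amp <- function(amp_matrix) {
  amp_matrix <- as.matrix(amp_matrix)
  if (nrow(amp_matrix) < 2) {
    stop("invalid input: need >= 2 replicates", call. = FALSE)
  }
  mean(amp_matrix)
}

#' Summarize an ensemble into a one-row noise table
#'
#' @param ensemble an [run_ensemble()] result.
#' @param label regime label carried into the output.
#' @return One-row data frame with columns `label`, `topology`, `noise`,
#'   `avg_amp`, `n_reps`, `T`, `seed`.
#' @export
summarize_ensemble <- function(ensemble, label = NA_character_) {
  stopifnot(inherits(ensemble, "amp_ensemble"))
  data.frame(label = label,
             topology = ensemble$params$topology,
             noise = noise_score(ensemble$amp),
             avg_amp = mean_amp(ensemble$amp),
             n_reps = ensemble$n_reps,
             T = ensemble$T,
             seed = ensemble$base_seed,
             stringsAsFactors = FALSE)
}

#' Average-matched noise comparison between two regimes
#'
#' Noise (a coefficient of variation) is confounded with the mean, so two
#' regimes are compared only between background parameter sets whose average
#' AMP expression is (almost) identical: all cross pairs with
#' `|avg_amp_b - avg_amp_a| <= tol` are kept (`match = "all"`, the default) or
#' reduced to greedy one-to-one nearest matches (`match = "nearest"`).
#' `table_a` is the reference regime (typically both NFLs knocked down), so
#' `delta_noise = noise_b - noise_a` is negative when the regime in `table_b`
#' suppresses noise.
#'
#' @param table_a,table_b data frames with columns `noise` and `avg_amp`
#'   (e.g. from [run_noise_sweep()]); `table_a` is the reference.
#' @param tol average-AMP matching tolerance (`> 0`). The full-scale study
#'   convention is 0.001; sparse desk-scale grids use a looser 0.05.
#' @param match `"all"` cross pairs or `"nearest"` one-to-one matching.
#' @return Data frame of matched pairs with columns `index_a`, `index_b`,
#'   `avg_a`, `avg_b`, `delta_avg`, `noise_a`, `noise_b`, `delta_noise`,
#'   `tanh_delta_noise`. May have zero rows.
#' @export
delta_noise_matched <- function(table_a, table_b, tol = 0.001,
                                match = c("all", "nearest")) {
  match <- match.arg(match)
  if (!is.numeric(tol) || tol <= 0) stop("tol must be > 0", call. = FALSE)
  ia <- rep(seq_len(nrow(table_a)), times = nrow(table_b))
  ib <- rep(seq_len(nrow(table_b)), each = nrow(table_a))
  d_avg <- table_b$avg_amp[ib] - table_a$avg_amp[ia]
  keep <- abs(d_avg) <= tol
  pairs <- data.frame(index_a = ia[keep], index_b = ib[keep],
                      avg_a = table_a$avg_amp[ia[keep]],
                      avg_b = table_b$avg_amp[ib[keep]],
                      delta_avg = d_avg[keep],
                      noise_a = table_a$noise[ia[keep]],
                      noise_b = table_b$noise[ib[keep]])
  if (match == "nearest" && nrow(pairs) > 0) {
    ord <- order(abs(pairs$delta_avg), pairs$index_a, pairs$index_b)
    used_a <- logical(nrow(table_a))
    used_b <- logical(nrow(table_b))
    take <- logical(nrow(pairs))
    for (k in ord) {
      a <- pairs$index_a[k]; b <- pairs$index_b[k]
      if (!used_a[a] && !used_b[b]) {
        take[k] <- TRUE
        used_a[a] <- TRUE
        used_b[b] <- TRUE
      }
    }
    pairs <- pairs[take, , drop = FALSE]
  }
  pairs$delta_noise <- pairs$noise_b - pairs$noise_a
  pairs$tanh_delta_noise <- tanh_normalize(pairs$delta_noise)
  rownames(pairs) <- NULL
  pairs
}

#' Hyperbolic-tangent normalization
#'
#' Maps a noise difference onto (-1, 1) for display, preserving sign and
#' order (strictly increasing and odd).
#'
#' @param x finite numeric.
#' @return `tanh(x)`.
#' @export
tanh_normalize <- function(x) tanh(x)

#' Strongest noise suppression among matched pairs
#'
#' The minimum `delta_noise` over a matched-pair table: the empirical limit
#' of noise suppression for a regime. Used to probe how suppression depends
#' on downstream-NFL strength (e.g. `beta4` in 1, 10, 20, and `beta4 = 10`
#' with 10x stronger promoter binding, `Zs = 0.1`).
#'
#' @param pairs nonempty data frame from [delta_noise_matched()].
#' @return Scalar minimum of `pairs$delta_noise`.
#' @export
min_delta_noise <- function(pairs) {
  if (is.null(pairs) || nrow(pairs) == 0) {
    stop("invalid input: no matched pairs", call. = FALSE)
  }
  min(pairs$delta_noise)
}

#' Noise-versus-positive-feedback slope analysis
#'
#' Within one regime, regresses the noise score on the swept positive
#' parameter (by default `beta1`, the receptor production rate that
#' constitutes the positive feedback loop) while holding the other background
#' parameters fixed, and returns the ordinary-least-squares slope for every
#' fixed combination. A negative slope means noise falls as the positive
#' feedback strengthens. Setting `sweep_param = "beta2"` gives the
#' positive-regulator (NF-kB activation) variant of the same analysis.
#'
#' @param summaries data frame with columns `beta1`, `beta2`, `beta5`, `lam`
#'   and `noise`, one row per grid point (e.g. from [run_noise_sweep()]).
#' @param sweep_param which background parameter was swept.
#' @return Data frame with one row per fixed-parameter combination: the fixed
#'   parameter columns, `slope`, and `n_levels`.
#' @export
pfl_slope_analysis <- function(summaries, sweep_param = "beta1") {
  backg <- c("beta1", "beta2", "beta5", "lam")
  stopifnot(sweep_param %in% backg, all(c(backg, "noise") %in% names(summaries)))
  fixed <- setdiff(backg, sweep_param)
  key <- interaction(summaries[fixed], drop = TRUE, lex.order = TRUE)
  groups <- split(seq_len(nrow(summaries)), key)
  rows <- lapply(groups, function(idx) {
    x <- summaries[[sweep_param]][idx]
    y <- summaries$noise[idx]
    if (length(unique(x)) < 2) {
      stop("invalid input: need >= 2 swept levels per fixed combination",
           call. = FALSE)
    }
    slope <- stats::cov(x, y) / stats::var(x) # OLS closed form
    cbind(summaries[idx[1], fixed, drop = FALSE],
          data.frame(slope = slope, n_levels = length(x)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
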