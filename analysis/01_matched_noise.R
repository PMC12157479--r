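#!/usr/bin/env Rscript

# How do upstream (Pirk) and downstream (Repressosome/Cactus) negative
# feedback loops change AMP expression noise, compared at matched average
# expression against a circuit with both NFLs knocked down?
#
# Desk-scale run: k = 3 levels per background parameter (81 sets per regime),
# 200 replicates per set, lifetime T = 500, k0 = 0.1, match tolerance 0.05.
# The full-scale study design is 10 levels (10,000 sets), 10,000 replicates,
# T = 1000 and tolerance 0.001.

suppressMessages(library(ampnoise))
dir.create("results", showWarnings = FALSE)

base_seed <- 20240222L
regimes <- c("both_knocked_down", "upstream_active", "downstream_active",
             "both_active")

for (topo in c("IMD", "TOLL")) {
  cat("==", topo, "topology ==\n")
  sweeps <- lapply(regimes, function(reg) {
    run_noise_sweep(fixture_grid(k = 3, n_reps = 200, T = 500,
                                 topology = topo, regime = reg,
                                 k0 = 0.1, base_seed = base_seed))
  })
  names(sweeps) <- regimes
  all_sum <- do.call(rbind, sweeps)
  write.csv(all_sum,
            sprintf("results/noise_summaries_%s.csv", tolower(topo)),
            row.names = FALSE)

  none <- sweeps$both_knocked_down
  for (reg in regimes[-1]) {
    pairs <- delta_noise_matched(none, sweeps[[reg]], tol = 0.05)
    write.csv(pairs,
              sprintf("results/matched_pairs_%s_%s.csv", tolower(topo), reg),
              row.names = FALSE)
    if (nrow(pairs) == 0) {
      cat(sprintf("  %-18s: no matched pairs\n", reg))
      next
    }
    lowavg <- pairs[pairs$avg_a < 2, , drop = FALSE]
    cat(sprintf(
      "  %-18s: %3d pairs, median dNoise %+.3f (%2.0f%% > 0);",
      reg, nrow(pairs), median(pairs$delta_noise),
      100 * mean(pairs$delta_noise > 0)))
    if (nrow(lowavg) > 0) {
      cat(sprintf(" low-expression pairs (avg < 2): median %+.3f (%2.0f%% > 0)",
                  median(lowavg$delta_noise),
                  100 * mean(lowavg$delta_noise > 0)))
    }
    cat("\n")
  }
}

cat("\nReading guide: negative dNoise = the regime suppresses noise relative\n",
    "to the no-NFL circuit at the same average AMP expression. At this\n",
    "replication level the average-AMP standard error exceeds the match\n",
    "tolerance, so matches are sparse and noisy; upstream-NFL noise\n",
    "amplification emerges with denser grids and tighter matching, where\n",
    "matched pairs concentrate in the low-expression region.\n")
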