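#!/usr/bin/env Rscript

# How strong can downstream-NFL noise suppression get? Probes the limit by
# computing min[dNoise] against the no-NFL reference for weak (beta4 = 1),
# strong (beta4 = 10) and very strong (beta4 = 20) downstream-NFL expression,
# and for strong expression with 10x stronger promoter binding
# (beta4 = 10, Zs = 0.1). IMD topology, desk scale.

suppressMessages(library(ampnoise))
dir.create("results", showWarnings = FALSE)

base_seed <- 20240222L
fixture <- function(reg, Zs = 1) {
  fixture_grid(k = 3, n_reps = 200, T = 500, topology = "IMD",
               regime = reg, k0 = 0.1, Zs = Zs, base_seed = base_seed)
}

none <- run_noise_sweep(fixture("both_knocked_down"))

cases <- list(list(beta4 = 1, Zs = 1), list(beta4 = 10, Zs = 1),
              list(beta4 = 20, Zs = 1), list(beta4 = 10, Zs = 0.1))
rows <- lapply(cases, function(cs) {
  reg <- list(label = sprintf("downstream_b4_%g_Zs_%g", cs$beta4, cs$Zs),
              beta3 = 0, beta4 = cs$beta4)
  tab <- run_noise_sweep(fixture(reg, Zs = cs$Zs))
  pairs <- delta_noise_matched(none, tab, tol = 0.05)
  data.frame(beta4 = cs$beta4, Zs = cs$Zs, n_pairs = nrow(pairs),
             min_delta_noise = if (nrow(pairs)) min_delta_noise(pairs) else NA,
             median_delta_noise = if (nrow(pairs))
               median(pairs$delta_noise) else NA)
})
limit <- do.call(rbind, rows)
write.csv(limit, "results/suppression_limit.csv", row.names = FALSE)
print(limit)
i <- which.min(limit$min_delta_noise[limit$Zs == 1])
cat(sprintf("\nStrongest suppression among Zs = 1 cases at beta4 = %g\n",
            limit$beta4[limit$Zs == 1][i]))
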