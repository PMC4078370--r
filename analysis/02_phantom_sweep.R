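#!/usr/bin/env Rscript
# Phantom simulation: how the measured overlap fraction of the residual
# uptake volume inside the baseline 40% subvolume tracks the generator's
# containment parameter, under scanner blur, noise, tumour shrinkage and
# caudal drift. Writes results/phantom_sweep.csv.

suppressMessages(library(petbtv))
dir.create("results", showWarnings = FALSE)

seed0 <- 20260924L %% 100000L
rhos <- seq(0.2, 1.0, by = 0.2)
n_rep <- 5

rowsl <- list()
for (i in seq_along(rhos)) {
  for (s in seq_len(n_rep)) {
    run <- run_phantom_patient(phantom_spec(containment_fraction = rhos[i],
                                            seed = seed0 + i * 100 + s))
    of <- run$result$overlap_pct
    rowsl[[length(rowsl) + 1]] <- data.frame(
      containment = rhos[i], replicate = s,
      achieved = run$pair$achieved_containment,
      of40_60 = of["Pre40", "Post60"], of40_90 = of["Pre40", "Post90"],
      of50_60 = of["Pre50", "Post60"],
      suvmax_pre = run$result$suvmax_pre,
      suvmax_post = run$result$suvmax_post)
  }
}
sweep_df <- do.call(rbind, rowsl)
write.csv(sweep_df, "results/phantom_sweep.csv", row.names = FALSE)

agg <- aggregate(cbind(achieved, of40_60, of40_90) ~ containment, sweep_df, mean)
cat("Mean over", n_rep, "replicates per containment level:\n")
print(round(agg, 2), row.names = FALSE)
cat(sprintf("\nOF(Pre40|Post60) monotone in containment: %s\n",
            all(diff(agg$of40_60) > 0)))
cat(sprintf("Max |achieved - requested| containment: %.4f\n",
            max(abs(sweep_df$achieved - sweep_df$containment))))
cat(sprintf("Partial-volume effect: post peak %.1f measured as %.2f (mean)\n",
            3.6, mean(sweep_df$suvmax_post)))
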