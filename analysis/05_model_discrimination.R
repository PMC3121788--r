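#!/usr/bin/env Rscript
# Discriminating the two loop-rearrangement models on synthetic ground
# truth: the end-to-end zone-recovery experiment, then MAR extension
# (mode B) versus MAR substitution (mode A) on the same ensemble.

library(nhoskit)

dir.create("results", showWarnings = FALSE)
report <- run_recovery_experiment(default_run_config(seed = 1))
print(report)
write_recovery_report(report, "results/recovery")
cat("Recovery tables written under results/recovery/\n\n")

m0 <- build_nucleoid_ensemble(1000, seed = 1)
e0 <- embedded_fraction(m0)

mB <- evolve_nhos(m0, "B_extension", list(extension = list(kind = "fraction", frac = 0.2)))
cat(sprintf("Mode B (MAR extension, 20%% of free DNA absorbed):\n"))
cat(sprintf("  total DNA: %.0f -> %.0f bp (conserved: %s)\n",
            sum(m0$loops$total_bp), sum(mB$loops$total_bp),
            sum(m0$loops$total_bp) == sum(mB$loops$total_bp)))
cat(sprintf("  embedded fraction: %.4f -> %.4f (identity e0 + 0.2(1-e0) = %.4f)\n",
            e0, embedded_fraction(mB), e0 + 0.2 * (1 - e0)))
cat(sprintf("  surviving loops: %d -> %d; mean size drift %+.3f%%\n\n",
            sum(m0$loops$free_bp > 0), sum(mB$loops$free_bp > 0),
            100 * (mean(mB$loops$total_bp[mB$loops$free_bp > 0]) /
                     mean(m0$loops$total_bp[m0$loops$free_bp > 0]) - 1)))

mA <- evolve_nhos(m0, "A_substitution",
                  list(p_sub = 1, size_mean_bp = 42000, size_cv = 0.1), seed = 2)
sz <- mA$loops$total_bp[startsWith(mA$loops$loop_id, "subst_")]
ks <- suppressWarnings(ks.test(sz, "pnorm", 42000, 4200))
cat(sprintf("Mode A (MAR substitution, p_sub = 1):\n"))
cat(sprintf("  total DNA conserved: %s; %d loops redrawn\n",
            sum(mA$loops$total_bp) == sum(m0$loops$total_bp), length(sz)))
cat(sprintf("  KS distance of redrawn sizes to target N(42000, 4200): D = %.4f\n",
            unname(ks$statistic)))
cat("\nMode B reproduces the neuronal signature: unchanged mean loop size\n")
cat("with a strictly larger embedded fraction; mode A changes the loop-size\n")
cat("distribution itself, the hepatocyte-like signature.\n")
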