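#!/usr/bin/env Rscript
# Pooled association of the five IL2RA SNPs with type 1 diabetes, from the
# packaged study table. Writes the per-SNP summary (the shape of the
# published pooled-measures table), per-study weights, and forest-plot data
# under results/pool/.

library(il2rameta)
source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(FALSE), value = TRUE)[1])), "00_common.R"))

results <- run_step(run_pool(out_dir = "results/pool"))

cat("Pooled minor-allelic associations with T1D (packaged study table):\n\n")
for (snp in names(results)) {
  res <- results[[snp]]
  cat(sprintf("  %-11s k=%d  cases=%6d controls=%6d  I2=%5.1f%%  p_Q=%.3f  %s OR %s  p %s\n",
              snp, res$k, res$n_cases, res$n_controls, res$i_squared, res$p_q,
              res$model, fmt_or(res), format_p(res$p_value)))
  alt <- attr(res, "alternate")
  cat(sprintf("  %-11s   (alternate %s model: OR %s)\n", "", alt$model, fmt_or(alt)))
}
cat("\nOnly rs41295061 triggers the heterogeneity rule (I2 > 50%), so it is\n")
cat("pooled by the DerSimonian-Laird random-effects model; the other four\n")
cat("SNPs pool by the fixed-effect model. The random-effects alternates are\n")
cat("close throughout, so the conclusions do not hinge on the model.\n")
cat("Tables written under results/pool/\n")
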