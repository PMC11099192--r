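#!/usr/bin/env Rscript
# Simulate a deep-enzymology reaction series: four methylation reactions on a
# randomized-flank CpG hairpin substrate, driven by a known two-decade NNCGNN
# rate table, emitted as bisulfite-converted hairpin FASTQ plus a truth table.
# Output: results/reads/reaction_<j>.fastq, results/reads/truth_<j>.tsv,
#         results/reads/true_rates.tsv

suppressPackageStartupMessages(library(flankpref))

dir.create("results/reads", showWarnings = FALSE, recursive = TRUE)
set.seed(20260923)

layout <- substrate_layout()
ctx <- all_contexts("CG")

## DNMT3C-like multiplicative preference: strong C(-2) and C(-1), moderate
## +2/+3 effects, times modest context-specific noise; spans ~100-fold
w <- list(
  "-2" = c(A = 0.8, C = 2.2, G = 0.7, T = 1.1),
  "-1" = c(A = 1.5, C = 1.8, G = 0.6, T = 0.4),
  "+2" = c(A = 1.2, C = 0.8, G = 1.6, T = 0.6),
  "+3" = c(A = 1.1, C = 1.0, G = 1.2, T = 0.7))
k_true <- exp(rnorm(256, 0, 0.15)) *
  w[["-2"]][substr(ctx, 1, 1)] * w[["-1"]][substr(ctx, 2, 2)] *
  w[["+2"]][substr(ctx, 5, 5)] * w[["+3"]][substr(ctx, 6, 6)]
k_true <- setNames(unname(k_true) / exp(mean(log(unname(k_true)))), ctx)
tau_true <- c(0.08, 0.35, 1.5, 6.5)   # virtual times covering the curve
kin <- true_kinetics(k_true, tau_true)

n_reads <- 20000L
for (j in seq_along(tau_true)) {
  sim <- simulate_reaction_reads(layout, kin, j, n_reads,
                                 noise_model(seed = 1000 + j))
  write_fastq(sim$reads, sprintf("results/reads/reaction_%d.fastq", j))
  write.table(sim$truth, sprintf("results/reads/truth_%d.tsv", j),
              sep = "\t", quote = FALSE, row.names = FALSE)
  frac <- mean(sim$truth$meth_state == "methylated")
  message(sprintf("reaction %d (tau %.2f): %d reads, %.1f%% methylated",
                  j, tau_true[j], n_reads, 100 * frac))
}
write.table(data.frame(context = names(k_true), k = unname(k_true)),
            "results/reads/true_rates.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message("true rate table spans ",
        sprintf("%.0f-fold", max(k_true) / min(k_true)),
        "; wrote results/reads/")
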