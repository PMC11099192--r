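#!/usr/bin/env Rscript
# Fit the 256 NNCGNN rate constants across the four reactions on a shared
# virtual time axis, compare with the generator's truth, and summarise the
# base composition of the extreme deciles. Requires 01 + 02 output.
# Output: results/rates/fitted_rates.tsv, tau.tsv, fit_report.json,
#         extreme_composition.tsv

suppressPackageStartupMessages(library(flankpref))

dir.create("results/rates", showWarnings = FALSE, recursive = TRUE)

levels <- lapply(1:4, function(j) {
  calls <- read.delim(sprintf("results/calls/reaction_%d_calls.tsv", j),
                      stringsAsFactors = FALSE)
  attr(calls, "central_offset") <- 11L
  context_levels(calls)
})

fit <- fit_virtual_time_rates(levels, min_count = 10, n_restarts = 3,
                              seed = 20260924)
print(fit)

k_true <- with(read.delim("results/reads/true_rates.tsv"), setNames(k, context))
kf <- fit$k[is.finite(fit$k) & fit$k > 0]
rho <- cor(k_true[names(kf)], kf, method = "spearman")
message(sprintf("Spearman(true, fitted) = %.4f over %d contexts", rho, length(kf)))

ord <- order(-fit$k)
write.table(data.frame(context = names(fit$k)[ord], k = unname(fit$k)[ord],
                       rank = seq_along(fit$k)),
            "results/rates/fitted_rates.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(data.frame(reaction = names(fit$tau), tau = unname(fit$tau)),
            "results/rates/tau.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
jsonlite::write_json(list(residual_sse = fit$residual_sse,
                          converged = fit$converged,
                          n_restarts_agreeing = fit$n_restarts_agreeing,
                          plateau = fit$plateau,
                          spearman_vs_truth = rho,
                          n_excluded = length(fit$excluded_contexts)),
                     "results/rates/fit_report.json", auto_unbox = TRUE)

## base composition of the 10% most / least preferred contexts
ex <- extreme_site_composition(kf, fraction = 0.10)
comp <- rbind(data.frame(set = "top", base = rownames(ex$top),
                         as.data.frame(ex$top, check.names = FALSE)),
              data.frame(set = "bottom", base = rownames(ex$bottom),
                         as.data.frame(ex$bottom, check.names = FALSE)))
write.table(comp, "results/rates/extreme_composition.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("top-decile contexts: ", paste(head(ex$top_contexts, 5), collapse = " "),
        " ...")
message("wrote results/rates/")
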