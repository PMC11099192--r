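#!/usr/bin/env Rscript
# Relate the fitted biochemical preferences to a (simulated) genomic
# methylome: context means and o/e, NNCG aggregation, the 22-CpG
# sliding-window local correlation, and the preference-randomization Z-test.
# Requires 03_fit_rates.R output.
# Output: results/genome/context_means.tsv, nncg_oe.tsv, window_r.tsv,
#         z_report.json

suppressPackageStartupMessages(library(flankpref))

dir.create("results/genome", showWarnings = FALSE, recursive = TRUE)
set.seed(20260925)

fitted <- read.delim("results/rates/fitted_rates.tsv", stringsAsFactors = FALSE)
pref <- setNames(fitted$k, fitted$context)
pref <- pref[is.finite(pref) & pref > 0]

## methylome driven by the fitted preferences; mean level matches the low
## global methylation of a DNMT3C-only methylome
sim <- simulate_methylome(1e6, pref, mean_level = 0.015, coverage_mean = 10,
                          seed = 20260926)
sites <- load_methylome(sim$calls, sim$genome, min_coverage = 5)
lg <- attr(sites, "log")
message(sprintf("retained %d of %d CpG records (coverage >= 5)",
                lg$n_out, lg$n_in))

cm <- mean_by_context(sites)
message(sprintf("mean methylation level: %.2f%%", 100 * cm$overall_mean))
message(sprintf("context means vs biochemical preference: r = %.3f",
                correlate_profiles(cm$context_means, pref)))
write.table(data.frame(context = names(cm$context_means),
                       mean_level = unname(cm$context_means),
                       n_sites = unname(cm$n_sites),
                       oe = unname(genomic_oe(cm))),
            "results/genome/context_means.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

nncg <- sort(genomic_oe(cm, granularity = "NNCG"), decreasing = TRUE)
message("top NN dinucleotides at the NNCG positions: ",
        paste(substr(names(head(nncg, 3)), 1, 2), collapse = " "))
write.table(data.frame(nncg = names(nncg), oe = unname(nncg)),
            "results/genome/nncg_oe.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

wc <- local_correlation(sites, pref, window = 22)
message(sprintf("local correlation: %d windows, %d positive / %d negative r",
                wc$n_windows, wc$n_positive, wc$n_negative))
write.table(data.frame(start_pos = wc$start_pos, r = wc$r),
            "results/genome/window_r.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

z <- randomization_z(sites, pref, n_randomizations = 20, seed = 20260927)
message(sprintf("randomization Z = %.1f (one-sided p = %.2e)", z$Z, z$p))
jsonlite::write_json(list(Z = z$Z, p = z$p, observed_mean_r = z$observed,
                          null_mean = z$null_mean, null_sd = z$null_sd,
                          n_windows = wc$n_windows,
                          n_positive = wc$n_positive,
                          n_negative = wc$n_negative),
                     "results/genome/z_report.json", auto_unbox = TRUE,
                     digits = NA)
message("wrote results/genome/")
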