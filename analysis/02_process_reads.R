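#!/usr/bin/env Rscript
# Process the simulated hairpin-bisulfite reads: trim/QC, deduplicate,
# reconstitute the original randomized sequences, call central-site
# methylation, and derive per-reaction -8..+8 o/e flanking profiles plus
# their merge. Requires 01_simulate_reads.R output.
# Output: results/calls/reaction_<j>_calls.tsv, results/profiles/*.tsv

suppressPackageStartupMessages(library(flankpref))

dir.create("results/calls", showWarnings = FALSE, recursive = TRUE)
dir.create("results/profiles", showWarnings = FALSE, recursive = TRUE)
layout <- substrate_layout()

profiles <- list()
for (j in 1:4) {
  reads <- read_fastq(sprintf("results/reads/reaction_%d.fastq", j))
  qc <- qc_filter(reads, target_length = 128, min_quality = 20)
  dd <- deduplicate(qc$reads)
  rec <- reconstitute_reads(dd, layout)
  write_calls(rec$calls, sprintf("results/calls/reaction_%d_calls.tsv", j),
              log = c(qc$log[c("n_short", "n_low_quality")], rec$log))
  message(sprintf("reaction %d: %d in, %d after dedup, %d calls (%d inconsistent)",
                  j, qc$log$n_in, nrow(dd), rec$log$n_out,
                  rec$log$n_inconsistent))
  prof <- oe_profile(base_frequencies(rec$calls))
  profiles[[j]] <- prof
  long <- data.frame(position = rep(prof$positions, each = 4),
                     base = rownames(prof$oe),
                     oe = as.vector(prof$oe))
  write.table(long, sprintf("results/profiles/reaction_%d_oe.tsv", j),
              sep = "\t", quote = FALSE, row.names = FALSE)
}

merged <- merge_profiles(profiles)
rr <- attr(merged, "replicate_correlations")
message(sprintf("replicate profile correlations: min r = %.3f",
                min(rr[upper.tri(rr)])))
long <- data.frame(position = rep(merged$positions, each = 4),
                   base = rownames(merged$oe), oe = as.vector(merged$oe))
write.table(long, "results/profiles/merged_oe.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(round(rr, 4), "results/profiles/replicate_correlations.tsv",
            sep = "\t", quote = FALSE)

## which base is most enriched at each position in the product pool?
top <- apply(merged$oe, 2, function(col) rownames(merged$oe)[which.max(col)])
message("most enriched base per position: ",
        paste(sprintf("%s:%s", colnames(merged$oe), top), collapse = " "))
message("wrote results/calls/ and results/profiles/")
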