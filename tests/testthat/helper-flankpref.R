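# shared fixtures: all built in code, deterministic seeds

default_layout <- substrate_layout()

# a fixed two-decade log-uniform NNCGNN rate table
make_rate_table <- function(seed = 42, lo = 0.1, hi = 10, central = "CG") {
  set.seed(seed)
  ctx <- all_contexts(central)
  setNames(exp(runif(length(ctx), log(lo), log(hi))), ctx)
}

# noise-free levels for a known (k, tau) under plateau 1
levels_from_truth <- function(k, tau, n_total = 1000L) {
  lapply(tau, function(t)
    data.frame(context = names(k), n_meth = NA_integer_, n_total = n_total,
               level = 1 - exp(-unname(k) * t), stringsAsFactors = FALSE))
}

# hand-built HairpinCall table: window of 22 with central C at offset 11
make_calls <- function(original_sequence, central_meth,
                       site_class = "CpG", ccwgg_flag = FALSE) {
  calls <- data.frame(read_id = sprintf("r%03d", seq_along(original_sequence)),
                      original_sequence = original_sequence,
                      central_meth = central_meth,
                      site_class = site_class,
                      ccwgg_flag = ccwgg_flag,
                      stringsAsFactors = FALSE)
  attr(calls, "central_offset") <- 11L
  calls
}

# random 22-mer windows with a fixed central dinucleotide
random_windows <- function(n, central = "CG", seed = 1) {
  set.seed(seed)
  left <- replicate(n, paste(sample(c("A", "C", "G", "T"), 10, TRUE), collapse = ""))
  right <- replicate(n, paste(sample(c("A", "C", "G", "T"), 10, TRUE), collapse = ""))
  paste0(left, central, right)
}

# run the full read pipeline for one simulated reaction
pipeline_calls <- function(layout, kinetics, reaction, n_reads, seed) {
  sim <- simulate_reaction_reads(layout, kinetics, reaction, n_reads,
                                 noise_model(seed = seed))
  qc <- qc_filter(sim$reads)
  rec <- reconstitute_reads(deduplicate(qc$reads), layout)
  list(calls = rec$calls, truth = sim$truth, log = rec$log)
}
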