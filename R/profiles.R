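profile_positions <- function(window = c(-8L, 8L)) {
  setdiff(seq(window[1], window[2]), c(0L, 1L))  # 0/+1 are the fixed CpN
}

count_bases_by_position <- function(seqs, positions, central_offset) {
  counts <- matrix(0, nrow = 4L, ncol = length(positions),
                   dimnames = list(BASES, as.character(positions)))
  for (j in seq_along(positions)) {
    p <- central_offset + positions[j]
    tab <- table(factor(substr(seqs, p, p), levels = BASES))
    counts[, j] <- as.numeric(tab)
  }
  counts
}

#' Per-position base frequencies of methylated and total read pools
#'
#' Counts bases at each flank position (default -8..+8, excluding the fixed
#' central dinucleotide at 0/+1) separately for the methylated product pool
#' and for all analysed reads.
#'
#' @param calls HairpinCall table from [reconstitute_reads()].
#' @param window integer length-2 position range (default `c(-8, 8)`).
#' @param central_offset 1-based offset of the central C within
#'   `original_sequence`; defaults to the attribute set by
#'   [reconstitute_reads()].
#' @return list with `counts_meth`, `counts_total` (4 x P count matrices),
#'   `f_meth`, `f_total` (column-normalised frequencies), `positions`,
#'   `n_methylated`, `n_total`.
#' @export
base_frequencies <- function(calls, window = c(-8L, 8L),
                             central_offset = attr(calls, "central_offset")) {
  if (is.null(central_offset)) stop("central_offset not supplied")
  positions <- profile_positions(window)
  meth <- calls$central_meth == "methylated"
  if (!any(meth)) stop("no product pool: zero methylated calls")
  counts_meth <- count_bases_by_position(calls$original_sequence[meth],
                                         positions, central_offset)
  counts_total <- count_bases_by_position(calls$original_sequence,
                                          positions, central_offset)
  list(counts_meth = counts_meth,
       counts_total = counts_total,
       f_meth = sweep(counts_meth, 2L, colSums(counts_meth), "/"),
       f_total = sweep(counts_total, 2L, colSums(counts_total), "/"),
       positions = positions,
       n_methylated = sum(meth),
       n_total = nrow(calls))
}

#' Observed/expected flanking base-enrichment profile
#'
#' o/e(b, p) = frequency of base `b` at position `p` among methylated product
#' reads divided by its frequency in the expectation pool. By default the
#' expectation is the total analysed pool (methylated + unmethylated), which
#' makes the profile robust to library composition bias; `expected =
#' "uniform"` substitutes the theoretical 0.25.
#'
#' @param freqs output of [base_frequencies()].
#' @param site_class site class label carried on the profile.
#' @param expected `"total_pool"` (default) or `"uniform"`.
#' @return an object of class `flank_profile`: list with `oe` (4 x P matrix),
#'   `positions`, count matrices and pool sizes. Entries where both pools are
#'   empty are `NA`.
#' @export
oe_profile <- function(freqs, site_class = "CpG",
                       expected = c("total_pool", "uniform")) {
  expected <- match.arg(expected)
  f_exp <- if (expected == "uniform") {
    matrix(0.25, nrow = 4L, ncol = ncol(freqs$f_meth),
           dimnames = dimnames(freqs$f_meth))
  } else freqs$f_total
  if (any(f_exp == 0 & freqs$f_meth > 0))
    stop("base observed in methylated pool but absent from expectation pool")
  oe <- freqs$f_meth / f_exp
  oe[f_exp == 0 & freqs$f_meth == 0] <- NA_real_
  structure(list(oe = oe, positions = freqs$positions,
                 counts_meth = freqs$counts_meth,
                 counts_total = freqs$counts_total,
                 n_methylated = freqs$n_methylated,
                 n_total = freqs$n_total,
                 site_class = site_class, expected = expected),
            class = "flank_profile")
}

#' @export
print.flank_profile <- function(x, ...) {
  cat(sprintf("flank_profile (%s): %d methylated / %d total reads, positions %s..%s\n",
              x$site_class, x$n_methylated, x$n_total,
              min(x$positions), max(x$positions)))
  print(round(x$oe, 3))
  invisible(x)
}

#' Merge replicate flanking profiles
#'
#' Pools the raw base counts of replicate profiles and recomputes o/e, which
#' weights replicates by read count (the default); `mode = "average"` instead
#' averages the per-replicate o/e values. Pairwise Pearson correlations of the
#' input profiles are reported alongside.
#'
#' @param profiles list of `flank_profile` objects sharing window and
#'   site class.
#' @param mode `"pool"` (count-weighted recomputation, default) or
#'   `"average"`.
#' @return a `flank_profile` with attribute `"replicate_correlations"`.
#' @export
merge_profiles <- function(profiles, mode = c("pool", "average")) {
  mode <- match.arg(mode)
  stopifnot(length(profiles) >= 1L)
  cls <- unique(vapply(profiles, `[[`, character(1), "site_class"))
  if (length(cls) != 1L) stop("cannot merge profiles of mixed site_class")
  pos <- profiles[[1]]$positions
  for (p in profiles) if (!identical(p$positions, pos))
    stop("cannot merge profiles with different windows")

  rr <- diag(1, length(profiles))
  if (length(profiles) > 1L)
    for (i in seq_along(profiles)) for (j in seq_along(profiles))
      if (i < j) rr[i, j] <- rr[j, i] <-
          correlate_profiles(profiles[[i]], profiles[[j]])

  if (mode == "pool") {
    cm <- Reduce(`+`, lapply(profiles, `[[`, "counts_meth"))
    ct <- Reduce(`+`, lapply(profiles, `[[`, "counts_total"))
    freqs <- list(counts_meth = cm, counts_total = ct,
                  f_meth = sweep(cm, 2L, colSums(cm), "/"),
                  f_total = sweep(ct, 2L, colSums(ct), "/"),
                  positions = pos,
                  n_methylated = sum(vapply(profiles, `[[`, numeric(1), "n_methylated")),
                  n_total = sum(vapply(profiles, `[[`, numeric(1), "n_total")))
    out <- oe_profile(freqs, site_class = cls,
                      expected = profiles[[1]]$expected)
  } else {
    oe <- Reduce(`+`, lapply(profiles, `[[`, "oe")) / length(profiles)
    out <- profiles[[1]]
    out$oe <- oe
  }
  attr(out, "replicate_correlations") <- rr
  out
}

#' Per-context methylation levels (NNCGNN / NNCXNN)
#'
#' For every observed 6-mer context (-2..-1 and +2..+3 around the central
#' site) counts methylated and total calls and their ratio. For CpA and CpT
#' site classes, calls inside a CCWGG motif are excluded first (dcm overlap).
#' Contexts never observed are absent from the table, not zero.
#'
#' @param calls HairpinCall table.
#' @param site_class which central-site class to analyse (default CpG).
#' @param central_offset see [base_frequencies()].
#' @return data.frame (context, n_meth, n_total, level), one row per observed
#'   context, in lexicographic context order.
#' @export
context_levels <- function(calls, site_class = "CpG",
                           central_offset = attr(calls, "central_offset")) {
  if (is.null(central_offset)) stop("central_offset not supplied")
  keep <- calls$site_class == site_class
  if (site_class %in% c("CpA", "CpT")) keep <- keep & !calls$ccwgg_flag
  x <- calls[keep, , drop = FALSE]
  ctx <- paste0(substr(x$original_sequence, central_offset - 2L, central_offset - 1L),
                substr(x$original_sequence, central_offset, central_offset + 1L),
                substr(x$original_sequence, central_offset + 2L, central_offset + 3L))
  meth <- x$central_meth == "methylated"
  n_total <- table(ctx)
  n_meth <- table(factor(ctx[meth], levels = names(n_total)))
  data.frame(context = names(n_total),
             n_meth = as.integer(n_meth),
             n_total = as.integer(n_total),
             level = as.integer(n_meth) / as.integer(n_total),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Base composition of extreme-decile contexts
#'
#' Takes the top and bottom `fraction` of contexts ranked by a value (fitted
#' rate, genomic methylation level, ...) and reports per-position base
#' frequencies within each extreme set divided by the all-context frequency
#' (0.25 per base for a complete NNCGNN set). Ties across the decile boundary
#' are broken by lexicographic context order after the value sort.
#'
#' @param values named numeric vector, context -> value.
#' @param fraction extreme fraction (default 0.10).
#' @return list with `top` and `bottom` 4 x 4 enrichment matrices
#'   (bases x positions -2, -1, +2, +3) and the context sets used.
#' @export
extreme_site_composition <- function(values, fraction = 0.10) {
  if (length(values) < 20L) stop("need at least 20 contexts")
  n_take <- ceiling(fraction * length(values))
  ctx <- names(values)
  top_ctx <- ctx[order(-values, ctx)][seq_len(n_take)]
  bot_ctx <- ctx[order(values, ctx)][seq_len(n_take)]
  flank_cols <- c(1L, 2L, 5L, 6L)
  pos_labels <- c("-2", "-1", "+2", "+3")
  comp <- function(set) {
    m <- seq_char_matrix(set, flank_cols)
    freq <- vapply(seq_along(flank_cols), function(j)
      as.numeric(table(factor(m[, j], levels = BASES))) / length(set),
      numeric(4))
    dimnames(freq) <- list(BASES, pos_labels)
    freq
  }
  all_freq <- comp(ctx)
  list(top = comp(top_ctx) / all_freq,
       bottom = comp(bot_ctx) / all_freq,
       top_contexts = top_ctx, bottom_contexts = bot_ctx)
}
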