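#' Substrate layout for randomized-flank hairpin libraries
#'
#' Describes the deep-enzymology substrate: a fixed 5' arm, `n_left` randomized
#' bases, a central CpN dinucleotide, `n_right` randomized bases, a fixed 3'
#' arm, and the single-stranded hairpin linker that covalently joins the two
#' strands before bisulfite conversion. The defaults give an upper strand of
#' 51 nt and a hairpin read of 129 nt, so a 128 nt trim retains the full
#' -10..+11 analysis window on both strands.
#'
#' @param five_prime_arm fixed upstream sequence.
#' @param n_left,n_right number of randomized bases on each side of the
#'   central site (default 10 each).
#' @param central_site central dinucleotide; first base must be C
#'   (CG, CA, CT or CC).
#' @param three_prime_arm fixed downstream sequence.
#' @param hairpin_linker hairpin oligonucleotide sequence (27 nt).
#' @param flank_probs base sampling probabilities (A,C,G,T) for the randomized
#'   flanks; the library is nominally uniform but downstream o/e normalisation
#'   must tolerate composition bias, so it is exposed here.
#' @return an object of class `substrate_layout`.
#' @export
substrate_layout <- function(five_prime_arm = "GTAGAGTTGAGTAGA",
                             n_left = 10L,
                             central_site = "CG",
                             n_right = 10L,
                             three_prime_arm = "AGTTGGAGTAGTGA",
                             hairpin_linker = "GGAGAGGATCCGAAGCTTGAGTCTTGC",
                             flank_probs = rep(0.25, 4)) {
  stopifnot(substr(central_site, 1L, 1L) == "C", nchar(central_site) == 2L,
            n_left >= 1L, n_right >= 1L,
            abs(sum(flank_probs) - 1) < 1e-8)
  upper_length <- nchar(five_prime_arm) + n_left + 2L + n_right +
    nchar(three_prime_arm)
  layout <- list(
    five_prime_arm = five_prime_arm,
    n_left = as.integer(n_left),
    central_site = central_site,
    n_right = as.integer(n_right),
    three_prime_arm = three_prime_arm,
    hairpin_linker = hairpin_linker,
    flank_probs = flank_probs,
    upper_length = upper_length,
    central_index = nchar(five_prime_arm) + n_left + 1L, # 1-based C position
    read_length = 2L * upper_length + nchar(hairpin_linker)
  )
  class(layout) <- "substrate_layout"
  layout
}

#' True kinetic model for simulated reactions
#'
#' Holds the per-context rate constants, per-reaction virtual times and the
#' methylation plateau of the monoexponential progress-curve model
#' `level = plateau * (1 - exp(-k * tau))`.
#'
#' @param rates named numeric vector, 6-mer context -> rate constant (>= 0).
#' @param virtual_times numeric vector of per-reaction virtual times (>= 0).
#' @param plateau maximal attainable methylation fraction in `[0, 1]`.
#' @return an object of class `true_kinetics`.
#' @export
true_kinetics <- function(rates, virtual_times, plateau = 1.0) {
  stopifnot(!is.null(names(rates)), all(is.finite(rates)), all(rates >= 0),
            all(virtual_times >= 0), plateau >= 0, plateau <= 1)
  structure(list(rates = rates, virtual_times = virtual_times,
                 plateau = plateau),
            class = "true_kinetics")
}

#' Noise model for read simulation
#'
#' @param bisulfite_conversion_rate probability an unmethylated C reads as T.
#' @param inappropriate_conversion_rate probability a methylated C reads as T.
#' @param sequencing_error_rate per-base substitution probability.
#' @param duplicate_fraction fraction of reads emitted twice.
#' @param flank_meth_rate probability a flank (non-central) upper-strand C is
#'   methylated, to stress-test the caller; 0 by default since only the
#'   central site is analysed.
#' @param quality_phred constant Phred score assigned to simulated bases.
#' @param seed integer RNG seed.
#' @return an object of class `noise_model`.
#' @export
noise_model <- function(bisulfite_conversion_rate = 1.0,
                        inappropriate_conversion_rate = 0.0,
                        sequencing_error_rate = 0.0,
                        duplicate_fraction = 0.0,
                        flank_meth_rate = 0.0,
                        quality_phred = 40L,
                        seed = NULL) {
  p <- c(bisulfite_conversion_rate, inappropriate_conversion_rate,
         sequencing_error_rate, duplicate_fraction, flank_meth_rate)
  stopifnot(all(p >= 0), all(p <= 1))
  structure(list(bisulfite_conversion_rate = bisulfite_conversion_rate,
                 inappropriate_conversion_rate = inappropriate_conversion_rate,
                 sequencing_error_rate = sequencing_error_rate,
                 duplicate_fraction = duplicate_fraction,
                 flank_meth_rate = flank_meth_rate,
                 quality_phred = as.integer(quality_phred),
                 seed = seed),
            class = "noise_model")
}

## bisulfite-convert a single-stranded sequence (all Cs unmethylated)
convert_ss <- function(x) chartr("C", "T", x)

#' Simulate one methylation reaction as hairpin-bisulfite reads
#'
#' Draws `n_reads` substrate molecules with uniformly (or biased) random
#' flanks, methylates each central site with Bernoulli probability
#' `plateau * (1 - exp(-k(context) * tau))` for the reaction's virtual time
#' `tau`, and emits bisulfite-converted hairpin reads: converted upper strand,
#' then converted linker, then the converted lower strand read back 5'->3'
#' from the ligation point. The aligned partner of upper-strand position `i`
#' is read position `2U + 28 - i` (1-based, `U` = upper strand length).
#'
#' @param layout a [substrate_layout()].
#' @param kinetics a [true_kinetics()]; contexts must cover every simulated
#'   flank combination.
#' @param reaction_index which virtual time in `kinetics$virtual_times` to use.
#' @param n_reads number of molecules to simulate (>= 1).
#' @param noise a [noise_model()].
#' @return list with `reads` (data.frame: id, sequence, qualities) and
#'   `truth` (data.frame: read_id, flank_seq, meth_state, context).
#' @export
simulate_reaction_reads <- function(layout, kinetics, reaction_index, n_reads,
                                    noise = noise_model()) {
  stopifnot(inherits(layout, "substrate_layout"),
            inherits(kinetics, "true_kinetics"))
  if (n_reads < 1L) stop("n_reads must be >= 1")
  if (reaction_index < 1L || reaction_index > length(kinetics$virtual_times))
    stop("reaction_index has no virtual time in kinetics")
  if (!is.null(noise$seed)) set.seed(noise$seed)

  tau <- kinetics$virtual_times[[reaction_index]]
  nl <- layout$n_left; nr <- layout$n_right
  left  <- random_base_matrix(n_reads, nl, layout$flank_probs)
  right <- random_base_matrix(n_reads, nr, layout$flank_probs)

  context <- paste0(left[, nl - 1L], left[, nl], layout$central_site,
                    right[, 1L], right[, 2L])
  k <- kinetics$rates[context]
  if (anyNA(k)) {
    bad <- unique(context[is.na(k)])
    stop("context(s) missing from rate table: ", paste(head(bad, 5), collapse = ", "))
  }
  p_meth <- kinetics$plateau * (1 - exp(-k * tau))
  meth <- stats::rbinom(n_reads, 1L, p_meth) == 1L

  upper <- paste0(layout$five_prime_arm, paste_rows(left), layout$central_site,
                  paste_rows(right), layout$three_prime_arm)

  U <- layout$upper_length
  ci <- layout$central_index
  umat <- matrix(unlist(strsplit(upper, "", fixed = TRUE), use.names = FALSE),
                 nrow = n_reads, byrow = TRUE)

  ## upper-strand conversion: unmethylated C -> T with conversion prob;
  ## methylated C stays C except inappropriate conversion
  isC <- umat == "C"
  meth_mask <- matrix(FALSE, n_reads, U)
  meth_mask[, ci] <- meth
  if (noise$flank_meth_rate > 0) {
    fl <- isC & !col(umat) %in% c(ci, ci + 1L)
    meth_mask[fl] <- stats::runif(sum(fl)) < noise$flank_meth_rate
  }
  conv <- matrix(FALSE, n_reads, U)
  un <- isC & !meth_mask
  conv[un] <- stats::runif(sum(un)) < noise$bisulfite_conversion_rate
  me <- isC & meth_mask
  if (noise$inappropriate_conversion_rate > 0)
    conv[me] <- stats::runif(sum(me)) < noise$inappropriate_conversion_rate
  cu <- umat
  cu[conv] <- "T"

  ## lower strand (fully unmethylated): complement of upper, read back from
  ## the ligation point, i.e. columns U..1 complemented; its Cs (upper Gs)
  ## convert with the same probability
  lmat <- matrix(COMPLEMENT[umat[, U:1L]], n_reads, U)
  isCl <- lmat == "C"
  convl <- matrix(FALSE, n_reads, U)
  convl[isCl] <- stats::runif(sum(isCl)) < noise$bisulfite_conversion_rate
  cl <- lmat
  cl[convl] <- "T"

  linker <- convert_ss(layout$hairpin_linker)
  reads <- paste0(paste_rows(cu), linker, paste_rows(cl))

  if (noise$sequencing_error_rate > 0) {
    L <- layout$read_length
    rmat <- matrix(unlist(strsplit(reads, "", fixed = TRUE), use.names = FALSE),
                   nrow = n_reads, byrow = TRUE)
    hit <- matrix(stats::runif(n_reads * L) < noise$sequencing_error_rate,
                  n_reads, L)
    n_hit <- sum(hit)
    if (n_hit) {
      ## substitute by one of the three other bases
      shift <- sample(1:3, n_hit, replace = TRUE)
      idx <- match(rmat[hit], BASES)
      rmat[hit] <- BASES[((idx - 1L + shift) %% 4L) + 1L]
      reads <- paste_rows(rmat)
    }
  }

  ids <- sprintf("read_%06d", seq_len(n_reads))
  qual <- strrep(rawToChar(as.raw(noise$quality_phred + 33L)),
                 layout$read_length)
  truth <- data.frame(read_id = ids,
                      flank_seq = paste0(paste_rows(left), paste_rows(right)),
                      meth_state = ifelse(meth, "methylated", "unmethylated"),
                      context = context,
                      stringsAsFactors = FALSE)
  if (noise$duplicate_fraction > 0) {
    n_dup <- ceiling(noise$duplicate_fraction * n_reads)
    dup <- seq_len(n_dup)
    reads <- c(reads, reads[dup])
    ids <- c(ids, paste0(ids[dup], "_dup"))
  }
  list(reads = data.frame(id = ids, sequence = reads,
                          qualities = rep(qual, length(reads)),
                          stringsAsFactors = FALSE),
       truth = truth)
}

#' Simulate a preference-driven methylome
#'
#' Generates an i.i.d. random genome and, at every CpG cytosine (both
#' strands), a true methylation level proportional to the site's NNCGNN
#' preference value, rescaled so the mean over sites equals `mean_level`
#' (clipped to `[0, 1]`). Observed counts are drawn binomially at
#' Poisson-distributed coverage.
#'
#' @param genome_length genome size in bp (>= 1000).
#' @param preference named numeric map, NNCGNN context -> preference value
#'   (e.g. a fitted rate table's `k`).
#' @param mean_level target mean methylation fraction in (0, 1).
#' @param coverage_mean mean sequencing coverage (Poisson); 0 gives an empty
#'   call table.
#' @param seed integer RNG seed.
#' @param gc genome GC content (default 0.42, mouse-like).
#' @param chrom chromosome name used in the call table.
#' @return list with `genome` (character, one sequence), `calls` (data.frame:
#'   chrom, pos (0-based), strand, meth_count, total_count) and `truth`
#'   (data.frame: pos, strand, context6, true_level).
#' @export
simulate_methylome <- function(genome_length, preference, mean_level = 0.015,
                               coverage_mean = 10, seed = NULL, gc = 0.42,
                               chrom = "chr1") {
  if (length(preference) == 0L) stop("empty preference map")
  stopifnot(genome_length >= 1000L, mean_level > 0, mean_level < 1)
  if (!is.null(seed)) set.seed(seed)
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  genome <- paste(sample(BASES, genome_length, replace = TRUE, prob = probs),
                  collapse = "")
  cg <- Biostrings::matchPattern("CG", Biostrings::DNAString(genome))
  cpos <- BiocGenerics::start(cg)                     # 1-based C of the CpG
  ## keep sites with a full -10..+11 window so contexts are always extractable
  cpos <- cpos[cpos > 10L & cpos + 11L <= genome_length]
  win <- substring(genome, cpos - 2L, cpos + 3L)
  ctx_plus <- win
  ctx_minus <- revcomp(win)

  pos <- c(cpos - 1L, cpos)                           # 0-based: C, then G
  strand <- rep(c("+", "-"), each = length(cpos))
  ctx <- c(ctx_plus, ctx_minus)
  pref <- preference[ctx]
  if (anyNA(pref)) stop("preference map missing context(s): ",
                        paste(head(unique(ctx[is.na(pref)]), 5), collapse = ", "))
  true_level <- pmin(1, pmax(0, mean_level * pref / mean(pref)))

  if (coverage_mean > 0) {
    total <- stats::rpois(length(pos), coverage_mean)
    keep <- total > 0L
    mcount <- stats::rbinom(sum(keep), total[keep], true_level[keep])
    calls <- data.frame(chrom = chrom, pos = pos[keep], strand = strand[keep],
                        meth_count = mcount, total_count = total[keep],
                        stringsAsFactors = FALSE)
  } else {
    calls <- data.frame(chrom = character(), pos = integer(),
                        strand = character(), meth_count = integer(),
                        total_count = integer(), stringsAsFactors = FALSE)
  }
  calls <- calls[order(calls$pos), , drop = FALSE]
  rownames(calls) <- NULL
  list(genome = stats::setNames(genome, chrom),
       calls = calls,
       truth = data.frame(pos = pos, strand = strand, context6 = ctx,
                          true_level = true_level, stringsAsFactors = FALSE))
}

#' Simulate a repeat-like sequence with planted motif copies
#'
#' i.i.d. background with the requested base composition, with
#' `planted_count` non-overlapping copies of `planted_motif` written at
#' random positions.
#'
#' @param length sequence length in bp.
#' @param base_composition numeric length-4 (A,C,G,T) frequencies.
#' @param planted_motif motif to insert (e.g. `"CCCG"`).
#' @param planted_count number of non-overlapping copies.
#' @param seed integer RNG seed.
#' @return a single character string.
#' @export
simulate_repeat <- function(length, base_composition = rep(0.25, 4),
                            planted_motif = "CCCG", planted_count = 0L,
                            seed = NULL) {
  w <- nchar(planted_motif)
  if (planted_count * w >= length)
    stop("cannot place ", planted_count, " copies of a ", w, "-mer in ",
         length, " bp")
  if (!is.null(seed)) set.seed(seed)
  s <- sample(BASES, length, replace = TRUE, prob = base_composition)
  if (planted_count > 0L) {
    taken <- integer(0)
    starts <- integer(0)
    tries <- 0L
    while (length(starts) < planted_count) {
      if ((tries <- tries + 1L) > 1000L * planted_count)
        stop("impossible placement of planted motifs")
      cand <- sample.int(length - w + 1L, 1L)
      if (!any(abs(cand - taken) < w)) {
        taken <- c(taken, cand)
        starts <- c(starts, cand)
      }
    }
    motif_chars <- strsplit(planted_motif, "", fixed = TRUE)[[1]]
    for (st in starts) s[st:(st + w - 1L)] <- motif_chars
  }
  paste(s, collapse = "")
}
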