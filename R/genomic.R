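#' Load a methylome as context-annotated CpG site records
#'
#' Joins a bedGraph-like methylation-call table with a genome, keeps CpG
#' cytosines with coverage >= `min_coverage`, and annotates every retained
#' site with its 22-nt sequence context (10 bases each side of the central
#' CpG) and the NNCGNN 6-mer. Each strand's cytosine is a separate record;
#' minus-strand records carry the reverse-complement context. Calls whose
#' position is not a CpG cytosine on the stated strand are rejected and
#' counted, as are sites too close to a contig edge for a full context.
#'
#' @param calls data.frame (chrom, pos 0-based, strand, meth_count,
#'   total_count) or a path readable by [read_meth_calls()].
#' @param genome named character vector of contig sequences, or a FASTA path.
#' @param min_coverage minimum total count (default 5).
#' @param collapse_strands if TRUE, the two records of a CpG are merged
#'   (counts summed, plus-strand context).
#' @return data.frame (class `methylome_sites`): chrom, pos, strand,
#'   meth_count, total_count, level, context22, context6, with a `log`
#'   attribute of drop counters.
#' @export
load_methylome <- function(calls, genome, min_coverage = 5L,
                           collapse_strands = FALSE) {
  if (is.character(calls) && length(calls) == 1L) calls <- read_meth_calls(calls)
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- read_fasta(genome)
  missing_contig <- setdiff(unique(calls$chrom), names(genome))
  if (length(missing_contig))
    stop("contig(s) missing from genome: ", paste(missing_contig, collapse = ", "))

  n_in <- nrow(calls)
  low <- calls$total_count < min_coverage
  calls <- calls[!low, , drop = FALSE]

  chroms <- unique(calls$chrom)
  out <- vector("list", length(chroms))
  n_edge <- 0L; n_not_cpg <- 0L
  for (ci in seq_along(chroms)) {
    chrom <- chroms[ci]
    x <- calls[calls$chrom == chrom, , drop = FALSE]
    g <- genome[[chrom]]
    glen <- nchar(g)
    p1 <- x$pos + 1L                                  # 1-based
    base <- substring(g, p1, p1)
    nxt <- substring(g, p1 + 1L, p1 + 1L)
    prv <- substring(g, pmax(p1 - 1L, 1L), pmax(p1 - 1L, 1L))
    is_cpg <- ifelse(x$strand == "-", base == "G" & prv == "C",
                     base == "C" & nxt == "G")
    n_not_cpg <- n_not_cpg + sum(!is_cpg)
    x <- x[is_cpg, , drop = FALSE]; p1 <- p1[is_cpg]
    ## C position of the duplex CpG (plus strand)
    cpos <- ifelse(x$strand == "-", p1 - 1L, p1)
    edge <- cpos - 10L < 1L | cpos + 11L > glen
    n_edge <- n_edge + sum(edge)
    x <- x[!edge, , drop = FALSE]; cpos <- cpos[!edge]
    win <- substring(g, cpos - 10L, cpos + 11L)
    ctx22 <- ifelse(x$strand == "-", revcomp(win), win)
    x$context22 <- ctx22
    x$context6 <- substr(ctx22, 9L, 14L)
    out[[ci]] <- x
  }
  sites <- do.call(rbind, out)
  if (is.null(sites) || nrow(sites) == 0L) {
    sites <- data.frame(chrom = character(), pos = integer(),
                        strand = character(), meth_count = integer(),
                        total_count = integer(), context22 = character(),
                        context6 = character(), stringsAsFactors = FALSE)
  }
  sites$level <- sites$meth_count / sites$total_count

  if (collapse_strands && nrow(sites)) {
    cpos0 <- ifelse(sites$strand == "-", sites$pos - 1L, sites$pos)
    key <- paste(sites$chrom, cpos0)
    agg_m <- tapply(sites$meth_count, key, sum)
    agg_t <- tapply(sites$total_count, key, sum)
    first <- !duplicated(key)
    plus_ctx <- ifelse(sites$strand == "-", revcomp(sites$context22),
                       sites$context22)
    sites <- data.frame(chrom = sites$chrom[first], pos = cpos0[first],
                        strand = "*",
                        meth_count = as.integer(agg_m[key[first]]),
                        total_count = as.integer(agg_t[key[first]]),
                        context22 = plus_ctx[first],
                        stringsAsFactors = FALSE)
    sites$context6 <- substr(sites$context22, 9L, 14L)
    sites$level <- sites$meth_count / sites$total_count
  }
  sites <- sites[order(sites$chrom, sites$pos), , drop = FALSE]
  rownames(sites) <- NULL
  attr(sites, "log") <- list(n_in = n_in, n_low_coverage = sum(low),
                             n_not_cpg = n_not_cpg, n_edge = n_edge,
                             n_out = nrow(sites))
  class(sites) <- c("methylome_sites", "data.frame")
  sites
}

#' Mean methylation level per NNCGNN context
#'
#' Unweighted mean of per-site levels (m/t) within each observed 6-mer
#' context, plus the overall mean over all retained sites.
#'
#' @param sites a `methylome_sites` table.
#' @param weighted if TRUE, weight sites by coverage instead.
#' @return list: `context_means` (named vector), `n_sites` (per context),
#'   `overall_mean`.
#' @export
mean_by_context <- function(sites, weighted = FALSE) {
  stopifnot(nrow(sites) >= 1L)
  if (weighted) {
    m <- tapply(sites$meth_count, sites$context6, sum)
    t <- tapply(sites$total_count, sites$context6, sum)
    cm <- m / t
    overall <- sum(sites$meth_count) / sum(sites$total_count)
  } else {
    cm <- tapply(sites$level, sites$context6, mean)
    overall <- mean(sites$level)
  }
  list(context_means = stats::setNames(as.numeric(cm), names(cm)),
       n_sites = stats::setNames(as.integer(table(sites$context6)[names(cm)]),
                                 names(cm)),
       overall_mean = overall)
}

#' Genomic methylation o/e per context
#'
#' o/e(c) = mean methylation of context c divided by the overall mean. At
#' `"NNCG"` granularity the 256 NNCGNN contexts are aggregated over the
#' +2/+3 positions, weighted by site counts.
#'
#' @param context_means output of [mean_by_context()].
#' @param granularity `"NNCGNN"` (default) or `"NNCG"`.
#' @return named numeric vector of o/e values.
#' @export
genomic_oe <- function(context_means, granularity = c("NNCGNN", "NNCG")) {
  granularity <- match.arg(granularity)
  if (context_means$overall_mean <= 0) stop("overall mean methylation is zero")
  cm <- context_means$context_means
  if (granularity == "NNCG") {
    nn <- substr(names(cm), 1L, 4L)
    w <- context_means$n_sites
    cm <- tapply(cm * w, nn, sum) / tapply(w, nn, sum)
    cm <- stats::setNames(as.numeric(cm), names(cm))
  }
  cm / context_means$overall_mean
}

## rolling Pearson r over windows of w consecutive entries (step 1), via
## cumulative sums; returns NA where either window is constant
rolling_pearson <- function(x, y, w) {
  n <- length(x)
  if (n < w) return(numeric(0))
  cs <- function(v) { s <- cumsum(v); c(s[w], diff(s, lag = w)) }
  sx <- cs(x); sy <- cs(y); sxx <- cs(x^2); syy <- cs(y^2); sxy <- cs(x * y)
  cov <- sxy - sx * sy / w
  vx <- sxx - sx^2 / w
  vy <- syy - sy^2 / w
  ## guard tiny negative variances from cancellation
  vx[vx < 0] <- 0; vy <- pmax(vy, 0)
  r <- ifelse(vx > 1e-12 & vy > 1e-12, cov / sqrt(vx * vy), NA_real_)
  pmin(pmax(r, -1), 1)
}

#' Sliding-window local correlation of methylation and preference
#'
#' Over windows of `window` consecutive retained CpG sites (step 1) on one
#' chromosome, computes the Pearson correlation between per-site methylation
#' level and the per-site NNCGNN preference value. Windows where either
#' vector is constant are skipped and counted.
#'
#' @param sites `methylome_sites` restricted to one chromosome, in genomic
#'   order.
#' @param preference `rate_table` or named context -> value vector.
#' @param window number of consecutive CpG sites per window (default 22).
#' @return list (class `window_correlation`): `r` (per-window vector, NA for
#'   skipped), `start_pos` (genomic position of each window's first site),
#'   `n_windows`, `n_skipped`, `n_positive`, `n_negative`, `mean_r`,
#'   `pos_excess` (= n_positive - n_negative).
#' @export
local_correlation <- function(sites, preference, window = 22L) {
  if (window < 3L) stop("window must be >= 3 sites")
  if (length(unique(sites$chrom)) > 1L)
    stop("local correlation is per-chromosome; got ",
         length(unique(sites$chrom)), " chromosomes")
  if (nrow(sites) < window) stop("fewer retained sites than one window")
  k <- if (inherits(preference, "rate_table")) preference$k else preference
  pref <- unname(k[sites$context6])
  if (anyNA(pref)) stop("preference missing for some contexts")
  r <- rolling_pearson(sites$level, pref, window)
  structure(list(r = r,
                 start_pos = sites$pos[seq_along(r)],
                 n_windows = length(r),
                 n_skipped = sum(is.na(r)),
                 n_positive = sum(r > 0, na.rm = TRUE),
                 n_negative = sum(r < 0, na.rm = TRUE),
                 mean_r = mean(r, na.rm = TRUE),
                 pos_excess = sum(r > 0, na.rm = TRUE) - sum(r < 0, na.rm = TRUE),
                 window = window),
            class = "window_correlation")
}

#' Randomization Z-test for the local-correlation statistic
#'
#' Permutes the 256 preference values among the context keys, repeats the
#' sliding-window analysis, and compares the observed summary statistic with
#' the permutation null: `Z = (obs - mean_null) / sd_null`, with a one-sided
#' upper-tail normal p value.
#'
#' @param sites `methylome_sites` on one chromosome.
#' @param preference `rate_table` or named context -> value vector.
#' @param statistic `"mean_r"` (default) or `"pos_excess"`
#'   (n_positive - n_negative).
#' @param n_randomizations number of permutations (>= 20).
#' @param window sites per window (default 22).
#' @param seed RNG seed.
#' @return list: `Z`, `p`, `observed`, `null_mean`, `null_sd`, `null_values`.
#' @export
randomization_z <- function(sites, preference,
                            statistic = c("mean_r", "pos_excess"),
                            n_randomizations = 20L, window = 22L,
                            seed = NULL) {
  statistic <- match.arg(statistic)
  if (n_randomizations < 20L) stop("need >= 20 randomizations")
  if (!is.null(seed)) set.seed(seed)
  k <- if (inherits(preference, "rate_table")) preference$k else preference
  obs <- local_correlation(sites, k, window)[[statistic]]
  null_values <- vapply(seq_len(n_randomizations), function(i) {
    kp <- stats::setNames(sample(unname(k)), names(k))
    local_correlation(sites, kp, window)[[statistic]]
  }, numeric(1))
  mu <- mean(null_values); sdev <- stats::sd(null_values)
  if (sdev == 0) stop("null distribution has zero spread")
  Z <- (obs - mu) / sdev
  list(Z = Z, p = stats::pnorm(Z, lower.tail = FALSE), observed = obs,
       null_mean = mu, null_sd = sdev, null_values = null_values)
}
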