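#' Mononucleotide composition of a sequence region
#'
#' @param sequence DNA string.
#' @param region optional 0-based half-open `c(start, end)`; default the
#'   whole sequence.
#' @return named numeric vector of A/C/G/T frequencies (ambiguous bases are
#'   excluded from the denominator).
#' @export
composition_model <- function(sequence, region = NULL) {
  s <- region_substr(sequence, region)
  counts <- Biostrings::letterFrequency(Biostrings::DNAString(s), BASES)
  freq <- counts / sum(counts)
  stats::setNames(as.numeric(freq), BASES)
}

region_substr <- function(sequence, region) {
  if (is.null(region)) return(sequence)
  stopifnot(region[1] >= 0, region[2] <= nchar(sequence), region[1] < region[2])
  substr(sequence, region[1] + 1L, region[2])
}

#' Count CG, CCCG and CGGG occurrences
#'
#' Sliding exact-match counts with overlaps allowed: a CCCGGG hexamer
#' contributes one CCCG and one CGGG. Start windows containing ambiguous
#' bases (N) never match and are counted as skipped.
#'
#' @param sequence DNA string.
#' @param region optional 0-based half-open `c(start, end)`.
#' @return list: `n_CG`, `n_CCCG`, `n_CGGG`, `n_ambiguous_windows`,
#'   `region_length`.
#' @export
motif_counts <- function(sequence, region = NULL) {
  s <- Biostrings::DNAString(region_substr(sequence, region))
  cnt <- function(m) Biostrings::countPattern(m, s)
  n_amb <- 0L
  if (sum(Biostrings::letterFrequency(s, "N")) > 0) {
    npos <- BiocGenerics::start(Biostrings::matchPattern("N", s))
    ## 4-mer start windows touched by at least one N never match
    amb <- unique(unlist(lapply(npos, function(p) max(1L, p - 3L):p)))
    n_amb <- sum(amb <= length(s) - 3L)
  }
  list(n_CG = cnt("CG"), n_CCCG = cnt("CCCG"), n_CGGG = cnt("CGGG"),
       n_ambiguous_windows = n_amb, region_length = length(s))
}

## expected motif count under the i.i.d. mononucleotide model
expected_count <- function(motif, comp, n_positions) {
  b <- strsplit(motif, "", fixed = TRUE)[[1]]
  n_positions * prod(comp[b])
}

#' Whole-element observed/expected motif density
#'
#' Expectation from the element's own mononucleotide composition ("C and G
#' content"): expected(CG) = n_pos * f_C * f_G; expected(CCCG) =
#' n_pos * f_C^3 * f_G; expected(CGGG) = n_pos * f_C * f_G^3, where n_pos is
#' the number of motif start positions in the region. `"fraction"` mode gives
#' the fraction of CpG sites lying in a CCCG or CGGG context relative to its
#' expectation: `[(n_CCCG + n_CGGG)/n_CG] / (f_C^2 + f_G^2)`.
#'
#' @param sequence DNA string.
#' @param region optional 0-based half-open `c(start, end)`.
#' @param motif_class `"CG"`, `"CCCG"`, `"CGGG"`, `"CCCG+CGGG"` or
#'   `"fraction"`.
#' @param comp optional composition override (e.g. the whole element's
#'   composition when scoring a sub-region).
#' @return a single o/e value (NA with a warning when `n_CG` is 0 in
#'   fraction mode).
#' @export
oe_element <- function(sequence, region = NULL,
                       motif_class = c("CG", "CCCG", "CGGG", "CCCG+CGGG",
                                       "fraction"),
                       comp = NULL) {
  motif_class <- match.arg(motif_class)
  if (is.null(comp)) comp <- composition_model(sequence, region)
  cnt <- motif_counts(sequence, region)
  L <- cnt$region_length
  if (motif_class == "CG") {
    expd <- expected_count("CG", comp, L - 1L)
    if (expd <= 0) stop("expected CG count is zero")
    return(cnt$n_CG / expd)
  }
  if (motif_class %in% c("CCCG", "CGGG")) {
    expd <- expected_count(motif_class, comp, L - 3L)
    if (expd <= 0) stop("expected ", motif_class, " count is zero")
    obs <- if (motif_class == "CCCG") cnt$n_CCCG else cnt$n_CGGG
    return(obs / expd)
  }
  if (motif_class == "CCCG+CGGG") {
    expd <- expected_count("CCCG", comp, L - 3L) +
      expected_count("CGGG", comp, L - 3L)
    if (expd <= 0) stop("expected CCCG/CGGG count is zero")
    return((cnt$n_CCCG + cnt$n_CGGG) / expd)
  }
  ## fraction of CpGs in CCCG or CGGG context
  if (cnt$n_CG == 0L) {
    warning("no CpG in region; fraction o/e undefined")
    return(NA_real_)
  }
  denom <- comp[["C"]]^2 + comp[["G"]]^2
  if (denom <= 0) stop("expected fraction is zero")
  ((cnt$n_CCCG + cnt$n_CGGG) / cnt$n_CG) / denom
}

#' Windowed o/e motif profile
#'
#' Non-overlapping tiles of `window` bp; the final partial tile is kept when
#' it is at least half a window. The expectation for every tile uses the
#' whole-element mononucleotide composition, so the profile shows where in
#' the element the motif density concentrates.
#'
#' @param sequence DNA string (length >= `window`).
#' @param motif_class `"CG"`, `"CCCG+CGGG"` or `"fraction"`.
#' @param window tile width in bp (default 50).
#' @return data.frame: start, end (0-based half-open), oe.
#' @export
windowed_oe <- function(sequence, motif_class = c("CG", "CCCG+CGGG", "fraction"),
                        window = 50L) {
  motif_class <- match.arg(motif_class)
  n <- nchar(sequence)
  stopifnot(n >= window)
  comp <- composition_model(sequence)
  starts <- seq(0L, n - 1L, by = window)
  ends <- pmin(starts + window, n)
  keep <- (ends - starts) >= window / 2
  starts <- starts[keep]; ends <- ends[keep]
  oe <- vapply(seq_along(starts), function(i) {
    suppressWarnings(oe_element(sequence, c(starts[i], ends[i]),
                                motif_class, comp = comp))
  }, numeric(1))
  oe[is.na(oe)] <- 0
  data.frame(start = starts, end = ends, oe = oe)
}

#' Welch two-sample t-test
#'
#' Two-sided t-test with unequal variances (Welch-Satterthwaite degrees of
#' freedom), as used to compare motif enrichment between element groups.
#' Delegates to [stats::t.test()].
#'
#' @param group_a,group_b numeric vectors (>= 2 values each).
#' @return list: `t`, `df`, `p`.
#' @export
welch_ttest <- function(group_a, group_b) {
  stopifnot(length(group_a) >= 2L, length(group_b) >= 2L)
  if (stats::sd(group_a) == 0 && stats::sd(group_b) == 0 &&
      mean(group_a) == mean(group_b))
    return(list(t = 0, df = NA_real_, p = 1))
  ht <- stats::t.test(group_a, group_b, var.equal = FALSE,
                      alternative = "two.sided")
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Scan a repeat element for CpG and CCCG/CGGG enrichment
#'
#' Convenience wrapper producing the full MotifScan record for one element
#' (or a stated sub-region such as a promoter): motif counts, the three
#' whole-region o/e statistics, and the 50-bp window profile of the
#' CCCG+CGGG density.
#'
#' @param sequence DNA string.
#' @param element_id element name.
#' @param region optional 0-based half-open `c(start, end)`.
#' @param window tile width for the profile (default 50).
#' @return list (class `motif_scan`).
#' @export
scan_element <- function(sequence, element_id = "element", region = NULL,
                         window = 50L) {
  s <- region_substr(sequence, region)
  cnt <- motif_counts(s)
  structure(list(element_id = element_id,
                 region = if (is.null(region)) c(0L, nchar(sequence)) else region,
                 counts = cnt,
                 oe_CG = oe_element(s, motif_class = "CG"),
                 oe_CCCG_CGGG = oe_element(s, motif_class = "CCCG+CGGG"),
                 oe_fraction = suppressWarnings(
                   oe_element(s, motif_class = "fraction")),
                 window_profile = if (nchar(s) >= window)
                   windowed_oe(s, "CCCG+CGGG", window) else NULL),
            class = "motif_scan")
}

#' Compare element groups by CCCG/CGGG fraction o/e
#'
#' Summarises element-level fraction-mode o/e values by group and runs a
#' Welch two-sided t-test between the designated target and control groups.
#' Groups with fewer than 2 elements are summarised but excluded from the
#' comparison (reported).
#'
#' @param scans list of `motif_scan` objects.
#' @param group_labels character vector, one label per scan.
#' @param target,control group labels to compare.
#' @return list: `summary` (data.frame group, n, mean_oe, sd_oe), `welch`
#'   (list t/df/p or NULL), `values` (per-element data.frame),
#'   `skipped_groups`.
#' @export
group_report <- function(scans, group_labels, target, control) {
  stopifnot(length(scans) == length(group_labels))
  vals <- data.frame(
    element_id = vapply(scans, `[[`, character(1), "element_id"),
    group = group_labels,
    oe_fraction = vapply(scans, `[[`, numeric(1), "oe_fraction"),
    stringsAsFactors = FALSE)
  agg <- do.call(rbind, lapply(split(vals, vals$group), function(d)
    data.frame(group = d$group[1], n = nrow(d),
               mean_oe = mean(d$oe_fraction, na.rm = TRUE),
               sd_oe = stats::sd(d$oe_fraction), stringsAsFactors = FALSE)))
  rownames(agg) <- NULL
  small <- agg$group[agg$n < 2L]
  welch <- NULL
  if (!(target %in% small) && !(control %in% small) &&
      target %in% vals$group && control %in% vals$group) {
    welch <- welch_ttest(vals$oe_fraction[vals$group == target],
                         vals$oe_fraction[vals$group == control])
  }
  list(summary = agg, welch = welch, values = vals,
       skipped_groups = small)
}
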