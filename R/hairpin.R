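#' Quality-control filter for hairpin-bisulfite reads
#'
#' Trims every read to exactly `target_length` and keeps only reads whose
#' Phred quality meets `min_quality` over the trimmed portion. Reads shorter
#' than `target_length` are dropped and counted. Input order is preserved.
#'
#' @param reads data.frame (id, sequence, qualities).
#' @param target_length trim length (default 128).
#' @param min_quality minimum Phred score (default 20).
#' @param quality_mode `"min"` (every base >= threshold, default, strict) or
#'   `"mean"` (mean Phred >= threshold).
#' @return list with `reads` (filtered, trimmed data.frame) and `log`
#'   (counters: n_in, n_short, n_low_quality, n_out).
#' @export
qc_filter <- function(reads, target_length = 128L, min_quality = 20,
                      quality_mode = c("min", "mean")) {
  quality_mode <- match.arg(quality_mode)
  stopifnot(target_length >= 1L)
  n_in <- nrow(reads)
  long_enough <- nchar(reads$sequence) >= target_length
  out <- reads[long_enough, , drop = FALSE]
  out$sequence <- substr(out$sequence, 1L, target_length)
  out$qualities <- substr(out$qualities, 1L, target_length)
  phred_stat <- vapply(out$qualities, function(q) {
    p <- utf8ToInt(q) - 33L
    if (quality_mode == "min") min(p) else mean(p)
  }, numeric(1), USE.NAMES = FALSE)
  ok <- phred_stat >= min_quality
  res <- out[ok, , drop = FALSE]
  rownames(res) <- NULL
  list(reads = res,
       log = list(n_in = n_in, n_short = sum(!long_enough),
                  n_low_quality = sum(!ok), n_out = nrow(res)))
}

#' Remove duplicate reads
#'
#' Sorts reads alphabetically by their full trimmed sequence (flanks and
#' methylation pattern together) and keeps one representative per distinct
#' string, so over-amplified molecules do not inflate the statistics. Reads
#' differing only in methylation state differ as strings and are not
#' duplicates.
#'
#' @param reads data.frame (id, sequence, qualities), already trimmed to a
#'   common length.
#' @return data.frame of unique reads in alphabetical sequence order.
#' @export
deduplicate <- function(reads) {
  o <- order(reads$sequence, method = "radix")
  out <- reads[o, , drop = FALSE]
  out <- out[!duplicated(out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify the central site and flag CCWGG overlap
#'
#' The site class (CpG/CpA/CpT/CpC) is determined by the base at +1 of the
#' reconstituted sequence; the CCWGG flag marks central-C sites inside a dcm
#' methyltransferase motif, i.e. bases at (-1, +1, +2, +3) equal to
#' (C, A or T, G, G). CpG sites can never carry the flag (+1 is G, not W).
#'
#' @param original_sequence character vector of reconstituted windows.
#' @param central_offset 1-based position of the central C within
#'   `original_sequence`.
#' @return data.frame with `site_class`, `ccwgg_flag` and `ok` (FALSE when
#'   the +1 base is not A/C/G/T).
#' @export
classify_site <- function(original_sequence, central_offset) {
  m1 <- substr(original_sequence, central_offset - 1L, central_offset - 1L)
  p1 <- substr(original_sequence, central_offset + 1L, central_offset + 1L)
  p2 <- substr(original_sequence, central_offset + 2L, central_offset + 2L)
  p3 <- substr(original_sequence, central_offset + 3L, central_offset + 3L)
  cls <- c(G = "CpG", A = "CpA", T = "CpT", C = "CpC")[p1]
  ccwgg <- m1 == "C" & p1 %in% c("A", "T") & p2 == "G" & p3 == "G"
  data.frame(site_class = unname(cls), ccwgg_flag = ccwgg,
             ok = !is.na(cls), stringsAsFactors = FALSE)
}

#' Reconstitute original substrate sequences from hairpin reads
#'
#' Uses the paired information of the two bisulfite-converted strands in one
#' hairpin read to recover the original (pre-conversion) sequence and the
#' methylation state of the central site. Per duplex position with
#' upper-read base `u` and aligned lower-read base `v`:
#' `u = A -> A`; `u = G -> G`; `u = C -> C` (central site: methylated);
#' `u = T, v = G -> C` (central: unmethylated); `u = T, v = A -> T`.
#' Any other combination is inconsistent; reads with an inconsistent pair in
#' the analysis window are discarded and counted.
#'
#' @param reads data.frame (id, sequence, qualities) of trimmed reads.
#' @param layout the [substrate_layout()] the library was built from.
#' @param window half-width of the reconstituted window around the central C
#'   (default 10, i.e. -10..+11 including the +1 partner base).
#' @param max_linker_mismatch number of tolerated mismatches against the
#'   converted linker before a read is discarded as unalignable.
#' @return list with `calls` (data.frame: read_id, original_sequence,
#'   central_meth, site_class, ccwgg_flag, central_offset attribute) and
#'   `log` (drop counters).
#' @export
reconstitute_reads <- function(reads, layout, window = 10L,
                               max_linker_mismatch = 0L) {
  stopifnot(inherits(layout, "substrate_layout"))
  U <- layout$upper_length
  ci <- layout$central_index
  nlink <- nchar(layout$hairpin_linker)
  n_in <- nrow(reads)
  if (n_in == 0L)
    return(list(calls = empty_calls(), log = list(n_in = 0L, n_short = 0L,
                n_linker = 0L, n_inconsistent = 0L, n_out = 0L)))

  dpos <- (ci - window):(ci + window + 1L)      # duplex positions, -w..+w+1
  partner <- 2L * U + 2L * nlink - nlink + 1L - dpos   # = 2U + nlink + 1 - i
  need <- max(c(dpos, partner, U + nlink))
  len <- nchar(reads$sequence)
  long_enough <- len >= need
  n_short <- sum(!long_enough)
  reads <- reads[long_enough, , drop = FALSE]

  ## linker check: at linker C positions accept C (unconverted) or T
  link_obs <- substr(reads$sequence, U + 1L, U + nlink)
  link_ref <- strsplit(layout$hairpin_linker, "", fixed = TRUE)[[1]]
  lm <- matrix(unlist(strsplit(link_obs, "", fixed = TRUE), use.names = FALSE),
               nrow = nrow(reads), byrow = TRUE)
  ok_base <- sweep(lm, 2L, link_ref, "==") |
    sweep(lm, 2L, chartr("C", "T", link_ref), "==")
  mism <- nlink - rowSums(ok_base)
  link_ok <- mism <= max_linker_mismatch
  n_linker <- sum(!link_ok)
  reads <- reads[link_ok, , drop = FALSE]
  if (nrow(reads) == 0L)
    return(list(calls = empty_calls(), log = list(n_in = n_in,
                n_short = n_short, n_linker = n_linker,
                n_inconsistent = 0L, n_out = 0L)))

  umat <- vapply(dpos, function(p) substr(reads$sequence, p, p),
                 character(nrow(reads)))
  vmat <- vapply(partner, function(p) substr(reads$sequence, p, p),
                 character(nrow(reads)))
  if (nrow(reads) == 1L) { umat <- matrix(umat, 1L); vmat <- matrix(vmat, 1L) }

  orig <- matrix(NA_character_, nrow(reads), length(dpos))
  okm  <- matrix(FALSE, nrow(reads), length(dpos))
  sel <- umat == "A";              orig[sel] <- "A"; okm[sel] <- vmat[sel] == "T"
  sel <- umat == "G";              orig[sel] <- "G"; okm[sel] <- vmat[sel] %in% c("C", "T")
  sel <- umat == "C";              orig[sel] <- "C"; okm[sel] <- vmat[sel] == "G"
  sel <- umat == "T" & vmat == "G"; orig[sel] <- "C"; okm[sel] <- TRUE
  sel <- umat == "T" & vmat == "A"; orig[sel] <- "T"; okm[sel] <- TRUE

  central_col <- window + 1L
  meth <- ifelse(umat[, central_col] == "C", "methylated",
          ifelse(umat[, central_col] == "T" & vmat[, central_col] == "G",
                 "unmethylated", NA_character_))
  ## the central original base must be a (methylatable) C
  consistent <- rowSums(okm) == ncol(okm) & !is.na(meth)
  n_inconsistent <- sum(!consistent)
  orig[is.na(orig)] <- "N"
  oseq <- paste_rows(orig)
  calls <- data.frame(read_id = reads$id, original_sequence = oseq,
                      central_meth = meth, stringsAsFactors = FALSE)
  calls <- calls[consistent, , drop = FALSE]
  cls <- classify_site(calls$original_sequence, central_col)
  calls$site_class <- cls$site_class
  calls$ccwgg_flag <- cls$ccwgg_flag
  bad_class <- !cls$ok
  calls <- calls[!bad_class, , drop = FALSE]
  rownames(calls) <- NULL
  attr(calls, "central_offset") <- central_col
  list(calls = calls,
       log = list(n_in = n_in, n_short = n_short, n_linker = n_linker,
                  n_inconsistent = n_inconsistent + sum(bad_class),
                  n_out = nrow(calls)))
}

empty_calls <- function() {
  data.frame(read_id = character(), original_sequence = character(),
             central_meth = character(), site_class = character(),
             ccwgg_flag = logical(), stringsAsFactors = FALSE)
}

#' Write a HairpinCall table and the JSON run log
#'
#' @param calls call table from [reconstitute_reads()].
#' @param path TSV output path.
#' @param log optional run-log list written as JSON next to `path`.
#' @export
write_calls <- function(calls, path, log = NULL) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(log))
    jsonlite::write_json(log, sub("\\.tsv$", ".log.json", path),
                         auto_unbox = TRUE)
  invisible(path)
}
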