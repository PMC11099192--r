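#' @importFrom stats cor lm optimise pnorm pt qnorm quantile rbinom rnorm
#'   rpois runif sd setNames t.test coef complete.cases
#' @importFrom utils head read.delim write.table
NULL

BASES <- c("A", "C", "G", "T")

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' All NNCGNN (or NNCXNN) 6-mer contexts
#'
#' Enumerates the 256 hexamer contexts formed by two bases 5' and two bases 3'
#' of a central dinucleotide, in lexicographic order.
#'
#' @param central central dinucleotide, e.g. `"CG"`, `"CA"`.
#' @return character vector of 256 contexts.
#' @export
all_contexts <- function(central = "CG") {
  stopifnot(nchar(central) == 2L, substr(central, 1L, 1L) == "C")
  g <- expand.grid(p3 = BASES, p2 = BASES, m1 = BASES, m2 = BASES,
                   stringsAsFactors = FALSE)
  ctx <- paste0(g$m2, g$m1, central, g$p2, g$p3)
  sort(ctx)
}

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement on plain character vectors (thin wrapper over
#' Biostrings so N and IUPAC codes behave).
#'
#' @param x character vector of DNA sequences.
#' @return character vector.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## fast per-position character extraction: one column per position
seq_char_matrix <- function(x, positions) {
  m <- vapply(positions, function(p) substr(x, p, p), character(length(x)))
  if (length(x) == 1L) m <- matrix(m, nrow = 1L)
  colnames(m) <- as.character(positions)
  m
}

## sample bases as a (n x k) character matrix
random_base_matrix <- function(n, k, prob = rep(0.25, 4)) {
  matrix(sample(BASES, n * k, replace = TRUE, prob = prob), nrow = n, ncol = k)
}

paste_rows <- function(m) {
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

## geometric mean over strictly positive finite entries
geomean <- function(x) {
  x <- x[is.finite(x) & x > 0]
  if (!length(x)) return(NA_real_)
  exp(mean(log(x)))
}

#' Pearson correlation of two profile-like vectors
#'
#' Pairwise-complete Pearson correlation used throughout for comparing
#' flanking-preference profiles and context-level vectors. Entries missing in
#' either vector are dropped pairwise; fewer than 3 shared finite entries is
#' an error.
#'
#' @param a,b numeric vectors of equal length, or named vectors whose shared
#'   names are matched first.
#' @return Pearson r in `[-1, 1]`.
#' @export
correlate_profiles <- function(a, b) {
  if (inherits(a, "flank_profile")) a <- as.vector(a$oe)
  if (inherits(b, "flank_profile")) b <- as.vector(b$oe)
  if (!is.null(names(a)) && !is.null(names(b))) {
    shared <- intersect(names(a), names(b))
    a <- a[shared]; b <- b[shared]
  }
  stopifnot(length(a) == length(b))
  ok <- is.finite(a) & is.finite(b)
  if (sum(ok) < 3L) stop("fewer than 3 shared entries for correlation")
  stats::cor(a[ok], b[ok])
}
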