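#' Round half away from zero
#'
#' Rounds to `digits` decimal places with halves moving away from zero
#' (unlike [base::round()], which rounds halves to even). Used wherever the
#' package reports percentages.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return numeric vector.
#' @export
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Report a count as a percentage
#'
#' @param n numerator count.
#' @param total denominator count.
#' @param digits decimal places (half away from zero); 1 by default, matching
#'   the package's frequency reporting convention.
#' @return percentage on the 0-100 scale.
#' @export
percent_of <- function(n, total, digits = 1) {
  stopifnot(total > 0)
  round_half_away(100 * n / total, digits)
}

#' Homopolymer context mask for a reference sequence
#'
#' Marks positions lying inside a run of >= `min_run` identical bases, or
#' immediately adjacent (1 bp) to such a run. These are the positions where
#' pyrosequencing chemistry concentrates its errors and where the
#' rule-based caller applies its stricter quality and consensus rules.
#'
#' @param seq character scalar or `Biostrings::DNAString` reference sequence.
#' @param min_run minimum run length, default 5 (a "5-mer or higher").
#' @return logical vector, one element per base, TRUE in/next to a long run.
#' @export
homopolymer_mask <- function(seq, min_run = 5L) {
  s <- strsplit(as.character(seq), "", fixed = TRUE)[[1]]
  n <- length(s)
  mask <- logical(n)
  if (n == 0L) return(mask)
  r <- rle(s)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  long <- which(r$lengths >= min_run)
  for (i in long) {
    lo <- max(1L, starts[i] - 1L)
    hi <- min(n, ends[i] + 1L)
    mask[lo:hi] <- TRUE
  }
  mask
}

# phred+33 string -> integer vector
qual_to_int <- function(q) utf8ToInt(q) - 33L

# integer vector -> phred+33 string (capped at Q40)
int_to_qual <- function(q) intToUtf8(pmin(pmax(as.integer(q), 0L), 41L) + 33L)

# deterministic sub-seed derivation, kept well below 2^31
derive_seed <- function(seed, k) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(k) %% 1000L
}

DNA_BASES <- c("A", "C", "G", "T")

# for each base, sample one of the other three
other_base <- function(base) {
  idx <- match(base, DNA_BASES)
  shift <- sample.int(3L, length(base), replace = TRUE)
  DNA_BASES[((idx - 1L + shift) %% 4L) + 1L]
}
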