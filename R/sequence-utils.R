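# IUPAC machinery shared by primer localization, simulation and matching.
# Read-side alphabet is A/C/G/T/N; pattern-side is the 15-letter IUPAC set.

IUPAC_SETS <- strsplit(Biostrings::IUPAC_CODE_MAP, "")
IUPAC_LETTERS <- names(IUPAC_SETS)
IUPAC_LETTERS_RE <- paste(IUPAC_LETTERS, collapse = "")

# logical matrix: rows = pattern letter, cols = read letter (A/C/G/T/N).
# A read 'N' carries no evidence for any base, so it matches only a
# pattern 'N' (a deliberate, conservative convention).
IUPAC_MATCH <- local({
  readl <- c("A", "C", "G", "T", "N")
  m <- matrix(FALSE, length(IUPAC_LETTERS), length(readl),
              dimnames = list(IUPAC_LETTERS, readl))
  for (p in IUPAC_LETTERS) {
    m[p, c("A", "C", "G", "T")] <- c("A", "C", "G", "T") %in% IUPAC_SETS[[p]]
    m[p, "N"] <- identical(p, "N")
  }
  m
})

#' Reverse complement of an IUPAC DNA string
#'
#' Standard complement with the IUPAC degenerate-base mapping
#' (R/Y, S/S, W/W, K/M, B/V, D/H, N/N), then reversed. An involution:
#' \code{revComp(revComp(x)) == x}.
#'
#' @param seq a single DNA string over the 15-letter IUPAC alphabet.
#' @return a character scalar.
#' @examples
#' revComp("AAGG")  # "CCTT"
#' revComp("RN")    # "NY"
#' @export
revComp <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (!nzchar(seq)) return(seq)
  if (grepl(sprintf("[^%s]", IUPAC_LETTERS_RE), seq))
    stop("revComp(): non-IUPAC character in sequence")
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' IUPAC base matching
#'
#' Does read base \code{base} fall in the set encoded by the (possibly
#' degenerate) \code{patternBase}? A read-side \code{"N"} matches only a
#' pattern \code{"N"}: an uncalled base carries no evidence of identity.
#'
#' @param patternBase IUPAC letter(s).
#' @param base read letter(s) in A/C/G/T/N. Recycled against
#'   \code{patternBase}.
#' @return logical vector.
#' @examples
#' iupacMatch("R", c("A", "C"))  # TRUE FALSE
#' @export
iupacMatch <- function(patternBase, base) {
  if (any(!patternBase %in% IUPAC_LETTERS))
    stop("iupacMatch(): pattern base not an IUPAC letter")
  if (any(!base %in% c("A", "C", "G", "T", "N")))
    stop("iupacMatch(): read base must be one of A/C/G/T/N")
  n <- max(length(patternBase), length(base))
  IUPAC_MATCH[cbind(rep_len(patternBase, n), rep_len(base, n))]
}

#' Mean read quality (error-probability averaged)
#'
#' The per-read quality used for filtering long reads:
#' \deqn{Q = -10 \log_{10}\left(\frac{1}{n}\sum_i 10^{-q_i/10}\right)}
#' i.e. the Phred transform of the mean per-base error probability --
#' not the arithmetic mean of Phred values, from which it differs
#' materially on heterogeneous reads (low-quality bases dominate).
#'
#' @param quals integer/numeric vector of per-base Phred scores.
#' @return a numeric scalar, bounded by \code{min(quals)} and
#'   \code{max(quals)}.
#' @examples
#' meanReadQuality(c(10, 20))  # ~12.60, not 15
#' @export
meanReadQuality <- function(quals) {
  if (length(quals) == 0L) stop("meanReadQuality(): empty quality vector")
  -10 * log10(mean(10^(-quals / 10)))
}

# ---- internal helpers ------------------------------------------------------

# Phred+33 encode/decode (the only encoding emitted by modern basecallers)
qualsToString <- function(q) intToUtf8(as.integer(q) + 33L)
stringToQuals <- function(s) utf8ToInt(s) - 33L

splitChars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

# ungapped IUPAC-aware mismatch counts of `pat` against `readChars` at
# 1-based offsets `offs`
iupacMismatchAt <- function(readChars, patChars, offs) {
  L <- length(patChars)
  vapply(offs, function(o) {
    sum(!IUPAC_MATCH[cbind(patChars, readChars[o:(o + L - 1L)])])
  }, numeric(1))
}

# per-read integer qualities from a QualityScaledDNAStringSet
readQuals <- function(reads) {
  as(Biostrings::quality(reads), "IntegerList")
}

#' Assemble a read set from sequences and per-base qualities
#'
#' @param seqs named character vector of read sequences.
#' @param quals list of integer Phred vectors, one per read, each the
#'   same length as its sequence.
#' @param ids read ids (default: \code{names(seqs)}).
#' @return a [Biostrings::QualityScaledDNAStringSet].
#' @export
makeReads <- function(seqs, quals, ids = names(seqs)) {
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(setNames(as.character(seqs), ids)),
    Biostrings::PhredQuality(vapply(quals, qualsToString, character(1)))
  )
  names(x) <- ids
  x
}
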