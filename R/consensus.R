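# Per-sample consensus building: greedy centroid clustering of reads,
# bin-size filtering, and majority-vote consensus against the bin
# centroid. Pairwise alignment is delegated to Biostrings.

CONS_SUBST <- Biostrings::nucleotideSubstitutionMatrix(match = 2,
                                                       mismatch = -3)

globalAln <- function(pattern, subject, type = "global") {
  Biostrings::pairwiseAlignment(pattern, subject, type = type,
                                substitutionMatrix = CONS_SUBST,
                                gapOpening = 5, gapExtension = 2)
}

# identity = matches / alignment length including gap columns (pinned
# definition; `denominator = "shorter"` gives matches / min length)
alnIdentity <- function(pattern, subject, denominator = c("alignment",
                                                          "shorter")) {
  denominator <- match.arg(denominator)
  aln <- globalAln(pattern, subject)
  m <- Biostrings::nmatch(aln)
  den <- switch(denominator,
    alignment = nchar(as.character(Biostrings::pattern(aln))),
    shorter = min(nchar(pattern), nchar(subject)))
  m / den
}

#' Greedy centroid clustering of reads
#'
#' Reads are processed in decreasing length order (ties broken by read
#' id); each read joins the \emph{first} existing bin whose centroid
#' identity (global-alignment matches / alignment length) reaches
#' \code{identityThreshold}, else it seeds a new bin with itself as
#' centroid. Deterministic; bin sizes sum to the number of input reads.
#'
#' @param reads a [Biostrings::DNAStringSet],
#'   [Biostrings::QualityScaledDNAStringSet] or named character vector.
#' @param identityThreshold minimum centroid identity (default 0.97).
#' @return list of [ReadBin-class], in creation order.
#' @export
greedyCluster <- function(reads, identityThreshold = 0.97) {
  seqs <- setNames(as.character(reads), names(reads))
  if (length(seqs) == 0L) stop("greedyCluster(): no reads")
  if (is.null(names(seqs)))
    names(seqs) <- sprintf("r%06d", seq_along(seqs))
  ord <- order(-nchar(seqs), names(seqs))
  seqs <- seqs[ord]
  centroids <- character(0)
  memberIdx <- list()
  for (i in seq_along(seqs)) {
    placed <- FALSE
    for (b in seq_along(centroids)) {
      if (alnIdentity(seqs[[i]], centroids[[b]]) >= identityThreshold) {
        memberIdx[[b]] <- c(memberIdx[[b]], i)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      centroids <- c(centroids, seqs[[i]])
      memberIdx[[length(centroids)]] <- i
    }
  }
  lapply(seq_along(centroids), function(b)
    methods::new("ReadBin", binId = sprintf("bin%d", b),
                 centroid = centroids[[b]],
                 members = Biostrings::DNAStringSet(seqs[memberIdx[[b]]])))
}

#' Keep bins larger than a size cutoff
#'
#' Strict inequality: only bins yielding \emph{more than}
#' \code{minSize} reads are kept, so a bin of exactly 10 reads is
#' dropped at the default.
#'
#' @param bins list of [ReadBin-class].
#' @param minSize strict lower bound on bin size (default 10).
#' @return filtered list.
#' @export
filterBins <- function(bins, minSize = 10) {
  Filter(function(b) binSize(b) > minSize, bins)
}

#' Majority-vote consensus sequence of a read bin
#'
#' Each member is globally aligned to the bin centroid; per centroid
#' column the majority base wins (ties keep the centroid base; a strict
#' majority of gaps deletes the column). Insertions relative to the
#' centroid are kept only when present in more than 50% of the members
#' (majority inserted string, lexicographic tie-break).
#'
#' @param bin a [ReadBin-class].
#' @return a character DNA string.
#' @export
consensusSequence <- function(bin) {
  members <- as.character(binMembers(bin))
  centroid <- binCentroid(bin)
  n <- length(members)
  if (n == 1L) return(centroid)
  Lc <- nchar(centroid)
  votes <- matrix(NA_character_, n, Lc)
  insertions <- list()   # key: after-position; value: member -> string
  for (m in seq_len(n)) {
    aln <- globalAln(members[[m]], centroid)
    P <- splitChars(as.character(Biostrings::pattern(aln)))
    S <- splitChars(as.character(Biostrings::subject(aln)))
    cpos <- 0L
    for (j in seq_along(S)) {
      if (S[j] != "-") {
        cpos <- cpos + 1L
        votes[m, cpos] <- P[j]
      } else {
        key <- as.character(cpos)
        cur <- insertions[[key]]
        if (is.null(cur)) cur <- setNames(character(0), character(0))
        cur[as.character(m)] <- paste0(
          if (is.na(cur[as.character(m)])) "" else cur[as.character(m)],
          P[j])
        insertions[[key]] <- cur
      }
    }
  }
  centroidChars <- splitChars(centroid)
  pieces <- character(0)
  insAt <- function(pos) {
    cur <- insertions[[as.character(pos)]]
    if (is.null(cur) || length(cur) <= n / 2) return("")
    tab <- sort(table(cur), decreasing = TRUE)
    cands <- names(tab)[tab == max(tab)]
    sort(cands)[1L]
  }
  pieces <- c(pieces, insAt(0L))
  for (pos in seq_len(Lc)) {
    col <- votes[, pos]
    col[is.na(col)] <- "-"
    tab <- sort(table(col), decreasing = TRUE)
    winners <- names(tab)[tab == max(tab)]
    base <- if (length(winners) > 1L) centroidChars[pos] else winners[1L]
    if (base != "-") pieces <- c(pieces, base)
    pieces <- c(pieces, insAt(pos))
  }
  paste(pieces, collapse = "")
}

#' Star multiple alignment to the longest sequence
#'
#' A fixed multiple alignment built by progressive alignment to the
#' longest input sequence (ties broken by name): every other sequence is
#' globally aligned to it and projected onto its coordinates
#' (insertions relative to the reference are dropped). Adequate as the
#' substrate for column-resampling bootstraps; not a substitute for a
#' dedicated MSA tool.
#'
#' @param seqs named [Biostrings::DNAStringSet] or character vector of
#'   >= 2 sequences.
#' @return character matrix (rows = sequences, columns = reference
#'   positions, \code{"-"} for deletions).
#' @export
starAlignment <- function(seqs) {
  seqs <- setNames(as.character(seqs), names(seqs))
  if (length(seqs) < 2L) stop("starAlignment(): need >= 2 sequences")
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("starAlignment(): sequences must have unique names")
  refIdx <- order(-nchar(seqs), names(seqs))[1L]
  ref <- seqs[[refIdx]]
  Lr <- nchar(ref)
  out <- matrix("-", length(seqs), Lr,
                dimnames = list(names(seqs), NULL))
  out[refIdx, ] <- splitChars(ref)
  for (i in setdiff(seq_along(seqs), refIdx)) {
    aln <- globalAln(seqs[[i]], ref)
    P <- splitChars(as.character(Biostrings::pattern(aln)))
    S <- splitChars(as.character(Biostrings::subject(aln)))
    # the aligned region may start inside the reference (free end gaps)
    rpos <- Biostrings::start(Biostrings::subject(aln)) - 1L
    row <- rep("-", Lr)
    for (j in seq_along(S)) {
      if (S[j] != "-") {
        rpos <- rpos + 1L
        row[rpos] <- P[j]
      }
    }
    out[i, ] <- row
  }
  out
}
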