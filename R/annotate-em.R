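# Species-level relative-abundance estimation: local alignment of each
# read against each reference, conversion to a per-read likelihood, and
# a mixture EM over taxon proportions.
#
# This is a minimal re-implementation of the role a long-read 16S
# profiler plays in the workflow (correct species, calibrated
# abundances at desk scale), not a port of any particular tool.

# blastn-like scoring for noisy long reads
EM_SUBST <- Biostrings::nucleotideSubstitutionMatrix(match = 2,
                                                     mismatch = -3)

#' Score reads against a reference database
#'
#' For each read, a local alignment against each reference (both
#' strands, best kept) is converted to a likelihood
#' \deqn{L = p_{err}^{\,mismatches+indels}\,(1-p_{err})^{matches}}
#' with a fixed per-base error rate \code{pErr}. Taxa whose best
#' alignment covers less than \code{minCoverage} of the read get
#' \eqn{L = 0}. Each row is rescaled by its maximum (a per-read
#' constant that cancels in the EM posteriors), keeping full-length-read
#' likelihoods representable; rows with no passing taxon are all zero.
#'
#' @param reads a [Biostrings::QualityScaledDNAStringSet],
#'   [Biostrings::DNAStringSet] or named character vector.
#' @param db a [ReferenceDb-class].
#' @param pErr assumed per-base error probability (default 0.1; fixed,
#'   not learned, to keep the model identifiable at toy scale).
#' @param minCoverage minimum fraction of the read covered by the local
#'   alignment (default 0.8).
#' @param bothStrands also score the reverse complement and keep the
#'   better strand (default TRUE; FALSE is a fast path for reads already
#'   in canonical orientation).
#' @return numeric matrix, rows = reads, columns = taxa.
#' @seealso [emAbundance()], [annotateSample()]
#' @export
scoreReads <- function(reads, db, pErr = 0.1, minCoverage = 0.8,
                       bothStrands = TRUE) {
  if (length(refSeqs(db)) == 0L) stop("scoreReads(): empty database")
  seqs <- Biostrings::DNAStringSet(as.character(reads))
  if (is.null(names(seqs)))
    names(seqs) <- sprintf("r%06d", seq_along(seqs))
  taxIds <- names(refSeqs(db))
  logL <- matrix(-Inf, length(seqs), length(taxIds),
                 dimnames = list(names(seqs), taxIds))
  if (length(seqs) == 0L)
    return(matrix(numeric(0), 0, length(taxIds),
                  dimnames = list(NULL, taxIds)))
  strands <- list(seqs)
  if (bothStrands) strands <- c(strands, Biostrings::reverseComplement(seqs))
  w <- Biostrings::width(seqs)
  for (t in seq_along(taxIds)) {
    subject <- refSeqs(db)[[t]]
    for (s in strands) {
      ll <- alignmentLogLik(s, subject, pErr, minCoverage, w)
      logL[, t] <- pmax(logL[, t], ll)
    }
  }
  rowMax <- apply(logL, 1L, max)
  L <- exp(logL - ifelse(is.finite(rowMax), rowMax, 0))
  L[!is.finite(L)] <- 0
  L
}

# vectorized over reads: log-likelihood of each read under one subject
alignmentLogLik <- function(patterns, subject, pErr, minCoverage, w) {
  aln <- Biostrings::pairwiseAlignment(
    patterns, subject, type = "local",
    substitutionMatrix = EM_SUBST, gapOpening = 5, gapExtension = 2)
  pat <- Biostrings::pattern(aln)
  covered <- Biostrings::end(pat) - Biostrings::start(pat) + 1L  # span in read
  matches <- Biostrings::nmatch(aln)
  insLen <- vapply(Biostrings::width(
    Biostrings::insertion(aln)), sum, numeric(1))
  delLen <- vapply(Biostrings::width(
    Biostrings::deletion(aln)), sum, numeric(1))
  edits <- Biostrings::nmismatch(aln) + insLen + delLen
  ll <- edits * log(pErr) + matches * log(1 - pErr)
  ll[covered / w < minCoverage] <- -Inf
  ll
}

#' EM estimation of taxon proportions from a read-taxon likelihood matrix
#'
#' Standard mixture EM: initialize proportions uniformly over taxa with
#' any support; E-step \eqn{P(t\mid r) \propto f_t L_{rt}}; M-step
#' \eqn{f_t = } mean over reads of \eqn{P(t \mid r)}; iterate until the
#' largest proportion change is below \code{tol} or \code{maxIter} is
#' reached. Taxa below \code{minAbundance} are then dropped and the
#' profile renormalized; estimated reads are \eqn{f_t \cdot n}, with
#' \eqn{n} the number of reads with non-empty candidate sets. The
#' observed-data log-likelihood (up to per-read constants) is recorded
#' per iteration in \code{metadata(profile)$loglik} and is
#' non-decreasing.
#'
#' @param L numeric matrix from [scoreReads()] (rows = reads, columns =
#'   taxa, non-negative).
#' @param tol convergence threshold on the max abundance change
#'   (default 1e-6).
#' @param maxIter maximum EM iterations (default 100).
#' @param minAbundance reporting floor (default 1e-4).
#' @param sampleId sample id recorded in the profile.
#' @param species optional named character vector taxon id -> species
#'   name.
#' @return an [AbundanceProfile-class]; empty (but with
#'   \code{totalReads} recorded) when no read has a candidate taxon.
#' @export
emAbundance <- function(L, tol = 1e-6, maxIter = 100,
                        minAbundance = 1e-4, sampleId = "sample",
                        species = NULL) {
  stopifnot(tol > 0, maxIter >= 1)
  totalReads <- nrow(L)
  use <- rowSums(L) > 0
  Lu <- L[use, , drop = FALSE]
  emptyEntries <- data.frame(tax_id = character(), species = character(),
                             abundance = numeric(), est_reads = numeric())
  if (nrow(Lu) == 0L)
    return(abundanceProfile(sampleId, emptyEntries, totalReads,
                            metadata = list(loglik = numeric(0),
                                            nUsed = 0L, converged = TRUE)))
  support <- colSums(Lu) > 0
  Lu <- Lu[, support, drop = FALSE]
  nt <- ncol(Lu)
  n <- nrow(Lu)
  f <- rep(1 / nt, nt)
  loglik <- numeric(0)
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    post <- sweep(Lu, 2L, f, `*`)
    rs <- rowSums(post)
    loglik <- c(loglik, sum(log(rs)))
    post <- post / rs
    fNew <- colMeans(post)
    delta <- max(abs(fNew - f))
    f <- fNew
    if (delta < tol) { converged <- TRUE; break }
  }
  keep <- f >= minAbundance
  if (!any(keep)) keep <- f == max(f)
  f <- f[keep] / sum(f[keep])
  taxIds <- colnames(Lu)[keep]
  entries <- data.frame(
    tax_id = taxIds,
    species = if (is.null(species)) taxIds else unname(species[taxIds]),
    abundance = unname(f),
    est_reads = unname(f) * n,
    stringsAsFactors = FALSE)
  abundanceProfile(sampleId, entries, totalReads,
                   metadata = list(loglik = loglik, nUsed = n,
                                   iterations = length(loglik),
                                   converged = converged))
}

#' Annotate one demultiplexed sample
#'
#' Composition of [scoreReads()] and [emAbundance()]: reads (a FASTQ
#' path or a read set) are scored against the reference database and a
#' relative-abundance profile is estimated. Deterministic for fixed
#' input. Pooling replicate FASTQ files before annotation equals
#' annotating their concatenation (replicates are pooled prior to
#' annotation).
#'
#' @param reads FASTQ path, [Biostrings::QualityScaledDNAStringSet],
#'   [Biostrings::DNAStringSet] or named character vector.
#' @param db a [ReferenceDb-class].
#' @param sampleId sample id for the profile (default: derived from the
#'   file name when reads is a path).
#' @inheritParams scoreReads
#' @inheritParams emAbundance
#' @param outTsv optional path; when given the profile is also written
#'   with [writeAbundanceTsv()].
#' @return an [AbundanceProfile-class].
#' @export
annotateSample <- function(reads, db, sampleId = NULL, pErr = 0.1,
                           minCoverage = 0.8, bothStrands = TRUE,
                           tol = 1e-6, maxIter = 100,
                           minAbundance = 1e-4, outTsv = NULL) {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    if (is.null(sampleId))
      sampleId <- sub("\\.(fastq|fq)(\\.gz)?$", "", basename(reads))
    reads <- readFastq(reads)
  }
  if (is.null(sampleId)) sampleId <- "sample"
  L <- scoreReads(reads, db, pErr = pErr, minCoverage = minCoverage,
                  bothStrands = bothStrands)
  sp <- setNames(taxonomy(db)$species, taxonomy(db)$tax_id)
  profile <- emAbundance(L, tol = tol, maxIter = maxIter,
                         minAbundance = minAbundance,
                         sampleId = sampleId, species = sp)
  if (!is.null(outTsv)) writeAbundanceTsv(profile, outTsv)
  profile
}
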