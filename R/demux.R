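# PCR-barcode demultiplexing with trimming, 1BC and 2BC modes.
#
# Orientation and anchoring are primer-driven: the (possibly degenerate)
# forward primer is located by an ungapped IUPAC-aware scan; barcode
# calls are plain Hamming comparisons at the fixed 12-base windows
# flanking the primer hits. Indel tolerance is folded into primer
# localization (the anchor), keeping barcode calls O(#barcodes).

#' Locate a primer near the ends of a read
#'
#' Scans the first \code{searchWindow} bases for the primer in forward
#' orientation and the last \code{searchWindow} bases for its reverse
#' complement. Returns the lowest-mismatch ungapped IUPAC-aware hit with
#' at most \code{maxMismatch} mismatches; ties are broken by smaller
#' offset, and across orientations by the forward strand. Absence is a
#' value (\code{NULL}), not an error.
#'
#' @param read a character DNA string (A/C/G/T/N).
#' @param primer an IUPAC DNA string.
#' @param maxMismatch maximum mismatches tolerated (default 3).
#' @param searchWindow bases scanned at each end (default 100).
#' @return \code{NULL}, or a list with \code{offset} (1-based start),
#'   \code{end}, \code{strand} (\code{"+"} forward occurrence,
#'   \code{"-"} reverse-complement occurrence near the 3' end) and
#'   \code{mismatches}.
#' @export
locatePrimer <- function(read, primer, maxMismatch = 3,
                         searchWindow = 100) {
  L <- nchar(primer)
  n <- nchar(read)
  if (searchWindow < L || n < L) return(NULL)
  rc <- splitChars(read)
  scan <- function(patChars, offs) {
    if (length(offs) == 0L) return(NULL)
    mm <- iupacMismatchAt(rc, patChars, offs)
    best <- which(mm == min(mm))[1L]
    if (mm[best] > maxMismatch) return(NULL)
    list(offset = offs[best], end = offs[best] + L - 1L,
         mismatches = mm[best])
  }
  fwdOffs <- seq_len(min(searchWindow, n) - L + 1L)
  revStart <- max(1L, n - min(searchWindow, n) + 1L)
  revOffs <- seq.int(revStart, n - L + 1L)
  hitF <- scan(splitChars(primer), fwdOffs)
  hitR <- scan(splitChars(revComp(primer)), revOffs)
  if (!is.null(hitF)) hitF$strand <- "+"
  if (!is.null(hitR)) hitR$strand <- "-"
  if (is.null(hitF)) return(hitR)
  if (is.null(hitR)) return(hitF)
  if (hitR$mismatches < hitF$mismatches) hitR else hitF
}

# Hamming call of a 12-base window against a matrix of barcode chars.
# Returns list(status = ok|none|ambiguous, bc, mm, minSet)
callBarcode <- function(windowChars, bcChars, maxMismatch) {
  if (is.null(windowChars))
    return(list(status = "none", bc = NA_character_, mm = NA_integer_,
                minSet = character(0)))
  d <- vapply(seq_len(ncol(bcChars)), function(j)
    sum(bcChars[, j] != windowChars), integer(1))
  dmin <- min(d)
  if (dmin > maxMismatch)
    return(list(status = "none", bc = NA_character_, mm = dmin,
                minSet = character(0)))
  minSet <- colnames(bcChars)[d == dmin]
  if (length(minSet) > 1L)
    return(list(status = "ambiguous", bc = NA_character_, mm = dmin,
                minSet = minSet))
  list(status = "ok", bc = minSet, mm = dmin, minSet = minSet)
}

#' Demultiplex one read by its PCR barcode(s)
#'
#' The engine behind [demultiplexPool()]:
#' \enumerate{
#'   \item orient: find the forward primer on either strand; a
#'     reverse-strand read is replaced by its reverse complement
#'     (canonical forward orientation).
#'   \item require both the forward primer (near the 5' end) and the
#'     reverse primer (as reverse complement near the 3' end); else
#'     \code{no_primer}.
#'   \item score the 12 bases immediately 5' of the forward-primer hit
#'     against every scheme barcode (Hamming, at most
#'     \code{maxBcMismatch}); in 2BC mode also score the 12 bases
#'     immediately 3' of the reverse-primer hit against the reverse
#'     complement of every barcode. In 1BC mode the reverse barcode is
#'     not required but, when readable, must not contradict the forward
#'     call (\code{conflicting}; such reads are discarded -- purity over
#'     yield).
#'   \item exactly one minimal-distance barcode (pair) within tolerance
#'     is assigned via the scheme layout; equal-distance ties are
#'     \code{ambiguous}; none within tolerance is \code{no_barcode}. A
#'     valid pair absent from the layout is \code{no_barcode} with
#'     reason \code{not_in_layout}.
#'   \item the trimmed insert is the sequence strictly between the
#'     forward-primer end and the reverse-primer start (barcodes and
#'     primers removed), in canonical orientation.
#' }
#'
#' @param seq read sequence (character).
#' @param quals integer Phred vector (same length), or NULL.
#' @param scheme a [BarcodeScheme-class].
#' @param poolId native pool id (default: the scheme's only pool).
#' @param mode demultiplexing mode; defaults to the scheme's. 1BC-
#'   constructed reads can also be demultiplexed in 2BC mode.
#' @param maxBcMismatch barcode Hamming tolerance (default 2 of 12).
#' @param maxPrimerMismatch primer mismatch tolerance (default 3).
#' @param searchWindow primer search window (default 100).
#' @param readId read identifier carried into the result.
#' @return list with \code{read_id}, \code{status} (one of
#'   \code{assigned}, \code{no_primer}, \code{no_barcode},
#'   \code{ambiguous}, \code{conflicting}), \code{reason},
#'   \code{sample}, \code{fwd_bc}, \code{rev_bc}, \code{fwd_mm},
#'   \code{rev_mm}, and for assigned reads \code{trimmed} /
#'   \code{trimmedQuals}.
#' @export
demultiplexRead <- function(seq, quals = NULL, scheme,
                            poolId = NULL, mode = schemeMode(scheme),
                            maxBcMismatch = 2, maxPrimerMismatch = 3,
                            searchWindow = 100, readId = "read") {
  lay <- schemeLayout(scheme)
  if (is.null(poolId)) {
    poolId <- unique(lay$pool)
    if (length(poolId) != 1L)
      stop("demultiplexRead(): poolId required for multi-pool schemes")
  }
  lay <- lay[lay$pool == poolId, , drop = FALSE]
  pr <- primers(scheme)
  res <- list(read_id = readId, status = "no_primer", reason = NA_character_,
              sample = NA_character_, fwd_bc = NA_character_,
              rev_bc = NA_character_, fwd_mm = NA_integer_,
              rev_mm = NA_integer_, trimmed = NULL, trimmedQuals = NULL)

  hitF <- locatePrimer(seq, pr$fwd, maxPrimerMismatch, searchWindow)
  if (is.null(hitF)) { res$reason <- "fwd_primer_not_found"; return(res) }
  if (hitF$strand == "-") {            # canonicalize to forward strand
    seq <- revComp(seq)
    if (!is.null(quals)) quals <- rev(quals)
    hitF <- locatePrimer(seq, pr$fwd, maxPrimerMismatch, searchWindow)
    if (is.null(hitF) || hitF$strand != "+") {
      res$reason <- "fwd_primer_not_found"; return(res)
    }
  }
  hitR <- locatePrimer(seq, pr$rev, maxPrimerMismatch, searchWindow)
  if (is.null(hitR) || hitR$strand != "-") {
    res$reason <- "rev_primer_not_found"; return(res)
  }

  ch <- splitChars(seq)
  bcMat <- vapply(barcodes(scheme), splitChars,
                  character(BC_LENGTH))            # fwd windows
  bcMatRc <- vapply(vapply(barcodes(scheme), revComp, character(1)),
                    splitChars, character(BC_LENGTH))
  colnames(bcMat) <- colnames(bcMatRc) <- names(barcodes(scheme))

  fwdWin <- if (hitF$offset > BC_LENGTH)
    ch[(hitF$offset - BC_LENGTH):(hitF$offset - 1L)] else NULL
  revWin <- if (hitR$end + BC_LENGTH <= length(ch))
    ch[(hitR$end + 1L):(hitR$end + BC_LENGTH)] else NULL

  fwdCall <- callBarcode(fwdWin, bcMat, maxBcMismatch)
  res$fwd_mm <- fwdCall$mm
  if (fwdCall$status == "none") {
    res$status <- "no_barcode"; res$reason <- "fwd_bc_no_match"; return(res)
  }
  if (fwdCall$status == "ambiguous") {
    res$status <- "ambiguous"; res$reason <- "fwd_bc_tie"; return(res)
  }
  res$fwd_bc <- fwdCall$bc

  if (mode == "2BC") {
    revCall <- callBarcode(revWin, bcMatRc, maxBcMismatch)
    res$rev_mm <- revCall$mm
    if (revCall$status == "none") {
      res$status <- "no_barcode"; res$reason <- "rev_bc_no_match"; return(res)
    }
    if (revCall$status == "ambiguous") {
      res$status <- "ambiguous"; res$reason <- "rev_bc_tie"; return(res)
    }
    res$rev_bc <- revCall$bc
  } else {
    # 1BC: reverse barcode not required, but must not contradict
    revCall <- callBarcode(revWin, bcMatRc, maxBcMismatch)
    if (!is.null(revWin) && length(revCall$minSet) &&
        !fwdCall$bc %in% revCall$minSet) {
      res$rev_mm <- revCall$mm
      res$status <- "conflicting"; res$reason <- "rev_bc_contradicts"
      return(res)
    }
    if (identical(revCall$status, "ok") || fwdCall$bc %in% revCall$minSet)
      res$rev_mm <- revCall$mm
    res$rev_bc <- fwdCall$bc
  }

  row <- lay[lay$fwd_bc == res$fwd_bc & lay$rev_bc == res$rev_bc, ,
             drop = FALSE]
  if (nrow(row) == 0L) {
    res$status <- "no_barcode"; res$reason <- "not_in_layout"; return(res)
  }
  res$status <- "assigned"
  res$sample <- row$sample[1L]
  from <- hitF$end + 1L
  to <- hitR$offset - 1L
  if (from <= to) {
    res$trimmed <- substr(seq, from, to)
    if (!is.null(quals)) res$trimmedQuals <- quals[from:to]
  } else {
    res$trimmed <- ""
    res$trimmedQuals <- integer(0)
  }
  res
}

#' Demultiplex a native pool of reads by PCR barcode
#'
#' Applies [demultiplexRead()] to every read of one native pool,
#' returning the full assignment table (every input read appears exactly
#' once) and the trimmed, canonically oriented reads grouped by sample.
#' Optionally writes one FASTQ per sample plus the assignment TSV.
#'
#' @param reads a [Biostrings::QualityScaledDNAStringSet] (one native
#'   pool; typically the output of [filterReads()]).
#' @param scheme a [BarcodeScheme-class].
#' @param poolId native pool id (default: the scheme's only pool).
#' @param outDir if non-NULL, write \code{<sample>.fastq} files and
#'   \code{assignments.tsv} there.
#' @inheritParams demultiplexRead
#' @return list with \code{assignments} (data.frame) and \code{samples}
#'   (named list of [Biostrings::QualityScaledDNAStringSet], one per
#'   layout sample, possibly empty).
#' @examples
#' scheme <- makeScheme(seed = 1)
#' db <- makeReferenceDb(4, 1500, 0.1, seed = 1)
#' sim <- simulatePool(scheme, db, nPerSample = 3, seed = 1)
#' dm <- demultiplexPool(sim$reads, scheme)
#' table(dm$assignments$status)
#' @export
demultiplexPool <- function(reads, scheme, poolId = NULL, outDir = NULL,
                            mode = schemeMode(scheme), maxBcMismatch = 2,
                            maxPrimerMismatch = 3, searchWindow = 100) {
  lay <- schemeLayout(scheme)
  if (is.null(poolId)) {
    poolId <- unique(lay$pool)
    if (length(poolId) != 1L)
      stop("demultiplexPool(): poolId required for multi-pool schemes")
  }
  if (!poolId %in% lay$pool)
    stop("demultiplexPool(): scheme layout does not cover pool ", poolId)
  if (length(reads) == 0L)
    warning("demultiplexPool(): empty input for pool ", poolId)
  quals <- readQuals(reads)
  seqs <- as.character(reads)
  calls <- lapply(seq_along(reads), function(i)
    demultiplexRead(seqs[[i]], as.integer(quals[[i]]), scheme,
                    poolId = poolId, mode = mode,
                    maxBcMismatch = maxBcMismatch,
                    maxPrimerMismatch = maxPrimerMismatch,
                    searchWindow = searchWindow,
                    readId = names(reads)[i]))
  assignments <- do.call(rbind, c(list(emptyAssignments()), lapply(calls,
    function(x) data.frame(read_id = x$read_id, status = x$status,
                           sample = x$sample, fwd_bc = x$fwd_bc,
                           rev_bc = x$rev_bc, fwd_mm = x$fwd_mm,
                           rev_mm = x$rev_mm, reason = x$reason,
                           stringsAsFactors = FALSE))))
  samples <- lay$sample[lay$pool == poolId]
  out <- setNames(vector("list", length(samples)), samples)
  for (s in samples) {
    idx <- which(vapply(calls, function(x)
      identical(x$status, "assigned") && identical(x$sample, s), logical(1)))
    out[[s]] <- if (length(idx))
      makeReads(setNames(vapply(calls[idx], `[[`, character(1), "trimmed"),
                         vapply(calls[idx], `[[`, character(1), "read_id")),
                lapply(calls[idx], `[[`, "trimmedQuals"))
    else makeReads(setNames(character(0), character(0)), list())
  }
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    for (s in samples)
      writeFastq(out[[s]], file.path(outDir, paste0(s, ".fastq")))
    writeAssignmentsTsv(assignments, file.path(outDir, "assignments.tsv"))
  }
  list(assignments = assignments, samples = out)
}

emptyAssignments <- function() {
  data.frame(read_id = character(), status = character(),
             sample = character(), fwd_bc = character(),
             rev_bc = character(), fwd_mm = integer(),
             rev_mm = integer(), reason = character(),
             stringsAsFactors = FALSE)
}
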