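#' @include nanotax-package.R
NULL

BC_LENGTH <- 12L

#' BarcodeScheme: PCR barcodes, primer pair and pool layout
#'
#' Describes a dual-barcoding scheme for full-length 16S amplicons: a set
#' of 12-bp PCR barcodes (non-degenerate, A/C/G/T only), one primer pair
#' (possibly containing IUPAC degenerate bases), the barcoding mode
#' (\code{"1BC"}: identical barcode on forward and reverse primer;
#' \code{"2BC"}: independent forward/reverse barcodes enabling
#' combinatorial multiplexing), and a layout table mapping
#' (native pool, forward barcode, reverse barcode) to a sample id.
#' Native pools correspond to the per-flow-cell barcoding step and are
#' modeled as separate input files.
#'
#' @slot barcodes named character vector of 12-bp barcode sequences;
#'   names are barcode ids.
#' @slot primerName character scalar, e.g. \code{"A"}.
#' @slot fwdPrimer,revPrimer IUPAC DNA strings (degenerate bases allowed).
#' @slot mode \code{"1BC"} or \code{"2BC"}.
#' @slot layout data.frame with columns \code{pool}, \code{fwd_bc},
#'   \code{rev_bc}, \code{sample}.
#'
#' @seealso [makeScheme()], [readScheme()], [demultiplexPool()]
#' @export
setClass("BarcodeScheme",
  representation(
    barcodes   = "character",
    primerName = "character",
    fwdPrimer  = "character",
    revPrimer  = "character",
    mode       = "character",
    layout     = "data.frame"
  )
)

setValidity("BarcodeScheme", function(object) {
  msg <- character()
  bc <- object@barcodes
  if (length(bc) == 0L || is.null(names(bc)) || anyDuplicated(names(bc)))
    msg <- c(msg, "barcodes must be a non-empty named vector with unique ids")
  if (any(nchar(bc) != BC_LENGTH))
    msg <- c(msg, sprintf("all barcodes must be exactly %d bases", BC_LENGTH))
  if (any(grepl("[^ACGT]", bc)))
    msg <- c(msg, "barcodes must contain only A/C/G/T")
  if (!object@mode %in% c("1BC", "2BC"))
    msg <- c(msg, "mode must be '1BC' or '2BC'")
  for (p in c(object@fwdPrimer, object@revPrimer))
    if (!nzchar(p) || grepl(sprintf("[^%s]", IUPAC_LETTERS_RE), p))
      msg <- c(msg, "primers must be non-empty IUPAC DNA strings")
  lay <- object@layout
  need <- c("pool", "fwd_bc", "rev_bc", "sample")
  if (!all(need %in% names(lay))) {
    msg <- c(msg, "layout must have columns pool, fwd_bc, rev_bc, sample")
  } else if (nrow(lay) > 0L) {
    if (!all(c(lay$fwd_bc, lay$rev_bc) %in% names(bc)))
      msg <- c(msg, "layout references barcode ids absent from barcodes")
    if (object@mode == "1BC" && !all(lay$fwd_bc == lay$rev_bc))
      msg <- c(msg, "in 1BC mode every layout row must have fwd_bc == rev_bc")
    key <- paste(lay$pool, lay$fwd_bc, lay$rev_bc)
    if (anyDuplicated(key))
      msg <- c(msg, "barcode pairs must be distinct within each native pool")
    if (anyDuplicated(paste(lay$pool, lay$sample)))
      msg <- c(msg, "sample ids must be unique within a pool")
  }
  if (length(msg)) msg else TRUE
})

#' ReferenceDb: full-length 16S reference sequences with taxonomy
#'
#' @slot seqs [Biostrings::DNAStringSet] named by taxon id.
#' @slot taxonomy data.frame with columns \code{tax_id}, \code{species},
#'   \code{lineage} (semicolon-separated ranks).
#' @slot lengthRange numeric length-2; plausible 16S length window used
#'   by the validity check (default 1200--1900 bp; configurable because
#'   test databases may be shorter).
#'
#' @seealso [makeReferenceDb()], [readReferenceDb()], [scoreReads()]
#' @export
setClass("ReferenceDb",
  representation(
    seqs        = "DNAStringSet",
    taxonomy    = "data.frame",
    lengthRange = "numeric"
  )
)

setValidity("ReferenceDb", function(object) {
  msg <- character()
  ids <- object@taxonomy$tax_id
  if (is.null(ids) || anyDuplicated(ids))
    msg <- c(msg, "taxonomy$tax_id must exist and be unique")
  if (!identical(as.character(names(object@seqs)), as.character(ids)))
    msg <- c(msg, "names(seqs) must equal taxonomy$tax_id, in order")
  lr <- object@lengthRange
  if (length(lr) != 2L || lr[1] > lr[2])
    msg <- c(msg, "lengthRange must be c(min, max)")
  else if (length(object@seqs) &&
           (min(Biostrings::width(object@seqs)) < lr[1] ||
            max(Biostrings::width(object@seqs)) > lr[2]))
    msg <- c(msg, "reference sequence lengths outside lengthRange")
  if (length(msg)) msg else TRUE
})

#' ErrorModel: per-base read error model for the simulator
#'
#' Substitutions, insertions and deletions are independent per-base
#' Bernoulli events; quality strings are drawn from a clipped normal and
#' are not correlated with the introduced errors (a documented
#' simplification: the quality filter only needs the marginal Q
#' distribution). \code{flipProb} is the probability that a read is
#' emitted reverse-complemented; \code{chimeraRate} (default 0) emits a
#' read whose second half comes from a different amplicon, for
#' adversarial demultiplexing fixtures.
#'
#' @slot sub,ins,del per-base error fractions in [0,1), summing to < 1.
#' @slot meanQuality,qualitySd parameters of the per-base Phred
#'   distribution (clipped to [1, 50]).
#' @slot flipProb probability of reverse-strand emission.
#' @slot chimeraRate probability a read is a two-template chimera.
#'
#' @seealso [errorModel()], [simulateReads()]
#' @export
setClass("ErrorModel",
  representation(
    sub         = "numeric",
    ins         = "numeric",
    del         = "numeric",
    meanQuality = "numeric",
    qualitySd   = "numeric",
    flipProb    = "numeric",
    chimeraRate = "numeric"
  )
)

setValidity("ErrorModel", function(object) {
  msg <- character()
  r <- c(object@sub, object@ins, object@del)
  if (any(r < 0) || any(r >= 1)) msg <- c(msg, "rates must be in [0,1)")
  if (sum(r) >= 1) msg <- c(msg, "sub + ins + del must be < 1")
  if (object@flipProb < 0 || object@flipProb > 1)
    msg <- c(msg, "flipProb must be in [0,1]")
  if (object@chimeraRate < 0 || object@chimeraRate > 1)
    msg <- c(msg, "chimeraRate must be in [0,1]")
  if (object@qualitySd < 0) msg <- c(msg, "qualitySd must be >= 0")
  if (length(msg)) msg else TRUE
})

#' AbundanceProfile: per-sample relative species abundances
#'
#' The profiler output for one sample: for each detected taxon its
#' relative abundance (fractions summing to 1) and the estimated number
#' of reads attributed to it. \code{totalReads} records the number of
#' input reads, including reads that could not be scored against any
#' reference.
#'
#' @slot sampleId character scalar.
#' @slot entries data.frame with columns \code{tax_id}, \code{species},
#'   \code{abundance}, \code{est_reads}, ordered by decreasing abundance.
#' @slot totalReads integer scalar.
#' @slot metadata free-form list (EM trace, convergence info, ...).
#'
#' @seealso [emAbundance()], [annotateSample()], [readAbundanceTsv()]
#' @export
setClass("AbundanceProfile",
  representation(
    sampleId   = "character",
    entries    = "data.frame",
    totalReads = "integer",
    metadata   = "list"
  )
)

setValidity("AbundanceProfile", function(object) {
  msg <- character()
  e <- object@entries
  need <- c("tax_id", "species", "abundance", "est_reads")
  if (!all(need %in% names(e)))
    msg <- c(msg, "entries must have columns tax_id, species, abundance, est_reads")
  else if (nrow(e) > 0L) {
    if (any(e$abundance < 0 | e$abundance > 1))
      msg <- c(msg, "abundances must be in [0,1]")
    if (abs(sum(e$abundance) - 1) > 1e-9)
      msg <- c(msg, "abundances must sum to 1 (tolerance 1e-9)")
    if (any(e$est_reads < 0)) msg <- c(msg, "est_reads must be non-negative")
    if (anyDuplicated(e$tax_id)) msg <- c(msg, "duplicate tax_id in entries")
  }
  if (length(object@totalReads) != 1L || object@totalReads < 0L)
    msg <- c(msg, "totalReads must be a single non-negative integer")
  if (length(msg)) msg else TRUE
})

#' ReadBin: a greedy-clustering read bin with its centroid
#'
#' @slot binId character scalar.
#' @slot centroid the centroid sequence (a member of the bin).
#' @slot members [Biostrings::DNAStringSet] of member reads.
#'
#' @seealso [greedyCluster()], [consensusSequence()]
#' @export
setClass("ReadBin",
  representation(
    binId    = "character",
    centroid = "character",
    members  = "DNAStringSet"
  )
)

setValidity("ReadBin", function(object) {
  msg <- character()
  if (length(object@members) < 1L) msg <- c(msg, "bin must have >= 1 member")
  if (!object@centroid %in% as.character(object@members))
    msg <- c(msg, "centroid must be a member of the bin")
  if (length(msg)) msg else TRUE
})
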