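# Accessors, constructors and show() methods for the S4 classes.

#' @rdname BarcodeScheme-class
#' @param object,x a \code{BarcodeScheme}.
#' @export
setGeneric("barcodes", function(x) standardGeneric("barcodes"))
#' @rdname BarcodeScheme-class
#' @export
setMethod("barcodes", "BarcodeScheme", function(x) x@barcodes)

#' @rdname BarcodeScheme-class
#' @export
setGeneric("schemeLayout", function(x) standardGeneric("schemeLayout"))
#' @rdname BarcodeScheme-class
#' @export
setMethod("schemeLayout", "BarcodeScheme", function(x) x@layout)

#' @rdname BarcodeScheme-class
#' @export
setGeneric("schemeMode", function(x) standardGeneric("schemeMode"))
#' @rdname BarcodeScheme-class
#' @export
setMethod("schemeMode", "BarcodeScheme", function(x) x@mode)

#' @rdname BarcodeScheme-class
#' @export
setGeneric("primers", function(x) standardGeneric("primers"))
#' @rdname BarcodeScheme-class
#' @export
setMethod("primers", "BarcodeScheme", function(x)
  list(name = x@primerName, fwd = x@fwdPrimer, rev = x@revPrimer))

setMethod("show", "BarcodeScheme", function(object) {
  lay <- object@layout
  cat(sprintf("BarcodeScheme (%s): %d barcodes, primer pair '%s'\n",
              object@mode, length(object@barcodes), object@primerName))
  cat(sprintf("  fwd: %s\n  rev: %s\n", object@fwdPrimer, object@revPrimer))
  cat(sprintf("  layout: %d samples in %d pool(s)\n",
              nrow(lay), length(unique(lay$pool))))
})

#' @rdname ReferenceDb-class
#' @param object,x a \code{ReferenceDb}.
#' @export
setGeneric("refSeqs", function(x) standardGeneric("refSeqs"))
#' @rdname ReferenceDb-class
#' @export
setMethod("refSeqs", "ReferenceDb", function(x) x@seqs)

#' @rdname ReferenceDb-class
#' @export
setGeneric("taxonomy", function(x) standardGeneric("taxonomy"))
#' @rdname ReferenceDb-class
#' @export
setMethod("taxonomy", "ReferenceDb", function(x) x@taxonomy)

setMethod("show", "ReferenceDb", function(object) {
  w <- Biostrings::width(object@seqs)
  cat(sprintf("ReferenceDb: %d taxa, lengths %d-%d bp\n",
              length(object@seqs),
              if (length(w)) min(w) else 0L, if (length(w)) max(w) else 0L))
})

setMethod("length", "ReferenceDb", function(x) length(x@seqs))

#' Construct an ErrorModel
#'
#' @param sub,ins,del per-base substitution/insertion/deletion rates.
#' @param meanQuality,qualitySd per-base Phred distribution parameters.
#' @param flipProb probability a read is emitted reverse-complemented.
#' @param chimeraRate probability of a two-template chimeric read.
#' @return an [ErrorModel-class].
#' @examples
#' errorModel(sub = 0.02, ins = 0.02, del = 0.02)
#' @export
errorModel <- function(sub = 0, ins = 0, del = 0, meanQuality = 14,
                       qualitySd = 3, flipProb = 0.5, chimeraRate = 0) {
  methods::new("ErrorModel", sub = sub, ins = ins, del = del,
               meanQuality = meanQuality, qualitySd = qualitySd,
               flipProb = flipProb, chimeraRate = chimeraRate)
}

setMethod("show", "ErrorModel", function(object) {
  cat(sprintf(
    "ErrorModel: sub=%.4g ins=%.4g del=%.4g  Q~N(%.3g,%.3g)  flip=%.3g chimera=%.3g\n",
    object@sub, object@ins, object@del, object@meanQuality,
    object@qualitySd, object@flipProb, object@chimeraRate))
})

#' Construct an AbundanceProfile
#'
#' @param sampleId sample identifier.
#' @param entries data.frame with \code{tax_id}, \code{abundance},
#'   \code{est_reads} and optionally \code{species}.
#' @param totalReads total input reads for the sample.
#' @param metadata free-form list.
#' @return an [AbundanceProfile-class].
#' @export
abundanceProfile <- function(sampleId, entries, totalReads,
                             metadata = list()) {
  if (is.null(entries$species)) entries$species <- entries$tax_id
  entries <- entries[order(-entries$abundance, entries$tax_id), , drop = FALSE]
  rownames(entries) <- NULL
  methods::new("AbundanceProfile", sampleId = as.character(sampleId),
               entries = entries[, c("tax_id", "species", "abundance",
                                     "est_reads")],
               totalReads = as.integer(totalReads), metadata = metadata)
}

#' @rdname AbundanceProfile-class
#' @param object,x an \code{AbundanceProfile}.
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))
#' @rdname AbundanceProfile-class
#' @export
setMethod("sampleId", "AbundanceProfile", function(x) x@sampleId)

#' @rdname AbundanceProfile-class
#' @export
setGeneric("totalReads", function(x) standardGeneric("totalReads"))
#' @rdname AbundanceProfile-class
#' @export
setMethod("totalReads", "AbundanceProfile", function(x) x@totalReads)

#' @rdname AbundanceProfile-class
#' @export
setGeneric("abundances", function(x) standardGeneric("abundances"))
#' @rdname AbundanceProfile-class
#' @export
setMethod("abundances", "AbundanceProfile", function(x) x@entries)

#' Abundance vector over a taxon universe
#'
#' Named numeric vector of relative abundances, optionally expanded to a
#' caller-supplied taxon universe (missing taxa get 0).
#'
#' @param x an [AbundanceProfile-class].
#' @param universe optional character vector of taxon ids.
#' @return named numeric vector.
#' @export
abundanceVector <- function(x, universe = NULL) {
  e <- abundances(x)
  v <- setNames(e$abundance, e$tax_id)
  if (is.null(universe)) return(v)
  out <- setNames(numeric(length(universe)), universe)
  out[intersect(names(v), universe)] <- v[intersect(names(v), universe)]
  out
}

setMethod("show", "AbundanceProfile", function(object) {
  cat(sprintf("AbundanceProfile '%s': %d taxa, %d reads\n",
              object@sampleId, nrow(object@entries), object@totalReads))
  if (nrow(object@entries))
    print(head(object@entries, 5))
})

#' @rdname ReadBin-class
#' @param object,x a \code{ReadBin}.
#' @export
setGeneric("binId", function(x) standardGeneric("binId"))
#' @rdname ReadBin-class
#' @export
setMethod("binId", "ReadBin", function(x) x@binId)

#' @rdname ReadBin-class
#' @export
setGeneric("binCentroid", function(x) standardGeneric("binCentroid"))
#' @rdname ReadBin-class
#' @export
setMethod("binCentroid", "ReadBin", function(x) x@centroid)

#' @rdname ReadBin-class
#' @export
setGeneric("binMembers", function(x) standardGeneric("binMembers"))
#' @rdname ReadBin-class
#' @export
setMethod("binMembers", "ReadBin", function(x) x@members)

#' @rdname ReadBin-class
#' @export
setGeneric("binSize", function(x) standardGeneric("binSize"))
#' @rdname ReadBin-class
#' @export
setMethod("binSize", "ReadBin", function(x) length(x@members))

setMethod("show", "ReadBin", function(object) {
  cat(sprintf("ReadBin '%s': %d reads, centroid %d bp\n",
              object@binId, length(object@members), nchar(object@centroid)))
})
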