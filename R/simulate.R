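# Synthetic-data generator: reference databases, barcode schemes and
# barcoded amplicon reads with a ground-truth sidecar.
#
# The read layout emulates a dual-barcoded full-length 16S amplicon:
#   [fwd barcode][fwd primer][16S insert][revComp(rev primer)][revComp(rev barcode)]
# at ~1.6 kb with 12-bp barcodes and ~20-bp primers.

# run `expr` under a temporary RNG state seeded with `seed`
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", globalenv())
  on.exit(if (has) assign(".Random.seed", old, globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

randomDna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                               collapse = "")

#' Generate a synthetic 16S-like reference database
#'
#' One random ancestor sequence; each taxon is derived by independent
#' per-site substitution at rate \code{divergence}. Deterministic given
#' \code{seed}.
#'
#' @param nTaxa number of taxa (>= 1).
#' @param seqLength template length in bp (default 1500, a full-length
#'   16S gene).
#' @param divergence per-site substitution probability from the ancestor,
#'   in (0, 0.5].
#' @param seed integer seed (optional).
#' @param lengthRange validity window passed to [ReferenceDb-class].
#' @return a [ReferenceDb-class].
#' @examples
#' db <- makeReferenceDb(4, seqLength = 1500, divergence = 0.1, seed = 1)
#' @export
makeReferenceDb <- function(nTaxa, seqLength = 1500, divergence = 0.1,
                            seed = NULL,
                            lengthRange = c(min(1200, seqLength), 1900)) {
  stopifnot(nTaxa >= 1, seqLength >= 1)
  if (divergence <= 0 || divergence > 0.5)
    stop("makeReferenceDb(): divergence must be in (0, 0.5]")
  withSeed(seed, {
    anc <- splitChars(randomDna(seqLength))
    seqs <- vapply(seq_len(nTaxa), function(i) {
      s <- anc
      hit <- runif(seqLength) < divergence
      if (any(hit))
        s[hit] <- vapply(s[hit], function(b)
          sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
      paste(s, collapse = "")
    }, character(1))
    ids <- sprintf("tax%02d", seq_len(nTaxa))
    tax <- data.frame(
      tax_id = ids,
      species = sprintf("Synthetica species%02d", seq_len(nTaxa)),
      lineage = sprintf(
        "Bacteria;SynthPhylum;SynthClass;SynthOrder;SynthFamily;Synthetica;species%02d",
        seq_len(nTaxa)),
      stringsAsFactors = FALSE)
    methods::new("ReferenceDb",
                 seqs = Biostrings::DNAStringSet(setNames(seqs, ids)),
                 taxonomy = tax, lengthRange = lengthRange)
  })
}

#' Generate random 12-bp barcodes with a minimum pairwise distance
#'
#' Rejection sampling keeps candidates whose Hamming distance to every
#' accepted barcode is at least \code{minHamming} (default 6, at which
#' the demultiplexer's default tolerance of 2 mismatches cannot collide).
#'
#' @param n number of barcodes.
#' @param minHamming minimum pairwise Hamming distance.
#' @param seed integer seed (optional).
#' @return named character vector (ids \code{bc01}, \code{bc02}, ...).
#' @export
makeBarcodes <- function(n = 8, minHamming = 6, seed = NULL) {
  withSeed(seed, {
    out <- character(0)
    tries <- 0L
    while (length(out) < n) {
      cand <- randomDna(BC_LENGTH)
      ok <- all(vapply(out, function(b)
        sum(splitChars(b) != splitChars(cand)) >= minHamming, logical(1)))
      if (ok) out <- c(out, cand)
      tries <- tries + 1L
      if (tries > 10000L) stop("makeBarcodes(): cannot satisfy minHamming")
    }
    setNames(out, sprintf("bc%02d", seq_len(n)))
  })
}

#' Default full-length 16S primer pair
#'
#' The canonical 27F/1492R full-length 16S primers, both carrying IUPAC
#' degenerate bases (cf. degenerate primer sets used to reduce
#' amplification bias).
#'
#' @return list with \code{name}, \code{fwd}, \code{rev}.
#' @export
defaultPrimers <- function() {
  list(name = "A",
       fwd = "AGRGTTYGATYMTGGCTCAG",   # 27F
       rev = "RGYTACCTTGTTACGACTT")    # 1492R
}

#' Build a BarcodeScheme with an auto-generated layout
#'
#' One sample per barcode per pool. In 1BC mode sample \emph{i} uses
#' barcode \emph{i} on both primers; in 2BC mode sample \emph{i} uses
#' forward barcode \emph{i} and reverse barcode \emph{i+1} (cyclic), so
#' all pairs within a pool are distinct.
#'
#' @param barcodes named character vector (see [makeBarcodes()]), or
#'   NULL to generate \code{nBarcodes} fresh ones.
#' @param mode \code{"1BC"} or \code{"2BC"}.
#' @param pools character vector of native pool ids.
#' @param primers list with \code{name}, \code{fwd}, \code{rev}.
#' @param nBarcodes,seed used when \code{barcodes} is NULL.
#' @return a [BarcodeScheme-class].
#' @examples
#' scheme <- makeScheme(mode = "2BC", seed = 7)
#' schemeLayout(scheme)
#' @export
makeScheme <- function(barcodes = NULL, mode = c("2BC", "1BC"),
                       pools = "pool1", primers = defaultPrimers(),
                       nBarcodes = 8, seed = NULL) {
  mode <- match.arg(mode)
  if (is.null(barcodes)) barcodes <- makeBarcodes(nBarcodes, seed = seed)
  n <- length(barcodes)
  ids <- names(barcodes)
  lay <- do.call(rbind, lapply(pools, function(p) {
    data.frame(pool = p, fwd_bc = ids,
               rev_bc = if (mode == "1BC") ids else ids[c(2:n, 1L)],
               sample = sprintf("%s_s%02d", p, seq_len(n)),
               stringsAsFactors = FALSE)
  }))
  methods::new("BarcodeScheme", barcodes = barcodes,
               primerName = primers$name, fwdPrimer = primers$fwd,
               revPrimer = primers$rev, mode = mode, layout = lay)
}

# one concrete base per degenerate position, sampled uniformly from the
# encoded set (emulates which template variant a degenerate primer bound)
resolvePrimer <- function(primer) {
  ch <- splitChars(primer)
  deg <- !ch %in% c("A", "C", "G", "T")
  if (any(deg))
    ch[deg] <- vapply(IUPAC_SETS[ch[deg]], function(s) sample(s, 1L),
                      character(1))
  paste(ch, collapse = "")
}

#' Assemble one barcoded amplicon sequence
#'
#' \code{assembleAmplicon()} concatenates literal parts:
#' \code{fwdBc + fwdPrimer + insert + revComp(revPrimer) + revComp(revBc)},
#' resolving each degenerate primer position to one concrete base
#' (seeded). \code{constructAmplicon()} looks barcode ids up in a
#' [BarcodeScheme-class] (error if unknown) and uses its primer pair.
#'
#' @param insert template sequence (for synthetic templates, the whole
#'   reference sequence).
#' @param fwdBc,revBc barcode sequences (may be \code{""}).
#' @param fwdPrimer,revPrimer primer sequences (may be \code{""}).
#' @param seed integer seed for degenerate-base resolution (optional).
#' @return a character scalar (the amplicon).
#' @export
assembleAmplicon <- function(insert, fwdBc = "", revBc = "",
                             fwdPrimer = "", revPrimer = "", seed = NULL) {
  withSeed(seed, {
    paste0(fwdBc,
           if (nzchar(fwdPrimer)) resolvePrimer(fwdPrimer) else "",
           insert,
           if (nzchar(revPrimer)) revComp(resolvePrimer(revPrimer)) else "",
           revComp(revBc))
  })
}

#' @param template a character sequence, or a [ReferenceDb-class]
#'   together with \code{taxId}.
#' @param scheme a [BarcodeScheme-class].
#' @param fwdBcId,revBcId barcode ids present in the scheme.
#' @param taxId taxon id when \code{template} is a ReferenceDb.
#' @rdname assembleAmplicon
#' @export
constructAmplicon <- function(template, scheme, fwdBcId, revBcId,
                              taxId = NULL, seed = NULL) {
  if (methods::is(template, "ReferenceDb")) {
    if (is.null(taxId) || !taxId %in% names(refSeqs(template)))
      stop("constructAmplicon(): unknown taxId")
    template <- as.character(refSeqs(template)[[taxId]])
  }
  bc <- barcodes(scheme)
  if (!all(c(fwdBcId, revBcId) %in% names(bc)))
    stop("constructAmplicon(): unknown barcode id")
  pr <- primers(scheme)
  assembleAmplicon(template, fwdBc = bc[[fwdBcId]], revBc = bc[[revBcId]],
                   fwdPrimer = pr$fwd, revPrimer = pr$rev, seed = seed)
}

# apply the per-base error process to one sequence:
# per position choose delete / substitute / keep, then insert after each
# retained base with prob ins (simple and rate-faithful at small rates)
mutateSequence <- function(seq, sub, ins, del) {
  ch <- splitChars(seq)
  n <- length(ch)
  u <- runif(n)
  keep <- u >= del
  subs <- keep & u < del + sub
  if (any(subs))
    ch[subs] <- vapply(ch[subs], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
  ch <- ch[keep]
  if (ins > 0 && length(ch)) {
    insHit <- runif(length(ch)) < ins
    if (any(insHit)) {
      extra <- character(length(ch))
      extra[insHit] <- sample(c("A", "C", "G", "T"), sum(insHit), TRUE)
      ch <- as.vector(rbind(ch, extra))
      ch <- ch[nzchar(ch)]
    }
  }
  paste(ch, collapse = "")
}

#' Simulate nanopore-style reads from labeled amplicons
#'
#' Each read copies its amplicon, applies per-base deletion/substitution
#' and between-base insertion at the model rates, is emitted
#' reverse-complemented with probability \code{flipProb}, and receives
#' per-base qualities drawn from Normal(meanQuality, qualitySd) clipped
#' to [1, 50] (independent of the introduced errors). Fully
#' deterministic given \code{seed}.
#'
#' @param amplicons named character vector of amplicon sequences (one
#'   per sample; names are sample ids).
#' @param labels data.frame aligned with \code{amplicons}, columns
#'   \code{native_pool}, \code{sample}, \code{taxon}.
#' @param nReadsPerSample integer scalar or vector (recycled).
#' @param model an [ErrorModel-class].
#' @param seed integer seed (optional).
#' @param idPrefix prefix for generated read ids.
#' @return list with \code{reads}
#'   ([Biostrings::QualityScaledDNAStringSet]) and \code{truth}
#'   (data.frame \code{read_id}, \code{native_pool}, \code{sample},
#'   \code{taxon}, \code{strand}).
#' @seealso [simulatePool()] for the scheme-driven wrapper.
#' @export
simulateReads <- function(amplicons, labels, nReadsPerSample,
                          model = errorModel(), seed = NULL,
                          idPrefix = "read") {
  stopifnot(length(amplicons) == nrow(labels), all(nReadsPerSample >= 0))
  nPer <- rep_len(as.integer(nReadsPerSample), length(amplicons))
  withSeed(seed, {
    total <- sum(nPer)
    seqs <- character(total)
    quals <- vector("list", total)
    truth <- data.frame(read_id = character(total),
                        native_pool = character(total),
                        sample = character(total),
                        taxon = character(total),
                        strand = character(total),
                        stringsAsFactors = FALSE)
    k <- 0L
    for (i in seq_along(amplicons)) {
      for (j in seq_len(nPer[i])) {
        k <- k + 1L
        src <- amplicons[[i]]
        if (model@chimeraRate > 0 && length(amplicons) > 1L &&
            runif(1) < model@chimeraRate) {
          other <- amplicons[[sample(setdiff(seq_along(amplicons), i), 1L)]]
          cut <- sample(seq_len(nchar(src) - 1L), 1L)
          src <- paste0(substr(src, 1L, cut),
                        substr(other, cut + 1L, nchar(other)))
        }
        s <- mutateSequence(src, model@sub, model@ins, model@del)
        strand <- "+"
        if (runif(1) < model@flipProb) {
          s <- revComp(s)
          strand <- "-"
        }
        q <- pmin(50L, pmax(1L, as.integer(round(
          rnorm(nchar(s), model@meanQuality, model@qualitySd)))))
        seqs[k] <- s
        quals[[k]] <- q
        truth[k, ] <- list(sprintf("%s%06d", idPrefix, k),
                           labels$native_pool[i], labels$sample[i],
                           labels$taxon[i], strand)
      }
    }
    keep <- nzchar(seqs[seq_len(k)])
    reads <- makeReads(setNames(seqs[seq_len(k)][keep],
                                truth$read_id[seq_len(k)][keep]),
                       quals[seq_len(k)][keep])
    list(reads = reads, truth = truth[seq_len(k)[keep], , drop = FALSE])
  })
}

#' Simulate a full barcoded pool from a scheme and reference database
#'
#' Assigns each layout sample a taxon (round-robin over the database
#' unless \code{taxonAssignment} maps sample ids to taxon ids), builds
#' its barcoded amplicon, and simulates reads.
#'
#' @param scheme a [BarcodeScheme-class].
#' @param db a [ReferenceDb-class].
#' @param nPerSample reads per sample.
#' @param model an [ErrorModel-class].
#' @param seed integer seed.
#' @param pools subset of native pools to simulate (default: all).
#' @param taxonAssignment optional named character vector
#'   sample id -> taxon id.
#' @return as [simulateReads()], plus \code{amplicons}.
#' @examples
#' scheme <- makeScheme(seed = 7)
#' db <- makeReferenceDb(4, 1500, 0.1, seed = 7)
#' sim <- simulatePool(scheme, db, nPerSample = 5,
#'                     model = errorModel(), seed = 7)
#' @export
simulatePool <- function(scheme, db, nPerSample, model = errorModel(),
                         seed = NULL, pools = NULL,
                         taxonAssignment = NULL) {
  lay <- schemeLayout(scheme)
  if (!is.null(pools)) lay <- lay[lay$pool %in% pools, , drop = FALSE]
  if (nrow(lay) == 0L) stop("simulatePool(): empty layout selection")
  taxIds <- names(refSeqs(db))
  if (is.null(taxonAssignment))
    taxonAssignment <- setNames(rep_len(taxIds, nrow(lay)), lay$sample)
  withSeed(seed, {
    amplicons <- vapply(seq_len(nrow(lay)), function(i)
      constructAmplicon(db, scheme, lay$fwd_bc[i], lay$rev_bc[i],
                        taxId = taxonAssignment[[lay$sample[i]]]),
      character(1))
    labels <- data.frame(native_pool = lay$pool, sample = lay$sample,
                         taxon = unname(taxonAssignment[lay$sample]),
                         stringsAsFactors = FALSE)
    sim <- simulateReads(setNames(amplicons, lay$sample), labels,
                         nPerSample, model)
    sim$amplicons <- setNames(amplicons, lay$sample)
    sim
  })
}

#' Simulate an unbarcoded taxon mixture (profiler test bed)
#'
#' Draws reads directly from reference templates (no barcodes/primers;
#' the analogue of demultiplexed, trimmed inserts) at exact per-taxon
#' counts \code{round(nReads * proportions)}, so the realized
#' composition is the stated one.
#'
#' @param db a [ReferenceDb-class].
#' @param proportions named numeric vector over taxon ids, summing to 1.
#' @param nReads total read count.
#' @param model an [ErrorModel-class].
#' @param seed integer seed.
#' @return as [simulateReads()].
#' @export
simulateMixture <- function(db, proportions, nReads,
                            model = errorModel(), seed = NULL) {
  stopifnot(abs(sum(proportions) - 1) < 1e-9,
            all(names(proportions) %in% names(refSeqs(db))))
  counts <- round(nReads * proportions)
  labels <- data.frame(native_pool = "mix", sample = "mix",
                       taxon = names(proportions), stringsAsFactors = FALSE)
  simulateReads(
    setNames(vapply(names(proportions),
                    function(t) as.character(refSeqs(db)[[t]]), character(1)),
             names(proportions)),
    labels, counts, model, seed = seed)
}
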