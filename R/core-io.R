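#' Read a FASTQ file into a QualityScaledDNAStringSet
#'
#' Sanger (Phred+33) encoding only. Parsing is delegated to
#' \pkg{Biostrings}; on a malformed file a quick diagnostic pass
#' identifies the offending record so the error names its index.
#'
#' @param path path to a FASTQ file (gzip accepted).
#' @return a [Biostrings::QualityScaledDNAStringSet]; names are read ids.
#' @seealso [writeFastq()]
#' @export
readFastq <- function(path) {
  if (!file.exists(path)) stop("readFastq(): no such file: ", path)
  x <- tryCatch({
    # the parser emits a cosmetic note about dropping its internal
    # quality metadata column; nothing user-facing is lost
    out <- withCallingHandlers(
      Biostrings::readQualityScaledDNAStringSet(path),
      warning = function(w) {
        if (grepl("metadata columns", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    q <- as(Biostrings::quality(out), "IntegerList")
    # a truncated quality line is nul-padded by the parser: decoded
    # scores fall outside the legal Phred range [0, 93]
    bad <- which(Biostrings::width(out) != lengths(q) |
                 vapply(q, function(v) length(v) > 0 &&
                        (min(v) < 0 || max(v) > 93), logical(1)))
    if (length(bad))
      stop(sprintf("sequence/quality length mismatch in record %d", bad[1]))
    out
  },
    error = function(e) {
      idx <- diagnoseFastq(path)
      if (!is.na(idx))
        stop(sprintf("readFastq(): malformed FASTQ record %d in %s (%s)",
                     idx, path, conditionMessage(e)), call. = FALSE)
      stop("readFastq(): failed to parse ", path, ": ",
           conditionMessage(e), call. = FALSE)
    }
  )
  x
}

# locate the first malformed 4-line record (NA if none found)
diagnoseFastq <- function(path) {
  lines <- tryCatch(readLines(path, warn = FALSE), error = function(e) character())
  n <- length(lines) %/% 4L
  if (length(lines) %% 4L != 0L) return(n + 1L)
  for (i in seq_len(n)) {
    b <- lines[(i - 1L) * 4L + 1:4]
    if (!startsWith(b[1], "@") || !startsWith(b[3], "+") ||
        nchar(b[2]) != nchar(b[4]) || nchar(b[2]) == 0L)
      return(i)
  }
  NA_integer_
}

#' Write reads to FASTQ (Phred+33)
#'
#' @param reads a [Biostrings::QualityScaledDNAStringSet].
#' @param path output path (".gz" suffix triggers gzip).
#' @return invisibly, `path`.
#' @export
writeFastq <- function(reads, path) {
  Biostrings::writeQualityScaledXStringSet(
    reads, path, compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read / write FASTA
#'
#' Thin wrappers over \pkg{Biostrings} kept for a uniform I/O surface.
#'
#' @param path file path.
#' @return `readFasta()`: a [Biostrings::DNAStringSet].
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) stop("readFasta(): no such file: ", path)
  Biostrings::readDNAStringSet(path)
}

#' @param seqs a [Biostrings::DNAStringSet] or named character vector.
#' @rdname readFasta
#' @export
writeFasta <- function(seqs, path) {
  if (!methods::is(seqs, "DNAStringSet"))
    seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path, compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read a reference database (FASTA + taxonomy TSV)
#'
#' The taxonomy TSV has columns \code{tax_id}, \code{species},
#' \code{lineage}; FASTA record names must start with the taxon id.
#'
#' @param fastaPath,taxPath input paths.
#' @param lengthRange plausible sequence-length window (validity check).
#' @return a [ReferenceDb-class].
#' @export
readReferenceDb <- function(fastaPath, taxPath, lengthRange = c(1200, 1900)) {
  seqs <- readFasta(fastaPath)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  tax <- read.delim(taxPath, stringsAsFactors = FALSE)
  if (!all(c("tax_id", "species", "lineage") %in% names(tax)))
    stop("readReferenceDb(): taxonomy TSV needs tax_id, species, lineage")
  if (!setequal(names(seqs), tax$tax_id))
    stop("readReferenceDb(): FASTA ids and taxonomy tax_ids disagree")
  seqs <- seqs[tax$tax_id]
  methods::new("ReferenceDb", seqs = seqs, taxonomy = tax,
               lengthRange = lengthRange)
}

#' @param db a [ReferenceDb-class].
#' @rdname readReferenceDb
#' @export
writeReferenceDb <- function(db, fastaPath, taxPath) {
  seqs <- refSeqs(db)
  names(seqs) <- paste(taxonomy(db)$tax_id, taxonomy(db)$species)
  writeFasta(seqs, fastaPath)
  write.table(taxonomy(db), taxPath, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(fastaPath, taxPath))
}

#' Read / write an abundance profile TSV
#'
#' Tab-separated with header \code{tax_id  species  abundance  est_reads}
#' (the Emu-style dialect consumed downstream); sample id and total read
#' count are carried in \code{#}-prefixed header lines.
#'
#' @param path file path.
#' @return `readAbundanceTsv()`: an [AbundanceProfile-class].
#' @export
readAbundanceTsv <- function(path) {
  if (!file.exists(path)) stop("readAbundanceTsv(): no such file: ", path)
  hdr <- grep("^#", readLines(path, warn = FALSE), value = TRUE)
  meta <- function(key, default) {
    hit <- grep(sprintf("^#\\s*%s:", key), hdr, value = TRUE)
    if (length(hit)) trimws(sub(sprintf("^#\\s*%s:", key), "", hit[1])) else default
  }
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (nrow(tab) == 0L)
    tab <- data.frame(tax_id = character(), species = character(),
                      abundance = numeric(), est_reads = numeric())
  abundanceProfile(
    sampleId = meta("sample_id", "sample"),
    entries = tab,
    totalReads = as.integer(meta("total_reads", sum(tab$est_reads)))
  )
}

#' @param profile an [AbundanceProfile-class].
#' @rdname readAbundanceTsv
#' @export
writeAbundanceTsv <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# sample_id: %s", sampleId(profile)),
               sprintf("# total_reads: %d", totalReads(profile))), con)
  write.table(abundances(profile), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read / write a barcode scheme config
#'
#' A single structured (YAML) text file with keys \code{mode},
#' \code{primers} (\code{name}/\code{fwd}/\code{rev}), \code{barcodes}
#' (id to sequence map) and \code{layout} (list of rows with
#' \code{pool}, \code{fwd_bc}, \code{rev_bc}, \code{sample}).
#'
#' @param path file path.
#' @return `readScheme()`: a [BarcodeScheme-class].
#' @export
readScheme <- function(path) {
  if (!file.exists(path)) stop("readScheme(): no such file: ", path)
  cfg <- yaml::read_yaml(path)
  lay <- do.call(rbind, lapply(cfg$layout, function(r)
    data.frame(pool = r$pool, fwd_bc = r$fwd_bc, rev_bc = r$rev_bc,
               sample = r$sample, stringsAsFactors = FALSE)))
  methods::new("BarcodeScheme",
    barcodes = unlist(cfg$barcodes),
    primerName = as.character(cfg$primers$name %||% "A"),
    fwdPrimer = toupper(cfg$primers$fwd),
    revPrimer = toupper(cfg$primers$rev),
    mode = toupper(cfg$mode),
    layout = lay)
}

#' @param scheme a [BarcodeScheme-class].
#' @rdname readScheme
#' @export
writeScheme <- function(scheme, path) {
  lay <- schemeLayout(scheme)
  yaml::write_yaml(list(
    mode = schemeMode(scheme),
    primers = list(name = scheme@primerName, fwd = scheme@fwdPrimer,
                   rev = scheme@revPrimer),
    barcodes = as.list(barcodes(scheme)),
    layout = lapply(seq_len(nrow(lay)), function(i) as.list(lay[i, ]))
  ), path)
  invisible(path)
}

#' Read / write the simulation ground-truth sidecar
#'
#' TSV with columns \code{read_id}, \code{native_pool}, \code{sample},
#' \code{taxon}, \code{strand}.
#'
#' @param truth data.frame as produced by [simulateReads()].
#' @param path file path.
#' @export
writeTruthTsv <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTruthTsv
#' @export
readTruthTsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE,
             colClasses = list(read_id = "character"))
}

#' Write a demultiplexing assignment table
#'
#' TSV: \code{read_id status sample fwd_bc rev_bc fwd_mm rev_mm reason}.
#'
#' @param assignments data.frame from [demultiplexPool()].
#' @param path file path.
#' @export
writeAssignmentsTsv <- function(assignments, path) {
  write.table(assignments, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname writeAssignmentsTsv
#' @export
readAssignmentsTsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
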