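# Run- and sample-level metrics: PCR-barcoding pool efficiency, purity
# calls for isolate identification, positive predictive value, and the
# categorical concordance statistics (Cramer's V, Theil's U).

#' Pool PCR-barcoding efficiency
#'
#' The fraction of a native pool's reads that also carry a recognizable
#' PCR barcode (pair): reads assigned a PCR barcode divided by the total
#' reads of that native pool (0 when the pool is empty).
#'
#' @param assignments assignment table from [demultiplexPool()]
#'   (optionally with a \code{pool} column for multi-pool tables).
#' @param poolId native pool id; required when the table has a
#'   \code{pool} column with several pools.
#' @return list with \code{pool}, \code{nTotal}, \code{nAssigned},
#'   \code{efficiency}.
#' @export
poolEfficiency <- function(assignments, poolId = NULL) {
  tab <- assignments
  if (!is.null(tab$pool)) {
    if (is.null(poolId)) {
      poolId <- unique(tab$pool)
      if (length(poolId) != 1L)
        stop("poolEfficiency(): poolId required for multi-pool tables")
    }
    if (!poolId %in% tab$pool)
      stop("poolEfficiency(): unknown pool ", poolId)
    tab <- tab[tab$pool == poolId, , drop = FALSE]
  }
  n <- nrow(tab)
  a <- sum(tab$status == "assigned")
  list(pool = if (is.null(poolId)) NA_character_ else poolId,
       nTotal = n, nAssigned = a,
       efficiency = if (n == 0L) 0 else a / n)
}

#' Purity / depth call for an isolate sample
#'
#' The isolate-identification gate: the sample's call is its most
#' abundant species (ties broken lexicographically by taxon id); its
#' purity is that species' relative abundance. The sample passes purity
#' iff purity >= \code{purityCutoff} (default 0.90: at least 90% of
#' annotated reads must correspond to the same species) and passes depth
#' iff it has at least \code{depthCutoff} reads (default 10).
#'
#' @param profile an [AbundanceProfile-class].
#' @param purityCutoff purity threshold (inclusive).
#' @param depthCutoff read-count threshold (inclusive).
#' @return list with \code{sample}, \code{topTaxon}, \code{topSpecies},
#'   \code{purity}, \code{nReads}, \code{passesDepth},
#'   \code{passesPurity}.
#' @export
callSample <- function(profile, purityCutoff = 0.90, depthCutoff = 10) {
  e <- abundances(profile)
  n <- totalReads(profile)
  if (nrow(e) == 0L)
    return(list(sample = sampleId(profile), topTaxon = NA_character_,
                topSpecies = NA_character_, purity = NA_real_,
                nReads = n, passesDepth = FALSE, passesPurity = FALSE))
  top <- e[order(-e$abundance, e$tax_id), ][1L, ]
  list(sample = sampleId(profile), topTaxon = top$tax_id,
       topSpecies = top$species, purity = top$abundance, nReads = n,
       passesDepth = n >= depthCutoff,
       passesPurity = top$abundance >= purityCutoff)
}

#' Positive predictive value
#'
#' \code{tp / (tp + fp)}: correctly identified samples over all samples
#' identified (no true/false negatives are observable in a
#' positives-only validation design).
#'
#' @param tp,fp non-negative counts; \code{tp + fp} must be positive.
#' @return a fraction in [0, 1].
#' @examples
#' ppv(36, 4)  # 0.90
#' @export
ppv <- function(tp, fp) {
  stopifnot(tp >= 0, fp >= 0)
  if (tp + fp == 0) stop("ppv(): undefined for tp + fp == 0")
  tp / (tp + fp)
}

# drop all-zero rows/columns; error if the table collapses below 2x2
trimTable <- function(counts, minDim = 2L) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("contingency table must be non-negative")
  counts <- counts[rowSums(counts) > 0, colSums(counts) > 0, drop = FALSE]
  if (nrow(counts) < minDim || ncol(counts) < minDim)
    stop(sprintf("contingency table collapses below %dx%d", minDim, minDim))
  counts
}

#' Cramer's V association statistic
#'
#' \deqn{V = \sqrt{\chi^2 / (N\,(\min(r,c)-1))}} with the Pearson
#' \eqn{\chi^2} statistic, no continuity or bias correction (the default
#' of the common implementations). All-zero rows/columns are dropped
#' first; a table collapsing below 2x2 is an error.
#'
#' @param counts r x c non-negative integer matrix (e.g. a confusion
#'   table of two annotation techniques).
#' @return V in [0, 1].
#' @examples
#' cramersV(matrix(c(10, 0, 0, 10), 2))  # 1: perfect association
#' @export
cramersV <- function(counts) {
  counts <- trimTable(counts)
  N <- sum(counts)
  if (N == 0) stop("cramersV(): empty table")
  chi2 <- suppressWarnings(
    chisq.test(counts, correct = FALSE)$statistic)
  unname(sqrt(chi2 / (N * (min(dim(counts)) - 1))))
}

#' Theil's U (uncertainty coefficient)
#'
#' Directional entropy-based association
#' \deqn{U(\mathrm{row}\mid\mathrm{col}) =
#'   \frac{H(\mathrm{row}) - H(\mathrm{row}\mid\mathrm{col})}
#'        {H(\mathrm{row})}}
#' with natural-log entropies. The direction of conditioning is an
#' explicit argument (\code{"row|col"} default); transpose semantics via
#' \code{"col|row"}. \eqn{H(\mathrm{row}) = 0} (a single effective row)
#' is an error.
#'
#' @param counts r x c non-negative matrix.
#' @param direction \code{"row|col"} or \code{"col|row"}.
#' @return U in [0, 1].
#' @export
theilsU <- function(counts, direction = c("row|col", "col|row")) {
  direction <- match.arg(direction)
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("theilsU(): negative counts")
  if (direction == "col|row") counts <- t(counts)
  N <- sum(counts)
  if (N == 0) stop("theilsU(): empty table")
  p <- counts / N
  ent <- function(x) { x <- x[x > 0]; -sum(x * log(x)) }
  hRow <- ent(rowSums(p))
  if (hRow == 0) stop("theilsU(): H(row) == 0, coefficient undefined")
  pCol <- colSums(p)
  hRowGivenCol <- sum(vapply(which(pCol > 0), function(j)
    pCol[j] * ent(p[, j] / pCol[j]), numeric(1)))
  (hRow - hRowGivenCol) / hRow
}
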