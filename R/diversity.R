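# Community diversity statistics over abundance profiles: alpha
# diversity, Bray-Curtis dissimilarity, PERMANOVA, paired-vs-unpaired
# dissimilarity reports and rarefaction. The distance and permutation
# machinery is delegated to vegan.

asAbundanceVec <- function(x, universe = NULL) {
  if (methods::is(x, "AbundanceProfile")) abundanceVector(x, universe)
  else if (is.numeric(x) && !is.null(names(x))) {
    if (is.null(universe)) x
    else {
      out <- setNames(numeric(length(universe)), universe)
      out[intersect(names(x), universe)] <- x[intersect(names(x), universe)]
      out
    }
  } else stop("expected an AbundanceProfile or a named numeric vector")
}

#' Alpha diversity of one profile
#'
#' Richness (number of taxa with abundance > 0), Shannon diversity
#' \eqn{-\sum p \ln p} in natural-log units (nats; the base is
#' configurable) and the Berger-Parker dominance index \eqn{\max p}.
#' An empty profile returns (0, 0, 0); Berger-Parker of an empty
#' profile is reported as 0 by convention (an explicit convention beats
#' an exception in batch reports).
#'
#' @param x an [AbundanceProfile-class] or named abundance vector.
#' @param base logarithm base for Shannon (default \code{exp(1)}).
#' @return list with \code{richness}, \code{shannon},
#'   \code{bergerParker}.
#' @examples
#' alphaDiversity(c(a = 0.25, b = 0.25, c = 0.25, d = 0.25))
#' @export
alphaDiversity <- function(x, base = exp(1)) {
  p <- asAbundanceVec(x)
  p <- p[p > 0]
  if (length(p) == 0L)
    return(list(richness = 0L, shannon = 0, bergerParker = 0))
  list(richness = length(p),
       shannon = -sum(p * log(p, base = base)) + 0,  # avoid IEEE -0
       bergerParker = max(p))
}

#' Bray-Curtis dissimilarity between two profiles
#'
#' For relative abundances on a shared taxon universe (missing taxa
#' count as 0) this equals \eqn{1 - \sum_t \min(p_t, q_t)}; 0 for
#' identical profiles, 1 for disjoint supports. Computed via
#' [vegan::vegdist()].
#'
#' @param p,q [AbundanceProfile-class] objects or named abundance
#'   vectors.
#' @return dissimilarity in [0, 1].
#' @examples
#' brayCurtis(c(A = 0.6, B = 0.4), c(A = 0.2, B = 0.8))  # 0.4
#' @export
brayCurtis <- function(p, q) {
  pv <- asAbundanceVec(p)
  qv <- asAbundanceVec(q)
  universe <- union(names(pv), names(qv))
  if (length(universe) == 0L)
    stop("brayCurtis(): both profiles are empty")
  m <- rbind(asAbundanceVec(p, universe), asAbundanceVec(q, universe))
  as.numeric(vegan::vegdist(m, method = "bray"))
}

#' Pairwise Bray-Curtis distance matrix over a set of profiles
#'
#' @param profiles named list of [AbundanceProfile-class] objects or
#'   named abundance vectors.
#' @return a symmetric matrix with zero diagonal.
#' @export
brayCurtisMatrix <- function(profiles) {
  universe <- Reduce(union, lapply(profiles, function(p)
    names(asAbundanceVec(p))))
  m <- do.call(rbind, lapply(profiles, asAbundanceVec, universe = universe))
  rownames(m) <- names(profiles)
  as.matrix(vegan::vegdist(m, method = "bray"))
}

#' One-way PERMANOVA on a distance matrix
#'
#' Permutational multivariate ANOVA: the pseudo-F statistic from
#' among/within sums of squared distances, with the p-value
#' \eqn{(1 + \#\{F_{perm} \ge F_{obs}\}) / (1 + n_{perm})} from seeded
#' label permutations. Delegated to [vegan::adonis2()].
#'
#' @param d a distance matrix ("dist" or symmetric matrix, zero
#'   diagonal).
#' @param groups grouping factor (>= 2 groups, each >= 2 members).
#' @param nPerm number of permutations (default 999).
#' @param seed integer seed for the permutations (optional).
#' @return list with \code{R2}, \code{p}, \code{F}.
#' @export
permanova <- function(d, groups, nPerm = 999, seed = NULL) {
  d <- stats::as.dist(d)
  groups <- factor(groups)
  if (nlevels(groups) < 2L || any(table(groups) < 2L))
    stop("permanova(): need >= 2 groups with >= 2 members each")
  if (attr(d, "Size") != length(groups))
    stop("permanova(): distance size and grouping length differ")
  dat <- data.frame(group = groups)
  fit <- withSeed(seed,
    vegan::adonis2(d ~ group, data = dat, permutations = nPerm))
  list(R2 = fit$R2[1L], p = fit$`Pr(>F)`[1L], F = fit$F[1L])
}

#' Paired vs unpaired dissimilarity between two techniques
#'
#' For two sets of profiles of the same biological samples measured by
#' two techniques, reports the Bray-Curtis value of each matched pair
#' and the pooled unpaired (cross-sample, cross-technique) values for
#' the same technique pair -- the comparison behind "paired samples are
#' more similar than unpaired ones".
#'
#' @param a,b named lists of profiles (names are sample ids).
#' @param pairing optional two-column data.frame (\code{a}, \code{b});
#'   by default samples are matched by name, and any unmatched id is an
#'   error listing the offenders.
#' @return list with \code{paired} (data.frame \code{sample},
#'   \code{bc}) and \code{unpaired} (data.frame \code{sample_a},
#'   \code{sample_b}, \code{bc}; empty with a single pair).
#' @export
pairedDissimilarity <- function(a, b, pairing = NULL) {
  if (is.null(pairing)) {
    miss <- c(setdiff(names(a), names(b)), setdiff(names(b), names(a)))
    if (length(miss))
      stop("pairedDissimilarity(): unmatched sample ids: ",
           paste(unique(miss), collapse = ", "))
    pairing <- data.frame(a = names(a), b = names(a),
                          stringsAsFactors = FALSE)
  } else {
    miss <- c(setdiff(pairing$a, names(a)), setdiff(pairing$b, names(b)))
    if (length(miss))
      stop("pairedDissimilarity(): unmatched sample ids: ",
           paste(unique(miss), collapse = ", "))
  }
  paired <- data.frame(
    sample = pairing$a,
    bc = vapply(seq_len(nrow(pairing)), function(i)
      brayCurtis(a[[pairing$a[i]]], b[[pairing$b[i]]]), numeric(1)),
    stringsAsFactors = FALSE)
  grid <- expand.grid(i = seq_len(nrow(pairing)), j = seq_len(nrow(pairing)))
  grid <- grid[grid$i != grid$j, , drop = FALSE]
  unpaired <- data.frame(
    sample_a = pairing$a[grid$i],
    sample_b = pairing$b[grid$j],
    bc = vapply(seq_len(nrow(grid)), function(k)
      brayCurtis(a[[pairing$a[grid$i[k]]]], b[[pairing$b[grid$j[k]]]]),
      numeric(1)),
    stringsAsFactors = FALSE)
  list(paired = paired, unpaired = unpaired)
}

#' Rarefy a count vector to a fixed depth
#'
#' Subsamples reads without replacement to exactly \code{depth}
#' (seeded), via [vegan::rrarefy()].
#'
#' @param counts named non-negative integer vector (taxon -> count).
#' @param depth target depth, at most \code{sum(counts)}.
#' @param seed integer seed (optional).
#' @return named integer vector summing to \code{depth}.
#' @export
rarefy <- function(counts, depth, seed = NULL) {
  stopifnot(all(counts >= 0), depth >= 0)
  total <- sum(counts)
  if (depth > total)
    stop("rarefy(): depth exceeds total count (", total, ")")
  if (depth == 0) return(setNames(integer(length(counts)), names(counts)))
  m <- matrix(as.integer(counts), nrow = 1,
              dimnames = list(NULL, names(counts)))
  # vegan notes when the table looks pre-rarefied; irrelevant here
  out <- withCallingHandlers(
    withSeed(seed, vegan::rrarefy(m, depth)),
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  setNames(as.integer(out[1L, ]), colnames(out))
}
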