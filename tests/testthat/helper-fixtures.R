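# Shared fixtures: small schemes/databases built in code, plus
# independent oracles used to freeze expected values.

# a short-template database keeps alignment-heavy unit tests fast;
# full-length (1500 bp) databases are used where the scenario calls
# for realistic amplicons
shortDb <- function(nTaxa = 3, seqLength = 300, divergence = 0.1,
                    seed = 11) {
  makeReferenceDb(nTaxa, seqLength, divergence, seed = seed,
                  lengthRange = c(1, 1900))
}

testScheme <- function(mode = "2BC", seed = 42, pools = "pool1") {
  makeScheme(mode = mode, pools = pools, seed = seed)
}

# scheme with hand-picked barcodes at known pairwise distances
# (bcA vs bcB differ at exactly 2 positions) for ambiguity fixtures
closeBarcodeScheme <- function() {
  bcs <- c(bcA = "AAAAAAAAAAAA",
           bcB = "AAAAAAAAAACC",          # Hamming 2 from bcA
           bcC = "GGGGGGGGGGGG")
  new("BarcodeScheme", barcodes = bcs, primerName = "T",
      fwdPrimer = "ACGTACGTACGTACGTACGT",
      revPrimer = "TTGGCCAATTGGCCAATTGG",
      mode = "2BC",
      layout = data.frame(pool = "pool1",
                          fwd_bc = c("bcA", "bcB", "bcC"),
                          rev_bc = c("bcB", "bcC", "bcA"),
                          sample = c("s1", "s2", "s3"),
                          stringsAsFactors = FALSE))
}

randomDnaStr <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                  collapse = "")

# ---- independent oracles ---------------------------------------------------

# Pearson chi-squared by direct expected-count enumeration
bruteChi2 <- function(m) {
  N <- sum(m)
  chi2 <- 0
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    e <- sum(m[i, ]) * sum(m[, j]) / N
    chi2 <- chi2 + (m[i, j] - e)^2 / e
  }
  chi2
}

bruteCramersV <- function(m) {
  sqrt(bruteChi2(m) / (sum(m) * (min(dim(m)) - 1)))
}

# uncertainty coefficient U(row|col) by direct entropy enumeration
bruteTheilsU <- function(m) {
  N <- sum(m)
  pRow <- rowSums(m) / N
  hRow <- -sum(ifelse(pRow > 0, pRow * log(pRow), 0))
  hCond <- 0
  for (j in seq_len(ncol(m))) {
    pj <- sum(m[, j]) / N
    if (pj > 0) {
      pc <- m[, j] / sum(m[, j])
      hCond <- hCond + pj * -sum(ifelse(pc > 0, pc * log(pc), 0))
    }
  }
  (hRow - hCond) / hRow
}

# dense grid-search maximizer of the mixture log-likelihood (step 0.01),
# independent of the EM path
gridSearchMixture <- function(L, step = 0.01) {
  L <- L[rowSums(L) > 0, , drop = FALSE]
  K <- ncol(L)
  grid <- seq(0, 1, by = step)
  best <- NULL
  bestLL <- -Inf
  if (K == 2) {
    for (f1 in grid) {
      f <- pmax(c(f1, 1 - f1), 0)
      ll <- sum(log(L %*% f))
      if (ll > bestLL) { bestLL <- ll; best <- f }
    }
  } else if (K == 3) {
    for (f1 in grid) for (f2 in grid[grid <= 1 - f1 + 1e-12]) {
      f <- pmax(c(f1, f2, 1 - f1 - f2), 0)
      ll <- sum(log(L %*% f))
      if (ll > bestLL) { bestLL <- ll; best <- f }
    }
  } else stop("oracle supports <= 3 components")
  setNames(best, colnames(L))
}

# exhaustive ungapped scan oracle for primer localization (forward
# orientation only)
bruteForwardScan <- function(read, primer) {
  rc <- strsplit(read, "")[[1]]
  pc <- strsplit(primer, "")[[1]]
  L <- length(pc)
  vapply(seq_len(length(rc) - L + 1L), function(o)
    sum(!iupacMatch(pc, rc[o:(o + L - 1L)])), numeric(1))
}
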