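test_that("greedy clustering bins identical and divergent reads correctly", {
  set.seed(401)
  tpl <- randomDnaStr(300)
  copies <- setNames(rep(tpl, 20), sprintf("c%02d", 1:20))
  bins <- greedyCluster(copies)
  expect_length(bins, 1L)
  expect_identical(binSize(bins[[1]]), 20L)
  expect_identical(binCentroid(bins[[1]]), tpl)

  # two templates at ~10% divergence, low noise: exactly two bins
  db <- shortDb(2, seqLength = 300, divergence = 0.1, seed = 21)
  mix <- simulateMixture(db, c(tax01 = 0.5, tax02 = 0.5), 20,
                         errorModel(sub = 0.01, flipProb = 0), seed = 5)
  bins2 <- greedyCluster(mix$reads, identityThreshold = 0.95)
  expect_length(bins2, 2L)
  truth <- setNames(mix$truth$taxon, mix$truth$read_id)
  for (b in bins2)
    expect_length(unique(truth[names(binMembers(b))]), 1L)

  # degenerate threshold 1.0: every distinct sequence seeds its own bin
  noisy <- simulateMixture(db, c(tax01 = 1), 6,
                           errorModel(sub = 0.05, flipProb = 0),
                           seed = 6)$reads
  bins3 <- greedyCluster(noisy, identityThreshold = 1.0)
  expect_length(bins3, length(unique(as.character(noisy))))
})

test_that("cluster sizes always sum to the number of input reads", {
  set.seed(402)
  db <- shortDb(3, seqLength = 300)
  mix <- simulateMixture(db, c(tax01 = 0.4, tax02 = 0.4, tax03 = 0.2), 15,
                         errorModel(sub = 0.03, flipProb = 0), seed = 9)
  bins <- greedyCluster(mix$reads, 0.9)
  expect_identical(sum(vapply(bins, binSize, integer(1))),
                   length(mix$reads))
})

test_that("bin-size filter is strictly greater-than", {
  mk <- function(n) methods::new("ReadBin", binId = paste0("b", n),
    centroid = "ACGT",
    members = Biostrings::DNAStringSet(rep("ACGT", n)))
  bins <- list(mk(9), mk(10), mk(11), mk(30))
  kept <- filterBins(bins)
  expect_identical(vapply(kept, binSize, integer(1)), c(11L, 30L))
  expect_identical(filterBins(list()), list())
})

test_that("majority-vote consensus corrects isolated errors", {
  set.seed(403)
  tpl <- randomDnaStr(200)
  # one member carries a single substitution; nine do not
  mut <- tpl
  substr(mut, 100, 100) <- if (substr(tpl, 100, 100) == "A") "C" else "A"
  members <- c(rep(tpl, 9), mut)
  names(members) <- sprintf("m%02d", 1:10)
  bin <- methods::new("ReadBin", binId = "b1", centroid = tpl,
                      members = Biostrings::DNAStringSet(members))
  expect_identical(consensusSequence(bin), tpl)
  # all members identical: consensus is the member sequence
  bin2 <- methods::new("ReadBin", binId = "b2", centroid = tpl,
                       members = Biostrings::DNAStringSet(
                         setNames(rep(tpl, 3), c("a", "b", "c"))))
  expect_identical(consensusSequence(bin2), tpl)
})

test_that("consensus of a noisy simulated bin recovers the template", {
  db <- shortDb(1, seqLength = 300, seed = 33)
  tpl <- as.character(refSeqs(db))[1]
  mix <- simulateMixture(db, c(tax01 = 1), 30,
                         errorModel(sub = 0.03, ins = 0.005, del = 0.005,
                                    flipProb = 0), seed = 11)
  bins <- greedyCluster(mix$reads, 0.85)
  expect_length(bins, 1L)
  cons <- consensusSequence(bins[[1]])
  aln <- Biostrings::pairwiseAlignment(cons, tpl)
  # edit distance = mismatches + unaligned overhang/gap bases
  edits <- Biostrings::nmismatch(aln) +
    (nchar(cons) - Biostrings::nmatch(aln) - Biostrings::nmismatch(aln)) +
    (nchar(tpl) - Biostrings::nmatch(aln) - Biostrings::nmismatch(aln))
  expect_lte(edits, 1)
})

test_that("distanceMatrix is 1 - identity with symmetric zero-diagonal output", {
  set.seed(404)
  s <- randomDnaStr(150)
  d0 <- distanceMatrix(c(a = s, b = s))
  expect_equal(d0, matrix(0, 2, 2, dimnames = list(c("a", "b"),
                                                   c("a", "b"))))
  # exactly 10 substitutions in 100 bases, no gaps: distance 0.10
  x <- randomDnaStr(100)
  y <- strsplit(x, "")[[1]]
  flip <- c("A" = "C", "C" = "G", "G" = "T", "T" = "A")
  y[1:10 * 10] <- flip[y[1:10 * 10]]
  d <- distanceMatrix(c(p = x, q = paste(y, collapse = "")))
  expect_equal(d["p", "q"], 0.10)
  # symmetry for random sequences
  r3 <- c(u = randomDnaStr(120), v = randomDnaStr(120), w = randomDnaStr(120))
  dm <- distanceMatrix(r3)
  expect_equal(dm, t(dm))
  expect_true(all(diag(dm) == 0))
  expect_error(distanceMatrix(c(a = s, a = s)), "duplicate")
})

test_that("njTree handles 2 and 3 taxa with closed-form branch lengths", {
  t2 <- njTree(matrix(c(0, 0.4, 0.4, 0), 2,
                      dimnames = list(c("A", "B"), c("A", "B"))))
  expect_identical(sort(t2$tip.label), c("A", "B"))
  expect_equal(sum(t2$edge.length), 0.4)
  # 3-taxon star: closed-form lengths (dAB + dAC - dBC)/2 etc.
  dab <- 0.3; dac <- 0.5; dbc <- 0.6
  d3 <- matrix(c(0, dab, dac, dab, 0, dbc, dac, dbc, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t3 <- njTree(d3)
  lens <- setNames(t3$edge.length, t3$tip.label[t3$edge[, 2]])
  expect_equal(lens[["A"]], (dab + dac - dbc) / 2)
  expect_equal(lens[["B"]], (dab + dbc - dac) / 2)
  expect_equal(lens[["C"]], (dac + dbc - dab) / 2)
  expect_error(njTree(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("njTree recovers a hand-built additive 4-taxon tree exactly", {
  # tree: (A:0.1, B:0.2)-x-[0.3]-y-(C:0.15, D:0.25)
  lab <- c("A", "B", "C", "D")
  tip <- c(A = 0.1, B = 0.2, C = 0.15, D = 0.25)
  d <- matrix(0, 4, 4, dimnames = list(lab, lab))
  d["A", "B"] <- d["B", "A"] <- 0.1 + 0.2
  d["C", "D"] <- d["D", "C"] <- 0.15 + 0.25
  for (i in c("A", "B")) for (j in c("C", "D"))
    d[i, j] <- d[j, i] <- tip[i] + 0.3 + tip[j]
  fit <- njTree(d)
  expect_equal(max(abs(ape::cophenetic.phylo(fit)[lab, lab] - d)), 0,
               tolerance = 1e-12)
  # the internal split is (AB | CD)
  ref <- ape::read.tree(text = "((A:0.1,B:0.2):0.3,C:0.15,D:0.25);")
  expect_equal(as.numeric(ape::dist.topo(fit, ref)), 0)
})

test_that("negative NJ branch lengths are clamped with the deficit moved", {
  # a non-additive matrix known to induce a negative NJ branch
  lab <- c("A", "B", "C", "D")
  d <- matrix(c(0, 0.1, 0.4, 0.45,
                0.1, 0, 0.45, 0.4,
                0.4, 0.45, 0, 0.02,
                0.45, 0.4, 0.02, 0), 4, dimnames = list(lab, lab))
  raw <- ape::nj(as.dist(d))
  fit <- njTree(d)
  expect_true(all(fit$edge.length >= 0))
  expect_equal(sum(fit$edge.length), sum(raw$edge.length), tolerance = 1e-12)
})

test_that("star alignment projects sequences onto the longest reference", {
  set.seed(405)
  ref <- randomDnaStr(120)
  # a variant with an internal 10-base deletion projects to 10 gap
  # columns; insertions relative to the reference are dropped
  del <- paste0(substr(ref, 1, 50), substr(ref, 61, 120))
  aln <- starAlignment(c(long = ref, del = del))
  expect_identical(dim(aln), c(2L, 120L))
  expect_identical(paste(aln["long", ], collapse = ""), ref)
  expect_identical(sum(aln["del", ] == "-"), 10L)
  expect_identical(paste(aln["del", aln["del", ] != "-"], collapse = ""),
                   del)
  ins <- paste0(substr(ref, 1, 60), "ACGTACGTAC", substr(ref, 61, 120))
  aln2 <- starAlignment(c(a = ins, b = ref))
  expect_identical(ncol(aln2), 130L)   # the longer variant is the reference
  expect_identical(paste(aln2["a", ], collapse = ""), ins)
})

test_that("bootstrap supports are deterministic, bounded and strong for clear signal", {
  db <- makeReferenceDb(4, 400, 0.15, seed = 51, lengthRange = c(1, 1900))
  seqs <- setNames(as.character(refSeqs(db)), names(refSeqs(db)))
  t1 <- bootstrapSupport(seqs, nBoot = 25, seed = 3)
  t2 <- bootstrapSupport(seqs, nBoot = 25, seed = 3)
  expect_identical(t1$node.label, t2$node.label)
  expect_true(all(t1$node.label >= 0 & t1$node.label <= 1))
  one <- bootstrapSupport(seqs, nBoot = 1, seed = 4)
  expect_true(all(one$node.label %in% c(0, 1)))
})

test_that("a strongly supported additive split gets near-full bootstrap support", {
  # two pairs of near-identical sequences, pairs well separated
  set.seed(406)
  base1 <- randomDnaStr(300)
  base2 <- randomDnaStr(300)
  tweak <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    idx <- seq(5, 5 * k, by = 5)
    ch[idx] <- vapply(ch[idx], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
    paste(ch, collapse = "")
  }
  seqs <- c(A = base1, B = tweak(base1, 3), C = base2, D = tweak(base2, 3))
  tree <- bootstrapSupport(seqs, nBoot = 100, seed = 8)
  internal <- tree$node.label[-1]   # drop the trivial root split
  expect_true(all(internal >= 0.95))
})

test_that("newick serialization round-trips topology, lengths and supports", {
  db <- makeReferenceDb(5, 300, 0.15, seed = 52, lengthRange = c(1, 1900))
  seqs <- setNames(as.character(refSeqs(db)), names(refSeqs(db)))
  tree <- bootstrapSupport(seqs, nBoot = 20, seed = 9)
  path <- withr::local_tempfile(fileext = ".nwk")
  writeNewick(tree, path)
  back <- readNewick(path)
  expect_identical(ape::dist.topo(tree, back)[[1]], 0)
  o <- match(back$tip.label, tree$tip.label)
  expect_equal(sort(back$edge.length), sort(tree$edge.length),
               tolerance = 1e-9)
  expect_equal(sort(back$node.label), sort(tree$node.label))
})
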