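mkRead <- function(seq, q) {
  makeReads(setNames(seq, "r1"), list(rep(q, nchar(seq))))
}

test_that("filterReads applies the length window and strict quality rule", {
  set.seed(102)
  reads <- c(mkRead(randomDnaStr(1299), 15),   # too short
             mkRead(randomDnaStr(1801), 15),   # too long
             mkRead(randomDnaStr(1500), 9),    # Q exactly 9: fails strict >
             mkRead(randomDnaStr(1500), 10))   # kept
  names(reads) <- paste0("r", 1:4)
  out <- filterReads(reads)
  expect_identical(names(out$kept), "r4")
  expect_identical(out$rejected$reason,
                   c("too_short", "too_long", "low_quality"))
  # partition: every read in exactly one of kept / rejected
  expect_setequal(c(names(out$kept), out$rejected$read_id), names(reads))
  # non-strict mode admits Q == 9
  expect_identical(names(filterReads(reads, strict = FALSE)$kept),
                   c("r3", "r4"))
})

test_that("filterReads preserves input order within the kept set", {
  set.seed(31)
  reads <- do.call(c, lapply(1:6, function(i)
    mkRead(randomDnaStr(sample(c(1200, 1500), 1)), 20)))
  names(reads) <- paste0("r", 1:6)
  out <- filterReads(reads)
  expect_identical(names(out$kept),
                   names(reads)[Biostrings::width(reads) >= 1300])
})

test_that("locatePrimer finds planted hits and honors the tie-break", {
  set.seed(103)
  primer <- "ACGTACGTACGTACGTACGT"
  read <- paste0(randomDnaStr(12), primer, randomDnaStr(300))
  hit <- locatePrimer(read, primer)
  expect_identical(hit$offset, 13L)
  expect_identical(hit$strand, "+")
  expect_identical(hit$mismatches, 0)

  # too many substitutions: absence is a value, not an error
  bad <- paste0(randomDnaStr(12), "TTTTACGTACGTACGTTTTT", randomDnaStr(300))
  expect_null(locatePrimer(bad, primer, maxMismatch = 3))

  # equal-mismatch hits at offsets 5 and 40: smaller offset wins,
  # confirmed against the exhaustive scan oracle
  p <- "AACCGGTTAA"
  r <- paste0("GGGG", p, paste(rep("C", 25), collapse = ""), p,
              paste(rep("G", 40), collapse = ""))
  hit2 <- locatePrimer(r, p, maxMismatch = 0)
  expect_identical(hit2$offset, 5L)
  mm <- bruteForwardScan(r, p)
  expect_identical(which(mm == 0), c(5L, 40L))

  # reverse-complement occurrence near the 3' end reports strand "-"
  rcRead <- paste0(randomDnaStr(300), revComp(primer), randomDnaStr(12))
  hitRc <- locatePrimer(rcRead, primer)
  expect_identical(hitRc$strand, "-")
  expect_identical(hitRc$offset, 301L)
})

test_that("locatePrimer matches degenerate primer bases via IUPAC sets", {
  primer <- "ARYN"   # A, A/G, C/T, any
  expect_identical(locatePrimer(paste0("AGTC", randomDnaStr(30)), primer,
                                maxMismatch = 0, searchWindow = 10)$offset, 1L)
  expect_null(locatePrimer(paste0("ACTC", paste(rep("G", 30), collapse = "")),
                           primer, maxMismatch = 0, searchWindow = 10))
})

noiselessPoolFixture <- function(mode = "2BC", nPerSample = 4, seed = 77,
                                 model = errorModel()) {
  scheme <- testScheme(mode = mode, seed = 55)
  db <- makeReferenceDb(4, 1500, 0.1, seed = 55)
  sim <- simulatePool(scheme, db, nPerSample, model, seed = seed)
  list(scheme = scheme, db = db, sim = sim)
}

test_that("noiseless reads demultiplex to their truth sample with exact trimming", {
  fx <- noiselessPoolFixture()
  dm <- demultiplexPool(fx$sim$reads, fx$scheme)
  expect_true(all(dm$assignments$status == "assigned"))
  truth <- setNames(fx$sim$truth$sample, fx$sim$truth$read_id)
  expect_identical(dm$assignments$sample,
                   unname(truth[dm$assignments$read_id]))
  # trimmed insert equals the template in forward orientation, including
  # reads emitted on the minus strand
  for (s in names(dm$samples)) {
    tax <- fx$sim$truth$taxon[fx$sim$truth$sample == s][1]
    tpl <- as.character(refSeqs(fx$db)[[tax]])
    expect_true(all(as.character(dm$samples[[s]]) == tpl))
  }
  expect_true(any(fx$sim$truth$strand == "-"))  # strand handling exercised
})

test_that("every input read appears exactly once in the assignment table", {
  fx <- noiselessPoolFixture(model = errorModel(sub = 0.05, ins = 0.02,
                                                del = 0.02))
  dm <- demultiplexPool(fx$sim$reads, fx$scheme)
  expect_identical(sort(dm$assignments$read_id), sort(names(fx$sim$reads)))
  counts <- table(dm$assignments$status)
  expect_identical(sum(counts), length(fx$sim$reads))
})

test_that("equidistant forward barcodes yield an ambiguous call", {
  set.seed(101)
  scheme <- closeBarcodeScheme()
  tpl <- randomDnaStr(200)
  # forward window at Hamming 1 from both bcA (AAA...A) and bcB (AAA...CC)
  window <- "AAAAAAAAAACA"
  amp <- assembleAmplicon(tpl, fwdBc = window,
                          revBc = barcodes(scheme)[["bcB"]],
                          fwdPrimer = primers(scheme)$fwd,
                          revPrimer = primers(scheme)$rev)
  res <- demultiplexRead(amp, NULL, scheme)
  expect_identical(res$status, "ambiguous")
  # brute-force Hamming confirms the two-way tie at distance 1
  d <- vapply(barcodes(scheme), function(b)
    sum(strsplit(b, "")[[1]] != strsplit(window, "")[[1]]), integer(1))
  expect_identical(unname(sort(d)[1:2]), c(1L, 1L))
})

test_that("a conflicting reverse barcode discards a 1BC read", {
  set.seed(105)
  scheme1 <- testScheme(mode = "1BC", seed = 55)
  bc <- barcodes(scheme1)
  tpl <- randomDnaStr(200)
  pr <- primers(scheme1)
  conflict <- assembleAmplicon(tpl, fwdBc = bc[["bc01"]],
                               revBc = bc[["bc03"]],
                               fwdPrimer = pr$fwd, revPrimer = pr$rev)
  res <- demultiplexRead(conflict, NULL, scheme1)
  expect_identical(res$status, "conflicting")
  # an unreadable reverse barcode is fine in 1BC mode (not required)
  noRev <- assembleAmplicon(tpl, fwdBc = bc[["bc01"]], revBc = "",
                            fwdPrimer = pr$fwd, revPrimer = pr$rev)
  res2 <- demultiplexRead(noRev, NULL, scheme1)
  expect_identical(res2$status, "assigned")
  expect_identical(res2$sample, "pool1_s01")
})

test_that("a valid barcode pair absent from the layout gets a distinct reason", {
  set.seed(106)
  scheme <- testScheme(seed = 55)
  bc <- barcodes(scheme)
  pr <- primers(scheme)
  # bc01 paired with bc05: both real barcodes, but not a layout pair
  amp <- assembleAmplicon(randomDnaStr(200), fwdBc = bc[["bc01"]],
                          revBc = bc[["bc05"]],
                          fwdPrimer = pr$fwd, revPrimer = pr$rev)
  res <- demultiplexRead(amp, NULL, scheme)
  expect_identical(res$status, "no_barcode")
  expect_identical(res$reason, "not_in_layout")
})

test_that("1BC-constructed reads demultiplex identically in 1BC and 2BC mode", {
  fx <- noiselessPoolFixture(mode = "1BC")
  dm1 <- demultiplexPool(fx$sim$reads, fx$scheme, mode = "1BC")
  dm2 <- demultiplexPool(fx$sim$reads, fx$scheme, mode = "2BC")
  a1 <- dm1$assignments[dm1$assignments$status == "assigned", ]
  a2 <- dm2$assignments[dm2$assignments$status == "assigned", ]
  shared <- intersect(a1$read_id, a2$read_id)
  expect_identical(setNames(a1$sample, a1$read_id)[shared],
                   setNames(a2$sample, a2$read_id)[shared])
  expect_true(all(dm1$assignments$status == "assigned"))
  expect_true(all(dm2$assignments$status == "assigned"))
})

test_that("raising the barcode tolerance never loses 2BC assignments", {
  fx <- noiselessPoolFixture(model = errorModel(sub = 0.06, ins = 0.02,
                                                del = 0.02), nPerSample = 3)
  counts <- vapply(0:4, function(mm)
    sum(demultiplexPool(fx$sim$reads, fx$scheme,
                        maxBcMismatch = mm)$assignments$status == "assigned"),
    numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("demultiplexPool writes per-sample FASTQ files and the table", {
  fx <- noiselessPoolFixture(nPerSample = 2)
  out <- withr::local_tempdir()
  dm <- demultiplexPool(fx$sim$reads, fx$scheme, outDir = out)
  files <- list.files(out, pattern = "\\.fastq$")
  expect_identical(sort(files),
                   sort(paste0(schemeLayout(fx$scheme)$sample, ".fastq")))
  tab <- readAssignmentsTsv(file.path(out, "assignments.tsv"))
  expect_identical(nrow(tab), length(fx$sim$reads))
  s1 <- readFastq(file.path(out, "pool1_s01.fastq"))
  expect_identical(length(s1), 2L)
  expect_warning(demultiplexPool(fx$sim$reads[0], fx$scheme), "empty input")
})
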