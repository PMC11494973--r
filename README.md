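# nanotax

Dual-barcoded full-length 16S rRNA amplicon workflows on long-read
(nanopore-style) data, as a self-contained R toolkit. It is written for
microbiologists and bioinformaticians who identify bacterial isolates or
profile communities by sequencing the ~1.5 kb 16S gene with PCR
barcodes embedded in the amplification primers, and who need the whole
chain — simulation with ground truth, filtering, demultiplexing,
taxonomic annotation, validation metrics, consensus and phylogeny —
testable on a desktop without any sequencing run.

## What it computes

**Read structure.** Amplicons carry a 12-bp PCR barcode on each side,
flanking the primer binding sites:
`bc_f + primer_f + insert + revcomp(primer_r) + revcomp(bc_r)`.
Either the same barcode on both sides (**1BC**, more depth) or
independent barcodes (**2BC**, combinatorial multiplexing). Samples
sharing a library barcode form a *native pool*, modeled as one input
FASTQ.

**Filtering.** Reads of 1,300–1,800 bp with error-probability-averaged
quality `Q = -10 log10(mean(10^(-q_i/10))) > 9`.

**Demultiplexing.** IUPAC-aware ungapped primer localization anchors a
Hamming-distance barcode call at the fixed 12-base windows beside each
primer (defaults: ≤ 2 of 12 barcode mismatches, ≤ 3 primer mismatches);
reads are canonicalized to the forward strand and trimmed to the
insert. Per-read statuses: `assigned`, `no_primer`, `no_barcode`,
`ambiguous`, `conflicting`.

**Annotation.** Species-level relative abundances by mixture EM over
per-read alignment likelihoods
`L[r,t] = p_err^(mismatches+indels) * (1-p_err)^matches`
(local alignment, both strands, 80% coverage gate), with
`f_t = mean_r P(t | r)` iterated to convergence.

**Metrics.** Pool efficiency (assigned / total reads per native pool);
isolate calls with a ≥ 90% purity gate and ≥ 10-read depth gate;
PPV = TP/(TP+FP); Cramér's V (`sqrt(chi2 / (N (min(r,c)-1)))`) and
Theil's U (uncertainty coefficient, explicit direction); richness,
Shannon (nats), Berger-Parker; Bray-Curtis `1 - sum(min(p,q))`;
one-way PERMANOVA with seeded permutations; seeded rarefaction.

**Consensus & phylogeny.** Greedy centroid clustering (identity =
matches / alignment length, default threshold 0.97; bins kept only
above 10 reads), majority-vote consensus, pairwise-identity distance
matrices, neighbor joining (exact on additive matrices; negative
branches clamped), column-resampling bootstrap supports, newick I/O.

## Worked example

Simulate a noisy 8-sample 2BC pool, demultiplex it, and annotate one
sample:

```r
library(nanotax)

scheme <- makeScheme(mode = "2BC", seed = 11)    # 8 barcodes, 27F/1492R
db     <- makeReferenceDb(8, seqLength = 1500, divergence = 0.1, seed = 11)
sim    <- simulatePool(scheme, db, nPerSample = 50,
                       model = errorModel(sub = 0.02, ins = 0.02, del = 0.02),
                       seed = 11)

kept <- filterReads(sim$reads)$kept
dm   <- demultiplexPool(kept, scheme)
table(dm$assignments$status)
#>   assigned no_barcode  no_primer
#>         71        112        217
poolEfficiency(dm$assignments)$efficiency
#> 0.1775

prof <- annotateSample(dm$samples[["pool1_s01"]], db, sampleId = "pool1_s01")
prof
#> AbundanceProfile 'pool1_s01': 1 taxa, 7 reads
#>   tax_id              species abundance est_reads
#> 1  tax01 Synthetica species01         1         7
callSample(prof)[c("topSpecies", "purity", "passesDepth", "passesPurity")]
#> $topSpecies: "Synthetica species01"   $purity: 1
#> $passesDepth: FALSE                   $passesPurity: TRUE
```

Reading the numbers: at 6% total error the ungapped barcode/primer
matching assigns ~18% of reads — but every assigned read is correct
(checking against `sim$truth` gives accuracy 1.000), the
purity-over-yield regime the dual-barcode design aims for. The
annotated sample is pure (abundance 1.0 for its true taxon) but, at 7
surviving reads, fails the 10-read depth gate and would be excluded
from an isolate report.

A command-line front end for shell pipelines is installed at
`system.file("scripts", "nanotax", package = "nanotax")` with
subcommands `simulate`, `filter`, `demux`, `annotate`, `alpha`, `call`,
`efficiency`, `concordance`, `consensus`, and `tree`.

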