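---
title: "Models and methods behind nanotax"
author: "nanotax authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nanotax}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressMessages(library(nanotax))
```

nanotax implements a complete desk-scale analogue of a dual-barcoded
full-length 16S rRNA amplicon workflow on long, error-prone
(nanopore-style) reads: read simulation with ground truth, quality/length
filtering, two-level demultiplexing by PCR barcodes within native pools,
EM-based species-level abundance estimation, the run/sample/concordance
and diversity metrics used to validate such workflows, and consensus +
phylogeny building. This vignette explains the models, the tunable
parameters, the numerical choices, and what the synthetic data do and do
not establish about real sequencing runs.

## The amplicon model

Every simulated read derives from a barcoded amplicon laid out as

```
[fwd barcode (12 bp)] [fwd primer] [16S insert (~1.5 kb)]
    [revcomp(rev primer)] [revcomp(rev barcode)]
```

for a total of roughly 1.6 kb. Two barcoding modes exist: **1BC** places
the same 12-bp barcode on both primers (fewer multiplexed samples, more
depth per sample), **2BC** places independent forward/reverse barcodes
(combinatorial multiplexing at lower per-sample depth). A *native pool*
is the set of samples sharing one library-preparation barcode; it is
modeled throughout as a separate input FASTQ file, so the native
demultiplexing step (a hardware/basecaller concern) is out of scope.

Barcodes are non-degenerate 12-mers. `makeBarcodes()` generates them
with pairwise Hamming distance at least 6; at the demultiplexer's
default tolerance of 2 mismatches, two such barcodes cannot be confused
by substitutions alone. Primers may contain IUPAC degenerate bases; the
default pair is the canonical full-length 16S 27F/1492R pair. The exact
barcode/primer sets of any particular laboratory protocol are
configuration, not code: `readScheme()`/`writeScheme()` serialize the
whole scheme (barcodes, primers, mode, pool layout) as one YAML file.

## The simulator: what it emulates, and what it does not

`simulateReads()` applies, per base, a three-way choice
(delete / substitute / pass) followed by an independent insertion after
each retained base, then emits the read reverse-complemented with
probability `flipProb` (default 0.5, as on a real flow cell). Per-base
qualities are drawn from Normal(`meanQuality` = 14, `qualitySd` = 3),
clipped to [1, 50]; the default mean matches the mid-teens average Phred
scores typical of current simplex basecalls. Reference databases come
from `makeReferenceDb()`: one random ancestor, each taxon an independent
per-site mutant at a configurable divergence (default 0.1, giving
pairwise identities around 81% — comfortably species-distinct).

Deliberate simplifications, so that passing tests are read correctly:

* **Qualities are independent of the introduced errors.** The filter
  only consumes the marginal quality distribution, so correlation is
  unnecessary; but quality-aware downstream methods would be flattered
  by this data.
* **Errors are i.i.d. per base.** Real nanopore error is
  homopolymer-structured and bursty; demultiplexing yields measured
  here (see below) transfer only qualitatively.
* **The insert is the whole reference sequence** — primer binding
  inside a longer gene is not modeled.
* Chimeras are off by default (`chimeraRate = 0`) and exist only as an
  adversarial fixture for ambiguity handling.

Everything is deterministic given `seed`, including byte-identical
FASTQ/truth output, which the test suite asserts.

## Filtering

`filterReads()` keeps reads of 1,300–1,800 bp whose
error-probability-averaged quality exceeds 9. The per-read quality is

$$Q = -10\,\log_{10}\Big(\tfrac1n\sum_i 10^{-q_i/10}\Big),$$

the Phred transform of the mean per-base error probability — the
convention of long-read filtering tools, and materially lower than the
arithmetic mean on heterogeneous reads (a read of half Q5 / half Q30
averages arithmetically to 17.5 but carries ~16% error mass, Q ≈ 8).
The quality cutoff is **strictly greater than** 9 by default — a read of
constant Q9 fails — with `strict = FALSE` available because common
filtering tools use ≥.

## Demultiplexing

`demultiplexRead()` is primer-anchored:

1. **Orient.** The forward primer is searched in the first 100 bases
   (forward orientation) and, reverse-complemented, in the last 100
   bases; a reverse-strand read is canonicalized by reverse
   complementation. The scan is *ungapped* and IUPAC-aware, tolerating
   3 mismatches by default; ties prefer the lower offset and the
   forward strand.
2. **Require both primers** (reverse primer as its reverse complement
   near the 3′ end), else `no_primer`.
3. **Call barcodes** at the fixed 12-base windows flanking the primer
   hits, by plain Hamming distance with tolerance 2. In 2BC mode both
   calls are required; in 1BC mode the reverse barcode is optional but,
   when readable, must not contradict the forward call — contradictions
   discard the read (`conflicting`), trading yield for purity. Tied
   minimal distances are `ambiguous`; a valid pair missing from the
   layout is `no_barcode` with reason `not_in_layout`.
4. **Trim** to the bases strictly between the primer hits, in forward
   orientation.

A read-side `N` matches only a pattern-side `N`: an uncalled base is no
evidence of barcode identity.

Design notes. The tolerances (2 of 12 barcode mismatches, 3 primer
mismatches, 100-base windows) are package defaults chosen so that
noiseless recovery is exact and minimum-distance-6 barcodes cannot
collide; no tolerance values are inherited from any particular wet-lab
protocol. Because both the primer scan and the barcode comparison are
ungapped, *insertions or deletions* inside the primer or barcode usually
push a read over the mismatch budget: at 2% substitution + 2% insertion
+ 2% deletion the assigned fraction drops to roughly 15% while assigned
reads remain 100% correct — the sound-but-conservative regime the
two-level design targets. Raising the barcode tolerance never loses 2BC
assignments (assignment requires a unique minimal-distance barcode,
which is tolerance-independent once reachable); in 1BC mode the
contradiction rule can, rarely, discard a read that a smaller tolerance
would have accepted, which is why the monotonicity property is asserted
for 2BC.

1BC-constructed reads demultiplex identically in 2BC mode, since their
layout pairs are diagonal; this equivalence is asserted on noiseless
pools.

## EM abundance estimation

`scoreReads()` aligns each read locally (both strands, best kept)
against each reference with blastn-like scores (match +2, mismatch −3,
gap open 5, gap extend 2) and converts the alignment to a likelihood

$$L_{rt} = p_{\mathrm{err}}^{\,\mathrm{mismatches}+\mathrm{indels}}
           (1-p_{\mathrm{err}})^{\mathrm{matches}},$$

with a fixed per-base error rate `pErr = 0.1` (fixed rather than learned
to keep the toy-scale model identifiable). Alignments covering less than
80% of the read are zeroed — junk reads get an all-zero row and are
excluded from estimation while still counted in `totalReads`. Rows are
rescaled by their maximum: a per-read constant that cancels in the EM
posterior and keeps 1.5-kb likelihoods inside double precision.

`emAbundance()` runs the standard mixture EM (uniform initialization
over supported taxa; E-step posterior ∝ \(f_t L_{rt}\); M-step
\(f_t\) = mean posterior) to a `1e-6` max-change tolerance or 100
iterations, then drops taxa below the reporting floor `minAbundance`
(default `1e-4`, a typical profiler floor) and renormalizes. The
observed-data log-likelihood is recorded per iteration and asserted
non-decreasing. For at most 3 taxa and 20 reads the EM solution is also
checked against a dense 0.01-step grid search of the mixture
likelihood, agreeing within 0.02 per component. This module
re-implements the *role* of a long-read 16S profiler — correct species
and calibrated abundances at desk scale — not any particular tool's
probability model or reference database.

## Metrics

* **Pool efficiency**: reads of a native pool that also received a PCR
  barcode assignment, divided by the pool's total reads.
* **Sample calls**: the top species by abundance (lexicographic
  tie-break for determinism), with a purity gate at ≥ 0.90 and a depth
  gate at ≥ 10 reads. Note the deliberate asymmetry with consensus
  bins, which require *more than* 10 reads: both thresholds follow
  their respective conventions literally.
* **PPV** = TP/(TP+FP); in a positives-only validation design neither
  sensitivity nor specificity is computable.
* **Cramér's V** uses the Pearson χ² statistic without continuity or
  bias correction (the default of the common implementations);
  all-zero rows/columns are dropped first. **Theil's U** is the
  natural-log uncertainty coefficient; because the literature rarely
  states its conditioning direction, the direction is an explicit
  argument rather than a guess.
* **Alpha diversity**: richness, Shannon in nats (base configurable),
  Berger-Parker dominance. An empty profile reports (0, 0, 0) — an
  explicit convention beats an exception in batch reports.
* **Bray-Curtis** on relative abundances over the union taxon universe,
  `vegan::vegdist` underneath; **PERMANOVA** delegates to
  `vegan::adonis2` with seeded permutations and the
  \((1+\#\{F_\pi \ge F\})/(1+n_\pi)\) p-value convention. Permutations
  that happen to preserve the grouping tie the observed statistic, so
  the attainable p floor can sit slightly above \(1/(1+n_\pi)\) in tiny
  designs.
* **Rarefaction** subsamples without replacement (`vegan::rrarefy`),
  seeded.

## Consensus and phylogeny

`greedyCluster()` processes reads longest-first (ties by id) and joins
each read to the first bin whose centroid identity reaches the
threshold (default 0.97), else seeds a new bin — a deterministic
centroid clustering in the vsearch tradition. Identity is pinned as
matches / alignment length *including gap columns* (configurable to
matches / shorter length). Only bins with **more than** 10 reads are
kept for consensus. `consensusSequence()` aligns members to the
centroid and takes per-column majority votes (ties keep the centroid
base; a strict gap majority deletes the column; insertions need > 50%
of members, with a lexicographic tie-break) — a dependency-free
majority-vote polisher that is adequate at these error rates, in place
of neural consensus polishing, and recovers simulated templates to
within one edit at 3% substitution / 1% indel with 30 reads.

`njTree()` delegates to canonical neighbor joining (exact on additive
matrices — asserted against random additive trees up to 8 taxa) and
then clamps negative branch lengths to zero, moving the deficit onto a
sibling edge so the tree's total length is preserved. Bootstraps
resample the columns of a star alignment built against the longest
sequence (insertions relative to the reference are dropped), rebuild
the NJ tree from pairwise-deletion p-distances per replicate, and
report bipartition frequencies as node labels in [0, 1]; the trivial
root split is reported as 1. Star alignment is a substrate for column
resampling, not a competitor to dedicated MSA tools; for distant
sequences its pairwise projections underestimate homology near indels.

## Problem sizes and determinism

The test suite and the acceptance script exercise, among others: an
8-sample 2BC pool at 100 reads/sample (noiseless and at 2%
substitution/insertion/deletion), a 600-read three-taxon mixture at
0.6/0.3/0.1 with 3% substitutions and 10% reference divergence, a
200-replicate PERMANOVA null calibration at 199 permutations, and
100-replicate bootstraps. These sizes give stable verdicts for every
assertion while keeping a full run in minutes on one core; all
randomness is seeded, and rerunning any component with the same seed
reproduces its output byte-for-byte.

## Known limitations

* The i.i.d. error model understates structured nanopore error; the
  demultiplexer's measured yield (not its soundness) will differ on
  real data, and the ungapped barcode/primer matching is the yield
  bottleneck under indels.
* The EM scorer's fixed `pErr` and coverage cutoff are not calibrated
  per run; abundances of taxa below ~10% divergence from each other
  will partially merge.
* Majority-vote consensus cannot correct systematic (correlated)
  errors the way a signal-aware polisher can.
* Star alignment quality bounds the bootstrap's meaningfulness for
  deep divergences; for publication-grade trees, export the consensus
  FASTA and use a dedicated MSA tool.
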