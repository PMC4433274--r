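---
title: "Methods: small RNA-seq miRNA quantification, discovery and pathway targeting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small RNA-seq miRNA quantification, discovery and pathway targeting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
options(mirflow.verbose = FALSE)
```

mirflow re-implements, as plain tested functions, the analysis chain of
a two-group small RNA-seq miRNA study: read QC and classification,
normalized differential expression, rule-based novel-candidate
discovery, seed-based conservation and target analysis, genomic
proximity clustering, and qPCR cross-validation. This vignette is the
package's own account of the methods: the procedures, their
assumptions, the tunable parameters, the numerical choices, and what
the synthetic data can and cannot show.

## The data model

The unit of input is a *collapsed read*: a unique small-RNA sequence
with the number of times it was observed. Ids follow the
`seq-<rank>_x<count>` convention, so counts travel with the sequence
through every stage. Internally all RNA-side sequences live in the
A/C/G/U alphabet (T is mapped to U on input; IUPAC ambiguity codes are
rejected rather than guessed at), genomes stay in DNA, and all genomic
intervals are 0-based half-open, which keeps gap and overlap arithmetic
free of off-by-one cases. Every stage logs its input and output tallies
at INFO so the whole QC cascade can be reconstructed from a log.

## Read classification

Each read takes the *first* matching category in a fixed order:
`too_short` (length < `min_read_length`, default 18 nt), `unaligned`
(no exact occurrence in the genome on either strand), `known_mirna`
(full-length string equality with a panel mature sequence), `ncrna`
(exact substring of a supplied non-miRNA ncRNA set), else
`unannotated`. Three choices deserve comment:

* "High quality" is operationalized as the length filter only. The
  upstream base-calling and adapter trimming of a real instrument are
  unrecoverable from collapsed reads, and the length threshold is the
  part of the definition that matters downstream.
* Known-miRNA matching requires *full-length* equality, not substring
  containment: a read that is a proper fragment of a mature sequence is
  deliberately left to the genome/ncRNA/unannotated logic. Exact
  matching keeps the stage deterministic; there is no mismatch
  tolerance anywhere, and hence no aligner.
* Multi-mapping reads keep all genome hits but contribute their count
  once to each cascade tally — no fractional assignment.

Cascade percentages are rounded half-up to two decimals (base R's
`round()` rounds half to even, which does not reproduce conventionally
printed percentages; `round_half_up()` does).

## Normalization and differential expression

Counts are normalized to reads per million of the sample's
genome-matched total — the denominator is a per-sample property of the
QC cascade, not a library-size estimate. Group comparison uses the
pooled-variance Student's t-test with df $= n_1 + n_2 - 2$ (df = 4 in
the 3-vs-3 design); Welch's correction is not used because the target
procedure names Student's test. The test runs on the RPM scale. Whether
to test raw, normalized, or log-transformed values was genuinely open;
plain RPM after normalization was chosen as the most direct reading,
and a `log2_transform` switch (with `pseudocount`) exists for
sensitivity analysis.

A miRNA is *significant* at p < `p_threshold` (0.05) and
*differentially expressed* only if additionally its late/mid ratio is
strictly greater than `fold_threshold` (2.0) or strictly less than its
reciprocal — a ratio of exactly 2.0 does not qualify. No
multiple-testing correction enters the calls, matching the target
procedure; a Benjamini–Hochberg column is attached as clearly
supplementary output. Degenerate inputs are defined, not errors: zero
pooled variance with equal means gives t = 0, p = 1; with unequal means
it gives p = 0 and an infinite t, flagged as degenerate; a miRNA absent
from the mid group gets an `Inf` ratio sentinel and is decided by
significance alone. By default no pseudocount is added.

## Novel-candidate discovery

This stage is a transparent rule-based stand-in for probabilistic
discovery tools, reproducing their three load-bearing ideas — genome
mapping, a count filter, and hairpin plausibility — without the scoring
model:

1. **Locus grouping.** Unannotated reads whose genome hits overlap or
   lie within `locus_merge_gap` (30 nt) are chained into loci.
2. **Excision.** The highest-count read of a locus is the putative
   mature; the precursor window runs from `precursor_upstream` (20 nt)
   before to `precursor_downstream` (50 nt) after it on its strand, and
   the mirrored window is also folded — the better hairpin wins. The
   asymmetric window reflects that a mature can sit on either arm.
3. **Folding.** `fold_nussinov()` maximizes total pair weight (GC = 3,
   AU = 2, GU = 1) over pseudoknot-free structures with loops of at
   least `min_loop` = 3 nt by dynamic programming. The weights are a
   monotone proxy for stack stability, not free energies, and the
   reported `energy_score` (the negated weight) is labelled a score.
   Traceback is deterministic: on ties the 3' base is left unpaired
   first, then the smallest 5' partner wins. (An alternative tie-break
   by helix count was considered and dropped: it would require
   enumerating co-optimal structures, and determinism is the actual
   requirement.)
4. **Hairpin criteria.** `assess_hairpin()` accepts a precursor iff
   (a) after discarding helices shorter than `min_helix_stack` = 3
   stacked pairs, the remaining pairs form one contiguous nesting chain
   — i.e. a single stem–loop, with no second disjoint stem; (b) the
   mature lies entirely on one arm, strictly 5' or 3' of the terminal
   loop; and (c) at least `min_mature_paired` = 60% of mature bases are
   paired *within the surviving stem*. The pruning in (a) matters in
   both directions: genuine precursors sit in genomic context whose
   flanks almost always fold into incidental 1–2-pair helices, while
   shuffled sequence pairs densely but in short fragments. Counting
   only stem pairs in (c) is what makes the criterion discriminative —
   measured on shuffles of a planted precursor, rejection exceeds 90%,
   while constructed stem–loops pass.
5. **Retention.** A candidate needs `min_candidate_count` (10) total
   supporting reads. The count is read as the total over all samples,
   consistent with the `_x<count>` id convention of summed collapsed
   counts; a per-sample reading would be stricter and is not
   implemented.

## Conservation and seed families

The seed is the 1-based inclusive slice [`seed_start`, `seed_end`] of
the mature sequence, default positions 2–8. A candidate is *conserved*
relative to a panel entry iff the seeds are exactly equal (no G:U
tolerance) and overall identity is at least `identity_threshold`
(50%). Identity is the maximal number of identical aligned nucleotides
(global alignment scoring match +1, mismatch 0, gaps free — equivalent
to the longest common subsequence) expressed as a percentage. The
denominator was an open choice: the longer sequence (conservative,
default), the shorter, or the alignment length; all three are
available via `identity_denominator` because the "percentage of the
overall mature sequence" phrasing admits each reading.

## Targets and pathway relatedness

A target site is an exact occurrence of the reverse complement of the
seed in a 3'UTR; all (including overlapping) occurrences are reported,
and a gene is targeted iff it has at least one site. The same seed rule
is applied uniformly to known miRNAs and novel candidates — duplex
scoring predictors with energy models are out of scope, and the uniform
rule makes one formal property available: miRNAs with equal seeds have
identical predicted target-gene sets, which is the mechanism behind
seed-family observations. A miRNA is pathway-related iff it targets at
least `min_pathway_targets` (2) *distinct* genes of the supplied
pathway list; overlapping sites in one gene cannot manufacture
relatedness. "Primary genes of the pathway" is operationalized as
exactly the user-supplied list; a demonstration TGF-β list (ligands,
receptors, SMADs, SAR1A) ships in `inst/extdata/`.

## Genomic clusters

Loci on one chromosome are chained single-linkage: a locus joins the
open cluster when its start is within `cluster_gap` (10 kb) of the
cluster's maximal end, i.e. distance is the end-to-start gap, zero for
overlaps. Midpoint distance was rejected because it depends on feature
length. Strand is ignored (real clusters mix arms), singletons are
dropped, and equality with a brute-force transitive-closure oracle is
part of the test suite. Per-cluster direction concordance tolerates at
most one member missing from the DE table when all the rest agree.

## qPCR cross-validation

Replicate Ct values are averaged per (target, sample); ΔCt subtracts
the U6 reference within the sample; group ΔCt values are averaged, and
ΔΔCt = ΔCt(late) − ΔCt(mid) gives the relative expression 2^−ΔΔCt with
amplification efficiency fixed at the canonical base 2. A ratio
strictly below 1.0 classifies as low expression. Averaging ΔCt over
samples before differencing groups (rather than differencing per
matched sample) was an open choice; the two agree in expectation, and
mean-then-difference requires no sample pairing. The sequencing-vs-qPCR
comparison is the Pearson correlation of log2 ratios (ratios live on a
multiplicative scale; log2 makes additive shifts out of rescalings),
with Spearman available.

## The synthetic-data generator

`simulate_dataset()` emulates the study at desk scale, with all
randomness under one seed and byte-identical outputs on repeat runs.
Defaults, chosen once as the simulated study conditions:

* **Design:** two groups of 3 samples; expected genome-matched depth
  200,000 reads/sample (the study's 12–13 million scaled ~60-fold so
  the suite runs in seconds), with per-sample depth factors drawn
  within ±10% so normalization is non-trivial.
* **Genome:** 3 chromosomes × 10 kb carrying 60 embedded known matures
  (screened to occur exactly once genome-wide), 8 stem–loop precursors
  (22 nt arm, 8 nt loop, reverse-complement arm with up to 2
  mismatches), 10 decoy loci (shuffles of precursor-like sequence,
  deliberately unscreened — a shuffle may fold by chance), and 5
  embedded ncRNAs. Each planted precursor is validated at generation
  time by excising its discovery window and running the discovery
  hairpin check, re-drawing the precursor *and its genomic flanks* on
  failure — a fixed flank can carry a helix that defeats the
  single-stem test for every redraw, which is why flanks are re-drawn
  too.
* **Counts:** per-miRNA baselines log-uniform over 20–2000 expected
  counts; late means are mid means times the planted ratio (defaults:
  10% of ids at 4.0, 15% at 0.25 — both beyond the 2.0-fold gate);
  counts are negative binomial with variance mu + dispersion·mu²,
  dispersion 0.1 by default (typical of human biological replicates).
  Dispersion 0 yields deterministic counts equal to the rounded means
  — the exact degenerate case used by the end-to-end recovery tests —
  rather than the Poisson limit, so "no noise" means literally none.
* **UTRs and pathway:** 30 genes with 200 nt UTRs; planted (miRNA,
  gene) pairs receive exactly one seed-complement site at a recorded
  offset (multi-site biology is out of scope), and all UTR sequence is
  screened so that no unplanted seed complement of any annotated
  mature occurs — the target stage therefore sees exactly the planted
  truth. Most differentially expressed novel hairpins are planted into
  2 pathway genes, with single-gene boundary cases.
* **qPCR:** Ct tables whose late-group shift is −log2(planted ratio)
  plus Gaussian sample (0.15 cycles) and replicate (0.1 cycles) noise.

What the generator does *not* emulate — and what passing tests
therefore do not show about real data: sequencing error and adapter
artifacts, multi-mapping repeat structure, non-uniform genomic base
composition, isomiR heterogeneity, partial-complementarity target
sites, and real thermodynamic folding. The generator validates the
pipeline's logic, not the biology of any particular dataset.

## Problem sizes and test design

The test suite builds all fixtures in code. Oracle-equivalence tests
run the folding DP against exhaustive structure enumeration (200
random sequences up to 14 nt), identity against exhaustive subsequence
enumeration (lengths ≤ 8), classification against a naive quadratic
scan, and clustering against transitive closure. Parameter-recovery
checks use 200 simulated miRNAs with planted ratios {0.25, 1, 4} at
dispersion 0.02 and measure the empirical type-I rate on 1000
simulated null miRNAs; the end-to-end smoke test runs the default
study spec. These sizes were chosen so the whole suite completes in
about two minutes while keeping every estimate's Monte-Carlo error
well inside the margins being asserted.

## Known limitations

* Exact-match classification cannot model the mismatch tolerance of a
  real aligner; reads with SNPs or sequencing errors land in
  `unaligned`/`unannotated` rather than their biological class.
* The weight-based folding stand-in has no loop-destabilization terms,
  so its scores order structures only roughly as free energies would;
  it is used strictly as a gate, never as an energy estimate.
* The t-test on three-vs-three RPM values has limited power and relies
  on approximate normality; the simulated type-I rate holds at the
  default dispersion, but heavy-tailed real data may deviate.
* Candidate per-sample counts attribute reads to the locus of their
  best-supported mature; ambiguous multi-locus reads are counted at
  every locus they hit.
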