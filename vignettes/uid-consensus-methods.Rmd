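---
title: "UID-consensus amplicon calling: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{UID-consensus amplicon calling: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampliclust)
```

## The problem

Detecting somatic variants at allele fractions of 1% and below in cell-free
DNA (cfDNA) requires separating true mutations from PCR and sequencing errors
that occur at comparable rates. ampliclust implements the computational side
of a tandem-enrichment assay: a multiplex PCR whose primers carry unique
identifiers (UIDs), followed by hybrid capture to strip off-target byproducts.
Each UID is 13 bases: a 3-base fixed tag identifying the primer and a 10-base
random barcode distinguishing molecules. Because every priming event installs
a fresh barcode while the daughter strand copies its template's far-end UID,
amplicons descending from one template form a connected family of UID pairs,
and reads can be grouped back to their source molecule by graph clustering.
A variant is then called from *cluster consensus*: the allele fraction is
`VAF = n_alt / (n_alt + n_ref)` where the counts are clusters, not reads, so
that amplification bias and stray read errors largely cancel.

## The genealogy model

The simulator tracks single strands through the UID-tagging PCR:

* At cycle 0 a template molecule contributes two original genomic strands,
  one primeable by each side's primer.
* Each original strand templates a UID primer **exactly once**; from then on
  it is inert. Its daughter carries one UID.
* Every UID-bearing strand (one or two UIDs) is primed in each cycle with
  probability `efficiency`; the daughter receives a fresh UID on the primed
  side and copies the template's far-end UID, so parent and daughter share
  exactly one UID.

Under this model the number of distinct complete UID pairs descending from one
molecule satisfies the recursion `P(c) = 2 P(c-1) + 2` with `P(2) = 2`, i.e.
`P(c) = 2^c - 2` at efficiency 1, and never exceeds that ceiling at any
efficiency. That ceiling is exactly the bound the cluster filter assumes
(clusters with more than `2^cycles - 2` UID pairs are discarded as barcode
collisions), so simulator and pipeline are mutually consistent; the tests
check both the attained equality (cycles 2-6 against an exhaustive
enumerator) and the bound under random efficiencies.

One structural consequence deserves emphasis: the two original strands of a
double-stranded molecule found **two disconnected UID families**, because two
strands can never share a random barcode. A molecule therefore maps to *up to
two* clusters. Cluster purity (every cluster from one molecule) is exactly 1
in collision-free runs, and VAF estimates are unaffected because mutant and
wild-type molecules split into families at the same rate; only absolute
cluster counts are roughly twice the molecule count. The tests assert purity
1.0 and at most two clusters per molecule.

Polymerase substitutions are drawn at `pcr_error` per synthesized base and
inherited by all descendants of a strand. An error that lands in a family's
root strand is carried by the entire family and is *by design*
indistinguishable from a true mutation; this is why the assay's specificity
rule tolerates non-reference clusters up to 0.1x the reference count rather
than demanding exact zero, and why the package's exact-zero regression test
switches polymerase errors off while leaving sequencing errors on (consensus
must suppress those completely).

## Later amplification, capture and sequencing

Index and final PCR multiply each complete amplicon through an exact
per-cycle binomial branching process (`N <- N + Binomial(N, efficiency)`); no
new UIDs appear. Copy numbers are tracked exactly, but polymerase errors from
these later cycles are applied per *sequenced read*, at rate
`pcr_error x cycles x efficiency / (1 + efficiency)` per base (the expected
number of syntheses in a surviving lineage). Storing per-copy error sets for
millions of copies is infeasible, and because later errors are essentially
never shared between sampled reads, the per-read approximation leaves
consensus behavior unchanged.

Byproducts emulate what multiplex PCR produces besides the intended
amplicons: primer-dimer chimeras (same-target chimeras pass exact primer
extraction and must be removed by the aligner's soft-clip/MAPQ filter;
cross-target chimeras fail extraction) and random-insert molecules, at
500-700 bp. Hybrid capture then retains each copy independently - 0.95 for
on-target molecules, 0.01 for byproducts by default; retentions of `(1, 1)`
are the PCR-only control protocol. Sequencing draws read pairs proportional
to copy number; read 1 is `[left UID][forward primer][insert...]` and read 2
mirrors it from the other end.

## What the generator emulates, and what it does not

The defaults are the emulated assay's stated study conditions: 2,900 haploid
genome equivalents (10 ng at 3.44 pg per haploid genome), each contributing a
template at every target locus; 8 tubes filled round-robin; 10 UID cycles;
10 index plus 20 final cycles; 2 x 150 bp reads; cfDNA fragment lengths
N(166, 10) truncated to span the amplicon. Values the protocol does not state
were fixed once at levels realistic for multiplex cfDNA work and are not
tuned per analysis:

| parameter | default | rationale |
|---|---|---|
| `efficiency` | 0.15 per cycle | keeps expected UID pairs per molecule in the single digits, the regime where the depth >= 2 and >= 2-pair filters bite realistically |
| `n_read_pairs` | 250,000 | mean UID-pair depth ~5, the usual UMI-consensus working depth |
| `pcr_error` | 1e-5 /base/synthesis | proofreading polymerase scale |
| `seq_error` | 1e-3 /base | short-read substitution scale |
| `byproduct_rate` | 0.30 | a visible byproduct load for the PCR-only control |
| capture retentions | 0.95 / 0.01 | strong but imperfect pulldown |

The generator is substitution-only (no indel errors: the panel's deletions
are true variants, not error processes), has no GC- or length-dependent
amplification bias, no polymerase error spectrum, and no quality-score
structure (all bases Phred 40). Passing tests therefore demonstrate the
pipeline's logic - grouping, clustering, consensus, the filter arithmetic -
under a faithful genealogy; they do not demonstrate robustness to real-world
artifacts such as context-dependent error hotspots, adapter chimeras beyond
the modeled classes, or mapping ambiguity in repetitive genomic regions (the
synthetic amplicons are non-repetitive by construction).

## Numerical and design choices

* **Coordinates.** 1-based inclusive in every file a user reads or writes;
  0-based half-open everywhere internally, which makes the indel
  intersection/union arithmetic exact.
* **Consensus tie rule.** The representative base must hold at least 50% of
  pooled calls *and be unique at that level*: a 50/50 split yields `N`. An
  "at least 50%" rule alone would admit two representatives at a tie, which
  is unusable for calling. Mates that disagree at an overlapping position
  contribute `N` there.
* **VAF denominator.** Clusters whose representative is `N` or a third
  allele are excluded - the published two-term formula counts only alternate
  and reference clusters. `n_alt + n_ref = 0` yields a no-call (`NA`), never
  a 0.
* **Indel overlap.** "Length of the overlapping region over the combined
  region" is implemented as intersection over union: the only reading that is
  symmetric, bounded by 1, and equal to 1 exactly for identical intervals,
  which the strict `> 0.9` same-event cutoff presupposes. The two overlapping
  panel deletions sit at 10/23 = 0.435 and can never cross-assign.
* **Indel observations.** VAFs averaged "across observations" use per-tube
  VAFs as the observation unit - tubes are the independent amplification
  replicates.
* **Melting temperature.** Unified nearest-neighbor parameters with terminal
  initiation terms, the entropic salt correction `0.368 (N-1) ln[Na+]` at
  50 mM, and 250 nM excess primer. The window filter (57.5-62.5 C) is
  inclusive at both bounds; the GC "optimal" window is `[40%, 60%)`,
  half-open to match the reporting bins (GC < 40%, 40-50%, 50-60%, >= 60%).
* **Dimer screen.** The longest stretch of one primer reverse-complementary
  to the other, flagged at >= 8 bases when the stretch includes either
  primer's 3' terminus (the extensible geometry). The threshold is a package
  default; no published value exists.
* **Aligner.** Reads carry an exactly matched primer immediately after the
  UID, so their error-free register on the amplicon is fixed; each mate is
  first compared at that register (C-speed Hamming), and only reads exceeding
  6 mismatches - deletion carriers, junk inserts, error bursts - go to the
  affine-gap global-local alignment (match +1, mismatch -4, gap open -6,
  extend -1). The mapping-quality surrogate is 60 at >= 80% of the maximal
  score, scaled toward 0 below; a terminal run of >= 5 covered-but-mismatching
  bases sets the soft-clip flag. The tests pin this aligner to a hand-written
  exhaustive affine DP on 200 random instances. When alignments are ingested
  from SAM, the native MAPQ applies instead.
* **Operating formulas.** Sensitivity `TP/(TP+FP)` and specificity
  `TN/(TN+FN)` are implemented exactly as the assay defines them, although
  they differ from the textbook quantities; `standard = TRUE` offers
  `TP/(TP+FN)` and `TN/(TN+FP)` for comparison. A missed positive therefore
  lowers *specificity*, which explains occasional sub-1.0 specificity in
  seeds where one variant falls just under the 0.4x-known-VAF rule.
* **Depth filter.** 0.05% of the maximum per-target cluster count for the
  primer set, applied to `n_alt + n_ref` (a maximum of 252,000 clusters gives
  the cutoff 126). The maximum is taken over per-target totals.
* **Ordering of filters.** UID pairs below depth 2 are removed *before*
  network construction, then clusters with fewer than 2 pairs or more than
  `2^cycles - 2` pairs are discarded, in that order.
* **RNG.** One integer seed per configuration, expanded deterministically
  into per-stage sub-seeds, so stages can be re-run independently and whole
  runs are byte-identical.
* **Deletion junctions in the synthetic panel.** The panel generator rewrites
  the bases flanking each deletion junction so the optimal affine-gap
  alignment is unique at the truth coordinates; with ambiguous junctions an
  equally scoring shifted gap fails the strict 0.9 overlap rule - a genuine
  property of overlap-based assignment worth knowing about on real data.

## Problem sizes

Simulation-backed analyses in the test suite and acceptance script run at the
study conditions (2,900 genome equivalents x 7 targets, 8 tubes, 250,000 read
pairs), about 15 seconds per run; aggregate checks use 5 independent seeds.
Unit-level properties (clustering oracles, aligner oracle, spike-in binomials)
run on reduced instances - random graphs up to 50 nodes, sequences up to
60 nt, 60-molecule libraries - where exhaustive oracles are feasible.

## Known limitations

* Insertions are out of scope (the panel contains SNVs, deletions and one
  codon target); the aligner handles them but no caller consumes them.
* Barcode-collision chimeras are simulated honestly (10-base barcodes drawn
  uniformly) but the pipeline's only defenses are the per-target fixed tags
  and the `2^c - 2` oversize filter, as in the emulated assay; collision
  rates at much larger molecule counts would need longer barcodes.
* The codon target's summary counts are taken from its middle base (its
  classification uses all three bases via the two-step rule); a multi-allelic
  codon caller is not implemented.
* `uniformity()` and the on-target ratio use fragments that survived
  alignment filtering; with an external aligner the equivalent quantities
  should be computed from its primary proper pairs.
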