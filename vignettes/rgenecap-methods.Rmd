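---
title: "Classifying plant resistance genes and designing capture probes with rgenecap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying plant resistance genes and designing capture probes with rgenecap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rgenecap)
```

## The problem

Plant disease-resistance genes (R-genes) encode immune receptors that
recognize pathogen effectors. Most fall into a handful of architectures:
TIR-NBS-LRR (**TNL**), CC-NBS-LRR (**CNL**), receptor-like kinases (**RLK**,
extracellular LRRs plus an intracellular kinase) and receptor-like proteins
(**RLP**, extracellular LRRs without a kinase). Finding new family members in
unannotated genomes, transcriptomes or crop wild relatives is hard because
R-genes diversify quickly; sequence-similarity searches against small
reference sets miss divergent homologs.

`rgenecap` addresses this with two coupled tools:

1. a **four-class one-vs-rest SVM classifier** over alignment-free,
   sequence-compositional protein features, so that divergent family members
   are recognized by their global compositional signature rather than by
   similarity to any particular reference; and
2. a **capture-probe designer** that tiles hybridization baits over the
   nucleotide sequences of predicted R-genes, for targeted enrichment
   sequencing (RenSeq-style SeqCap experiments) that validates predictions
   and recovers allelic variants from non-sequenced material.

Transcript input is supported directly: an open-reading-frame extractor
produces one protein per transcript, and predictions map back to nucleotide
space for probe design.

## The feature encoding

Each protein is encoded as a fixed-layout vector of six concatenated
compositional blocks (default width 8444):

| block            | width | definition                                                           |
|------------------|------:|----------------------------------------------------------------------|
| `aac`            | 20    | frequency of each canonical residue                                  |
| `dpc`            | 400   | overlapping dipeptide frequencies (lexicographic bins)               |
| `tpc`            | 8000  | overlapping tripeptide frequencies                                   |
| `multiplet`      | 20    | per-residue fraction lying inside homopolymer runs of length ≥ 2     |
| `charge`         | 2     | fractions of positively / negatively charged residues                |
| `hydrophobicity` | 2     | fractions of hydrophobic / canonical non-hydrophobic residues        |

k-mer blocks are normalized by window count (`length − k + 1`), the others by
length, so every entry lies in `[0, 1]` and block sums are bounded by 1.

Three definitions are deliberately explicit **package choices**, since binary
set-membership compositions admit several reasonable conventions:

* *multiplet*: residues inside maximal homopolymer runs of length ≥ 2,
  normalized by sequence length — a run-length view of low-complexity
  content;
* *charge sets*: positive {K, R, H}, negative {D, E} — histidine is counted
  as positive (its physiological charge is pH-dependent; including it makes
  the positive set the full basic triad);
* *hydrophobic set*: {A, C, F, I, L, M, V}, the residues with positive
  Kyte–Doolittle hydropathy.

All three sets are arguments of `encoding_config()`, so alternative
definitions can be swapped in and compared without touching the rest of the
pipeline. Non-canonical residues (`X` and friends) contribute to no bin but
stay in every denominator: vectors remain comparable across sequences with
rare ambiguity, and an all-`X` sequence encodes to (near) zero and is flagged
`low_information` at prediction time rather than dropped.

`min_length` defaults to 50 residues: tripeptide frequencies on shorter
fragments are dominated by sampling noise. Shorter sequences are rejected
with a reason and reported, never silently skipped.

## The classifier

One binary soft-margin SVM is trained per class against everything else
(other classes plus negatives), mirroring the one-vs-rest construction of
binary family classifiers. Kernels:

* polynomial: `K(x, y) = (x·y + 1)^d` — scale and offset are fixed at 1, the
  long-standing defaults of binary SVM tools for this kind of composition
  vector;
* RBF: `K(x, y) = exp(−g‖x − y‖²)`.

The default search grid sweeps `d ∈ 1..9` with `C ∈ 10⁻⁷..10¹³` for the
polynomial kernel (189 combinations) and `g ∈ 10⁻¹⁵..10³` with
`C ∈ 10⁻⁵..10¹⁵` for the RBF kernel (399 combinations) — 588 per class. Each
grid point is scored by stratified 5-fold cross-validation; folds differ in
size by at most one and keep each fold's positive:negative ratio within one
item of the global ratio, deterministically for a fixed seed.

Model selection maximizes the **mean Matthews correlation coefficient**
across folds — MCC is the natural criterion here because every binary
problem is heavily imbalanced (one class against four others' worth of
data), where accuracy saturates trivially. MCC is defined as 0 whenever a
confusion-matrix marginal is zero (the correlation is undefined there, and 0
— "no better than chance" — is the standard convention). Ties are broken by
higher mean accuracy, then polynomial before RBF, then smaller `d`, `C`,
`g`; the tie-break chain is a package choice made so that selection is
reproducible and prefers the simpler model.

Multi-label policy: a sequence receives every class whose decision value is
positive, plus a `primary` label (the argmax) — or `NON-R` when no decision
is positive. Independent binary models can in principle claim one sequence
for two classes; keeping all labels and a primary makes that visible instead
of hiding it.

Numerical choices: the solver is libsvm (through `e1071`) at tolerance
`1e-3`, without feature scaling — all features are already in `[0, 1]` and
rescaling would distort the relative weight of the wide, sparse k-mer blocks
against the narrow dense ones (a `standardize` step can be emulated by
pre-transforming the matrix if wanted). Internally the feature matrix is
converted to a sparse representation when every row has at least one nonzero
entry (tripeptide blocks are >90% zeros, and the sparse kernel evaluations
are several-fold faster); rows of all zeros fall back to dense, which libsvm
handles. Training is deterministic for fixed data and parameters.

Model bundles are saved with a format version and a fingerprint of the
encoding configuration; both are verified when a bundle is loaded, so a
model can never silently score features produced under a different encoding.
Reloaded bundles reproduce decision values to better than `1e-10`.

## Training-set curation

Positive training sequences are labeled from user-supplied domain
annotations by ordered rules:

1. TNL ⇐ {TIR, NB-ARC, LRR};
2. CNL ⇐ {CC, NB-ARC, LRR} without TIR;
3. RLK ⇐ {KINASE, LRR} without NB-ARC;
4. RLP ⇐ LRR without KINASE, NB-ARC or TIR;
5. otherwise UNCLASSIFIED.

TIR precedence over CC, and the NB-ARC exclusions for the receptor-like
classes, disambiguate sequences that carry domains of several architectures;
the composite annotation tokens `STK-LRR` and `KINASE-LRR` expand to
{KINASE, LRR} before matching. Domain detection itself (HMM scans) is out of
scope — annotations arrive as a TSV, which keeps the curation step
independent of any particular domain-scanning tool.

Redundancy removal uses greedy incremental clustering on shared distinct
k-mer fractions (k = 5, threshold 0.9 of the shorter sequence's k-mers), a
CD-HIT-like procedure without alignment. Records are processed longest
first (ties by id), so the output is invariant to input file order. A
"negative" whose annotation matches an R-gene rule is expelled and logged; a
duplicate sequence appearing in two classes is kept only in the first class
by rule order. Every drop, expulsion and cluster-collapse lands in a
provenance log.

## ORF extraction

Transcripts are reduced to proteins by a minimal built-in ORF finder: every
maximal ATG→stop ORF (earliest in-frame start per stop) on both strands,
with codon count — stop included — of at least `min_len_codons`
(default 100, the conventional floor for transcript ORF calling). ORFs
running off the transcript end are excluded; candidate spans containing `N`
are skipped with a warning; `N` inside a translated codon yields `X`.
Coordinates are 0-based half-open on the forward strand regardless of ORF
strand (BED-conformant, which makes the probe coordinate map trivial). The
pipeline takes the single longest ORF per transcript (ties: `+` strand, then
smaller start), which matches how transcript-to-protein extractors are
conventionally run with a single best ORF; `find_orfs()` exposes the full
set when all ORFs are wanted.

## Probe design

Probes are tiled at fixed length and step along each source: starts at
`0, S, 2S, …` while `start + L ≤ N`, plus (by default) one terminal probe
`[N − L, N)` when the last regular probe does not reach the 3' end — so every
base of a source at least `L` long is covered, and interior bases are
covered ≥ 2× whenever `S ≤ L/2`. Defaults are 120-nt probes at step 60 (2×
tiling), the common RenSeq/NimbleGen-style bait geometry. Filters: GC within
25–65%, homopolymer runs capped at 10, non-ACGT bases rejected — standard
capture-bait hygiene defaults, all configurable; a failed probe records
*every* rule it violates. Deduplication collapses exact duplicates (and, by
default, reverse-complement duplicates, since capture is strand-agnostic)
onto the first occurrence, keeps a collapse map, and warns when a collapse
removes the only coverage of a region. Output is probe FASTA plus BED;
re-extracting any BED interval from the source reproduces the probe exactly.

## The synthetic data generator

`generate_training_set()` emulates a curated positive/negative training set
with class-separable structure: each class couples a composition bias (three
class-specific residues at triple weight) with a planted 10-residue motif
(pairwise Hamming distance ≥ 5) inserted three times at random
non-overlapping positions; negatives are uniform i.i.d. sequences. Lengths
are uniform on 150–400 residues, roughly the span from a bare kinase domain
to a small NBS-LRR fragment. Both signal channels matter: the bias feeds the
single-residue blocks, the motifs feed the di/tripeptide blocks, mirroring
the premise that domain-bearing proteins differ both globally and locally
from the background. Default sizes are 100 positives per class and 400
negatives — a balanced, desk-scale stand-in for a curated training corpus of
a few hundred sequences per family.

What passing on synthetic data shows — and what it does not: recovery of
all four classes (cross-validated MCC ≥ 0.9 on this generator is expected by
construction) demonstrates that the feature encoding, fold stratification,
grid search, selection and prediction machinery are wired correctly, not
that real R-gene families are this separable. Real proteins violate the
generator's assumptions in known ways: residues are not i.i.d., domains are
long and structured rather than 10-mers, families share ancestry (the
negatives here are maximally unrelated), and class imbalance in real corpora
is larger. Performance claims on real data require real curated sets.

All generator outputs are deterministic under a single seed threaded through
every sampler; the class profiles themselves are fixed constants.

## Problem sizes used by the test suite

The packaged tests exercise the full study configuration once — training
on the 100-per-class/400-negative synthetic set with the reduced grid
(`d ∈ {1,2}`, polynomial `C ∈ {0.1, 1, 10}`; RBF `g ∈ {10⁻³, 10⁻¹}`,
`C ∈ {1, 10}`), 5-fold CV, and a disjoint stratified 30% holdout — and use
smaller draws from the same generator (8–15 per class) plus single-point
grids elsewhere, which keeps the suite's SVM work proportionate while still
covering every code path. On small training sets the soft-margin cost needs
to be ≥ ~10 for the near-constant polynomial kernel on compositional vectors
to fit at all, which is why the quick-test grids pin `C = 100`.

## Known limitations

* Feature definitions for multiplet/charge/hydrophobicity are stated package
  conventions, configurable but not validated against any external standard.
* The curation rules assume trustworthy domain annotations; no HMM scanning
  is performed.
* The ORF finder requires a complete ATG→stop ORF; truncated transcripts
  with partial ORFs yield nothing.
* Probe filtering is geometric/compositional only — no melting-temperature
  model and no cross-hybridization screen against a host genome.
* The classifier bundles are R serializations; they are versioned and
  fingerprinted but not portable to other languages.
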