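---
title: "Methods: mlncRNA discovery, miRNA annotation and qPCR analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mlncRNA discovery, miRNA annotation and qPCR analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mlncTools)
```

## The problem

De novo transcriptomes of non-model plants contain, alongside
protein-coding mRNAs, a substantial population of mRNA-like long
non-coding RNAs (mlncRNAs): spliced, capped, polyadenylated transcripts
with no open reading frame above the coding-potential cutoff.  With no
genome available, the evidence for calling a unigene non-coding is
indirect — absence of protein homology, absence of a sufficiently long
ORF, absence of a housekeeping-RNA signature — and downstream questions
(does the mlncRNA belong to a family? is it conserved? does it produce a
microRNA? does it relate to a coding gene in sense or antisense? does it
respond to stress?) each need their own screen.  mlncTools implements
that full chain as composable, deterministic functions, and pairs every
stage with a synthetic-data generator that plants known truth so the
chain is testable without any external database.

## Classification tree

`classifySet()` partitions a unigene set with these rules, in order:

1. **ANNOTATED_CODING** — the six-frame translation aligns to a supplied
   protein reference with E ≤ `annotation_evalue` (default `1e-5`), or a
   precomputed annotation table names the transcript.
2. **SHORT_UNANNOTATED** — unannotated and shorter than `min_length`
   (default 300 bp).  These are set aside, not analysed further.
3. **NOVEL_CODING** — best ORF of at least `orf_cutoff_aa` amino acids
   (default 100).
4. **HOUSEKEEPING_NPCRNA** — nucleotide homology to a housekeeping RNA
   reference (tRNA/snoRNA-class) at E ≤ `housekeeping_evalue`.
5. **MLNC_CANDIDATE** — everything else.

Two points were genuinely open and are package decisions:

* *Housekeeping screen placement.* The screen runs **after** the ORF
  test, so a long-ORF transcript is never called housekeeping; the
  housekeeping class is a subset of the non-coding branch.
* *Partial ORFs.* 3'-open ORFs (ATG to sequence end, no stop) count
  toward the 100-aa test by default (`countPartialOrfs = TRUE`),
  because EST/454 unigenes are frequently 3'-truncated and an
  interrupted ORF is weak evidence of non-coding status.  The flag is
  exposed for users who want complete ORFs only.

ORF conventions: ATG-initiated, stop-terminated, both strands, all
three frames; per (strand, frame, stop) the maximal ORF is reported;
`aa_length` excludes the stop codon.  Coordinates are 0-based half-open
internally and 1-based inclusive in written reports.  Frameshift-
tolerant ORF models were deliberately not implemented: the exhaustive
scan is deterministic and verifiable against a brute-force oracle.

## Homology, E-values, families and relations

All nucleotide homology steps (housekeeping screen, family clustering,
conservation screen, mlncRNA/coding relations) run through one local
aligner: Smith–Waterman with match +2, mismatch −3, and affine gaps
costing 5 + 2 per base — a desk-scale stand-in for BLASTN.  Both strands
are searched; antisense hits are alignments to the reverse complement,
with strand recorded on the subject.

Significance uses the Karlin–Altschul form `E = K·m·n·e^(−λS)` with
`K = 0.41`, `λ = 0.625` for the default nucleotide scoring (standard
ungapped-approximation constants, applied unchanged to gapped scores at
this scale); for the translated search the BLOSUM62 gapped constants
`K = 0.041`, `λ = 0.267` are used.  All four constants are arguments,
not magic numbers.  The pipeline's behaviour depends only on threshold
crossings at `E ≤ 1e-5`, which the synthetic designs place far from the
boundary: an embedded homolog scores hundreds of bits, a shuffled
control scores near the chance level.  The effective database length
`n` is the total length of the searched set, mirroring an all-vs-all
search.

Families are single-linkage connected components (size ≥ 2) of the
all-vs-all hit graph at the E-value cutoff; numbering is deterministic
by lexicographically smallest member.  Relations between an mlncRNA and
a coding transcript are localized on the coding gene relative to its
best ORF: `CDS` when the aligned subject interval is inside the ORF,
`UTR5`/`UTR3` when inside the respective untranslated interval (labels
follow transcript orientation for minus-strand ORFs), `junction`
otherwise.  The three region calls plus `junction` are exhaustive and
mutually exclusive for any interval.

## miRNA precursor annotation

The conserved-miRNA screen has three stages:

1. **Mature scan** (`scanKnownMirnas`): every transcript window on
   either strand within Hamming distance 3 of a known mature miRNA
   (19–24 nt, equal-length windows, no indels).  G:U counts as a
   mismatch here — this stage is sequence homology, not structure.  A
   word-size-4 seeded scan is lossless under this budget (pigeonhole:
   3 mismatches cannot break all exact 4-mers of a ≥ 19-nt window), so
   the implementation uses the equivalent exact mismatch-limited scan;
   a seed-free sliding-Hamming oracle checks the equivalence.
2. **Folding** (`rnaFold`): the mature ± 150 nt of context is folded by
   a Zuker-type minimum-free-energy dynamic program (no pseudoknots).
   The energy model is a simplified Turner-style nearest-neighbour set:
   stacking energies for all canonical pairs including G:U, tabulated
   hairpin/bulge/internal-loop initiation penalties with
   Jacobson–Stockmayer log extrapolation of long hairpin loops, a
   linear internal-loop asymmetry penalty (0.5/nt, capped at 3), and an
   affine multibranch model (3.4 + 0.4 per helix).  Dangling ends,
   terminal-mismatch bonuses, special tetraloops and coaxial stacking
   are omitted; bulge/internal loops above 30 nt are treated as
   prohibitively unstable.  The full table is returned by
   `foldEnergyParams()` and is editable.  Published mfold 3.x energies
   are **not** reproduced exactly — energy-parameter versions disagree
   at the ±0.05 MFEI level, which is why the accession-based MFEI
   checks carry that tolerance.
3. **Acceptance** (`evaluatePrecursor`): operationalized plant-miRNA
   annotation criteria — the mature must lie wholly on one arm of a
   single stem-loop, with at most 4 unpaired mature bases and no bulge
   larger than 2 nt within the mature:star duplex.  All thresholds are
   arguments of `precursorCriteria()`.

The minimal folding free energy index is
`MFEI = (|MFE| / length × 100) / GC%`.  Whether published MFEI values
refer to the whole unigene or the hairpin region alone is ambiguous in
the EST literature, so both are provided
(`mfeiRegion = "hairpin"` trims to the stem-loop containing the mature,
first to last paired base, and refolds it; `"full"` uses the extracted
context) and reports state which mode was used.

Mature miRNAs are grouped into families by single-linkage Hamming
distance ≤ 3 at the best ungapped offset, with length differences
counted as mismatches.  On the bundled 13-sequence mature set this
yields 8 families, 4 of them singletons — the package's standing worked
example (recomputed in the test suite and the acceptance script, never
hard-coded in the implementation).

## Target prediction

`predictTargets` slides a window along the forward strand and scores
each window with a weighted duplex penalty computed by dynamic
programming: Watson–Crick 0, G:U wobble 0.5, mismatch 1.0, each gap
position 2.0, with penalties at miRNA positions 2–13 (1-based from the
5' end) doubled, at most 2 gap positions per duplex, and a reporting
cutoff of 3.0.  The exact weights of the historical target-prediction
servers are version-dependent and unpublished; this schema follows the
classic plant-miRNA scoring lineage and every weight is an argument of
`penaltySchema()`.  Gap positions adjacent to the seed take the
multiplier of the next miRNA position to be aligned.  Overlapping
admissible windows are collapsed to the local minimum (leftmost on
ties), and the emitted set is exactly the set of windows at or below
the cutoff — the threshold is not approximate.  A sound per-window
lower bound (each miRNA base's cheapest apposition within the gap band)
prunes hopeless windows before the DP without affecting results.

## qPCR analytics

* `genormM` re-implements the reference-stability statistic: Cq values
  become relative quantities `2^(Cqmin − Cq)` per gene; for each gene
  pair the pairwise variation is the standard deviation of the log2
  ratio across samples; M is the mean over partners.  Per-gene
  constants and per-sample plate shifts cancel exactly.
* `deltaDeltaCq` implements comparative quantification,
  `fold = 2^−((ΔCq_s) − (ΔCq_calibrator))`; the calibrator has fold 1
  by construction and undetected reactions propagate as `NA`, never 0.
* Stress-response typing: published descriptions of cold types A/B/C
  and dehydration groups I/II/III are qualitative, so this module
  formalizes them with explicit cutoffs built on the 2-fold
  responsiveness criterion ("more than 2-fold between at least two
  time-points" is read literally as max/min > 2 over any pair).  Cold:
  A = not responsive; B = fold(1 h) ≤ 1/2; C = maximum fold ≥ 2 at
  1/5/10 h followed by decline at 24 h; B is checked before C.
  Dehydration: I = folds at 1/5/10 h within (1/2, 2) and
  fold(24 h) ≥ 2; II = fold(1 h) ≤ 1/2; III = fold(1 h) ≥ 2 and
  fold(24 h) < fold(1 h)/2.  Series that are responsive but match no
  template are reported `unclassified` rather than forced into a type.
  All thresholds are function arguments.
* `correlatePair` correlates log2 fold changes (Pearson) over a chosen
  time subset (default 5/10/24 h, the late phase where co-regulation is
  most visible); |r| < 0.5 or undefined correlation reports "none".

## The synthetic-data generator

`generateTranscriptome()` emulates the composition of a 454-era plant
unigene set: coding transcripts with planted 110–160-aa ORFs flanked by
UTRs (half of them entered into the generated protein reference, making
them "annotated"); mlncRNA-like transcripts of 300–700 bp whose ORFs
are suppressed below 80 aa by stop-codon seeding; short (< 300 bp)
fragments; housekeeping transcripts embedding entries of a bundled
*synthetic* structural-RNA reference; hairpin precursors built as
mature + 4–8-nt loop + near-perfect star (0–2 planted G:U wobbles) in
random flanks, each verified against `evaluatePrecursor` before
emission; target transcripts whose sites are written backwards from the
penalty schema so the planted penalty is exact by construction; and
mlncRNA families of sizes 2–8 as mutated copies (5% substitutions) of a
seed.  Background composition is uniform within a GC range of
0.35–0.55.  `generateCq()` emits technical-triplicate Cq time courses
(0/1/5/10/24 h) from subclass fold-change templates with Gaussian
replicate noise (default sd 0.2 cycles); the stable reference is
constant while the two alternative reference candidates carry fixed
condition-dependent shifts, so the stability ranking is a property of
the design rather than of a particular noise draw.

What the generator does **not** emulate: 454 homopolymer errors,
assembly chimeras and frameshifts, expression-level-dependent coverage,
paralog families of coding genes, isoforms, and chance near-threshold
ORFs (ORF suppression leaves a deliberate margin between 80 and
100 aa).  Passing the planted-truth tests therefore demonstrates that
the decision rules are implemented exactly as specified and are
recoverable under clean conditions — not that the thresholds themselves
are optimal for noisy biological data.

## Numerical and testing choices

* Folding energies are held as doubles in kcal/mol; traceback ties are
  broken in a fixed rule order (hairpin, stack/interior by increasing
  5' offset, multibranch by split point), making structures
  deterministic.  The folded-energy/enumeration equivalence is checked
  on sequences of ≤ 14 nt, where exhaustive structure enumeration under
  the identical energy tables is feasible; the enumerator and its loop-
  decomposition evaluator share no code with the C++ DP.
* The local aligner is cross-checked against an independent plain-R
  affine-gap DP; the duplex DP against recursive enumeration of all
  gapped pairings; the ORF scan against a six-frame brute-force
  enumeration; the mature scan against a seed-free sliding-Hamming
  scan.
* Default problem sizes: the standard synthetic transcriptome has 202
  transcripts (50 coding, 80 mlncRNA including 22 family members, 40
  short, 8 housekeeping, 10 precursors, 14 targets); expression
  recovery is measured on 1,000 simulated genes (500 per stress).
  These sizes keep the full suite comfortably reproducible on a single
  CPU while leaving every decision rule exercised many times over.
* The four accession-based checks (two MFEI values, one target penalty,
  one deposited length) require the corresponding TSA records on disk;
  `scripts/fetch_tsa.R` fetches them once, after which the checks run
  offline.  They are the only part of the suite with an external data
  dependency.

## Known limitations

* E-values are calibrated for threshold behaviour, not for absolute
  accuracy; do not compare them with BLAST output numerically.
* The folding model's simplifications (no dangles/tetraloop bonuses,
  capped interior loops) shift MFE values relative to mfold/ViennaRNA;
  MFEI comparisons across packages should allow ±0.05.
* The mature-miRNA scan finds the star sequence of a planted hairpin on
  the minus strand as well — a real property of near-palindromic
  precursors; downstream reports deduplicate per (transcript, mature).
* `classifyCold`/`classifyDehydration` implement one explicit
  formalization of qualitative published patterns; other reasonable
  cutoffs exist, which is why every threshold is an argument.
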