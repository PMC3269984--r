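# mlncTools

Discovery and characterization of mRNA-like long non-coding RNAs
(mlncRNAs) in de novo plant transcriptomes.

Assembled unigene sets from non-model plants mix protein-coding mRNAs
with a large population of polyadenylated non-coding transcripts.  With
no genome to map against, calling a unigene non-coding rests on a chain
of screens, and the interesting biology lives downstream of the call:
family structure, conservation, microRNA production, sense/antisense
relations to coding genes, and stress-responsive expression.
`mlncTools` implements that chain end to end for analysts working with
EST/454-style unigene sets (or any transcript FASTA), with every
threshold exposed and every stage testable against planted ground
truth.

## What it computes

* **Coding/non-coding classification** — a decision tree over protein
  homology (six-frame translated search, E ≤ 10⁻⁵), length (≥ 300 bp),
  ORF coding potential (≥ 100 aa, both strands, 3'-open partials
  counted), and a housekeeping-RNA homology screen; classes are
  `ANNOTATED_CODING`, `SHORT_UNANNOTATED`, `NOVEL_CODING`,
  `HOUSEKEEPING_NPCRNA`, `MLNC_CANDIDATE`.
* **mlncRNA families** — single-linkage components of the all-vs-all
  Smith–Waterman hit graph at E ≤ 10⁻⁵, with Karlin–Altschul
  statistics `E = K·m·n·e^(−λS)`.
* **Conserved miRNA precursors** — mismatch-limited (≤ 3) scans against
  known mature miRNAs, Zuker-type minimum-free-energy hairpin folding,
  plant-miRNA acceptance criteria (single stem-loop, ≤ 4 unpaired
  mature bases, ≤ 2-nt duplex bulges), and the minimal folding free
  energy index `MFEI = (|MFE|/L × 100)/GC%`.
* **miRNA targets** — weighted duplex penalty in 20-nt windows
  (mismatch 1, G:U 0.5, gap 2, positions 2–13 doubled), cutoff 0–3,
  exact dynamic programming.
* **mlncRNA ↔ coding-gene relations** — sense/antisense homology with
  CDS/UTR5/UTR3/junction localization against predicted ORFs.
* **qPCR analytics** — geNorm reference stability (M), comparative
  2^−ΔΔCq quantification, rule-based cold (A/B/C) and dehydration
  (I/II/III) response typing, and log-scale expression correlation of
  gene pairs.
* **Synthetic data** — `generateTranscriptome()` / `generateCq()` plant
  coding ORFs, ORF-suppressed mlncRNAs, families, housekeeping copies,
  verified hairpin precursors, exact-penalty target sites and
  subclass-templated Cq series, with full truth tables.

The methods vignette (`vignettes/mlnc-discovery-methods.Rmd`) documents
the models, parameter defaults, numerical choices and limitations.

## Worked example

Group the bundled set of 13 conserved mature miRNAs into families by
single-linkage at ≤ 3 mismatches, then verify a constructed hairpin
precursor and score a perfect target site:

```r
library(mlncTools)

matures <- bundledMatureMirnas()
fam <- groupMatureFamilies(matures)
fam$sizes
#> MIR156 MIR160 MIR166 MIR167 MIR172 MIR396 MIR397 MIR408
#>      2      1      2      3      2      1      1      1
fam$n_families
#> [1] 8
```

Eight families; MIR160, MIR396, MIR397 and MIR408 are singletons, while
MIR156/166/172 have two members and MIR167 three — the family structure
expected for these deeply conserved plant miRNAs.

```r
m <- chartr("U", "T", as.character(matures[["MIR160"]]))
hairpin <- paste0(m, "TCTCA", revComp(m))            # mature + loop + star
host <- paste0(strrep("A", 60), hairpin, strrep("A", 60))
ev <- evaluatePrecursor(host, list(transcript_id = "demo", start = 60L,
                                   end = 81L, strand = "+"))
ev
#> HairpinCandidate (accepted) on demo
#>   precursor: 47 nt, GC 55.3%
#>   MFE: -43.74 kcal/mol  MFEI: 1.682
#>   mature: 5p arm, offset 0, 0 unpaired
```

The perfect 21-bp stem folds at −43.74 kcal/mol; an MFEI of 1.68 is
well above the ~0.85 typical of genuine precursors and far above
mRNA-like values (~0.65) — exactly what a designed perfect hairpin
should show.

```r
site <- revComp(m)                                    # perfect complement
scoreDuplex(chartr("T", "U", m), site)$penalty
#> [1] 0
```

For a full pipeline run over a synthetic transcriptome with planted
truth, see `?runPipeline` and `?synthDesign`, or
`scripts/run_pipeline.R` for the command-line entry point.

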