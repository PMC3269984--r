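Package: mlncTools
Title: Discovery and Characterization of mRNA-Like Long Non-Coding RNAs
        in De Novo Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
        role = c("aut", "cre"))
Description: A pipeline for transcriptome-wide discovery of mRNA-like long
        non-coding RNA (mlncRNA) candidates from an assembled unigene set,
        modelled on EST-era screens of non-model plants. Classifies unigenes
        into annotated-coding, novel-coding, housekeeping non-coding and
        mlncRNA-candidate classes by ORF coding potential and homology;
        clusters mlncRNA families by single-linkage sequence homology;
        annotates conserved microRNA precursors by mismatch-limited mature
        scans, minimum-free-energy hairpin folding and the minimal folding
        free energy index (MFEI); predicts microRNA targets with a weighted
        duplex penalty score; relates mlncRNAs to protein-coding genes in
        sense/antisense orientation with CDS/UTR localization; and analyses
        qPCR time courses (geNorm reference stability, comparative
        2^-ddCq quantification, rule-based stress-response typing). A
        synthetic-transcriptome generator with planted ground truth makes
        every stage testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, tools, Rcpp, Biostrings, IRanges,
        S4Vectors, SummarizedExperiment, jsonlite, yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Transcriptomics, Sequencing, GenePrediction, qPCR
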