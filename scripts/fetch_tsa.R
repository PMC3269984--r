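#!/usr/bin/env Rscript
# One-time download of the deposited TSA records used by the
# accession-based checks (network required).  Records are written as
# plain FASTA under inst/extdata/tsa/ so that the checks can run offline
# afterwards.
#
#   Rscript scripts/fetch_tsa.R [outdir]

accessions <- c("JO463945", "JO467104", "JO460174", "JO460015")
args <- commandArgs(trailingOnly = TRUE)
outdir <- if (length(args)) args[1] else "inst/extdata/tsa"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

base <- paste0("https://eutils.ncbi.nlm.nih.gov/entrez/eutils/",
               "efetch.fcgi?db=nuccore&rettype=fasta&retmode=text&id=")
for (acc in accessions) {
  dest <- file.path(outdir, paste0(acc, ".fasta"))
  if (file.exists(dest)) {
    message(acc, " already present, skipping")
    next
  }
  message("fetching ", acc)
  utils::download.file(paste0(base, acc), dest, quiet = TRUE)
  Sys.sleep(0.4) # NCBI rate limit
}
message("done; re-install the package so the records ship with it")
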