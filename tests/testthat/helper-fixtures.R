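# shared fixtures: built once per run, cached in the helper environment

.cache <- new.env(parent = emptyenv())

# standard synthetic transcriptome used across planted-truth tests
getSim <- function() {
  if (is.null(.cache$sim))
    .cache$sim <- generateTranscriptome(synthDesign(seed = 7))
  .cache$sim
}

getClassification <- function() {
  if (is.null(.cache$cls)) {
    sim <- getSim()
    .cache$cls <- classifySet(sim$transcripts, sim$proteins,
                              hkdb = sim$hk)
  }
  .cache$cls
}

randDna <- function(n, bases = c("A", "C", "G", "T")) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}

randRna <- function(n) randDna(n, c("A", "C", "G", "U"))

# canonical string encoding of a partition (set of groups of ids) so two
# partitions can be compared irrespective of labels
canonicalPartition <- function(ids, labels) {
  keep <- !is.na(labels)
  groups <- split(ids[keep], labels[keep])
  unname(sort(vapply(groups, function(g) paste(sort(g), collapse = "+"),
                     character(1)), method = "radix"))
}
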