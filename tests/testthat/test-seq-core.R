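test_that("FASTA reading normalizes case and U/T and keeps descriptions", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">t1 some description", "acguACGU", ">t2", "NNNACGT"), f)
  x <- readTranscripts(f)
  expect_length(x, 2L)
  expect_identical(as.character(x[["t1"]]), "ACGTACGT")
  expect_identical(as.character(x[["t2"]]), "NNNACGT")
  expect_identical(S4Vectors::mcols(x)$description,
                   c("some description", ""))
})

test_that("FASTA round-trip reproduces ids and sequences with 60-col wrap", {
  f <- withr::local_tempfile(fileext = ".fasta")
  set.seed(42)
  seqs <- Biostrings::DNAStringSet(stats::setNames(
    vapply(c(30, 60, 61, 150), randDna, character(1)),
    paste0("seq", 1:4)))
  writeTranscripts(seqs, f)
  back <- readTranscripts(f)
  expect_identical(names(back), names(seqs))
  expect_identical(as.character(back), as.character(seqs))
  # writing what was read reproduces the file byte-identically
  f2 <- withr::local_tempfile(fileext = ".fasta")
  writeTranscripts(back, f2)
  expect_identical(readLines(f), readLines(f2))
  # wrap is 60 columns
  expect_true(all(nchar(readLines(f)) <= 60))
})

test_that("malformed and empty FASTA inputs are handled as specified", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c("ACGT", ">h"), f)
  expect_error(readTranscripts(f), "line 1")
  writeLines(c(">only-header"), f)
  expect_error(readTranscripts(f), "empty sequence")
  writeLines(character(0), f)
  expect_warning(x <- readTranscripts(f), "empty")
  expect_length(x, 0L)
})

test_that("gcFraction follows the N-exclusion rule", {
  expect_equal(gcFraction("GGCC"), 1.0)
  expect_equal(gcFraction("ATAT"), 0.0)
  expect_equal(gcFraction("ATGCN"), 0.5)  # N excluded from both sides
  expect_error(gcFraction("NNNN"), "undefined")
  set.seed(5)
  s <- vapply(rep(50, 20), randDna, character(1))
  expect_equal(gcFraction(s), gcFraction(revComp(s)))
})

test_that("revComp is a correct involution and preserves N", {
  expect_identical(revComp("ATGC"), "GCAT")
  expect_identical(revComp("AAAN"), "NTTT")
  set.seed(6)
  s <- vapply(rep(40, 25), randDna, character(1))
  expect_identical(revComp(revComp(s)), s)
})

test_that("findOrfs reports the constructed complete ORF exactly", {
  s <- paste0("ATG", strrep("GCT", 99), "TAA")
  orfs <- findOrfs(s)
  complete <- orfs[orfs$complete, ]
  expect_identical(nrow(complete), 1L)
  expect_identical(complete$aa_length, 100L)
  expect_identical(complete$start, 0L)
  expect_identical(complete$end, nchar(s))
})

test_that("sequences without ATG yield no complete ORFs", {
  s <- strrep("CCG", 60) # no ATG on either strand (revcomp = CGG...)
  orfs <- findOrfs(s)
  expect_identical(sum(orfs$complete), 0L)
})

test_that("findOrfs agrees with the exhaustive six-frame oracle", {
  set.seed(11)
  for (i in 1:300) {
    s <- randDna(sample(10:300, 1))
    got <- findOrfs(s)
    got <- got[order(got$strand, got$frame, got$start),
               c("strand", "frame", "start", "end", "aa_length",
                 "complete")]
    rownames(got) <- NULL
    want <- mlncTools:::.oracleOrfs(s)
    rownames(want) <- NULL
    expect_identical(got, want)
  }
})
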