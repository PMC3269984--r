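test_that("identical sequences cluster; unrelated randoms stay singletons", {
  set.seed(31)
  core <- randDna(300)
  seqs <- Biostrings::DNAStringSet(c(a = core, b = core, c = core,
                                     x = randDna(300), y = randDna(300)))
  out <- clusterFamilies(seqs)
  expect_identical(nrow(out$families), 3L)
  expect_identical(unique(out$families$family_id), "FAM001")
  expect_setequal(out$singletons, c("x", "y"))
})

test_that("single-linkage transitivity joins chains A~B~C", {
  set.seed(32)
  a <- randDna(400)
  # B shares its left half with A and its right half with C
  left <- substr(a, 1, 200)
  rightC <- randDna(200)
  b <- paste0(left, rightC)
  c_ <- paste0(randDna(200), rightC)
  seqs <- Biostrings::DNAStringSet(c(A = a, B = b, C = c_))
  out <- clusterFamilies(seqs)
  expect_identical(sort(out$families$member_id), c("A", "B", "C"))
  expect_length(unique(out$families$family_id), 1L)
})

test_that("clusterFamilies output is a partition of the input", {
  sim <- getSim()
  ids <- sim$truth$id[sim$truth$role == "mlnc"]
  out <- clusterFamilies(sim$transcripts[ids])
  covered <- c(out$families$member_id, out$singletons)
  expect_setequal(covered, ids)
  expect_identical(anyDuplicated(covered), 0L)
  sizes <- table(out$families$family_id)
  expect_true(all(sizes >= 2))
})

test_that("planted families are recovered exactly", {
  sim <- getSim()
  ids <- sim$truth$id[sim$truth$role == "mlnc"]
  out <- clusterFamilies(sim$transcripts[ids])
  got <- canonicalPartition(ids, out$membership[ids])
  want <- canonicalPartition(ids, sim$truth$family[match(ids,
                                                         sim$truth$id)])
  expect_identical(got, want)
})

test_that("conservation screen finds verbatim embeddings only", {
  set.seed(33)
  db <- Biostrings::DNAStringSet(c(known1 = randDna(120),
                                   known2 = randDna(150)))
  cons <- paste0(randDna(150), as.character(db[["known2"]]), randDna(80))
  shuf <- paste(sample(strsplit(cons, "")[[1]]), collapse = "")
  mlncs <- Biostrings::DNAStringSet(c(m1 = cons, m2 = shuf,
                                      m3 = randDna(350)))
  out <- conservationScreen(mlncs, db)
  expect_identical(out$id, "m1")
  expect_identical(out$db_id, "known2")
  expect_identical(nrow(conservationScreen(mlncs,
                                           Biostrings::DNAStringSet())),
                   0L)
})

test_that("mlnc/coding relations localize to UTR5, UTR3, CDS and junction", {
  set.seed(34)
  utr5 <- randDna(150)
  orf <- paste0("ATG", paste(sample(mlncTools:::.NONSTOP, 120, TRUE),
                             collapse = ""), "TAA")
  utr3 <- randDna(150)
  coding <- paste0(utr5, orf, utr3)
  orfTab <- data.frame(transcript_id = "gene1", strand = "+",
                       start = 150L, end = 150L + nchar(orf))
  codingSet <- Biostrings::DNAStringSet(c(gene1 = coding))
  # sense copy of the 5' UTR
  m1 <- Biostrings::DNAStringSet(c(q = paste0(utr5, randDna(150))))
  r1 <- relateMlncToCoding(m1, codingSet, orfTab)
  expect_identical(r1$orientation, "sense")
  expect_identical(r1$region, "UTR5")
  # antisense (reverse complement) of the 5' UTR
  m2 <- Biostrings::DNAStringSet(c(q = paste0(revComp(utr5),
                                              randDna(150))))
  r2 <- relateMlncToCoding(m2, codingSet, orfTab)
  expect_identical(r2$orientation, "antisense")
  expect_identical(r2$region, "UTR5")
  # copy of the 3' UTR
  m3 <- Biostrings::DNAStringSet(c(q = paste0(utr3, randDna(150))))
  r3 <- relateMlncToCoding(m3, codingSet, orfTab)
  expect_identical(r3$region, "UTR3")
  # copy inside the ORF
  m4 <- Biostrings::DNAStringSet(c(q = substr(orf, 10, 200)))
  r4 <- relateMlncToCoding(m4, codingSet, orfTab)
  expect_identical(r4$region, "CDS")
  # span across the ATG
  m5 <- Biostrings::DNAStringSet(c(q = substr(coding, 100, 300)))
  r5 <- relateMlncToCoding(m5, codingSet, orfTab)
  expect_identical(r5$region, "junction")
})

test_that("coding transcripts without ORF coordinates are skipped", {
  set.seed(35)
  m <- Biostrings::DNAStringSet(c(q = randDna(300)))
  coding <- Biostrings::DNAStringSet(c(noOrf = randDna(300)))
  orfTab <- data.frame(transcript_id = character(0), strand = character(0),
                       start = integer(0), end = integer(0))
  expect_warning(out <- relateMlncToCoding(m, coding, orfTab), "skipped")
  expect_identical(nrow(out), 0L)
})
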