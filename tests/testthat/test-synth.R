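test_that("the generator is byte-identical for a fixed seed", {
  d <- synthDesign(seed = 7, nCoding = 4L, nMlnc = 6L, nShort = 2L,
                   nHk = 2L, nPrecursors = 1L, nTargets = 1L,
                   familySizes = c(2L, 3L))
  a <- generateTranscriptome(d)
  b <- generateTranscriptome(d)
  expect_identical(as.character(a$transcripts),
                   as.character(b$transcripts))
  expect_identical(a$truth, b$truth)
  ca <- generateCq(d, "cold", nGenes = 12)
  cb <- generateCq(d, "cold", nGenes = 12)
  expect_identical(ca$table, cb$table)
})

test_that("truth-table row counts equal the design counts", {
  sim <- getSim()
  d <- synthDesign(seed = 7)
  tt <- table(sim$truth$role)
  expect_identical(unname(tt[["coding"]]), d$n_coding)
  expect_identical(unname(tt[["mlnc"]]), d$n_mlnc)
  expect_identical(unname(tt[["short"]]), d$n_short)
  expect_identical(unname(tt[["housekeeping"]]), d$n_hk)
  expect_identical(unname(tt[["precursor"]]), d$n_precursors)
  expect_identical(unname(tt[["target"]]), d$n_targets)
  expect_identical(anyDuplicated(sim$truth$id), 0L)
})

test_that("no generated mlncRNA-class transcript carries a >= 100 aa ORF", {
  sim <- getSim()
  ids <- sim$truth$id[sim$truth$class == "MLNC_CANDIDATE"]
  for (id in ids)
    expect_lt(bestOrfAa(as.character(sim$transcripts[[id]])), 100L)
})

test_that("planted precursors carry a scannable mature and pass criteria", {
  sim <- getSim()
  prec <- sim$truth[sim$truth$role == "precursor", ]
  for (i in seq_len(nrow(prec))) {
    hits <- scanKnownMirnas(sim$transcripts[prec$id[i]],
                            sim$matures[prec$mirna_id[i]])
    plus <- hits[hits$strand == "+" & hits$mismatches == 0L, ]
    expect_gte(nrow(plus), 1L)
    expect_identical(plus$start[1], prec$site_start[i])
  }
})

test_that("contradictory designs are rejected at validation", {
  expect_error(synthDesign(mlncLenRange = c(200, 500)), "contradictory")
  expect_error(synthDesign(shortLenRange = c(100, 350)), "contradictory")
  expect_error(synthDesign(familySizes = c(1L)), "between 2 and 8")
  expect_error(synthDesign(mutationRate = 0.5), "mutationRate")
  expect_error(synthDesign(nMlnc = 3, familySizes = c(2L, 2L)),
               "exceed")
})

test_that("zero-noise Cq series reproduce planted subclasses exactly", {
  d <- synthDesign(seed = 19)
  for (st in c("cold", "dehydration")) {
    g <- generateCq(d, st, nGenes = 30, noiseSd = 0)
    for (i in seq_len(nrow(g$truth))) {
      fc <- deltaDeltaCq(g$cq, g$truth$gene[i], "UBQ",
                         colnames(cqValues(g$cq))[1])
      series <- stats::setNames(
        fc$fold, sub("^[CD]", "", colnames(cqValues(g$cq))))
      got <- if (st == "cold") classifyCold(series)
             else classifyDehydration(series)
      expect_identical(got$subclass, g$truth$subclass[i])
    }
  }
})

test_that("the planted stable reference has the smallest geNorm M", {
  g <- generateCq(synthDesign(seed = 23), "cold")
  out <- genormM(g$cq, c("UBQ", "ACT", "R18S"))
  expect_identical(out$gene[1], "UBQ")
})
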