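test_that("perfect complementary sites score zero penalty", {
  set.seed(51)
  matures <- bundledMatureMirnas()
  for (k in c(1, 5, 13)) {
    m <- chartr("T", "U", as.character(matures[[k]]))
    site <- revComp(chartr("U", "T", m))
    expect_equal(scoreDuplex(m, site)$penalty, 0)
  }
})

test_that("schema arithmetic: wobbles, seed weighting, gaps", {
  m <- chartr("T", "U", as.character(bundledMatureMirnas()[["MIR160"]]))
  sitev <- strsplit(revComp(chartr("U", "T", m)), "")[[1]]
  L <- nchar(m)
  mv <- strsplit(m, "")[[1]]
  # one G:U wobble opposite miRNA position 18 (outside the 2-13 seed)
  p <- 18L
  stopifnot(mv[p] %in% c("G", "U"))
  s2 <- sitev
  s2[L - p + 1L] <- if (mv[p] == "G") "T" else "G"
  expect_equal(scoreDuplex(m, paste(s2, collapse = ""))$penalty, 0.5)
  # a seed mismatch costs double
  seedPos <- 5L
  s3 <- sitev
  s3[L - seedPos + 1L] <- switch(mv[seedPos],
                                 A = "C", C = "A", G = "A", U = "C")
  expect_equal(scoreDuplex(m, paste(s3, collapse = ""))$penalty, 2)
  # deleting one site base forces one gap position
  s4 <- paste(sitev[-3L], collapse = "")
  expect_equal(scoreDuplex(m, s4)$penalty, 2)
})

test_that("duplex DP matches the exhaustive gapped-pairing oracle", {
  set.seed(52)
  for (i in 1:150) {
    L <- sample(19:24, 1)
    m <- randRna(L)
    site <- randDna(L + sample(-2:2, 1))
    expect_equal(scoreDuplex(m, site)$penalty,
                 mlncTools:::.oracleDuplexPenalty(m, site),
                 tolerance = 1e-9)
  }
})

test_that("penalty never decreases when a paired position is mutated", {
  set.seed(53)
  m <- randRna(21)
  site <- revComp(chartr("U", "T", m))
  base <- scoreDuplex(m, site)$penalty
  for (p in c(1, 7, 15, 21)) {
    sv <- strsplit(site, "")[[1]]
    sv[p] <- sample(setdiff(c("A", "C", "G", "T"), sv[p]), 1)
    expect_gte(scoreDuplex(m, paste(sv, collapse = ""))$penalty, base)
  }
})

test_that("predictTargets emits exactly the windows within the cutoff", {
  set.seed(54)
  m <- chartr("T", "U", as.character(bundledMatureMirnas()[["MIR397"]]))
  perfect <- revComp(chartr("U", "T", m))
  host <- paste0(randDna(150), perfect, randDna(150))
  hits <- predictTargets(c(miR = m),
                         Biostrings::DNAStringSet(c(h = host)))
  expect_identical(nrow(hits), 1L)
  expect_equal(hits$penalty, 0)
  expect_identical(hits$t_start, 150L)
  # sites above the cutoff are absent: plant two seed mismatches (4.0)
  sv <- strsplit(perfect, "")[[1]]
  L <- nchar(m); mv <- strsplit(m, "")[[1]]
  for (p in c(4L, 9L))
    sv[L - p + 1L] <- switch(mv[p], A = "C", C = "A", G = "A", U = "C")
  host2 <- paste0(randDna(150), paste(sv, collapse = ""), randDna(150))
  expect_identical(nrow(predictTargets(c(miR = m),
      Biostrings::DNAStringSet(c(h = host2)))), 0L)
})

test_that("planted sites of graded penalty are recovered exactly", {
  sim <- getSim()
  tt <- sim$truth[sim$truth$role == "target", ]
  for (i in seq_len(nrow(tt))) {
    m <- chartr("T", "U", as.character(sim$matures[[tt$mirna_id[i]]]))
    hits <- predictTargets(stats::setNames(m, tt$mirna_id[i]),
                           sim$transcripts[tt$id[i]])
    expect_identical(nrow(hits), 1L)
    expect_equal(hits$penalty, tt$site_penalty[i], tolerance = 1e-9)
    expect_identical(hits$t_start, tt$site_start[i])
  }
})
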