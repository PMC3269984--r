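test_that("folding pairs complementary stems and leaves poly-A open", {
  f <- rnaFold("GGGGAAAACCCC")
  expect_identical(f$structure, "((((....))))")
  expect_lt(f$mfe, 0)
  open <- rnaFold(strrep("A", 30))
  expect_identical(open$structure, strrep(".", 30))
  expect_equal(open$mfe, 0)
})

test_that("GC stems fold more stably than AU stems of the same shape", {
  gc <- rnaFold("GGGGGGAAAACCCCCC")$mfe
  au <- rnaFold("AAAAAAGGGGUUUUUU")$mfe
  expect_lt(gc, au)
})

test_that("fold output is balanced, obeys the loop minimum, and mfe <= 0", {
  set.seed(41)
  for (i in 1:50) {
    s <- randRna(sample(10:60, 1))
    f <- rnaFold(s)
    expect_lte(f$mfe, 0)
    v <- strsplit(f$structure, "")[[1]]
    depth <- cumsum((v == "(") - (v == ")"))
    expect_true(all(depth >= 0) && depth[length(depth)] == 0)
    pt <- mlncTools:::.pairTable(f$structure)
    paired <- which(!is.na(pt) & pt > seq_along(pt))
    if (length(paired))
      expect_true(all(pt[paired] - paired - 1L >= 3L))
  }
  expect_error(rnaFold("ACGUA"), "below the folding minimum")
})

test_that("fold is optimal against exhaustive structure enumeration", {
  set.seed(42)
  for (i in 1:60) {
    s <- randRna(sample(10:14, 1))
    expect_equal(rnaFold(s)$mfe, mlncTools:::.oracleFoldMfe(s),
                 tolerance = 1e-9)
  }
})

test_that("mfei computes the normalized folding index", {
  expect_equal(mfei(-49.5, 100, 50), 0.99)
  expect_equal(mfei(0, 90, 45), 0)
  # hand arithmetic: (40.59 / 90 * 100) / 45
  expect_equal(mfei(-40.59, 90, 45), 1.00222222, tolerance = 1e-8)
  expect_error(mfei(-10, 100, 0), "undefined")
  # strictly increasing in |mfe|
  m <- mfei(seq(-60, -10, by = 10), 100, 50)
  expect_true(all(diff(m) < 0))
})

test_that("mature scan finds embedded matures within the mismatch budget", {
  set.seed(43)
  matures <- bundledMatureMirnas()
  m <- as.character(matures[[4]])
  host <- paste0(randDna(100), m, randDna(100))
  hits <- scanKnownMirnas(
    Biostrings::DNAStringSet(c(h = host)), matures[4])
  exact <- hits[hits$strand == "+", ]
  expect_identical(nrow(exact), 1L)
  expect_identical(exact$mismatches, 0L)
  expect_identical(exact$start, 100L)
  # four substitutions exceed the budget
  mv <- strsplit(m, "")[[1]]
  for (p in c(3, 8, 13, 18)) mv[p] <- setdiff(c("A", "C", "G", "T"),
                                              mv[p])[1]
  host4 <- paste0(randDna(100), paste(mv, collapse = ""), randDna(100))
  hits4 <- scanKnownMirnas(Biostrings::DNAStringSet(c(h = host4)),
                           matures[4])
  expect_identical(nrow(hits4), 0L)
  expect_error(scanKnownMirnas(Biostrings::DNAStringSet(c(h = host)),
                               Biostrings::DNAStringSet(c(x = "ACG"))),
               "seed word size")
  expect_error(scanKnownMirnas(Biostrings::DNAStringSet(c(h = host)),
                               Biostrings::DNAStringSet(
                                 c(x = "ACGTACGTAC"))),
               "19-24")
})

test_that("mature scan agrees with the seed-free sliding-Hamming oracle", {
  set.seed(44)
  matures <- bundledMatureMirnas()[c(1, 4, 13)]
  for (i in 1:10) {
    # embed a mutated mature to guarantee some signal amid the noise
    m <- as.character(matures[[sample(3, 1)]])
    mv <- strsplit(m, "")[[1]]
    for (p in sample(length(mv), sample(0:3, 1)))
      mv[p] <- sample(setdiff(c("A", "C", "G", "T"), mv[p]), 1)
    host <- paste0(randDna(80), paste(mv, collapse = ""), randDna(80))
    tset <- Biostrings::DNAStringSet(stats::setNames(host, "h"))
    got <- scanKnownMirnas(tset, matures)
    raw <- do.call(rbind, lapply(seq_along(matures), function(k)
      mlncTools:::.oracleMatureScan(host, "h",
                                    as.character(matures[[k]]),
                                    names(matures)[k])))
    want <- mlncTools:::.collapseOverlapping(raw)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got[order(got$known_mirna_id, got$strand, got$start), ],
                 want[order(want$known_mirna_id, want$strand,
                            want$start), ],
                 ignore_attr = TRUE)
  }
})

test_that("a constructed perfect hairpin is accepted with a clean duplex", {
  set.seed(45)
  m <- as.character(bundledMatureMirnas()[["MIR160"]])
  hp <- paste0(m, "TCTCA", revComp(m))
  host <- paste0(strrep("A", 60), hp, strrep("A", 60))
  hit <- list(transcript_id = "syn", start = 60L,
              end = 60L + nchar(m), strand = "+")
  ev <- evaluatePrecursor(host, hit)
  expect_true(isAccepted(ev))
  expect_identical(ev@n_unpaired_in_mature, 0L)
  expect_identical(matureArm(ev), "5p")
  expect_gt(mfeiValue(ev), 0)
  # the mfei slot is consistent with its inputs (class validity invariant)
  expect_equal(mfeiValue(ev),
               (abs(mfeValue(ev)) / ev@length_nt * 100) / ev@gc_percent)
})

test_that("a mature lying in the terminal loop is rejected", {
  set.seed(46)
  m <- as.character(bundledMatureMirnas()[["MIR160"]])
  stem <- randDna(30)
  host <- paste0(strrep("A", 40), stem, m, revComp(stem), strrep("A", 40))
  hit <- list(transcript_id = "syn", start = 70L,
              end = 70L + nchar(m), strand = "+")
  ev <- evaluatePrecursor(host, hit)
  expect_false(isAccepted(ev))
  expect_match(rejectionReason(ev), "spans loop")
})

test_that("hairpins violating the unpaired-base budget are rejected", {
  m <- as.character(bundledMatureMirnas()[["MIR160"]])
  mv <- strsplit(m, "")[[1]]
  star <- strsplit(revComp(m), "")[[1]]
  # disrupt pairing opposite five scattered mature C/A positions
  ca <- which(mv %in% c("C", "A"))
  pick <- ca[round(seq(1, length(ca), length.out = 5))]
  for (p in pick) {
    sp <- length(mv) - p + 1L
    star[sp] <- if (mv[p] == "C") "A" else "C"
  }
  hp <- paste0(m, "TCTCA", paste(star, collapse = ""))
  host <- paste0(strrep("A", 60), hp, strrep("A", 60))
  hit <- list(transcript_id = "syn", start = 60L,
              end = 60L + nchar(m), strand = "+")
  ev <- evaluatePrecursor(host, hit)
  expect_false(isAccepted(ev))
  expect_match(rejectionReason(ev), "unpaired>4")
})

test_that("mature families group by near-identity with length-aware gaps", {
  g <- groupMatureFamilies(c(x = "UGACAGAAGAGAGGGAGCAC",
                             y = "UGACAGAAGAGAGGGAGCAC"))
  expect_identical(g$n_families, 1L)
  # distance counts overhang: 21-mer vs its 19-nt core differs by 2
  d <- mlncTools:::.matureDistance(
    chartr("U", "T", "UGCCUGGCUCCUUGUAUGCCA"),
    chartr("U", "T", "CCUGGCUCCUUGUAUGCCA"))
  expect_equal(d, 2)
})
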