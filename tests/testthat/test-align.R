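test_that("identical sequences give a full-length perfect local hit", {
  set.seed(21)
  s <- randDna(50)
  hit <- localAlign(s, s)
  expect_equal(hit$score, 100) # 50 matches at +2
  expect_equal(hit$identity, 1.0)
  expect_identical(c(hit$q_start, hit$q_end), c(0L, 50L))
})

test_that("disjoint alphabets give an empty zero-score hit", {
  hit <- localAlign("AAAA", "GGGG")
  expect_equal(hit$score, 0)
  expect_identical(hit$q_start, hit$q_end)
})

test_that("local alignment score is symmetric and matches the plain-R DP", {
  set.seed(22)
  for (i in 1:200) {
    q <- randDna(sample(4:12, 1))
    s <- randDna(sample(4:12, 1))
    sc <- localAlign(q, s)$score
    expect_identical(sc, localAlign(s, q)$score)
    expect_equal(sc, mlncTools:::.oracleLocalAlign(q, s))
  }
})

test_that("E-values follow the Karlin-Altschul form", {
  # linear in database size
  expect_equal(estimateEvalue(30, 100, 2e6),
               2 * estimateEvalue(30, 100, 1e6))
  # closed-form score dependence
  expect_equal(estimateEvalue(40, 100, 1e6) / estimateEvalue(30, 100, 1e6),
               exp(-0.625 * 10))
  # frozen direct evaluation: 0.41 * 400 * 1e6 * exp(-0.625 * 60)
  expect_equal(estimateEvalue(60, 400, 1e6), 8.487910e-09,
               tolerance = 1e-6)
  expect_error(estimateEvalue(10, -1, 10), "positive")
  expect_error(estimateEvalue(0, 10, 10), "positive score")
})

test_that("E-value decreases in score and increases in search space", {
  scores <- seq(10, 80, by = 10)
  e <- estimateEvalue(scores, 300, 1e6)
  expect_true(all(diff(e) < 0))
  sizes <- c(1e4, 1e5, 1e6, 1e7)
  e2 <- estimateEvalue(50, 300, sizes)
  expect_true(all(diff(e2) > 0))
})

test_that("translated protein homology detects embedded coding segments", {
  set.seed(23)
  prot <- Biostrings::AAStringSet(c(
    ref1 = paste(sample(Biostrings::AA_STANDARD, 120, TRUE), collapse = ""),
    ref2 = paste(sample(Biostrings::AA_STANDARD, 90, TRUE), collapse = "")))
  # transcript carrying an exact 60-aa segment of ref1
  seg <- substr(as.character(prot[["ref1"]]), 20, 79)
  codons <- vapply(strsplit(seg, "")[[1]], function(a) {
    names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE == a][1]
  }, character(1))
  t1 <- paste0(randDna(30), paste(codons, collapse = ""), randDna(30))
  expect_true(annotateByProteinHomology(t1, "t1", prot))
  # random non-coding sequence: all six-frame E-values stay above cutoff
  t2 <- randDna(400)
  expect_false(annotateByProteinHomology(t2, "t2", prot))
  # annotation table overrides the sequence entirely
  tab <- data.frame(id = "t2", annotated = TRUE)
  expect_true(annotateByProteinHomology(t2, "t2", prot, tab))
  expect_error(annotateByProteinHomology(t2, "t2", NULL, NULL),
               "protein set or an annotation table")
})

test_that("housekeeping screen flags embedded reference RNAs only", {
  hk <- bundledHkReference()
  set.seed(24)
  embedded <- paste0(randDna(100), as.character(hk[[1]]), randDna(100))
  hit <- screenHousekeeping(embedded, hk)
  expect_identical(hit$hk_id, names(hk)[1])
  # shuffled control of the same composition: no hit at the cutoff
  shuffled <- paste(sample(strsplit(embedded, "")[[1]]), collapse = "")
  expect_null(screenHousekeeping(shuffled, hk))
  expect_null(screenHousekeeping(embedded, NULL))
})
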