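.mkCq <- function(mat, times = NULL) {
  cd <- S4Vectors::DataFrame(sample = colnames(mat),
                             row.names = colnames(mat))
  if (!is.null(times)) cd$time_h <- times
  CqExperiment(mat, cd)
}

test_that("2^-ddCq follows the comparative-Cq formula", {
  cq <- rbind(tgt = c(s0 = 25, s1 = 24, s2 = 26),
              ref = c(s0 = 20, s1 = 20, s2 = 20))
  x <- .mkCq(cq)
  fc <- deltaDeltaCq(x, "tgt", "ref", "s0")
  expect_equal(fc$fold[fc$sample == "s0"], 1)   # calibrator
  expect_equal(fc$fold[fc$sample == "s1"], 2)   # ddCq = -1
  expect_equal(fc$fold[fc$sample == "s2"], 0.5)
})

test_that("ddCq folds equal direct formula evaluation on random matrices", {
  set.seed(71)
  for (rep in 1:20) {
    cq <- matrix(runif(24, 18, 32), 4, 6,
                 dimnames = list(paste0("g", 1:4), paste0("s", 1:6)))
    x <- .mkCq(cq)
    fc <- deltaDeltaCq(x, "g1", "g4", "s3")
    direct <- 2^(-((cq["g1", ] - cq["g4", ]) -
                     (cq["g1", "s3"] - cq["g4", "s3"])))
    expect_equal(fc$fold, unname(direct), tolerance = 1e-12)
  }
})

test_that("ddCq folds are invariant to per-sample plate shifts", {
  set.seed(72)
  cq <- matrix(runif(20, 18, 32), 4, 5,
               dimnames = list(paste0("g", 1:4), paste0("s", 1:5)))
  shift <- runif(5, -3, 3)
  f1 <- deltaDeltaCq(.mkCq(cq), "g1", "g2", "s1")$fold
  f2 <- deltaDeltaCq(.mkCq(sweep(cq, 2, shift, "+")),
                     "g1", "g2", "s1")$fold
  expect_equal(f1, f2, tolerance = 1e-12)
})

test_that("undetected reactions propagate as NA folds, never zero", {
  cq <- rbind(tgt = c(s0 = 25, s1 = NA), ref = c(s0 = 20, s1 = 20))
  fc <- deltaDeltaCq(.mkCq(cq), "tgt", "ref", "s0")
  expect_true(is.na(fc$fold[fc$sample == "s1"]))
  expect_true(fc$undetected[fc$sample == "s1"])
  cqBad <- rbind(tgt = c(s0 = NA, s1 = 24), ref = c(s0 = 20, s1 = 20))
  expect_error(deltaDeltaCq(.mkCq(cqBad), "tgt", "ref", "s0"),
               "calibrator")
})

test_that("geNorm M is zero for perfectly covarying genes", {
  cq <- rbind(g1 = c(20, 22, 24, 21), g2 = c(25, 27, 29, 26))
  colnames(cq) <- paste0("s", 1:4)
  out <- genormM(.mkCq(cq))
  expect_equal(out$M, c(0, 0), tolerance = 1e-12)
})

test_that("geNorm M is plate-shift and per-gene-offset invariant, and
           ranks a noisy gene last", {
  set.seed(73)
  base <- runif(6, 19, 23)
  cq <- rbind(g1 = base, g2 = base + 3, g3 = base + rnorm(6, 0, 1.5))
  colnames(cq) <- paste0("s", 1:6)
  out <- genormM(.mkCq(cq))
  expect_identical(out$gene[3], "g3")
  # direct recomputation of pairwise log-ratio SDs for g3
  v31 <- sd((-cq["g3", ]) - (-cq["g1", ]))
  v32 <- sd((-cq["g3", ]) - (-cq["g2", ]))
  expect_equal(out$M[out$gene == "g3"], mean(c(v31, v32)),
               tolerance = 1e-12)
  # per-gene constant offset cancels
  out2 <- genormM(.mkCq(cq + c(5, -2, 1)[row(cq)]))
  expect_equal(out$M, out2$M, tolerance = 1e-12)
  # plate shift cancels
  out3 <- genormM(.mkCq(sweep(cq, 2, rnorm(6, 0, 2), "+")))
  expect_equal(sort(out$M), sort(out3$M), tolerance = 1e-12)
})

test_that("geNorm excludes undetected candidates with a warning", {
  cq <- rbind(g1 = c(20, 21, 22), g2 = c(24, 25, 26),
              g3 = c(NA, 25, 26))
  colnames(cq) <- paste0("s", 1:3)
  expect_warning(out <- genormM(.mkCq(cq)), "undetected")
  expect_setequal(out$gene, c("g1", "g2"))
})

test_that("cold response types follow the stated rules", {
  mk <- function(v) stats::setNames(v, c("0", "1", "5", "10", "24"))
  expect_identical(classifyCold(mk(c(1, 1.3, 0.8, 1.1, 0.9)))$subclass,
                   "A")
  b <- classifyCold(mk(c(1, 0.4, 0.3, 0.3, 0.6)))
  expect_true(b$responsive)
  expect_identical(b$subclass, "B")
  cc <- classifyCold(mk(c(1, 5, 2, 0.5, 0.3)))
  expect_identical(cc$subclass, "C")
  # missing time-point refuses classification
  expect_error(classifyCold(stats::setNames(c(1, 2, 3),
                                            c("0", "1", "5"))),
               "refused")
  # undetected value gives no subclass
  expect_identical(classifyCold(mk(c(1, NA, 2, 1, 1)))$subclass,
                   "undetected")
})

test_that("dehydration groups follow the stated rules", {
  mk <- function(v) stats::setNames(v, c("0", "1", "5", "10", "24"))
  expect_identical(
    classifyDehydration(mk(c(1, 1.1, 0.9, 1.2, 2.5)))$subclass, "I")
  expect_identical(
    classifyDehydration(mk(c(1, 0.3, 0.25, 0.3, 0.4)))$subclass, "II")
  expect_identical(
    classifyDehydration(mk(c(1, 3.2, 0.8, 0.4, 0.3)))$subclass, "III")
  expect_identical(
    classifyDehydration(mk(c(1, 1.2, 0.9, 1.1, 1.0)))$subclass,
    "nonresponsive")
})

test_that("subclass rules are mutually exclusive on random series", {
  set.seed(74)
  mk <- function(v) stats::setNames(v, c("0", "1", "5", "10", "24"))
  for (i in 1:200) {
    s <- mk(c(1, 2^rnorm(4, 0, 1.5)))
    cold <- classifyCold(s)
    expect_true(cold$subclass %in% c("A", "B", "C", "unclassified"))
    if (cold$subclass == "A") expect_false(cold$responsive)
    dehy <- classifyDehydration(s)
    expect_true(dehy$subclass %in% c("I", "II", "III", "nonresponsive",
                                     "unclassified"))
  }
})

test_that("correlatePair reports sign on log-scale correlation", {
  mk <- function(v) stats::setNames(v, c("0", "1", "5", "10", "24"))
  a <- mk(c(1, 2, 4, 1, 0.5))
  expect_identical(correlatePair(a, 2 * a)$sign, "positive")
  expect_equal(correlatePair(a, 2 * a)$r, 1)
  expect_identical(correlatePair(a, 1 / a)$sign, "negative")
  expect_equal(correlatePair(a, 1 / a)$r, -1)
  flat <- mk(rep(2, 5))
  expect_identical(correlatePair(a, flat)$sign, "none")
  # independent random series: mean correlation near zero
  set.seed(75)
  rs <- replicate(1000, {
    x <- mk(c(1, 2^rnorm(4))); y <- mk(c(1, 2^rnorm(4)))
    correlatePair(x, y)$r
  })
  expect_lt(abs(mean(rs)), 0.1)
})

test_that("readCqTable averages replicates and flags undetected", {
  f <- withr::local_tempfile(fileext = ".tsv")
  tab <- data.frame(gene = rep(c("g1", "g2"), each = 4),
                    sample = rep(c("s1", "s1", "s2", "s2"), 2),
                    replicate = rep(1:2, 4),
                    cq = c(20, 21, 22, 23, 30, 31, 41, 45))
  write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
  x <- readCqTable(f)
  expect_s4_class(x, "CqExperiment")
  m <- cqValues(x)
  expect_equal(m["g1", "s1"], 20.5)
  expect_true(is.na(m["g2", "s2"])) # >= cycle 40: undetected
})
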