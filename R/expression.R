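#' Read a long-format Cq table into a CqExperiment
#'
#' Input TSV columns: `gene`, `sample`, `cq`, optionally `replicate`,
#' `stress`, `time_h`.  Technical replicates are averaged per
#' (gene, sample); reactions with no amplification by the detection cutoff
#' cycle are flagged undetected (`NA`).
#'
#' @param path TSV path.
#' @param undetectedCq Detection cutoff cycle (default 40): Cq values at or
#'   above it, or missing, count as undetected.
#' @return A [CqExperiment-class].
#' @export
readCqTable <- function(path, undetectedCq = 40) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("gene", "sample", "cq")
  if (!all(required %in% names(tab)))
    stop("Cq table must have columns gene, sample, cq")
  tab$cq[!is.finite(tab$cq) | tab$cq >= undetectedCq] <- NA_real_
  genes <- unique(tab$gene)
  samples <- unique(tab$sample)
  cq <- matrix(NA_real_, length(genes), length(samples),
               dimnames = list(genes, samples))
  agg <- stats::aggregate(cq ~ gene + sample, data = tab, FUN = mean,
                          na.action = stats::na.pass)
  cq[cbind(match(agg$gene, genes), match(agg$sample, samples))] <- agg$cq
  cd <- S4Vectors::DataFrame(sample = samples, row.names = samples)
  for (extra in c("stress", "time_h")) {
    if (extra %in% names(tab)) {
      v <- tab[[extra]][match(samples, tab$sample)]
      cd[[extra]] <- v
    }
  }
  CqExperiment(cq, cd)
}

#' geNorm expression-stability value M
#'
#' For each candidate reference gene, Cq values are converted to relative
#' quantities `2^(Cqmin - Cq)`; for every gene pair the pairwise variation
#' V is the standard deviation of the log2 ratio of their quantities across
#' samples, and M for a gene is the mean V over all partner candidates.
#' Lower M means more stable expression.
#'
#' @param x A [CqExperiment-class].
#' @param candidates Candidate gene names (default: all genes).
#' @return `data.frame` with `gene` and `M`, ranked by ascending M.
#' @export
genormM <- function(x, candidates = rownames(cqValues(x))) {
  cq <- cqValues(x)[candidates, , drop = FALSE]
  undet <- apply(cq, 1, function(r) any(is.na(r)))
  if (any(undet)) {
    warning("candidate(s) undetected in some sample, excluded: ",
            paste(rownames(cq)[undet], collapse = ", "))
    cq <- cq[!undet, , drop = FALSE]
  }
  if (nrow(cq) < 2L) stop("geNorm needs at least two detected candidates")
  if (ncol(cq) < 2L) stop("geNorm needs at least two samples")
  # log2 relative quantity = Cqmin - Cq; ratios subtract, so any per-gene
  # constant cancels
  lq <- sweep(-cq, 1, apply(-cq, 1, max), "-")
  g <- nrow(lq)
  M <- numeric(g)
  for (i in seq_len(g)) {
    vs <- vapply(setdiff(seq_len(g), i), function(j)
      stats::sd(lq[i, ] - lq[j, ]), numeric(1))
    M[i] <- mean(vs)
  }
  out <- data.frame(gene = rownames(lq), M = M)
  out <- out[order(out$M), ]
  rownames(out) <- NULL
  out
}

#' Relative quantification by the comparative Cq method (2^-ddCq)
#'
#' `dCq_s = Cq_target,s - Cq_ref,s`; `ddCq_s = dCq_s - dCq_calibrator`;
#' `fold_s = 2^-ddCq_s`.  The calibrator sample has fold change 1 by
#' construction.  Undetected target reactions give `NA` fold (flagged),
#' never zero.
#'
#' @param x A [CqExperiment-class].
#' @param targetGene,refGene Gene names.
#' @param calibratorSample Sample name used as calibrator.
#' @return `data.frame`: `gene`, `sample`, `fold`, `undetected`.
#' @export
deltaDeltaCq <- function(x, targetGene, refGene, calibratorSample) {
  cq <- cqValues(x)
  stopifnot(targetGene %in% rownames(cq), refGene %in% rownames(cq),
            calibratorSample %in% colnames(cq))
  if (is.na(cq[targetGene, calibratorSample]) ||
      is.na(cq[refGene, calibratorSample]))
    stop("target and reference must be detected in the calibrator sample")
  dcq <- cq[targetGene, ] - cq[refGene, ]
  ddcq <- dcq - dcq[calibratorSample]
  fold <- 2^(-ddcq)
  undet <- is.na(cq[targetGene, ]) | is.na(cq[refGene, ])
  fold[undet] <- NA_real_
  data.frame(gene = targetGene, sample = colnames(cq),
             fold = unname(fold), undetected = unname(undet))
}

.checkSeries <- function(series, times) {
  if (!all(as.character(times) %in% names(series)))
    stop("classification refused: missing time-point(s) ",
         paste(setdiff(as.character(times), names(series)),
               collapse = ", "))
  s <- series[as.character(times)]
  if (any(is.na(s))) return(NULL) # undetected somewhere
  s
}

#' Classify a cold-stress expression time course
#'
#' Fold changes relative to t = 0 h at 0/1/5/10/24 h.  A gene is
#' responsive when the max/min fold ratio across time-points exceeds
#' `foldThreshold`.  Subtypes: `A` — not responsive; `B` — immediate
#' decrease (fold at 1 h at or below `1/foldThreshold`); `C` — rapid
#' increase (maximum fold at 1, 5 or 10 h at least `foldThreshold`,
#' followed by decline by 24 h); anything else responsive is reported as
#' `unclassified`.  `B` is checked before `C` (documented tie-break).
#'
#' @param series Named numeric vector of fold changes, names are times in
#'   hours ("0","1","5","10","24"); fold at 0 h must be 1.
#' @param times Time grid (default `c(0, 1, 5, 10, 24)`).
#' @param foldThreshold Responsiveness threshold (default 2).
#' @return A list: `responsive` (logical or NA if undetected), `subclass`
#'   (`"A"`, `"B"`, `"C"`, `"unclassified"`, or `"undetected"`).
#' @export
classifyCold <- function(series, times = c(0, 1, 5, 10, 24),
                         foldThreshold = 2) {
  s <- .checkSeries(series, times)
  if (is.null(s))
    return(list(responsive = NA, subclass = "undetected"))
  responsive <- max(s) / min(s) > foldThreshold
  if (!responsive) return(list(responsive = FALSE, subclass = "A"))
  if (s[["1"]] <= 1 / foldThreshold)
    return(list(responsive = TRUE, subclass = "B"))
  inner <- s[c("1", "5", "10")]
  tmax <- names(inner)[which.max(inner)]
  if (max(inner) >= foldThreshold && max(inner) >= max(s) &&
      s[["24"]] < max(inner))
    return(list(responsive = TRUE, subclass = "C"))
  list(responsive = TRUE, subclass = "unclassified")
}

#' Classify a dehydration-stress expression time course
#'
#' Subgroups: `I` — slow response (folds at 1/5/10 h within
#' `(1/foldThreshold, foldThreshold)`, fold at 24 h at least
#' `foldThreshold`); `II` — rapid decrease at 1 h (fold at or below
#' `1/foldThreshold`); `III` — induction at 1 h (fold at least
#' `foldThreshold`) followed by down-regulation (fold at 24 h below half
#' the 1 h fold).  Non-responsive genes carry no subgroup (`"A"`-analogue
#' reported as `"nonresponsive"`).
#'
#' @inheritParams classifyCold
#' @return A list: `responsive`, `subclass` (`"I"`, `"II"`, `"III"`,
#'   `"nonresponsive"`, `"unclassified"`, or `"undetected"`).
#' @export
classifyDehydration <- function(series, times = c(0, 1, 5, 10, 24),
                                foldThreshold = 2) {
  s <- .checkSeries(series, times)
  if (is.null(s))
    return(list(responsive = NA, subclass = "undetected"))
  responsive <- max(s) / min(s) > foldThreshold
  if (!responsive) return(list(responsive = FALSE,
                               subclass = "nonresponsive"))
  f1 <- s[["1"]]; f24 <- s[["24"]]
  inner <- s[c("1", "5", "10")]
  if (all(inner > 1 / foldThreshold & inner < foldThreshold) &&
      f24 >= foldThreshold)
    return(list(responsive = TRUE, subclass = "I"))
  if (f1 <= 1 / foldThreshold)
    return(list(responsive = TRUE, subclass = "II"))
  if (f1 >= foldThreshold && f24 < f1 / 2)
    return(list(responsive = TRUE, subclass = "III"))
  list(responsive = TRUE, subclass = "unclassified")
}

#' Correlate the expression of a gene pair across time
#'
#' Pearson correlation of log2 fold changes on a chosen subset of
#' time-points, with the sign reported as positive/negative/none
#' (`|r| < rThreshold` or undefined correlation gives `"none"`).
#'
#' @param seriesA,seriesB Named fold-change vectors (names = times).
#' @param timePoints Time subset to correlate over (default
#'   `c(5, 10, 24)`, the late phase; at least 3 shared points required).
#' @param rThreshold Sign-call threshold on |r| (default 0.5).
#' @return A list: `r`, `sign` (`"positive"`, `"negative"`, `"none"`).
#' @export
correlatePair <- function(seriesA, seriesB, timePoints = c(5, 10, 24),
                          rThreshold = 0.5) {
  tp <- as.character(timePoints)
  if (length(tp) < 3L) stop("need at least 3 shared time-points")
  if (!all(tp %in% names(seriesA)) || !all(tp %in% names(seriesB)))
    stop("time-points missing from one of the series")
  a <- log2(seriesA[tp]); b <- log2(seriesB[tp])
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    return(list(r = NA_real_, sign = "none"))
  r <- stats::cor(a, b)
  sign <- if (!is.finite(r) || abs(r) < rThreshold) "none"
          else if (r > 0) "positive" else "negative"
  list(r = unname(r), sign = sign)
}
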