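#' Penalty schema for miRNA target scoring
#'
#' The weighted mismatch-pattern schema for miRNA:mRNA duplexes: a
#' Watson-Crick pair costs 0, a G:U wobble `guPenalty`, any other
#' apposition `mismatchPenalty`, and each gap position `gapPenalty`.
#' Penalties at miRNA positions within the seed range (1-based from the
#' miRNA 5' end) are multiplied by `seedMultiplier`.  Sites are scored in
#' sliding windows of about `windowNt` bases with at most `maxGaps` gap
#' positions per duplex.
#'
#' @param mismatchPenalty,guPenalty,gapPenalty Penalty weights (defaults
#'   1, 0.5, 2).
#' @param seedStart,seedEnd Seed range, miRNA positions 2-13 by default.
#' @param seedMultiplier Seed weighting (default 2).
#' @param maxScore Penalty cutoff for reported sites (default 3).
#' @param windowNt Window size (default 20).
#' @param maxGaps Gap cap per duplex (default 2).
#' @return Named list of validated schema parameters.
#' @export
penaltySchema <- function(mismatchPenalty = 1, guPenalty = 0.5,
                          gapPenalty = 2, seedStart = 2L, seedEnd = 13L,
                          seedMultiplier = 2, maxScore = 3,
                          windowNt = 20L, maxGaps = 2L) {
  stopifnot(mismatchPenalty >= 0, guPenalty >= 0, gapPenalty >= 0,
            seedStart >= 1, seedEnd >= seedStart, seedMultiplier >= 0,
            maxScore >= 0, windowNt > 0, maxGaps >= 0)
  list(mismatch_penalty = mismatchPenalty, gu_penalty = guPenalty,
       gap_penalty = gapPenalty, seed_start = as.integer(seedStart),
       seed_end = as.integer(seedEnd), seed_multiplier = seedMultiplier,
       max_score = maxScore, window_nt = as.integer(windowNt),
       max_gaps = as.integer(maxGaps))
}

#' Score a miRNA against a candidate target site
#'
#' Optimal (minimum-penalty) gapped antiparallel pairing of the full miRNA
#' against the full site under the penalty schema, by dynamic programming.
#'
#' @param mirna miRNA sequence, 5'->3' (RNA or DNA alphabet).
#' @param site Target mRNA window, 5'->3'.
#' @param schema See [penaltySchema()].
#' @return A list: `penalty`, and `duplex` (three aligned strings: miRNA
#'   5'->3', pairing line with `|` for Watson-Crick and `o` for G:U, and
#'   the site rendered 3'->5').
#' @examples
#' scoreDuplex("UGACAGAAGAGAGUGAGCAC", revComp(chartr("U", "T",
#'   "UGACAGAAGAGAGUGAGCAC")))$penalty # 0
#' @export
scoreDuplex <- function(mirna, site, schema = penaltySchema()) {
  m <- .encodeRna(as.character(mirna))
  s <- .encodeRna(as.character(site))
  if (length(m) == 0L || length(s) == 0L) stop("empty sequence")
  if (any(m < 0) || any(s < 0))
    stop("sequences must contain only A, C, G, T/U")
  if (schema$seed_end > length(m))
    stop("seed range extends beyond the miRNA length")
  if (abs(length(s) - length(m)) > schema$max_gaps)
    stop("site and miRNA lengths differ by more than the gap cap")
  r <- .scoreDuplexCpp(m, s, schema)
  list(penalty = r$penalty,
       duplex = c(mirna = r$mirna_line, pairing = r$pairing_line,
                  site = r$site_line))
}

#' Predict miRNA target sites across transcripts
#'
#' Slides a window along the forward strand of each transcript (site
#' lengths within the gap cap of the miRNA length), scores every window
#' with the penalty schema, keeps windows at or below `max_score`, and
#' collapses overlapping windows per (miRNA, transcript) to the local
#' minimum (leftmost on ties).  Output is sorted by penalty, then
#' coordinate.
#'
#' @param mirnas Named character vector or XStringSet of mature miRNAs
#'   (5'->3').
#' @param transcripts Named [Biostrings::DNAStringSet].
#' @param schema See [penaltySchema()].
#' @return `data.frame`: `mirna_id`, `transcript_id`, `t_start`, `t_end`
#'   (0-based half-open), `penalty`.
#' @export
predictTargets <- function(mirnas, transcripts,
                           schema = penaltySchema()) {
  empty <- data.frame(mirna_id = character(0), transcript_id = character(0),
                      t_start = integer(0), t_end = integer(0),
                      penalty = numeric(0))
  mseqs <- as.character(mirnas)
  if (!is.null(names(mirnas))) names(mseqs) <- names(mirnas)
  if (is.null(names(mseqs)))
    names(mseqs) <- sprintf("mirna%02d", seq_along(mseqs))
  out <- list()
  for (mi in seq_along(mseqs)) {
    m <- .encodeRna(mseqs[mi])
    for (ti in seq_along(transcripts)) {
      tcode <- .encodeRna(as.character(transcripts[[ti]]))
      windows <- .scanTargetsCpp(m, tcode, schema, schema$max_score)
      if (nrow(windows) == 0L) next
      windows <- .collapseWindows(windows)
      windows$mirna_id <- names(mseqs)[mi]
      windows$transcript_id <- names(transcripts)[ti]
      out[[length(out) + 1L]] <- windows
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$penalty, res$transcript_id, res$t_start),
             c("mirna_id", "transcript_id", "t_start", "t_end", "penalty")]
  rownames(res) <- NULL
  res
}

# collapse overlapping admissible windows to the local penalty minimum
.collapseWindows <- function(w) {
  w <- w[order(w$t_start), , drop = FALSE]
  ir <- IRanges::IRanges(w$t_start + 1L, w$t_end)
  grp <- S4Vectors::subjectHits(IRanges::findOverlaps(
    ir, IRanges::reduce(ir)))
  keep <- unlist(lapply(split(seq_len(nrow(w)), grp), function(idx) {
    idx[which.min(w$penalty[idx])]
  }), use.names = FALSE)
  w[sort(keep), , drop = FALSE]
}

#' Write a target-prediction report
#'
#' TSV of hits (1-based inclusive coordinates) plus a companion text file
#' with the three-line duplex rendering of each hit.
#'
#' @param hits Output of [predictTargets()].
#' @param mirnas,transcripts The sequence sets used for prediction.
#' @param path Output TSV path; the duplex report is written alongside with
#'   suffix `.duplexes.txt`.
#' @param schema See [penaltySchema()].
#' @return `path`, invisibly.
#' @export
writeTargetReport <- function(hits, mirnas, transcripts, path,
                              schema = penaltySchema()) {
  tab <- data.frame(mirna_id = hits$mirna_id,
                    transcript_id = hits$transcript_id,
                    start1 = hits$t_start + 1L, end1 = hits$t_end,
                    penalty = hits$penalty)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  dpath <- paste0(path, ".duplexes.txt")
  con <- file(dpath, "w")
  on.exit(close(con))
  mseqs <- as.character(mirnas)
  for (i in seq_len(nrow(hits))) {
    site <- substr(as.character(transcripts[[hits$transcript_id[i]]]),
                   hits$t_start[i] + 1L, hits$t_end[i])
    d <- scoreDuplex(mseqs[[hits$mirna_id[i]]], site, schema)
    writeLines(c(sprintf("# %s vs %s (penalty %.2f)", hits$mirna_id[i],
                         hits$transcript_id[i], hits$penalty[i]),
                 sprintf("miRNA 5' %s 3'", d$duplex["mirna"]),
                 sprintf("         %s", d$duplex["pairing"]),
                 sprintf("site  3' %s 5'", d$duplex["site"]), ""), con)
  }
  invisible(path)
}
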