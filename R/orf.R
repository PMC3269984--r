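#' Find open reading frames on both strands
#'
#' Exhaustive six-frame ORF scan.  A complete ORF runs from an ATG to the
#' first in-frame stop codon; in each (strand, frame) the maximal ORF per
#' stop (the one starting at the earliest usable ATG) is reported.  Because
#' EST/454 unigenes are frequently 3'-truncated, ORFs running from an ATG to
#' the sequence end without a stop are also reported, flagged
#' `complete = FALSE`.  Coordinates are 0-based half-open on the forward
#' strand; `aa_length` excludes the stop codon.
#'
#' @param seq A single sequence (character or DNAString) of length `>= 3`.
#' @param id Transcript identifier recorded in the output.
#' @return A `data.frame` with columns `transcript_id`, `strand`, `frame`,
#'   `start`, `end`, `aa_length`, `complete`, sorted by decreasing
#'   `aa_length`.
#' @examples
#' findOrfs(paste0("ATG", strrep("GCT", 99), "TAA"))
#' @export
findOrfs <- function(seq, id = "seq") {
  s <- chartr("Uu", "Tt", toupper(as.character(seq)))
  n <- nchar(s)
  if (n < 3L) stop("sequence shorter than one codon")
  fwd <- .orfScanStrand(s, "+")
  rev <- .orfScanStrand(revComp(s), "-")
  if (nrow(rev)) { # map reverse-strand coordinates back to forward strand
    newStart <- n - rev$end
    rev$end <- n - rev$start
    rev$start <- newStart
  }
  out <- rbind(fwd, rev)
  if (nrow(out)) {
    out$transcript_id <- id
    out <- out[order(-out$aa_length, out$start), c("transcript_id", "strand",
                                                   "frame", "start", "end",
                                                   "aa_length", "complete")]
    rownames(out) <- NULL
  } else {
    out <- data.frame(transcript_id = character(0), strand = character(0),
                      frame = integer(0), start = integer(0),
                      end = integer(0), aa_length = integer(0),
                      complete = logical(0))
  }
  out
}

.STOPS <- c("TAA", "TAG", "TGA")

# scan one strand; coordinates local to the scanned strand
.orfScanStrand <- function(s, strand) {
  n <- nchar(s)
  res <- list()
  for (frame in 0:2) {
    ncod <- (n - frame) %/% 3L
    if (ncod < 1L) next
    codons <- substring(s, frame + 1L + 3L * (seq_len(ncod) - 1L),
                        frame + 3L * seq_len(ncod))
    isStop <- codons %in% .STOPS
    isAtg <- codons == "ATG"
    prevStop <- 0L # codon index of last stop seen (0 = none yet)
    k <- 1L
    stopIdx <- which(isStop)
    for (st in c(stopIdx, NA_integer_)) {
      lim <- if (is.na(st)) ncod else st - 1L
      atg <- which(isAtg[seq_len(lim)])
      atg <- atg[atg > prevStop]
      if (length(atg)) {
        a <- atg[1L]
        if (is.na(st)) { # 3'-open partial: ATG to last complete codon
          start <- frame + 3L * (a - 1L)
          end <- frame + 3L * ncod
          aa <- (end - start) %/% 3L
          res[[length(res) + 1L]] <- data.frame(
            strand = strand, frame = frame, start = start, end = end,
            aa_length = aa, complete = FALSE)
        } else {
          start <- frame + 3L * (a - 1L)
          end <- frame + 3L * st
          aa <- (end - start) %/% 3L - 1L
          res[[length(res) + 1L]] <- data.frame(
            strand = strand, frame = frame, start = start, end = end,
            aa_length = aa, complete = TRUE)
        }
      }
      if (!is.na(st)) prevStop <- st
      k <- k + 1L
    }
  }
  if (length(res)) do.call(rbind, res) else
    data.frame(strand = character(0), frame = integer(0), start = integer(0),
               end = integer(0), aa_length = integer(0),
               complete = logical(0))
}

#' Length (aa) of the best ORF of a transcript
#'
#' @param seq Sequence as for [findOrfs()].
#' @param includePartial Count 3'-open partial ORFs toward the maximum
#'   (default `TRUE`; EST unigenes are often truncated).
#' @return Integer, 0 if no ORF.
#' @export
bestOrfAa <- function(seq, includePartial = TRUE) {
  orfs <- findOrfs(seq)
  if (!includePartial) orfs <- orfs[orfs$complete, , drop = FALSE]
  if (nrow(orfs) == 0L) return(0L)
  max(orfs$aa_length)
}

#' Write a tab-separated ORF report (1-based inclusive coordinates)
#'
#' @param orfs Output of [findOrfs()] (possibly row-bound over transcripts).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
writeOrfReport <- function(orfs, path) {
  rep <- data.frame(transcript_id = orfs$transcript_id,
                    strand = orfs$strand, frame = orfs$frame,
                    start1 = orfs$start + 1L, end1 = orfs$end,
                    aa_length = orfs$aa_length, complete = orfs$complete)
  utils::write.table(rep, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
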