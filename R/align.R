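#' Optimal local alignment of two nucleotide sequences
#'
#' Smith-Waterman local alignment (via [Biostrings::pairwiseAlignment()])
#' under simple match/mismatch scoring with affine gaps: a gap of length L
#' costs `gapOpen + L * gapExt`.  Used as the desk-scale stand-in for BLASTN
#' throughout the homology stages.
#'
#' @param query,subject Sequences (character or DNAString).
#' @param match,mismatch Match/mismatch scores (defaults +2 / -3).
#' @param gapOpen,gapExt Affine gap penalties (positive costs; defaults 5, 2).
#' @param bothStrands Also align against the reverse complement of the
#'   subject and keep the better hit (strand recorded on the subject).
#' @return A one-row `data.frame`: `score`, `identity`, `strand`,
#'   `q_start`, `q_end`, `s_start`, `s_end` (0-based half-open on the
#'   original forward strands), or a zero-score empty hit when no positive-
#'   scoring local alignment exists.
#' @examples
#' localAlign(strrep("ACGT", 12), strrep("ACGT", 12))$score # 96
#' @export
localAlign <- function(query, subject, match = 2, mismatch = -3,
                       gapOpen = 5, gapExt = 2, bothStrands = FALSE) {
  q <- toupper(as.character(query))
  s <- toupper(as.character(subject))
  if (nchar(q) == 0L || nchar(s) == 0L) stop("empty sequence")
  hit <- .alignOne(q, s, match, mismatch, gapOpen, gapExt, "+")
  if (bothStrands) {
    hit2 <- .alignOne(q, revComp(s), match, mismatch, gapOpen, gapExt, "-")
    if (hit2$score > hit$score) {
      # map subject coordinates back to the forward strand
      n <- nchar(s)
      tmp <- hit2
      tmp$s_start <- n - hit2$s_end
      tmp$s_end <- n - hit2$s_start
      hit <- tmp
    }
  }
  hit
}

.subMatrix <- function(match, mismatch) {
  letters <- c("A", "C", "G", "T", "N")
  m <- matrix(mismatch, 5, 5, dimnames = list(letters, letters))
  diag(m) <- match
  m["N", ] <- mismatch
  m[, "N"] <- mismatch
  m
}

.alignOne <- function(q, s, match, mismatch, gapOpen, gapExt, strand) {
  aln <- Biostrings::pairwiseAlignment(
    q, s, type = "local",
    substitutionMatrix = .subMatrix(match, mismatch),
    gapOpening = gapOpen, gapExtension = gapExt)
  sc <- Biostrings::score(aln)
  if (sc <= 0) {
    return(data.frame(score = 0, identity = NA_real_, strand = strand,
                      q_start = 0L, q_end = 0L, s_start = 0L, s_end = 0L))
  }
  p <- Biostrings::pattern(aln)
  t <- Biostrings::subject(aln)
  data.frame(score = sc,
             identity = Biostrings::nmatch(aln) / Biostrings::nchar(aln),
             strand = strand,
             q_start = Biostrings::start(p) - 1L,
             q_end = Biostrings::end(p),
             s_start = Biostrings::start(t) - 1L,
             s_end = Biostrings::end(t))
}

#' Karlin-Altschul E-value for a local alignment score
#'
#' `E = K * m * n * exp(-lambda * S)`.  The default constants are standard
#' ungapped-approximation values for the +2/-3 nucleotide scoring; gapped
#' alignments are approximated with the same constants at desk scale (the
#' pipeline's decisions depend only on threshold behaviour, not on absolute
#' E-values).
#'
#' @param score Alignment score (`> 0`).
#' @param m Query length.
#' @param n Total length of the searched subject database.
#' @param K,lambda Karlin-Altschul constants.
#' @return The expected number of chance hits with score `>= score`.
#' @examples
#' estimateEvalue(60, 400, 1e6) # direct formula
#' @export
estimateEvalue <- function(score, m, n, K = 0.41, lambda = 0.625) {
  if (any(m <= 0) || any(n <= 0)) stop("sequence lengths must be positive")
  if (any(score <= 0)) stop("E-value estimation requires a positive score")
  K * m * n * exp(-lambda * score)
}

# constants for the translated (BLOSUM62) search
.PROT_K <- 0.041
.PROT_LAMBDA <- 0.267

# best translated-search E-value of transcript sequence q against an
# AAStringSet of proteins (six-frame translation, local BLOSUM62 alignment)
.translatedBestE <- function(q, proteins, gapOpen = 11, gapExt = 1) {
  frames <- .sixFrameTranslate(q)
  n <- sum(Biostrings::width(proteins))
  bestE <- Inf
  data("BLOSUM62", package = "Biostrings", envir = environment())
  B62 <- get("BLOSUM62", envir = environment())
  for (fr in frames) {
    if (nchar(fr) < 5L) next
    m <- nchar(fr)
    sc <- Biostrings::pairwiseAlignment(
      proteins, Biostrings::AAString(fr), type = "local",
      substitutionMatrix = B62,
      gapOpening = gapOpen, gapExtension = gapExt, scoreOnly = TRUE)
    sc <- max(sc)
    if (sc > 0) {
      e <- estimateEvalue(sc, m, n, K = .PROT_K, lambda = .PROT_LAMBDA)
      if (e < bestE) bestE <- e
    }
  }
  bestE
}

# six-frame translation, stops rendered as '*', ambiguous codons as 'X'
.sixFrameTranslate <- function(q) {
  s <- chartr("Uu", "Tt", toupper(as.character(q)))
  code <- Biostrings::GENETIC_CODE
  out <- character(0)
  for (str in c(s, revComp(s))) {
    n <- nchar(str)
    for (frame in 0:2) {
      ncod <- (n - frame) %/% 3L
      if (ncod < 1L) next
      starts <- frame + 1L + 3L * (seq_len(ncod) - 1L)
      aa <- unname(code[substring(str, starts, starts + 2L)])
      aa[is.na(aa)] <- "X"
      out <- c(out, paste(aa, collapse = ""))
    }
  }
  out
}
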