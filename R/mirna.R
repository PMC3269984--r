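#' Scan transcripts for regions matching known mature miRNAs
#'
#' Finds every transcript window on either strand within a Hamming distance
#' of `maxMismatch` of a known mature miRNA (equal-length windows, no
#' indels).  G:U wobbles count as mismatches here — the scan is a sequence
#' homology screen, not a structural one.  The word-size-4 seeded search is
#' lossless at this mismatch budget (a 19-24 nt window with at most 3
#' mismatches always contains an exact 4-mer), so the implementation uses
#' the equivalent mismatch-limited exact window scan.  Overlapping hits of
#' the same mature on the same strand are collapsed to the minimum-mismatch
#' window.
#'
#' @param transcripts Named [Biostrings::DNAStringSet].
#' @param matures Named [Biostrings::DNAStringSet] (or RNA; normalized to
#'   DNA internally) of mature miRNAs, 19-24 nt.
#' @param maxMismatch Maximum mismatches (default 3).
#' @param word Seed word size (default 4); matures shorter than this are an
#'   error.
#' @return `data.frame`: `transcript_id`, `known_mirna_id`, `mature_seq`
#'   (RNA rendering of the matched window), `mismatches`, `strand`,
#'   `start`, `end` (0-based half-open on the transcript forward strand).
#' @export
scanKnownMirnas <- function(transcripts, matures, maxMismatch = 3L,
                            word = 4L) {
  if (length(matures) == 0L) stop("no mature miRNA sequences supplied")
  mseq <- chartr("Uu", "Tt", toupper(as.character(matures)))
  if (any(nchar(mseq) < word))
    stop("mature sequence(s) shorter than the seed word size (", word, ")")
  if (any(nchar(mseq) < 19L | nchar(mseq) > 24L))
    stop("mature miRNA sequences must be 19-24 nt")
  res <- list()
  for (ti in seq_along(transcripts)) {
    subj <- transcripts[[ti]]
    tid <- names(transcripts)[ti]
    for (mi in seq_along(mseq)) {
      pat <- Biostrings::DNAString(mseq[mi])
      L <- length(pat)
      if (length(subj) < L) next
      for (strand in c("+", "-")) {
        p <- if (strand == "+") pat else Biostrings::reverseComplement(pat)
        m <- Biostrings::matchPattern(p, subj, max.mismatch = maxMismatch,
                                      with.indels = FALSE)
        if (length(m) == 0L) next
        starts <- Biostrings::start(m)
        mm <- Biostrings::neditStartingAt(p, subj, starting.at = starts,
                                          with.indels = FALSE)
        res[[length(res) + 1L]] <- data.frame(
          transcript_id = tid, known_mirna_id = names(matures)[mi],
          mature_seq = chartr("T", "U", as.character(m)),
          mismatches = as.integer(mm), strand = strand,
          start = starts - 1L, end = starts - 1L + L)
      }
    }
  }
  if (!length(res))
    return(data.frame(transcript_id = character(0),
                      known_mirna_id = character(0),
                      mature_seq = character(0), mismatches = integer(0),
                      strand = character(0), start = integer(0),
                      end = integer(0)))
  hits <- do.call(rbind, res)
  .collapseOverlapping(hits)
}

# within (transcript, mature, strand), collapse overlapping windows to the
# minimum-mismatch one (leftmost on ties)
.collapseOverlapping <- function(hits) {
  keyed <- split(hits, paste(hits$transcript_id, hits$known_mirna_id,
                             hits$strand))
  out <- lapply(keyed, function(h) {
    h <- h[order(h$start), , drop = FALSE]
    ir <- IRanges::IRanges(h$start + 1L, h$end)
    grp <- S4Vectors::subjectHits(IRanges::findOverlaps(
      ir, IRanges::reduce(ir)))
    keep <- unlist(lapply(split(seq_len(nrow(h)), grp), function(idx) {
      idx[which.min(h$mismatches[idx])]
    }), use.names = FALSE)
    h[sort(keep), , drop = FALSE]
  })
  out <- do.call(rbind, out)
  out <- out[order(out$transcript_id, out$known_mirna_id, out$start), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Criteria for accepting a hairpin as a miRNA precursor
#'
#' Operationalized plant-miRNA annotation thresholds: the mature must sit
#' wholly on one arm of a single stem-loop, with at most
#' `maxMatureUnpaired` unpaired mature bases and no bulge larger than
#' `maxBulgeInMature` nucleotides within the mature:star duplex.
#'
#' @param maxMatureUnpaired Maximum unpaired mature bases (default 4).
#' @param maxBulgeInMature Maximum bulge size in the duplex (default 2).
#' @param requireSingleArm Require a single stem-loop containing the mature
#'   (default `TRUE`).
#' @param flankNt Context extracted on each side of the mature hit before
#'   folding (default 150 nt).
#' @return Named list of validated criteria.
#' @export
precursorCriteria <- function(maxMatureUnpaired = 4L, maxBulgeInMature = 2L,
                              requireSingleArm = TRUE, flankNt = 150L) {
  stopifnot(maxMatureUnpaired >= 0, maxBulgeInMature >= 0, flankNt >= 0)
  list(max_mature_unpaired = as.integer(maxMatureUnpaired),
       max_bulge_in_mature = as.integer(maxBulgeInMature),
       require_single_arm = isTRUE(requireSingleArm),
       flank_nt = as.integer(flankNt))
}

#' Evaluate a mature-miRNA hit as a hairpin precursor
#'
#' Extracts the mature hit plus `flank_nt` of context on each side, folds
#' it with [rnaFold()], and applies the precursor criteria.  On acceptance
#' the MFEI is computed over the chosen precursor region: `"hairpin"`
#' trims to the stem-loop containing the mature (first to last paired base,
#' refolded), `"full"` uses the whole extracted context.
#'
#' @param transcript Host transcript sequence (character or DNAString).
#' @param hit One row of [scanKnownMirnas()] output (or a list with
#'   `start`, `end`, `strand`, `transcript_id`).
#' @param criteria See [precursorCriteria()].
#' @param mfeiRegion `"hairpin"` (default) or `"full"`.
#' @param params Folding energy parameters.
#' @return A [HairpinCandidate-class]; check [isAccepted()] /
#'   [rejectionReason()].
#' @export
evaluatePrecursor <- function(transcript, hit,
                              criteria = precursorCriteria(),
                              mfeiRegion = c("hairpin", "full"),
                              params = foldEnergyParams()) {
  mfeiRegion <- match.arg(mfeiRegion)
  s <- chartr("Uu", "Tt", toupper(as.character(transcript)))
  n <- nchar(s)
  ms <- as.integer(hit$start); me <- as.integer(hit$end)
  stopifnot(ms >= 0, me <= n, ms < me)
  ps <- max(0L, ms - criteria$flank_nt)
  pe <- min(n, me + criteria$flank_nt)
  ctx <- substr(s, ps + 1L, pe)
  if (identical(as.character(hit$strand), "-")) {
    ctx <- revComp(ctx)
    # mature coords within the reversed context
    newMs <- pe - me
    newMe <- pe - ms
  } else {
    newMs <- ms - ps
    newMe <- me - ps
  }
  fold <- rnaFold(ctx, params = params)
  pairTab <- .pairTable(fold$structure)
  matureIdx <- (newMs + 1L):newMe  # 1-based within ctx

  tid <- as.character(hit$transcript_id)
  reject <- function(reason) {
    new("HairpinCandidate", transcript_id = tid,
        precursor_seq = chartr("T", "U", ctx), structure = fold$structure,
        mfe = fold$mfe, length_nt = nchar(ctx),
        gc_percent = gcFraction(ctx) * 100, mfei = NA_real_,
        mature_arm = NA_character_, mature_offset = as.integer(newMs),
        mature_length = length(matureIdx),
        n_unpaired_in_mature = NA_integer_,
        largest_bulge_in_duplex = NA_integer_,
        accepted = FALSE, reason = reason)
  }

  partners <- pairTab[matureIdx]
  paired <- which(!is.na(partners))
  if (length(paired) == 0L) return(reject("mature entirely unpaired"))
  if (any(partners[paired] %in% matureIdx))
    return(reject("mature spans loop"))
  nUnpaired <- sum(is.na(partners))
  if (nUnpaired > criteria$max_mature_unpaired)
    return(reject(paste0("unpaired>", criteria$max_mature_unpaired)))
  # bulge sizes: runs of unpaired bases between paired mature bases, and
  # skipped star bases between partners of consecutive paired mature bases
  bulge <- 0L
  if (length(paired) >= 2L) {
    gapsMat <- diff(paired) - 1L
    gapsStar <- abs(diff(partners[paired])) - 1L
    bulge <- max(c(gapsMat, gapsStar), 0L)
  }
  if (bulge > criteria$max_bulge_in_mature)
    return(reject(paste0("bulge>", criteria$max_bulge_in_mature)))

  span <- range(c(matureIdx[paired], partners[paired]))
  nLoops <- .countHairpinLoops(pairTab, span[1], span[2])
  if (criteria$require_single_arm && nLoops != 1L)
    return(reject("mature not on a single stem-loop"))

  arm <- if (all(partners[paired] > matureIdx[paired])) "5p" else "3p"

  # trim to the stem-loop containing the mature: walk outward from the
  # enclosing pair through stacked/bulged/internal loops only
  bounds <- .stemLoopBounds(pairTab, span[1], span[2])
  if (mfeiRegion == "hairpin") {
    pseq <- substr(ctx, bounds[1], bounds[2])
    pfold <- rnaFold(pseq, params = params, minLength = 10L)
    off <- as.integer(newMs - (bounds[1] - 1L))
    struct <- pfold$structure
    mfeVal <- pfold$mfe
  } else {
    pseq <- ctx
    off <- as.integer(newMs)
    struct <- fold$structure
    mfeVal <- fold$mfe
  }
  gc <- gcFraction(pseq) * 100
  new("HairpinCandidate", transcript_id = tid,
      precursor_seq = chartr("T", "U", pseq), structure = struct,
      mfe = mfeVal, length_nt = nchar(pseq), gc_percent = gc,
      mfei = mfei(mfeVal, nchar(pseq), gc), mature_arm = arm,
      mature_offset = off, mature_length = length(matureIdx),
      n_unpaired_in_mature = as.integer(nUnpaired),
      largest_bulge_in_duplex = as.integer(bulge),
      accepted = TRUE, reason = "")
}

# 1-based partner table from a dot-bracket string (NA = unpaired)
.pairTable <- function(db) {
  v <- strsplit(db, "")[[1]]
  out <- rep(NA_integer_, length(v))
  stack <- integer(0)
  for (i in seq_along(v)) {
    if (v[i] == "(") stack <- c(stack, i)
    else if (v[i] == ")") {
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      out[i] <- j; out[j] <- i
    }
  }
  out
}

# number of hairpin loops whose closing pair lies within [lo, hi]
.countHairpinLoops <- function(pairTab, lo, hi) {
  n <- 0L
  for (i in lo:hi) {
    j <- pairTab[i]
    if (!is.na(j) && j > i && j <= hi) {
      inner <- if (j - i > 1L) pairTab[(i + 1L):(j - 1L)] else integer(0)
      if (all(is.na(inner))) n <- n + 1L
    }
  }
  n
}

# expand [lo, hi] outward through two-sided (stack/bulge/internal) loops;
# returns 1-based first and last paired positions of the stem-loop
.stemLoopBounds <- function(pairTab, lo, hi) {
  # innermost enclosing pair of the region
  i <- lo; j <- hi
  if (is.na(pairTab[i]) || pairTab[i] != j) {
    # find outermost pair within the span
    cand <- which(!is.na(pairTab) & seq_along(pairTab) >= lo &
                  pairTab >= lo & seq_along(pairTab) <= hi & pairTab <= hi)
    if (!length(cand)) return(c(lo, hi))
    i <- min(cand); j <- pairTab[i]
  }
  repeat {
    # is there an enclosing pair (i', j') with only unpaired bases between?
    ip <- i - 1L
    while (ip >= 1L && is.na(pairTab[ip])) ip <- ip - 1L
    if (ip < 1L) break
    jp <- pairTab[ip]
    if (is.na(jp) || jp < j) break
    if (any(!is.na(pairTab[seq(j + 1L, length.out = max(0L, jp - j - 1L))])))
      break
    i <- ip; j <- jp
  }
  c(i, j)
}

#' Group accepted mature miRNA sequences into families
#'
#' Single-linkage grouping of mature sequences by Hamming distance at the
#' best ungapped offset, with length difference counted as mismatches.
#' Family names are taken from the member ids (common prefix after
#' stripping a trailing lowercase variant letter, e.g. MIR156a/MIR156b ->
#' MIR156).
#'
#' @param matures Named character vector (or DNA/RNAStringSet) of mature
#'   sequences.
#' @param maxMismatch Linkage threshold (default 3).
#' @return A list with `families` (`data.frame`: `family`, `member_id`,
#'   `sequence`), `n_families`, and `sizes` (named integer vector).
#' @export
groupMatureFamilies <- function(matures, maxMismatch = 3L) {
  raw <- as.character(matures)
  if (length(raw) == 0L) stop("no mature sequences supplied")
  ids <- names(raw)
  seqs <- chartr("Uu", "Tt", toupper(raw)) # chartr drops names
  if (is.null(ids)) ids <- sprintf("mature%02d", seq_along(seqs))
  n <- length(seqs)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      if (.matureDistance(seqs[i], seqs[j]) <= maxMismatch) {
        a <- find(i); b <- find(j)
        if (a != b) parent[max(a, b)] <- min(a, b)
      }
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  groups <- split(seq_len(n), comp)
  fam <- character(n)
  for (g in groups) {
    nm <- sort(ids[g])[1]
    fam[g] <- sub("[a-z]$", "", nm)
  }
  tab <- data.frame(family = fam, member_id = ids,
                    sequence = chartr("T", "U", seqs))
  tab <- tab[order(tab$family, tab$member_id), ]
  rownames(tab) <- NULL
  sizes <- vapply(split(tab$member_id, tab$family), length, integer(1))
  list(families = tab, n_families = length(groups), sizes = sizes)
}

# Hamming distance at the best ungapped offset; overhanging bases count as
# mismatches
.matureDistance <- function(a, b) {
  va <- strsplit(a, "")[[1]]; vb <- strsplit(b, "")[[1]]
  la <- length(va); lb <- length(vb)
  best <- Inf
  for (off in -(lb - 1L):(la - 1L)) {
    # b shifted right by off relative to a
    astart <- max(1L, 1L + off); aend <- min(la, lb + off)
    if (aend < astart) next
    overlap <- aend - astart + 1L
    mm <- sum(va[astart:aend] != vb[(astart - off):(aend - off)])
    d <- mm + (max(la, lb) - overlap)
    if (d < best) best <- d
  }
  best
}
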