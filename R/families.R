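#' Cluster mlncRNA candidates into families by sequence homology
#'
#' All-vs-all local alignment (both strands); pairs whose E-value is at or
#' below the cutoff are linked, and single-linkage connected components of
#' size two or more become families.  The effective database length for the
#' E-value is the total length of the set, mirroring an all-vs-all search.
#' Family numbering is deterministic: families are ordered by their
#' lexicographically smallest member id.
#'
#' @param seqs A named [Biostrings::DNAStringSet] of mlncRNA candidates.
#' @param eCutoff E-value cutoff (default 1e-5).
#' @return A list with `families` (`data.frame` of `family_id`,
#'   `member_id`), `singletons` (character vector) and `membership` (named
#'   family id per input, `NA` for singletons).
#' @export
clusterFamilies <- function(seqs, eCutoff = 1e-5) {
  S4Vectors::mcols(seqs) <- NULL
  n <- length(seqs)
  if (n == 0L) stop("at least one sequence is required")
  ids <- names(seqs)
  dbLen <- sum(Biostrings::width(seqs))
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      scF <- Biostrings::pairwiseAlignment(
        seqs[(i + 1L):n], seqs[[i]], type = "local",
        substitutionMatrix = .subMatrix(2, -3),
        gapOpening = 5, gapExtension = 2, scoreOnly = TRUE)
      scR <- Biostrings::pairwiseAlignment(
        seqs[(i + 1L):n], Biostrings::reverseComplement(seqs[[i]]),
        type = "local", substitutionMatrix = .subMatrix(2, -3),
        gapOpening = 5, gapExtension = 2, scoreOnly = TRUE)
      sc <- pmax(scF, scR)
      ok <- sc > 0
      if (any(ok)) {
        e <- rep(Inf, length(sc))
        e[ok] <- estimateEvalue(sc[ok], Biostrings::width(seqs)[i], dbLen)
        for (j in which(e <= eCutoff)) {
          a <- find(i); b <- find(i + j)
          if (a != b) parent[max(a, b)] <- min(a, b)
        }
      }
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  groups <- split(ids, comp)
  fams <- groups[vapply(groups, length, integer(1)) >= 2L]
  singles <- unlist(groups[vapply(groups, length, integer(1)) == 1L],
                    use.names = FALSE)
  # deterministic numbering by smallest member id
  if (length(fams)) {
    ord <- order(vapply(fams, function(g) sort(g)[1], character(1)))
    fams <- fams[ord]
    famIds <- sprintf("FAM%03d", seq_along(fams))
    famTab <- data.frame(
      family_id = rep(famIds, vapply(fams, length, integer(1))),
      member_id = unlist(lapply(fams, sort), use.names = FALSE))
  } else {
    famIds <- character(0)
    famTab <- data.frame(family_id = character(0),
                         member_id = character(0))
  }
  membership <- stats::setNames(rep(NA_character_, n), ids)
  if (nrow(famTab))
    membership[famTab$member_id] <- famTab$family_id
  list(families = famTab, singletons = sort(singles),
       membership = membership)
}

#' Screen mlncRNA candidates against a known non-coding RNA database
#'
#' Reports candidates whose best (both-strand) local-alignment hit against
#' the reference reaches `E <= eCutoff` — the conservation analogue of a
#' BLASTN search of a known-npcRNA collection.
#'
#' @param mlncs Named [Biostrings::DNAStringSet] of candidates.
#' @param db Named [Biostrings::DNAStringSet] reference (may be empty).
#' @param eCutoff E-value cutoff (default 1e-5).
#' @return `data.frame` with `id`, `db_id`, `score`, `evalue` for conserved
#'   candidates (zero rows if none).
#' @export
conservationScreen <- function(mlncs, db, eCutoff = 1e-5) {
  empty <- data.frame(id = character(0), db_id = character(0),
                      score = numeric(0), evalue = numeric(0))
  if (is.null(db) || length(db) == 0L || length(mlncs) == 0L) return(empty)
  S4Vectors::mcols(mlncs) <- NULL
  S4Vectors::mcols(db) <- NULL
  dbLen <- sum(Biostrings::width(db))
  out <- empty
  for (i in seq_along(mlncs)) {
    scF <- Biostrings::pairwiseAlignment(
      db, mlncs[[i]], type = "local",
      substitutionMatrix = .subMatrix(2, -3),
      gapOpening = 5, gapExtension = 2, scoreOnly = TRUE)
    scR <- Biostrings::pairwiseAlignment(
      db, Biostrings::reverseComplement(mlncs[[i]]), type = "local",
      substitutionMatrix = .subMatrix(2, -3),
      gapOpening = 5, gapExtension = 2, scoreOnly = TRUE)
    sc <- pmax(scF, scR)
    k <- which.max(sc)
    if (sc[k] > 0) {
      e <- estimateEvalue(sc[k], Biostrings::width(mlncs)[i], dbLen)
      if (e <= eCutoff)
        out <- rbind(out, data.frame(id = names(mlncs)[i],
                                     db_id = names(db)[k],
                                     score = sc[k], evalue = e))
    }
  }
  rownames(out) <- NULL
  out
}

#' Relate mlncRNA candidates to protein-coding transcripts
#'
#' Finds mlncRNA regions significantly homologous (sense) or complementary
#' (antisense) to coding transcripts and localizes the aligned region on the
#' coding gene relative to its ORF: `CDS` when the subject interval lies
#' inside the ORF, `UTR5`/`UTR3` when inside the respective untranslated
#' interval, `junction` otherwise.  For minus-strand ORFs the UTR labels
#' follow transcript orientation (the 5' UTR is 3'-ward in forward
#' coordinates).
#'
#' @param mlncs Named [Biostrings::DNAStringSet] of mlncRNA candidates.
#' @param coding Named [Biostrings::DNAStringSet] of coding transcripts.
#' @param orfTable `data.frame` as from [findOrfs()] rows (best ORF per
#'   coding transcript; columns `transcript_id`, `strand`, `start`, `end`).
#' @param eCutoff E-value cutoff (default 1e-5).
#' @return `data.frame`: `mlnc_id`, `coding_id`, `orientation`
#'   (sense/antisense), `region` (CDS/UTR5/UTR3/junction), `identity`,
#'   `evalue`, and 0-based half-open aligned spans on both sequences.
#' @export
relateMlncToCoding <- function(mlncs, coding, orfTable, eCutoff = 1e-5) {
  out <- data.frame(mlnc_id = character(0), coding_id = character(0),
                    orientation = character(0), region = character(0),
                    identity = numeric(0), evalue = numeric(0),
                    q_start = integer(0), q_end = integer(0),
                    s_start = integer(0), s_end = integer(0))
  if (length(mlncs) == 0L || length(coding) == 0L) return(out)
  dbLen <- sum(Biostrings::width(coding))
  for (i in seq_along(mlncs)) {
    for (k in seq_along(coding)) {
      cid <- names(coding)[k]
      orf <- orfTable[orfTable$transcript_id == cid, , drop = FALSE]
      if (nrow(orf) == 0L) {
        warning("coding transcript without ORF skipped: ", cid)
        next
      }
      orf <- orf[1L, ]
      hit <- localAlign(mlncs[[i]], coding[[k]], bothStrands = TRUE)
      if (hit$score <= 0) next
      e <- estimateEvalue(hit$score, Biostrings::width(mlncs)[i], dbLen)
      if (e > eCutoff) next
      region <- .regionCall(hit$s_start, hit$s_end, orf$start, orf$end,
                            orf$strand, Biostrings::width(coding)[k])
      out <- rbind(out, data.frame(
        mlnc_id = names(mlncs)[i], coding_id = cid,
        orientation = if (hit$strand == "+") "sense" else "antisense",
        region = region, identity = hit$identity, evalue = e,
        q_start = hit$q_start, q_end = hit$q_end,
        s_start = hit$s_start, s_end = hit$s_end))
    }
  }
  rownames(out) <- NULL
  out
}

# region of [s, e) relative to ORF [os, oe) on a transcript of length len
.regionCall <- function(s, e, os, oe, orfStrand, len) {
  if (s >= os && e <= oe) return("CDS")
  upstream <- (e <= os)    # entirely 5'-ward of the ORF in forward coords
  downstream <- (s >= oe)
  if (orfStrand == "+") {
    if (upstream) return("UTR5")
    if (downstream) return("UTR3")
  } else {
    if (upstream) return("UTR3")
    if (downstream) return("UTR5")
  }
  "junction"
}
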