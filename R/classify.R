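#' Parameters for the unigene classification tree
#'
#' @param minLength Minimum unigene length (bp) for detailed
#'   characterization; shorter unannotated unigenes are set aside (default
#'   300).
#' @param orfCutoffAa ORF length cutoff (amino acids) separating putative
#'   protein-coding transcripts from non-coding candidates (default 100).
#' @param annotationEvalue E-value cutoff for the protein-homology
#'   annotation step (default 1e-5).
#' @param housekeepingEvalue E-value cutoff for the housekeeping
#'   non-coding-RNA screen (default 1e-5).
#' @param countPartialOrfs Whether 3'-open partial ORFs count toward the
#'   ORF cutoff (default `TRUE`; 454 unigenes are often truncated).
#' @return A named list of validated parameters.
#' @export
classifyParams <- function(minLength = 300L, orfCutoffAa = 100L,
                           annotationEvalue = 1e-5,
                           housekeepingEvalue = 1e-5,
                           countPartialOrfs = TRUE) {
  stopifnot(minLength > 0, orfCutoffAa > 0, annotationEvalue > 0,
            housekeepingEvalue > 0)
  list(min_length = as.integer(minLength),
       orf_cutoff_aa = as.integer(orfCutoffAa),
       annotation_evalue = annotationEvalue,
       housekeeping_evalue = housekeepingEvalue,
       count_partial_orfs = isTRUE(countPartialOrfs))
}

.CLASSES <- c("ANNOTATED_CODING", "SHORT_UNANNOTATED", "NOVEL_CODING",
              "MLNC_CANDIDATE", "HOUSEKEEPING_NPCRNA")

#' Protein-homology annotation of a transcript
#'
#' Six-frame translated local alignment (BLOSUM62) against a user-supplied
#' protein set, the desk-scale stand-in for a BLASTX search of a reference
#' protein database.  Alternatively, a precomputed annotation table
#' (`id -> annotated`) can be supplied and overrides the search.
#'
#' @param transcript Sequence (character or DNAString).
#' @param id Transcript identifier (used for the table lookup).
#' @param proteins An [Biostrings::AAStringSet] of reference proteins, or
#'   `NULL`.
#' @param annotationTable Optional `data.frame` with columns `id` and
#'   `annotated` (logical); ids present in the table bypass the search.
#' @param params See [classifyParams()].
#' @return `TRUE` if annotated.
#' @export
annotateByProteinHomology <- function(transcript, id = "seq",
                                      proteins = NULL,
                                      annotationTable = NULL,
                                      params = classifyParams()) {
  if (!is.null(annotationTable) && id %in% annotationTable$id)
    return(isTRUE(annotationTable$annotated[match(id, annotationTable$id)]))
  if (is.null(proteins) || length(proteins) == 0L) {
    if (is.null(annotationTable))
      stop("provide a protein set or an annotation table")
    return(FALSE)
  }
  e <- .translatedBestE(transcript, proteins)
  is.finite(e) && e <= params$annotation_evalue
}

#' Screen a transcript against a housekeeping non-coding RNA reference
#'
#' Nucleotide local alignment (both strands) against a reference set of
#' structural RNAs (tRNA/snoRNA-class), the stand-in for a BLASTN search of
#' a covariance-model database.  An empty reference passes everyone.
#'
#' @param transcript Sequence.
#' @param hkdb [Biostrings::DNAStringSet] of housekeeping RNA references
#'   (may be empty or `NULL`).
#' @param params See [classifyParams()].
#' @param dbLength Effective database length for the E-value (defaults to
#'   the total reference length).
#' @return A one-row `data.frame` (`hk_id`, `score`, `evalue`) for the best
#'   hit with `E <= housekeeping_evalue`, or `NULL`.
#' @export
screenHousekeeping <- function(transcript, hkdb,
                               params = classifyParams(),
                               dbLength = NULL) {
  if (is.null(hkdb) || length(hkdb) == 0L) return(NULL)
  if (is.null(dbLength)) dbLength <- sum(Biostrings::width(hkdb))
  m <- nchar(as.character(transcript))
  best <- NULL
  for (k in seq_along(hkdb)) {
    hit <- localAlign(transcript, hkdb[[k]], bothStrands = TRUE)
    if (hit$score <= 0) next
    e <- estimateEvalue(hit$score, m, dbLength)
    if (e <= params$housekeeping_evalue &&
        (is.null(best) || e < best$evalue)) {
      best <- data.frame(hk_id = names(hkdb)[k], score = hit$score,
                         evalue = e)
    }
  }
  best
}

#' Classify a single transcript
#'
#' The decision tree: annotated transcripts are `ANNOTATED_CODING`;
#' unannotated ones shorter than `min_length` are `SHORT_UNANNOTATED`;
#' those with an ORF of at least `orf_cutoff_aa` amino acids are
#' `NOVEL_CODING`; the remainder are `HOUSEKEEPING_NPCRNA` when they hit
#' the housekeeping reference, and `MLNC_CANDIDATE` otherwise.  The
#' housekeeping screen is applied after the ORF test, so a long-ORF
#' transcript is never called housekeeping.
#'
#' @param length Transcript length (bp).
#' @param annotated Logical, from [annotateByProteinHomology()].
#' @param bestOrfAa Best ORF length in amino acids.
#' @param hkHit Housekeeping hit (`NULL` if none), from
#'   [screenHousekeeping()].
#' @param params See [classifyParams()].
#' @return One of `"ANNOTATED_CODING"`, `"SHORT_UNANNOTATED"`,
#'   `"NOVEL_CODING"`, `"HOUSEKEEPING_NPCRNA"`, `"MLNC_CANDIDATE"`.
#' @export
classifyTranscript <- function(length, annotated, bestOrfAa, hkHit = NULL,
                               params = classifyParams()) {
  if (isTRUE(annotated)) return("ANNOTATED_CODING")
  if (length < params$min_length) return("SHORT_UNANNOTATED")
  if (bestOrfAa >= params$orf_cutoff_aa) return("NOVEL_CODING")
  if (!is.null(hkHit)) return("HOUSEKEEPING_NPCRNA")
  "MLNC_CANDIDATE"
}

#' Classify a transcript set
#'
#' Runs the full decision tree over a unigene set.  Expensive steps are
#' applied only where the tree needs them: the ORF scan for unannotated
#' transcripts of sufficient length, the housekeeping screen for those that
#' fail the ORF cutoff.
#'
#' @param transcripts A named [Biostrings::DNAStringSet].
#' @param proteins Optional [Biostrings::AAStringSet] protein reference.
#' @param annotationTable Optional precomputed annotation table (columns
#'   `id`, `annotated`).
#' @param hkdb Optional [Biostrings::DNAStringSet] housekeeping reference.
#' @param params See [classifyParams()].
#' @return A list with `table` (one row per transcript: `id`, `length`,
#'   `class`, `best_orf_aa`, `hk_hit_id`, `annotation_evidence`) and
#'   `counts` (named integer vector over the five classes).
#' @export
classifySet <- function(transcripts, proteins = NULL,
                        annotationTable = NULL, hkdb = NULL,
                        params = classifyParams()) {
  ids <- names(transcripts)
  if (is.null(ids) && length(transcripts) > 0L)
    stop("transcripts must be named")
  if (anyDuplicated(ids))
    stop("duplicate transcript ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  n <- length(transcripts)
  cls <- character(n); orfAa <- integer(n)
  hkId <- rep(NA_character_, n); evid <- rep(NA_character_, n)
  lens <- Biostrings::width(transcripts)
  for (i in seq_len(n)) {
    s <- as.character(transcripts[[i]])
    ann <- annotateByProteinHomology(s, ids[i], proteins, annotationTable,
                                     params)
    if (ann) {
      cls[i] <- "ANNOTATED_CODING"
      evid[i] <- "protein_homology"
      orfAa[i] <- NA_integer_
      next
    }
    if (lens[i] < params$min_length) {
      cls[i] <- "SHORT_UNANNOTATED"
      orfAa[i] <- NA_integer_
      next
    }
    orfAa[i] <- bestOrfAa(s, includePartial = params$count_partial_orfs)
    if (orfAa[i] >= params$orf_cutoff_aa) {
      cls[i] <- "NOVEL_CODING"
      next
    }
    hk <- screenHousekeeping(s, hkdb, params)
    if (!is.null(hk)) {
      cls[i] <- "HOUSEKEEPING_NPCRNA"
      hkId[i] <- hk$hk_id
    } else {
      cls[i] <- "MLNC_CANDIDATE"
    }
  }
  tab <- data.frame(id = ids, length = lens, class = cls,
                    best_orf_aa = orfAa, hk_hit_id = hkId,
                    annotation_evidence = evid)
  counts <- stats::setNames(integer(length(.CLASSES)), .CLASSES)
  tc <- table(factor(cls, levels = .CLASSES))
  counts[names(tc)] <- as.integer(tc)
  list(table = tab, counts = counts)
}
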