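#' @import methods
NULL

#' HairpinCandidate: an evaluated miRNA precursor
#'
#' Holds the folded precursor context around a mature-miRNA hit together
#' with the acceptance decision under plant-miRNA annotation criteria
#' (single stem-loop, mature wholly on one arm, bounded unpaired bases and
#' bulges in the mature:star duplex) and, for accepted candidates, the
#' minimal folding free energy index (MFEI) of the precursor region.
#'
#' @slot transcript_id Host transcript identifier.
#' @slot precursor_seq Precursor sequence (RNA alphabet).
#' @slot structure Dot-bracket string, same length as the precursor.
#' @slot mfe Minimum free energy of the precursor fold (kcal/mol, `<= 0`).
#' @slot length_nt Precursor length (nt).
#' @slot gc_percent G+C percentage of the precursor, `(0, 100]`.
#' @slot mfei `(|mfe| / length_nt * 100) / gc_percent`.
#' @slot mature_arm `"5p"` or `"3p"`.
#' @slot mature_offset 0-based offset of the mature within the precursor.
#' @slot mature_length Mature length (nt).
#' @slot n_unpaired_in_mature Unpaired mature bases in the fold.
#' @slot largest_bulge_in_duplex Largest bulge (nt) within the mature:star
#'   duplex, on either side.
#' @slot accepted Whether the candidate passed the criteria.
#' @slot reason Rejection reason (`""` when accepted).
#' @export
setClass("HairpinCandidate",
         representation(transcript_id = "character",
                        precursor_seq = "character",
                        structure = "character",
                        mfe = "numeric",
                        length_nt = "integer",
                        gc_percent = "numeric",
                        mfei = "numeric",
                        mature_arm = "character",
                        mature_offset = "integer",
                        mature_length = "integer",
                        n_unpaired_in_mature = "integer",
                        largest_bulge_in_duplex = "integer",
                        accepted = "logical",
                        reason = "character"))

setValidity("HairpinCandidate", function(object) {
  msgs <- character(0)
  if (nchar(object@structure) != nchar(object@precursor_seq))
    msgs <- c(msgs, "structure length != precursor length")
  db <- strsplit(object@structure, "")[[1]]
  depth <- cumsum((db == "(") - (db == ")"))
  if (length(depth) && (any(depth < 0) || utils::tail(depth, 1) != 0))
    msgs <- c(msgs, "unbalanced dot-bracket structure")
  if (length(object@mfe) && object@mfe > 0)
    msgs <- c(msgs, "mfe must be <= 0")
  if (isTRUE(object@accepted)) {
    expect <- (abs(object@mfe) / object@length_nt * 100) / object@gc_percent
    if (abs(expect - object@mfei) > 1e-6)
      msgs <- c(msgs, "mfei inconsistent with mfe, length and GC")
    if (!object@mature_arm %in% c("5p", "3p"))
      msgs <- c(msgs, "mature_arm must be 5p or 3p")
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "HairpinCandidate", function(object) {
  if (isTRUE(object@accepted)) {
    cat("HairpinCandidate (accepted) on", object@transcript_id, "\n",
        " precursor:", object@length_nt, "nt, GC",
        sprintf("%.1f%%", object@gc_percent), "\n",
        " MFE:", sprintf("%.2f kcal/mol", object@mfe),
        " MFEI:", sprintf("%.3f", object@mfei), "\n",
        " mature:", paste0(object@mature_arm, " arm, offset ",
                           object@mature_offset, ", ",
                           object@n_unpaired_in_mature, " unpaired"), "\n")
  } else {
    cat("HairpinCandidate (rejected) on", object@transcript_id,
        "-", object@reason, "\n")
  }
  invisible(NULL)
})

#' @rdname HairpinCandidate-accessors
#' @export
setGeneric("isAccepted", function(x) standardGeneric("isAccepted"))
#' @rdname HairpinCandidate-accessors
#' @export
setGeneric("rejectionReason", function(x)
  standardGeneric("rejectionReason"))
#' @rdname HairpinCandidate-accessors
#' @export
setGeneric("mfeValue", function(x) standardGeneric("mfeValue"))
#' @rdname HairpinCandidate-accessors
#' @export
setGeneric("mfeiValue", function(x) standardGeneric("mfeiValue"))
#' @rdname HairpinCandidate-accessors
#' @export
setGeneric("structureString", function(x)
  standardGeneric("structureString"))
#' @rdname HairpinCandidate-accessors
#' @export
setGeneric("matureArm", function(x) standardGeneric("matureArm"))

#' Accessors for HairpinCandidate
#'
#' @param x A `HairpinCandidate`.
#' @return The corresponding slot value.
#' @name HairpinCandidate-accessors
NULL

#' @rdname HairpinCandidate-accessors
setMethod("isAccepted", "HairpinCandidate", function(x) x@accepted)
#' @rdname HairpinCandidate-accessors
setMethod("rejectionReason", "HairpinCandidate", function(x) x@reason)
#' @rdname HairpinCandidate-accessors
setMethod("mfeValue", "HairpinCandidate", function(x) x@mfe)
#' @rdname HairpinCandidate-accessors
setMethod("mfeiValue", "HairpinCandidate", function(x) x@mfei)
#' @rdname HairpinCandidate-accessors
setMethod("structureString", "HairpinCandidate", function(x) x@structure)
#' @rdname HairpinCandidate-accessors
setMethod("matureArm", "HairpinCandidate", function(x) x@mature_arm)

#' CqExperiment: a qPCR quantification-cycle experiment
#'
#' A thin [SummarizedExperiment::SummarizedExperiment] subclass holding one
#' `cq` assay (genes x samples, technical replicates already averaged) with
#' sample annotations (`sample`, and for stress series `stress` and
#' `time_h`).  Undetected reactions (no amplification by the detection
#' cutoff cycle) are `NA`.
#'
#' @export
setClass("CqExperiment",
         contains = "SummarizedExperiment")

setValidity("CqExperiment", function(object) {
  msgs <- character(0)
  if (!"cq" %in% SummarizedExperiment::assayNames(object))
    msgs <- c(msgs, "assay 'cq' is required")
  else if (!is.numeric(SummarizedExperiment::assay(object, "cq")))
    msgs <- c(msgs, "assay 'cq' must be numeric")
  if (length(msgs)) msgs else TRUE
})

#' Construct a CqExperiment
#'
#' @param cq Numeric genes x samples matrix of Cq values (`NA` =
#'   undetected).
#' @param colData Optional [S4Vectors::DataFrame] of sample annotations
#'   (e.g. `stress`, `time_h`).
#' @return A [CqExperiment-class] object.
#' @export
CqExperiment <- function(cq, colData = NULL) {
  if (is.null(colData))
    colData <- S4Vectors::DataFrame(sample = colnames(cq),
                                    row.names = colnames(cq))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(cq = cq), colData = colData)
  new("CqExperiment", se)
}

#' @rdname CqExperiment-accessors
#' @export
setGeneric("cqValues", function(x) standardGeneric("cqValues"))

#' Accessors for CqExperiment
#'
#' @param x A [CqExperiment-class].
#' @return `cqValues` returns the Cq matrix.
#' @name CqExperiment-accessors
NULL

#' @rdname CqExperiment-accessors
setMethod("cqValues", "CqExperiment", function(x)
  SummarizedExperiment::assay(x, "cq"))
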