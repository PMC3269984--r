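#' Read a transcript (unigene) set from a FASTA file
#'
#' Sequences are upper-cased and U is normalized to T, so transcripts are
#' held in the DNA alphabet internally (mature miRNAs supplied as RNA are
#' handled the same way and rendered back as RNA in reports).  The record
#' identifier is the header up to the first whitespace; any remainder is
#' kept in the `description` metadata column.  Metadata columns `source`
#' (contig/singleton/synthetic) and `read_count` are initialized and can be
#' filled from assembler output.
#'
#' @param path Path to a FASTA file.
#' @param source Provenance tag recorded for every record, one of
#'   `"contig"`, `"singleton"`, `"synthetic"`.
#' @return A [Biostrings::DNAStringSet] with metadata columns `description`,
#'   `source`, `read_count`.
#' @export
readTranscripts <- function(path, source = c("contig", "singleton",
                                             "synthetic")) {
  source <- match.arg(source)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  .validateFastaLines(path)
  raw <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("malformed FASTA ", path, ": ",
                                           conditionMessage(e)))
  if (length(raw) == 0L) {
    warning("empty FASTA file: ", path)
    out <- Biostrings::DNAStringSet()
    S4Vectors::mcols(out) <- S4Vectors::DataFrame(
      description = character(0), source = character(0),
      read_count = integer(0))
    return(out)
  }
  seqs <- chartr("Uu", "Tt", toupper(as.character(raw)))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("invalid sequence characters in record(s): ",
         paste(utils::head(sub("\\s.*", "", names(raw)[bad]), 5),
               collapse = ", "))
  ids <- sub("\\s.*", "", names(raw))
  desc <- ifelse(grepl("\\s", names(raw)), sub("^\\S+\\s+", "", names(raw)),
                 "")
  if (anyDuplicated(ids))
    stop("duplicate transcript ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(
    description = desc, source = rep(source, length(out)),
    read_count = rep(NA_integer_, length(out)))
  out
}

# structural validation with line numbers, ahead of the actual parse
.validateFastaLines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) return(invisible(TRUE))
  nonempty <- which(nzchar(trimws(lines)))
  if (length(nonempty) == 0L) return(invisible(TRUE))
  if (!startsWith(trimws(lines[nonempty[1]]), ">"))
    stop("malformed FASTA: line ", nonempty[1],
         " contains sequence data before any header")
  headers <- which(startsWith(trimws(lines), ">"))
  for (h in headers) {
    nxt <- headers[headers > h]
    blockEnd <- if (length(nxt)) nxt[1] - 1L else length(lines)
    block <- lines[seq(h + 1L, length.out = max(0L, blockEnd - h))]
    if (!any(nzchar(trimws(block))))
      stop("malformed FASTA: record starting at line ", h,
           " has an empty sequence")
  }
  invisible(TRUE)
}

#' Write transcripts to FASTA (60-column wrap)
#'
#' @param x A [Biostrings::DNAStringSet] (or other XStringSet).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeTranscripts <- function(x, path) {
  nm <- names(x)
  desc <- S4Vectors::mcols(x)$description
  if (!is.null(desc) && any(nzchar(desc))) {
    nm <- ifelse(nzchar(desc), paste(nm, desc), nm)
    y <- x
    names(y) <- nm
    Biostrings::writeXStringSet(y, path, width = 60L)
  } else {
    Biostrings::writeXStringSet(x, path, width = 60L)
  }
  invisible(path)
}

#' G+C fraction of a sequence
#'
#' Computes `(G + C) / (A + C + G + T)`; ambiguous `N` bases are excluded
#' from both numerator and denominator.
#'
#' @param seq Character vector of sequences, or a
#'   [Biostrings::DNAStringSet]/[Biostrings::DNAString].
#' @return Numeric vector of fractions in `[0, 1]`.
#' @examples
#' gcFraction(c("GGCC", "ATAT", "ATGCN"))
#' @export
gcFraction <- function(seq) {
  if (is(seq, "DNAString")) seq <- Biostrings::DNAStringSet(seq)
  if (!is(seq, "DNAStringSet"))
    seq <- Biostrings::DNAStringSet(chartr("Uu", "Tt", toupper(
      as.character(seq))))
  if (any(Biostrings::width(seq) == 0L)) stop("empty sequence")
  f <- Biostrings::letterFrequency(seq, c("A", "C", "G", "T"))
  denom <- rowSums(f)
  if (any(denom == 0))
    stop("GC fraction undefined: sequence contains no unambiguous base")
  unname((f[, "C"] + f[, "G"]) / denom)
}

#' Reverse complement
#'
#' Thin wrapper over [Biostrings::reverseComplement()] that accepts plain
#' character input and returns the same type it was given.  `N` maps to `N`.
#'
#' @param seq Character vector or a DNAString/DNAStringSet.
#' @return The reverse complement, same type as the input.
#' @examples
#' revComp("ATGC") # "GCAT"
#' @export
revComp <- function(seq) {
  if (is(seq, "DNAString") || is(seq, "DNAStringSet"))
    return(Biostrings::reverseComplement(seq))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(
    toupper(seq))))
}
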