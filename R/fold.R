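#' Fold an RNA sequence into its minimum-free-energy secondary structure
#'
#' Dynamic-programming minimum-free-energy folding (Zuker-type recursions,
#' no pseudoknots) under the nearest-neighbour model of
#' [foldEnergyParams()].  The open chain (energy 0) is always admissible, so
#' the returned energy is never positive.  Hairpin loops have at least three
#' unpaired bases; G:U wobbles are valid pairs.
#'
#' @param seq A single sequence (character scalar, [Biostrings::DNAString] or
#'   [Biostrings::RNAString]).  DNA input is read as its RNA transcript
#'   (T treated as U).
#' @param params Energy parameter list, see [foldEnergyParams()].
#' @param minLength,maxLength Admissible sequence length range.
#' @return A list with elements `structure` (dot-bracket string) and `mfe`
#'   (kcal/mol, `<= 0`).
#' @examples
#' rnaFold("GGGGAAAACCCC")
#' @export
rnaFold <- function(seq, params = foldEnergyParams(),
                    minLength = 10L, maxLength = 1000L) {
  s <- toupper(as.character(seq))
  stopifnot(length(s) == 1L)
  n <- nchar(s)
  if (n < minLength)
    stop("sequence of length ", n, " is below the folding minimum (",
         minLength, " nt)")
  if (n > maxLength)
    stop("sequence of length ", n, " exceeds the folding cap (",
         maxLength, " nt)")
  code <- .encodeRna(s)
  res <- .foldCpp(code, params)
  res$mfe <- round(res$mfe, 10)
  res
}

# A=0, C=1, G=2, U/T=3; any other letter (incl. N) is given code -1 and can
# never pair
.encodeRna <- function(s) {
  v <- strsplit(chartr("T", "U", toupper(s)), "")[[1]]
  code <- match(v, c("A", "C", "G", "U")) - 1L
  code[is.na(code)] <- -1L
  code
}

#' Minimal folding free energy index (MFEI)
#'
#' The MFEI normalizes the folding energy of a candidate precursor for both
#' its length and its base composition:
#' `MFEI = (|MFE| / length * 100) / GC%`.  miRNA precursors typically show
#' markedly higher MFEI than mRNAs, tRNAs or rRNAs, which makes the index a
#' useful screen for hairpin candidates.
#'
#' @param mfe Minimum free energy in kcal/mol (`<= 0`).
#' @param lengthNt Sequence length in nucleotides (`> 0`).
#' @param gcPercent G+C percentage in `(0, 100]`.
#' @return The (non-negative) MFEI value.
#' @examples
#' mfei(-49.5, 100, 50) # 0.99
#' @export
mfei <- function(mfe, lengthNt, gcPercent) {
  if (any(lengthNt <= 0)) stop("lengthNt must be positive")
  if (any(mfe > 0)) stop("mfe must be <= 0")
  if (any(gcPercent <= 0 | gcPercent > 100))
    stop("gcPercent must be in (0, 100]; MFEI is undefined at GC = 0")
  (abs(mfe) / lengthNt * 100) / gcPercent
}
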