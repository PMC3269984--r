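# Independent reference implementations used for validation.  These are
# deliberately naive (brute-force enumeration, direct formula evaluation)
# and share no code with the production paths they are compared against;
# they are internal and exercised by the test suite and the acceptance
# script.

# exhaustive ORF oracle: every (strand, frame, ATG) with its first in-frame
# stop; per (strand, frame, stop-or-none) the earliest ATG is the maximal ORF
.oracleOrfs <- function(seq) {
  s <- chartr("Uu", "Tt", toupper(as.character(seq)))
  n <- nchar(s)
  stops <- c("TAA", "TAG", "TGA")
  recs <- list()
  for (strand in c("+", "-")) {
    str <- if (strand == "+") s else revComp(s)
    for (frame in 0:2) {
      if (frame + 3L > n) next
      starts <- seq(frame + 1L, n - 2L, by = 3L)
      cods <- substring(str, starts, starts + 2L)
      atgIdx <- which(cods == "ATG")
      seen <- character(0)
      for (a in atgIdx) {
        stopAfter <- which(cods %in% stops & seq_along(cods) >= a)
        if (length(stopAfter)) {
          st <- stopAfter[1]
          key <- paste(strand, frame, st)
          if (key %in% seen) next
          seen <- c(seen, key)
          lo <- starts[a] - 1L
          hi <- starts[st] + 2L
          rec <- data.frame(strand = strand, frame = frame, start = lo,
                            end = hi, aa_length = (hi - lo) %/% 3L - 1L,
                            complete = TRUE)
        } else {
          key <- paste(strand, frame, "open")
          if (key %in% seen) next
          seen <- c(seen, key)
          lo <- starts[a] - 1L
          hi <- starts[length(cods)] + 2L
          rec <- data.frame(strand = strand, frame = frame, start = lo,
                            end = hi, aa_length = (hi - lo) %/% 3L,
                            complete = FALSE)
        }
        if (strand == "-") {
          tmp <- n - rec$end
          rec$end <- n - rec$start
          rec$start <- tmp
        }
        recs[[length(recs) + 1L]] <- rec
      }
    }
  }
  if (!length(recs))
    return(data.frame(strand = character(0), frame = integer(0),
                      start = integer(0), end = integer(0),
                      aa_length = integer(0), complete = logical(0)))
  out <- do.call(rbind, recs)
  out[order(out$strand, out$frame, out$start), ]
}

# plain-R Smith-Waterman with affine gaps (gap of length L costs
# open + L * ext), score only; independent of the Biostrings path
.oracleLocalAlign <- function(q, s, match = 2, mismatch = -3,
                              gapOpen = 5, gapExt = 2) {
  qv <- strsplit(toupper(q), "")[[1]]
  sv <- strsplit(toupper(s), "")[[1]]
  n <- length(qv); m <- length(sv)
  NEG <- -1e9
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1) # gap in query direction
  F <- matrix(NEG, n + 1, m + 1)
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      E[i + 1, j + 1] <- max(H[i, j + 1] - gapOpen - gapExt,
                             E[i, j + 1] - gapExt)
      F[i + 1, j + 1] <- max(H[i + 1, j] - gapOpen - gapExt,
                             F[i + 1, j] - gapExt)
      sub <- if (qv[i] == sv[j] && qv[i] != "N") match else mismatch
      H[i + 1, j + 1] <- max(0, H[i, j] + sub, E[i + 1, j + 1],
                             F[i + 1, j + 1])
      if (H[i + 1, j + 1] > best) best <- H[i + 1, j + 1]
    }
  }
  best
}

# -- folding oracle: exhaustive structure enumeration + independent loop
#    decomposition under the same energy tables ---------------------------

.oraclePairOk <- function(a, b) {
  p <- paste0(a, b)
  p %in% c("AU", "UA", "CG", "GC", "GU", "UG")
}

# all pseudoknot-free structures over [i, j] (1-based), min hairpin loop 3
.enumStructures <- function(v, i, j) {
  if (j - i < 4L) return(list(list()))
  out <- .enumStructures(v, i + 1L, j) # i unpaired
  for (k in seq(i + 4L, j)) {
    if (!.oraclePairOk(v[i], v[k])) next
    inner <- .enumStructures(v, i + 1L, k - 1L)
    outer <- .enumStructures(v, k + 1L, j)
    for (a in inner) for (b in outer)
      out[[length(out) + 1L]] <- c(a, b, list(c(i, k)))
  }
  out
}

.oracleLoopTables <- function(par) {
  list(
    hairpin = function(l) {
      if (l < 3) return(Inf)
      if (l <= 30) par$hairpin[l] else
        par$hairpin[30] + par$js_coef * log(l / 30)
    },
    bulge = function(l) if (l >= 1 && l <= 30) par$bulge[l] else Inf,
    internal = function(l1, l2) {
      l <- l1 + l2
      if (l > par$max_loop || l > 30) return(Inf)
      par$internal[l] + min(par$asym_max, par$asym * abs(l1 - l2))
    })
}

# energy of one enumerated structure by loop decomposition
.oracleStructureEnergy <- function(v, pairs, par) {
  if (!length(pairs)) return(0)
  tab <- .oracleLoopTables(par)
  partner <- rep(NA_integer_, length(v))
  for (p in pairs) { partner[p[1]] <- p[2]; partner[p[2]] <- p[1] }
  pairName <- function(i, j) paste0(v[i], v[j])
  total <- 0
  for (p in pairs) {
    i <- p[1]; j <- p[2]
    # direct children and unpaired count inside the loop closed by (i, j)
    kids <- list(); unpaired <- 0L
    q <- i + 1L
    while (q < j) {
      if (is.na(partner[q])) { unpaired <- unpaired + 1L; q <- q + 1L }
      else { kids[[length(kids) + 1L]] <- c(q, partner[q])
             q <- partner[q] + 1L }
    }
    if (length(kids) == 0L) {
      total <- total + tab$hairpin(j - i - 1L)
    } else if (length(kids) == 1L) {
      k <- kids[[1]]
      l1 <- k[1] - i - 1L; l2 <- j - k[2] - 1L
      if (l1 == 0L && l2 == 0L) {
        total <- total + par$stack[pairName(i, j), pairName(k[1], k[2])]
      } else if (l1 == 0L || l2 == 0L) {
        l <- l1 + l2
        e <- tab$bulge(l)
        if (l == 1L && is.finite(e))
          e <- e + par$stack[pairName(i, j), pairName(k[1], k[2])]
        total <- total + e
      } else {
        total <- total + tab$internal(l1, l2)
      }
    } else {
      total <- total + par$multi_a + par$multi_b * (length(kids) + 1L) +
        par$multi_c * unpaired
    }
    if (!is.finite(total)) return(Inf)
  }
  total
}

# minimum energy over all enumerated structures (sequences <= ~14 nt)
.oracleFoldMfe <- function(seq, par = foldEnergyParams()) {
  v <- strsplit(chartr("Tt", "Uu", toupper(as.character(seq))), "")[[1]]
  structs <- .enumStructures(v, 1L, length(v))
  best <- 0
  for (st in structs) {
    e <- .oracleStructureEnergy(v, st, par)
    if (e < best) best <- e
  }
  best
}

# -- duplex penalty oracle: recursive enumeration of all gapped pairings --

.oracleDuplexPenalty <- function(mirna, site, schema = penaltySchema()) {
  mv <- strsplit(chartr("Tt", "Uu", toupper(mirna)), "")[[1]]
  sv <- rev(strsplit(chartr("Tt", "Uu", toupper(site)), "")[[1]])
  L <- length(mv); S <- length(sv)
  mult <- function(p) if (p >= schema$seed_start && p <= schema$seed_end)
    schema$seed_multiplier else 1
  pcost <- function(m, b, pos) {
    wc <- (m == "A" && b == "U") || (m == "U" && b == "A") ||
      (m == "C" && b == "G") || (m == "G" && b == "C")
    gu <- (m == "G" && b == "U") || (m == "U" && b == "G")
    (if (wc) 0 else if (gu) schema$gu_penalty else
      schema$mismatch_penalty) * mult(pos)
  }
  rec <- function(i, j, g) {
    if (i == L && j == S) return(0)
    best <- Inf
    if (i < L && j < S)
      best <- min(best, pcost(mv[i + 1], sv[j + 1], i + 1) +
                    rec(i + 1, j + 1, g))
    if (g < schema$max_gaps) {
      if (i < L)
        best <- min(best, schema$gap_penalty * mult(i + 1) +
                      rec(i + 1, j, g + 1))
      if (j < S)
        best <- min(best, schema$gap_penalty * mult(min(i + 1, L)) +
                      rec(i, j + 1, g + 1))
    }
    best
  }
  rec(0L, 0L, 0L)
}

# -- seed-free sliding Hamming scan for the mature-miRNA search -----------

.oracleMatureScan <- function(tseq, tid, mseq, mid, maxMismatch = 3L) {
  s <- toupper(as.character(tseq))
  m <- chartr("Uu", "Tt", toupper(as.character(mseq)))
  L <- nchar(m)
  n <- nchar(s)
  sv <- strsplit(s, "")[[1]]
  out <- list()
  for (strand in c("+", "-")) {
    pv <- strsplit(if (strand == "+") m else revComp(m), "")[[1]]
    if (n < L) next
    for (st in 0:(n - L)) {
      mm <- sum(sv[(st + 1):(st + L)] != pv)
      if (mm <= maxMismatch)
        out[[length(out) + 1L]] <- data.frame(
          transcript_id = tid, known_mirna_id = mid,
          mature_seq = chartr("T", "U",
                              paste(sv[(st + 1):(st + L)], collapse = "")),
          mismatches = mm, strand = strand, start = st, end = st + L)
    }
  }
  if (!length(out))
    return(data.frame(transcript_id = character(0),
                      known_mirna_id = character(0),
                      mature_seq = character(0), mismatches = integer(0),
                      strand = character(0), start = integer(0),
                      end = integer(0)))
  do.call(rbind, out)
}
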