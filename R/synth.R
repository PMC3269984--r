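#' Design of a synthetic transcriptome with planted ground truth
#'
#' The generator emulates the composition of an EST-era plant unigene set:
#' coding transcripts with planted >= 100-aa ORFs plus UTRs, mlncRNA-like
#' transcripts whose ORFs are suppressed below the coding cutoff,
#' housekeeping-RNA copies of a bundled reference, hairpin precursors
#' embedding bundled mature miRNAs, target transcripts carrying sites of
#' controlled duplex penalty, homologous mlncRNA families (mutated copies
#' of a seed), and short fragments.  mlncRNA lengths default to the
#' 300-700 bp range typical of such assemblies.
#'
#' @param seed Integer RNG seed.
#' @param nCoding Number of coding transcripts (half are "annotated": their
#'   translations enter the generated protein reference).
#' @param nMlnc Number of mlncRNA-like transcripts; the first
#'   `sum(familySizes)` of them are family members.
#' @param nShort Number of short (< 300 bp) fragments.
#' @param nHk Number of housekeeping-RNA transcripts.
#' @param nPrecursors Number of miRNA-precursor transcripts.
#' @param nTargets Number of target-site transcripts.
#' @param familySizes Integer vector of planted family sizes (each 2-8).
#' @param mutationRate Per-base substitution rate within families
#'   (`[0, 0.3]`).
#' @param gcRange Background GC-content interval.
#' @param mlncLenRange,shortLenRange Length ranges (bp).
#' @param cqNoiseSd Gaussian Cq noise per technical replicate (cycles).
#' @param nResponseGenes Genes per stress series in [generateCq()].
#' @return Validated design list.
#' @export
synthDesign <- function(seed = 101L, nCoding = 50L, nMlnc = 80L,
                        nShort = 40L, nHk = 8L, nPrecursors = 10L,
                        nTargets = 14L, familySizes = c(2L, 3L, 4L, 5L, 8L),
                        mutationRate = 0.05, gcRange = c(0.35, 0.55),
                        mlncLenRange = c(300L, 700L),
                        shortLenRange = c(120L, 299L),
                        cqNoiseSd = 0.2, nResponseGenes = 60L) {
  counts <- c(nCoding, nMlnc, nShort, nHk, nPrecursors, nTargets)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (length(familySizes) && any(familySizes < 2 | familySizes > 8))
    stop("family sizes must be between 2 and 8")
  if (sum(familySizes) > nMlnc)
    stop("family members exceed nMlnc")
  if (mutationRate < 0 || mutationRate > 0.3)
    stop("mutationRate must be in [0, 0.3]")
  if (mlncLenRange[1] < 300)
    stop("contradictory design: mlncRNAs shorter than 300 bp would be ",
         "classified as short fragments")
  if (shortLenRange[2] >= 300)
    stop("contradictory design: short fragments must be < 300 bp")
  list(seed = as.integer(seed), n_coding = as.integer(nCoding),
       n_mlnc = as.integer(nMlnc), n_short = as.integer(nShort),
       n_hk = as.integer(nHk), n_precursors = as.integer(nPrecursors),
       n_targets = as.integer(nTargets),
       family_sizes = as.integer(familySizes),
       mutation_rate = mutationRate, gc_range = gcRange,
       mlnc_len_range = as.integer(mlncLenRange),
       short_len_range = as.integer(shortLenRange),
       cq_noise_sd = cqNoiseSd,
       n_response_genes = as.integer(nResponseGenes))
}

#' Bundled mature miRNA set
#'
#' The mature miRNA sequences used by the generator and the worked
#' examples (13 conserved plant mature miRNAs, DNA-normalized on read).
#'
#' @return A [Biostrings::DNAStringSet].
#' @export
bundledMatureMirnas <- function() {
  readTranscripts(system.file("extdata", "mature_mirnas.fasta",
                              package = "mlncTools"), source = "synthetic")
}

#' Bundled synthetic housekeeping-RNA reference
#'
#' A small synthetic stand-in for a structural-RNA reference set
#' (tRNA/snoRNA-class); fixed sequences, not biological.
#'
#' @return A [Biostrings::DNAStringSet].
#' @export
bundledHkReference <- function() {
  readTranscripts(system.file("extdata", "synthetic_hk_reference.fasta",
                              package = "mlncTools"), source = "synthetic")
}

.BASES <- c("A", "C", "G", "T")

.randSeq <- function(n, gc) {
  paste(sample(.BASES, n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

.NONSTOP <- setdiff(apply(expand.grid(.BASES, .BASES, .BASES), 1, paste,
                          collapse = ""), c("TAA", "TAG", "TGA"))

# suppress ORFs >= aaThreshold by seeding in-frame stop codons, leaving
# protected forward-strand intervals (list of c(start, end), 0-based
# half-open) untouched; returns NULL when impossible
.breakOrfs <- function(s, aaThreshold = 80L, protect = list(),
                       maxIter = 100L) {
  overlaps <- function(a, b) a[1] < b[2] && b[1] < a[2]
  for (iter in seq_len(maxIter)) {
    orfs <- findOrfs(s)
    orfs <- orfs[orfs$aa_length >= aaThreshold, , drop = FALSE]
    if (nrow(orfs) == 0L) return(s)
    o <- orfs[1L, ]
    ncod <- (o$end - o$start) %/% 3L
    placed <- FALSE
    # try codon slots from the middle outwards
    ord <- order(abs(seq_len(ncod) - (ncod / 2)))
    for (k in ord - 1L) {
      fwd <- if (o$strand == "+")
        c(o$start + 3L * k, o$start + 3L * k + 3L)
      else
        c(o$end - 3L * (k + 1L), o$end - 3L * k)
      if (fwd[1] < 3L || fwd[2] > nchar(s)) next  # keep first codon intact
      if (any(vapply(protect, overlaps, logical(1), a = fwd))) next
      stopCodon <- if (o$strand == "+") "TAA" else "TTA"
      substr(s, fwd[1] + 1L, fwd[2]) <- stopCodon
      placed <- TRUE
      break
    }
    if (!placed) return(NULL)
  }
  NULL
}

.mutateSeq <- function(s, rate) {
  v <- strsplit(s, "")[[1]]
  hit <- which(stats::runif(length(v)) < rate)
  for (i in hit) v[i] <- sample(setdiff(.BASES, v[i]), 1)
  paste(v, collapse = "")
}

.drawGc <- function(design) stats::runif(1, design$gc_range[1],
                                         design$gc_range[2])

#' Generate a synthetic transcriptome with planted truth
#'
#' See [synthDesign()] for the planted components.  Fully reproducible for
#' a fixed design seed.  Every planted precursor is verified to pass
#' [evaluatePrecursor()] (with bounded resampling) and every mlncRNA-class
#' transcript is verified to carry no ORF of 80 aa or more, so planted
#' classes are recoverable by construction rather than by chance.
#'
#' @param design A [synthDesign()] list.
#' @return A list: `transcripts` (named [Biostrings::DNAStringSet]),
#'   `truth` (`data.frame`: `id`, `class`, `role`, `family`, `mirna_id`,
#'   `site_start`, `site_end`, `site_penalty`), `proteins`
#'   ([Biostrings::AAStringSet] reference for the annotation step), `hk`
#'   (housekeeping reference) and `matures` (mature miRNA set).
#' @export
generateTranscriptome <- function(design = synthDesign()) {
  set.seed(design$seed)
  matures <- bundledMatureMirnas()
  hkRef <- bundledHkReference()
  seqs <- character(0); ids <- character(0)
  truth <- list()
  addTruth <- function(id, class, role, family = NA_character_,
                       mirna = NA_character_, ss = NA_integer_,
                       se = NA_integer_, pen = NA_real_) {
    truth[[length(truth) + 1L]] <<- data.frame(
      id = id, class = class, role = role, family = family,
      mirna_id = mirna, site_start = ss, site_end = se, site_penalty = pen)
  }

  proteins <- character(0); protIds <- character(0)
  nAnn <- design$n_coding %/% 2L
  for (i in seq_len(design$n_coding)) {
    gc <- .drawGc(design)
    aaLen <- sample(110:160, 1)
    orf <- paste0("ATG", paste(sample(.NONSTOP, aaLen, replace = TRUE),
                               collapse = ""),
                  sample(c("TAA", "TAG", "TGA"), 1))
    s <- paste0(.randSeq(sample(40:150, 1), gc), orf,
                .randSeq(sample(40:150, 1), gc))
    annotated <- i <= nAnn
    id <- sprintf(if (annotated) "CODA_%03d" else "CODN_%03d", i)
    if (annotated) {
      aa <- as.character(Biostrings::translate(
        Biostrings::DNAString(substr(orf, 1, nchar(orf) - 3))))
      proteins <- c(proteins, aa)
      protIds <- c(protIds, paste0("PROT_", id))
    }
    ids <- c(ids, id); seqs <- c(seqs, s)
    addTruth(id, if (annotated) "ANNOTATED_CODING" else "NOVEL_CODING",
             "coding")
  }

  # mlncRNAs: family members first, then singletons
  fam <- 0L; made <- 0L
  for (size in design$family_sizes) {
    fam <- fam + 1L
    gc <- .drawGc(design)
    seedLen <- sample(design$mlnc_len_range[1]:design$mlnc_len_range[2], 1)
    seedSeq <- NULL
    while (is.null(seedSeq))
      seedSeq <- .breakOrfs(.randSeq(seedLen, gc))
    for (k in seq_len(size)) {
      made <- made + 1L
      s <- NULL
      while (is.null(s)) {
        s <- if (k == 1L) seedSeq else
          .breakOrfs(.mutateSeq(seedSeq, design$mutation_rate))
      }
      id <- sprintf("MLNC_%03d", made)
      ids <- c(ids, id); seqs <- c(seqs, s)
      addTruth(id, "MLNC_CANDIDATE", "mlnc",
               family = sprintf("TRUEFAM%02d", fam))
    }
  }
  while (made < design$n_mlnc) {
    made <- made + 1L
    gc <- .drawGc(design)
    s <- NULL
    while (is.null(s))
      s <- .breakOrfs(.randSeq(
        sample(design$mlnc_len_range[1]:design$mlnc_len_range[2], 1), gc))
    id <- sprintf("MLNC_%03d", made)
    ids <- c(ids, id); seqs <- c(seqs, s)
    addTruth(id, "MLNC_CANDIDATE", "mlnc")
  }

  for (i in seq_len(design$n_short)) {
    id <- sprintf("SHRT_%03d", i)
    s <- .randSeq(sample(design$short_len_range[1]:design$short_len_range[2],
                         1), .drawGc(design))
    ids <- c(ids, id); seqs <- c(seqs, s)
    addTruth(id, "SHORT_UNANNOTATED", "short")
  }

  for (i in seq_len(design$n_hk)) {
    ref <- as.character(hkRef[[((i - 1L) %% length(hkRef)) + 1L]])
    gc <- .drawGc(design)
    s <- NULL
    while (is.null(s)) {
      left <- .randSeq(sample(100:150, 1), gc)
      insert <- .mutateSeq(ref, 0.02)
      right <- .randSeq(sample(100:150, 1), gc)
      cand <- paste0(left, insert, right)
      prot <- list(c(nchar(left), nchar(left) + nchar(insert)))
      s <- .breakOrfs(cand, protect = prot)
    }
    id <- sprintf("HKRNA_%03d", i)
    ids <- c(ids, id); seqs <- c(seqs, s)
    addTruth(id, "HOUSEKEEPING_NPCRNA", "housekeeping")
  }

  # precursors: mature + short loop + near-perfect star, random flanks;
  # verified against the precursor criteria before emission
  for (i in seq_len(design$n_precursors)) {
    mi <- ((i - 1L) %% length(matures)) + 1L
    m <- as.character(matures[[mi]])
    id <- sprintf("PREC_%03d", i)
    ok <- FALSE
    for (try in 1:20) {
      hp <- .buildHairpin(m, nWobble = sample(0:2, 1))
      gc <- .drawGc(design)
      left <- .randSeq(sample(130:200, 1), gc)   # host stays >= 300 bp
      right <- .randSeq(sample(130:200, 1), gc)
      cand <- paste0(left, hp, right)
      prot <- list(c(nchar(left), nchar(left) + nchar(hp)))
      cand <- .breakOrfs(cand, protect = prot)
      if (is.null(cand)) next
      hitStart <- nchar(left)
      hit <- list(transcript_id = id, start = hitStart,
                  end = hitStart + nchar(m), strand = "+")
      ev <- evaluatePrecursor(cand, hit)
      if (isAccepted(ev)) {
        ids <- c(ids, id); seqs <- c(seqs, cand)
        addTruth(id, "MLNC_CANDIDATE", "precursor",
                 mirna = names(matures)[mi],
                 ss = hitStart, se = hitStart + nchar(m))
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("failed to build an acceptable precursor for ",
                  names(matures)[mi])
  }

  penaltyMenu <- c(0, 0.5, 1, 1.5, 2, 2.5, 3)
  for (i in seq_len(design$n_targets)) {
    mi <- ((i - 1L) %% length(matures)) + 1L
    m <- as.character(matures[[mi]])
    want <- penaltyMenu[((i - 1L) %% length(penaltyMenu)) + 1L]
    site <- .buildTargetSite(m, want)
    gc <- .drawGc(design)
    id <- sprintf("TARG_%03d", i)
    s <- NULL
    while (is.null(s)) {
      left <- .randSeq(sample(150:250, 1), gc)   # host stays >= 300 bp
      right <- .randSeq(sample(150:250, 1), gc)
      cand <- paste0(left, site$site, right)
      prot <- list(c(nchar(left), nchar(left) + nchar(site$site)))
      s <- .breakOrfs(cand, protect = prot)
    }
    ids <- c(ids, id); seqs <- c(seqs, s)
    addTruth(id, "MLNC_CANDIDATE", "target", mirna = names(matures)[mi],
             ss = nchar(left), se = nchar(left) + nchar(site$site),
             pen = site$penalty)
  }

  transcripts <- Biostrings::DNAStringSet(stats::setNames(seqs, ids))
  S4Vectors::mcols(transcripts) <- S4Vectors::DataFrame(
    description = rep("", length(transcripts)),
    source = rep("synthetic", length(transcripts)),
    read_count = sample(2:50, length(transcripts), replace = TRUE))
  prot <- Biostrings::AAStringSet(stats::setNames(proteins, protIds))
  list(transcripts = transcripts,
       truth = do.call(rbind, truth),
       proteins = prot, hk = hkRef, matures = matures)
}

# mature + loop + star hairpin; wobbles are planted on the star strand at
# positions facing a mature G or U
.buildHairpin <- function(m, nWobble = 1L, loopLen = NULL) {
  if (is.null(loopLen)) loopLen <- sample(4:8, 1)
  loop <- paste(sample(c("A", "C", "T"), loopLen, replace = TRUE),
                collapse = "")
  star <- strsplit(revComp(m), "")[[1]]
  mv <- strsplit(m, "")[[1]]
  L <- length(mv)
  eligible <- which(mv %in% c("G", "T"))
  if (nWobble > 0 && length(eligible)) {
    pos <- sample(eligible, min(nWobble, length(eligible)))
    for (p in pos) {
      sp <- L - p + 1L  # star index facing mature position p
      star[sp] <- if (mv[p] == "G") "T" else "G"
    }
  }
  paste0(m, loop, paste(star, collapse = ""))
}

# write a target site of prescribed duplex penalty by working backwards
# from the schema (seed positions 2-13 doubled); returns the site and the
# penalty actually planted
.buildTargetSite <- function(m, penalty, schema = penaltySchema()) {
  mv <- strsplit(m, "")[[1]]
  L <- length(mv)
  site <- strsplit(revComp(m), "")[[1]] # site index L-p+1 faces miRNA pos p
  seedPos <- schema$seed_start:schema$seed_end
  nonSeed <- setdiff(seq_len(L), seedPos)
  guEligible <- function(pos) mv[pos] %in% c("G", "T")
  used <- integer(0)
  planted <- 0
  applyMod <- function(pos, kind) {
    sp <- L - pos + 1L
    if (kind == "gu") {
      site[sp] <<- if (mv[pos] == "G") "T" else "G"
    } else {
      site[sp] <<- switch(mv[pos], A = "C", C = "A", G = "A", T = "C")
    }
    used <<- c(used, pos)
    mult <- if (pos %in% seedPos) schema$seed_multiplier else 1
    planted <<- planted + mult *
      (if (kind == "gu") schema$gu_penalty else schema$mismatch_penalty)
  }
  pick <- function(pool, needGu = FALSE) {
    pool <- setdiff(pool, used)
    if (needGu) pool <- pool[guEligible(pool)]
    if (!length(pool)) return(NA_integer_)
    if (length(pool) == 1L) pool else sample(pool, 1)
  }
  remaining <- penalty
  while (remaining > 1e-9) {
    if (remaining >= 2 && !is.na(p <- pick(seedPos))) {
      applyMod(p, "mm"); remaining <- remaining - 2
    } else if (remaining >= 1 && !is.na(p <- pick(nonSeed))) {
      applyMod(p, "mm"); remaining <- remaining - 1
    } else if (remaining >= 0.5 && !is.na(p <- pick(nonSeed, TRUE))) {
      applyMod(p, "gu"); remaining <- remaining - 0.5
    } else if (remaining >= 1 && !is.na(p <- pick(seedPos, TRUE))) {
      applyMod(p, "gu"); remaining <- remaining - 1
    } else {
      break # no eligible position left; planted < requested
    }
  }
  list(site = paste(site, collapse = ""), penalty = planted)
}

#' Generate a synthetic qPCR Cq data set with planted response types
#'
#' Emulates a stress time-course experiment (0/1/5/10/24 h, technical
#' triplicates): a stable reference gene with constant Cq, two less stable
#' reference candidates, and response genes whose fold-change profiles
#' follow the planted subclass templates (cold types A/B/C or dehydration
#' groups I/II/III).  Gaussian noise of `cq_noise_sd` cycles is added per
#' replicate measurement.
#'
#' @param design A [synthDesign()] list.
#' @param stress `"cold"` or `"dehydration"`.
#' @param nGenes Number of response genes (default
#'   `design$n_response_genes`).
#' @param noiseSd Override for the replicate noise (default
#'   `design$cq_noise_sd`).
#' @return A list: `cq` (a [CqExperiment-class], replicates averaged),
#'   `table` (long-format `data.frame` with replicates), `truth`
#'   (`data.frame`: `gene`, `stress`, `subclass`).
#' @export
generateCq <- function(design = synthDesign(),
                       stress = c("cold", "dehydration"),
                       nGenes = design$n_response_genes,
                       noiseSd = design$cq_noise_sd) {
  stress <- match.arg(stress)
  set.seed(design$seed + if (stress == "cold") 7L else 13L)
  times <- c(0, 1, 5, 10, 24)
  templates <- if (stress == "cold") list(
    A = c(1, 1.1, 0.9, 1.05, 0.95),
    B = c(1, 0.35, 0.3, 0.3, 0.6),
    C = c(1, 4, 1.5, 0.6, 0.4)
  ) else list(
    I = c(1, 1.1, 0.95, 1.2, 3.0),
    II = c(1, 0.3, 0.25, 0.3, 0.4),
    III = c(1, 3.0, 0.9, 0.5, 0.4)
  )
  subclass <- rep(names(templates), length.out = nGenes)
  genes <- sprintf("RESP_%s_%s_%04d", substr(stress, 1, 4), subclass,
                   seq_len(nGenes))
  samples <- paste0(toupper(substr(stress, 1, 1)), times)
  rows <- list()
  emit <- function(gene, cqPerSample) {
    for (si in seq_along(samples)) for (r in 1:3) {
      rows[[length(rows) + 1L]] <<- data.frame(
        gene = gene, sample = samples[si], stress = stress,
        time_h = times[si], replicate = r,
        cq = cqPerSample[si] + stats::rnorm(1, 0, noiseSd))
    }
  }
  # reference candidates: the stable reference has constant expression;
  # the two alternatives carry fixed condition-dependent shifts (their
  # instability is a property of the design, not of the noise draw)
  emit("UBQ", rep(20, length(samples)))
  emit("ACT", 21 + c(0, 0.6, -0.6, 0.9, -0.9))
  emit("R18S", 12 + c(0, -1.5, 1.8, -1.0, 2.0))
  for (g in seq_len(nGenes)) {
    base <- stats::runif(1, 22, 30)
    emit(genes[g], base - log2(templates[[subclass[g]]]))
  }
  tab <- do.call(rbind, rows)
  truth <- data.frame(gene = genes, stress = stress, subclass = subclass)
  list(cq = .cqFromLong(tab), table = tab, truth = truth)
}

.cqFromLong <- function(tab, undetectedCq = 40) {
  tab$cq[!is.finite(tab$cq) | tab$cq >= undetectedCq] <- NA_real_
  genes <- unique(tab$gene)
  samples <- unique(tab$sample)
  cq <- matrix(NA_real_, length(genes), length(samples),
               dimnames = list(genes, samples))
  agg <- stats::aggregate(cq ~ gene + sample, data = tab, FUN = mean,
                          na.action = stats::na.pass)
  cq[cbind(match(agg$gene, genes), match(agg$sample, samples))] <- agg$cq
  cd <- S4Vectors::DataFrame(sample = samples, row.names = samples)
  for (extra in c("stress", "time_h"))
    if (extra %in% names(tab))
      cd[[extra]] <- tab[[extra]][match(samples, tab$sample)]
  CqExperiment(cq, cd)
}

#' Shuffled-context hairpin decoys
#'
#' For each planted precursor, the transcript background is shuffled
#' (single-base permutation) and the mature sequence is re-planted
#' verbatim at its original offset: the homology scan still finds the hit,
#' but the context no longer folds into a qualifying hairpin.  Used to
#' measure the specificity of the precursor acceptance criteria.
#'
#' @param sim Output of [generateTranscriptome()].
#' @param nPerPrecursor Decoys per planted precursor (default 5).
#' @param seed RNG seed.
#' @return A list: `transcripts` (named character vector) and `hits`
#'   (`data.frame` of mature hits to evaluate).
#' @export
makePrecursorDecoys <- function(sim, nPerPrecursor = 5L, seed = 1L) {
  set.seed(seed)
  prec <- sim$truth[sim$truth$role == "precursor", , drop = FALSE]
  seqs <- character(0)
  hits <- list()
  for (i in seq_len(nrow(prec))) {
    s <- as.character(sim$transcripts[[prec$id[i]]])
    m <- as.character(sim$matures[[prec$mirna_id[i]]])
    for (k in seq_len(nPerPrecursor)) {
      shuf <- paste(sample(strsplit(s, "")[[1]]), collapse = "")
      substr(shuf, prec$site_start[i] + 1L,
             prec$site_start[i] + nchar(m)) <- m
      id <- sprintf("DECOY_%s_%02d", prec$id[i], k)
      seqs[id] <- shuf
      hits[[length(hits) + 1L]] <- data.frame(
        transcript_id = id, start = prec$site_start[i],
        end = prec$site_start[i] + nchar(m), strand = "+")
    }
  }
  list(transcripts = seqs, hits = do.call(rbind, hits))
}

#' Write synthetic data to disk
#'
#' @param sim Output of [generateTranscriptome()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeSynthData <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeTranscripts(sim$transcripts, file.path(dir, "transcripts.fasta"))
  Biostrings::writeXStringSet(sim$proteins,
                              file.path(dir, "proteins.fasta"), width = 60L)
  writeTranscripts(sim$hk, file.path(dir, "housekeeping.fasta"))
  writeTranscripts(sim$matures, file.path(dir, "matures.fasta"))
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
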