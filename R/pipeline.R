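#' Read and validate a pipeline run configuration
#'
#' The configuration is a YAML (or already-parsed list) with input paths
#' (`unigenes` required; `proteins`, `annotation_table`, `hk`, `matures`,
#' `known_ncrna`, `cq` optional), an `outdir`, a `seed`, and optional
#' parameter blocks `classify`, `schema`, `criteria`, `expression`
#' (arguments forwarded to [classifyParams()], [penaltySchema()],
#' [precursorCriteria()], and the expression functions).  All referenced
#' files must exist at validation time.
#'
#' @param config Path to a YAML file, or a list.
#' @return Validated configuration list.
#' @export
readRunConfig <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$unigenes))
    stop("config validation failed: 'unigenes' path is required")
  for (key in c("unigenes", "proteins", "annotation_table", "hk",
                "matures", "known_ncrna", "cq")) {
    p <- config[[key]]
    if (!is.null(p) && !file.exists(p))
      stop("config validation failed: '", key, "' file not found: ", p)
  }
  if (is.null(config$outdir)) stop("config requires an 'outdir'")
  if (is.null(config$seed)) config$seed <- 1L
  config$classify_params <- do.call(classifyParams,
                                    as.list(config$classify %||% list()))
  config$schema <- do.call(penaltySchema,
                           as.list(config$schema %||% list()))
  config$criteria <- do.call(precursorCriteria,
                             as.list(config$criteria %||% list()))
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full discovery pipeline
#'
#' Stage order: classification -> mlncRNA families and conservation ->
#' conserved-miRNA discovery -> target prediction -> mlncRNA/coding-gene
#' relations -> (optional) expression analysis.  Each stage writes a TSV
#' into `outdir`; a run manifest (package version, parameters, input
#' checksums, per-class counts) is written as `manifest.json`.  Outputs
#' are pure functions of inputs and configuration: re-running reproduces
#' the TSVs byte-identically (the manifest differs only in its timestamp).
#'
#' @param config A configuration (path or list), see [readRunConfig()].
#' @return Invisibly, a list with the per-stage results and the manifest.
#' @export
runPipeline <- function(config) {
  cfg <- readRunConfig(config)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  logMsg <- function(...) message("[mlncTools] ", ...)
  stage <- "read_inputs"
  result <- list()
  tryCatch({
    unigenes <- readTranscripts(cfg$unigenes)
    proteins <- if (!is.null(cfg$proteins))
      Biostrings::readAAStringSet(cfg$proteins) else NULL
    annTab <- if (!is.null(cfg$annotation_table))
      utils::read.delim(cfg$annotation_table) else NULL
    hk <- if (!is.null(cfg$hk)) readTranscripts(cfg$hk) else NULL
    matures <- if (!is.null(cfg$matures)) readTranscripts(cfg$matures)
      else NULL
    ncdb <- if (!is.null(cfg$known_ncrna))
      readTranscripts(cfg$known_ncrna) else NULL

    stage <- "classify"
    logMsg("classifying ", length(unigenes), " unigenes")
    cls <- classifySet(unigenes, proteins, annTab, hk,
                       cfg$classify_params)
    utils::write.table(cls$table, file.path(cfg$outdir, "classes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    result$classification <- cls

    mlncIds <- cls$table$id[cls$table$class == "MLNC_CANDIDATE"]
    codingIds <- cls$table$id[cls$table$class %in%
                                c("ANNOTATED_CODING", "NOVEL_CODING")]
    mlncs <- unigenes[mlncIds]

    stage <- "families"
    if (length(mlncs) > 0L) {
      logMsg("clustering ", length(mlncs), " mlncRNA candidates")
      fams <- clusterFamilies(mlncs)
      utils::write.table(fams$families,
                         file.path(cfg$outdir, "families.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      result$families <- fams
      cons <- conservationScreen(mlncs, ncdb)
      utils::write.table(cons, file.path(cfg$outdir, "conserved.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      result$conserved <- cons
    }

    stage <- "mirna"
    accepted <- list()
    if (!is.null(matures) && length(unigenes) > 0L) {
      logMsg("scanning for conserved mature miRNAs")
      hits <- scanKnownMirnas(unigenes, matures)
      cand <- list()
      for (i in seq_len(nrow(hits))) {
        ev <- evaluatePrecursor(unigenes[[hits$transcript_id[i]]],
                                hits[i, ], cfg$criteria)
        if (isAccepted(ev)) {
          cand[[length(cand) + 1L]] <- data.frame(
            transcript_id = hits$transcript_id[i],
            known_mirna_id = hits$known_mirna_id[i],
            mature_seq = hits$mature_seq[i],
            mismatches = hits$mismatches[i],
            arm = matureArm(ev), precursor_len = ev@length_nt,
            mfe = mfeValue(ev), gc_percent = ev@gc_percent,
            mfei = mfeiValue(ev))
        }
      }
      mir <- if (length(cand)) do.call(rbind, cand) else
        data.frame(transcript_id = character(0),
                   known_mirna_id = character(0),
                   mature_seq = character(0), mismatches = integer(0),
                   arm = character(0), precursor_len = integer(0),
                   mfe = numeric(0), gc_percent = numeric(0),
                   mfei = numeric(0))
      # one candidate per (transcript, mature): keep the best-scoring hit
      if (nrow(mir)) {
        key <- paste(mir$transcript_id, mir$known_mirna_id)
        mir <- do.call(rbind, lapply(split(mir, key), function(h)
          h[which.min(h$mismatches), , drop = FALSE]))
        rownames(mir) <- NULL
      }
      utils::write.table(mir, file.path(cfg$outdir, "mirna.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      result$mirna <- mir
      if (nrow(mir)) {
        famg <- groupMatureFamilies(
          stats::setNames(mir$mature_seq, mir$known_mirna_id))
        result$mirna_families <- famg
      }

      stage <- "targets"
      if (nrow(mir)) {
        logMsg("predicting targets for ", nrow(mir), " miRNA candidates")
        mseq <- stats::setNames(mir$mature_seq, mir$known_mirna_id)
        mseq <- mseq[!duplicated(names(mseq))]
        tg <- predictTargets(mseq, unigenes, cfg$schema)
        utils::write.table(tg, file.path(cfg$outdir, "targets.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        result$targets <- tg
      }
    }

    stage <- "relations"
    if (length(mlncs) > 0L && length(codingIds) > 0L) {
      logMsg("relating mlncRNAs to coding genes")
      orfTab <- do.call(rbind, lapply(codingIds, function(id) {
        o <- findOrfs(unigenes[[id]], id)
        if (nrow(o)) o[1L, ] else NULL
      }))
      rel <- relateMlncToCoding(mlncs, unigenes[codingIds], orfTab)
      utils::write.table(rel, file.path(cfg$outdir, "relations.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      result$relations <- rel
    }

    stage <- "expression"
    if (!is.null(cfg$cq)) {
      logMsg("expression analysis")
      cqe <- readCqTable(cfg$cq)
      refs <- intersect(c("UBQ", "ACT", "R18S"), rownames(cqValues(cqe)))
      if (length(refs) >= 2L) {
        stab <- genormM(cqe, refs)
        utils::write.table(stab, file.path(cfg$outdir, "stability.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        result$stability <- stab
      }
    }
  }, error = function(e) {
    marker <- file.path(cfg$outdir, "FAILED")
    writeLines(paste("stage:", stage), marker)
    stop("pipeline aborted at stage '", stage, "': ",
         conditionMessage(e), call. = FALSE)
  })

  manifest <- list(
    package = "mlncTools",
    version = as.character(utils::packageVersion("mlncTools")),
    seed = cfg$seed,
    parameters = list(classify = cfg$classify_params,
                      schema = cfg$schema, criteria = cfg$criteria),
    inputs = lapply(
      Filter(Negate(is.null),
             cfg[c("unigenes", "proteins", "annotation_table", "hk",
                   "matures", "known_ncrna", "cq")]),
      function(p) list(path = p, md5 = unname(tools::md5sum(p)))),
    counts = as.list(result$classification$counts),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(result, list(manifest = manifest)))
}
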