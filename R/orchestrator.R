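#' @include simulate.R
#' @importFrom tools md5sum
NULL

.readRecordsTsv <- function(path) {
  hdr <- utils::read.delim(path, nrows = 1L, check.names = FALSE,
                           quote = "", comment.char = "")
  cls <- ifelse(grepl("^(read_id$|seq_|qual_)", names(hdr)),
                "character", NA)
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                    quote = "", comment.char = "", na.strings = "NA",
                    colClasses = cls)
}

.writeRecordsTsv <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
}

# segment names whose per-base qualities must be carried (pass-through
# payloads of non-valued variables)
.passthroughSegments <- function(cfg) {
  unlist(lapply(Filter(function(v) !v@valued, cfg@variables),
                function(v) v@segments))
}

#' Interpret structured reads: extract, filter, correct, and build the
#' value tree
#'
#' Streams the input FASTQ tuple in chunks, applies the compiled matchers
#' (first declared structure wins), the quality policy, then merges the
#' per-chunk segment tallies and builds correction tables once over the
#' merged counts, so every artifact is independent of the chunking.
#' Corrected per-chunk record files, correction tables, rank-count curves,
#' the merged value tree and a run manifest are written under `outDir`.
#'
#' @param config a [PipelineConfig-class] or a configuration file path.
#' @param fastqs input FASTQ(.gz) paths in read-tuple order.
#' @param outDir output directory for intermediate artifacts.
#' @param chunkSize read tuples per chunk; defaults to the configuration's.
#' @return list with `manifest` (named counts), `correction`
#'   ([CorrectionTable-class]), `tree` ([ValueTree-class]), `tally` (merged
#'   [SegmentTally-class]) and `outDir`.
#' @export
runInterpret <- function(config, fastqs, outDir, chunkSize = NULL) {
  cfg <- if (is(config, "PipelineConfig")) config else
    parseConfig(path = config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(outDir, "corrected"), showWarnings = FALSE)
  configPath <- file.path(outDir, "config.txt")
  writeLines(formatConfig(cfg), configPath)
  if (is.null(chunkSize)) chunkSize <- cfg@chunkSize

  matchers <- lapply(cfg@structures, compileMatcher)
  needQual <- .passthroughSegments(cfg)
  governed <- as.character(
    unlist(lapply(Filter(function(v) v@correction != "none",
                         cfg@variables), function(v) v@segments)))

  chunks <- list()
  tallies <- list()
  nInput <- 0L; nMatched <- 0L; nQualityFail <- 0L
  perStructure <- setNames(integer(length(cfg@structures)),
                           vapply(cfg@structures, function(s) s@name, ""))
  streamReadTuples(fastqs, chunkSize, function(tup) {
    nInput <<- nInput + length(tup$ids)
    rec <- extractSegments(tup, matchers, needQual)
    nMatched <<- nMatched + nrow(rec)
    if (nrow(rec)) {
      tb <- table(rec$structure)
      perStructure[as.integer(names(tb))] <<-
        perStructure[as.integer(names(tb))] + as.integer(tb)
    }
    pass <- qualityFilter(rec, cfg@quality)
    nQualityFail <<- nQualityFail + sum(!pass)
    rec <- rec[pass, , drop = FALSE]
    tallies[[tup$chunk]] <<- tallySegments(rec, governed, tup$chunk)
    chunks[[tup$chunk]] <<- rec
  })

  tally <- mergeTallies(tallies)
  ctab <- buildCorrectionTable(tally, cfg)

  # persist correction tables and rank-count curves
  ctRows <- list(); rcRows <- list()
  for (seg in names(ctab@tables)) {
    v <- ctab@tables[[seg]]
    ctRows[[seg]] <- data.frame(segment = seg, raw = names(v),
                                corrected = ifelse(is.na(v), "-", v),
                                stringsAsFactors = FALSE)
    counts <- tally@counts[[seg]]
    if (length(counts)) {
      cv <- rankCountCurve(counts)
      rcRows[[seg]] <- cbind(segment = seg, cv)
    }
  }
  if (length(ctRows))
    writeTsv(do.call(rbind, ctRows), file.path(outDir,
                                               "correction_tables.tsv"))
  if (length(rcRows))
    writeTsv(do.call(rbind, rcRows), file.path(outDir, "rank_counts.tsv"))

  nCorrectionDrop <- 0L; nCorrected <- 0L
  trees <- list()
  for (k in seq_along(chunks)) {
    res <- applyCorrection(chunks[[k]], ctab)
    nCorrectionDrop <- nCorrectionDrop + res$dropped
    enc <- encodeValues(res$records, cfg)
    nCorrected <- nCorrected + nrow(res$records)
    trees[[k]] <- enc$tree
    .writeRecordsTsv(res$records,
                     file.path(outDir, "corrected",
                               sprintf("chunk_%05d.tsv", k)))
  }
  tree <- mergeValueTrees(trees)
  writeTsv(setNames(tree@entries,
                    c("variable", "parent_path", "value", "count")),
           file.path(outDir, "value_tree.tsv"))

  manifest <- c(input = nInput, matched = nMatched,
                no_match = nInput - nMatched, quality = nQualityFail,
                correction_drop = nCorrectionDrop, corrected = nCorrected,
                chunks = length(chunks))
  mf <- data.frame(key = c("config_checksum", "seed", "chunk_size",
                           paste0("matched_", names(perStructure)),
                           names(manifest)),
                   value = c(unname(md5sum(configPath)), cfg@seed, chunkSize,
                             unname(perStructure), unname(manifest)),
                   stringsAsFactors = FALSE)
  writeTsv(mf, file.path(outDir, "manifest.tsv"))
  list(manifest = manifest, perStructure = perStructure,
       correction = ctab, tree = tree, tally = tally, outDir = outDir)
}

#' Translate interpreted reads into the destination structure
#'
#' Reads the artifacts of [runInterpret()], optimizes the value space (or
#' enumerates raw global values when `optimize = FALSE`, the degraded
#' control mode), renders every record through the destination
#' specifications and emits destination FASTQ files plus a manifest of
#' translated/dropped counts.
#'
#' @param interpDir output directory of a previous [runInterpret()] run.
#' @param outDir output directory for destination FASTQ files.
#' @param optimize use scope-wise value-space optimization (default) or raw
#'   global value enumeration.
#' @param gzip write gzip-compressed FASTQ.
#' @return list with `manifest` (named counts), `opt`
#'   ([OptimizationMap-class]) and `fastqs` (output paths).
#' @export
runTranslate <- function(interpDir, outDir, optimize = TRUE, gzip = FALSE) {
  configPath <- file.path(interpDir, "config.txt")
  if (!file.exists(configPath))
    stop("missing interpret artifacts: ", configPath,
         " (run runInterpret first)")
  cfg <- parseConfig(path = configPath)
  if (!length(cfg@destinations))
    stop("configuration declares no destination segments")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

  treeTsv <- readTsv(file.path(interpDir, "value_tree.tsv"),
                     quote = "", comment.char = "",
                     colClasses = c(value = "character",
                                    parent_path = "character"))
  vnames <- vapply(cfg@variables, function(v) v@name, "")
  hier <- setNames(vapply(cfg@variables, function(v) v@parent, ""), vnames)
  valued <- vnames[vapply(cfg@variables, function(v) v@valued, TRUE)]
  tree <- new("ValueTree",
              entries = data.frame(variable = treeTsv$variable,
                                   path = treeTsv$parent_path,
                                   key = treeTsv$value,
                                   count = treeTsv$count,
                                   stringsAsFactors = FALSE),
              hierarchy = hier[valued])
  opt <- if (optimize) optimizeValueSpace(tree) else rawValueMap(tree)
  writeTsv(opt@assignments,
           file.path(outDir, "optimization_map.tsv"))

  translator <- buildTranslator(cfg, opt)
  nReads <- translator$nReads
  ext <- if (gzip) ".fastq.gz" else ".fastq"
  fastqs <- file.path(outDir, sprintf("dest_R%d%s", seq_len(nReads), ext))
  reasons <- c(capacity = 0L, table_miss = 0L)
  nTranslated <- 0L
  acc <- list(ids = list(), seqs = rep(list(list()), nReads),
              quals = rep(list(list()), nReads))
  chunkFiles <- sort(list.files(file.path(interpDir, "corrected"),
                                full.names = TRUE, pattern = "^chunk_"))
  for (cf in chunkFiles) {
    records <- .readRecordsTsv(cf)
    records <- addValueColumns(records, cfg)
    out <- translateRecords(records, cfg, opt, translator)
    reasons <- reasons + out$droppedReasons
    nTranslated <- nTranslated + length(out$ids)
    k <- length(acc$ids) + 1L
    acc$ids[[k]] <- out$ids
    for (ri in seq_len(nReads)) {
      acc$seqs[[ri]][[k]] <- out$seqs[[ri]]
      acc$quals[[ri]][[k]] <- out$quals[[ri]]
    }
  }
  tuples <- list(ids = unlist(acc$ids),
                 seqs = lapply(acc$seqs, function(x)
                   as.character(unlist(x))),
                 quals = lapply(acc$quals, function(x)
                   as.character(unlist(x))))
  if (is.null(tuples$ids)) tuples$ids <- character(0)
  emitDestinationFastq(tuples, fastqs)
  manifest <- c(corrected = nTranslated + sum(reasons),
                translated = nTranslated, reasons)
  writeTsv(data.frame(key = names(manifest), value = unname(manifest)),
           file.path(outDir, "manifest.tsv"))
  list(manifest = manifest, opt = opt, fastqs = fastqs)
}

#' Derive a source configuration for the destination structure
#'
#' Builds the configuration under which the emitted destination reads can
#' themselves be interpreted (e.g. for round-trip conversions): destination
#' segments become fixed-span source segments in placement order, valued
#' destinations become variables mirroring the parental-local hierarchy of
#' their source variables, and pass-through destinations stay pass-through.
#'
#' @param cfg the [PipelineConfig-class] used for translation.
#' @param destinations optional destination list for the new configuration
#'   (defaults to none: interpret-only).
#' @return a [PipelineConfig-class] describing the destination reads.
#' @export
destinationAsSource <- function(cfg, destinations = list()) {
  dests <- cfg@destinations
  if (!length(dests)) stop("configuration has no destinations")
  ord <- order(vapply(dests, function(d) d@readIndex, 0L),
               vapply(dests, function(d) d@order, 0L))
  dests <- dests[ord]
  segWidth <- function(d) {
    switch(d@strategy,
      reassign = buildDestinationPool(d)$width,
      bequeath_pad = d@length,
      conversion_table = {
        tab <- readConversionTable(d@tablePath)
        w <- unique(nchar(tab))
        if (length(w) != 1L)
          stop("conversion table of '", d@name,
               "' mixes destination lengths")
        w
      },
      constant = nchar(d@constantSeq),
      passthrough = NA_integer_)
  }
  segs <- list(); offset <- list()
  for (d in dests) {
    ri <- as.character(d@readIndex)
    if (is.null(offset[[ri]])) offset[[ri]] <- 0L
    w <- segWidth(d)
    if (is.na(w)) {
      segs[[d@name]] <- segmentSpec(paste0(d@name, "Seg"), d@readIndex,
                                    start = offset[[ri]], end = NA)
      offset[[ri]] <- NA_integer_  # open-ended: must be last on its read
    } else {
      if (is.na(offset[[ri]]))
        stop("destination '", d@name,
             "' placed after an open-ended pass-through on read ",
             d@readIndex)
      segs[[d@name]] <- segmentSpec(paste0(d@name, "Seg"), d@readIndex,
                                    start = offset[[ri]],
                                    end = offset[[ri]] + w)
      offset[[ri]] <- offset[[ri]] + w
    }
  }
  srcVar <- function(d) if (is.na(d@sourceVariable)) NULL else
    variableByName(cfg, d@sourceVariable)
  destOfVar <- setNames(
    vapply(dests, function(d) d@name, ""),
    vapply(dests, function(d) d@sourceVariable, ""))
  vars <- list()
  for (d in dests) {
    if (d@strategy == "constant") next
    v <- srcVar(d)
    if (d@strategy == "passthrough") {
      vars[[d@name]] <- variableSpec(d@name, paste0(d@name, "Seg"),
                                     role = "independent",
                                     correction = "none")
      next
    }
    parentDest <- if (!is.na(v@parent) && v@parent %in% names(destOfVar))
      destOfVar[[v@parent]] else NA
    hasChild <- any(vapply(cfg@variables, function(x)
      identical(x@parent, v@name), TRUE))
    role <- if (!is.na(parentDest)) "local" else
      if (hasChild) "parental" else "independent"
    vars[[d@name]] <- variableSpec(d@name, paste0(d@name, "Seg"),
                                   role = role, parent = parentDest,
                                   correction = "none", valued = TRUE)
  }
  pipelineConfig(list(readStructure("destination", unname(segs))),
                 unname(vars), cfg@quality, destinations,
                 chunkSize = cfg@chunkSize, seed = cfg@seed)
}
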