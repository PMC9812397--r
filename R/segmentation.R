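#' @include matcher.R
#' @importFrom Biostrings readDNAStringSet writeXStringSet DNAStringSet
#'   BStringSet fastq.geometry
#' @importFrom S4Vectors mcols
NULL

#' Stream co-indexed FASTQ files as chunks of read tuples
#'
#' Files are read sequentially in blocks and split into logical chunks of at
#' most `chunkSize` tuples, order-preserving; downstream results are
#' invariant to the chunking because tallies and value trees are merged
#' before any table is built. Gzip-compressed input is handled
#' transparently. Read pairing is positional (by record order); `strictIds`
#' additionally verifies that read identifiers agree across files up to the
#' first whitespace.
#'
#' @param paths character vector of FASTQ or FASTQ.gz paths (one per read of
#'   the tuple).
#' @param chunkSize maximum tuples per chunk.
#' @param callback function called once per chunk with
#'   `list(ids, seqs, quals, chunk)`; `ids` are the first whitespace-delimited
#'   tokens of file 1's headers, `seqs`/`quals` lists per file.
#' @param strictIds verify read-identifier agreement across files.
#' @return invisibly, the total number of read tuples streamed.
#' @export
streamReadTuples <- function(paths, chunkSize, callback, strictIds = FALSE) {
  counts <- vapply(paths, function(p) {
    g <- tryCatch(fastq.geometry(p), error = function(e)
      stop("FASTQ parse error in ", p, ": ", conditionMessage(e)))
    as.integer(g[1L])
  }, 0L)
  if (length(unique(counts)) != 1L)
    stop("record-count mismatch across FASTQ files: ",
         paste(sprintf("%s has %d", basename(paths), counts),
               collapse = ", "))
  total <- counts[[1L]]
  chunkSize <- max(1L, as.integer(chunkSize))
  blockSize <- max(chunkSize, 20000L)
  skip <- 0L
  chunk <- 0L
  while (skip < total) {
    nrec <- min(blockSize, total - skip)
    block <- lapply(paths, function(p)
      readDNAStringSet(p, format = "fastq", with.qualities = TRUE,
                       nrec = nrec, skip = skip))
    ids <- sub("[[:space:]].*$", "", names(block[[1L]]))
    if (strictIds && length(block) > 1L) {
      for (k in 2:length(block)) {
        other <- sub("[[:space:]].*$", "", names(block[[k]]))
        if (!identical(ids, other))
          stop("read identifiers disagree between ", basename(paths[1L]),
               " and ", basename(paths[k]))
      }
    }
    seqs <- lapply(block, as.character)
    quals <- lapply(block, function(b) as.character(mcols(b)$qualities))
    seqs <- lapply(seqs, unname)
    quals <- lapply(quals, unname)
    off <- 0L
    while (off < nrec) {
      take <- min(chunkSize, nrec - off)
      sel <- seq.int(off + 1L, off + take)
      chunk <- chunk + 1L
      callback(list(ids = ids[sel],
                    seqs = lapply(seqs, `[`, sel),
                    quals = lapply(quals, `[`, sel),
                    chunk = chunk))
      off <- off + take
    }
    skip <- skip + nrec
  }
  invisible(total)
}

#' Apply a quality policy to extracted records
#'
#' A record fails when any governed segment present in its structure has an
#' average Phred score below `minAvgQ` or a minimum per-base score below
#' `minBaseQ` (exclusive thresholds: exactly at the threshold passes). The
#' whole read is dropped — a record must be complete to translate.
#'
#' @param records data.frame from [extractSegments()].
#' @param policy a [QualityPolicy-class].
#' @return logical vector, `TRUE` for records that pass.
#' @export
qualityFilter <- function(records, policy) {
  n <- nrow(records)
  pass <- rep(TRUE, n)
  if (n == 0L) return(pass)
  segCols <- sub("^avgq_", "", grep("^avgq_", names(records), value = TRUE))
  governed <- if (identical(policy@appliesTo, "all")) segCols
              else intersect(segCols, policy@appliesTo)
  for (seg in governed) {
    avg <- records[[paste0("avgq_", seg)]]
    mn <- records[[paste0("minq_", seg)]]
    present <- !is.na(avg)
    pass <- pass & (!present | (avg >= policy@minAvgQ &
                                mn >= policy@minBaseQ))
  }
  pass
}

#' Tally unique segment sequences of a chunk
#'
#' @param records data.frame from [extractSegments()] (one chunk).
#' @param segments segment names to tally; defaults to all.
#' @param chunkId chunk identifier.
#' @return a [SegmentTally-class].
#' @export
tallySegments <- function(records, segments = NULL, chunkId = NA_integer_) {
  segCols <- sub("^seq_", "", grep("^seq_", names(records), value = TRUE))
  if (is.null(segments)) segments <- segCols
  counts <- list()
  for (seg in intersect(segments, segCols)) {
    v <- records[[paste0("seq_", seg)]]
    v <- v[!is.na(v)]
    if (!length(v)) { counts[[seg]] <- setNames(numeric(0), character(0)); next }
    tb <- table(v)
    counts[[seg]] <- setNames(as.numeric(tb), names(tb))
  }
  new("SegmentTally", counts = counts, chunkId = as.integer(chunkId))
}

#' Merge segment tallies from different chunks
#'
#' Counts are summed per sequence; merging is associative and commutative,
#' so tables built from the merged tally are independent of the chunking.
#'
#' @param tallies list of [SegmentTally-class] objects.
#' @return a merged [SegmentTally-class].
#' @export
mergeTallies <- function(tallies) {
  if (!length(tallies))
    return(new("SegmentTally", counts = list(), chunkId = NA_integer_))
  segs <- unique(unlist(lapply(tallies, function(t) names(t@counts))))
  counts <- list()
  for (seg in segs) {
    parts <- lapply(unname(tallies), function(t) t@counts[[seg]])
    parts <- parts[!vapply(parts, is.null, TRUE)]
    all <- unlist(parts)
    if (!length(all)) {
      counts[[seg]] <- setNames(numeric(0), character(0))
      next
    }
    agg <- rowsum(as.numeric(all), names(all))
    counts[[seg]] <- setNames(agg[, 1L], rownames(agg))
  }
  new("SegmentTally", counts = counts, chunkId = NA_integer_)
}
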