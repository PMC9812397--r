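#' @include segmentation.R
NULL

#' Rank-read-count curve of a segment tally
#'
#' Sequences sorted by descending count; ties are ordered lexicographically
#' so that ranks are deterministic across runs and chunkings.
#'
#' @param counts named numeric vector of read counts per sequence.
#' @return data.frame with columns rank, sequence, count.
#' @export
rankCountCurve <- function(counts) {
  o <- order(-counts, names(counts))
  data.frame(rank = seq_along(counts), sequence = names(counts)[o],
             count = as.numeric(counts[o]), stringsAsFactors = FALSE)
}

#' Detect the knee of a rank-count curve
#'
#' The knee is the maximum-curvature rank on the descending rank-count
#' curve, separating abundant (true) from rare (error) sequences. Curvature
#' is measured on the polyline of (log10 rank, log10 count), keeping for
#' every equal-count run its first and last rank as vertices (interior
#' vertices of a run are collinear and carry no curvature), as the turn
#' angle between the adjacent chord directions at each interior vertex.
#' The maximum angle wins; ties go to the smaller rank. Degenerate curves
#' (n <= 2 or all counts equal) accept everything: the knee is rank n.
#'
#' @param counts numeric vector of counts sorted in non-increasing order
#'   (e.g. the `count` column of [rankCountCurve()]).
#' @return the knee rank; sequences with rank <= knee form the accepted set.
#' @export
detectKnee <- function(counts) {
  n <- length(counts)
  if (n == 0L) return(0L)
  if (n <= 2L || length(unique(counts)) == 1L) return(n)
  if (is.unsorted(rev(counts)))
    stop("counts must be sorted in non-increasing order")
  runEnds <- c(which(diff(counts) != 0), n)
  runStarts <- c(1L, runEnds[-length(runEnds)] + 1L)
  verts <- sort(unique(c(runStarts, runEnds)))
  if (length(verts) < 3L) return(n)
  x <- log10(verts)
  y <- log10(counts[verts])
  dx <- diff(x); dy <- diff(y)
  len <- sqrt(dx^2 + dy^2)
  ux <- dx / len; uy <- dy / len
  m <- length(ux)
  dots <- ux[-m] * ux[-1L] + uy[-m] * uy[-1L]
  ang <- acos(pmin(1, pmax(-1, dots)))
  as.integer(verts[which.max(ang) + 1L])
}

# nearest accepted sequence for each query, distance-capped; ties broken by
# higher count then lexicographic order; NA when no candidate within levMax
# or (requireUnique) when the minimal distance is ambiguous.
.nearestMap <- function(queries, accepted, acceptedCounts, levMax,
                        requireUnique = FALSE) {
  if (!length(queries)) return(setNames(character(0), character(0)))
  out <- rep(NA_character_, length(queries))
  # block the distance matrix to bound memory on large pools
  blk <- max(1L, 2e6 %/% max(1L, length(accepted)))
  for (i0 in seq(1L, length(queries), by = blk)) {
    i1 <- min(length(queries), i0 + blk - 1L)
    d <- levenshteinDist(queries[i0:i1], accepted)
    for (k in seq_len(i1 - i0 + 1L)) {
      dr <- d[k, ]
      dm <- min(dr)
      if (dm > levMax) next
      cand <- which(dr == dm)
      if (requireUnique && length(cand) > 1L) next
      if (length(cand) > 1L) {
        cnt <- acceptedCounts[cand]
        cand <- cand[order(-cnt, accepted[cand])]
      }
      out[k + i0 - 1L] <- accepted[cand[1L]]
    }
  }
  setNames(out, queries)
}

#' Build a correction table for one segment
#'
#' * `imputation`: the rank-count knee splits the tally; above-knee
#'   sequences map to themselves and below-knee sequences map to the nearest
#'   above-knee sequence within `levMax` edits (ties: higher count, then
#'   lexicographic), else DROP.
#' * `allowlist`: exact members map to themselves; other observed sequences
#'   map to the unique nearest allowlist entry within `levMax`, else DROP
#'   (an ambiguous nearest entry is a DROP — correcting to an arbitrary
#'   barcode would fabricate identity).
#' * `plugin`: the external command is invoked as
#'   `command <input.tsv> <output.tsv>`; the input is a two-column TSV
#'   (sequence, count) and the output must be a two-column TSV
#'   (raw, corrected or `-` for DROP), total over the input sequences.
#'
#' @param counts named numeric vector: observed sequence -> read count.
#' @param method `"imputation"`, `"allowlist"` or `"plugin"`.
#' @param levMax maximum Levenshtein distance.
#' @param allowlist character vector of allowlist sequences (for
#'   `"allowlist"`).
#' @param pluginCommand external command (for `"plugin"`).
#' @return named character vector raw -> corrected, `NA` = DROP, plus
#'   attribute `kneeRank` for imputation.
#' @export
buildSegmentCorrection <- function(counts, method, levMax = 1L,
                                   allowlist = NULL, pluginCommand = NULL) {
  seqs <- names(counts)
  if (method == "imputation") {
    curve <- rankCountCurve(counts)
    knee <- detectKnee(curve$count)
    accepted <- curve$sequence[seq_len(knee)]
    acceptedCounts <- curve$count[seq_len(knee)]
    below <- curve$sequence[-seq_len(knee)]
    map <- setNames(accepted, accepted)
    if (length(below))
      map <- c(map, .nearestMap(below, accepted, acceptedCounts, levMax))
    map <- map[seqs]
    attr(map, "kneeRank") <- knee
    return(map)
  }
  if (method == "allowlist") {
    if (is.null(allowlist) || !length(allowlist))
      stop("config error: allowlist correction without allowlist entries")
    map <- setNames(rep(NA_character_, length(seqs)), seqs)
    inList <- seqs %in% allowlist
    map[inList] <- seqs[inList]
    rest <- seqs[!inList]
    if (length(rest)) {
      cnt <- rep(0, length(allowlist))
      map[rest] <- .nearestMap(rest, allowlist, cnt, levMax,
                               requireUnique = TRUE)
    }
    return(map)
  }
  if (method == "plugin") {
    if (is.null(pluginCommand) || is.na(pluginCommand))
      stop("config error: plugin correction without a command")
    tin <- tempfile(fileext = ".tsv"); tout <- tempfile(fileext = ".tsv")
    on.exit(unlink(c(tin, tout)), add = TRUE)
    utils::write.table(data.frame(seqs, as.numeric(counts)), tin,
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    status <- system(paste(pluginCommand, shQuote(tin), shQuote(tout)))
    if (status != 0L)
      stop("plugin error: '", pluginCommand, "' exited with status ", status)
    if (!file.exists(tout))
      stop("plugin error: no output table written")
    tab <- utils::read.delim(tout, header = FALSE, stringsAsFactors = FALSE,
                             colClasses = "character")
    map <- setNames(tab[[2L]], tab[[1L]])
    map[map == "-"] <- NA_character_
    if (!all(seqs %in% names(map)))
      stop("plugin error: output table is not total over input sequences")
    return(map[seqs])
  }
  stop("unknown correction method '", method, "'")
}

#' Build correction tables for all governed segments of a configuration
#'
#' Tables are built from a merged tally (all chunks summed), so they are
#' independent of the chunking. A combinatorial variable's member segments
#' are corrected independently; per-segment allowlists are recycled across
#' members in declaration order.
#'
#' @param tally merged [SegmentTally-class].
#' @param cfg a [PipelineConfig-class].
#' @return a [CorrectionTable-class] covering every segment of every
#'   variable whose correction method is not `"none"`.
#' @export
buildCorrectionTable <- function(tally, cfg) {
  tables <- list(); method <- character(0); levMax <- integer(0)
  kneeRank <- integer(0)
  for (v in cfg@variables) {
    if (v@correction == "none") next
    paths <- v@allowlistPath
    for (si in seq_along(v@segments)) {
      seg <- v@segments[[si]]
      counts <- tally@counts[[seg]]
      if (is.null(counts)) counts <- setNames(numeric(0), character(0))
      allow <- NULL
      if (v@correction == "allowlist") {
        p <- paths[[(si - 1L) %% length(paths) + 1L]]
        allow <- readAllowlist(p)
      }
      map <- buildSegmentCorrection(counts, v@correction, v@levMax,
                                    allowlist = allow,
                                    pluginCommand = v@pluginCommand)
      kneeRank[[seg]] <- if (is.null(attr(map, "kneeRank"))) NA_integer_
                         else attr(map, "kneeRank")
      attr(map, "kneeRank") <- NULL
      tables[[seg]] <- map
      method[[seg]] <- v@correction
      levMax[[seg]] <- v@levMax
    }
  }
  new("CorrectionTable", tables = tables, method = method,
      levMax = levMax, kneeRank = kneeRank)
}

#' Apply correction tables to extracted records
#'
#' Every governed segment sequence is replaced by its corrected sequence;
#' any DROP drops the whole record. Per-segment qualities are carried over
#' unchanged. Applying a table twice equals applying it once (corrected
#' sequences are members of the accepted set, which maps to itself).
#'
#' @param records data.frame from [extractSegments()].
#' @param ctab a [CorrectionTable-class].
#' @return list with `records` (corrected, drops removed) and `dropped`
#'   (number of records dropped by correction).
#' @export
applyCorrection <- function(records, ctab) {
  n <- nrow(records)
  if (n == 0L) return(list(records = records, dropped = 0L))
  drop <- rep(FALSE, n)
  for (seg in names(ctab@tables)) {
    col <- paste0("seq_", seg)
    if (!col %in% names(records)) next
    raw <- records[[col]]
    present <- !is.na(raw)
    if (!any(present)) next
    map <- ctab@tables[[seg]]
    idx <- match(raw[present], names(map))
    if (anyNA(idx))
      stop("internal consistency error: sequence absent from correction ",
           "table for segment '", seg, "'")
    corrected <- unname(map[idx])
    drop[present] <- drop[present] | is.na(corrected)
    raw[present] <- corrected
    records[[col]] <- raw
  }
  list(records = records[!drop, , drop = FALSE],
       dropped = sum(drop))
}
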