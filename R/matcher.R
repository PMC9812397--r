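#' @include config.R
NULL

# ---- anchored flank search -------------------------------------------------

# Count substitutions between two equal-length strings (vector-free, small).
.mismatches <- function(a, b) {
  if (!nchar(a)) return(0L)
  sum(utf8ToInt(a) != utf8ToInt(b))
}

# Candidate start positions (1-based) where `motif` matches `seq` under the
# inner-exact / outer-max-mismatch policy. `innerSide` is "right" for
# upstream motifs (the bases adjacent to the segment are the motif's last
# `inner` bases) and "left" for downstream motifs. Positions are returned in
# increasing order.
.flankCandidates <- function(seq, motif, inner, outerMM, innerSide) {
  L <- nchar(motif)
  inner <- min(inner, L)
  if (inner > 0L) {
    innerPart <- if (innerSide == "right")
      substr(motif, L - inner + 1L, L) else substr(motif, 1L, inner)
    hits <- gregexpr(innerPart, seq, fixed = TRUE)[[1L]]
    if (hits[1L] == -1L) return(integer(0))
    starts <- if (innerSide == "right") hits - (L - inner) else hits
  } else {
    starts <- seq_len(max(0L, nchar(seq) - L + 1L))
  }
  starts <- starts[starts >= 1L & starts + L - 1L <= nchar(seq)]
  if (!length(starts)) return(integer(0))
  if (L == inner || outerMM >= L - inner) return(as.integer(starts))
  outer <- if (innerSide == "right")
    substr(motif, 1L, L - inner) else substr(motif, inner + 1L, L)
  off <- if (innerSide == "right") 0L else inner
  keep <- vapply(starts, function(p) {
    window <- substr(seq, p + off, p + off + nchar(outer) - 1L)
    .mismatches(window, outer) <= outerMM
  }, logical(1))
  as.integer(starts[keep])
}

# Locate one anchored segment on one read. Scans left to right and returns
# the first admissible flank pair (smallest upstream position, then smallest
# segment length); NULL when no placement is admissible.
locateAnchoredSegment <- function(seq, spec) {
  hasUp <- !is.na(spec@upstream) && nzchar(spec@upstream)
  hasDn <- !is.na(spec@downstream) && nzchar(spec@downstream)
  n <- nchar(seq)
  if (hasUp) {
    ups <- .flankCandidates(seq, spec@upstream, spec@innerExact,
                            spec@outerMaxMismatch, "right")
    for (p in ups) {
      segStart <- p + nchar(spec@upstream)
      if (!hasDn) {
        segEnd <- segStart + spec@minLen - 1L
        if (segEnd <= n) return(c(segStart, segEnd))
        next
      }
      for (len in spec@minLen:spec@maxLen) {
        dnStart <- segStart + len
        if (dnStart + nchar(spec@downstream) - 1L > n) break
        window <- substr(seq, dnStart, dnStart + nchar(spec@downstream) - 1L)
        if (.motifMatches(window, spec@downstream, spec@innerExact,
                          spec@outerMaxMismatch, "left"))
          return(c(segStart, segStart + len - 1L))
      }
    }
    return(NULL)
  }
  # downstream-only anchoring, fixed segment length
  dns <- .flankCandidates(seq, spec@downstream, spec@innerExact,
                          spec@outerMaxMismatch, "left")
  for (q in dns) {
    segStart <- q - spec@minLen
    if (segStart >= 1L) return(c(segStart, q - 1L))
  }
  NULL
}

.motifMatches <- function(window, motif, inner, outerMM, innerSide) {
  if (nchar(window) != nchar(motif)) return(FALSE)
  L <- nchar(motif); inner <- min(inner, L)
  innerPart <- if (innerSide == "left") substr(motif, 1L, inner)
               else substr(motif, L - inner + 1L, L)
  innerWin <- if (innerSide == "left") substr(window, 1L, inner)
              else substr(window, L - inner + 1L, L)
  if (innerPart != innerWin) return(FALSE)
  outerM <- if (innerSide == "left") substr(motif, inner + 1L, L)
            else substr(motif, 1L, L - inner)
  outerW <- if (innerSide == "left") substr(window, inner + 1L, L)
            else substr(window, 1L, L - inner)
  .mismatches(outerW, outerM) <= outerMM
}

# ---- compiled matchers -----------------------------------------------------

#' Compile a ReadStructure into a matcher
#'
#' The matcher, applied to a chunk of read tuples, either yields all segment
#' spans of the structure or reports no-match per read. Fixed spans are
#' extracted vectorially; anchored segments honor the inner-exact /
#' outer-max-mismatch flank policy and take the leftmost admissible
#' placement.
#'
#' @param structure a [ReadStructure-class].
#' @return a matcher object (list) for [matchChunk()].
#' @export
compileMatcher <- function(structure) {
  segs <- structure@segments
  # validity of spans is re-checked config-wide; keep per-structure check
  byRead <- split(segs, vapply(segs, function(x) x@readIndex, 0L))
  for (group in byRead) {
    fx <- Filter(function(x) x@locator == "fixed", group)
    if (length(fx) >= 2L) {
      starts <- vapply(fx, function(x) x@start, 0L)
      ends <- vapply(fx, function(x) x@end, 0L)
      o <- order(starts)
      s <- starts[o]; e <- ends[o]
      if (anyNA(e[-length(e)]) || any(e[-length(e)] > s[-1L]))
        stop("validation error: overlapping fixed spans in structure '",
             structure@name, "'")
    }
  }
  list(name = structure@name, segments = segs,
       anchored = any(vapply(segs, function(x) x@locator == "anchored",
                             TRUE)))
}

# Apply one matcher to a chunk. seqs/quals: list per file of character
# vectors (parallel across files). Returns list(ok = logical mask, data =
# data.frame of seq_/avgq_/minq_/qual_ columns for matched reads), where
# `data` rows correspond to which(ok). `needQual`: segment names whose
# per-base quality string must be retained (pass-through payloads).
matchChunk <- function(matcher, seqs, quals, needQual = character(0)) {
  n <- length(seqs[[1L]])
  ok <- rep(TRUE, n)
  spans <- list()  # per segment: matrix n x 2 of 1-based [start, end]
  for (spec in matcher$segments) {
    sv <- seqs[[spec@readIndex + 1L]]
    if (spec@locator == "fixed") {
      s1 <- spec@start + 1L
      e1 <- if (is.na(spec@end)) nchar(sv) else spec@end
      good <- nchar(sv) >= e1 & e1 >= s1
      ok <- ok & good
      spans[[spec@name]] <- cbind(rep(s1, n), e1)
    } else {
      sp <- matrix(NA_integer_, n, 2L)
      idx <- which(ok)
      for (i in idx) {
        hit <- locateAnchoredSegment(sv[i], spec)
        if (is.null(hit)) ok[i] <- FALSE else sp[i, ] <- hit
      }
      spans[[spec@name]] <- sp
    }
  }
  keep <- which(ok)
  if (!length(keep))
    return(list(ok = ok, data = NULL))
  data <- list()
  for (spec in matcher$segments) {
    sv <- seqs[[spec@readIndex + 1L]][keep]
    qv <- quals[[spec@readIndex + 1L]][keep]
    sp <- spans[[spec@name]][keep, , drop = FALSE]
    sq <- substr(sv, sp[, 1L], sp[, 2L])
    qq <- substr(qv, sp[, 1L], sp[, 2L])
    fixedWidth <- length(unique(nchar(qq))) == 1L
    st <- if (fixedWidth) qualStatsFixed(qq) else qualStatsVar(qq)
    data[[paste0("seq_", spec@name)]] <- sq
    data[[paste0("avgq_", spec@name)]] <- st$avg
    data[[paste0("minq_", spec@name)]] <- st$min
    if (spec@name %in% needQual)
      data[[paste0("qual_", spec@name)]] <- qq
  }
  list(ok = ok, data = as.data.frame(data, stringsAsFactors = FALSE))
}

#' Extract segments from a chunk of read tuples
#'
#' Applies the compiled matchers in configuration order; the first matcher
#' that fully matches claims the read (no-match is a normal outcome, counted
#' by the caller).
#'
#' @param tuples list with elements `ids` (character), `seqs` and `quals`
#'   (lists per file of character vectors), as produced by
#'   [streamReadTuples()].
#' @param matchers list of compiled matchers in configuration order.
#' @param needQual segment names whose per-base qualities are retained.
#' @return data.frame with columns read_id, structure (1-based index of the
#'   claiming structure) and per-segment seq_/avgq_/minq_(/qual_) columns;
#'   reads matching no structure are absent.
#' @export
extractSegments <- function(tuples, matchers, needQual = character(0)) {
  n <- length(tuples$ids)
  unclaimed <- rep(TRUE, n)
  pieces <- list()
  for (si in seq_along(matchers)) {
    if (!any(unclaimed)) break
    idx <- which(unclaimed)
    seqs <- lapply(tuples$seqs, `[`, idx)
    quals <- lapply(tuples$quals, `[`, idx)
    res <- matchChunk(matchers[[si]], seqs, quals, needQual)
    if (is.null(res$data)) next
    hit <- idx[res$ok]
    df <- cbind(data.frame(read_id = tuples$ids[hit],
                           structure = si,
                           stringsAsFactors = FALSE),
                res$data)
    df$.row <- hit
    pieces[[length(pieces) + 1L]] <- df
    unclaimed[hit] <- FALSE
  }
  if (!length(pieces))
    return(data.frame(read_id = character(0), structure = integer(0)))
  all <- do.call(rbindFill, list(pieces))
  all <- all[order(all$.row), , drop = FALSE]
  all$.row <- NULL
  rownames(all) <- NULL
  all
}

# rbind data.frames with differing columns (missing filled with NA)
rbindFill <- function(dfs) {
  cols <- unique(unlist(lapply(dfs, names)))
  out <- lapply(dfs, function(d) {
    for (cc in setdiff(cols, names(d))) d[[cc]] <- NA
    d[cols]
  })
  do.call(rbind, out)
}
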