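#' @include value-space.R
NULL

# ---- destination segment pools --------------------------------------------

# Build the deterministic index -> sequence generator of one reassign
# destination: a list of units with capacities; total capacity C is the
# product. Allowlist files are opened here (not at config parse time).
buildDestinationPool <- function(dest) {
  units <- lapply(dest@units, function(u) {
    if (u$kind == "allowlist") {
      seqs <- readAllowlist(u$path)
      if (length(unique(nchar(seqs))) != 1L)
        stop("allowlist unit of destination '", dest@name,
             "' mixes sequence lengths: ", u$path)
      list(kind = "allowlist", seqs = seqs, capacity = length(seqs),
           width = nchar(seqs[[1L]]))
    } else {
      chars <- strsplit(u$template, "")[[1L]]
      sets <- IUPAC_SETS[chars]
      if (any(vapply(sets, is.null, TRUE)))
        stop("unknown IUPAC code in template '", u$template, "'")
      list(kind = "iupac", sets = sets,
           capacity = prod(vapply(sets, length, 0L)),
           width = length(sets))
    }
  })
  caps <- vapply(units, function(u) u$capacity, 0)
  list(name = dest@name, units = units, capacities = caps,
       capacity = prod(caps),
       width = sum(vapply(units, function(u) u$width, 0)))
}

#' Capacity of a destination variable's unit pool
#'
#' The number of distinct sequences the destination segment can represent:
#' the product over units of the unit capacity (allowlist length, or the
#' product of per-position IUPAC base-set sizes; fixed positions contribute
#' 1).
#'
#' @param dest a [DestinationSpec-class] with strategy `"reassign"`.
#' @return the integer capacity C.
#' @export
destinationCapacity <- function(dest) {
  buildDestinationPool(dest)$capacity
}

#' Render optimized values as destination segment sequences
#'
#' Mixed-radix encoding of the value over the unit capacities, most
#' significant unit first; each digit is rendered by the unit's generator
#' (allowlist: file order; IUPAC template: per-position digits over the
#' code's base set in alphabetical order, leftmost position most
#' significant). The map is injective over [0, C); values >= C signal a
#' capacity overflow (`NA`, caller drops the read).
#'
#' @param values integer vector of optimized values.
#' @param pool pool built by `buildDestinationPool()` (or a
#'   [DestinationSpec-class], converted on the fly).
#' @return character vector of destination sequences, `NA` on overflow.
#' @export
assignDestinationSequence <- function(values, pool) {
  if (is(pool, "DestinationSpec")) pool <- buildDestinationPool(pool)
  caps <- pool$capacities
  k <- length(caps)
  place <- rev(cumprod(rev(c(caps[-1L], 1))))
  over <- is.na(values) | values >= pool$capacity | values < 0L
  v <- ifelse(over, 0, as.numeric(values))
  parts <- vector("list", k)
  for (i in seq_len(k)) {
    digit <- (v %/% place[[i]]) %% caps[[i]]
    u <- pool$units[[i]]
    if (u$kind == "allowlist") {
      parts[[i]] <- u$seqs[digit + 1L]
    } else {
      sizes <- vapply(u$sets, length, 0L)
      m <- length(sizes)
      pplace <- rev(cumprod(rev(c(sizes[-1L], 1))))
      sub <- vector("list", m)
      for (j in seq_len(m)) {
        dj <- (digit %/% pplace[[j]]) %% sizes[[j]]
        sub[[j]] <- u$sets[[j]][dj + 1L]
      }
      parts[[i]] <- do.call(paste0, sub)
    }
  }
  out <- do.call(paste0, parts)
  out[over] <- NA_character_
  out
}

# ---- quality bequeathing ---------------------------------------------------

#' Bequeath source segment qualities to a destination segment
#'
#' Inherited positions receive the round-half-up mean of the contributing
#' source segments' average Phred scores, clamped to [2, 40]; positions not
#' associated with inherited values (pad bases, constant fillers) receive
#' exactly Phred 40 (`"I"`).
#'
#' @param avgQ numeric vector (one mean source quality per record; average
#'   the contributing segments' averages beforehand for combinatorial
#'   sources).
#' @param destLen destination segment length.
#' @param inheritedLen number of leading inherited positions (default: all).
#' @return character vector of Phred+33 quality strings.
#' @export
bequeathQuality <- function(avgQ, destLen, inheritedLen = destLen) {
  q <- pmin(40, pmax(2, roundHalfUp(avgQ)))
  ch <- phredChars(q)
  paste0(strrep(ch, inheritedLen),
         strrep("I", pmax(0L, destLen - inheritedLen)))
}

# ---- record translation ----------------------------------------------------

# Precompile per-destination translation state against a config + map.
buildTranslator <- function(cfg, opt) {
  dests <- cfg@destinations
  ord <- order(vapply(dests, function(d) d@readIndex, 0L),
               vapply(dests, function(d) d@order, 0L))
  dests <- dests[ord]
  state <- lapply(dests, function(d) {
    st <- list(dest = d)
    if (d@strategy == "reassign") {
      st$pool <- buildDestinationPool(d)
      a <- opt@assignments
      a <- a[a$variable == d@sourceVariable, , drop = FALSE]
      st$lookup <- setNames(a$optValue, paste(a$path, a$key, sep = "\r"))
    }
    if (d@strategy == "conversion_table")
      st$table <- readConversionTable(d@tablePath)
    if (d@strategy %in% c("bequeath_pad", "passthrough", "reassign",
                          "conversion_table"))
      st$variable <- variableByName(cfg, d@sourceVariable)
    st
  })
  list(dests = state,
       nReads = max(vapply(dests, function(d) d@readIndex, 0L)) + 1L)
}

#' Translate corrected, valued records into destination read tuples
#'
#' For each destination segment: `reassign` renders the record's optimized
#' value through the unit pool (capacity overflow drops the whole record);
#' `bequeath_pad` carries the source sequence padded with the pad base to
#' the destination length; `conversion_table` maps the corrected source
#' sequence (a missing key drops the record); `passthrough` copies sequence
#' and per-base quality verbatim; `constant` emits the literal filler.
#' Average source qualities are bequeathed to all inherited positions; new
#' bases get Phred 40.
#'
#' @param records corrected records with value columns (from
#'   [encodeValues()]).
#' @param cfg a [PipelineConfig-class].
#' @param opt an [OptimizationMap-class].
#' @param translator precompiled translation state (built once per run by
#'   `buildTranslator`; rebuilt from `cfg` and `opt` when omitted).
#' @return list with `ids`, `seqs`/`quals` (lists per output read of
#'   character vectors, surviving records only) and `droppedReasons`
#'   (named integer: capacity, table_miss).
#' @export
translateRecords <- function(records, cfg, opt,
                             translator = buildTranslator(cfg, opt)) {
  n <- nrow(records)
  reasons <- c(capacity = 0L, table_miss = 0L)
  if (n == 0L)
    return(list(ids = character(0),
                seqs = rep(list(character(0)), translator$nReads),
                quals = rep(list(character(0)), translator$nReads),
                droppedReasons = reasons, dropReason = character(0)))
  dropReason <- rep(NA_character_, n)
  segSeq <- list(); segQual <- list()
  for (st in translator$dests) {
    d <- st$dest
    key <- d@name
    if (d@strategy == "constant") {
      segSeq[[key]] <- rep(d@constantSeq, n)
      segQual[[key]] <- rep(strrep("I", nchar(d@constantSeq)), n)
      next
    }
    v <- st$variable
    avgq <- records[[paste0("avgq_var_", v@name)]]
    if (is.null(avgq)) {
      qc <- paste0("avgq_", v@segments)
      avgq <- if (length(qc) == 1L) records[[qc]] else
        rowMeans(as.matrix(records[qc]))
    }
    if (d@strategy == "reassign") {
      rk <- paste(records[[paste0("path_", v@name)]],
                  records[[paste0("key_", v@name)]], sep = "\r")
      vals <- unname(st$lookup[rk])
      seqs <- assignDestinationSequence(vals, st$pool)
      miss <- is.na(seqs)
      dropReason[miss & is.na(dropReason)] <- "capacity"
      segSeq[[key]] <- seqs
      segQual[[key]] <- bequeathQuality(avgq, st$pool$width)
    } else if (d@strategy == "bequeath_pad") {
      src <- if (length(v@segments) == 1L)
        records[[paste0("seq_", v@segments)]] else
        do.call(paste0, records[paste0("seq_", v@segments)])
      srcLen <- nchar(src)
      if (any(srcLen > d@length, na.rm = TRUE))
        stop("bequeath_pad destination '", d@name,
             "' is shorter than the source sequence")
      seqs <- paste0(src, strrep(d@padBase, d@length - srcLen))
      quals <- paste0(substr(bequeathQuality(avgq, d@length), 1L, srcLen),
                      strrep("I", d@length - srcLen))
      segSeq[[key]] <- seqs
      segQual[[key]] <- quals
    } else if (d@strategy == "conversion_table") {
      src <- if (length(v@segments) == 1L)
        records[[paste0("seq_", v@segments)]] else
        do.call(paste0, records[paste0("seq_", v@segments)])
      seqs <- unname(st$table[src])
      miss <- is.na(seqs)
      dropReason[miss & is.na(dropReason)] <- "table_miss"
      segSeq[[key]] <- seqs
      segQual[[key]] <- bequeathQuality(avgq, ifelse(miss, 0L, nchar(seqs)))
    } else if (d@strategy == "passthrough") {
      seg <- v@segments[[1L]]
      segSeq[[key]] <- records[[paste0("seq_", seg)]]
      q <- records[[paste0("qual_", seg)]]
      if (is.null(q))
        q <- bequeathQuality(records[[paste0("avgq_", seg)]],
                             1L)  # degenerate: no stored qualities
      segQual[[key]] <- q
    }
  }
  keep <- is.na(dropReason)
  if (any(!keep)) {
    tb <- table(dropReason[!keep])
    reasons[names(tb)] <- reasons[names(tb)] + as.integer(tb)
  }
  outSeqs <- vector("list", translator$nReads)
  outQuals <- vector("list", translator$nReads)
  for (ri in seq_len(translator$nReads)) {
    ds <- Filter(function(st) st$dest@readIndex == ri - 1L,
                 translator$dests)
    sq <- lapply(ds, function(st) segSeq[[st$dest@name]][keep])
    ql <- lapply(ds, function(st) segQual[[st$dest@name]][keep])
    outSeqs[[ri]] <- if (length(sq)) do.call(paste0, sq) else
      rep("", sum(keep))
    outQuals[[ri]] <- if (length(ql)) do.call(paste0, ql) else
      rep("", sum(keep))
  }
  list(ids = records$read_id[keep], seqs = outSeqs, quals = outQuals,
       droppedReasons = reasons, dropReason = dropReason)
}

# ---- FASTQ emission --------------------------------------------------------

#' Emit destination read tuples as FASTQ files
#'
#' One valid four-line FASTQ record per surviving read per output file;
#' read identifiers are preserved from the source. Paths ending in `.gz`
#' are compressed.
#'
#' @param tuples list as returned by [translateRecords()].
#' @param paths output FASTQ path per output read.
#' @param append append to existing files.
#' @return invisibly, the number of records written.
#' @export
emitDestinationFastq <- function(tuples, paths, append = FALSE) {
  if (length(paths) < length(tuples$seqs))
    stop("need one output path per destination read")
  for (ri in seq_along(tuples$seqs)) {
    x <- DNAStringSet(tuples$seqs[[ri]])
    names(x) <- tuples$ids
    writeXStringSet(x, paths[[ri]], format = "fastq",
                    qualities = BStringSet(tuples$quals[[ri]]),
                    append = append,
                    compress = grepl("\\.gz$", paths[[ri]]))
  }
  invisible(length(tuples$ids))
}
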