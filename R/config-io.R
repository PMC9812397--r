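#' @include config.R
NULL

# The process-configuration dialect is a sectioned key=value text format:
#
#   [structure <name>]
#   segment <name> read=<i> span=<start>:<end|*>
#   segment <name> read=<i> anchor upstream=ACGT.. downstream=ACGT.. \
#           inner=<n> mismatch=<n> len=<min>:<max>
#
#   [variables]
#   variable <name> segments=<s1,s2,..> role=<independent|parental|local> \
#            parent=<name> correction=<imputation|allowlist|plugin|none> \
#            lev_max=<n> allowlist=<p1,p2,..> plugin=<cmd> valued=<yes|no>
#
#   [quality]
#   min_avg_q=<q>  min_base_q=<q>  applies_to=<all|s1,s2,..>
#
#   [destination <name>]
#   source=<variable> strategy=<...> read=<i> order=<k>
#   unit template=<IUPAC>  |  unit allowlist=<path>
#   length=<n> pad=<base> table=<path> sequence=<ACGT..>
#
#   [options]
#   chunk_size=<n>  seed=<n>
#
# Coordinates are 0-based half-open; read indices are 0-based; '#' starts a
# comment line. Reads are taken as stored in FASTQ (no reverse-complement
# inference: declare a separate structure instead).

.splitFields <- function(rest, line, lineno) {
  if (!nzchar(rest)) return(list())
  toks <- strsplit(trimws(rest), "[[:space:]]+")[[1L]]
  out <- list()
  for (tk in toks) {
    kv <- regmatches(tk, regexec("^([A-Za-z_][A-Za-z0-9_]*)=(.*)$", tk))[[1L]]
    if (length(kv) != 3L)
      stop(sprintf("config error (line %d): cannot parse token '%s' in: %s",
                   lineno, tk, line))
    out[[kv[2L]]] <- kv[3L]
  }
  out
}

.checkKeys <- function(fields, allowed, lineno, what) {
  bad <- setdiff(names(fields), allowed)
  if (length(bad))
    stop(sprintf("config error (line %d): unknown key '%s' in %s",
                 lineno, bad[1L], what))
}

.parseSpan <- function(x, lineno) {
  m <- regmatches(x, regexec("^([0-9]+):([0-9]+|\\*)$", x))[[1L]]
  if (length(m) != 3L)
    stop(sprintf("config error (line %d): bad span '%s'", lineno, x))
  list(start = as.integer(m[2L]),
       end = if (m[3L] == "*") NA_integer_ else as.integer(m[3L]))
}

#' Parse a process configuration
#'
#' Reads the sectioned key=value dialect documented in the package vignette
#' and returns a validated [PipelineConfig-class]. File paths referenced in
#' the configuration are recorded but not opened.
#'
#' @param text configuration text (character vector of lines or a single
#'   string), or `NULL` when `path` is given.
#' @param path path to a configuration file.
#' @return a validated [PipelineConfig-class].
#' @export
parseConfig <- function(text = NULL, path = NULL) {
  if (is.null(text)) text <- readLines(path)
  if (length(text) == 1L && grepl("\n", text))
    text <- strsplit(text, "\n", fixed = TRUE)[[1L]]

  structures <- list(); variables <- list(); destinations <- list()
  qual <- qualityPolicy()
  chunkSize <- 10000L; seed <- 1L

  section <- NULL; secName <- NULL
  curSegments <- NULL   # for [structure]
  curDest <- NULL       # for [destination]

  flushStructure <- function() {
    if (!is.null(curSegments))
      structures[[length(structures) + 1L]] <<-
        readStructure(secName, curSegments)
    curSegments <<- NULL
  }
  flushDestination <- function() {
    if (!is.null(curDest)) {
      f <- curDest$fields
      destinations[[length(destinations) + 1L]] <<- destinationSpec(
        name = curDest$name,
        sourceVariable = if (is.null(f$source)) NA else f$source,
        strategy = if (is.null(f$strategy)) "reassign" else f$strategy,
        units = curDest$units,
        padBase = if (is.null(f$pad)) "A" else f$pad,
        length = if (is.null(f$length)) NA else as.integer(f$length),
        tablePath = if (is.null(f$table)) NA else f$table,
        readIndex = if (is.null(f$read)) 0L else as.integer(f$read),
        order = if (is.null(f$order)) 0L else as.integer(f$order),
        constantSeq = if (is.null(f$sequence)) NA else f$sequence)
    }
    curDest <<- NULL
  }

  for (i in seq_along(text)) {
    line <- text[[i]]
    line <- sub("[[:space:]]*#.*$", "", line)
    line <- trimws(line)
    if (!nzchar(line)) next

    hdr <- regmatches(line,
      regexec("^\\[([a-z_]+)([[:space:]]+([A-Za-z0-9_.-]+))?\\]$", line))[[1L]]
    if (length(hdr)) {
      flushStructure(); flushDestination()
      section <- hdr[2L]; secName <- hdr[4L]
      if (!section %in% c("structure", "variables", "quality", "destination",
                          "options"))
        stop(sprintf("config error (line %d): unknown section '[%s]'",
                     i, section))
      if (section == "structure") {
        if (!nzchar(secName))
          stop(sprintf("config error (line %d): [structure] needs a name", i))
        curSegments <- list()
      }
      if (section == "destination") {
        if (!nzchar(secName))
          stop(sprintf("config error (line %d): [destination] needs a name", i))
        curDest <- list(name = secName, fields = list(), units = list())
      }
      next
    }
    if (is.null(section))
      stop(sprintf("config error (line %d): content before first section", i))

    if (section == "structure") {
      m <- regmatches(line,
        regexec("^segment[[:space:]]+([A-Za-z0-9_.-]+)[[:space:]]*(.*)$",
                line))[[1L]]
      if (!length(m))
        stop(sprintf("config error (line %d): expected 'segment <name> ...'",
                     i))
      anchored <- grepl("(^|[[:space:]])anchor([[:space:]]|$)", m[3L])
      if (anchored) {
        rest <- sub("(^|[[:space:]])anchor([[:space:]]|$)", " ", m[3L])
        fields <- .splitFields(rest, line, i)
        .checkKeys(fields, c("read", "upstream", "downstream", "inner",
                             "mismatch", "len"), i, "anchored segment")
        lens <- .parseSpan(if (is.null(fields$len)) "1:999999" else
          sub(":\\*$", ":999999", fields$len), i)
        curSegments[[length(curSegments) + 1L]] <- segmentSpec(
          name = m[2L], readIndex = as.integer(fields$read),
          upstream = if (is.null(fields$upstream)) NA else fields$upstream,
          downstream = if (is.null(fields$downstream)) NA else
            fields$downstream,
          innerExact = if (is.null(fields$inner)) 3L else
            as.integer(fields$inner),
          outerMaxMismatch = if (is.null(fields$mismatch)) 0L else
            as.integer(fields$mismatch),
          minLen = lens$start, maxLen = lens$end)
      } else {
        fields <- .splitFields(m[3L], line, i)
        .checkKeys(fields, c("read", "span"), i, "fixed segment")
        if (is.null(fields$span))
          stop(sprintf("config error (line %d): fixed segment needs span=", i))
        sp <- .parseSpan(fields$span, i)
        curSegments[[length(curSegments) + 1L]] <- segmentSpec(
          name = m[2L], readIndex = as.integer(fields$read),
          start = sp$start, end = sp$end)
      }
    } else if (section == "variables") {
      m <- regmatches(line,
        regexec("^variable[[:space:]]+([A-Za-z0-9_.-]+)[[:space:]]*(.*)$",
                line))[[1L]]
      if (!length(m))
        stop(sprintf("config error (line %d): expected 'variable <name> ...'",
                     i))
      fields <- .splitFields(m[3L], line, i)
      .checkKeys(fields, c("segments", "role", "parent", "correction",
                           "lev_max", "allowlist", "plugin", "valued"),
                 i, "variable")
      if (is.null(fields$segments))
        stop(sprintf("config error (line %d): variable needs segments=", i))
      variables[[length(variables) + 1L]] <- variableSpec(
        name = m[2L],
        segments = strsplit(fields$segments, ",", fixed = TRUE)[[1L]],
        role = if (is.null(fields$role)) "independent" else fields$role,
        parent = if (is.null(fields$parent)) NA else fields$parent,
        correction = if (is.null(fields$correction)) "none" else
          fields$correction,
        levMax = if (is.null(fields$lev_max)) 1L else
          as.integer(fields$lev_max),
        allowlistPath = if (is.null(fields$allowlist)) character(0) else
          strsplit(fields$allowlist, ",", fixed = TRUE)[[1L]],
        pluginCommand = if (is.null(fields$plugin)) NA else fields$plugin,
        valued = if (is.null(fields$valued)) NULL else
          fields$valued %in% c("yes", "true", "1"))
    } else if (section == "quality") {
      fields <- .splitFields(line, line, i)
      .checkKeys(fields, c("min_avg_q", "min_base_q", "applies_to"),
                 i, "[quality]")
      if (!is.null(fields$min_avg_q))
        qual@minAvgQ <- as.numeric(fields$min_avg_q)
      if (!is.null(fields$min_base_q))
        qual@minBaseQ <- as.numeric(fields$min_base_q)
      if (!is.null(fields$applies_to))
        qual@appliesTo <- strsplit(fields$applies_to, ",", fixed = TRUE)[[1L]]
      validObject(qual)
    } else if (section == "destination") {
      if (grepl("^unit([[:space:]]|$)", line)) {
        fields <- .splitFields(sub("^unit", "", line), line, i)
        .checkKeys(fields, c("template", "allowlist"), i, "destination unit")
        if (!is.null(fields$template))
          curDest$units[[length(curDest$units) + 1L]] <-
            list(kind = "iupac", template = fields$template)
        else if (!is.null(fields$allowlist))
          curDest$units[[length(curDest$units) + 1L]] <-
            list(kind = "allowlist", path = fields$allowlist)
        else stop(sprintf(
          "config error (line %d): unit needs template= or allowlist=", i))
      } else {
        fields <- .splitFields(line, line, i)
        .checkKeys(fields, c("source", "strategy", "read", "order", "length",
                             "pad", "table", "sequence"), i, "destination")
        curDest$fields[names(fields)] <- fields
      }
    } else if (section == "options") {
      fields <- .splitFields(line, line, i)
      .checkKeys(fields, c("chunk_size", "seed"), i, "[options]")
      if (!is.null(fields$chunk_size)) chunkSize <- as.integer(fields$chunk_size)
      if (!is.null(fields$seed)) seed <- as.integer(fields$seed)
    }
  }
  flushStructure(); flushDestination()

  pipelineConfig(structures = structures, variables = variables,
                 quality = qual, destinations = destinations,
                 chunkSize = chunkSize, seed = seed)
}

#' Serialize a PipelineConfig back to configuration text
#'
#' `parseConfig(formatConfig(cfg))` reproduces `cfg` exactly.
#'
#' @param cfg a [PipelineConfig-class].
#' @return character vector of configuration lines.
#' @export
formatConfig <- function(cfg) {
  out <- character(0)
  emit <- function(...) out <<- c(out, paste0(...))
  for (s in cfg@structures) {
    emit("[structure ", s@name, "]")
    for (x in s@segments) {
      if (x@locator == "fixed") {
        emit("segment ", x@name, " read=", x@readIndex, " span=", x@start,
             ":", if (is.na(x@end)) "*" else x@end)
      } else {
        emit("segment ", x@name, " read=", x@readIndex, " anchor",
             if (!is.na(x@upstream)) paste0(" upstream=", x@upstream) else "",
             if (!is.na(x@downstream))
               paste0(" downstream=", x@downstream) else "",
             " inner=", x@innerExact, " mismatch=", x@outerMaxMismatch,
             " len=", x@minLen, ":", x@maxLen)
      }
    }
    emit("")
  }
  emit("[variables]")
  for (v in cfg@variables) {
    emit("variable ", v@name,
         " segments=", paste(v@segments, collapse = ","),
         " role=", v@role,
         if (!is.na(v@parent)) paste0(" parent=", v@parent) else "",
         " correction=", v@correction,
         if (v@correction != "none") paste0(" lev_max=", v@levMax) else "",
         if (length(v@allowlistPath))
           paste0(" allowlist=", paste(v@allowlistPath, collapse = ","))
         else "",
         if (!is.na(v@pluginCommand))
           paste0(" plugin=", v@pluginCommand) else "",
         " valued=", if (v@valued) "yes" else "no")
  }
  emit("")
  emit("[quality]")
  emit("min_avg_q=", cfg@quality@minAvgQ, " min_base_q=", cfg@quality@minBaseQ,
       " applies_to=", paste(cfg@quality@appliesTo, collapse = ","))
  emit("")
  for (d in cfg@destinations) {
    emit("[destination ", d@name, "]")
    emit(if (!is.na(d@sourceVariable))
           paste0("source=", d@sourceVariable, " ") else "",
         "strategy=", d@strategy, " read=", d@readIndex, " order=", d@order,
         if (!is.na(d@length)) paste0(" length=", d@length) else "",
         if (d@strategy == "bequeath_pad") paste0(" pad=", d@padBase) else "",
         if (!is.na(d@tablePath)) paste0(" table=", d@tablePath) else "",
         if (!is.na(d@constantSeq))
           paste0(" sequence=", d@constantSeq) else "")
    for (u in d@units)
      emit("unit ", if (u$kind == "iupac") paste0("template=", u$template)
           else paste0("allowlist=", u$path))
    emit("")
  }
  emit("[options]")
  emit("chunk_size=", cfg@chunkSize, " seed=", cfg@seed)
  out
}
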