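#' @include AllClasses.R
NULL

#' Construct a SegmentSpec
#'
#' @param name segment identifier.
#' @param readIndex 0-based FASTQ file index within the read tuple.
#' @param start,end fixed span (0-based half-open); `end = NA` extends to the
#'   end of the read.
#' @param upstream,downstream anchor motifs for anchored locators.
#' @param innerExact exact-match bases of each motif adjacent to the segment.
#' @param outerMaxMismatch substitutions tolerated in the remaining motif.
#' @param minLen,maxLen admissible segment lengths (anchored locators).
#' @return a [SegmentSpec-class].
#' @export
segmentSpec <- function(name, readIndex, start = NA, end = NA,
                        upstream = NA, downstream = NA,
                        innerExact = 3L, outerMaxMismatch = 0L,
                        minLen = NA, maxLen = NA) {
  locator <- if (!is.na(start)) "fixed" else "anchored"
  new("SegmentSpec", name = name, readIndex = as.integer(readIndex),
      locator = locator, start = as.integer(start), end = as.integer(end),
      upstream = as.character(upstream), downstream = as.character(downstream),
      innerExact = as.integer(innerExact),
      outerMaxMismatch = as.integer(outerMaxMismatch),
      minLen = as.integer(minLen), maxLen = as.integer(maxLen))
}

#' Construct a VariableSpec
#'
#' @param name variable identifier.
#' @param segments ordered member segment names (several = combinatorial).
#' @param role `"independent"`, `"parental"` or `"local"`.
#' @param parent parent variable name (required when role is `"local"`).
#' @param correction `"imputation"`, `"allowlist"`, `"plugin"` or `"none"`.
#' @param levMax maximum Levenshtein distance for correction.
#' @param allowlistPath allowlist file path(s).
#' @param pluginCommand external plugin command.
#' @param valued whether the variable is value-encoded and translated;
#'   defaults to `TRUE` unless correction is `"none"`. Uncorrected but valued
#'   variables (UMIs) set `valued = TRUE` explicitly.
#' @return a [VariableSpec-class].
#' @export
variableSpec <- function(name, segments, role = "independent", parent = NA,
                         correction = "none", levMax = 1L,
                         allowlistPath = character(0),
                         pluginCommand = NA_character_, valued = NULL) {
  if (is.null(valued)) valued <- !identical(correction, "none")
  new("VariableSpec", name = name, segments = as.character(segments),
      role = role, parent = as.character(parent), correction = correction,
      levMax = as.integer(levMax), allowlistPath = as.character(allowlistPath),
      pluginCommand = as.character(pluginCommand), valued = isTRUE(valued))
}

#' Construct a QualityPolicy
#' @param minAvgQ,minBaseQ exclusive Phred thresholds (a segment at exactly
#'   the threshold passes).
#' @param appliesTo `"all"` or governed segment names.
#' @return a [QualityPolicy-class].
#' @export
qualityPolicy <- function(minAvgQ = 20, minBaseQ = 10, appliesTo = "all") {
  new("QualityPolicy", minAvgQ = as.numeric(minAvgQ),
      minBaseQ = as.numeric(minBaseQ), appliesTo = as.character(appliesTo))
}

#' Construct a DestinationSpec
#'
#' @param name destination segment identifier.
#' @param sourceVariable source variable name (`NA` for constants).
#' @param strategy reassign, bequeath_pad, conversion_table, passthrough or
#'   constant.
#' @param units list of units for reassign; each
#'   `list(kind = "iupac", template = "NN..")` or
#'   `list(kind = "allowlist", path = "...")`.
#' @param padBase pad base for bequeath_pad.
#' @param length destination length for bequeath_pad.
#' @param tablePath conversion-table path.
#' @param readIndex 0-based output read index.
#' @param order placement rank within the output read.
#' @param constantSeq literal filler sequence for constants.
#' @return a [DestinationSpec-class].
#' @export
destinationSpec <- function(name, sourceVariable = NA, strategy,
                            units = list(), padBase = "A", length = NA,
                            tablePath = NA, readIndex = 0L, order = 0L,
                            constantSeq = NA) {
  new("DestinationSpec", name = name,
      sourceVariable = as.character(sourceVariable), strategy = strategy,
      units = units, padBase = padBase, length = as.integer(length),
      tablePath = as.character(tablePath), readIndex = as.integer(readIndex),
      order = as.integer(order), constantSeq = as.character(constantSeq))
}

#' Construct a ReadStructure
#' @param name structure identifier.
#' @param segments list of [SegmentSpec-class] objects.
#' @return a [ReadStructure-class].
#' @export
readStructure <- function(name, segments) {
  new("ReadStructure", name = name, segments = segments)
}

#' Construct and validate a PipelineConfig
#'
#' @param structures list of [ReadStructure-class] objects; when a read
#'   matches several, the first declared structure claims it.
#' @param variables list of [VariableSpec-class] objects.
#' @param quality a [QualityPolicy-class].
#' @param destinations list of [DestinationSpec-class] objects.
#' @param chunkSize read tuples per processing chunk.
#' @param seed integer seed recorded in manifests.
#' @return a validated [PipelineConfig-class].
#' @export
pipelineConfig <- function(structures, variables, quality = qualityPolicy(),
                           destinations = list(), chunkSize = 10000L,
                           seed = 1L) {
  cfg <- new("PipelineConfig", structures = structures, variables = variables,
             quality = quality, destinations = destinations,
             chunkSize = as.integer(chunkSize), seed = as.integer(seed))
  validatePipelineConfig(cfg)
  cfg
}

# ---- cross-reference validation -------------------------------------------

#' Validate cross-references and invariants of a PipelineConfig
#'
#' Checks that every segment belongs to exactly one variable, that the
#' parental graph is a forest, that fixed spans do not overlap within a read,
#' and that destination references resolve. Paths are recorded but not
#' opened.
#'
#' @param cfg a [PipelineConfig-class].
#' @return invisibly `TRUE`; stops with a validation error otherwise.
#' @export
validatePipelineConfig <- function(cfg) {
  segNames <- unlist(lapply(cfg@structures, function(s)
    vapply(s@segments, function(x) x@name, "")))
  if (anyDuplicated(segNames))
    stop("validation error: segment name declared twice: ",
         segNames[duplicated(segNames)][1L])

  claimed <- unlist(lapply(cfg@variables, function(v) v@segments))
  if (anyDuplicated(claimed))
    stop("validation error: segment referenced by two variables: ",
         claimed[duplicated(claimed)][1L])
  missingSeg <- setdiff(claimed, segNames)
  if (length(missingSeg))
    stop("validation error: variable references unknown segment: ",
         missingSeg[1L])

  varNames <- vapply(cfg@variables, function(v) v@name, "")
  if (anyDuplicated(varNames))
    stop("validation error: duplicated variable name: ",
         varNames[duplicated(varNames)][1L])

  # parental graph must be a forest (no cycles, parents exist)
  parent <- setNames(vapply(cfg@variables, function(v) v@parent, ""), varNames)
  for (v in varNames) {
    p <- parent[[v]]
    if (!is.na(p) && !p %in% varNames)
      stop("validation error: parent variable '", p, "' of '", v,
           "' is not declared")
    seen <- character(0)
    cur <- v
    while (!is.na(parent[[cur]])) {
      if (cur %in% seen)
        stop("validation error: parental cycle involving variable '", cur, "'")
      seen <- c(seen, cur)
      cur <- parent[[cur]]
      if (cur %in% seen)
        stop("validation error: parental cycle involving variable '", cur, "'")
    }
  }

  # a variable's member segments must live in a single structure
  segOwner <- list()
  for (s in cfg@structures)
    for (x in s@segments) segOwner[[x@name]] <- s@name
  for (v in cfg@variables) {
    owners <- unique(unlist(segOwner[v@segments]))
    if (length(owners) > 1L)
      stop("validation error: variable '", v@name,
           "' spans segments of different structures")
  }

  # fixed spans within one read of one structure must not overlap; an
  # open-ended span must be rightmost on its read
  for (s in cfg@structures) {
    byRead <- split(s@segments,
                    vapply(s@segments, function(x) x@readIndex, 0L))
    for (segs in byRead) {
      fx <- Filter(function(x) x@locator == "fixed", segs)
      if (length(fx) < 2L) next
      starts <- vapply(fx, function(x) x@start, 0L)
      ends <- vapply(fx, function(x) x@end, 0L)
      o <- order(starts)
      starts <- starts[o]; ends <- ends[o]
      if (anyNA(ends[-length(ends)]))
        stop("validation error: open-ended span must be the rightmost ",
             "segment of its read in structure '", s@name, "'")
      if (any(ends[-length(ends)] > starts[-1L]))
        stop("validation error: overlapping fixed spans on one read in ",
             "structure '", s@name, "'")
    }
  }

  # destination references
  for (d in cfg@destinations) {
    if (d@strategy == "constant") next
    if (!d@sourceVariable %in% varNames)
      stop("validation error: destination '", d@name,
           "' references unknown variable '", d@sourceVariable, "'")
    v <- cfg@variables[[match(d@sourceVariable, varNames)]]
    if (d@strategy %in% c("reassign", "bequeath_pad", "conversion_table") &&
        !v@valued)
      stop("validation error: destination '", d@name,
           "' needs a valued source variable")
    if (d@strategy == "passthrough" && v@valued)
      stop("validation error: passthrough destination '", d@name,
           "' requires a pass-through (non-valued) source variable")
  }
  dnames <- vapply(cfg@destinations, function(d) d@name, "")
  if (anyDuplicated(dnames))
    stop("validation error: duplicated destination name: ",
         dnames[duplicated(dnames)][1L])
  place <- vapply(cfg@destinations, function(d)
    paste(d@readIndex, d@order), "")
  if (anyDuplicated(place))
    stop("validation error: two destinations share read/order placement")

  # IUPAC templates: uppercase known codes only
  for (d in cfg@destinations)
    for (u in d@units)
      if (identical(u$kind, "iupac")) {
        chars <- strsplit(u$template, "")[[1L]]
        if (!all(chars %in% names(IUPAC_SETS)))
          stop("validation error: IUPAC template '", u$template,
               "' contains unknown or lowercase codes")
      }
  invisible(TRUE)
}

# ---- variable/structure helpers -------------------------------------------

variableByName <- function(cfg, name) {
  for (v in cfg@variables) if (v@name == name) return(v)
  stop("unknown variable '", name, "'")
}

segmentOwnerStructure <- function(cfg) {
  out <- character(0)
  for (i in seq_along(cfg@structures))
    for (x in cfg@structures[[i]]@segments) out[[x@name]] <- names(i)
  out
}

# variables whose member segments belong to structure index i
variablesOfStructure <- function(cfg, i) {
  segs <- vapply(cfg@structures[[i]]@segments, function(x) x@name, "")
  Filter(function(v) all(v@segments %in% segs), cfg@variables)
}

# topological order of valued variables (parents before children)
variableTopoOrder <- function(cfg) {
  varNames <- vapply(cfg@variables, function(v) v@name, "")
  parent <- setNames(vapply(cfg@variables, function(v) v@parent, ""), varNames)
  depth <- vapply(varNames, function(v) {
    d <- 0L
    while (!is.na(parent[[v]])) { v <- parent[[v]]; d <- d + 1L }
    d
  }, 0L)
  varNames[order(depth, seq_along(varNames))]
}

# ancestor chain of a variable, root first, excluding the variable itself
variableAncestors <- function(cfg, name) {
  chain <- character(0)
  v <- variableByName(cfg, name)
  while (!is.na(v@parent)) {
    chain <- c(v@parent, chain)
    v <- variableByName(cfg, v@parent)
  }
  chain
}
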