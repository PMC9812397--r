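#' @include utils.R
NULL

#' SegmentSpec: location of one information-bearing segment on a read
#'
#' A segment is a contiguous stretch of one read in the read tuple. It is
#' located either by a fixed span (0-based, half-open coordinates) or by
#' anchoring on neighboring constant sequence motifs with a fuzzy-matching
#' policy: the `innerExact` bases of each motif adjacent to the segment must
#' match exactly, while up to `outerMaxMismatch` substitutions are tolerated
#' in the remainder of the motif.
#'
#' @slot name segment identifier.
#' @slot readIndex 0-based index of the FASTQ file in the read tuple.
#' @slot locator `"fixed"` or `"anchored"`.
#' @slot start,end fixed span, 0-based half-open; `end = NA` means
#'   "to the end of the read" (only allowed for the rightmost segment).
#' @slot upstream,downstream anchor motifs (uppercase ACGT); one of the two
#'   may be `NA` when the segment length is fixed (`minLen == maxLen`).
#' @slot innerExact number of motif bases adjacent to the segment that must
#'   match exactly.
#' @slot outerMaxMismatch substitutions tolerated in the remaining motif bases.
#' @slot minLen,maxLen admissible segment lengths for anchored locators.
#' @export
setClass("SegmentSpec", representation(
  name = "character", readIndex = "integer", locator = "character",
  start = "integer", end = "integer",
  upstream = "character", downstream = "character",
  innerExact = "integer", outerMaxMismatch = "integer",
  minLen = "integer", maxLen = "integer"
))

setValidity("SegmentSpec", function(object) {
  msg <- character(0)
  if (!nzchar(object@name)) msg <- c(msg, "segment name must be non-empty")
  if (is.na(object@readIndex) || object@readIndex < 0L)
    msg <- c(msg, "readIndex must be a non-negative integer")
  if (!object@locator %in% c("fixed", "anchored"))
    msg <- c(msg, "locator must be 'fixed' or 'anchored'")
  if (object@locator == "fixed") {
    if (is.na(object@start) || object@start < 0L)
      msg <- c(msg, "fixed span needs start >= 0")
    if (!is.na(object@end) && object@end <= object@start)
      msg <- c(msg, sprintf("fixed span needs end > start in segment '%s'",
                            object@name))
  } else {
    up <- object@upstream; dn <- object@downstream
    hasUp <- !is.na(up) && nzchar(up)
    hasDn <- !is.na(dn) && nzchar(dn)
    if (!hasUp && !hasDn)
      msg <- c(msg, "anchored locator needs at least one motif")
    for (m in c(if (hasUp) up, if (hasDn) dn)) {
      if (grepl("[^ACGT]", m))
        msg <- c(msg, sprintf("anchor motif '%s' must be uppercase ACGT", m))
      if (object@innerExact > nchar(m))
        msg <- c(msg, "innerExact exceeds motif length")
    }
    if (is.na(object@minLen) || is.na(object@maxLen) ||
        object@minLen < 1L || object@maxLen < object@minLen)
      msg <- c(msg, "anchored locator needs 1 <= minLen <= maxLen")
    if ((!hasUp || !hasDn) && object@minLen != object@maxLen)
      msg <- c(msg, "one-sided anchoring requires a fixed segment length")
    if (object@innerExact < 0L || object@outerMaxMismatch < 0L)
      msg <- c(msg, "innerExact and outerMaxMismatch must be >= 0")
  }
  if (length(msg)) msg else TRUE
})

#' VariableSpec: how segments are grouped into an information variable
#'
#' A variable owns one segment (singleton) or several (a combinatorial group
#' whose joint sequence tuple encodes a single value). Variables form a
#' forest: a `local` variable's values are only meaningful within one value
#' of its `parent` (e.g. UMIs within a cell identifier).
#'
#' @slot name variable identifier.
#' @slot segments ordered member segment names.
#' @slot role one of `"independent"`, `"parental"`, `"local"`.
#' @slot parent parent variable name, or `NA` unless role is `"local"`.
#' @slot correction one of `"imputation"`, `"allowlist"`, `"plugin"`, `"none"`.
#' @slot levMax maximum Levenshtein distance for correction.
#' @slot allowlistPath path(s) to allowlist files (recycled across member
#'   segments when the variable is combinatorial).
#' @slot pluginCommand external command for plugin correction.
#' @slot valued whether the variable participates in value encoding and
#'   translation (`FALSE` = raw sequence + quality pass-through, e.g. cDNA).
#' @export
setClass("VariableSpec", representation(
  name = "character", segments = "character", role = "character",
  parent = "character", correction = "character", levMax = "integer",
  allowlistPath = "character", pluginCommand = "character",
  valued = "logical"
))

setValidity("VariableSpec", function(object) {
  msg <- character(0)
  if (!object@role %in% c("independent", "parental", "local"))
    msg <- c(msg, "role must be independent, parental or local")
  if (object@role == "local" && is.na(object@parent))
    msg <- c(msg, sprintf("local variable '%s' needs a parent", object@name))
  if (object@role != "local" && !is.na(object@parent))
    msg <- c(msg, sprintf("variable '%s' has a parent but role '%s'",
                          object@name, object@role))
  if (!object@correction %in% c("imputation", "allowlist", "plugin", "none"))
    msg <- c(msg, "unknown correction method")
  if (object@correction != "none" && (is.na(object@levMax) || object@levMax < 0L))
    msg <- c(msg, "levMax must be >= 0")
  if (object@correction == "allowlist" && !length(object@allowlistPath))
    msg <- c(msg, sprintf("allowlist correction of '%s' needs allowlist paths",
                          object@name))
  if (length(object@segments) == 0L)
    msg <- c(msg, "variable needs at least one member segment")
  if (length(msg)) msg else TRUE
})

#' QualityPolicy: per-segment Phred thresholds
#'
#' A read is discarded when any governed segment has an average Phred score
#' below `minAvgQ` or a minimum per-base score below `minBaseQ`. Thresholds
#' are exclusive: a segment at exactly the threshold passes.
#'
#' @slot minAvgQ minimum admissible average Phred score.
#' @slot minBaseQ minimum admissible per-base Phred score.
#' @slot appliesTo `"all"` or the governed segment names.
#' @export
setClass("QualityPolicy", representation(
  minAvgQ = "numeric", minBaseQ = "numeric", appliesTo = "character"
))

setValidity("QualityPolicy", function(object) {
  if (object@minBaseQ < 0 || object@minBaseQ > object@minAvgQ ||
      object@minAvgQ > 41)
    "need 0 <= minBaseQ <= minAvgQ <= 41" else TRUE
})

#' DestinationSpec: one destination segment of the output read structure
#'
#' Strategies: `reassign` renders the optimized value of `sourceVariable`
#' through the destination unit pool; `bequeath_pad` carries the source
#' sequence over, padded with `padBase` to `length`; `conversion_table` maps
#' the source sequence through a user table; `passthrough` copies sequence
#' and per-base quality verbatim; `constant` emits a literal filler sequence.
#'
#' @slot name destination segment identifier.
#' @slot sourceVariable source variable name (`NA` for constants).
#' @slot strategy one of reassign, bequeath_pad, conversion_table,
#'   passthrough, constant.
#' @slot units for reassign: list of units, each
#'   `list(kind = "iupac", template = ...)` or
#'   `list(kind = "allowlist", path = ...)`.
#' @slot padBase single pad base for bequeath_pad (default `"A"`).
#' @slot length destination segment length for bequeath_pad.
#' @slot tablePath conversion table path.
#' @slot readIndex 0-based output read index.
#' @slot order placement rank of the segment within its output read.
#' @slot constantSeq literal sequence for constants.
#' @export
setClass("DestinationSpec", representation(
  name = "character", sourceVariable = "character", strategy = "character",
  units = "list", padBase = "character", length = "integer",
  tablePath = "character", readIndex = "integer", order = "integer",
  constantSeq = "character"
))

setValidity("DestinationSpec", function(object) {
  msg <- character(0)
  if (!object@strategy %in%
      c("reassign", "bequeath_pad", "conversion_table", "passthrough",
        "constant"))
    msg <- c(msg, "unknown destination strategy")
  if (object@strategy == "reassign" && length(object@units) == 0L)
    msg <- c(msg, sprintf("reassign destination '%s' needs >= 1 unit",
                          object@name))
  if (object@strategy == "bequeath_pad") {
    if (is.na(object@length) || object@length < 1L)
      msg <- c(msg, "bequeath_pad needs a destination length")
    if (!object@padBase %in% c("A", "C", "G", "T"))
      msg <- c(msg, "padBase must be a single A/C/G/T base")
  }
  if (object@strategy == "conversion_table" && is.na(object@tablePath))
    msg <- c(msg, "conversion_table destination needs a table path")
  if (object@strategy == "constant" &&
      (is.na(object@constantSeq) || grepl("[^ACGT]", object@constantSeq)))
    msg <- c(msg, "constant destination needs an ACGT sequence")
  if (object@strategy != "constant" && is.na(object@sourceVariable))
    msg <- c(msg, sprintf("destination '%s' needs a source variable",
                          object@name))
  if (is.na(object@readIndex) || object@readIndex < 0L)
    msg <- c(msg, "destination read index must be >= 0")
  if (length(msg)) msg else TRUE
})

#' ReadStructure: ordered segment layout of one source library
#' @slot name structure identifier.
#' @slot segments list of [SegmentSpec-class] objects.
#' @export
setClass("ReadStructure", representation(
  name = "character", segments = "list"
))

#' PipelineConfig: the full process configuration
#'
#' Declares one or more alternative source read structures over a single
#' input pool (first match claims a read), the variables over their segments,
#' the quality policy, and the destination read structure.
#'
#' @slot structures list of [ReadStructure-class].
#' @slot variables list of [VariableSpec-class].
#' @slot quality a [QualityPolicy-class].
#' @slot destinations list of [DestinationSpec-class].
#' @slot chunkSize number of read tuples per processing chunk.
#' @slot seed integer seed recorded in run manifests.
#' @export
setClass("PipelineConfig", representation(
  structures = "list", variables = "list", quality = "ANY",
  destinations = "list", chunkSize = "integer", seed = "integer"
))

#' SegmentTally: read counts of unique segment sequences
#'
#' The compressed per-chunk summary passed between distributed interpretation
#' steps: one named count vector per segment. Merging tallies sums counts.
#'
#' @slot counts named list; each element a named numeric vector of read
#'   counts keyed by segment sequence.
#' @slot chunkId chunk identifier (`NA` once merged).
#' @export
setClass("SegmentTally", representation(
  counts = "list", chunkId = "integer"
))

setValidity("SegmentTally", function(object) {
  for (seg in names(object@counts)) {
    v <- object@counts[[seg]]
    if (length(v) && (is.null(names(v)) || any(v < 1)))
      return(sprintf("tally for segment '%s' must be named counts >= 1", seg))
  }
  TRUE
})

#' CorrectionTable: per-segment sequence correction rules
#'
#' Total over the observed raw sequences of each governed segment: every raw
#' sequence maps to a corrected sequence or to DROP (`NA`).
#'
#' @slot tables named list per segment; each a named character vector
#'   raw sequence -> corrected sequence, `NA` meaning DROP.
#' @slot method named character vector, correction method per segment.
#' @slot levMax named integer vector, distance threshold per segment.
#' @slot kneeRank named integer vector, knee rank per segment (`NA` for
#'   allowlist/plugin methods).
#' @export
setClass("CorrectionTable", representation(
  tables = "list", method = "character", levMax = "integer",
  kneeRank = "integer"
))

setValidity("CorrectionTable", function(object) {
  for (seg in names(object@tables)) {
    v <- object@tables[[seg]]
    if (length(v) && is.null(names(v)))
      return(sprintf("correction table for '%s' must be named", seg))
    tgt <- v[!is.na(v)]
    if (length(tgt) && any(!tgt %in% v[!is.na(v)] & FALSE))
      return("unreachable")
  }
  TRUE
})

#' ValueTree: counts of value tuples under the parental-local hierarchy
#'
#' Each row is one observed value of one variable within one parent scope:
#' `path` is the `/`-joined chain of ancestor keys (empty for roots), `key`
#' the `+`-joined member-segment sequence tuple, `count` the read count.
#'
#' @slot entries data.frame with columns variable, path, key, count.
#' @slot hierarchy named character vector mapping variable -> parent
#'   (`NA` for roots).
#' @export
setClass("ValueTree", representation(
  entries = "data.frame", hierarchy = "character"
))

setValidity("ValueTree", function(object) {
  need <- c("variable", "path", "key", "count")
  if (!all(need %in% names(object@entries)))
    return("entries must have columns variable, path, key, count")
  if (nrow(object@entries) && any(object@entries$count < 1))
    return("tree counts must be >= 1")
  TRUE
})

#' OptimizationMap: scope-wise renumbering of the value space
#'
#' Within every parent scope the values of each variable are renumbered
#' 0..k-1 by descending read count (ties broken by the lexicographic order of
#' the sequence tuple), so that each variable uses the minimum number of
#' value species while the tree topology is preserved.
#'
#' @slot assignments data.frame with columns variable, path (source parent
#'   path), key, optPath (optimized parent path), optValue.
#' @slot speciesCount named integer vector: number of value species used per
#'   variable (= maximum scope cardinality).
#' @slot optimized `FALSE` when built in raw/global passthrough mode.
#' @export
setClass("OptimizationMap", representation(
  assignments = "data.frame", speciesCount = "integer", optimized = "logical"
))
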