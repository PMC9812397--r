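#' @include AllClasses.R
NULL

#' Number of value species used per variable
#' @param x an [OptimizationMap-class].
#' @return named integer vector.
#' @export
setGeneric("speciesCount", function(x) standardGeneric("speciesCount"))

#' @rdname speciesCount
#' @export
setMethod("speciesCount", "OptimizationMap", function(x) x@speciesCount)

#' Entries of a value tree
#' @param x a [ValueTree-class].
#' @return data.frame with columns variable, path, key, count.
#' @export
setGeneric("treeEntries", function(x) standardGeneric("treeEntries"))

#' @rdname treeEntries
#' @export
setMethod("treeEntries", "ValueTree", function(x) x@entries)

#' Correction rules of one segment
#' @param x a [CorrectionTable-class].
#' @param segment segment name.
#' @return named character vector raw -> corrected (`NA` = DROP).
#' @export
setGeneric("correctionRules", function(x, segment) {
  standardGeneric("correctionRules")
})

#' @rdname correctionRules
#' @export
setMethod("correctionRules", "CorrectionTable", function(x, segment) {
  if (!segment %in% names(x@tables))
    stop("no correction table for segment '", segment, "'")
  x@tables[[segment]]
})

#' Per-segment sequence counts of a tally
#' @param x a [SegmentTally-class].
#' @param segment segment name; all segments when missing.
#' @return named numeric vector of counts, or the full list.
#' @export
setGeneric("tallyCounts", function(x, segment) standardGeneric("tallyCounts"))

#' @rdname tallyCounts
#' @export
setMethod("tallyCounts", "SegmentTally", function(x, segment) {
  if (missing(segment)) return(x@counts)
  x@counts[[segment]]
})

setMethod("show", "PipelineConfig", function(object) {
  cat("PipelineConfig:", length(object@structures), "source structure(s),",
      length(object@variables), "variable(s),",
      length(object@destinations), "destination segment(s)\n")
  for (s in object@structures)
    cat("  structure '", s@name, "': ",
        paste(vapply(s@segments, function(x) x@name, ""), collapse = ", "),
        "\n", sep = "")
  for (v in object@variables)
    cat("  variable '", v@name, "' (", v@role,
        if (!is.na(v@parent)) paste0(" of ", v@parent) else "",
        ", correction=", v@correction, ")\n", sep = "")
})

setMethod("show", "SegmentTally", function(object) {
  cat("SegmentTally over", length(object@counts), "segment(s)\n")
  for (seg in names(object@counts))
    cat(sprintf("  %s: %d unique sequences, %d reads\n", seg,
                length(object@counts[[seg]]), sum(object@counts[[seg]])))
})

setMethod("show", "CorrectionTable", function(object) {
  cat("CorrectionTable for", length(object@tables), "segment(s)\n")
  for (seg in names(object@tables)) {
    v <- object@tables[[seg]]
    cat(sprintf("  %s [%s]: %d rules (%d drop)%s\n", seg,
                object@method[[seg]], length(v), sum(is.na(v)),
                if (!is.na(object@kneeRank[[seg]]))
                  sprintf(", knee rank %d", object@kneeRank[[seg]]) else ""))
  }
})

setMethod("show", "ValueTree", function(object) {
  cat("ValueTree:", nrow(object@entries), "value entries over",
      length(object@hierarchy), "variable(s)\n")
  for (v in names(object@hierarchy)) {
    e <- object@entries[object@entries$variable == v, , drop = FALSE]
    cat(sprintf("  %s%s: %d values in %d scope(s), %d reads\n", v,
                if (!is.na(object@hierarchy[[v]]))
                  paste0(" (local to ", object@hierarchy[[v]], ")") else "",
                nrow(e), length(unique(e$path)), sum(e$count)))
  }
})

setMethod("show", "OptimizationMap", function(object) {
  cat("OptimizationMap (", if (object@optimized) "scope-wise optimized"
      else "raw global values", ")\n", sep = "")
  for (v in names(object@speciesCount))
    cat(sprintf("  %s: %d value species\n", v, object@speciesCount[[v]]))
})
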