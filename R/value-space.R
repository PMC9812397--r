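#' @include correction.R
NULL

# Per-record value keys: for each valued variable present in `records`
# (structure-matched subsets), add columns key_<var> (the "+"-joined member
# segment tuple), path_<var> (the "/"-joined chain of ancestor keys, empty
# for roots) and avgq_var_<var> (mean of member segment average qualities).
addValueColumns <- function(records, cfg) {
  if (nrow(records) == 0L) return(records)
  for (vname in variableTopoOrder(cfg)) {
    v <- variableByName(cfg, vname)
    if (!v@valued) next
    segCols <- paste0("seq_", v@segments)
    if (!all(segCols %in% names(records))) next
    present <- !is.na(records[[segCols[[1L]]]])
    key <- if (length(segCols) == 1L) records[[segCols]]
           else do.call(paste, c(records[segCols], sep = TUPLE_SEP))
    key[!present] <- NA_character_
    records[[paste0("key_", vname)]] <- key
    qCols <- paste0("avgq_", v@segments)
    avg <- if (length(qCols) == 1L) records[[qCols]]
           else rowMeans(as.matrix(records[qCols]))
    records[[paste0("avgq_var_", vname)]] <- avg
    if (is.na(v@parent)) {
      records[[paste0("path_", vname)]] <- ifelse(present, "", NA_character_)
    } else {
      pPath <- records[[paste0("path_", v@parent)]]
      pKey <- records[[paste0("key_", v@parent)]]
      if (is.null(pPath))
        stop("internal error: parent variable '", v@parent,
             "' not valued before '", vname, "'")
      records[[paste0("path_", vname)]] <- joinPath(pPath, pKey)
    }
  }
  records
}

#' Encode corrected records into a value tree
#'
#' Each unique corrected segment-sequence tuple of a valued variable is one
#' value; values of a local variable live in independent scopes, one per
#' observed value path of its parent chain, so the same UMI sequence under
#' different cell identifiers is a different object. Counts equal record
#' multiplicities.
#'
#' @param records corrected data.frame (from [applyCorrection()]).
#' @param cfg a [PipelineConfig-class].
#' @return list with `records` (with key_/path_ columns added) and `tree`
#'   (a [ValueTree-class]).
#' @export
encodeValues <- function(records, cfg) {
  records <- addValueColumns(records, cfg)
  vnames <- vapply(cfg@variables, function(v) v@name, "")
  valued <- vnames[vapply(cfg@variables, function(v) v@valued, TRUE)]
  hier <- setNames(vapply(cfg@variables, function(v) v@parent, ""), vnames)
  hier <- hier[valued]
  rows <- list()
  for (vname in valued) {
    kc <- records[[paste0("key_", vname)]]
    if (is.null(kc)) next
    pc <- records[[paste0("path_", vname)]]
    keep <- !is.na(kc)
    if (!any(keep)) next
    fac <- paste(pc[keep], kc[keep], sep = "\r")
    agg <- rowsum(rep(1, sum(keep)), fac)
    parts <- strsplit(rownames(agg), "\r", fixed = TRUE)
    rows[[vname]] <- data.frame(
      variable = vname,
      path = vapply(parts, function(p) if (length(p) > 1L) p[[1L]] else "",
                    ""),
      key = vapply(parts, function(p) p[[length(p)]], ""),
      count = agg[, 1L], stringsAsFactors = FALSE)
  }
  entries <- if (length(rows)) do.call(rbind, rows) else
    data.frame(variable = character(0), path = character(0),
               key = character(0), count = numeric(0))
  rownames(entries) <- NULL
  list(records = records,
       tree = new("ValueTree", entries = entries, hierarchy = hier))
}

#' Merge value trees from different chunks
#'
#' Scopes are unioned and counts summed; value identity is sequence-keyed,
#' so the merge equals a single-pass encoding of the concatenated input.
#'
#' @param trees list of [ValueTree-class] objects with identical hierarchies.
#' @return a merged [ValueTree-class].
#' @export
mergeValueTrees <- function(trees) {
  if (!length(trees))
    return(new("ValueTree",
               entries = data.frame(variable = character(0),
                                    path = character(0), key = character(0),
                                    count = numeric(0)),
               hierarchy = setNames(character(0), character(0))))
  h0 <- trees[[1L]]@hierarchy
  for (t in trees[-1L])
    if (!identical(t@hierarchy, h0))
      stop("value-tree hierarchy mismatch between chunks")
  all <- do.call(rbind, lapply(trees, function(t) t@entries))
  if (nrow(all) == 0L)
    return(new("ValueTree", entries = all, hierarchy = h0))
  fac <- paste(all$variable, all$path, all$key, sep = "\r")
  agg <- rowsum(all$count, fac)
  first <- !duplicated(fac)
  out <- all[first, c("variable", "path", "key")]
  out$count <- agg[match(fac[first], rownames(agg)), 1L]
  out <- out[order(out$variable, out$path, out$key), , drop = FALSE]
  rownames(out) <- NULL
  new("ValueTree", entries = out, hierarchy = h0)
}

#' Optimize the value space of a merged tree
#'
#' Values are renumbered scope-by-scope to minimize the number of value
#' species per variable while uniquely preserving the tree topology: root
#' variables are renumbered 0..n-1 by descending total count; every local
#' variable is renumbered independently within each parent scope 0..k-1 by
#' descending in-scope count (frequent values get small numbers, so they
#' survive a capacity cut), recursing through multilayer hierarchies with
#' scope paths expressed in the parent's optimized values. Frequency ties
#' are broken by the lexicographic order of the sequence tuple. The species
#' count of a variable equals its maximum scope cardinality, which no
#' topology-preserving renumbering can undercut.
#'
#' @param tree a merged [ValueTree-class].
#' @return an [OptimizationMap-class].
#' @export
optimizeValueSpace <- function(tree) {
  e <- tree@entries
  hier <- tree@hierarchy
  vnames <- names(hier)
  depth <- vapply(vnames, function(v) {
    d <- 0L
    while (!is.na(hier[[v]])) { v <- hier[[v]]; d <- d + 1L }
    d
  }, 0L)
  order_ <- vnames[order(depth, seq_along(vnames))]
  # source path -> optimized path translation, built level by level
  pathMap <- list()  # per variable: named chr, srcPath(+key) -> optPath(+val)
  assign <- list()
  species <- setNames(integer(length(vnames)), vnames)
  for (vname in order_) {
    rows <- e[e$variable == vname, , drop = FALSE]
    if (nrow(rows) == 0L) { species[[vname]] <- 0L; next }
    parent <- hier[[vname]]
    optPath <- if (is.na(parent)) rows$path else {
      pm <- pathMap[[parent]]
      got <- pm[rows$path]
      if (anyNA(got))
        stop("value tree inconsistency: scope path of '", vname,
             "' not found under parent '", parent, "'")
      unname(got)
    }
    o <- order(optPath, -rows$count, rows$key)
    rows <- rows[o, , drop = FALSE]
    op <- optPath[o]
    newScope <- !duplicated(op)
    optValue <- seq_len(nrow(rows)) -
      rep(which(newScope), diff(c(which(newScope), nrow(rows) + 1L)))
    rows$optPath <- op
    rows$optValue <- as.integer(optValue)
    species[[vname]] <- max(table(op))
    pathMap[[vname]] <- setNames(
      joinPath(op, as.character(rows$optValue)),
      joinPath(rows$path, rows$key))
    assign[[vname]] <- rows
  }
  out <- if (length(assign)) do.call(rbind, assign) else
    data.frame(variable = character(0), path = character(0),
               key = character(0), count = numeric(0),
               optPath = character(0), optValue = integer(0))
  rownames(out) <- NULL
  new("OptimizationMap", assignments = out,
      speciesCount = vapply(species, as.integer, 0L), optimized = TRUE)
}

#' Raw (global) value map: the optimization-off control
#'
#' Every variable's distinct sequence tuples are enumerated globally (all
#' scopes pooled), ordered by descending total count then lexicographically,
#' and numbered 0..n-1. Used to reproduce degraded translations where the
#' parental-local structure is ignored, so a destination segment must host
#' every value species of the whole dataset.
#'
#' @param tree a merged [ValueTree-class].
#' @return an [OptimizationMap-class] with `optimized = FALSE`.
#' @export
rawValueMap <- function(tree) {
  e <- tree@entries
  assign <- list()
  species <- setNames(integer(length(tree@hierarchy)), names(tree@hierarchy))
  for (vname in names(tree@hierarchy)) {
    rows <- e[e$variable == vname, , drop = FALSE]
    if (nrow(rows) == 0L) { species[[vname]] <- 0L; next }
    tot <- rowsum(rows$count, rows$key)
    keys <- rownames(tot)
    o <- order(-tot[, 1L], keys)
    val <- setNames(seq_along(keys) - 1L, keys[o])
    rows$optPath <- ""
    rows$optValue <- as.integer(val[rows$key])
    species[[vname]] <- length(keys)
    assign[[vname]] <- rows
  }
  out <- if (length(assign)) do.call(rbind, assign) else
    data.frame(variable = character(0), path = character(0),
               key = character(0), count = numeric(0),
               optPath = character(0), optValue = integer(0))
  rownames(out) <- NULL
  new("OptimizationMap", assignments = out, speciesCount = species,
      optimized = FALSE)
}
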