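# Independent oracles and small fixture builders used across the suite.

# Dynamic-programming Levenshtein distance, written independently of the
# package's implementation. N matches nothing, including another N.
dpEdit <- function(a, b) {
  x <- strsplit(a, "")[[1L]]
  y <- strsplit(b, "")[[1L]]
  n <- length(x); m <- length(y)
  prev <- 0:m
  for (i in seq_len(n)) {
    cur <- numeric(m + 1L)
    cur[1L] <- i
    for (j in seq_len(m)) {
      subCost <- if (x[i] == y[j] && x[i] != "N") 0L else 1L
      cur[j + 1L] <- min(prev[j] + subCost, prev[j + 1L] + 1L, cur[j] + 1L)
    }
    prev <- cur
  }
  prev[m + 1L]
}

# Brute-force knee oracle: maximum turn angle over ALL interior vertices of
# the uncollapsed (log10 rank, log10 count) polyline; ties -> smaller rank;
# degenerate curves accept everything.
kneeOracle <- function(counts) {
  n <- length(counts)
  if (n <= 2L || length(unique(counts)) == 1L) return(n)
  x <- log10(seq_len(n)); y <- log10(counts)
  best <- -Inf; bestRank <- n
  for (v in 2:(n - 1L)) {
    d1 <- c(x[v] - x[v - 1L], y[v] - y[v - 1L])
    d2 <- c(x[v + 1L] - x[v], y[v + 1L] - y[v])
    u1 <- d1 / sqrt(sum(d1^2)); u2 <- d2 / sqrt(sum(d2^2))
    ang <- acos(min(1, max(-1, sum(u1 * u2))))
    if (ang > best + 1e-12) { best <- ang; bestRank <- v }
  }
  bestRank
}

# Does an injective assignment of `s` scope members into k values exist?
# Exhaustive search (the trivial answer is s <= k; the search keeps the
# oracle independent of that insight).
existsInjection <- function(s, k) {
  recur <- function(i, used) {
    if (i > s) return(TRUE)
    for (v in seq_len(k)) {
      if (!used[v] && recur(i + 1L, replace(used, v, TRUE))) return(TRUE)
    }
    FALSE
  }
  if (k == 0L) return(s == 0L)
  recur(1L, rep(FALSE, k))
}

# Random parental-local value tree with small scopes, for minimality and
# topology-preservation checks.
randomValueTree <- function(maxRoots = 4L, maxKids = 4L, threeLayer = FALSE) {
  hier <- c(root = NA_character_, kid = "root")
  if (threeLayer) hier <- c(hier, grand = "kid")
  nRoots <- sample.int(maxRoots, 1L)
  rows <- list()
  rootKeys <- paste0("R", seq_len(nRoots))
  rows[[1L]] <- data.frame(variable = "root", path = "", key = rootKeys,
                           count = sample.int(50L, nRoots, replace = TRUE),
                           stringsAsFactors = FALSE)
  kidPaths <- character(0); kidKeys <- character(0)
  for (r in rootKeys) {
    nk <- sample.int(maxKids, 1L)
    keys <- paste0("k", seq_len(nk))
    rows[[length(rows) + 1L]] <- data.frame(
      variable = "kid", path = r, key = keys,
      count = sample.int(30L, nk, replace = TRUE), stringsAsFactors = FALSE)
    kidPaths <- c(kidPaths, rep(r, nk)); kidKeys <- c(kidKeys, keys)
  }
  if (threeLayer) {
    for (i in seq_along(kidKeys)) {
      ng <- sample.int(3L, 1L)
      rows[[length(rows) + 1L]] <- data.frame(
        variable = "grand", path = paste(kidPaths[i], kidKeys[i], sep = "/"),
        key = paste0("g", seq_len(ng)),
        count = sample.int(10L, ng, replace = TRUE), stringsAsFactors = FALSE)
    }
  }
  new("ValueTree", entries = do.call(rbind, rows), hierarchy = hier)
}

# In-memory read-tuple chunk for extractSegments().
makeTuples <- function(seqsPerFile, quals = NULL, ids = NULL) {
  n <- length(seqsPerFile[[1L]])
  if (is.null(ids)) ids <- sprintf("r%03d", seq_len(n))
  if (is.null(quals))
    quals <- lapply(seqsPerFile, function(s) strrep("F", nchar(s)))
  list(ids = ids, seqs = seqsPerFile, quals = quals, chunk = 1L)
}

readFastqAll <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  list(ids = names(x), seqs = unname(as.character(x)),
       quals = unname(as.character(S4Vectors::mcols(x)$qualities)))
}

readAllCorrected <- function(interpDir) {
  fl <- sort(list.files(file.path(interpDir, "corrected"),
                        full.names = TRUE))
  do.call(rbind, lapply(fl, seqBabel:::.readRecordsTsv))
}

# Minimal one-structure config: 16-base cell + 12-base UMI on read 1,
# open-ended payload on read 2.
simpleScrnaConfig <- function(correction = "none",
                              destinations = list()) {
  segs <- list(segmentSpec("cellSeg", 0L, start = 0L, end = 16L),
               segmentSpec("umiSeg", 0L, start = 16L, end = 28L),
               segmentSpec("cdnaSeg", 1L, start = 0L, end = NA))
  vars <- list(
    variableSpec("cell", "cellSeg", role = "parental",
                 correction = correction, levMax = 1L, valued = TRUE),
    variableSpec("umi", "umiSeg", role = "local", parent = "cell",
                 correction = "none", valued = TRUE),
    variableSpec("cdna", "cdnaSeg", correction = "none"))
  pipelineConfig(list(readStructure("scrna", segs)), vars,
                 qualityPolicy(20, 10), destinations)
}
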