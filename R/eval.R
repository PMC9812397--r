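#' @include spatial.R
#' @importFrom stats wilcox.test
NULL

#' Distinct-UMI count matrix per (cell, gene tag)
#'
#' @param cells,genes,umis parallel character vectors: per-read cell value,
#'   gene tag and UMI value.
#' @return integer matrix, rows = cells, columns = gene tags, entries =
#'   number of distinct UMIs observed for the pair.
#' @export
umiCountMatrix <- function(cells, genes, umis) {
  if (!length(cells))
    return(matrix(integer(0), 0L, 0L))
  trip <- paste(cells, genes, umis, sep = "\r")
  first <- !duplicated(trip)
  tb <- table(cells[first], genes[first])
  m <- matrix(as.integer(tb), nrow(tb), ncol(tb),
              dimnames = dimnames(tb))
  m
}

#' Rank-difference statistic between two high-dimensional embeddings
#'
#' Samples pairs of shared data points, measures their Euclidean distances
#' in both datasets, ranks the distances within each sampled set, and
#' reports the per-pair absolute rank difference. The null distribution
#' ranks a second, independently sampled pair set in the second dataset, so
#' it reflects no preserved pair structure. Summarized by a two-sided
#' Wilcoxon rank-sum comparison of the two distributions.
#'
#' @param x,y numeric matrices with identical row names (data points) in
#'   possibly different feature spaces.
#' @param nPairs number of sampled point pairs.
#' @param seed integer seed for pair sampling.
#' @return list with `delta` (observed |rank difference| per pair), `null`
#'   (null |rank difference|), and `test` (the `wilcox.test` result, `NULL`
#'   when degenerate).
#' @export
rankDifferenceStat <- function(x, y, nPairs = 1000L, seed = 1L) {
  ids <- intersect(rownames(x), rownames(y))
  if (length(ids) < 2L)
    stop("x and y must share at least two row identifiers")
  if (!setequal(rownames(x), rownames(y)))
    stop("row identifier mismatch between the two datasets")
  x <- x[ids, , drop = FALSE]
  y <- y[ids, , drop = FALSE]
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed",
                                                     .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  samplePairs <- function() {
    i <- sample.int(length(ids), nPairs, replace = TRUE)
    j <- sample.int(length(ids) - 1L, nPairs, replace = TRUE)
    j <- ifelse(j >= i, j + 1L, j)  # j != i, uniform over ordered pairs
    cbind(i, j)
  }
  pdist <- function(m, p) sqrt(rowSums((m[p[, 1L], , drop = FALSE] -
                                        m[p[, 2L], , drop = FALSE])^2))
  p1 <- samplePairs()
  r1 <- rank(pdist(x, p1))
  r2 <- rank(pdist(y, p1))
  delta <- abs(r1 - r2)
  p2 <- samplePairs()
  r3 <- rank(pdist(y, p2))
  null <- abs(r1 - r3)
  test <- if (stats::sd(c(delta, null)) > 0)
    wilcox.test(delta, null, exact = FALSE) else NULL
  list(delta = delta, null = null, test = test)
}

#' Call clonal wells from row-column-plate PCR tallies
#'
#' Two library structures cover each well: Tag reads encode both the Uptag
#' and the Dntag; Lox reads encode one tag plus the recombination sites. A
#' well is called clonal when (i) the most frequent Uptag and Dntag both
#' occupy strictly more than 50% of the well's Tag reads, (ii) at least 70%
#' of the well's Lox reads encode intact recombination sites, (iii) the most
#' frequent tag in the Lox reads also occupies strictly more than 50%, and
#' (iv) the dominant Tag-read and Lox-read tags agree. Anything else is
#' rejected with the first failing reason.
#'
#' @param tagReads data.frame with columns `well`, `uptag`, `dntag` (one row
#'   per Tag-structure read).
#' @param loxReads data.frame with columns `well`, `tag` (the tag carried by
#'   the Lox structure) and `loxValid` (logical, recombination sites
#'   intact).
#' @param whichTag `"uptag"` or `"dntag"`: which tag the Lox structure
#'   carries.
#' @return data.frame per well: dominant tags, occupancies, lox-valid
#'   fraction, verdict (`clonal` logical) and `reason`.
#' @export
callClonalWells <- function(tagReads, loxReads, whichTag = "uptag") {
  wells <- sort(unique(c(tagReads$well, loxReads$well)))
  dominant <- function(v) {
    if (!length(v)) return(list(tag = NA_character_, occ = 0))
    tb <- sort(table(v), decreasing = TRUE)
    list(tag = names(tb)[[1L]], occ = as.numeric(tb[[1L]]) / length(v))
  }
  out <- lapply(wells, function(w) {
    tg <- tagReads[tagReads$well == w, , drop = FALSE]
    lx <- loxReads[loxReads$well == w, , drop = FALSE]
    up <- dominant(tg$uptag)
    dn <- dominant(tg$dntag)
    lt <- dominant(lx$tag)
    loxFrac <- if (nrow(lx)) mean(lx$loxValid) else 0
    reason <- "clonal"
    if (up$occ <= 0.5 || dn$occ <= 0.5) reason <- "tag_not_dominant"
    else if (loxFrac < 0.7) reason <- "lox_invalid"
    else if (lt$occ <= 0.5) reason <- "lox_tag_not_dominant"
    else if (!identical(lt$tag, if (whichTag == "uptag") up$tag else dn$tag))
      reason <- "conflict"
    data.frame(well = w, uptag = up$tag, dntag = dn$tag,
               uptagOcc = up$occ, dntagOcc = dn$occ,
               loxTag = lt$tag, loxTagOcc = lt$occ, loxValidFrac = loxFrac,
               clonal = reason == "clonal", reason = reason,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
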