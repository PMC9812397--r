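#' @import methods
#' @importFrom stats setNames
NULL

# Standard IUPAC degenerate nucleotide codes, each expanded to its base set in
# alphabetical order. Lowercase codes are rejected at config validation.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Encode integer Phred scores as FASTQ (Phred+33) characters
#'
#' @param q integer vector of Phred scores.
#' @return character vector of single quality characters.
#' @keywords internal
phredChars <- function(q) {
  rawToChar(as.raw(as.integer(q) + 33L), multiple = TRUE)
}

#' Decode a Phred+33 quality string to integer scores
#' @param s single quality string.
#' @return integer vector of Phred scores.
#' @keywords internal
phredInts <- function(s) {
  if (nchar(s) == 0L) return(integer(0))
  utf8ToInt(s) - 33L
}

# Mean/min Phred over a vector of equal-width quality substrings.
# Uses one utf8ToInt call over the concatenation: fast for large chunks.
qualStatsFixed <- function(qsub) {
  n <- length(qsub)
  if (n == 0L) return(list(avg = numeric(0), min = integer(0)))
  w <- nchar(qsub[1L])
  if (w == 0L) return(list(avg = rep(NA_real_, n), min = rep(NA_integer_, n)))
  m <- matrix(utf8ToInt(paste(qsub, collapse = "")) - 33L, nrow = w)
  list(avg = colMeans(m), min = Reduce(pmin, asplit(m, 1L)))
}

# Mean/min Phred over variable-width quality substrings.
qualStatsVar <- function(qsub) {
  st <- vapply(qsub, function(s) {
    if (nchar(s) == 0L) return(c(NA_real_, NA_real_))
    v <- utf8ToInt(s) - 33L
    c(mean(v), min(v))
  }, numeric(2), USE.NAMES = FALSE)
  list(avg = st[1L, ], min = as.integer(st[2L, ]))
}

#' Levenshtein distances between two sets of DNA sequences
#'
#' Unit-cost edit distance over \{A,C,G,T,N\}. `N` is treated as matching
#' nothing, including another `N` (it marks an uncalled base, not a wildcard),
#' implemented by masking `N` to distinct sentinels on the two sides.
#'
#' @param a,b character vectors of uppercase DNA sequences.
#' @return integer matrix of dimension `length(a)` x `length(b)`.
#' @export
levenshteinDist <- function(a, b) {
  am <- chartr("N", "#", a)
  bm <- chartr("N", "%", b)
  d <- utils::adist(am, bm)
  storage.mode(d) <- "integer"
  dimnames(d) <- list(a, b)
  d
}

# Round half-up (floor(x + .5)); base round() rounds half to even.
roundHalfUp <- function(x) floor(x + 0.5)

readTsv <- function(path, ...) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE, ...)
}

writeTsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an allowlist file
#'
#' One uppercase DNA sequence per line; blank lines ignored. File order is
#' meaningful: it defines the index-to-sequence mapping of allowlist
#' destination units.
#'
#' @param path path to the allowlist file.
#' @return character vector of sequences in file order.
#' @export
readAllowlist <- function(path) {
  x <- readLines(path)
  x <- trimws(x)
  x <- x[nzchar(x)]
  if (length(x) == 0L)
    stop("allowlist file is empty: ", path)
  bad <- grepl("[^ACGT]", x)
  if (any(bad))
    stop("allowlist contains non-ACGT sequences (line ",
         which(bad)[1L], "): ", path)
  x
}

#' Read a two-column sequence conversion table
#'
#' Tab-separated, no header: source sequence, destination sequence.
#'
#' @param path path to the TSV file.
#' @return named character vector mapping source to destination sequence.
#' @export
readConversionTable <- function(path) {
  x <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (ncol(x) < 2L)
    stop("conversion table must have two tab-separated columns: ", path)
  if (anyDuplicated(x[[1L]]))
    stop("conversion table has duplicated source sequences: ", path)
  setNames(x[[2L]], x[[1L]])
}

# Hierarchical path separator for parental value paths. Keys within a
# combinatorial tuple are joined with "+".
PATH_SEP <- "/"
TUPLE_SEP <- "+"

joinPath <- function(parent, key) {
  ifelse(parent == "", key, paste(parent, key, sep = PATH_SEP))
}
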