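test_that("the knee splits a two-level curve at the abundance cliff", {
  counts <- setNames(c(rep(1000, 100), rep(5, 900)),
                     sprintf("s%04d", 1:1000))
  curve <- rankCountCurve(counts)
  expect_equal(detectKnee(curve$count), 100L)
  expect_equal(kneeOracle(curve$count), 100L)
})

test_that("degenerate curves accept everything", {
  expect_equal(detectKnee(rep(7, 5)), 5L)   # no curvature
  expect_equal(detectKnee(42), 1L)          # single sequence
  expect_equal(detectKnee(c(9, 3)), 2L)     # n = 2
})

test_that("knee detection agrees with brute-force curvature on random curves", {
  withr::with_seed(11, {
    for (i in 1:30) {
      nTop <- sample(3:40, 1L)
      nTail <- sample(20:300, 1L)
      counts <- sort(c(round(stats::runif(nTop, 200, 400)),
                       sample(1:4, nTail, replace = TRUE)),
                     decreasing = TRUE)
      expect_equal(detectKnee(counts), kneeOracle(counts))
    }
  })
})

test_that("imputation corrects below-knee sequences to their nearest majority", {
  counts <- c(AACGA = 900, TTTTT = 800, AACGT = 3, GGGGG = 2)
  map <- buildSegmentCorrection(counts, "imputation", levMax = 1L)
  expect_equal(attr(map, "kneeRank"), 2L)
  expect_equal(unname(map[["AACGA"]]), "AACGA")
  expect_equal(unname(map[["AACGT"]]), "AACGA")   # distance 1
  expect_true(is.na(map[["GGGGG"]]))              # distance > 1: DROP
  expect_equal(dpEdit("AACGT", "AACGA"), 1L)
  expect_equal(dpEdit("GGGGG", "AACGA"), 4L)
})

test_that("equidistant imputation candidates resolve to the higher count", {
  # below-knee AAAT is distance 1 from both AAAA (500) and AAAC (400)
  counts <- c(AAAA = 500, AAAC = 400, CCCC = 450, AAAT = 2)
  map <- buildSegmentCorrection(counts, "imputation", levMax = 1L)
  expect_equal(unname(map[["AAAT"]]), "AAAA")
  # exhaustive candidate check: no accepted sequence is closer
  d <- vapply(c("AAAA", "AAAC", "CCCC"), function(a) dpEdit("AAAT", a), 0)
  expect_equal(min(d), 1)
  expect_equal(sort(names(d[d == 1])), c("AAAA", "AAAC"))
  # count tie falls back to lexicographic order
  counts2 <- c(AAAA = 500, AAAC = 500, AAAT = 2)
  map2 <- buildSegmentCorrection(counts2, "imputation", levMax = 1L)
  expect_equal(unname(map2[["AAAT"]]), "AAAA")
})

test_that("allowlist mapping drops distant and ambiguous sequences", {
  counts <- c(AAAAA = 10, AAAAT = 5, GGGGG = 4, ACCCG = 2)
  allow <- c("AAAAA", "CCCCC")
  map <- buildSegmentCorrection(counts, "allowlist", levMax = 1L,
                                allowlist = allow)
  expect_equal(unname(map[["AAAAA"]]), "AAAAA")  # exact member
  expect_equal(unname(map[["AAAAT"]]), "AAAAA")  # distance 1
  expect_true(is.na(map[["GGGGG"]]))             # beyond threshold
  # equidistant from two allowlist entries at the minimum: DROP
  d <- vapply(allow, function(a) dpEdit("ACCCG", a), 0)
  expect_equal(unname(d), c(4, 2))
  mapA <- buildSegmentCorrection(c(ACCCC = 1), "allowlist", levMax = 1L,
                                 allowlist = allow)
  expect_equal(vapply(allow, function(a) dpEdit("ACCCC", a), 0),
               c(AAAAA = 4, CCCCC = 1))
  expect_equal(unname(mapA[["ACCCC"]]), "CCCCC")
  amb <- buildSegmentCorrection(c(AACCG = 1), "allowlist", levMax = 3L,
                                allowlist = allow)
  expect_equal(unname(vapply(allow, function(a) dpEdit("AACCG", a), 0)),
               c(3, 3))
  expect_true(is.na(amb[["AACCG"]]))
})

test_that("N never matches, including against another N", {
  # the aligned N-N pair is one mismatch, so identical N-bearing strings
  # are at distance 1 per N position
  expect_equal(as.integer(levenshteinDist("ANGT", "ANGT")), 1L)
  expect_equal(as.integer(levenshteinDist("ANGN", "ANGN")), 2L)
  expect_equal(as.integer(levenshteinDist("ACGT", "ACGT")), 0L)
  expect_equal(dpEdit("ANGT", "ANGT"), 1)
  expect_equal(dpEdit("ANGN", "ANGN"), 2)
  expect_equal(as.integer(levenshteinDist("N", "A")), 1L)
})

test_that("nearest-neighbor mapping agrees with the DP oracle on a pool", {
  withr::with_seed(21, {
    accepted <- unique(vapply(1:40, function(i)
      paste(sample(c("A", "C", "G", "T"), 8L, replace = TRUE),
            collapse = ""), ""))
    queries <- vapply(1:60, function(i) {
      base <- sample(accepted, 1L)
      p <- sample.int(8L, 1L)
      substr(base, p, p) <- sample(c("A", "C", "G", "T", "N"), 1L)
      base
    }, "")
    queries <- setdiff(unique(queries), accepted)
    # a flat abundance plateau puts the knee exactly at the cliff (the two
    # boundary vertices tie on curvature; the smaller rank wins)
    counts <- setNames(c(rep(1000, length(accepted)),
                         rep(1, length(queries))),
                       c(accepted, queries))
    map <- buildSegmentCorrection(counts, "imputation", levMax = 1L)
    expect_equal(attr(map, "kneeRank"), length(accepted))
    for (q in queries) {
      d <- vapply(accepted, function(a) dpEdit(q, a), 0)
      if (min(d) > 1) {
        expect_true(is.na(map[[q]]), info = q)
      } else {
        best <- names(d)[d == min(d)]
        cand <- best[order(-counts[best], best)][1L]
        expect_equal(unname(map[[q]]), cand, info = q)
      }
    }
  })
})

test_that("correction application replaces, drops, and is idempotent", {
  counts <- c(AACGA = 900, TTTTT = 850, AACGT = 3)
  ctab <- new("CorrectionTable",
              tables = list(cellSeg = buildSegmentCorrection(
                counts, "imputation", levMax = 1L)),
              method = c(cellSeg = "imputation"),
              levMax = c(cellSeg = 1L), kneeRank = c(cellSeg = 2L))
  rec <- data.frame(read_id = c("a", "b"), structure = 1L,
                    seq_cellSeg = c("AACGT", "AACGA"),
                    seq_umiSeg = c("TTTT", "GGGG"),
                    avgq_cellSeg = c(30, 31))
  res <- applyCorrection(rec, ctab)
  expect_equal(res$records$seq_cellSeg, c("AACGA", "AACGA"))
  expect_equal(res$records$seq_umiSeg, c("TTTT", "GGGG"))  # untouched
  expect_equal(res$records$avgq_cellSeg, c(30, 31))        # carried over
  res2 <- applyCorrection(res$records, ctab)
  expect_identical(res2$records, res$records)
  expect_equal(res2$dropped, 0L)
  # a sequence outside the table is an internal consistency error
  bad <- data.frame(read_id = "z", structure = 1L, seq_cellSeg = "CCCCC")
  expect_error(applyCorrection(bad, ctab), "consistency")
  # every corrected value is in the accepted set; DROP never maps forward
  tab <- correctionRules(ctab, "cellSeg")
  expect_true(all(stats::na.omit(tab) %in% names(tab)[!is.na(tab)]))
})

test_that("an external plugin supplies the correction table", {
  skip_on_os("windows")
  plugin <- tempfile(fileext = ".sh")
  writeLines(c("#!/bin/sh",
               "awk -F'\t' '{print $1\"\t\"$1}' \"$1\" > \"$2\""), plugin)
  Sys.chmod(plugin, "0755")
  counts <- c(AAAA = 5, CCCC = 2)
  map <- buildSegmentCorrection(counts, "plugin",
                                pluginCommand = paste("sh", plugin))
  expect_equal(unname(map[c("AAAA", "CCCC")]), c("AAAA", "CCCC"))
  # non-total output is a plugin error
  bad <- tempfile(fileext = ".sh")
  writeLines(c("#!/bin/sh", "head -n 1 \"$1\" | awk '{print $1\"\t-\"}' > \"$2\""),
             bad)
  expect_error(buildSegmentCorrection(counts, "plugin",
                                      pluginCommand = paste("sh", bad)),
               "not total")
  expect_error(buildSegmentCorrection(counts, "plugin",
                                      pluginCommand = "false"),
               "exited")
})

test_that("well-separated barcodes are recovered perfectly at depth", {
  # pairwise Levenshtein >= 3, one substitution per erroneous read,
  # >= 50x coverage: every below-knee sequence within threshold 1 recovers
  # its true barcode
  withr::with_seed(31, {
    bcs <- randomBarcodes(20L, 12L, minDist = 3L)
    reads <- rep(bcs, each = 60L)
    err <- sample(length(reads), 80L)
    for (i in err) {
      p <- sample.int(12L, 1L)
      cur <- substr(reads[[i]], p, p)
      substr(reads[[i]], p, p) <- sample(setdiff(c("A", "C", "G", "T"), cur),
                                         1L)
    }
    truth <- rep(bcs, each = 60L)
    tb <- table(reads)
    counts <- setNames(as.numeric(tb), names(tb))
    map <- buildSegmentCorrection(counts, "imputation", levMax = 1L)
    knee <- attr(map, "kneeRank")
    accepted <- rankCountCurve(counts)$sequence[seq_len(knee)]
    expect_true(all(bcs %in% accepted))
    corrected <- unname(map[reads])
    expect_false(anyNA(corrected))
    below <- !(reads %in% accepted)
    expect_gt(sum(below), 0L)
    expect_equal(mean(corrected[below] == truth[below]), 1)
  })
})
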