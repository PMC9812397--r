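mkReassignDest <- function(units) {
  destinationSpec("d", "v", "reassign", units = units)
}

test_that("destination capacity is the product of unit capacities", {
  expect_equal(destinationCapacity(mkReassignDest(
    list(list(kind = "iupac", template = "NNNN")))), 256)
  expect_equal(destinationCapacity(mkReassignDest(
    list(list(kind = "iupac", template = "ANNA")))), 16)
  expect_equal(destinationCapacity(mkReassignDest(
    list(list(kind = "iupac", template = "RYN")))), 16)  # 2*2*4
  # five units each from a 10-row allowlist: 10^5
  allow <- tempfile()
  writeLines(c("AACC", "AAGG", "ACAC", "AGAG", "CCAA", "CCTT", "CTCT",
               "GGAA", "GGTT", "GTGT"), allow)
  units <- rep(list(list(kind = "allowlist", path = allow)), 5L)
  expect_equal(destinationCapacity(mkReassignDest(units)), 1e5)
  expect_equal(prod(rep(10, 5)), 1e5)  # product oracle
})

test_that("values render as mixed-radix sequences, most significant first", {
  nn <- mkReassignDest(list(list(kind = "iupac", template = "NN")))
  expect_equal(assignDestinationSequence(0L, nn), "AA")
  expect_equal(assignDestinationSequence(5L, nn), "CC")  # 5 = 1*4 + 1
  # base-4 encoding oracle over the whole space, digit map A<C<G<T
  bases <- c("A", "C", "G", "T")
  oracle <- vapply(0:15, function(v)
    paste0(bases[v %/% 4L + 1L], bases[v %% 4L + 1L]), "")
  expect_equal(assignDestinationSequence(0:15, nn), oracle)
  expect_true(!anyDuplicated(assignDestinationSequence(0:15, nn)))
  # allowlist units index in file order
  allow <- tempfile()
  writeLines(c("AAAA", "CCCC", "GGGG"), allow)
  au <- mkReassignDest(list(list(kind = "allowlist", path = allow)))
  expect_equal(assignDestinationSequence(2L, au), "GGGG")  # third line
  # multi-unit: allowlist digit is more significant than template digit
  mix <- mkReassignDest(list(list(kind = "allowlist", path = allow),
                             list(kind = "iupac", template = "N")))
  expect_equal(assignDestinationSequence(0L, mix), "AAAAA")
  expect_equal(assignDestinationSequence(5L, mix), "CCCCC")  # 5 = 1*4 + 1
  expect_equal(assignDestinationSequence(11L, mix), "GGGGT")
  # overflow signals NA for the caller to drop
  expect_true(is.na(assignDestinationSequence(12L, mix)))
  expect_true(is.na(assignDestinationSequence(16L, nn)))
  # fixed positions contribute nothing to the encoding
  anna <- mkReassignDest(list(list(kind = "iupac", template = "ANNA")))
  expect_equal(assignDestinationSequence(c(0L, 15L), anna),
               c("AAAA", "ATTA"))
})

test_that("bequeathed qualities round half-up, clamp, and fill with Q40", {
  expect_equal(bequeathQuality(31.4, 12L), strrep(phredChars(31L), 12L))
  expect_equal(bequeathQuality(31.5, 2L), strrep(phredChars(32L), 2L))
  expect_equal(bequeathQuality(mean(c(30, 40)), 4L), "DDDD")  # Q35
  expect_equal(bequeathQuality(1, 3L), "###")    # clamp at Q2
  expect_equal(bequeathQuality(45, 3L), "III")   # clamp at Q40
  expect_equal(bequeathQuality(30, 10L, inheritedLen = 6L),
               paste0(strrep("?", 6L), "IIII"))  # pad bases are exactly Q40
})

test_that("record translation applies every strategy and drops with reason", {
  ct <- tempfile()
  writeLines(c("AAAA\tGGGGG", "CCCC\tTTTTT"), ct)
  segs <- list(segmentSpec("bcSeg", 0L, start = 0L, end = 4L),
               segmentSpec("umiSeg", 0L, start = 4L, end = 12L),
               segmentSpec("cdnaSeg", 1L, start = 0L, end = NA))
  vars <- list(
    variableSpec("bc", "bcSeg", role = "parental", correction = "none",
                 valued = TRUE),
    variableSpec("umi", "umiSeg", role = "local", parent = "bc",
                 correction = "none", valued = TRUE),
    variableSpec("cdna", "cdnaSeg", correction = "none"))
  dests <- list(
    destinationSpec("bcDst", "bc", "conversion_table", tablePath = ct,
                    readIndex = 0L, order = 0L),
    destinationSpec("umiDst", "umi", "bequeath_pad", length = 12L,
                    padBase = "A", readIndex = 0L, order = 1L),
    destinationSpec("fill", strategy = "constant", constantSeq = "ACGT",
                    readIndex = 0L, order = 2L),
    destinationSpec("cdnaDst", "cdna", "passthrough", readIndex = 1L,
                    order = 0L))
  cfg <- pipelineConfig(list(readStructure("s", segs)), vars,
                        qualityPolicy(20, 10), dests)
  rec <- data.frame(read_id = c("a", "b", "c"), structure = 1L,
                    seq_bcSeg = c("AAAA", "CCCC", "TTTT"),
                    seq_umiSeg = c("ACGTACGT", "ACGTACGT", "ACGTACGT"),
                    seq_cdnaSeg = c("GATTACA", "GATTACA", "GATTACA"),
                    avgq_bcSeg = c(30, 32.6, 30),
                    avgq_umiSeg = c(35, 21.2, 35),
                    avgq_cdnaSeg = 33,
                    minq_bcSeg = 28L, minq_umiSeg = 20L, minq_cdnaSeg = 30L,
                    qual_cdnaSeg = "IIFF#FF", stringsAsFactors = FALSE)
  enc <- encodeValues(rec, cfg)
  out <- translateRecords(enc$records, cfg, optimizeValueSpace(enc$tree))
  # read "c" has no conversion-table entry: dropped with reason
  expect_equal(out$ids, c("a", "b"))
  expect_equal(out$droppedReasons[["table_miss"]], 1L)
  # 8-base UMI, 12-base destination: elongated by A nucleotides
  expect_equal(out$seqs[[1L]][1L],
               paste0("GGGGG", "ACGTACGT", "AAAA", "ACGT"))
  expect_equal(out$seqs[[2L]][1L], "GATTACA")
  # qualities: table segment Q30; UMI part Q35 + AAAA at Q40; filler Q40
  expect_equal(out$quals[[1L]][1L],
               paste0(strrep("?", 5L), strrep("D", 8L), "IIII", "IIII"))
  # payload quality passes through verbatim
  expect_equal(out$quals[[2L]][1L], "IIFF#FF")
  # round-half-up on the second record: 32.6 -> 33, 21.2 -> 21
  expect_equal(out$quals[[1L]][2L],
               paste0(strrep("B", 5L), strrep("6", 8L), "IIII", "IIII"))
})

test_that("capacity overflow drops the read at the boundary", {
  segs <- list(segmentSpec("bcSeg", 0L, start = 0L, end = 4L))
  vars <- list(variableSpec("bc", "bcSeg", correction = "none",
                            valued = TRUE))
  dests <- list(destinationSpec("bcDst", "bc", "reassign",
                                units = list(list(kind = "iupac",
                                                  template = "N"))))
  cfg <- pipelineConfig(list(readStructure("s", segs)), vars,
                        qualityPolicy(20, 10), dests)
  bcs <- c("AAAA", "CCCC", "GGGG", "TTTT", "ACGT")
  rec <- data.frame(read_id = sprintf("r%d", 1:5), structure = 1L,
                    seq_bcSeg = bcs, avgq_bcSeg = 30, minq_bcSeg = 30L,
                    stringsAsFactors = FALSE)
  enc <- encodeValues(rec, cfg)
  out <- translateRecords(enc$records, cfg, optimizeValueSpace(enc$tree))
  # capacity 4 hosts values 0..3; the fifth value overflows
  expect_length(out$ids, 4L)
  expect_equal(out$droppedReasons[["capacity"]], 1L)
})

test_that("spatial tables assign beads to nearest spots with stable ties", {
  spots <- data.frame(barcode = c("S1", "S2", "S3"),
                      x = c(0, 10, 5), y = c(0, 0, 9))
  # one bead, one tile, unique nearest spot
  one <- buildSpatialConversionTable(
    data.frame(barcode = "b1", x = 1, y = 1), spots,
    scale = 1, tileDim = c(12, 12), grid = c(1L, 1L))
  expect_equal(nrow(one$table), 1L)
  expect_equal(one$table$spot, "S1")
  expect_equal(one$uniqueFraction, 1)
  # two beads nearest to the same spot: both map, uniqueness 0
  two <- buildSpatialConversionTable(
    data.frame(barcode = c("b1", "b2"), x = c(1, 2), y = c(0.5, 1)), spots,
    scale = 1, tileDim = c(12, 12), grid = c(1L, 1L))
  expect_equal(two$table$spot, c("S1", "S1"))
  expect_equal(two$uniqueFraction, 0)
  # equidistant bead: lowest spot index wins (exhaustive 3-spot oracle)
  mid <- buildSpatialConversionTable(
    data.frame(barcode = "b", x = 5, y = 0), spots,
    scale = 1, tileDim = c(12, 12), grid = c(1L, 1L))
  d <- sqrt((spots$x - 5)^2 + (spots$y - 0)^2)
  expect_equal(which(d == min(d)), c(1L, 2L))
  expect_equal(mid$table$spot, "S1")
  # scaling moves a bead into a farther tile; outside beads are recorded
  sc <- buildSpatialConversionTable(
    data.frame(barcode = c("in", "out"), x = c(3, 50), y = c(1, 1)), spots,
    scale = 5, tileDim = c(12, 12), grid = c(2L, 1L))
  expect_equal(sc$table$barcode, "in")
  expect_equal(sc$table$tile, 1L)
  expect_equal(sc$unassigned, "out")
})

test_that("emitted FASTQ parses back bit-exactly and drops are absent", {
  tuples <- list(ids = c("a", "b", "c"),
                 seqs = list(c("ACGT", "GGGG", "TTTT"),
                             c("AAAA", "CCCC", "GGGG")),
                 quals = list(c("IIII", "FFFF", "####"),
                              c("!!!!", "JJJJ", "IIII")))
  f <- c(tempfile(fileext = ".fastq"), tempfile(fileext = ".fastq"))
  emitDestinationFastq(tuples, f)
  expect_length(readLines(f[[1L]]), 12L)
  for (ri in 1:2) {
    back <- readFastqAll(f[[ri]])
    expect_equal(back$ids, tuples$ids)
    expect_equal(back$seqs, tuples$seqs[[ri]])
    expect_equal(back$quals, tuples$quals[[ri]])
  }
})
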