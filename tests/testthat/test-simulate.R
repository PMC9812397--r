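test_that("the same seed reproduces byte-identical libraries", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  s1 <- simulateStructuredReads(scrnaDesign(nCells = 8L, nGenes = 5L),
                                d1, seed = 17)
  s2 <- simulateStructuredReads(scrnaDesign(nCells = 8L, nGenes = 5L),
                                d2, seed = 17)
  for (k in seq_along(s1$fastqs))
    expect_identical(readLines(s1$fastqs[[k]]), readLines(s2$fastqs[[k]]))
  expect_identical(s1$truth, s2$truth)
  s3 <- simulateStructuredReads(scrnaDesign(nCells = 8L, nGenes = 5L),
                                withr::local_tempdir(), seed = 18)
  expect_false(identical(readLines(s3$fastqs[[1L]]),
                         readLines(s1$fastqs[[1L]])))
})

test_that("the well-barcoding design uses the full 384-well geometry", {
  d <- withr::local_tempdir()
  sim <- simulateStructuredReads(
    rcppcrDesign(plates = 2L, wellsPerPlate = 24L, readsPerWell = 4L),
    d, seed = 19)
  expect_length(readAllowlist(sim$allowlists[["rbc"]]), 16L)
  expect_length(readAllowlist(sim$allowlists[["cbc"]]), 24L)
  expect_length(readAllowlist(sim$allowlists[["pbc"]]), 2L)
  expect_length(sim$config@structures, 4L)
  expect_true(all(sim$truth$row %in% 1:16))
  expect_true(all(sim$truth$col %in% 1:24))
})

test_that("every simulated family decodes exactly at zero error rate", {
  for (design in list(atacDesign(tierSize = 6L, nCells = 10L,
                                 readsPerCell = 5L),
                      spatialDesign(nBeads = 25L, umisPerBead = 3L),
                      longreadDesign(nClones = 8L, readsPerClone = 3L))) {
    d <- withr::local_tempdir()
    sim <- simulateStructuredReads(design, d, seed = 23)
    it <- runInterpret(sim$config, sim$fastqs, file.path(d, "interp"))
    expect_equal(it$manifest[["matched"]], it$manifest[["input"]])
    expect_equal(it$manifest[["corrected"]], it$manifest[["input"]])
    rec <- readAllCorrected(file.path(d, "interp"))
    expect_equal(nrow(rec), nrow(sim$truth))
    if (design$family == "spatial") {
      j <- match(sim$truth$read_id, rec$read_id)
      expect_equal(rec$seq_beadSeg[j], sim$truth$bead)
      expect_equal(rec$seq_umiSeg[j], sim$truth$umi)
    }
    if (design$family == "longread") {
      j <- match(sim$truth$read_id, rec$read_id)
      expect_equal(rec$seq_bcSeg[j], sim$truth$barcode)
      expect_equal(rec$seq_varSeg[j], sim$truth$variant)
    }
  }
})

test_that("fuzzy flanks keep anchored long reads decodable", {
  d <- withr::local_tempdir()
  sim <- simulateStructuredReads(
    longreadDesign(nClones = 10L, readsPerClone = 3L, flankErrors = 2L),
    d, seed = 29)
  matchers <- lapply(sim$config@structures, compileMatcher)
  rec <- NULL
  streamReadTuples(sim$fastqs, 1000L, function(tup)
    rec <<- extractSegments(tup, matchers))
  j <- match(sim$truth$read_id, rec$read_id)
  expect_equal(rec$seq_bcSeg[j], sim$truth$barcode)
  expect_equal(rec$seq_varSeg[j], sim$truth$variant)
})

test_that("distinct UMIs are counted per cell and gene tag", {
  m <- umiCountMatrix(c("C1", "C1", "C1", "C2"),
                      c("G1", "G1", "G1", "G1"),
                      c("U1", "U1", "U2", "U1"))
  expect_equal(m[["C1", "G1"]], 2L)
  expect_equal(m[["C2", "G1"]], 1L)
  expect_equal(dim(umiCountMatrix(character(0), character(0),
                                  character(0))), c(0L, 0L))
})

test_that("rank differences vanish on identical inputs and match a hand
          example", {
  withr::with_seed(51, {
    x <- matrix(stats::rnorm(60), 20L, 3L,
                dimnames = list(sprintf("p%02d", 1:20), NULL))
    for (sd in c(1L, 99L)) {
      rd <- rankDifferenceStat(x, x, nPairs = 200L, seed = sd)
      expect_true(all(rd$delta == 0))
    }
    # permuted distances: observed deltas resemble the null (medians close
    # relative to the null spread)
    y <- x[sample(rownames(x)), , drop = FALSE]
    rownames(y) <- rownames(x)
    rd <- rankDifferenceStat(x, y, nPairs = 1000L, seed = 7L)
    expect_gt(stats::median(rd$delta), 0)
    expect_lt(abs(stats::median(rd$delta) - stats::median(rd$null)),
              stats::sd(rd$null))
    expect_error(rankDifferenceStat(x, x[1:10, ]), "mismatch")
  })
  # 3-point worked example, ranks by hand: points on a line in x, order
  # swapped in y; with all three pairs the rank vectors are hand-checkable
  x <- matrix(c(0, 1, 4), 3L, 1L, dimnames = list(c("a", "b", "c"), NULL))
  y <- matrix(c(0, 3, 1), 3L, 1L, dimnames = list(c("a", "b", "c"), NULL))
  # pair distances (ab, ac, bc): x -> 1, 4, 3 (ranks 1, 3, 2)
  #                              y -> 3, 1, 2 (ranks 3, 1, 2)
  dx <- c(1, 4, 3); dy <- c(3, 1, 2)
  expect_equal(abs(rank(dx) - rank(dy)), c(2, 2, 0))
})

test_that("clonal wells are called by the 50%/70% occupancy rules", {
  tag <- rbind(
    data.frame(well = 1L, uptag = c(rep("T1", 9L), "T9"),
               dntag = c(rep("D1", 8L), "D8", "D9")),
    data.frame(well = 2L, uptag = c("T1", "T1", "T2", "T2"),
               dntag = rep("D1", 4L)),
    data.frame(well = 3L, uptag = rep("T3", 6L), dntag = rep("D3", 6L)))
  lox <- rbind(
    data.frame(well = 1L, tag = rep("T1", 20L),
               loxValid = c(rep(TRUE, 19L), FALSE)),
    data.frame(well = 2L, tag = rep("T1", 4L), loxValid = TRUE),
    data.frame(well = 3L, tag = rep("T4", 6L), loxValid = TRUE))
  v <- callClonalWells(tag, lox)
  # well 1: 0.9/0.8 occupancy, lox 0.95, agreement -> clonal
  expect_true(v$clonal[v$well == 1L])
  # well 2: dominant occupancy exactly 0.50 -> rejected ("above 50%" is
  # strict)
  expect_false(v$clonal[v$well == 2L])
  expect_equal(v$reason[v$well == 2L], "tag_not_dominant")
  # well 3: Tag says T3, Lox says T4 -> conflict
  expect_false(v$clonal[v$well == 3L])
  expect_equal(v$reason[v$well == 3L], "conflict")
  # lox validity below 70% rejects
  lox2 <- data.frame(well = 1L, tag = rep("T1", 10L),
                     loxValid = c(rep(TRUE, 6L), rep(FALSE, 4L)))
  tag1 <- tag[tag$well == 1L, ]
  v2 <- callClonalWells(tag1, lox2)
  expect_equal(v2$reason, "lox_invalid")
  # exactly 70% passes (">= 70%")
  lox3 <- data.frame(well = 1L, tag = rep("T1", 10L),
                     loxValid = c(rep(TRUE, 7L), rep(FALSE, 3L)))
  expect_true(callClonalWells(tag1, lox3)$clonal)
})

test_that("simulated clonal wells are recovered end to end", {
  d <- withr::local_tempdir()
  sim <- simulateStructuredReads(
    rcppcrDesign(plates = 2L, wellsPerPlate = 16L, readsPerWell = 10L,
                 contamRate = 0.25, contamFrac = 1.0, loxBrokenRate = 0.05),
    d, seed = 31)
  it <- runInterpret(sim$config, sim$fastqs, file.path(d, "interp"))
  rec <- readAllCorrected(file.path(d, "interp"))
  j <- match(rec$read_id, sim$truth$read_id)
  rec$well <- sim$truth$well[j]
  verdict <- function(cassette) {
    tagRec <- rec[!is.na(rec[[paste0("seq_tag_", cassette, "tag")]]), ]
    loxRec <- rec[!is.na(rec[[paste0("seq_tag_", cassette, "lox")]]), ]
    whichTag <- if (cassette == "db") "uptag" else "dntag"
    tagReads <- data.frame(
      well = tagRec$well,
      uptag = tagRec[[paste0("seq_tag_", cassette, "tag")]],
      dntag = tagRec[[paste0("seq_dntag_", cassette, "tag")]])
    if (cassette == "ad") {  # AD-Tag read 1 carries the Dntag
      tmp <- tagReads$uptag; tagReads$uptag <- tagReads$dntag
      tagReads$dntag <- tmp
    }
    loxReads <- data.frame(
      well = loxRec$well,
      tag = loxRec[[paste0("seq_tag_", cassette, "lox")]],
      loxValid = loxRec[[paste0("seq_lox_", cassette, "lox")]] ==
        sim$loxSite)
    callClonalWells(tagReads, loxReads, whichTag = whichTag)
  }
  v <- rbind(verdict("db"), verdict("ad"))
  w <- sim$wells
  clean <- w$well[!w$contaminated]
  # uncontaminated wells with intact sites are recovered as clonal with the
  # true tags
  vm <- v[match(clean, v$well), ]
  expect_true(all(vm$clonal))
  expect_equal(vm$uptag, w$uptag[!w$contaminated])
  expect_equal(vm$dntag, w$dntag[!w$contaminated])
  # heavily contaminated wells cannot be dominant at > 50%
  contam <- w$well[w$contaminated]
  if (length(contam))
    expect_false(any(v$clonal[v$well %in% contam]))
})
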