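encodeToy <- function(cells, umis, cfg = simpleScrnaConfig()) {
  rec <- data.frame(read_id = sprintf("r%02d", seq_along(cells)),
                    structure = 1L, seq_cellSeg = cells, seq_umiSeg = umis,
                    seq_cdnaSeg = "ACGT", avgq_cellSeg = 30,
                    avgq_umiSeg = 30, avgq_cdnaSeg = 30,
                    stringsAsFactors = FALSE)
  encodeValues(rec, cfg)
}

test_that("the same UMI under different cells is a different object", {
  enc <- encodeToy(cells = c("C1", "C1", "C1", "C2"),
                   umis = c("U1", "U2", "U1", "U1"))
  e <- treeEntries(enc$tree)
  cells <- e[e$variable == "cell", ]
  expect_equal(sort(cells$key), c("C1", "C2"))
  expect_equal(cells$count[match(c("C1", "C2"), cells$key)], c(3, 1))
  umis <- e[e$variable == "umi", ]
  # scopes of sizes 2 (under C1) and 1 (under C2); U1 appears in both
  expect_equal(sum(umis$path == "C1"), 2L)
  expect_equal(sum(umis$path == "C2"), 1L)
  expect_equal(sum(umis$key == "U1"), 2L)
})

test_that("an empty input yields an empty tree", {
  cfg <- simpleScrnaConfig()
  enc <- encodeValues(data.frame(read_id = character(0),
                                 structure = integer(0)), cfg)
  expect_equal(nrow(treeEntries(enc$tree)), 0L)
})

test_that("a combinatorial split-pool cell identifier is one variable", {
  segs <- list(segmentSpec("t1", 0L, start = 0L, end = 8L),
               segmentSpec("t2", 0L, start = 8L, end = 16L),
               segmentSpec("t3", 0L, start = 16L, end = 24L))
  cfg <- pipelineConfig(
    list(readStructure("splitpool", segs)),
    list(variableSpec("cell", c("t1", "t2", "t3"), correction = "none",
                      valued = TRUE)))
  rec <- data.frame(read_id = c("a", "b", "c"), structure = 1L,
                    seq_t1 = c("AA", "AA", "CC"),
                    seq_t2 = c("GG", "GG", "GG"),
                    seq_t3 = c("TT", "AA", "TT"),
                    avgq_t1 = 30, avgq_t2 = 30, avgq_t3 = 30)
  enc <- encodeValues(rec, cfg)
  e <- treeEntries(enc$tree)
  expect_equal(sort(e$key), c("AA+GG+AA", "AA+GG+TT", "CC+GG+TT"))
  expect_equal(e$count, rep(1, 3))
})

test_that("merging chunk trees equals a single-pass encode", {
  withr::with_seed(41, {
    cells <- sample(paste0("C", 1:5), 40L, replace = TRUE)
    umis <- sample(paste0("U", 1:6), 40L, replace = TRUE)
    whole <- encodeToy(cells, umis)$tree
    parts <- lapply(split(seq_along(cells), rep(1:4, each = 10L)),
                    function(i) encodeToy(cells[i], umis[i])$tree)
    merged <- mergeValueTrees(unname(parts))
    a <- treeEntries(whole); a <- a[order(a$variable, a$path, a$key), ]
    b <- treeEntries(merged); b <- b[order(b$variable, b$path, b$key), ]
    rownames(a) <- rownames(b) <- NULL
    expect_equal(b, a)
    # disjoint cells from two chunks union at the root
    t1 <- encodeToy("CA", "U1")$tree
    t2 <- encodeToy("CB", "U1")$tree
    u <- treeEntries(mergeValueTrees(list(t1, t2)))
    expect_equal(sort(u$key[u$variable == "cell"]), c("CA", "CB"))
    # the same (cell, UMI) in two chunks sums its count
    t3 <- mergeValueTrees(list(t1, t1))
    expect_equal(treeEntries(t3)$count, c(2, 2))
    expect_error(mergeValueTrees(list(t1, randomValueTree())), "mismatch")
  })
})

test_that("local values are renumbered per scope, not globally", {
  tree <- new("ValueTree",
              entries = data.frame(
                variable = c("root", "root", "loc", "loc", "loc", "loc",
                             "loc"),
                path = c("", "", "A", "A", "A", "B", "B"),
                key = c("A", "B", "x", "y", "z", "p", "q"),
                count = c(10, 5, 3, 2, 1, 8, 7)),
              hierarchy = c(root = NA, loc = "root"))
  opt <- optimizeValueSpace(tree)
  sc <- speciesCount(opt)
  expect_equal(sc[["loc"]], 3L)   # max scope size, not 5
  expect_equal(sc[["root"]], 2L)
  a <- opt@assignments
  # frequency ranking within each scope
  locA <- a[a$variable == "loc" & a$path == "A", ]
  expect_equal(locA$optValue[match(c("x", "y", "z"), locA$key)], 0:2)
})

test_that("root values are renumbered by descending frequency", {
  tree <- new("ValueTree",
              entries = data.frame(variable = "v", path = "",
                                   key = c("v1", "v2"), count = c(10, 30)),
              hierarchy = c(v = NA_character_))
  a <- optimizeValueSpace(tree)@assignments
  expect_equal(a$optValue[match(c("v2", "v1"), a$key)], c(0L, 1L))
})

test_that("three-layer species counts equal the maximum scope cardinality", {
  withr::with_seed(42, {
    for (i in 1:20) {
      tree <- randomValueTree(maxRoots = 3L, maxKids = 3L,
                              threeLayer = TRUE)
      opt <- optimizeValueSpace(tree)
      e <- treeEntries(tree)
      for (v in c("kid", "grand")) {
        scopes <- table(e$path[e$variable == v])
        expect_equal(speciesCount(opt)[[v]], max(scopes))
      }
    }
  })
})

test_that("optimization preserves topology as a bijection onto its image", {
  withr::with_seed(43, {
    for (i in 1:20) {
      tree <- randomValueTree(threeLayer = i %% 2L == 0L)
      opt <- optimizeValueSpace(tree)
      a <- opt@assignments
      # injective within each scope
      for (v in unique(a$variable)) {
        av <- a[a$variable == v, ]
        expect_false(anyDuplicated(paste(av$optPath, av$optValue)) > 0)
        # 0..k-1 per scope
        for (p in unique(av$optPath)) {
          vals <- sort(av$optValue[av$optPath == p])
          expect_equal(vals, seq_along(vals) - 1L)
        }
      }
      # reconstructing the tree from optimized values is isomorphic:
      # identical multiset of (variable, scope size) and counts
      orig <- treeEntries(tree)
      for (v in unique(a$variable)) {
        s1 <- sort(as.vector(table(orig$path[orig$variable == v])))
        s2 <- sort(as.vector(table(a$optPath[a$variable == v])))
        expect_equal(s2, s1)
      }
      # determinism
      expect_identical(optimizeValueSpace(tree)@assignments, a)
    }
  })
})

test_that("no smaller species count admits an injective renumbering", {
  withr::with_seed(44, {
    for (i in 1:25) {
      tree <- randomValueTree(maxRoots = 3L, maxKids = 4L)
      opt <- optimizeValueSpace(tree)
      e <- treeEntries(tree)
      k <- speciesCount(opt)[["kid"]]
      scopes <- as.vector(table(e$path[e$variable == "kid"]))
      expect_true(all(vapply(scopes, existsInjection, TRUE, k = k)))
      expect_false(all(vapply(scopes, existsInjection, TRUE, k = k - 1L)))
    }
  })
})

test_that("raw global enumeration pools all scopes of a variable", {
  tree <- new("ValueTree",
              entries = data.frame(
                variable = c("root", "root", "loc", "loc", "loc"),
                path = c("", "", "A", "B", "B"),
                key = c("A", "B", "u", "u", "w"),
                count = c(5, 4, 3, 2, 6)),
              hierarchy = c(root = NA, loc = "root"))
  raw <- rawValueMap(tree)
  expect_false(raw@optimized)
  expect_equal(speciesCount(raw)[["loc"]], 2L)  # u and w pooled globally
  a <- raw@assignments
  # same key gets the same global value in every scope; ranked by total
  u <- unique(a$optValue[a$variable == "loc" & a$key == "u"])
  expect_length(u, 1L)
  expect_equal(a$optValue[a$variable == "loc" & a$key == "w"][1L], 0L)
})
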