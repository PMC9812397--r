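#' @include eval.R
NULL

# ---- random sequence helpers ----------------------------------------------

randomSeqs <- function(n, len) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE),
              nrow = len)
  apply(m, 2L, paste, collapse = "")
}

#' Random barcodes with a minimum pairwise Levenshtein distance
#'
#' Greedy rejection sampling; barcodes this far apart are unambiguously
#' correctable for substitution errors up to `(minDist - 1) %/% 2` edits.
#'
#' @param n number of barcodes.
#' @param len barcode length.
#' @param minDist minimum pairwise Levenshtein distance.
#' @return character vector of `n` distinct barcodes.
#' @export
randomBarcodes <- function(n, len, minDist = 3L) {
  out <- character(0)
  guard <- 0L
  while (length(out) < n) {
    guard <- guard + 1L
    if (guard > 200L * n)
      stop("cannot draw ", n, " barcodes of length ", len,
           " at min distance ", minDist)
    cand <- randomSeqs(1L, len)
    if (!length(out) ||
        min(levenshteinDist(cand, out)) >= minDist)
      out <- c(out, cand)
  }
  out
}

# Sparse per-base substitution injection; returns the mutated sequences and
# the number of injected edits per sequence.
injectSubstitutions <- function(seqs, rate) {
  edits <- integer(length(seqs))
  if (rate <= 0 || !length(seqs)) return(list(seqs = seqs, edits = edits))
  lens <- nchar(seqs)
  nHits <- stats::rbinom(length(seqs), lens, rate)
  for (i in which(nHits > 0L)) {
    pos <- sample.int(lens[[i]], nHits[[i]])
    for (p in pos) {
      cur <- substr(seqs[[i]], p, p)
      substr(seqs[[i]], p, p) <- sample(setdiff(c("A", "C", "G", "T"), cur),
                                        1L)
    }
    edits[[i]] <- nHits[[i]]
  }
  list(seqs = seqs, edits = edits)
}

writeFastq <- function(ids, seqs, quals, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(quals),
                              compress = grepl("\\.gz$", path))
  path
}

withSimSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
          else suppressWarnings(rm(".Random.seed", envir = .GlobalEnv)))
  set.seed(seed)
  force(expr)
}

# ---- library designs -------------------------------------------------------

#' Design a droplet scRNA-seq style library
#'
#' Read 1 carries a cell identifier followed by a UMI; read 2 carries a
#' fixed synthetic 20-base gene-tag payload standing in for cDNA (no
#' transcriptome is simulated). UMIs per (cell, gene) are drawn from a
#' geometric distribution truncated to `1..maxUmis`, producing the unequal
#' local scope sizes that make value-space optimization non-trivial.
#'
#' @param nCells number of cells.
#' @param nGenes number of gene tags.
#' @param maxUmis maximum distinct UMIs per (cell, gene).
#' @param geomP geometric success parameter of the truncated UMI count
#'   distribution.
#' @param readsPerUmi sequencing reads per molecule.
#' @param cellLen,umiLen segment lengths (defaults: droplet V3 geometry).
#' @param errorRate per-base substitution rate.
#' @param baseQ constant per-base Phred score of simulated reads.
#' @param correction correction method declared for the cell identifier
#'   (`"allowlist"` or `"imputation"`).
#' @return a design list for [simulateStructuredReads()].
#' @export
scrnaDesign <- function(nCells = 50L, nGenes = 20L, maxUmis = 5L,
                        geomP = 0.45, readsPerUmi = 1L, cellLen = 16L,
                        umiLen = 12L, errorRate = 0, baseQ = 37L,
                        correction = "allowlist") {
  structure(class = "sbDesign", list(
    family = "scrna", nCells = as.integer(nCells),
    nGenes = as.integer(nGenes), maxUmis = as.integer(maxUmis),
    geomP = geomP, readsPerUmi = as.integer(readsPerUmi),
    cellLen = as.integer(cellLen), umiLen = as.integer(umiLen),
    errorRate = errorRate, baseQ = as.integer(baseQ),
    correction = correction))
}

#' Design a row-column-plate PCR well-barcoding library
#'
#' Four read structures share one pool (Tag and Lox libraries for two
#' cassette types), discriminated by structure-specific 10-base constant
#' handles. Tag reads carry both well tags; Lox reads carry one tag plus a
#' 20-base recombination-site region whose intactness is scored. The well
#' geometry is the full 384-well plate: 16 row barcodes and 24 column
#' barcodes.
#'
#' @param plates number of plate barcodes.
#' @param wellsPerPlate wells sampled per plate (<= 384).
#' @param readsPerWell sequencing reads per well per structure.
#' @param contamRate fraction of wells contaminated by a second clone.
#' @param contamFrac read fraction of the contaminating clone.
#' @param loxBrokenRate fraction of Lox reads with a damaged site.
#' @param errorRate per-base substitution rate.
#' @param baseQ constant per-base Phred score.
#' @return a design list for [simulateStructuredReads()].
#' @export
rcppcrDesign <- function(plates = 2L, wellsPerPlate = 48L, readsPerWell = 12L,
                         contamRate = 0.15, contamFrac = 0.4,
                         loxBrokenRate = 0.05, errorRate = 0, baseQ = 37L) {
  structure(class = "sbDesign", list(
    family = "rcppcr", rows = 16L, cols = 24L, plates = as.integer(plates),
    wellsPerPlate = as.integer(wellsPerPlate),
    readsPerWell = as.integer(readsPerWell), contamRate = contamRate,
    contamFrac = contamFrac, loxBrokenRate = loxBrokenRate,
    errorRate = errorRate, baseQ = as.integer(baseQ)))
}

#' Design a combinatorial-index ATAC-style library
#'
#' The cell identity is a combinatorial group of four 8-base index tiers
#' split across two index reads; two genomic reads carry payload.
#'
#' @param tierSize barcodes per index tier.
#' @param nCells distinct tier combinations observed.
#' @param readsPerCell reads per cell.
#' @param gdnaLen genomic payload length per read.
#' @param errorRate per-base substitution rate.
#' @param baseQ constant per-base Phred score.
#' @return a design list for [simulateStructuredReads()].
#' @export
atacDesign <- function(tierSize = 12L, nCells = 40L, readsPerCell = 25L,
                       gdnaLen = 30L, errorRate = 0, baseQ = 37L) {
  structure(class = "sbDesign", list(
    family = "combinatorial_atac", tierSize = as.integer(tierSize),
    nCells = as.integer(nCells), readsPerCell = as.integer(readsPerCell),
    gdnaLen = as.integer(gdnaLen), errorRate = errorRate,
    baseQ = as.integer(baseQ)))
}

#' Design a spatial bead-array library
#'
#' Beads with 14-base positional barcodes are scattered uniformly over a
#' square field; read 1 carries the bead barcode and a 9-base UMI, read 2 a
#' 20-base payload. Bead coordinates are part of the ground truth so a
#' spatial conversion table can be built.
#'
#' @param nBeads number of beads.
#' @param fieldSize side length of the square bead field.
#' @param umisPerBead distinct UMIs per bead.
#' @param errorRate per-base substitution rate.
#' @param baseQ constant per-base Phred score.
#' @return a design list for [simulateStructuredReads()].
#' @export
spatialDesign <- function(nBeads = 150L, fieldSize = 60, umisPerBead = 4L,
                          errorRate = 0, baseQ = 37L) {
  structure(class = "sbDesign", list(
    family = "spatial", nBeads = as.integer(nBeads), fieldSize = fieldSize,
    umisPerBead = as.integer(umisPerBead), errorRate = errorRate,
    baseQ = as.integer(baseQ)))
}

#' Design an anchored long-read barcode/variant library
#'
#' Each read embeds a 13-base clone barcode and a variant region, both
#' flanked by 20-base constant motifs, at variable offsets; flanks receive
#' up to `flankErrors` substitutions in their outer region to exercise
#' fuzzy anchoring (inner 3 bases exact, up to 2 outer mismatches).
#'
#' @param nClones number of barcoded clones.
#' @param variantLen variant region length.
#' @param readsPerClone reads per clone.
#' @param flankErrors substitutions injected into each outer flank region.
#' @param baseQ constant per-base Phred score.
#' @return a design list for [simulateStructuredReads()].
#' @export
longreadDesign <- function(nClones = 30L, variantLen = 60L,
                           readsPerClone = 4L, flankErrors = 0L,
                           baseQ = 30L) {
  structure(class = "sbDesign", list(
    family = "longread", nClones = as.integer(nClones),
    variantLen = as.integer(variantLen),
    readsPerClone = as.integer(readsPerClone),
    flankErrors = as.integer(flankErrors), baseQ = as.integer(baseQ)))
}

# ---- destination presets ---------------------------------------------------

#' Destination presets for scRNA-seq translations
#'
#' `destChromiumV3()` declares the droplet V3 layout: a 16-base cell
#' identifier and a 12-base UMI on output read 1, payload pass-through on
#' output read 2. `destHypothetical(dir)` declares a deliberately small
#' multilayered layout: the cell identifier is rendered through two units
#' (one unit drawn from a ten-sequence 4-base allowlist written into `dir`,
#' one `NNNN` template; capacity 2560) and the UMI through a 7-base
#' template (capacity 16384). `destDropseq()` uses 12-base cell and 8-base
#' UMI templates.
#'
#' @param cdnaVariable name of the pass-through payload variable.
#' @param cellVariable,umiVariable source variable names.
#' @param dir directory receiving the unit allowlist file.
#' @return list of [DestinationSpec-class] objects.
#' @export
destChromiumV3 <- function(cellVariable = "cell", umiVariable = "umi",
                           cdnaVariable = "cdna") {
  list(
    destinationSpec("cellDst", cellVariable, "reassign",
                    units = list(list(kind = "iupac",
                                      template = strrep("N", 16L))),
                    readIndex = 0L, order = 0L),
    destinationSpec("umiDst", umiVariable, "reassign",
                    units = list(list(kind = "iupac",
                                      template = strrep("N", 12L))),
                    readIndex = 0L, order = 1L),
    destinationSpec("cdnaDst", cdnaVariable, "passthrough",
                    readIndex = 1L, order = 0L))
}

#' @rdname destChromiumV3
#' @export
destHypothetical <- function(dir, cellVariable = "cell",
                             umiVariable = "umi", cdnaVariable = "cdna") {
  unitPath <- file.path(dir, "hyp_unit_allowlist.txt")
  if (!file.exists(unitPath))
    writeLines(c("AACC", "AAGG", "ACAC", "AGAG", "CCAA", "CCTT", "CTCT",
                 "GGAA", "GGTT", "GTGT"), unitPath)
  list(
    destinationSpec("cellDst", cellVariable, "reassign",
                    units = list(list(kind = "allowlist", path = unitPath),
                                 list(kind = "iupac", template = "NNNN")),
                    readIndex = 0L, order = 0L),
    destinationSpec("umiDst", umiVariable, "reassign",
                    units = list(list(kind = "iupac", template = "NNNNNNN")),
                    readIndex = 0L, order = 1L),
    destinationSpec("cdnaDst", cdnaVariable, "passthrough",
                    readIndex = 1L, order = 0L))
}

#' @rdname destChromiumV3
#' @export
destDropseq <- function(cellVariable = "cell", umiVariable = "umi",
                        cdnaVariable = "cdna") {
  list(
    destinationSpec("cellDst", cellVariable, "reassign",
                    units = list(list(kind = "iupac",
                                      template = strrep("N", 12L))),
                    readIndex = 0L, order = 0L),
    destinationSpec("umiDst", umiVariable, "reassign",
                    units = list(list(kind = "iupac",
                                      template = strrep("N", 8L))),
                    readIndex = 0L, order = 1L),
    destinationSpec("cdnaDst", cdnaVariable, "passthrough",
                    readIndex = 1L, order = 0L))
}

# ---- simulators ------------------------------------------------------------

#' Simulate a structured-read library with ground truth
#'
#' Generates FASTQ files, allowlists, a matching process configuration and
#' a per-read truth table for the requested library family. The same seed
#' reproduces byte-identical output; with `errorRate = 0` the reads are
#' exactly decodable (extraction recovers the truth verbatim).
#'
#' @param design a design from [scrnaDesign()], [rcppcrDesign()],
#'   [atacDesign()], [spatialDesign()] or [longreadDesign()].
#' @param dir output directory (created).
#' @param seed integer seed governing all randomness of the simulation.
#' @param destinations optional list of [DestinationSpec-class] overriding
#'   the family's default destination layout.
#' @return list with `config` (a [PipelineConfig-class]), `configPath`,
#'   `fastqs` (input FASTQ paths in read-tuple order), `truth` (per-read
#'   data.frame) and family-specific extras (allowlist paths, bead
#'   coordinates, well tables).
#' @export
simulateStructuredReads <- function(design, dir, seed = 1L,
                                    destinations = NULL) {
  stopifnot(inherits(design, "sbDesign"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  withSimSeed(seed, switch(design$family,
    scrna = .simScrna(design, dir, destinations),
    rcppcr = .simRcppcr(design, dir),
    combinatorial_atac = .simAtac(design, dir, destinations),
    spatial = .simSpatial(design, dir, destinations),
    longread = .simLongread(design, dir),
    stop("unknown design family '", design$family, "'")))
}

.truncGeom <- function(n, p, maxK) {
  k <- stats::rgeom(n, p) + 1L
  ((k - 1L) %% maxK) + 1L
}

.simScrna <- function(d, dir, destinations) {
  cells <- randomBarcodes(d$nCells, d$cellLen, minDist = 3L)
  genes <- randomSeqs(d$nGenes, 20L)
  while (anyDuplicated(genes)) genes <- randomSeqs(d$nGenes, 20L)
  geneNames <- sprintf("gene%03d", seq_len(d$nGenes))
  pair <- expand.grid(cell = seq_len(d$nCells), gene = seq_len(d$nGenes))
  nu <- .truncGeom(nrow(pair), d$geomP, d$maxUmis)
  cellIdx <- rep(pair$cell, nu)
  geneIdx <- rep(pair$gene, nu)
  nMol <- length(cellIdx)
  umis <- randomSeqs(nMol, d$umiLen)
  # distinct UMIs within each (cell, gene): regenerate clashes
  key <- paste(cellIdx, geneIdx, umis)
  while (anyDuplicated(key)) {
    dup <- duplicated(key)
    umis[dup] <- randomSeqs(sum(dup), d$umiLen)
    key <- paste(cellIdx, geneIdx, umis)
  }
  rep_ <- rep(seq_len(nMol), each = d$readsPerUmi)
  n <- length(rep_)
  ids <- sprintf("read%07d", seq_len(n))
  r1 <- paste0(cells[cellIdx[rep_]], umis[rep_])
  r2 <- genes[geneIdx[rep_]]
  e1 <- injectSubstitutions(r1, d$errorRate)
  e2 <- injectSubstitutions(r2, d$errorRate)
  q1 <- strrep(phredChars(d$baseQ), nchar(r1))
  q2 <- strrep(phredChars(d$baseQ), nchar(r2))
  f1 <- writeFastq(ids, e1$seqs, q1, file.path(dir, "R1.fastq"))
  f2 <- writeFastq(ids, e2$seqs, q2, file.path(dir, "R2.fastq"))
  allowPath <- file.path(dir, "cell_allowlist.txt")
  writeLines(cells, allowPath)

  segs <- list(
    segmentSpec("cellSeg", 0L, start = 0L, end = d$cellLen),
    segmentSpec("umiSeg", 0L, start = d$cellLen,
                end = d$cellLen + d$umiLen),
    segmentSpec("cdnaSeg", 1L, start = 0L, end = NA))
  vars <- list(
    variableSpec("cell", "cellSeg", role = "parental",
                 correction = d$correction, levMax = 1L,
                 allowlistPath = if (d$correction == "allowlist") allowPath
                                 else character(0)),
    variableSpec("umi", "umiSeg", role = "local", parent = "cell",
                 correction = "none", valued = TRUE),
    variableSpec("cdna", "cdnaSeg", role = "independent",
                 correction = "none"))
  if (is.null(destinations)) destinations <- destChromiumV3()
  cfg <- pipelineConfig(list(readStructure("scrna", segs)), vars,
                        qualityPolicy(20, 10), destinations)
  configPath <- file.path(dir, "config.txt")
  writeLines(formatConfig(cfg), configPath)
  truth <- data.frame(read_id = ids, cell = cells[cellIdx[rep_]],
                      umi = umis[rep_], gene = geneNames[geneIdx[rep_]],
                      edits = e1$edits + e2$edits, stringsAsFactors = FALSE)
  list(config = cfg, configPath = configPath, fastqs = c(f1, f2),
       truth = truth, cellAllowlist = allowPath, cells = cells,
       genes = setNames(genes, geneNames))
}

.simRcppcr <- function(d, dir) {
  rbcs <- randomBarcodes(d$rows, 8L)
  cbcs <- randomBarcodes(d$cols, 8L)
  pbcs <- randomBarcodes(d$plates, 8L)
  handles <- c(dbtag = "ACGTTGCACT", dblox = "TGCAACGTGA",
               adtag = "CATGGTACTG", adlox = "GTACCATGAC")
  loxSite <- "ATAACTTCGTATAGCATACA"  # 20-base intact-site proxy
  allowDir <- file.path(dir, "allowlists")
  dir.create(allowDir, showWarnings = FALSE)
  aw <- c(rbc = file.path(allowDir, "rbc.txt"),
          cbc = file.path(allowDir, "cbc.txt"),
          pbc = file.path(allowDir, "pbc.txt"))
  writeLines(rbcs, aw[["rbc"]]); writeLines(cbcs, aw[["cbc"]])
  writeLines(pbcs, aw[["pbc"]])

  nWells <- d$plates * d$wellsPerPlate
  wellPlate <- rep(seq_len(d$plates), each = d$wellsPerPlate)
  wellRow <- integer(0); wellCol <- integer(0)
  for (p in seq_len(d$plates)) {
    pos <- sample.int(d$rows * d$cols, d$wellsPerPlate)
    wellRow <- c(wellRow, (pos - 1L) %/% d$cols + 1L)
    wellCol <- c(wellCol, (pos - 1L) %% d$cols + 1L)
  }
  upPool <- randomBarcodes(nWells + ceiling(nWells / 2), 10L)
  dnPool <- randomBarcodes(nWells + ceiling(nWells / 2), 10L)
  wellUp <- upPool[seq_len(nWells)]
  wellDn <- dnPool[seq_len(nWells)]
  contam <- stats::runif(nWells) < d$contamRate
  extraUp <- upPool[nWells + cumsum(contam)]
  extraDn <- dnPool[nWells + cumsum(contam)]

  ids <- character(0); r1 <- character(0); r2 <- character(0)
  truth <- list()
  brokenLox <- function(k) {
    out <- rep(loxSite, k)
    for (i in seq_len(k)) {
      for (p in sample.int(nchar(loxSite), 2L)) {
        cur <- substr(out[[i]], p, p)
        substr(out[[i]], p, p) <- sample(setdiff(c("A", "C", "G", "T"), cur),
                                         1L)
      }
    }
    out
  }
  emit <- function(struct, well, up, dn, loxOk, n0) {
    h <- handles[[struct]]
    isLox <- grepl("lox", struct)
    lox <- rep("", n0)
    if (isLox) {
      lox <- rep(loxSite, n0)
      if (any(!loxOk)) lox[!loxOk] <- brokenLox(sum(!loxOk))
    }
    # DB structures read the Uptag first; AD structures read the Dntag
    # first, with the partner tag on read 2 of the Tag library
    tag <- if (grepl("^db", struct)) up else dn
    other <- if (grepl("^db", struct)) dn else up
    read1 <- paste0(rbcs[wellRow[well]], h, tag, lox)
    read2 <- paste0(pbcs[wellPlate[well]], cbcs[wellCol[well]],
                    if (!isLox) other else rep("", n0))
    id0 <- sprintf("%s_w%03d_%05d", struct, well,
                   length(ids) + seq_len(n0))
    ids <<- c(ids, id0); r1 <<- c(r1, read1); r2 <<- c(r2, read2)
    truth[[length(truth) + 1L]] <<- data.frame(
      read_id = id0, structure = struct, well = well,
      plate = wellPlate[well], row = wellRow[well], col = wellCol[well],
      uptag = up, dntag = dn, loxValid = if (isLox) loxOk else NA,
      stringsAsFactors = FALSE)
  }
  for (w in seq_len(nWells)) {
    cassette <- if (wellPlate[w] %% 2L == 1L) "db" else "ad"
    nMain <- d$readsPerWell
    nCont <- if (contam[w]) round(d$readsPerWell * d$contamFrac) else 0L
    for (struct in paste0(cassette, c("tag", "lox"))) {
      isLox <- grepl("lox", struct)
      okMain <- if (isLox) stats::runif(nMain) >= d$loxBrokenRate else
        rep(TRUE, nMain)
      emit(struct, w, rep(wellUp[w], nMain), rep(wellDn[w], nMain),
           okMain, nMain)
      if (nCont > 0L) {
        okC <- if (isLox) stats::runif(nCont) >= d$loxBrokenRate else
          rep(TRUE, nCont)
        emit(struct, w, rep(extraUp[w], nCont), rep(extraDn[w], nCont),
             okC, nCont)
      }
    }
  }
  err1 <- injectSubstitutions(r1, d$errorRate)
  err2 <- injectSubstitutions(r2, d$errorRate)
  q1 <- strrep(phredChars(d$baseQ), nchar(r1))
  q2 <- strrep(phredChars(d$baseQ), nchar(r2))
  f1 <- writeFastq(ids, err1$seqs, q1, file.path(dir, "R1.fastq"))
  f2 <- writeFastq(ids, err2$seqs, q2, file.path(dir, "R2.fastq"))

  mkStructure <- function(struct) {
    h <- handles[[struct]]
    isLox <- grepl("lox", struct)
    segs <- list(
      segmentSpec(paste0("rbc_", struct), 0L, start = 0L, end = 8L),
      segmentSpec(paste0("tag_", struct), 0L, upstream = h,
                  innerExact = 3L, outerMaxMismatch = 2L,
                  minLen = 10L, maxLen = 10L),
      segmentSpec(paste0("pbc_", struct), 1L, start = 0L, end = 8L),
      segmentSpec(paste0("cbc_", struct), 1L, start = 8L, end = 16L))
    if (isLox)
      segs <- c(segs, list(segmentSpec(paste0("lox_", struct), 0L,
                                       start = 28L, end = 48L)))
    else
      segs <- c(segs, list(segmentSpec(paste0("dntag_", struct), 1L,
                                       start = 16L, end = 26L)))
    readStructure(struct, segs)
  }
  mkVars <- function(struct) {
    isLox <- grepl("lox", struct)
    v <- list(
      variableSpec(paste0("rbc_", struct), paste0("rbc_", struct),
                   correction = "allowlist", levMax = 1L,
                   allowlistPath = aw[["rbc"]]),
      variableSpec(paste0("cbc_", struct), paste0("cbc_", struct),
                   correction = "allowlist", levMax = 1L,
                   allowlistPath = aw[["cbc"]]),
      variableSpec(paste0("pbc_", struct), paste0("pbc_", struct),
                   correction = "allowlist", levMax = 1L,
                   allowlistPath = aw[["pbc"]]),
      variableSpec(paste0("tag_", struct), paste0("tag_", struct),
                   correction = "none", valued = TRUE))
    if (isLox)
      v <- c(v, list(variableSpec(paste0("lox_", struct),
                                  paste0("lox_", struct),
                                  correction = "none")))
    else
      v <- c(v, list(variableSpec(paste0("dntag_", struct),
                                  paste0("dntag_", struct),
                                  correction = "none", valued = TRUE)))
    v
  }
  structNames <- names(handles)
  cfg <- pipelineConfig(lapply(structNames, mkStructure),
                        do.call(c, lapply(structNames, mkVars)),
                        qualityPolicy(20, 10))
  configPath <- file.path(dir, "config.txt")
  writeLines(formatConfig(cfg), configPath)
  truth <- do.call(rbind, truth)
  wells <- data.frame(well = seq_len(nWells), plate = wellPlate,
                      row = wellRow, col = wellCol, uptag = wellUp,
                      dntag = wellDn, contaminated = contam,
                      stringsAsFactors = FALSE)
  list(config = cfg, configPath = configPath, fastqs = c(f1, f2),
       truth = truth, wells = wells, allowlists = aw, loxSite = loxSite,
       handles = handles)
}

.simAtac <- function(d, dir, destinations) {
  tiers <- lapply(1:4, function(i) randomBarcodes(d$tierSize, 8L))
  allowDir <- file.path(dir, "allowlists")
  dir.create(allowDir, showWarnings = FALSE)
  aw <- vapply(1:4, function(i) {
    p <- file.path(allowDir, sprintf("tier%d.txt", i))
    writeLines(tiers[[i]], p); p
  }, "")
  combos <- unique(replicate(d$nCells * 2L,
    vapply(tiers, sample, "", size = 1L), simplify = FALSE))
  combos <- combos[seq_len(min(d$nCells, length(combos)))]
  cellIdx <- rep(seq_along(combos), each = d$readsPerCell)
  n <- length(cellIdx)
  ids <- sprintf("read%07d", seq_len(n))
  g1 <- randomSeqs(n, d$gdnaLen)
  g2 <- randomSeqs(n, d$gdnaLen)
  i1 <- vapply(combos, function(cb) paste0(cb[[1L]], cb[[2L]]), "")[cellIdx]
  i2 <- vapply(combos, function(cb) paste0(cb[[3L]], cb[[4L]]), "")[cellIdx]
  e <- lapply(list(g1, g2, i1, i2), injectSubstitutions, rate = d$errorRate)
  q <- function(x) strrep(phredChars(d$baseQ), nchar(x))
  paths <- file.path(dir, c("R1.fastq", "R2.fastq", "I1.fastq", "I2.fastq"))
  f <- mapply(writeFastq, list(ids, ids, ids, ids),
              lapply(e, `[[`, "seqs"),
              lapply(lapply(e, `[[`, "seqs"), q), paths)
  segs <- list(
    segmentSpec("gdna1Seg", 0L, start = 0L, end = NA),
    segmentSpec("gdna2Seg", 1L, start = 0L, end = NA),
    segmentSpec("tier1Seg", 2L, start = 0L, end = 8L),
    segmentSpec("tier2Seg", 2L, start = 8L, end = 16L),
    segmentSpec("tier3Seg", 3L, start = 0L, end = 8L),
    segmentSpec("tier4Seg", 3L, start = 8L, end = 16L))
  vars <- list(
    variableSpec("cell", paste0("tier", 1:4, "Seg"), role = "independent",
                 correction = "allowlist", levMax = 1L, allowlistPath = aw),
    variableSpec("gdna1", "gdna1Seg", correction = "none"),
    variableSpec("gdna2", "gdna2Seg", correction = "none"))
  if (is.null(destinations))
    destinations <- list(
      destinationSpec("cellDst", "cell", "reassign",
                      units = list(list(kind = "iupac",
                                        template = strrep("N", 16L))),
                      readIndex = 1L, order = 0L),
      destinationSpec("gdna1Dst", "gdna1", "passthrough",
                      readIndex = 0L, order = 0L),
      destinationSpec("gdna2Dst", "gdna2", "passthrough",
                      readIndex = 2L, order = 0L))
  cfg <- pipelineConfig(list(readStructure("atac", segs)), vars,
                        qualityPolicy(20, 5), destinations)
  configPath <- file.path(dir, "config.txt")
  writeLines(formatConfig(cfg), configPath)
  truth <- data.frame(read_id = ids,
                      cell = vapply(combos, paste, "", collapse = "+")[cellIdx],
                      stringsAsFactors = FALSE)
  list(config = cfg, configPath = configPath, fastqs = f, truth = truth,
       allowlists = aw, combos = combos)
}

.simSpatial <- function(d, dir, destinations) {
  beads <- data.frame(
    barcode = randomBarcodes(d$nBeads, 14L),
    x = stats::runif(d$nBeads, 0, d$fieldSize),
    y = stats::runif(d$nBeads, 0, d$fieldSize), stringsAsFactors = FALSE)
  beadIdx <- rep(seq_len(d$nBeads), each = d$umisPerBead)
  n <- length(beadIdx)
  ids <- sprintf("read%07d", seq_len(n))
  umis <- randomSeqs(n, 9L)
  pay <- randomSeqs(n, 20L)
  r1 <- paste0(beads$barcode[beadIdx], umis)
  e1 <- injectSubstitutions(r1, d$errorRate)
  q <- function(x) strrep(phredChars(d$baseQ), nchar(x))
  f1 <- writeFastq(ids, e1$seqs, q(r1), file.path(dir, "R1.fastq"))
  f2 <- writeFastq(ids, pay, q(pay), file.path(dir, "R2.fastq"))
  allowPath <- file.path(dir, "bead_allowlist.txt")
  writeLines(beads$barcode, allowPath)
  segs <- list(
    segmentSpec("beadSeg", 0L, start = 0L, end = 14L),
    segmentSpec("umiSeg", 0L, start = 14L, end = 23L),
    segmentSpec("cdnaSeg", 1L, start = 0L, end = NA))
  vars <- list(
    variableSpec("bead", "beadSeg", role = "parental",
                 correction = "allowlist", levMax = 1L,
                 allowlistPath = allowPath),
    variableSpec("umi", "umiSeg", role = "local", parent = "bead",
                 correction = "none", valued = TRUE),
    variableSpec("cdna", "cdnaSeg", correction = "none"))
  cfg <- pipelineConfig(list(readStructure("beadarray", segs)), vars,
                        qualityPolicy(20, 5),
                        if (is.null(destinations)) list() else destinations)
  configPath <- file.path(dir, "config.txt")
  writeLines(formatConfig(cfg), configPath)
  truth <- data.frame(read_id = ids, bead = beads$barcode[beadIdx],
                      umi = umis, stringsAsFactors = FALSE)
  list(config = cfg, configPath = configPath, fastqs = c(f1, f2),
       truth = truth, beads = beads, beadAllowlist = allowPath)
}

.simLongread <- function(d, dir) {
  up1 <- "TCAGGACTGAACTTGCACCA"; dn1 <- "GTTCACGGATCCTAGCAATG"
  up2 <- "CCATTAGGCTTACCAGTGGA"; dn2 <- "TGGATCACGTTCAGGCCTAA"
  bcs <- randomBarcodes(d$nClones, 13L)
  vars <- randomSeqs(d$nClones, d$variantLen)
  cloneIdx <- rep(seq_len(d$nClones), each = d$readsPerClone)
  n <- length(cloneIdx)
  ids <- sprintf("read%07d", seq_len(n))
  mangleOuter <- function(motif, innerSide) {
    # substitutions restricted to the outer 17 bases of a 20-base flank
    if (d$flankErrors == 0L) return(rep(motif, n))
    out <- rep(motif, n)
    for (i in seq_len(n)) {
      pos <- sample(if (innerSide == "right") 1:17 else 4:20, d$flankErrors)
      for (p in pos) {
        cur <- substr(out[[i]], p, p)
        substr(out[[i]], p, p) <-
          sample(setdiff(c("A", "C", "G", "T"), cur), 1L)
      }
    }
    out
  }
  lead <- vapply(sample(5:15, n, replace = TRUE), function(k)
    paste(sample(c("A", "C", "G", "T"), k, replace = TRUE), collapse = ""),
    "")
  mid <- randomSeqs(n, 10L)
  reads <- paste0(lead, mangleOuter(up1, "right"), bcs[cloneIdx],
                  mangleOuter(dn1, "left"), mid,
                  mangleOuter(up2, "right"), vars[cloneIdx],
                  mangleOuter(dn2, "left"))
  q1 <- strrep(phredChars(d$baseQ), nchar(reads))
  f1 <- writeFastq(ids, reads, q1, file.path(dir, "R1.fastq"))
  segs <- list(
    segmentSpec("bcSeg", 0L, upstream = up1, downstream = dn1,
                innerExact = 3L, outerMaxMismatch = 2L,
                minLen = 13L, maxLen = 13L),
    segmentSpec("varSeg", 0L, upstream = up2, downstream = dn2,
                innerExact = 3L, outerMaxMismatch = 2L,
                minLen = max(10L, d$variantLen - 20L),
                maxLen = d$variantLen + 20L))
  vs <- list(
    variableSpec("clonebc", "bcSeg", role = "parental",
                 correction = "imputation", levMax = 1L),
    variableSpec("variant", "varSeg", role = "independent",
                 correction = "none"))
  cfg <- pipelineConfig(list(readStructure("longread", segs)), vs,
                        qualityPolicy(20, 5))
  configPath <- file.path(dir, "config.txt")
  writeLines(formatConfig(cfg), configPath)
  truth <- data.frame(read_id = ids, barcode = bcs[cloneIdx],
                      variant = vars[cloneIdx], stringsAsFactors = FALSE)
  list(config = cfg, configPath = configPath, fastqs = f1, truth = truth,
       barcodes = bcs, variants = vars,
       flanks = c(up1 = up1, dn1 = dn1, up2 = up2, dn2 = dn2))
}
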