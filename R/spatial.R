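#' @include translate.R
NULL

#' Build a bead-to-spot spatial conversion table by tiling
#'
#' Emulates translating a bead-array spatial library (thousands of randomly
#' placed barcoded beads) into a spotted-array layout (a fixed grid of spot
#' barcodes per slide): slide tiles are laid across the bead field enlarged
#' by `scale`, each scaled bead coordinate is assigned to its containing
#' tile, and within the tile to the Euclidean-nearest spot. Several beads
#' may share a spot (many-to-one); enlarging the field (larger `scale`)
#' raises the fraction of beads that hold a spot of their own.
#'
#' @param beads data.frame with columns `barcode`, `x`, `y` (bead
#'   coordinates in source units).
#' @param spots data.frame with columns `barcode`, `x`, `y`: the spot layout
#'   of one tile, coordinates relative to the tile origin, rows in spot
#'   index order (ties in distance go to the lowest spot index).
#' @param scale multiplier applied to bead coordinates before tiling.
#' @param tileDim numeric `c(width, height)` of one tile; spots must fall
#'   inside.
#' @param grid integer `c(nx, ny)`: number of tiles along x and y, origin at
#'   (0, 0). Scaled beads outside the grid are recorded as unassigned.
#' @return list with `table` (data.frame barcode, tile, spot, and the
#'   concatenated destination `sequence` = spot barcode), `unassigned`
#'   (bead barcodes outside all tiles), `beadsPerSpot` (data.frame tile,
#'   spot, beads), and `uniqueFraction` (fraction of assigned beads that are
#'   the sole bead of their spot).
#' @export
buildSpatialConversionTable <- function(beads, spots, scale = 1,
                                        tileDim = c(max(spots$x) + 1,
                                                    max(spots$y) + 1),
                                        grid = c(1L, 1L)) {
  stopifnot(all(c("barcode", "x", "y") %in% names(beads)),
            all(c("barcode", "x", "y") %in% names(spots)))
  if (!all(is.finite(beads$x)) || !all(is.finite(beads$y)))
    stop("bead coordinates must be finite")
  sx <- beads$x * scale
  sy <- beads$y * scale
  ti <- floor(sx / tileDim[[1L]])
  tj <- floor(sy / tileDim[[2L]])
  inside <- ti >= 0 & ti < grid[[1L]] & tj >= 0 & tj < grid[[2L]]
  lx <- sx - ti * tileDim[[1L]]
  ly <- sy - tj * tileDim[[2L]]
  nearest <- rep(NA_integer_, nrow(beads))
  idx <- which(inside)
  if (length(idx)) {
    # squared distances to every spot of the tile template; lowest spot
    # index wins ties (max.col with "first" on negated distances)
    d2 <- outer(lx[idx], spots$x, "-")^2 + outer(ly[idx], spots$y, "-")^2
    nearest[idx] <- max.col(-d2, ties.method = "first")
  }
  tile <- ifelse(inside, tj * grid[[1L]] + ti, NA_integer_)
  tab <- data.frame(barcode = beads$barcode[inside],
                    tile = as.integer(tile[inside]),
                    spot = spots$barcode[nearest[inside]],
                    stringsAsFactors = FALSE)
  tab$sequence <- tab$spot
  key <- paste(tab$tile, tab$spot)
  perSpot <- as.data.frame(table(key), stringsAsFactors = FALSE)
  occupancy <- setNames(perSpot$Freq, perSpot$key)
  uniqueFrac <- if (nrow(tab)) mean(occupancy[key] == 1L) else NA_real_
  parts <- strsplit(perSpot$key, " ", fixed = TRUE)
  beadsPerSpot <- data.frame(
    tile = as.integer(vapply(parts, `[[`, "", 1L)),
    spot = vapply(parts, `[[`, "", 2L),
    beads = perSpot$Freq, stringsAsFactors = FALSE)
  list(table = tab, unassigned = beads$barcode[!inside],
       beadsPerSpot = beadsPerSpot, uniqueFraction = uniqueFrac)
}

#' Write a spatial conversion table as a two-column TSV
#'
#' Source bead barcode to destination spot barcode, the format accepted by
#' `conversion_table` destinations. Beads of different tiles are written to
#' separate files when `byTile` is set (each tile is one destination
#' library).
#'
#' @param spatial result of [buildSpatialConversionTable()].
#' @param path output path (or directory when `byTile`).
#' @param byTile write one table per tile.
#' @return invisibly, the written path(s).
#' @export
writeSpatialConversionTable <- function(spatial, path, byTile = FALSE) {
  tab <- spatial$table
  if (!byTile) {
    utils::write.table(tab[, c("barcode", "sequence")], path, sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    return(invisible(path))
  }
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  outs <- character(0)
  for (t in sort(unique(tab$tile))) {
    p <- file.path(path, sprintf("tile_%d.tsv", t))
    sub <- tab[tab$tile == t, c("barcode", "sequence")]
    utils::write.table(sub, p, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    outs <- c(outs, p)
  }
  invisible(outs)
}
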