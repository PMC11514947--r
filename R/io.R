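#' Read a count matrix
#'
#' Reads either MatrixMarket triplet counts with companion gene and
#' barcode lists (the 10x convention stores genes in rows; set
#' \code{genesInRows = FALSE} for spot-by-gene files) or a dense CSV/TSV
#' with spot ids in the first column and gene ids as header.
#'
#' @param path .mtx, .csv or .tsv file
#' @param genesPath,barcodesPath companion files for the .mtx route (one
#'   id per line)
#' @param genesInRows for .mtx input, whether rows are genes (default TRUE)
#' @return a \linkS4class{SpatialCounts}
#' @export
readCounts <- function(path, genesPath = NULL, barcodesPath = NULL,
                       genesInRows = TRUE) {
  if (grepl("\\.mtx$", path)) {
    if (is.null(genesPath) || is.null(barcodesPath))
      stop("MTX input needs genesPath and barcodesPath")
    m <- Matrix::readMM(path)
    genes <- readLines(genesPath)
    barcodes <- readLines(barcodesPath)
    if (genesInRows) m <- Matrix::t(m)
    SpatialCounts(as(m, "CsparseMatrix"), spotIds = barcodes, geneIds = genes)
  } else {
    sep <- if (grepl("\\.tsv$", path)) "\t" else ","
    df <- utils::read.csv(path, sep = sep, check.names = FALSE)
    ids <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- ids
    SpatialCounts(m)
  }
}

#' Read spot positions
#'
#' CSV/TSV with columns spot_id, x, y and an optional in_tissue flag
#' (only rows with a truthy flag are kept).
#'
#' @param path file path
#' @return data.frame with spot_id, x, y
#' @export
readSpotPositions <- function(path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- utils::read.csv(path, sep = sep)
  stopifnot(all(c("spot_id", "x", "y") %in% names(df)))
  if ("in_tissue" %in% names(df))
    df <- df[as.logical(df$in_tissue) | df$in_tissue == 1, , drop = FALSE]
  df[, c("spot_id", "x", "y")]
}

#' Read a cell table
#'
#' CSV with columns cell_id, x, y, cell_type, as produced by any nuclei
#' segmentation/classification tool.
#'
#' @param path file path
#' @return data.frame with those four columns
#' @export
readCellTable <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("cell_id", "x", "y", "cell_type") %in% names(df)))
  df[, c("cell_id", "x", "y", "cell_type")]
}

#' Write an image profile as CSV
#'
#' One row per spot: spot_id then one column per cell type.
#'
#' @param image an \linkS4class{ImageProfile}
#' @param path output file
#' @export
writeImageProfile <- function(image, path) {
  df <- data.frame(spot_id = image@spotIds, image@V, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read an image profile written by \code{\link{writeImageProfile}}
#' @param path input file
#' @return an \linkS4class{ImageProfile}
#' @export
readImageProfile <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  V <- as.matrix(df[, -1, drop = FALSE])
  rownames(V) <- df[[1]]
  ImageProfile(V, spotIds = df[[1]])
}

#' Write adjacency as a sparse triplet CSV
#'
#' Columns i, j, value with one row per (unordered, i < j) edge, plus a
#' header comment carrying the ids.
#'
#' @param geo a \linkS4class{GeospatialProfile}
#' @param path output file
#' @export
writeAdjacency <- function(geo, path) {
  tr <- Matrix::summary(as(geo@adjacency, "TsparseMatrix"))
  tr <- tr[tr$i < tr$j, , drop = FALSE]
  utils::write.csv(data.frame(i = geo@spotIds[tr$i], j = geo@spotIds[tr$j],
                              value = tr$x),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write Stage-I domain labels as CSV
#'
#' Columns: spot_id, domain, max_prob, boundary_flag, zone_id (NA for
#' non-boundary spots, 0 for singleton boundary spots).
#'
#' @param call a \linkS4class{DomainCall}
#' @param path output file
#' @export
writeDomainLabels <- function(call, path) {
  zone <- rep(NA_integer_, length(call@zHat))
  for (zi in seq_along(call@zones)) zone[call@zones[[zi]]] <- zi
  zone[call@singletons] <- 0L
  df <- data.frame(spot_id = call@spotIds, domain = call@zHat,
                   max_prob = apply(call@marginalProbs, 1, max),
                   boundary_flag = call@boundary, zone_id = zone)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
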