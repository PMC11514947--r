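#' Normalize counts to log relative expression
#'
#' Divides each count by its spot's size factor (total count) to obtain
#' relative expression, then applies log(x + 1). Spots whose size factor
#' is zero carry no molecular information and are dropped with a warning;
#' the kept-spot mask is attached as attribute \code{"kept"}.
#'
#' @param counts a \linkS4class{SpatialCounts} object
#' @return numeric matrix of log relative expression for the kept spots,
#'   with attribute \code{"kept"}: a named logical over all input spots
#' @examples
#' sc <- SpatialCounts(matrix(rpois(40, 4), 5, 8))
#' norm <- normalizeCounts(sc)
#' @export
normalizeCounts <- function(counts) {
  stopifnot(is(counts, "SpatialCounts"))
  s <- counts@sizeFactors
  kept <- s > 0
  names(kept) <- counts@spotIds
  if (!all(kept))
    warning(sum(!kept), " spot(s) with zero total count dropped: ",
            paste(utils::head(counts@spotIds[!kept], 5), collapse = ", "))
  cts <- as.matrix(counts@counts[kept, , drop = FALSE])
  out <- log1p(cts / s[kept])
  dimnames(out) <- list(counts@spotIds[kept], counts@geneIds)
  attr(out, "kept") <- kept
  out
}

#' Select highly variable genes
#'
#' Ranks genes by the variance of their normalized relative expression
#' and returns the indices of the top \code{nTop}, in decreasing variance
#' order. Ties break by gene index (stable sort), so the selection is
#' deterministic.
#'
#' @param normalized matrix from \code{\link{normalizeCounts}}
#' @param nTop number of genes to keep (default 2000)
#' @return integer vector of column indices, length \code{nTop}
#' @export
selectHVG <- function(normalized, nTop = 2000) {
  P <- ncol(normalized)
  if (nTop > P)
    stop("nTop (", nTop, ") exceeds the number of genes (", P, ")")
  n <- nrow(normalized)
  mu <- colMeans(normalized)
  v <- (colMeans(normalized^2) - mu^2) * n / max(n - 1, 1)
  order(v, decreasing = TRUE)[seq_len(nTop)]
}

#' Reduce dimension by principal component analysis
#'
#' Computes the first \code{pPrime} principal component scores of the
#' column-centered input. Each component's sign is fixed so that its
#' largest-magnitude loading is positive, making the result deterministic
#' across linear algebra backends.
#'
#' @param normalizedHVG matrix restricted to the selected genes
#' @param pPrime number of components to keep (default 3)
#' @param method tag recorded in the result (default "pca")
#' @return a \linkS4class{MolecularProfile}
#' @export
reducePCA <- function(normalizedHVG, pPrime = 3, method = "pca") {
  if (!all(is.finite(normalizedHVG)))
    stop("non-finite values in the normalized matrix")
  if (pPrime > min(dim(normalizedHVG)))
    stop("pPrime exceeds min(n spots, n genes)")
  pc <- stats::prcomp(normalizedHVG, center = TRUE, scale. = FALSE)
  scores <- pc$x[, seq_len(pPrime), drop = FALSE]
  load <- pc$rotation[, seq_len(pPrime), drop = FALSE]
  for (p in seq_len(pPrime)) {
    j <- which.max(abs(load[, p]))
    if (load[j, p] < 0) scores[, p] <- -scores[, p]
  }
  colnames(scores) <- paste0("PC", seq_len(pPrime))
  MolecularProfile(scores, method = method, spotIds = rownames(normalizedHVG))
}

#' Build the spot adjacency graph
#'
#' Two spots are neighbors when their Euclidean distance is below a
#' threshold. With \code{threshold = "auto"} the cutoff is 1.2 times the
#' minimal nonzero inter-spot distance, which is robust to coordinate
#' jitter and yields 4 neighbors per interior spot on square/grid
#' lattices and 6 on triangular lattices.
#'
#' @param coords N-by-2 coordinate matrix (or data.frame with x, y)
#' @param lattice "square", "triangular" or "grid"
#' @param threshold distance cutoff, or "auto"
#' @param spotIds optional identifiers
#' @return a \linkS4class{GeospatialProfile}
#' @examples
#' g <- buildAdjacency(expand.grid(x = 1:3, y = 1:3), "square")
#' Matrix::rowSums(adjacencyMatrix(g))
#' @export
buildAdjacency <- function(coords, lattice = c("square", "triangular", "grid"),
                           threshold = "auto", spotIds = NULL) {
  lattice <- match.arg(lattice)
  coords <- as.matrix(coords[, 1:2])
  storage.mode(coords) <- "double"
  N <- nrow(coords)
  if (N < 2) stop("need at least 2 spots")
  if (anyDuplicated(coords)) stop("duplicate spot coordinates")
  if (is.null(spotIds))
    spotIds <- if (!is.null(rownames(coords))) rownames(coords) else
      paste0("spot", seq_len(N))
  d <- as.matrix(stats::dist(coords))
  if (identical(threshold, "auto"))
    threshold <- 1.2 * min(d[d > 0])
  adj <- Matrix::Matrix((d > 0) & (d < threshold), sparse = TRUE) * 1
  new("GeospatialProfile", coords = coords, lattice = lattice,
      adjacency = as(adj, "generalMatrix"), threshold = threshold,
      spotIds = as.character(spotIds))
}

#' Build the image profile from a cell table
#'
#' Assigns every classified nucleus to the spot whose center is nearest
#' (the spot's "expanded area" is its Voronoi cell, so the whole tissue
#' is tiled and no cell is counted twice), then tabulates cell types per
#' spot.
#'
#' @param cells data.frame with columns cell_id, x, y, cell_type
#' @param geo a \linkS4class{GeospatialProfile} in the same coordinate frame
#' @param cellTypes the cell-type vocabulary; defaults to the sorted
#'   unique types present
#' @return an \linkS4class{ImageProfile}
#' @export
buildImageProfile <- function(cells, geo, cellTypes = NULL) {
  stopifnot(is(geo, "GeospatialProfile"))
  stopifnot(all(c("x", "y", "cell_type") %in% names(cells)))
  if (is.null(cellTypes)) cellTypes <- sort(unique(as.character(cells$cell_type)))
  bad <- setdiff(unique(as.character(cells$cell_type)), cellTypes)
  if (length(bad))
    stop("cell types outside the declared vocabulary: ",
         paste(bad, collapse = ", "))
  centers <- geo@coords
  N <- nrow(centers)
  V <- matrix(0L, N, length(cellTypes),
              dimnames = list(geo@spotIds, cellTypes))
  if (nrow(cells)) {
    # nearest spot center per cell, chunked to bound memory
    idx <- integer(nrow(cells))
    chunk <- 5000L
    xy <- cbind(cells$x, cells$y)
    for (start in seq(1L, nrow(cells), by = chunk)) {
      rows <- start:min(start + chunk - 1L, nrow(cells))
      d2 <- outer(xy[rows, 1], centers[, 1], "-")^2 +
            outer(xy[rows, 2], centers[, 2], "-")^2
      idx[rows] <- max.col(-d2, ties.method = "first")
    }
    tab <- table(factor(idx, levels = seq_len(N)),
                 factor(as.character(cells$cell_type), levels = cellTypes))
    V <- V + unclass(as.matrix(tab))
  }
  dimnames(V) <- list(geo@spotIds, cellTypes)
  ImageProfile(V, cellTypes = cellTypes, spotIds = geo@spotIds)
}

#' Bin single-cell resolution data onto a square grid
#'
#' For imaging-based platforms measured at single-cell resolution, lays a
#' square lattice of side \code{gridSize} over the tissue and treats each
#' occupied unit as a spot. Molecular values are normalized,
#' log-transformed and reduced at the single-cell level, then averaged
#' across the cells of each unit; the image profile counts cell types per
#' unit. Units use half-open intervals [a, b) on both axes with 0-based
#' indices, so a cell on an interior grid line belongs to exactly one
#' unit. Empty units are dropped; adjacency is rook (4-neighbor).
#'
#' @param cellCounts a cell-by-gene \linkS4class{SpatialCounts}
#' @param cells data.frame with cell_id, x, y, cell_type (rows matching
#'   \code{cellCounts} spots)
#' @param gridSize side length of a grid unit, in coordinate units
#' @param nTop number of highly variable genes for the reduction
#' @param pPrime number of components
#' @return list with elements \code{molecular}, \code{image}, \code{geo},
#'   and \code{unitOfCell} (the unit id each cell was assigned to, NA for
#'   cells dropped during normalization)
#' @export
gridBinSingleCell <- function(cellCounts, cells, gridSize, nTop = 2000,
                              pPrime = 3) {
  stopifnot(gridSize > 0, nrow(cells) == length(cellCounts@spotIds))
  ix <- floor((cells$x - min(cells$x)) / gridSize)
  iy <- floor((cells$y - min(cells$y)) / gridSize)
  unit <- paste0("u", ix, "_", iy)
  units <- unique(unit)
  if (length(units) == 1)
    warning("grid so coarse that only one unit remains")

  norm <- normalizeCounts(cellCounts)
  kept <- attr(norm, "kept")
  hvg <- selectHVG(norm, min(nTop, ncol(norm)))
  cellY <- molecularY(reducePCA(norm[, hvg, drop = FALSE], pPrime))

  unitKept <- unit[kept]
  units <- sort(unique(unitKept))
  Y <- do.call(rbind, lapply(units, function(u)
    colMeans(cellY[unitKept == u, , drop = FALSE])))
  rownames(Y) <- units

  V <- unclass(as.matrix(table(
    factor(unit, levels = units),
    factor(as.character(cells$cell_type)))))
  # drop units holding only zero-count cells from all outputs jointly
  centers <- cbind(
    x = min(cells$x) + (as.numeric(sub("u(\\d+)_.*", "\\1", units)) + 0.5) *
      gridSize,
    y = min(cells$y) + (as.numeric(sub(".*_(\\d+)$", "\\1", units)) + 0.5) *
      gridSize)
  rownames(centers) <- units
  geo <- if (length(units) == 1) {
    new("GeospatialProfile", coords = centers, lattice = "grid",
        adjacency = as(Matrix::Matrix(0, 1, 1, sparse = TRUE),
                       "generalMatrix"),
        threshold = 1.2 * gridSize, spotIds = units)
  } else {
    buildAdjacency(centers, lattice = "grid",
                   threshold = 1.2 * gridSize, spotIds = units)
  }
  list(molecular = MolecularProfile(Y, method = "mean-pooled pca",
                                    spotIds = units),
       image = ImageProfile(V[units, , drop = FALSE], spotIds = units),
       geo = geo,
       unitOfCell = ifelse(kept, unit, NA_character_))
}

#' Prepare the three model profiles from raw inputs
#'
#' Convenience wrapper running the standard NGS-based preparation:
#' normalize counts, select highly variable genes, reduce by PCA, build
#' the adjacency graph, and tabulate the image profile from a cell table
#' (or accept a precomputed abundance table). Spots with zero total
#' counts are removed from all three profiles jointly.
#'
#' @param counts a \linkS4class{SpatialCounts}
#' @param coords N-by-2 coordinates aligned with \code{counts} spots
#' @param cells optional cell table (cell_id, x, y, cell_type)
#' @param abundance optional precomputed spot-by-cell-type count matrix
#'   (used when \code{cells} is NULL)
#' @param lattice lattice type for the adjacency
#' @param nTop,pPrime,threshold tuning parameters (defaults 2000, 3, auto)
#' @return list with elements \code{molecular}, \code{image}, \code{geo}
#' @export
prepareProfiles <- function(counts, coords, cells = NULL, abundance = NULL,
                            lattice = "triangular", nTop = 2000, pPrime = 3,
                            threshold = "auto") {
  norm <- normalizeCounts(counts)
  kept <- attr(norm, "kept")
  coords <- as.matrix(coords[, 1:2])[kept, , drop = FALSE]
  rownames(coords) <- counts@spotIds[kept]
  hvg <- selectHVG(norm, min(nTop, ncol(norm)))
  mol <- reducePCA(norm[, hvg, drop = FALSE], pPrime)
  geo <- buildAdjacency(coords, lattice = lattice, threshold = threshold,
                        spotIds = counts@spotIds[kept])
  img <- if (!is.null(cells)) {
    buildImageProfile(cells, geo)
  } else if (!is.null(abundance)) {
    ImageProfile(as.matrix(abundance)[kept, , drop = FALSE],
                 spotIds = counts@spotIds[kept])
  } else stop("supply either a cell table or an abundance table")
  list(molecular = mol, image = img, geo = geo)
}
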