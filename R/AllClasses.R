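#' @importClassesFrom Matrix Matrix
NULL

setClassUnion("matrixOrMatrix", c("matrix", "Matrix"))

#' Spot-level count matrix
#'
#' Raw spot-by-gene (or cell-by-gene) integer counts with per-spot size
#' factors. Size factors default to the per-spot total count and are used
#' both for normalization ahead of dimension reduction and as offsets in
#' the Stage-II negative binomial regression.
#'
#' @slot counts spot-by-gene non-negative count matrix (base or Matrix)
#' @slot spotIds character vector of spot (or cell) identifiers
#' @slot geneIds character vector of gene identifiers
#' @slot sizeFactors numeric vector of per-spot totals; spots with a zero
#'   size factor are permitted here but are dropped by
#'   \code{\link{normalizeCounts}}
#' @export
setClass("SpatialCounts",
  representation(counts = "matrixOrMatrix", spotIds = "character",
                 geneIds = "character", sizeFactors = "numeric"))

setValidity("SpatialCounts", function(object) {
  cts <- object@counts
  msg <- character()
  if (nrow(cts) != length(object@spotIds))
    msg <- c(msg, "nrow(counts) != length(spotIds)")
  if (ncol(cts) != length(object@geneIds))
    msg <- c(msg, "ncol(counts) != length(geneIds)")
  if (length(object@sizeFactors) != nrow(cts))
    msg <- c(msg, "sizeFactors length != number of spots")
  if (anyDuplicated(object@spotIds))
    msg <- c(msg, "duplicated spot ids")
  if (anyDuplicated(object@geneIds))
    msg <- c(msg, "duplicated gene ids")
  if (min(cts) < 0) msg <- c(msg, "negative counts")
  if (any(object@sizeFactors < 0)) msg <- c(msg, "negative size factors")
  if (length(msg)) msg else TRUE
})

#' Construct a SpatialCounts object
#'
#' @param counts spot-by-gene non-negative matrix
#' @param spotIds,geneIds identifiers; default from dimnames or generated
#' @param sizeFactors per-spot totals; defaults to row sums
#' @return a \linkS4class{SpatialCounts} object
#' @examples
#' sc <- SpatialCounts(matrix(rpois(12, 5), 3, 4))
#' sizeFactors(sc)
#' @export
SpatialCounts <- function(counts, spotIds = NULL, geneIds = NULL,
                          sizeFactors = NULL) {
  if (is.null(spotIds))
    spotIds <- if (!is.null(rownames(counts))) rownames(counts) else
      paste0("spot", seq_len(nrow(counts)))
  if (is.null(geneIds))
    geneIds <- if (!is.null(colnames(counts))) colnames(counts) else
      paste0("gene", seq_len(ncol(counts)))
  if (is.null(sizeFactors)) sizeFactors <- Matrix::rowSums(counts)
  new("SpatialCounts", counts = counts, spotIds = as.character(spotIds),
      geneIds = as.character(geneIds),
      sizeFactors = as.numeric(sizeFactors))
}

#' Molecular profile: low-dimensional expression representation
#'
#' Holds the spot-by-P' matrix Y of low-dimensional expression values
#' (by default the top principal component scores of the normalized,
#' log-transformed, highly variable genes).
#'
#' @slot Y numeric spot-by-P' matrix of scores
#' @slot method reduction used ("pca", "mean-pooled pca", "simulated", ...)
#' @slot spotIds spot identifiers matching the source counts
#' @export
setClass("MolecularProfile",
  representation(Y = "matrix", method = "character", spotIds = "character"))

setValidity("MolecularProfile", function(object) {
  msg <- character()
  if (!all(is.finite(object@Y))) msg <- c(msg, "non-finite entries in Y")
  if (nrow(object@Y) != length(object@spotIds))
    msg <- c(msg, "nrow(Y) != length(spotIds)")
  if (length(msg)) msg else TRUE
})

#' Construct a MolecularProfile
#'
#' @param Y spot-by-P' score matrix
#' @param method reduction tag
#' @param spotIds identifiers; default from rownames
#' @return a \linkS4class{MolecularProfile}
#' @export
MolecularProfile <- function(Y, method = "pca", spotIds = NULL) {
  if (is.null(spotIds))
    spotIds <- if (!is.null(rownames(Y))) rownames(Y) else
      paste0("spot", seq_len(nrow(Y)))
  new("MolecularProfile", Y = as.matrix(Y), method = method,
      spotIds = as.character(spotIds))
}

#' Image profile: cell-type abundance table
#'
#' Spot-by-cell-type counts of AI-classified nuclei assigned to each spot
#' and its expanded area. Zero-cell spots are permitted; their
#' multinomial likelihood term is vacuous.
#'
#' @slot V non-negative integer spot-by-Q matrix of cell counts
#' @slot cellTypes the Q cell-type names
#' @slot spotIds spot identifiers
#' @slot totals per-spot total cell counts m_i (row sums of V)
#' @export
setClass("ImageProfile",
  representation(V = "matrix", cellTypes = "character",
                 spotIds = "character", totals = "numeric"))

setValidity("ImageProfile", function(object) {
  msg <- character()
  if (ncol(object@V) < 2) msg <- c(msg, "need at least 2 cell types")
  if (any(object@V < 0)) msg <- c(msg, "negative cell counts")
  if (any(object@V != round(object@V))) msg <- c(msg, "non-integer cell counts")
  if (!isTRUE(all.equal(unname(rowSums(object@V)), unname(object@totals))))
    msg <- c(msg, "totals do not equal row sums of V")
  if (ncol(object@V) != length(object@cellTypes))
    msg <- c(msg, "ncol(V) != length(cellTypes)")
  if (nrow(object@V) != length(object@spotIds))
    msg <- c(msg, "nrow(V) != length(spotIds)")
  if (length(msg)) msg else TRUE
})

#' Construct an ImageProfile
#'
#' @param V spot-by-cell-type count matrix
#' @param cellTypes,spotIds identifiers; default from dimnames
#' @return an \linkS4class{ImageProfile}
#' @export
ImageProfile <- function(V, cellTypes = NULL, spotIds = NULL) {
  if (is.null(cellTypes))
    cellTypes <- if (!is.null(colnames(V))) colnames(V) else
      paste0("type", seq_len(ncol(V)))
  if (is.null(spotIds))
    spotIds <- if (!is.null(rownames(V))) rownames(V) else
      paste0("spot", seq_len(nrow(V)))
  V <- as.matrix(V)
  storage.mode(V) <- "double"
  new("ImageProfile", V = V, cellTypes = as.character(cellTypes),
      spotIds = as.character(spotIds), totals = as.numeric(rowSums(V)))
}

#' Geospatial profile: coordinates and adjacency
#'
#' Spot coordinates on a square, triangular or manually added grid
#' lattice, together with the binary symmetric adjacency matrix G built
#' by thresholding pairwise Euclidean distances. Interior spots have 4
#' neighbors on square/grid lattices and 6 on triangular lattices.
#'
#' @slot coords numeric N-by-2 matrix of spot centers (platform units)
#' @slot lattice one of "square", "triangular", "grid"
#' @slot adjacency sparse binary symmetric adjacency with zero diagonal
#' @slot threshold the distance cutoff that was applied
#' @slot spotIds spot identifiers
#' @export
setClass("GeospatialProfile",
  representation(coords = "matrix", lattice = "character",
                 adjacency = "Matrix", threshold = "numeric",
                 spotIds = "character"))

setValidity("GeospatialProfile", function(object) {
  msg <- character()
  G <- object@adjacency
  if (ncol(object@coords) != 2) msg <- c(msg, "coords must have 2 columns")
  if (nrow(G) != nrow(object@coords))
    msg <- c(msg, "adjacency dimension != number of spots")
  if (!Matrix::isSymmetric(G)) msg <- c(msg, "adjacency not symmetric")
  if (any(Matrix::diag(G) != 0)) msg <- c(msg, "adjacency diagonal not zero")
  vals <- unique(G@x)
  if (length(vals) && !all(vals %in% c(0, 1)))
    msg <- c(msg, "adjacency entries must be 0/1")
  if (!object@lattice %in% c("square", "triangular", "grid"))
    msg <- c(msg, "lattice must be square, triangular or grid")
  if (length(msg)) msg else TRUE
})

#' Posterior chain from the Stage-I Gibbs sampler
#'
#' Post-burn-in draws of domain labels z, normal sub-component parameters
#' (mu, Sigma) and cell-type compositions omega. When relabeled, every
#' stored draw satisfies the order restriction that omega[, qRef] is
#' decreasing in the domain index.
#'
#' @slot zDraws U-by-N integer matrix of label draws (1..K)
#' @slot mu K-by-P'-by-U array of domain mean draws
#' @slot sigma K-by-P'-by-P'-by-U array of domain covariance draws
#' @slot omega K-by-Q-by-U array of composition draws
#' @slot K number of domains
#' @slot w image-profile weight in [0, 1]
#' @slot f MRF smoothness parameter
#' @slot d MRF offsets (length K)
#' @slot priors the hyperparameter list used (see \code{\link{domainPriors}})
#' @slot burnIn,nIter burn-in and total sweep counts
#' @slot seed integer seed fanned out to the sampler streams
#' @slot qRef reference cell-type index used for relabeling (NA if none)
#' @slot covariance "diagonal" or "full"
#' @slot relabeled whether the order restriction was applied
#' @slot spotIds,cellTypes identifiers carried from the profiles
#' @slot adjacency the spot adjacency used (for zone calling)
#' @export
setClass("DomainChain",
  representation(zDraws = "matrix", mu = "array", sigma = "array",
                 omega = "array", K = "integer", w = "numeric",
                 f = "numeric", d = "numeric", priors = "list",
                 burnIn = "integer", nIter = "integer", seed = "integer",
                 qRef = "integer", covariance = "character",
                 relabeled = "logical", spotIds = "character",
                 cellTypes = "character", adjacency = "Matrix"))

setValidity("DomainChain", function(object) {
  msg <- character()
  if (nrow(object@zDraws) < 1) msg <- c(msg, "need at least one stored draw")
  if (any(object@zDraws < 1 | object@zDraws > object@K))
    msg <- c(msg, "label draws outside 1..K")
  if (dim(object@omega)[1] != object@K)
    msg <- c(msg, "omega first dimension != K")
  if (length(msg)) msg else TRUE
})

#' Domain call: point estimates, uncertainty and interactive zones
#'
#' @slot zHat modal domain label per spot
#' @slot marginalProbs N-by-K matrix of marginal posterior probabilities
#' @slot boundary TRUE where no domain reaches the confidence threshold
#' @slot zones list of integer vectors: connected boundary components of
#'   size >= 2 under the spot adjacency (interactive zones)
#' @slot singletons integer vector of isolated boundary spots
#' @slot threshold the confidence cutoff (default 0.9)
#' @slot spotIds spot identifiers
#' @export
setClass("DomainCall",
  representation(zHat = "integer", marginalProbs = "matrix",
                 boundary = "logical", zones = "list",
                 singletons = "integer", threshold = "numeric",
                 spotIds = "character"))

setValidity("DomainCall", function(object) {
  msg <- character()
  rs <- rowSums(object@marginalProbs)
  if (any(abs(rs - 1) > 1e-8))
    msg <- c(msg, "marginal probability rows must sum to 1")
  if (length(object@zHat) != nrow(object@marginalProbs))
    msg <- c(msg, "zHat length != nrow(marginalProbs)")
  if (length(msg)) msg else TRUE
})
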