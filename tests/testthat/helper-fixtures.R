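# Small fixtures shared across test files; everything is generated in
# code so the suite has no binary data.

# tiny dataset from the generative model (64 spots, runs in < 1 s)
tinySim <- function(seed = 3, nRow = 8, nCol = 8, ...) {
  simulateDataset(simulationSpec(nRow = nRow, nCol = nCol, seed = seed, ...))
}

# regular square lattice coordinates
squareCoords <- function(nRow, nCol) {
  coords <- cbind(x = rep(seq_len(nCol), nRow),
                  y = rep(seq_len(nRow), each = nCol))
  rownames(coords) <- paste0("s", seq_len(nRow * nCol))
  coords
}

# triangular (offset-row) lattice coordinates with unit spacing
triCoords <- function(nRow, nCol) {
  coords <- cbind(
    x = rep(seq_len(nCol), nRow) +
      0.5 * (rep(seq_len(nRow), each = nCol) %% 2),
    y = rep(seq_len(nRow), each = nCol) * sqrt(3) / 2)
  rownames(coords) <- paste0("s", seq_len(nRow * nCol))
  coords
}

# hand-built DomainChain with prescribed label draws (for call/zone tests)
handChain <- function(zDraws, adjacency, K = max(zDraws), Q = 2,
                      omega = NULL) {
  U <- nrow(zDraws); N <- ncol(zDraws); P <- 2
  if (is.null(omega)) {
    omega <- array(0, c(K, Q, U))
    for (u in seq_len(U)) omega[, , u] <- rep(1 / Q, K * Q)
  }
  new("DomainChain", zDraws = zDraws,
      mu = array(0, c(K, P, U)),
      sigma = array(rep(diag(P), K * U), c(K, P, P, U)),
      omega = omega, K = as.integer(K), w = 1, f = 1,
      d = rep(1, K), priors = list(), burnIn = 0L, nIter = U,
      seed = 1L, qRef = 1L, covariance = "diagonal", relabeled = TRUE,
      spotIds = paste0("s", seq_len(N)), cellTypes = paste0("t", seq_len(Q)),
      adjacency = as(Matrix::Matrix(adjacency, sparse = TRUE),
                     "generalMatrix"))
}

# brute-force connected components of a spot subset (BFS oracle)
bfsComponents <- function(adj, subset) {
  adj <- as.matrix(adj)
  remaining <- subset
  comps <- list()
  while (length(remaining)) {
    queue <- remaining[1]
    comp <- c()
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (v %in% comp) next
      comp <- c(comp, v)
      nb <- intersect(which(adj[v, ] != 0), remaining)
      queue <- c(queue, setdiff(nb, comp))
    }
    comps[[length(comps) + 1]] <- sort(comp)
    remaining <- setdiff(remaining, comp)
  }
  comps[order(vapply(comps, min, numeric(1)))]
}

# adjusted Rand index (mclust)
ari <- function(a, b) mclust::adjustedRandIndex(a, b)
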