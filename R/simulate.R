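#' Specification of a synthetic SRT dataset
#'
#' Describes a dataset drawn from the same generative model the Stage-I
#' and Stage-II methods assume: a lattice of spots partitioned into K
#' spatially contiguous domains; per-spot cell totals m_i ~ Poisson;
#' cell-type counts v_i ~ Multinomial(m_i, omega[z_i, ]); molecular
#' values y_i ~ MN(mu[z_i, ], Sigma[[z_i]]); and gene counts
#' c_ij ~ NB(s_i lambda_ij, psi) with a multiplicative domain shift
#' exp(lfc) for the designated spaDEG genes in the target domain.
#'
#' Defaults describe a 20 x 20 square lattice with K = 3 contiguous
#' block domains, Q = 4 cell types with dominated compositions
#' (0.7 on the signature type), unit-variance molecular components with
#' mean separation 2.5, 20 cells per spot on average, and 200 null plus
#' 50 shifted genes at log-fold-change 1 - a strong but non-degenerate
#' signal that runs in seconds.
#'
#' @param nRow,nCol lattice dimensions
#' @param lattice "square" or "triangular"
#' @param K number of domains
#' @param partition "blocks" (contiguous vertical bands) or "potts"
#'   (sampled from the MRF prior at strength \code{fTrue})
#' @param fTrue Potts interaction strength for \code{partition = "potts"}
#' @param Q number of cell types
#' @param omega K-by-Q composition matrix (rows on the simplex);
#'   default dominated rows
#' @param mu K-by-P' molecular means; default separation 2.5
#' @param Sigma list of K covariance matrices (default identity)
#' @param cellsPerSpot Poisson mean of the per-spot cell total
#' @param nGenesNull,nGenesDE null and shifted gene counts
#' @param lfc log-fold-change of the shifted genes (natural log)
#' @param baselineMean mean of the per-gene baseline expression level
#' @param dispersion NB size parameter psi (default 2)
#' @param degDomain domain carrying the expression shift (default 1)
#' @param seed integer seed
#' @return list of class "simulationSpec"
#' @export
simulationSpec <- function(nRow = 20, nCol = 20, lattice = "square", K = 3,
                           partition = c("blocks", "potts"), fTrue = 1,
                           Q = 4, omega = NULL, mu = NULL, Sigma = NULL,
                           cellsPerSpot = 20, nGenesNull = 200,
                           nGenesDE = 50, lfc = 1.0, baselineMean = 5,
                           dispersion = 2, degDomain = 1, seed = 1) {
  partition <- match.arg(partition)
  if (is.null(omega)) {
    # dominated compositions with cell type 1's abundance strictly
    # decreasing across domains, so the relabeling order restriction on
    # type 1 identifies every domain
    omega <- matrix(0, K, Q)
    w1 <- seq(0.7, 0.1, length.out = K)
    for (k in seq_len(K)) {
      if (k == 1) {
        omega[1, 1] <- w1[1]
        omega[1, -1] <- (1 - w1[1]) / (Q - 1)
      } else {
        dk <- 2 + ((k - 2) %% (Q - 1))
        rem <- 1 - w1[k]
        omega[k, 1] <- w1[k]
        omega[k, dk] <- 0.6 * rem
        others <- setdiff(seq_len(Q)[-1], dk)
        omega[k, others] <- 0.4 * rem / length(others)
      }
    }
  }
  if (is.null(mu)) {
    mu <- matrix(0, K, 3)
    if (K >= 2)
      for (k in 2:K)
        mu[k, ((k - 2) %% 3) + 1] <- 2.5 * (-1)^((k - 2) %/% 3)
  }
  if (is.null(Sigma)) Sigma <- replicate(K, diag(ncol(mu)), simplify = FALSE)
  spec <- list(nRow = nRow, nCol = nCol, lattice = lattice, K = K,
               partition = partition, fTrue = fTrue, Q = Q, omega = omega,
               mu = mu, Sigma = Sigma, cellsPerSpot = cellsPerSpot,
               nGenesNull = nGenesNull, nGenesDE = nGenesDE, lfc = lfc,
               baselineMean = baselineMean, dispersion = dispersion,
               degDomain = degDomain, seed = seed)
  problems <- character()
  if (K < 1) problems <- c(problems, "K must be >= 1")
  if (nrow(omega) != K || ncol(omega) != Q)
    problems <- c(problems, "omega must be K x Q")
  if (any(omega <= 0) || any(abs(rowSums(omega) - 1) > 1e-8))
    problems <- c(problems, "omega rows must lie on the simplex")
  if (nrow(mu) != K) problems <- c(problems, "mu must have K rows")
  if (length(Sigma) != K) problems <- c(problems, "Sigma must have K blocks")
  if (cellsPerSpot < 0) problems <- c(problems, "cellsPerSpot must be >= 0")
  if (dispersion <= 0) problems <- c(problems, "dispersion must be > 0")
  if (length(problems)) stop(paste(problems, collapse = "; "))
  structure(spec, class = "simulationSpec")
}

.latticeCoords <- function(nRow, nCol, lattice) {
  if (lattice == "triangular") {
    coords <- cbind(
      x = rep(seq_len(nCol), nRow) + 0.5 * (rep(seq_len(nRow), each = nCol) %% 2),
      y = rep(seq_len(nRow), each = nCol) * sqrt(3) / 2)
  } else {
    coords <- cbind(x = rep(seq_len(nCol), nRow),
                    y = rep(seq_len(nRow), each = nCol))
  }
  rownames(coords) <- paste0("spot", seq_len(nRow * nCol))
  coords
}

#' Sample a spatially smooth partition from the Potts model
#'
#' Gibbs-samples labels from the MRF prior
#' pi(z_i = k | z_-i) proportional to exp(d_k + f * n_k(i)); at f = 0
#' the labels are iid uniform over K.
#'
#' @param geo a \linkS4class{GeospatialProfile}
#' @param K number of labels
#' @param f interaction strength (>= 0)
#' @param seed integer seed
#' @param sweeps Gibbs sweeps (default 50)
#' @return integer label vector
#' @export
pottsPartition <- function(geo, K, f, seed = 1, sweeps = 50) {
  stopifnot(sweeps >= 1, f >= 0)
  G <- adjacencyMatrix(geo)
  nb <- .neighborList(G)
  N <- nrow(G)
  set.seed(seed)
  z <- sample.int(K, N, replace = TRUE)
  for (s in seq_len(sweeps)) {
    for (i in seq_len(N)) {
      nn <- tabulate(z[nb[[i]] + 1L], nbins = K)
      p <- exp(f * nn - max(f * nn))
      z[i] <- sample.int(K, 1, prob = p)
    }
  }
  z
}

#' Simulate a full synthetic SRT dataset
#'
#' Draws all observables of the generative model described by a
#' \code{\link{simulationSpec}}: the lattice and adjacency, the true
#' domain partition, the image profile, the molecular profile, and a
#' count matrix with designated spaDEG genes. Deterministic given the
#' spec's seed.
#'
#' @param spec a \code{\link{simulationSpec}}
#' @return list with counts (\linkS4class{SpatialCounts}), molecular
#'   (\linkS4class{MolecularProfile}), image
#'   (\linkS4class{ImageProfile}), geo
#'   (\linkS4class{GeospatialProfile}), trueZ, trueOmega, trueMu,
#'   degGenes (logical), sizeFactorsTrue
#' @export
simulateDataset <- function(spec) {
  stopifnot(inherits(spec, "simulationSpec"))
  set.seed(spec$seed)
  coords <- .latticeCoords(spec$nRow, spec$nCol, spec$lattice)
  geo <- buildAdjacency(coords,
                        lattice = if (spec$lattice == "triangular")
                          "triangular" else "square")
  N <- nrow(coords)

  z <- if (spec$partition == "blocks") {
    col <- rep(seq_len(spec$nCol), spec$nRow)
    as.integer(ceiling(col * spec$K / spec$nCol))
  } else {
    pottsPartition(geo, spec$K, spec$fTrue, seed = spec$seed + 1)
  }

  # image profile: m_i ~ Poisson, v_i ~ Multinomial(m_i, omega[z_i, ])
  m <- rpois(N, spec$cellsPerSpot)
  V <- matrix(0L, N, spec$Q,
              dimnames = list(rownames(coords),
                              paste0("type", seq_len(spec$Q))))
  for (i in seq_len(N))
    if (m[i] > 0) V[i, ] <- rmultinom(1, m[i], spec$omega[z[i], ])

  # molecular profile: y_i ~ MN(mu[z_i, ], Sigma[[z_i]])
  P <- ncol(spec$mu)
  Y <- matrix(0, N, P, dimnames = list(rownames(coords),
                                       paste0("PC", seq_len(P))))
  for (k in seq_len(spec$K)) {
    idx <- which(z == k)
    if (!length(idx)) next
    L <- chol(spec$Sigma[[k]])
    Y[idx, ] <- sweep(matrix(rnorm(length(idx) * P), ncol = P) %*% L,
                      2, spec$mu[k, ], "+")
  }

  # counts: c_ij ~ NB(s_i * lambda_ij, psi)
  nGenes <- spec$nGenesNull + spec$nGenesDE
  baseline <- stats::rgamma(nGenes, shape = 2,
                            rate = 2 / spec$baselineMean)
  deg <- c(rep(FALSE, spec$nGenesNull), rep(TRUE, spec$nGenesDE))
  s <- rlnorm(N, meanlog = 0, sdlog = 0.2)
  lambda <- matrix(baseline, N, nGenes, byrow = TRUE)
  if (any(deg)) {
    inDom <- z == spec$degDomain
    lambda[inDom, deg] <- lambda[inDom, deg] * exp(spec$lfc)
  }
  cts <- matrix(rnbinom(N * nGenes, size = spec$dispersion,
                        mu = s * lambda),
                N, nGenes,
                dimnames = list(rownames(coords),
                                paste0("gene", seq_len(nGenes))))

  list(counts = SpatialCounts(cts),
       molecular = MolecularProfile(Y, method = "simulated"),
       image = ImageProfile(V),
       geo = geo,
       trueZ = z, trueOmega = spec$omega, trueMu = spec$mu,
       degGenes = deg, sizeFactorsTrue = s)
}

#' Write a simulated dataset to disk
#'
#' Writes the same CSV artifacts the readers consume (counts, spot
#' positions, image profile, adjacency) plus truth files true_z.csv,
#' true_omega.csv and true_deg.csv.
#'
#' @param sim result of \code{\link{simulateDataset}}
#' @param dir output directory (created if needed)
#' @return the directory, invisibly
#' @export
writeDataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cts <- as.matrix(countsMatrix(sim$counts))
  utils::write.csv(data.frame(spot_id = spotIds(sim$counts), cts,
                              check.names = FALSE),
                   file.path(dir, "counts.csv"), row.names = FALSE)
  utils::write.csv(data.frame(spot_id = spotIds(sim$geo),
                              x = spotCoords(sim$geo)[, 1],
                              y = spotCoords(sim$geo)[, 2]),
                   file.path(dir, "positions.csv"), row.names = FALSE)
  writeImageProfile(sim$image, file.path(dir, "image_profile.csv"))
  writeAdjacency(sim$geo, file.path(dir, "adjacency.csv"))
  utils::write.csv(data.frame(spot_id = spotIds(sim$geo),
                              domain = sim$trueZ),
                   file.path(dir, "true_z.csv"), row.names = FALSE)
  utils::write.csv(data.frame(domain = seq_len(nrow(sim$trueOmega)),
                              sim$trueOmega),
                   file.path(dir, "true_omega.csv"), row.names = FALSE)
  utils::write.csv(data.frame(gene = geneIds(sim$counts),
                              deg = sim$degGenes),
                   file.path(dir, "true_deg.csv"), row.names = FALSE)
  invisible(dir)
}
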