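#' Hyperparameters for the Stage-I mixture model
#'
#' Builds the prior/hyperparameter list consumed by
#' \code{\link{fitDomains}}. Defaults follow a weakly informative
#' conjugate setup: the normal prior mean defaults to the empirical mean
#' of Y (resolved at fit time when NULL), tau0 = 0.01 so the data
#' dominate the domain means, inverse-Wishart degrees of freedom
#' P' + 1 with identity scale, inverse-gamma(0.1, 0.1) in the diagonal
#' variant, Dirichlet concentration 1/2, MRF offsets d = 1 and
#' smoothness f = 1.
#'
#' @param nu0 normal prior mean vector (NULL = empirical mean of Y)
#' @param tau0 prior precision scale (> 0)
#' @param eta0 inverse-Wishart degrees of freedom (NULL = P' + 1)
#' @param Phi0 inverse-Wishart scale matrix (NULL = identity)
#' @param igShape,igRate inverse-gamma shape/rate for the diagonal
#'   variant's per-component variances
#' @param alpha0 Dirichlet concentration, scalar or length-Q vector
#' @param d MRF offsets, scalar or length-K vector
#' @param f MRF smoothness (>= 0); larger values give smoother domain maps
#'   but risk a phase transition when too large
#' @return list of class "domainPriors"
#' @export
domainPriors <- function(nu0 = NULL, tau0 = 0.01, eta0 = NULL, Phi0 = NULL,
                         igShape = 0.1, igRate = 0.1, alpha0 = 0.5,
                         d = 1, f = 1) {
  stopifnot(tau0 > 0, igShape > 0, igRate > 0, all(alpha0 > 0), f >= 0)
  structure(list(nu0 = nu0, tau0 = tau0, eta0 = eta0, Phi0 = Phi0,
                 igShape = igShape, igRate = igRate, alpha0 = alpha0,
                 d = d, f = f),
            class = "domainPriors")
}

.resolvePriors <- function(priors, Y, Q, K) {
  P <- ncol(Y)
  if (is.null(priors$nu0)) priors$nu0 <- colMeans(Y)
  if (is.null(priors$eta0)) priors$eta0 <- P + 1
  if (is.null(priors$Phi0)) priors$Phi0 <- diag(P)
  if (length(priors$alpha0) == 1) priors$alpha0 <- rep(priors$alpha0, Q)
  if (length(priors$d) == 1) priors$d <- rep(priors$d, K)
  stopifnot(length(priors$nu0) == P, priors$eta0 > P - 1,
            length(priors$alpha0) == Q, length(priors$d) == K)
  priors
}

.asY <- function(molecular) {
  if (is(molecular, "MolecularProfile")) molecularY(molecular)
  else as.matrix(molecular)
}

.asV <- function(image) {
  if (is(image, "ImageProfile")) imageV(image) else as.matrix(image)
}

.neighborList <- function(adjacency) {
  tr <- Matrix::summary(as(adjacency, "TsparseMatrix"))
  split(tr$j - 1L, factor(tr$i, levels = seq_len(nrow(adjacency))))
}

# k-means initialization on standardized Y plus standardized cell-type
# proportions (proportions of zero-cell spots set to 0)
.initLabels <- function(Y, V, K, seed, useImage = TRUE) {
  feat <- scale(Y)
  if (useImage) {
    m <- rowSums(V)
    prop <- V / ifelse(m > 0, m, 1)
    sdp <- apply(prop, 2, stats::sd)
    prop <- sweep(prop, 2, ifelse(sdp > 0, sdp, 1), "/")
    feat <- cbind(feat, prop)
  }
  set.seed(seed)
  km <- try(stats::kmeans(feat, centers = K, nstart = 5, iter.max = 50),
            silent = TRUE)
  if (inherits(km, "try-error")) sample.int(K, nrow(Y), replace = TRUE)
  else km$cluster
}

#' Fit the Stage-I normal-multinomial mixture by Gibbs sampling
#'
#' Partitions the tissue into K histology-based spatial domains by
#' sampling from the joint posterior of domain labels z, normal
#' sub-component parameters (mu_k, Sigma_k) for the molecular profile,
#' and cell-type compositions omega_k for the image profile, under a
#' Markov random field prior on z. Each sweep updates all z_i in index
#' order, then (mu_k, Sigma_k) and omega_k for every domain. Post-burn-in
#' draws are relabeled by the order restriction that omega[, qRef] be
#' decreasing in the domain index, resolving label switching.
#'
#' @param molecular \linkS4class{MolecularProfile} or N-by-P' matrix Y
#' @param image \linkS4class{ImageProfile} or N-by-Q count matrix V
#' @param geo \linkS4class{GeospatialProfile} (or sparse adjacency matrix)
#' @param K number of domains (>= 2)
#' @param priors a \code{\link{domainPriors}} list
#' @param w image-profile weight in [0, 1]; 0.05 is a good default for
#'   spot-level platforms and 0.5 for grid-binned single-cell data;
#'   w = 0 ignores the image profile entirely
#' @param nIter,burnIn total and discarded sweep counts (defaults 2000, 1000)
#' @param seed integer seed; all sampler randomness is derived from it
#' @param covariance "diagonal" (default, appropriate after PCA) or "full"
#' @param qRef reference cell type (index or name) for relabeling;
#'   default the type with the largest global cell count
#' @param temperedOmega when w < 1, temper the multinomial likelihood in
#'   the omega update (alpha_kq = alpha0q + w * sum of counts) so the
#'   conditional matches the tempered full posterior; FALSE reproduces
#'   the untempered update. Both coincide at w = 1.
#' @param relabel apply the order restriction (default TRUE when the
#'   image profile is used with w > 0)
#' @param zInit optional initial labels (default: k-means on standardized
#'   Y and cell-type proportions)
#' @param useImage internal switch for a molecular-only chain that never
#'   touches V (used to verify the w = 0 equivalence); default TRUE
#' @return a \linkS4class{DomainChain}
#' @seealso \code{\link{callDomains}}, \code{\link{estimateComposition}},
#'   \code{\link{computeICL}}, \code{\link{selectK}}
#' @export
fitDomains <- function(molecular, image, geo, K, priors = domainPriors(),
                       w = 0.05, nIter = 2000, burnIn = 1000, seed = 1,
                       covariance = c("diagonal", "full"), qRef = NULL,
                       temperedOmega = TRUE, relabel = NULL, zInit = NULL,
                       useImage = TRUE) {
  covariance <- match.arg(covariance)
  Y <- .asY(molecular)
  V <- .asV(image)
  stopifnot(K >= 2, nIter > burnIn, burnIn >= 0, w >= 0, w <= 1,
            nrow(V) == nrow(Y))
  adjacency <- if (is(geo, "GeospatialProfile")) adjacencyMatrix(geo) else geo
  stopifnot(nrow(adjacency) == nrow(Y))
  priors <- .resolvePriors(priors, Y, ncol(V), K)

  ctypes <- if (is(image, "ImageProfile")) cellTypes(image) else
    colnames(V) %||% paste0("type", seq_len(ncol(V)))
  if (is.null(qRef)) qRef <- which.max(colSums(V))
  if (is.character(qRef)) qRef <- match(qRef, ctypes)
  stopifnot(qRef >= 1, qRef <= ncol(V))

  if (is.null(zInit)) zInit <- .initLabels(Y, V, K, seed, useImage)
  stopifnot(length(zInit) == nrow(Y), all(zInit %in% seq_len(K)))

  storage.mode(V) <- "integer"
  res <- gibbs_fit_cpp(Y, V, .neighborList(adjacency), K,
                       priors$nu0, priors$tau0, priors$eta0, priors$Phi0,
                       priors$igShape, priors$igRate, priors$alpha0,
                       priors$d, priors$f, w,
                       nIter, burnIn, as.integer(seed),
                       covariance == "diagonal", useImage, temperedOmega,
                       as.integer(zInit) - 1L)

  P <- ncol(Y); U <- nIter - burnIn; Q <- ncol(V)
  sigma <- array(res$sigma, dim = c(K, P, P, U))
  chain <- new("DomainChain", zDraws = res$z, mu = res$mu, sigma = sigma,
               omega = res$omega, K = as.integer(K), w = w, f = priors$f,
               d = priors$d, priors = unclass(priors),
               burnIn = as.integer(burnIn), nIter = as.integer(nIter),
               seed = as.integer(seed), qRef = as.integer(qRef),
               covariance = covariance, relabeled = FALSE,
               spotIds = rownames(Y) %||% paste0("spot", seq_len(nrow(Y))),
               cellTypes = ctypes,
               adjacency = as(adjacency, "generalMatrix"))
  if (is.null(relabel)) relabel <- useImage && w > 0
  if (relabel) chain <- relabelChain(chain) else chain
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Relabel one draw by the composition order restriction
#'
#' Permutes domain indices (jointly over z, mu, Sigma and omega) so that
#' the reference cell type's composition omega[, qRef] is strictly
#' decreasing in the domain index; ties break by original index.
#'
#' @param draw list with elements z (length-N labels), mu (K x P'),
#'   sigma (K x P' x P'), omega (K x Q)
#' @param qRef reference cell-type column
#' @return the permuted draw (same structure)
#' @export
relabelDraw <- function(draw, qRef) {
  ord <- order(-draw$omega[, qRef])       # stable: ties keep original index
  if (all(ord == seq_along(ord))) return(draw)
  inv <- order(ord)
  list(z = inv[draw$z],
       mu = draw$mu[ord, , drop = FALSE],
       sigma = draw$sigma[ord, , , drop = FALSE],
       omega = draw$omega[ord, , drop = FALSE])
}

#' Apply the order restriction to every stored draw of a chain
#'
#' @param chain a \linkS4class{DomainChain}
#' @param qRef reference cell type (default: the chain's stored qRef)
#' @return the relabeled chain
#' @export
relabelChain <- function(chain, qRef = NULL) {
  qRef <- qRef %||% chain@qRef
  U <- nrow(chain@zDraws)
  for (u in seq_len(U)) {
    ord <- order(-chain@omega[, qRef, u])
    if (all(ord == seq_len(chain@K))) next
    inv <- order(ord)
    chain@zDraws[u, ] <- inv[chain@zDraws[u, ]]
    chain@mu[, , u] <- chain@mu[ord, , u]
    chain@sigma[, , , u] <- chain@sigma[ord, , , u, drop = FALSE]
    chain@omega[, , u] <- chain@omega[ord, , u]
  }
  chain@relabeled <- TRUE
  chain@qRef <- as.integer(qRef)
  chain
}

#' Log likelihood of one spot under one mixture component
#'
#' Evaluates log MN(y; mu_k, Sigma_k) + w * log Multi(v; m, omega_k),
#' the log of the mixture component density that combines the molecular
#' and (tempered) image sub-components. With w = 0 or an empty spot
#' (m = 0) the multinomial term contributes nothing.
#'
#' @param y length-P' molecular vector
#' @param v length-Q cell-type count vector
#' @param mu,Sigma,omega component parameters
#' @param w image weight
#' @return scalar log density
#' @export
logComponentLikelihood <- function(y, v, mu, Sigma, omega, w) {
  Sigma <- as.matrix(Sigma)
  ch <- tryCatch(chol(Sigma), error = function(e)
    stop("Sigma is not symmetric positive definite"))
  q <- backsolve(ch, y - mu, transpose = TRUE)
  ll <- -0.5 * (length(y) * log(2 * pi) + 2 * sum(log(diag(ch))) +
                sum(q^2))
  m <- sum(v)
  if (w > 0 && m > 0)
    ll <- ll + w * stats::dmultinom(v, size = m, prob = omega, log = TRUE)
  ll
}

#' Full-conditional label probabilities for one spot
#'
#' Returns the normalized probabilities pi(z_i = k | .) over k = 1..K,
#' combining the component likelihood with the MRF term
#' exp(d_k + f * n_k(i)) where n_k(i) counts neighbors of spot i
#' currently in domain k. Computed in log space with max-subtraction.
#'
#' @param y,v spot data (length P' and Q)
#' @param mu K-by-P' means
#' @param sigma K-by-P'-by-P' covariances
#' @param omega K-by-Q compositions
#' @param neighborCounts length-K vector n_k(i)
#' @param d length-K MRF offsets
#' @param f MRF smoothness
#' @param w image weight
#' @param covariance "diagonal" or "full"
#' @return length-K probability vector summing to 1
#' @export
zConditionalProbs <- function(y, v, mu, sigma, omega, neighborCounts,
                              d, f, w, covariance = "full") {
  K <- nrow(mu); P <- ncol(mu)
  sigflat <- matrix(0, K, P * P)
  for (k in seq_len(K)) sigflat[k, ] <- as.vector(matrix(sigma[k, , ], P, P))
  as.vector(z_cond_probs_cpp(y, as.integer(v), mu, sigflat, omega,
                             as.integer(neighborCounts), d, f, w,
                             covariance == "diagonal", TRUE))
}

#' Conjugate posterior hyperparameters for one domain
#'
#' Given labels z and the molecular matrix Y, returns the
#' normal-inverse-Wishart posterior hyperparameters
#' (tau_k, eta_k, nu_k, Phi_k) for domain k (\code{covariance = "full"}),
#' or the per-component normal-inverse-gamma hyperparameters
#' (tau_k, shape, nu_k, rate) in the diagonal variant. An empty domain
#' returns the prior.
#'
#' @param Y N-by-P' matrix
#' @param z length-N labels in 1..K
#' @param k domain index
#' @param priors resolved \code{\link{domainPriors}} (nu0 must be set)
#' @param covariance "full" or "diagonal"
#' @return list of posterior hyperparameters
#' @export
conjugatePosterior <- function(Y, z, k, priors, covariance = "full") {
  if (is.null(priors$nu0)) priors$nu0 <- colMeans(Y)
  if (is.null(priors$eta0)) priors$eta0 <- ncol(Y) + 1
  if (is.null(priors$Phi0)) priors$Phi0 <- diag(ncol(Y))
  if (covariance == "full")
    niw_posterior_cpp(Y, as.integer(z), as.integer(k), priors$nu0,
                      priors$tau0, priors$eta0, priors$Phi0)
  else
    nig_posterior_cpp(Y, as.integer(z), as.integer(k), priors$nu0,
                      priors$tau0, priors$igShape, priors$igRate)
}

#' Draw from the normal-inverse-Wishart posterior
#'
#' @param n number of joint draws
#' @param post list from \code{\link{conjugatePosterior}} (full variant)
#' @param seed integer seed
#' @return list with mu (n x P') and Sigma (P' x P' x n)
#' @export
sampleNIW <- function(n, post, seed = 1) {
  sample_niw_cpp(n, post$nu, post$tau, post$eta, post$Phi, as.integer(seed))
}

#' Draw from the normal-inverse-gamma posterior (diagonal variant)
#'
#' @param n number of draws
#' @param post list from \code{\link{conjugatePosterior}} (diagonal variant)
#' @param seed integer seed
#' @return list with mu (n x P') and sig2 (n x P')
#' @export
sampleNIG <- function(n, post, seed = 1) {
  sample_nig_cpp(n, post$nu, post$tau, post$shape, post$rate,
                 as.integer(seed))
}

#' Draw from a Dirichlet distribution
#'
#' @param n number of draws
#' @param alpha concentration vector
#' @param seed integer seed
#' @return n-by-Q matrix of simplex points
#' @export
sampleDirichlet <- function(n, alpha, seed = 1) {
  sample_dirichlet_cpp(n, alpha, as.integer(seed))
}

#' Dirichlet concentration of the omega full conditional
#'
#' alpha_kq = alpha0q + wEff * sum over spots in domain k of v_iq, where
#' wEff = w under the tempered update and 1 under the untempered one.
#'
#' @param V N-by-Q cell counts
#' @param z length-N labels
#' @param k domain
#' @param alpha0 prior concentration (length Q)
#' @param w image weight
#' @param tempered logical
#' @return length-Q concentration vector
#' @export
omegaConcentration <- function(V, z, k, alpha0, w = 1, tempered = TRUE) {
  wl <- if (tempered) w else 1
  alpha0 + wl * colSums(V[z == k, , drop = FALSE])
}
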