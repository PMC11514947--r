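#' Call spatial domains from a posterior chain
#'
#' Estimates per-spot marginal posterior probabilities pi(z_i = k | .) as
#' label frequencies across the stored draws, assigns each spot to the
#' modal domain (argmax; ties go to the lowest index and are necessarily
#' boundary spots), flags boundary spots where no domain reaches the
#' confidence threshold, and groups connected boundary spots (under the
#' spot adjacency) into interactive zones. Singleton boundary components
#' are reported separately.
#'
#' @param chain a \linkS4class{DomainChain}
#' @param threshold confidence cutoff for boundary calling (default 0.9)
#' @return a \linkS4class{DomainCall}
#' @export
callDomains <- function(chain, threshold = 0.9) {
  z <- zDraws(chain)
  U <- nrow(z); N <- ncol(z); K <- chain@K
  probs <- matrix(0, N, K, dimnames = list(chain@spotIds,
                                           paste0("domain", seq_len(K))))
  for (k in seq_len(K)) probs[, k] <- colMeans(z == k)
  zHat <- max.col(probs, ties.method = "first")
  boundary <- apply(probs, 1, max) < threshold

  zones <- list(); singletons <- integer()
  if (any(boundary)) {
    idx <- which(boundary)
    sub <- chain@adjacency[idx, idx, drop = FALSE]
    g <- igraph::graph_from_adjacency_matrix(sub, mode = "undirected")
    comp <- igraph::components(g)
    for (ci in seq_len(comp$no)) {
      members <- unname(idx[comp$membership == ci])
      if (length(members) >= 2) zones[[length(zones) + 1L]] <- members
      else singletons <- c(singletons, members)
    }
  }
  new("DomainCall", zHat = as.integer(zHat), marginalProbs = probs,
      boundary = unname(boundary), zones = zones,
      singletons = as.integer(singletons), threshold = threshold,
      spotIds = chain@spotIds)
}

#' Posterior summaries of domain cell-type compositions
#'
#' Posterior means and equal-tailed credible intervals of omega_kq from
#' the post-burn-in draws.
#'
#' @param chain a \linkS4class{DomainChain}
#' @param level credible level (default 0.95)
#' @return data.frame with domain, cell_type, mean, ci_low, ci_high
#' @export
estimateComposition <- function(chain, level = 0.95) {
  om <- omegaDraws(chain)
  K <- dim(om)[1]; Q <- dim(om)[2]; U <- dim(om)[3]
  if (U < 2) warning("fewer than 2 draws; intervals are degenerate")
  a <- (1 - level) / 2
  out <- expand.grid(domain = seq_len(K), cell_type = chain@cellTypes,
                     stringsAsFactors = FALSE)
  out <- out[order(out$domain), ]
  rownames(out) <- NULL
  stat <- t(apply(out, 1, function(r) {
    k <- as.integer(r[["domain"]])
    q <- match(r[["cell_type"]], chain@cellTypes)
    dr <- om[k, q, ]
    c(mean(dr), stats::quantile(dr, c(a, 1 - a), names = FALSE))
  }))
  out$mean <- stat[, 1]; out$ci_low <- stat[, 2]; out$ci_high <- stat[, 3]
  out
}

#' Posterior probability of a composition contrast
#'
#' Approximates pi(omega[k, q] > omega[kPrime, q] | .) by the fraction of
#' stored draws satisfying the inequality.
#'
#' @param chain a \linkS4class{DomainChain}
#' @param k,kPrime domain indices
#' @param q cell type (index or name)
#' @return scalar probability
#' @export
compositionProb <- function(chain, k, kPrime, q) {
  if (is.character(q)) q <- match(q, chain@cellTypes)
  om <- omegaDraws(chain)
  mean(om[k, q, ] > om[kPrime, q, ])
}

.dmvnormLog <- function(y, mu, Sigma) {
  ch <- chol(Sigma)
  q <- backsolve(ch, y - mu, transpose = TRUE)
  -0.5 * (length(y) * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(q^2))
}

#' Integrated completed likelihood for a fitted chain
#'
#' Computes ICL(K) = -2 log L(Y, V, zHat | plug-in estimates) +
#' d log(N), where the complete-data likelihood is the product over
#' spots of the mixture component density at the modal label, the
#' plug-in estimates are posterior means of (mu, Sigma, omega), and
#' d = 2 K P' + K (Q - 1) is the number of model parameters.
#'
#' @param chain a \linkS4class{DomainChain}
#' @param molecular the molecular profile (or Y matrix) the chain was
#'   fitted to
#' @param image the image profile (or V matrix)
#' @param call optional precomputed \code{\link{callDomains}} result
#' @return list with icl, logLik, dParams, K
#' @export
computeICL <- function(chain, molecular, image, call = NULL) {
  Y <- .asY(molecular); V <- .asV(image)
  K <- chain@K; P <- ncol(Y); Q <- ncol(V); N <- nrow(Y)
  if (is.null(call)) call <- callDomains(chain)
  zHat <- call@zHat
  muHat <- apply(chain@mu, c(1, 2), mean)
  SigHat <- apply(chain@sigma, c(1, 2, 3), mean)
  omHat <- apply(chain@omega, c(1, 2), mean)
  ll <- 0
  for (i in seq_len(N)) {
    k <- zHat[i]
    ll <- ll + .dmvnormLog(Y[i, ], muHat[k, ], matrix(SigHat[k, , ], P, P))
    m <- sum(V[i, ])
    if (chain@w > 0 && m > 0)
      ll <- ll + chain@w * stats::dmultinom(V[i, ], size = m,
                                            prob = omHat[k, ], log = TRUE)
  }
  dParams <- dParamsICL(K, P, Q)
  list(icl = -2 * ll + dParams * log(N), logLik = ll, dParams = dParams,
       K = K)
}

#' Number of model parameters in the ICL penalty
#'
#' d = 2 K P' + K (Q - 1): K mean vectors and K variance vectors of
#' length P' plus K compositions on the (Q - 1)-simplex.
#'
#' @param K,pPrime,Q model dimensions
#' @return integer
#' @export
dParamsICL <- function(K, pPrime, Q) {
  as.integer(2 * K * pPrime + K * (Q - 1))
}

#' Select the number of domains by ICL
#'
#' Fits the Stage-I model for each candidate K and returns the ICL
#' table; the recommended K minimizes ICL.
#'
#' @param molecular,image,geo profiles as in \code{\link{fitDomains}}
#' @param Ks candidate numbers of domains (default 2:6)
#' @param ... further arguments passed to \code{\link{fitDomains}}
#' @return data.frame (K, icl, dParams) with attribute "best" = argmin K
#' @export
selectK <- function(molecular, image, geo, Ks = 2:6, ...) {
  rows <- lapply(Ks, function(K) {
    chain <- fitDomains(molecular, image, geo, K = K, ...)
    icl <- computeICL(chain, molecular, image)
    data.frame(K = K, icl = icl$icl, dParams = icl$dParams)
  })
  out <- do.call(rbind, rows)
  attr(out, "best") <- out$K[which.min(out$icl)]
  out
}
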