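test_that("component log likelihood matches hand-computed normal x binomial", {
  # P' = 1, Q = 2 toy: MN is a univariate normal, Multi is a binomial
  y <- 0.4; v <- c(3, 1); mu <- 0.1; Sigma <- matrix(0.8); om <- c(0.7, 0.3)
  for (w in c(0, 0.3, 1)) {
    expected <- dnorm(y, mu, sqrt(0.8), log = TRUE) +
      w * dbinom(3, 4, 0.7, log = TRUE)
    expect_equal(logComponentLikelihood(y, v, mu, Sigma, om, w), expected)
  }
  # w = 0 reduces exactly to the normal log density
  expect_equal(logComponentLikelihood(y, v, mu, Sigma, om, 0),
               dnorm(y, mu, sqrt(0.8), log = TRUE))
  # empty spot: multinomial term vacuous at any w
  expect_equal(logComponentLikelihood(y, c(0, 0), mu, Sigma, om, 1),
               dnorm(y, mu, sqrt(0.8), log = TRUE))
  # non-SPD covariance rejected
  expect_error(logComponentLikelihood(c(1, 2), v, c(0, 0),
                                      matrix(c(1, 2, 2, 1), 2), om, 1),
               "positive definite")
})

test_that("label conditionals match brute-force enumeration", {
  # symmetric case: identical components, f = 0, w = 0 -> uniform
  mu <- matrix(0, 3, 1); sig <- array(1, c(3, 1, 1))
  om <- matrix(1 / 2, 3, 2)
  p <- zConditionalProbs(0.3, c(2, 1), mu, sig, om, c(5, 0, 0),
                         d = rep(1, 3), f = 0, w = 0)
  expect_equal(p, rep(1 / 3, 3), tolerance = 1e-12)
  # K = 2, P' = 1: enumerate the two unnormalized terms by hand
  mu <- matrix(c(-0.5, 0.8), 2, 1)
  sig <- array(c(0.6, 1.4), c(2, 1, 1))
  om <- rbind(c(0.8, 0.2), c(0.3, 0.7))
  y <- 0.25; v <- c(4, 2); nn <- c(2, 1); d <- c(1, 0.5); f <- 0.7; w <- 0.4
  t1 <- dnorm(y, -0.5, sqrt(0.6), log = TRUE) +
    w * dmultinom(v, prob = om[1, ], log = TRUE) + d[1] + f * nn[1]
  t2 <- dnorm(y, 0.8, sqrt(1.4), log = TRUE) +
    w * dmultinom(v, prob = om[2, ], log = TRUE) + d[2] + f * nn[2]
  oracle <- exp(c(t1, t2)) / sum(exp(c(t1, t2)))
  expect_equal(zConditionalProbs(y, v, mu, sig, om, nn, d, f, w), oracle,
               tolerance = 1e-12)
  expect_equal(sum(zConditionalProbs(y, v, mu, sig, om, nn, d, f, w)), 1,
               tolerance = 1e-12)
})

test_that("MRF term increases the majority-neighbor probability in f", {
  mu <- matrix(0, 2, 1); sig <- array(1, c(2, 1, 1))
  om <- matrix(1 / 2, 2, 2)
  last <- 0
  for (f in c(0, 0.5, 1, 2)) {
    p <- zConditionalProbs(0, c(1, 1), mu, sig, om, c(3, 0),
                           d = c(1, 1), f = f, w = 0)[1]
    expect_gte(p, last)
    last <- p
  }
  expect_gt(last, 0.99)              # saturates toward the unanimous label
})

test_that("conjugate posterior hyperparameters match symbolic recomputation", {
  set.seed(10)
  for (rep in 1:20) {
    N <- sample(3:12, 1); P <- sample(1:3, 1); K <- sample(2:3, 1)
    Y <- matrix(rnorm(N * P), N, P)
    z <- sample(seq_len(K), N, replace = TRUE)
    pri <- domainPriors(nu0 = rnorm(P), tau0 = runif(1, 0.01, 2),
                        eta0 = P + 1 + runif(1), Phi0 = diag(P))
    k <- sample(seq_len(K), 1)
    post <- conjugatePosterior(Y, z, k, pri, covariance = "full")
    # independent symbolic recomputation of the printed formulas
    nk <- sum(z == k)
    expect_equal(post$tau, pri$tau0 + nk)
    expect_equal(post$eta, pri$eta0 + nk)
    if (nk == 0) {
      expect_equal(as.vector(post$nu), pri$nu0)
      expect_equal(post$Phi, pri$Phi0)
    } else {
      ybar <- colMeans(Y[z == k, , drop = FALSE])
      expect_equal(as.vector(post$nu),
                   (pri$tau0 * pri$nu0 + nk * ybar) / (nk + pri$tau0),
                   tolerance = 1e-12)
      S <- matrix(0, P, P)
      for (i in which(z == k)) S <- S + tcrossprod(Y[i, ] - ybar)
      PhiOracle <- pri$Phi0 + S + nk * pri$tau0 / (pri$tau0 + nk) *
        tcrossprod(ybar - pri$nu0)
      expect_equal(post$Phi, PhiOracle, tolerance = 1e-12)
    }
    # diagonal variant
    postd <- conjugatePosterior(Y, z, k, pri, covariance = "diagonal")
    expect_equal(postd$shape, pri$igShape + nk / 2)
    if (nk > 0) {
      ybar <- colMeans(Y[z == k, , drop = FALSE])
      for (p in seq_len(P)) {
        ssq <- sum((Y[z == k, p] - ybar[p])^2)
        expect_equal(postd$rate[p],
                     pri$igRate + 0.5 * (ssq + nk * pri$tau0 /
                       (pri$tau0 + nk) * (ybar[p] - pri$nu0[p])^2),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("prior domination limit pulls the posterior mean to nu0", {
  Y <- matrix(rnorm(30), 10, 3)
  z <- rep(1:2, 5)
  pri <- domainPriors(nu0 = c(5, 5, 5), tau0 = 1e9)
  post <- conjugatePosterior(Y, z, 1, pri)
  expect_equal(as.vector(post$nu), c(5, 5, 5), tolerance = 1e-6)
})

test_that("posterior samplers match analytic moments", {
  # NIW: E[Sigma] = Phi / (eta - P - 1), E[mu] = nu,
  #      Var(mu_p) = E[Sigma_pp] / tau
  post <- list(nu = c(1, -2), tau = 4, eta = 12,
               Phi = matrix(c(3, 1, 1, 2), 2))
  dr <- sampleNIW(30000, post, seed = 42)
  ESig <- apply(dr$Sigma, c(1, 2), mean)
  expect_equal(ESig, post$Phi / (post$eta - 2 - 1), tolerance = 0.03)
  expect_equal(colMeans(dr$mu), post$nu, tolerance = 0.02)
  expect_equal(apply(dr$mu, 2, var),
               diag(post$Phi) / ((post$eta - 2 - 1) * post$tau),
               tolerance = 0.03)
  # NIG: sig2 ~ IG(shape, rate): E = rate / (shape - 1)
  postd <- list(nu = c(0.5), tau = 2, shape = 6, rate = c(10))
  drd <- sampleNIG(30000, postd, seed = 43)
  expect_equal(mean(drd$sig2), 10 / 5, tolerance = 0.03)
  expect_equal(mean(drd$mu), 0.5, tolerance = 0.02)
})

test_that("omega update uses the tempered Dirichlet concentration", {
  V <- rbind(c(3, 1), c(0, 0), c(2, 2))
  z <- c(1, 1, 2)
  # untempered (w = 1): alpha0 + counts
  expect_equal(omegaConcentration(V, z, 1, c(0.5, 0.5), w = 1),
               c(3.5, 1.5))
  # tempered at w = 0.5 halves the data contribution
  expect_equal(omegaConcentration(V, z, 1, c(0.5, 0.5), w = 0.5,
                                  tempered = TRUE), c(2.0, 1.0))
  # empty domain: prior only
  expect_equal(omegaConcentration(V, z, 2, c(0.5, 0.5), w = 1)[2], 2.5)
  expect_equal(omegaConcentration(V, c(2, 2, 2), 1, c(0.5, 0.5), w = 1),
               c(0.5, 0.5))
  # Monte-Carlo means match the analytic Dirichlet means
  dr <- sampleDirichlet(50000, c(3.5, 1.5), seed = 7)
  expect_equal(colMeans(dr), c(0.7, 0.3), tolerance = 0.01)
  dr2 <- sampleDirichlet(50000, c(2, 1), seed = 8)
  expect_equal(colMeans(dr2), c(2 / 3, 1 / 3), tolerance = 0.01)
  expect_true(all(abs(rowSums(dr) - 1) < 1e-12))
})

test_that("the sampler enforces its preconditions and determinism", {
  sim <- tinySim()
  expect_error(fitDomains(sim$molecular, sim$image, sim$geo, K = 1),
               "K")
  expect_error(fitDomains(sim$molecular, sim$image, sim$geo, K = 2,
                          nIter = 10, burnIn = 10), "burnIn|nIter")
  a <- fitDomains(sim$molecular, sim$image, sim$geo, K = 2, w = 0.5,
                  nIter = 120, burnIn = 60, seed = 11)
  b <- fitDomains(sim$molecular, sim$image, sim$geo, K = 2, w = 0.5,
                  nIter = 120, burnIn = 60, seed = 11)
  expect_identical(zDraws(a), zDraws(b))
  expect_identical(a@mu, b@mu)
  expect_identical(a@omega, b@omega)
})

test_that("stored draws satisfy simplex and SPD invariants", {
  sim <- tinySim(seed = 4)
  ch <- fitDomains(sim$molecular, sim$image, sim$geo, K = 3, w = 1,
                   nIter = 150, burnIn = 50, seed = 2,
                   covariance = "full")
  om <- omegaDraws(ch)
  expect_true(all(abs(apply(om, c(1, 3), sum) - 1) < 1e-12))
  expect_true(all(om > 0))
  U <- dim(ch@sigma)[4]
  for (u in seq(1, U, by = 20))
    for (k in 1:3)
      expect_true(all(eigen(ch@sigma[k, , , u],
                            symmetric = TRUE)$values > 0))
})

test_that("a w = 0 chain equals a molecular-only chain draw for draw", {
  sim <- tinySim(seed = 5)
  init <- rep_len(1:3, length(spotIds(sim$geo)))
  w0 <- fitDomains(sim$molecular, sim$image, sim$geo, K = 3, w = 0,
                   nIter = 150, burnIn = 50, seed = 6, zInit = init,
                   relabel = FALSE)
  molOnly <- fitDomains(sim$molecular, sim$image, sim$geo, K = 3, w = 0,
                        nIter = 150, burnIn = 50, seed = 6, zInit = init,
                        relabel = FALSE, useImage = FALSE)
  expect_identical(zDraws(w0), zDraws(molOnly))
  expect_identical(w0@mu, molOnly@mu)
  expect_identical(w0@sigma, molOnly@sigma)
})

test_that("relabeling applies the composition order restriction jointly", {
  # K = 3 with omega[, qRef] = (0.2, 0.5, 0.3): permutation (2, 3, 1)
  draw <- list(z = c(1, 2, 3, 1),
               mu = matrix(1:6, 3, 2),
               sigma = array(rep(diag(2), 3), c(3, 2, 2)),
               omega = rbind(c(0.2, 0.8), c(0.5, 0.5), c(0.3, 0.7)))
  out <- relabelDraw(draw, qRef = 1)
  expect_equal(out$omega[, 1], c(0.5, 0.3, 0.2))
  expect_equal(out$mu, draw$mu[c(2, 3, 1), ])
  # labels move with the blocks: what was domain 2 is now domain 1
  expect_equal(out$z, c(3, 1, 2, 3))
  # already ordered: identity
  ordered <- draw; ordered$omega <- rbind(c(0.6, 0.4), c(0.3, 0.7),
                                          c(0.1, 0.9))
  expect_identical(relabelDraw(ordered, 1), ordered)
  # property: after relabeling any random draw the restriction holds
  set.seed(9)
  for (r in 1:25) {
    K <- sample(2:5, 1)
    dr <- list(z = sample(seq_len(K), 10, TRUE),
               mu = matrix(rnorm(K * 2), K, 2),
               sigma = array(rep(diag(2), K), c(K, 2, 2)),
               omega = t(apply(matrix(rgamma(K * 3, 1), K, 3), 1,
                               function(x) x / sum(x))))
    out <- relabelDraw(dr, qRef = 2)
    expect_true(all(diff(out$omega[, 2]) <= 0))
    # the induced partition of spots is unchanged
    expect_equal(ari(out$z, dr$z), 1)
  }
})

test_that("relabeled chains keep omega[, qRef] decreasing in every draw", {
  sim <- tinySim(seed = 6)
  ch <- fitDomains(sim$molecular, sim$image, sim$geo, K = 3, w = 1,
                   nIter = 150, burnIn = 50, seed = 3)
  om <- omegaDraws(ch)
  for (u in seq_len(dim(om)[3]))
    expect_true(all(diff(om[, ch@qRef, u]) <= 0))
})

test_that("permuting spots permutes the domain call accordingly", {
  sim <- tinySim(seed = 7)
  ch <- fitDomains(sim$molecular, sim$image, sim$geo, K = 2, w = 1,
                   nIter = 150, burnIn = 50, seed = 4)
  call <- callDomains(ch)
  perm <- sample(length(ch@spotIds))
  chp <- ch
  chp@zDraws <- ch@zDraws[, perm]
  chp@spotIds <- ch@spotIds[perm]
  chp@adjacency <- ch@adjacency[perm, perm]
  callp <- callDomains(chp)
  expect_equal(callp@zHat, call@zHat[perm])
  expect_equal(unname(callp@marginalProbs), unname(call@marginalProbs[perm, ]))
  expect_equal(callp@boundary, call@boundary[perm])
})
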