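#' Detect domain-specific differentially expressed genes (spaDEGs)
#'
#' For each gene j, fits a negative binomial regression of the raw
#' counts on the binary indicator x_i = I(zHat_i = k) of membership in
#' the target domain, with offset log(s_i) for the per-spot size factor
#' and a log link, and tests H0: beta = 0. The baseline coefficient is
#' the (log) expression level outside the domain and beta the
#' domain-specific shift; genes whose Benjamini-Hochberg adjusted
#' p-value falls below \code{level} are flagged as spaDEGs. Since x is
#' binary, the log-link model is an exact reparameterization of the
#' additive mean model with the same null hypothesis, while keeping the
#' mean positive; \code{link = "identity"} fits the literal additive
#' form instead.
#'
#' All-zero genes are skipped; genes whose fit does not converge are
#' flagged, get a missing p-value, and are excluded from the BH family
#' (the count is reported in attribute \code{"nNonConverged"}).
#'
#' With \code{refineNormalization = TRUE} (the default for the
#' median-ratio normalization) a second pass re-estimates the size
#' factors from the genes the first pass did not flag and refits: a
#' strongly shifted minority of genes otherwise leaks a small
#' domain-correlated bias into every offset, which no single-pass
#' robust location estimate can fully reject when per-gene counts are
#' noisy.
#'
#' @param counts a \linkS4class{SpatialCounts} (spots must match the call)
#' @param domains a \linkS4class{DomainCall} or an integer label vector
#' @param domain target domain k
#' @param test "wald" (default) or "lrt"
#' @param level significance level on adjusted p-values (default 0.05)
#' @param link "log" (default) or "identity"
#' @param normalization size factors for the offset: "median-ratio"
#'   (default) or "total" (the raw per-spot totals stored in
#'   \code{counts})
#' @param refineNormalization re-estimate size factors excluding
#'   first-pass discoveries and refit (default TRUE for "median-ratio")
#' @return data.frame with gene, domain, alpha, beta, psi, p, p_adj,
#'   spadeg, converged; attributes "nSkipped", "nNonConverged",
#'   "sizeFactors"
#' @export
fitSpaDEG <- function(counts, domains, domain, test = c("wald", "lrt"),
                      level = 0.05, link = c("log", "identity"),
                      normalization = c("median-ratio", "total"),
                      refineNormalization = NULL) {
  test <- match.arg(test)
  link <- match.arg(link)
  normalization <- match.arg(normalization)
  stopifnot(is(counts, "SpatialCounts"))
  z <- if (is(domains, "DomainCall")) domains@zHat else as.integer(domains)
  stopifnot(length(z) == length(counts@spotIds))
  x <- as.integer(z == domain)
  if (all(x == 0)) stop("target domain ", domain, " is empty")
  if (all(x == 1)) stop("all spots lie in the target domain")
  if (is.null(refineNormalization))
    refineNormalization <- normalization == "median-ratio"
  s <- if (normalization == "median-ratio") estimateSizeFactors(counts)
       else counts@sizeFactors
  stopifnot(all(s > 0))
  cts <- as.matrix(counts@counts)

  res <- .spadegPass(cts, counts@geneIds, x, s, domain, test, level, link)
  if (refineNormalization && any(res$spadeg)) {
    keep <- !res$spadeg
    if (sum(keep) >= 2) {
      s <- estimateSizeFactors(
        SpatialCounts(cts[, keep, drop = FALSE],
                      spotIds = counts@spotIds))
      res <- .spadegPass(cts, counts@geneIds, x, s, domain, test, level,
                         link)
    }
  }
  attr(res, "sizeFactors") <- s
  res
}

.spadegPass <- function(cts, geneIds, x, s, domain, test, level, link) {
  res <- data.frame(gene = geneIds, domain = domain,
                    alpha = NA_real_, beta = NA_real_, psi = NA_real_,
                    p = NA_real_, p_adj = NA_real_, spadeg = FALSE,
                    converged = FALSE)
  allzero <- colSums(cts) == 0
  offs <- log(s)
  for (j in which(!allzero)) {
    cj <- cts[, j]
    if (link == "identity") {
      fit <- .fitNBIdentity(cj, x, s)
      res$alpha[j] <- fit$alpha; res$beta[j] <- fit$beta
      res$psi[j] <- fit$psi; res$p[j] <- fit$p
      res$converged[j] <- fit$converged
      next
    }
    fit <- tryCatch(suppressWarnings(MASS::glm.nb(cj ~ x + offset(offs))),
                    error = function(e) NULL)
    if (is.null(fit) || !fit$converged) next
    cf <- summary(fit)$coefficients
    if (nrow(cf) < 2 || any(!is.finite(cf[, 2]))) next
    res$alpha[j] <- cf[1, 1]
    res$beta[j] <- cf[2, 1]
    res$psi[j] <- fit$theta
    res$converged[j] <- TRUE
    if (test == "wald") {
      res$p[j] <- 2 * stats::pnorm(-abs(cf[2, 1] / cf[2, 2]))
    } else {
      fit0 <- tryCatch(suppressWarnings(
        MASS::glm.nb(cj ~ 1 + offset(offs))), error = function(e) NULL)
      if (is.null(fit0)) { res$converged[j] <- FALSE; next }
      dev <- 2 * (as.numeric(stats::logLik(fit)) -
                  as.numeric(stats::logLik(fit0)))
      res$p[j] <- stats::pchisq(max(dev, 0), df = 1, lower.tail = FALSE)
    }
  }
  fam <- which(res$converged & !is.na(res$p))
  bh <- adjustBH(res$p[fam], level = level)
  res$p_adj[fam] <- bh$p_adj
  res$spadeg[fam] <- bh$discovery
  attr(res, "nSkipped") <- sum(allzero)
  attr(res, "nNonConverged") <- sum(!allzero & !res$converged)
  res
}

#' Median-of-ratios size factors
#'
#' Per-spot size factor as the median, over genes, of the ratio of the
#' spot's count to the gene's geometric mean across spots (geometric
#' means taken over positive counts so sparse data remain usable).
#' Rescaled to geometric mean one. Unlike raw totals, the estimate is
#' robust to a minority of genes with strong domain-specific shifts.
#'
#' @param counts a \linkS4class{SpatialCounts}
#' @return positive numeric vector, one size factor per spot
#' @export
estimateSizeFactors <- function(counts) {
  cts <- as.matrix(counts@counts)
  lg <- log(cts)
  lg[!is.finite(lg)] <- NA
  gm <- exp(colMeans(lg, na.rm = TRUE))     # per-gene geometric mean
  ok <- is.finite(gm) & gm > 0
  s <- apply(cts[, ok, drop = FALSE], 1, function(r) {
    ratio <- r[r > 0] / gm[ok][r > 0]
    if (!length(ratio)) return(NA_real_)
    stats::median(ratio)
  })
  if (anyNA(s)) {
    # all-zero spots: fall back to (zero) totals so the caller's
    # positivity check reports them
    s[is.na(s)] <- 0
  }
  pos <- s > 0
  s[pos] <- s[pos] / exp(mean(log(s[pos])))
  setNames(s, counts@spotIds)
}

# direct ML fit of the additive-mean NB model c ~ NB(s * (alpha + beta x),
# psi); used only behind link = "identity"
.fitNBIdentity <- function(cj, x, s) {
  nll <- function(par) {
    lam <- par[1] + par[2] * x
    if (any(lam <= 0) || par[3] > 20) return(1e10)
    -sum(stats::dnbinom(cj, size = exp(par[3]), mu = s * lam, log = TRUE))
  }
  a0 <- max(mean(cj[x == 0] / s[x == 0]), 1e-4)
  b0 <- mean(cj[x == 1] / s[x == 1]) - a0
  opt <- tryCatch(stats::optim(c(a0, b0, 0), nll, method = "BFGS",
                               hessian = TRUE),
                  error = function(e) NULL)
  bad <- list(alpha = NA_real_, beta = NA_real_, psi = NA_real_,
              p = NA_real_, converged = FALSE)
  if (is.null(opt) || opt$convergence != 0) return(bad)
  vc <- tryCatch(solve(opt$hessian), error = function(e) NULL)
  if (is.null(vc) || any(diag(vc)[1:2] <= 0)) return(bad)
  se <- sqrt(diag(vc)[2])
  list(alpha = opt$par[1], beta = opt$par[2], psi = exp(opt$par[3]),
       p = 2 * stats::pnorm(-abs(opt$par[2] / se)), converged = TRUE)
}

#' Benjamini-Hochberg adjustment with discovery flags
#'
#' Step-up BH adjusted p-values (running-minimum enforced, as in
#' \code{p.adjust}) and the discovery indicator at the given level.
#' Missing p-values propagate as missing and do not enter the family
#' size.
#'
#' @param p numeric vector of p-values in [0, 1] (NAs allowed)
#' @param level significance level (default 0.05)
#' @return list with p_adj and discovery
#' @export
adjustBH <- function(p, level = 0.05) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  padj <- stats::p.adjust(p, method = "BH")
  list(p_adj = padj, discovery = !is.na(padj) & padj < level)
}

#' Per-spot gene expression richness
#'
#' The fraction of genes with a nonzero count at each spot. When
#' \code{groups} is supplied (e.g. "interactive zone" vs "other
#' boundary"), per-group summaries are attached as attribute
#' \code{"groupSummary"}.
#'
#' @param counts a \linkS4class{SpatialCounts}
#' @param spots optional subset of spot indices or ids
#' @param groups optional factor over the selected spots
#' @return named numeric vector of richness values in [0, 1]
#' @export
spotRichness <- function(counts, spots = NULL, groups = NULL) {
  cts <- counts@counts
  idx <- seq_len(nrow(cts))
  if (!is.null(spots))
    idx <- if (is.character(spots)) match(spots, counts@spotIds) else spots
  r <- Matrix::rowSums(cts[idx, , drop = FALSE] > 0) / ncol(cts)
  names(r) <- counts@spotIds[idx]
  if (!is.null(groups)) {
    gs <- vapply(split(r, groups), function(v)
      c(mean = mean(v), median = stats::median(v), n = length(v)),
      numeric(3))
    attr(r, "groupSummary") <- t(gs)
  }
  r
}

#' Moran's I spatial autocorrelation
#'
#' I = (N / S0) * sum_{i,i'} g_{ii'} (x_i - xbar)(x_{i'} - xbar) /
#' sum_i (x_i - xbar)^2 with binary weights g from the spot adjacency
#' (S0 is the total weight). Returns NA with a warning for a constant
#' input, where the statistic is undefined.
#'
#' @param values per-spot numeric vector
#' @param geo a \linkS4class{GeospatialProfile} or adjacency matrix
#' @return scalar in approximately [-1, 1]
#' @export
moransI <- function(values, geo) {
  G <- if (is(geo, "GeospatialProfile")) adjacencyMatrix(geo) else geo
  N <- length(values)
  stopifnot(nrow(G) == N, N >= 2)
  S0 <- sum(G)
  if (S0 == 0) stop("adjacency has no edges")
  xc <- values - mean(values)
  denom <- sum(xc^2)
  if (denom == 0) {
    warning("constant values: Moran's I undefined")
    return(NA_real_)
  }
  num <- sum(xc * as.numeric(G %*% xc))
  (N / S0) * num / denom
}
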