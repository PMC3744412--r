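## Penalised binomial B-spline smoothing of pooled SNP variant frequencies.
##
## Model: variant reads v_i ~ Binomial(n_i, p(x_i)), logit p(x) = eta(x)
## expanded in a cubic B-spline basis with quantile-placed interior knots.
## eta maximises the binomial log-likelihood minus lambda * second-order
## difference penalty on the coefficients, via penalised IRLS.  lambda is
## chosen by minimising an effective-df-corrected deviance (AIC).

#' Build the smoothing basis for one chromosome
#'
#' Cubic B-splines with \code{k} interior knots placed at quantiles of the
#' marker positions; the evaluation grid is the union of the markers and a
#' regular grid (default every 1000 bp) spanning the marker range.
#'
#' @param markerPos sorted marker positions (bp)
#' @param k number of interior knots (default 20)
#' @param gridBp spacing of the regular part of the grid (bp)
#' @return list(knots, degree, grid)
#' @export
makeSmoothBasis <- function(markerPos, k = 20L, gridBp = 1000) {
  markerPos <- sort(unique(markerPos))
  if (length(markerPos) < k + 2L)
    stop("only ", length(markerPos), " markers but k = ", k,
         " interior knots; use a smaller k (need at least k + 2 markers)")
  b0 <- min(markerPos); b1 <- max(markerPos)
  interior <- unique(as.numeric(
    quantile(markerPos, probs = seq_len(k) / (k + 1), names = FALSE)))
  interior <- interior[interior > b0 & interior < b1]
  knots <- c(rep(b0, 4L), interior, rep(b1, 4L))
  grid <- sort(unique(c(markerPos, seq(b0, b1, by = gridBp))))
  list(knots = knots, degree = 3L, grid = grid)
}

.binomDeviance <- function(v, n, mu) {
  use <- n > 0
  v <- v[use]; n <- n[use]; mu <- pmin(pmax(mu[use], 1e-12), 1 - 1e-12)
  t1 <- ifelse(v > 0, v * log(v / (n * mu)), 0)
  t2 <- ifelse(v < n, (n - v) * log((n - v) / (n * (1 - mu))), 0)
  2 * sum(t1 + t2)
}

## one penalised IRLS fit at fixed lambda; returns NULL on failure
.pirls <- function(X, v, n, S, lambda, maxIter = 50L, etaCap = 15,
                   beta0 = NULL) {
  use <- n > 0
  if (is.null(beta0)) {
    p0 <- ifelse(use, (v + 0.5) / (n + 1), 0.5)
    eta <- qlogis(pmin(pmax(p0, 0.01), 0.99))
    beta <- NULL
  } else {
    beta <- beta0
    eta <- pmin(pmax(drop(X %*% beta), -etaCap), etaCap)
  }
  pdev <- function(beta, eta)
    .binomDeviance(v, n, plogis(eta)) +
      lambda * drop(crossprod(diff(beta, differences = 2L)))
  ## note: S == crossprod(D2), so beta' S beta == ||diff(beta, 2)||^2
  dev <- Inf; devTrace <- numeric(0); converged <- FALSE
  for (it in seq_len(maxIter)) {
    mu <- plogis(eta)
    w <- n * mu * (1 - mu)
    w[!use] <- 0
    z <- eta + ifelse(w > 0, (v - n * mu) / pmax(w, 1e-12), 0)
    XtWX <- crossprod(X, X * w)
    A <- XtWX + lambda * S
    betaNew <- tryCatch(solve(A, crossprod(X, w * z)),
                        error = function(e) NULL)
    if (is.null(betaNew)) return(NULL)
    betaNew <- drop(betaNew)
    etaNew <- pmin(pmax(drop(X %*% betaNew), -etaCap), etaCap)
    devNew <- pdev(betaNew, etaNew)
    ## step halving on the penalised objective
    if (!is.null(beta) && is.finite(dev)) {
      half <- 0
      while (devNew > dev + 1e-10 && half < 15L) {
        betaNew <- (betaNew + beta) / 2
        etaNew <- pmin(pmax(drop(X %*% betaNew), -etaCap), etaCap)
        devNew <- pdev(betaNew, etaNew)
        half <- half + 1L
      }
    }
    devTrace <- c(devTrace, devNew)
    done <- (is.finite(dev) &&
             abs(devNew - dev) < 1e-8 * (abs(devNew) + 0.1)) ||
            max(abs(etaNew - eta)) < 1e-6
    beta <- betaNew; eta <- etaNew; dev <- devNew
    if (done) { converged <- TRUE; break }
  }
  dev <- .binomDeviance(v, n, plogis(eta))
  mu <- plogis(eta)
  w <- n * mu * (1 - mu); w[!use] <- 0
  XtWX <- crossprod(X, X * w)
  A <- XtWX + lambda * S
  Vm <- tryCatch(solve(A), error = function(e) NULL)
  if (is.null(Vm)) return(NULL)
  Vm <- (Vm + t(Vm)) / 2
  edf <- sum(diag(Vm %*% XtWX))
  list(beta = beta, eta = eta, dev = dev, edf = edf, Vm = Vm, XtWX = XtWX,
       w = w, converged = converged, devTrace = devTrace)
}

## segregant-sampling (finite pool) component of the coefficient covariance:
## Vm (X'W K W X) Vm, with K the working-scale covariance of the pool's
## realised allele-frequency curve under Haldane correlation exp(-2 d).
## Computed in the numerically stable form M_ij = n_i n_j sqrt(pq_i pq_j)
## rho_ij / N (zero where coverage is zero).
.poolSamplingCov <- function(X, pos, n, mu, Vm, nSegregants, morgansPerBp) {
  if (!is.finite(nSegregants) || nSegregants <= 0 || morgansPerBp <= 0)
    return(matrix(0, ncol(X), ncol(X)))
  pq <- mu * (1 - mu)
  sq <- n * sqrt(pq)
  rho <- exp(-2 * morgansPerBp * abs(outer(pos, pos, "-")))
  M <- rho * outer(sq, sq) / nSegregants
  Vm %*% (crossprod(X, M %*% X)) %*% Vm
}

#' Fit the smoothed variant-frequency curve of one pool on one chromosome
#'
#' Maximises the binomial log-likelihood of the per-marker counts minus a
#' second-order roughness penalty (penalised IRLS); the smoothing parameter
#' is selected by minimising deviance + 2 * effective df over a log-spaced
#' grid unless \code{lambda} is given.  Markers with zero total count carry
#' zero weight but stay in the frame.  The model-based coefficient
#' covariance is the inverse penalised information; when the sample is a
#' finite pool of \code{nSegregants} recombinant genomes and a
#' recombination rate is supplied, \code{vcovTotal} additionally carries
#' the segregant-sampling component used for pool contrasts.
#'
#' @param pos,variantCount,totalCount per-marker data (one chromosome)
#' @param pool,chrom identifiers stored in the fit
#' @param k,gridBp see \code{\link{makeSmoothBasis}}
#' @param lambda optional fixed smoothing parameter (NULL = select by AIC)
#' @param lambdaGrid candidate smoothing parameters for selection
#' @param maxIter IRLS iteration cap
#' @param etaCap cap on |logit frequency| used for stability and when
#'   reporting frequencies (default 15)
#' @param nSegregants number of segregants in the pool (Inf for a parent)
#' @param morgansPerBp assumed genome-averaged recombination rate; 0
#'   disables the segregant-sampling component
#' @return a \code{\link{FrequencyFit}}
#' @export
fitPoolChromosome <- function(pos, variantCount, totalCount,
                              pool = "pool", chrom = "chr",
                              k = 20L, gridBp = 1000,
                              lambda = NULL,
                              lambdaGrid = 10^seq(-4, 8, length.out = 13L),
                              maxIter = 50L, etaCap = 15,
                              nSegregants = Inf, morgansPerBp = 0) {
  stopifnot(length(pos) == length(variantCount),
            length(pos) == length(totalCount))
  if (any(variantCount > totalCount) || any(variantCount < 0))
    stop("need 0 <= variantCount <= totalCount")
  ord <- order(pos)
  pos <- as.numeric(pos[ord])
  v <- as.numeric(variantCount[ord]); n <- as.numeric(totalCount[ord])
  if (sum(n > 0) < k + 2L)
    stop("only ", sum(n > 0), " covered markers but k = ", k,
         " interior knots; use a smaller k")
  basis <- makeSmoothBasis(pos[n > 0], k = k, gridBp = gridBp)
  X <- splineDesign(basis$knots, pmin(pmax(pos, basis$knots[1L]),
                                      basis$knots[length(basis$knots)]),
                    ord = 4L)
  p <- ncol(X)
  D <- diff(diag(p), differences = 2L)
  S <- crossprod(D)
  if (!is.null(lambda)) {
    fit <- .pirls(X, v, n, S, lambda, maxIter, etaCap)
    if (is.null(fit)) stop("penalised IRLS failed at lambda = ", lambda)
  } else {
    best <- NULL; bestAic <- Inf; lambda <- NA_real_
    beta0 <- NULL
    for (lam in sort(lambdaGrid, decreasing = TRUE)) {
      f <- .pirls(X, v, n, S, lam, maxIter, etaCap, beta0 = beta0)
      if (is.null(f)) next
      beta0 <- f$beta
      aic <- f$dev + 2 * f$edf
      if (aic < bestAic - 1e-9) { bestAic <- aic; best <- f; lambda <- lam }
    }
    if (is.null(best)) stop("penalised IRLS failed for every candidate lambda")
    fit <- best
  }
  if (!fit$converged)
    stop("IRLS did not converge in ", maxIter, " iterations; deviance trace: ",
         paste(signif(tail(fit$devTrace, 6L), 6L), collapse = ", "))
  ## sampling covariance of the penalised estimator (delta method):
  ## Vm (X'W Cov(z) W X) Vm with Cov(z) = W^{-1} + K, i.e. read sampling
  ## plus the finite-pool segregant-sampling component
  Vtot <- fit$Vm %*% fit$XtWX %*% fit$Vm +
    .poolSamplingCov(X, pos, n, plogis(fit$eta), fit$Vm,
                     nSegregants, morgansPerBp)
  Vtot <- (Vtot + t(Vtot)) / 2
  Xg <- splineDesign(basis$knots, basis$grid, ord = 4L)
  eta <- drop(Xg %*% fit$beta)
  se <- sqrt(pmax(rowSums((Xg %*% fit$Vm) * Xg), 0))
  new("FrequencyFit", pool = pool, chrom = chrom,
      knots = basis$knots, degree = 3L,
      coef = fit$beta, vcov = fit$Vm, vcovTotal = Vtot,
      lambda = lambda, edf = fit$edf, deviance = fit$dev,
      converged = fit$converged,
      grid = basis$grid, eta = eta, se = se, etaCap = etaCap,
      markerPos = pos, markerV = v, markerN = n,
      nSegregants = nSegregants, morgansPerBp = morgansPerBp)
}

#' Evaluate a fitted frequency curve
#'
#' @param fit a \code{\link{FrequencyFit}}
#' @param positions positions (bp) within the fitted marker range
#' @return list(eta, se): fitted logit frequency and its model-based
#'   standard error
#' @export
predictFit <- function(fit, positions) {
  b0 <- fit@knots[1L]; b1 <- fit@knots[length(fit@knots)]
  if (any(positions < b0) || any(positions > b1))
    stop("position(s) outside the fitted range [", b0, ", ", b1,
         "] of chromosome ", fit@chrom)
  X <- splineDesign(fit@knots, positions, ord = fit@degree + 1L)
  eta <- drop(X %*% fit@coef)
  se <- sqrt(pmax(rowSums((X %*% fit@vcov) * X), 0))
  list(eta = eta, se = se)
}

#' @rdname FrequencyFit-class
#' @aliases fittedLogit,FrequencyFit-method
setMethod("fittedLogit", "FrequencyFit", function(object) object@eta)

#' @rdname FrequencyFit-class
#' @aliases fittedFrequency,FrequencyFit-method
setMethod("fittedFrequency", "FrequencyFit", function(object)
  plogis(pmin(pmax(object@eta, -object@etaCap), object@etaCap)))

setMethod("show", "FrequencyFit", function(object) {
  cat(sprintf(
    "FrequencyFit: pool '%s', chromosome %s\n  %d markers, lambda = %.3g, edf = %.1f, deviance = %.1f\n",
    object@pool, object@chrom, length(object@markerPos), object@lambda,
    object@edf, object@deviance))
  f <- fittedFrequency(object)
  cat(sprintf("  fitted frequency range: %.3f - %.3f\n", min(f), max(f)))
})

#' Serialise a frequency fit as a profile TSV
#'
#' Columns: chrom, pos, eta, se, p_hat.
#'
#' @param fit a \code{\link{FrequencyFit}}
#' @param path output file
#' @export
writeFrequencyProfile <- function(fit, path) {
  d <- data.frame(chrom = fit@chrom, pos = fit@grid,
                  eta = fit@eta, se = fit@se,
                  p_hat = fittedFrequency(fit))
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
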