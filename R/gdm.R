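## Generalized dissimilarity modelling. Pairwise community dissimilarity
## d_ij in [0, 1) is regressed on site predictors through monotone
## I-spline transforms f_k and the link mu = 1 - exp(-eta), with
## eta_ij = beta0 + sum_k |f_k(x_ki) - f_k(x_kj)|. Non-negative
## coefficients keep each f_k monotone non-decreasing, so predicted
## dissimilarity can only grow as sites separate along a predictor.

#' Monotone I-spline basis
#'
#' Evaluates `nSplines` I-spline (integrated B-spline) functions at `x`,
#' built on quantile knots (0/50/100th percentiles by default for 3
#' splines). Each function is monotone non-decreasing, 0 at the range
#' minimum and 1 at the maximum. Values outside the knot range are
#' clamped (the transform saturates).
#'
#' @param x numeric vector to evaluate at.
#' @param knots knot vector on the predictor scale (default: quantiles of
#'   `x` implied by `nSplines`).
#' @param nSplines number of basis functions (default 3).
#' @return length(x) x nSplines matrix; attribute `knots`.
#' @export
isplineBasis <- function(x, knots = NULL, nSplines = 3) {
  if (is.null(knots)) {
    knots <- unname(quantile(x, probs = seq(0, 1, length.out = nSplines)))
    ## tied quantiles (heavily repeated values): fall back to an equally
    ## spaced knot grid over the observed range
    if (anyDuplicated(knots) && diff(range(x)) > 0)
      knots <- seq(min(x), max(x), length.out = nSplines)
  }
  if (anyDuplicated(knots))
    stop("degenerate knots; predictor is constant", call. = FALSE)
  ord <- 3                                 # quadratic B-splines
  aug <- c(rep(knots[1], ord), knots[-c(1, length(knots))],
           rep(knots[length(knots)], ord))
  nB <- length(aug) - ord
  stopifnot(nB == nSplines + 1)
  xc <- pmin(pmax(x, knots[1]), knots[length(knots)])
  B <- splines::splineDesign(aug, xc, ord = ord, outer.ok = TRUE)
  ## I-spline identity: I_i(x) = sum of B-splines j > i at x
  I <- sapply(seq_len(nSplines), function(i)
    rowSums(B[, (i + 1):nB, drop = FALSE]))
  I <- matrix(I, nrow = length(x))
  colnames(I) <- paste0("I", seq_len(nSplines))
  attr(I, "knots") <- knots
  I
}

#' Build a GDM site-pair table
#'
#' One row per unordered site pair: the observed dissimilarity and, per
#' predictor and spline, the absolute difference of I-spline values at
#' the two sites (all terms >= 0). Constant predictors are excluded with
#' a warning.
#'
#' @param d square dissimilarity matrix (sites as dimnames).
#' @param covariates a [CovariateTable-class] or sites x predictors
#'   matrix, rows ordered/named consistently with `d`.
#' @param nSplines I-splines per predictor (default 3, knots at the
#'   0/50/100th percentiles).
#' @return object of class `sitePairTable`: list with `dissim`, `terms`
#'   (pairs x (predictors*nSplines)), `predictors`, `knots`, `siteValues`,
#'   `pairs` (two-column index matrix), `nSplines`.
#' @export
buildSitePairTable <- function(d, covariates, nSplines = 3) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3) stop("need at least 3 sites", call. = FALSE)
  X <- if (is(covariates, "CovariateTable")) covariateValues(covariates)
  else as.matrix(covariates)
  if (!is.null(rownames(X)) && !is.null(rownames(d))) {
    if (!all(rownames(d) %in% rownames(X)))
      stop("covariates missing for some sites", call. = FALSE)
    X <- X[rownames(d), , drop = FALSE]
  }
  if (nrow(X) != n) stop("site count mismatch", call. = FALSE)
  keep <- apply(X, 2, function(v) var(v) > 0)
  if (any(!keep))
    warning("excluding constant predictor(s): ",
            paste(colnames(X)[!keep], collapse = ", "), call. = FALSE)
  X <- X[, keep, drop = FALSE]
  if (!ncol(X)) stop("no usable (non-constant) predictors", call. = FALSE)
  preds <- colnames(X)
  basis <- lapply(preds, function(p) isplineBasis(X[, p], nSplines = nSplines))
  names(basis) <- preds
  pairs <- t(utils::combn(n, 2))
  terms <- do.call(cbind, lapply(preds, function(p) {
    Bm <- basis[[p]]
    tm <- abs(Bm[pairs[, 1], , drop = FALSE] - Bm[pairs[, 2], , drop = FALSE])
    colnames(tm) <- paste0(p, ".", seq_len(ncol(tm)))
    tm
  }))
  structure(list(
    dissim = d[pairs], terms = terms, predictors = preds,
    knots = lapply(basis, attr, "knots"), siteValues = X,
    pairs = pairs, nSplines = nSplines,
    siteNames = rownames(d) %||% as.character(seq_len(n))),
    class = "sitePairTable")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Non-negative least squares with a ridge-stabilized fallback for
## rank-deficient designs (e.g. duplicated predictors).
.nnlsSolve <- function(A, b) {
  fit <- tryCatch(pracma::lsqnonneg(A, b)$x, error = function(e) NULL)
  if (is.null(fit)) {
    eps <- 1e-5 * max(abs(A))
    Aa <- rbind(A, diag(eps, ncol(A)))
    fit <- pracma::lsqnonneg(Aa, c(b, numeric(ncol(A))))$x
  }
  fit
}

.gdmDeviance <- function(y, mu) {
  eps <- 1e-9
  mu <- pmin(pmax(mu, eps), 1 - eps)
  t1 <- ifelse(y > 0, y * log(y / mu), 0)
  t2 <- ifelse(y < 1, (1 - y) * log((1 - y) / (1 - mu)), 0)
  2 * sum(t1 + t2)
}

#' Fit a generalized dissimilarity model
#'
#' Minimizes the binomial-type deviance of observed pair dissimilarities
#' against `mu = 1 - exp(-eta)` with `eta = beta0 + sum(beta * terms)`,
#' all coefficients constrained non-negative, by iteratively reweighted
#' least squares with a non-negative least-squares solve at each step
#' (tolerance 1e-8 on the deviance, max 100 iterations). Deviance
#' explained is `100 (1 - residual/null)` with an intercept-only null.
#' Observed dissimilarities of exactly 1 are shrunk to `1 - 1e-6` before
#' the link inversion used at initialization.
#'
#' @param spt a `sitePairTable` from [buildSitePairTable()].
#' @param tol convergence tolerance on the deviance.
#' @param maxIter maximum IRLS iterations.
#' @return a [GdmModel-class].
#' @export
fitGdm <- function(spt, tol = 1e-8, maxIter = 100L) {
  stopifnot(inherits(spt, "sitePairTable"))
  y <- spt$dissim
  if (any(y < 0 | y > 1)) stop("dissimilarities must lie in [0, 1]", call. = FALSE)
  if (var(y) == 0)
    stop("all dissimilarities equal; deviance explained undefined",
         call. = FALSE)
  X <- cbind(`(Intercept)` = 1, spt$terms)
  ys <- pmin(pmax(y, 1e-6), 1 - 1e-6)
  eta <- -log(1 - (ys + mean(ys)) / 2)      # mild shrink toward the mean
  dev <- Inf
  beta <- NULL
  for (it in seq_len(maxIter)) {
    mu <- 1 - exp(-eta)
    mu <- pmin(pmax(mu, 1e-9), 1 - 1e-9)
    w <- (1 - mu) / mu                      # (dmu/deta)^2 / V(mu)
    z <- eta + (y - mu) / (1 - mu)
    sw <- sqrt(w)
    beta <- .nnlsSolve(sw * X, sw * z)
    eta <- pmax(drop(X %*% beta), 0)
    devNew <- .gdmDeviance(y, 1 - exp(-eta))
    if (is.finite(dev) && abs(dev - devNew) < tol * (abs(devNew) + 1)) {
      dev <- devNew
      break
    }
    dev <- devNew
    if (it == maxIter)
      stop(sprintf("GDM IRLS did not converge in %d iterations (deviance %.6g)",
                   maxIter, dev), call. = FALSE)
  }
  nullDev <- .gdmDeviance(y, mean(ys))
  names(beta) <- colnames(X)
  fitted <- 1 - exp(-pmax(drop(X %*% beta), 0))
  new("GdmModel", intercept = unname(beta[1]), coefficients = beta[-1],
      predictors = spt$predictors, knots = spt$knots,
      nullDeviance = nullDev, residualDeviance = dev,
      devianceExplained = 100 * (1 - dev / nullDev), fitted = fitted,
      converged = TRUE, iterations = it)
}

#' Permutation predictor importance for a fitted GDM
#'
#' For each predictor, its site values are permuted across sites
#' (`nPerm` times), the pair terms rebuilt and the model refit; the
#' importance is the mean drop in percent deviance explained, floored at
#' 0.
#'
#' @param model a fitted [GdmModel-class].
#' @param spt the `sitePairTable` the model was fit on.
#' @param nPerm permutations per predictor (default 100; a warning below
#'   10).
#' @param seed RNG seed.
#' @return named numeric vector of importances (percentage points).
#' @export
predictorImportance <- function(model, spt, nPerm = 100L, seed = NULL) {
  stopifnot(inherits(spt, "sitePairTable"))
  if (nPerm < 10) warning("fewer than 10 permutations; importance noisy",
                          call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(spt$siteValues)
  full <- model@devianceExplained
  imp <- setNames(numeric(length(spt$predictors)), spt$predictors)
  for (p in spt$predictors) {
    drops <- numeric(nPerm)
    for (b in seq_len(nPerm)) {
      Xp <- spt$siteValues
      Xp[, p] <- Xp[sample.int(n), p]
      sptP <- spt
      Bm <- isplineBasis(Xp[, p], nSplines = spt$nSplines)
      tm <- abs(Bm[spt$pairs[, 1], , drop = FALSE] -
                  Bm[spt$pairs[, 2], , drop = FALSE])
      cols <- paste0(p, ".", seq_len(ncol(tm)))
      sptP$terms[, cols] <- tm
      fitP <- fitGdm(sptP)
      drops[b] <- full - fitP@devianceExplained
    }
    imp[p] <- max(mean(drops), 0)
  }
  imp
}

#' Fitted monotone transform of each predictor on a grid
#'
#' @param model a fitted [GdmModel-class].
#' @param nGrid grid points per predictor.
#' @return named list of data.frames with `x` and `f` (curve value); the
#'   curve maximum equals the sum of that predictor's coefficients.
#' @export
splineCurves <- function(model, nGrid = 200) {
  out <- lapply(model@predictors, function(p) {
    kn <- model@knots[[p]]
    x <- seq(kn[1], kn[length(kn)], length.out = nGrid)
    Bm <- isplineBasis(x, knots = kn)
    beta <- model@coefficients[paste0(p, ".", seq_len(ncol(Bm)))]
    data.frame(x = x, f = drop(Bm %*% beta))
  })
  names(out) <- model@predictors
  out
}
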