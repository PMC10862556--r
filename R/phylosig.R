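## Pagel's lambda phylogenetic signal. Under Brownian motion on a rooted
## tree with branch lengths, tip traits are multivariate normal with
## covariance proportional to shared root-to-tip path length. The lambda
## transform multiplies the off-diagonal (shared) part by lambda in
## [0, lambda_max]: 0 = no signal (star-like), 1 = full Brownian signal.
## The ML fit profiles the rate and root state by GLS and searches lambda
## in one dimension (grid pre-scan + Brent).

#' Brownian-motion covariance implied by a phylogeny
#'
#' Entry (i, j) is the depth (distance from the root) of the most recent
#' common ancestor of tips i and j; the diagonal holds root-to-tip
#' distances.
#'
#' @param tree a rooted `phylo` with branch lengths.
#' @return tips x tips symmetric matrix.
#' @export
phyloCovariance <- function(tree) {
  validatePhylogeny(tree)
  n <- length(tree$tip.label)
  tr <- stats::reorder(tree, "cladewise")
  depth <- numeric(n + tr$Nnode)
  for (e in seq_len(nrow(tr$edge)))
    depth[tr$edge[e, 2]] <- depth[tr$edge[e, 1]] + tr$edge.length[e]
  M <- ape::mrca(tree)
  C <- matrix(depth[M], n, n,
              dimnames = list(tree$tip.label, tree$tip.label))
  C
}

#' Lambda branch-length transform of a phylogenetic covariance
#'
#' Multiplies off-diagonal entries by `lambda`, leaving the diagonal
#' unchanged. `lambda = 1` returns the matrix unchanged; `lambda = 0`
#' gives a diagonal (star-like) covariance.
#'
#' @param C tips x tips covariance from [phyloCovariance()].
#' @param lambda value in `[0, lambdaMax(C)]`.
#' @export
lambdaTransform <- function(C, lambda) {
  if (lambda < 0) stop("lambda must be non-negative", call. = FALSE)
  if (lambda > lambdaMax(C) + 1e-8)
    stop(sprintf("lambda = %g exceeds the positive-definite bound %.4f",
                 lambda, lambdaMax(C)), call. = FALSE)
  Cl <- C * lambda
  diag(Cl) <- diag(C)
  Cl
}

#' Upper bound of the lambda search range
#'
#' 1 for ultrametric trees; for non-ultrametric trees, the largest lambda
#' keeping the transformed covariance positive definite, found by
#' bisection on the smallest eigenvalue.
#'
#' @param C tips x tips covariance from [phyloCovariance()].
#' @export
lambdaMax <- function(C) {
  d <- diag(C)
  if (diff(range(d)) < 1e-8 * max(d)) return(1)
  minEig <- function(l) {
    Cl <- C * l
    diag(Cl) <- d
    min(eigen(Cl, symmetric = TRUE, only.values = TRUE)$values)
  }
  if (minEig(1) <= 0) {                      # bound below 1
    lo <- 0; hi <- 1
  } else {
    hi <- 1
    while (minEig(hi * 2) > 0 && hi < 8) hi <- hi * 2
    lo <- hi; hi <- hi * 2
  }
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    if (minEig(mid) > 0) lo <- mid else hi <- mid
  }
  lo
}

## Profile log-likelihood machinery. For ultrametric trees (constant
## diagonal h) the transform lambda*C + (1-lambda)*h*I shares the
## eigenbasis of C, so after one eigendecomposition each likelihood
## evaluation is O(n); otherwise a Cholesky factorization per evaluation.
.lambdaEngine <- function(C) {
  n <- nrow(C)
  d <- diag(C)
  ultra <- diff(range(d)) < 1e-8 * max(d)
  if (ultra) {
    h <- d[1]
    eig <- eigen(C, symmetric = TRUE)
    U <- eig$vectors
    ev <- eig$values
    u1 <- drop(crossprod(U, rep(1, n)))
    list(
      n = n, ultra = TRUE,
      prep = function(x) drop(crossprod(U, x)),
      logLik = function(lambda, y) {
        w <- lambda * ev + (1 - lambda) * h
        if (any(w <= 0)) return(-Inf)
        a <- sum(u1 * y / w) / sum(u1^2 / w)
        q <- sum((y - a * u1)^2 / w)
        s2 <- q / n
        c(logL = -0.5 * (n * log(2 * pi * s2) + sum(log(w)) + n),
          sigma2 = s2, root = a)
      })
  } else {
    one <- rep(1, n)
    list(
      n = n, ultra = FALSE,
      prep = function(x) x,
      logLik = function(lambda, y) {
        Cl <- C * lambda
        diag(Cl) <- d
        R <- tryCatch(chol(Cl), error = function(e) NULL)
        if (is.null(R)) return(-Inf)
        z <- backsolve(R, cbind(y, one), transpose = TRUE)
        a <- sum(z[, 1] * z[, 2]) / sum(z[, 2]^2)
        q <- sum((z[, 1] - a * z[, 2])^2)
        s2 <- q / n
        c(logL = -0.5 * (n * log(2 * pi * s2) + 2 * sum(log(diag(R))) + n),
          sigma2 = s2, root = a)
      })
  }
}

.fitLambdaCore <- function(engine, y, lmax, gridSize, tol) {
  grid <- seq(0, lmax, length.out = gridSize)
  gl <- vapply(grid, function(l) engine$logLik(l, y)[["logL"]], numeric(1))
  best <- which.max(gl)
  lo <- grid[max(1, best - 1)]
  hi <- grid[min(gridSize, best + 1)]
  opt <- optimize(function(l) engine$logLik(l, y)[["logL"]],
                  interval = c(lo, hi), maximum = TRUE, tol = tol)
  if (opt$objective < gl[best]) {       # grid point beat the refinement
    opt <- list(maximum = grid[best], objective = gl[best])
  }
  list(lambda = opt$maximum, logL = opt$objective,
       logL0 = gl[1], at = engine$logLik(opt$maximum, y))
}

#' Maximum-likelihood Pagel's lambda with a Monte-Carlo null
#'
#' Maximizes the multivariate-normal log-likelihood over (lambda, rate,
#' root state), profiling rate and root state by generalized least
#' squares and searching lambda on `[0, lambdaMax]` with a grid pre-scan
#' (21 points) followed by Brent refinement (tolerance 1e-6). The
#' estimate is invariant to affine transformation of the trait.
#'
#' Significance of lambda > 0 comes from a Monte-Carlo null: `nSims`
#' permutations of trait values across tips, each refit, with
#' `p = (1 + #(permuted logL gain >= observed)) / (nSims + 1)` where the
#' gain is `logL(lambda_hat) - logL(0)`. A likelihood-ratio chi-square(1)
#' test is available via `method = "lr"`.
#'
#' On a star phylogeny the likelihood is constant in lambda; the fit is
#' then reported as non-identifiable rather than returning an arbitrary
#' optimum.
#'
#' @param tree rooted `phylo` with branch lengths (>= 4 tips).
#' @param trait named (or tip-ordered) numeric trait vector with positive
#'   variance; e.g. per-OTU relative abundance on one sampling day,
#'   optionally `log(x + pseudo)` transformed (see [abundanceTrait()]).
#' @param nSims Monte-Carlo permutations (default 999).
#' @param seed RNG seed for the permutation null (required for
#'   reproducibility when `method = "permutation"`).
#' @param method `"permutation"` (default) or `"lr"`.
#' @param gridSize pre-scan grid points.
#' @param tol Brent tolerance on lambda.
#' @return a [LambdaFit-class].
#' @export
fitLambda <- function(tree, trait, nSims = 999L, seed = NULL,
                      method = c("permutation", "lr"), gridSize = 21L,
                      tol = 1e-6) {
  method <- match.arg(method)
  C <- phyloCovariance(tree)
  n <- nrow(C)
  if (n < 4) stop("need at least 4 tips", call. = FALSE)
  if (!is.null(names(trait))) {
    if (!all(rownames(C) %in% names(trait)))
      stop("trait is missing values for some tips", call. = FALSE)
    trait <- trait[rownames(C)]
  } else if (length(trait) != n) {
    stop("trait length does not match number of tips", call. = FALSE)
  }
  if (var(trait) == 0)
    stop("constant trait: signal undefined", call. = FALSE)
  offdiag <- C[upper.tri(C)]
  if (max(abs(offdiag)) < 1e-12 * max(diag(C))) {
    return(new("LambdaFit", lambda = NA_real_, lambdaMax = 1,
               sigma2 = NA_real_, rootState = NA_real_,
               logLik = NA_real_, logLik0 = NA_real_, pValue = NA_real_,
               nSims = 0L, identifiable = FALSE))
  }
  lmax <- lambdaMax(C)
  engine <- .lambdaEngine(C)
  y <- engine$prep(trait)
  fit <- .fitLambdaCore(engine, y, lmax, gridSize, tol)
  statObs <- fit$logL - fit$logL0
  if (method == "lr") {
    p <- pchisq(2 * statObs, df = 1, lower.tail = FALSE)
    nSims <- 0L
  } else {
    if (!is.null(seed)) set.seed(seed)
    exceed <- 0L
    for (b in seq_len(nSims)) {
      yb <- engine$prep(trait[sample.int(n)])
      fb <- .fitLambdaCore(engine, yb, lmax, gridSize, tol)
      if (fb$logL - fb$logL0 >= statObs - 1e-10) exceed <- exceed + 1L
    }
    p <- (1 + exceed) / (nSims + 1)
  }
  new("LambdaFit", lambda = fit$lambda, lambdaMax = lmax,
      sigma2 = unname(fit$at[["sigma2"]]),
      rootState = unname(fit$at[["root"]]),
      logLik = fit$logL, logLik0 = fit$logL0, pValue = p,
      nSims = as.integer(nSims), identifiable = TRUE)
}

#' Per-tip abundance trait from an OTU table
#'
#' Extracts one sampling day's relative abundances for the OTUs matching
#' the tree tips, optionally log-transformed with a pseudo-count
#' defaulting to half the smallest nonzero proportion.
#'
#' @param table an [OtuTable-class].
#' @param sample sample id (column) to extract.
#' @param tree optional `phylo`; when given, the trait is restricted and
#'   ordered to its tip labels (error if a tip has no matching OTU).
#' @param log take `log(x + pseudo)`.
#' @param pseudo pseudo-count; default half the smallest nonzero
#'   proportion.
#' @return named numeric vector.
#' @export
abundanceTrait <- function(table, sample, tree = NULL, log = TRUE,
                           pseudo = NULL) {
  prop <- relativeAbundance(table)
  if (!sample %in% colnames(prop))
    stop("no sample '", sample, "' in OTU table", call. = FALSE)
  x <- prop[, sample]
  if (!is.null(tree)) {
    miss <- setdiff(tree$tip.label, names(x))
    if (length(miss))
      stop("tree tips with no matching OTU: ",
           paste(head(miss, 5), collapse = ", "), call. = FALSE)
    x <- x[tree$tip.label]
  }
  if (log) {
    if (is.null(pseudo)) {
      nz <- x[x > 0]
      pseudo <- if (length(nz)) min(nz) / 2 else 1e-6
    }
    x <- base::log(x + pseudo)
  }
  x
}
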