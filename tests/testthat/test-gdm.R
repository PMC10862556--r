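test_that("I-spline basis matches a naive Cox-de Boor oracle and is monotone", {
  x <- seq(0, 1, length.out = 101)
  B <- isplineBasis(x, knots = c(0, 0.5, 1))
  # independent evaluation: cumulative-sum identity over naive B-splines
  aug <- c(0, 0, 0, 0.5, 1, 1, 1)
  for (i in 1:3) {
    ref <- rowSums(sapply((i + 1):4, function(j)
      vapply(x, bsplineNaive, numeric(1), knots = aug, i = j, ord = 3)))
    expect_equal(unname(B[, i]), ref, tolerance = 1e-10)
  }
  expect_equal(unname(B[1, ]), c(0, 0, 0))
  expect_equal(unname(B[101, ]), c(1, 1, 1))
  expect_true(all(apply(B, 2, function(col) all(diff(col) >= -1e-12))))
  # out-of-range values saturate
  Bo <- isplineBasis(c(-5, 7), knots = c(0, 0.5, 1))
  expect_equal(unname(Bo[1, ]), c(0, 0, 0))
  expect_equal(unname(Bo[2, ]), c(1, 1, 1))
})

test_that("site-pair table has n(n-1)/2 rows and zero terms for tied sites", {
  set.seed(1)
  n <- 9
  d <- matrix(runif(n * n, 0.2, 0.9), n)
  d[lower.tri(d)] <- t(d)[lower.tri(d)]
  diag(d) <- 0
  dimnames(d) <- list(paste0("S", 1:n), paste0("S", 1:n))
  X <- matrix(runif(n * 2), n, dimnames = list(rownames(d), c("Ca", "dust")))
  X[2, ] <- X[1, ]                       # two sites share covariates
  spt <- buildSitePairTable(d, X)
  expect_equal(length(spt$dissim), n * (n - 1) / 2)
  expect_equal(ncol(spt$terms), 6)
  pairRow <- which(spt$pairs[, 1] == 1 & spt$pairs[, 2] == 2)
  expect_equal(unname(spt$terms[pairRow, ]), rep(0, 6))
  expect_true(all(spt$terms >= 0))
  # constant predictors are excluded with a warning
  Xc <- cbind(X, flat = 1)
  expect_warning(sptC <- buildSitePairTable(d, Xc), "constant")
  expect_equal(sptC$predictors, c("Ca", "dust"))
})

test_that("GDM recovers an exactly exponential response", {
  set.seed(2)
  n <- 15
  g <- sort(runif(n))
  X <- matrix(g, n, 1, dimnames = list(paste0("G", 1:n), "grad"))
  B <- isplineBasis(g)
  pairs <- t(combn(n, 2))
  term1 <- abs(B[pairs[, 1], 1] - B[pairs[, 2], 1])
  eta <- 0.1 + 2 * term1
  d <- matrix(0, n, n, dimnames = list(rownames(X), rownames(X)))
  d[pairs] <- 1 - exp(-eta)
  d <- d + t(d)
  spt <- buildSitePairTable(d, X)
  fit <- fitGdm(spt)
  expect_gt(fit@devianceExplained, 99)
  etaHat <- -log(1 - fit@fitted)
  expect_lt(max(abs(etaHat - eta) / eta), 0.01)
  expect_true(all(fit@coefficients >= 0))
  expect_true(all(fit@fitted >= 0 & fit@fitted < 1))
})

test_that("GDM degenerate inputs error and the null shows no signal", {
  set.seed(3)
  n <- 10
  d <- matrix(0.5, n, n); diag(d) <- 0
  X <- matrix(runif(n), n, 1, dimnames = list(NULL, "x"))
  expect_error(fitGdm(buildSitePairTable(d, X)), "all dissimilarities equal")
  expect_error(buildSitePairTable(d[1:2, 1:2], X[1:2, , drop = FALSE]),
               "at least 3 sites")
  # shuffled predictors: little explainable deviance (20 desk-scale
  # replicates; the acceptance suite runs 100)
  comm <- genTurnoverCommunities(nSites = 20, rate = 2, noise = 0.05,
                                 seed = 3)
  bc <- brayCurtis(comm)
  g <- attr(comm, "truth")$gradient
  de <- vapply(1:20, function(i) {
    gp <- sample(g)
    Xp <- matrix(gp, 20, 1, dimnames = list(names(g), "grad"))
    fitGdm(buildSitePairTable(bc, Xp))@devianceExplained
  }, numeric(1))
  expect_lt(mean(de), 5)
})

test_that("deviance explained is invariant to monotone predictor rescaling", {
  comm <- genTurnoverCommunities(nSites = 15, rate = 2, noise = 0.05, seed = 4)
  bc <- brayCurtis(comm)
  g <- attr(comm, "truth")$gradient
  X1 <- matrix(g, 15, 1, dimnames = list(names(g), "grad"))
  X2 <- matrix(10 * g + 3, 15, 1, dimnames = list(names(g), "grad"))
  f1 <- fitGdm(buildSitePairTable(bc, X1))
  f2 <- fitGdm(buildSitePairTable(bc, X2))
  expect_equal(f1@devianceExplained, f2@devianceExplained, tolerance = 1e-6)
})

test_that("permutation importance separates signal from noise and dilutes under collinearity", {
  comm <- genTurnoverCommunities(nSites = 16, rate = 2, noise = 0.05, seed = 5)
  bc <- brayCurtis(comm)
  g <- attr(comm, "truth")$gradient
  set.seed(5)
  X <- cbind(grad = g, noise1 = runif(16), noise2 = runif(16))
  rownames(X) <- names(g)
  spt <- buildSitePairTable(bc, X)
  fit <- fitGdm(spt)
  imp <- predictorImportance(fit, spt, nPerm = 20, seed = 9)
  expect_equal(names(which.max(imp)), "grad")
  expect_true(all(imp >= 0))
  # a predictor the model ignores has ~zero importance
  expect_lt(max(imp[c("noise1", "noise2")]), imp["grad"] / 2)
  # near-duplicated signal predictors share (dilute) importance: either
  # one can stand in for the other, so each drops less than the lone
  # informative predictor did
  Xd <- cbind(gradA = g, gradB = g + rnorm(16, 0, 0.02 * sd(g)),
              noise1 = X[, "noise1"])
  rownames(Xd) <- names(g)
  sptD <- buildSitePairTable(bc, Xd)
  fitD <- fitGdm(sptD)
  impD <- predictorImportance(fitD, sptD, nPerm = 20, seed = 9)
  expect_lt(max(impD[c("gradA", "gradB")]), imp["grad"])
  expect_gte(max(impD[c("gradA", "gradB")]), impD["noise1"])
})

test_that("spline curves are monotone with heights equal to coefficient sums", {
  comm <- genTurnoverCommunities(nSites = 12, rate = 1.5, noise = 0.05,
                                 seed = 6)
  bc <- brayCurtis(comm)
  g <- attr(comm, "truth")$gradient
  spt <- buildSitePairTable(bc, matrix(g, 12, 1,
                                       dimnames = list(names(g), "grad")))
  fit <- fitGdm(spt)
  cur <- splineCurves(fit)$grad
  expect_true(all(diff(cur$f) >= -1e-10))
  expect_equal(max(cur$f), sum(fit@coefficients), tolerance = 1e-9)
  # hand-set coefficients: curve equals the first I-spline
  fit2 <- fit
  fit2@coefficients[] <- c(1, 0, 0)
  cur2 <- splineCurves(fit2, nGrid = 50)$grad
  B <- isplineBasis(cur2$x, knots = fit@knots$grad)
  expect_equal(cur2$f, unname(B[, 1]), tolerance = 1e-12)
  # all-zero coefficients: flat zero transform
  fit2@coefficients[] <- 0
  expect_equal(splineCurves(fit2)$grad$f, rep(0, 200))
})

test_that("deviance explained approaches 100% as turnover noise vanishes", {
  de <- vapply(c(0.3, 0.1, 0.02), function(ns) {
    comm <- genTurnoverCommunities(nSites = 14, rate = 2, noise = ns,
                                   seed = 7)
    g <- attr(comm, "truth")$gradient
    fitGdm(buildSitePairTable(brayCurtis(comm),
                              matrix(g, 14, 1,
                                     dimnames = list(names(g), "grad"))))@devianceExplained
  }, numeric(1))
  expect_true(all(diff(de) > 0))
  expect_gt(de[3], 95)
})
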