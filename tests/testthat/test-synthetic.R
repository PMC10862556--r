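test_that("generators are deterministic at fixed seed", {
  expect_equal(massFractions(genSourceProfiles(seed = 9)),
               massFractions(genSourceProfiles(seed = 9)))
  pr <- genSourceProfiles(seed = 9)
  S <- matrix(c(5, 2, 1, 1, 2, 1, 0.5), 1)
  expect_equal(concentrations(genElementPanel(pr, S, seed = 2)),
               concentrations(genElementPanel(pr, S, seed = 2)))
  expect_equal(otuCounts(genOtuTable(seed = 3)),
               otuCounts(genOtuTable(seed = 3)))
  t1 <- genTreeTraits(10, seed = 4); t2 <- genTreeTraits(10, seed = 4)
  expect_equal(t1$traits, t2$traits)
  expect_equal(ape::write.tree(t1$tree), ape::write.tree(t2$tree))
  expect_equal(otuCounts(genTurnoverCommunities(seed = 5)),
               otuCounts(genTurnoverCommunities(seed = 5)))
})

test_that("profile generator yields well-conditioned, physical profiles", {
  pr <- genSourceProfiles(seed = 1)
  fr <- massFractions(pr)
  expect_equal(nrow(fr), 7)
  expect_true(all(fr >= 0 & fr <= 1))
  expect_true(all(rowSums(fr) <= 1.2))
  Fn <- t(fr); Fn <- sweep(Fn, 2, sqrt(colSums(Fn^2)), "/")
  expect_lt(kappa(Fn, exact = TRUE), 100)
  # crustal and oil end-members have the advertised character
  expect_gt(fr["African dust", "Al"], 0.05)
  expect_gt(fr["oil combustion", "V"] / max(fr[-7, "V"]), 10)
  one <- genSourceProfiles(nSources = 1, seed = 2)
  expect_true(all(massFractions(one) <= 1))
})

test_that("element mixtures have the requested noise and scale linearly", {
  pr <- genSourceProfiles(nSources = 3, seed = 1)
  S0 <- matrix(c(10, 5, 2), 1, dimnames = list("A1", sourceNames(pr)))
  # zero noise: exact linear mixture, and doubling S doubles C
  p0 <- genElementPanel(pr, S0, noiseCV = 0, seed = 1)
  p2 <- genElementPanel(pr, 2 * S0, noiseCV = 0, seed = 1)
  expect_equal(concentrations(p2), 2 * concentrations(p0), tolerance = 1e-12)
  expect_equal(unname(concentrations(p0)),
               unname(1000 * S0 %*% massFractions(pr)), tolerance = 1e-12)
  # moment check: empirical CV of 1000 replicate samples within 10%
  Srep <- S0[rep(1, 1000), ]
  rownames(Srep) <- paste0("A", 1:1000)
  pn <- genElementPanel(pr, Srep, noiseCV = 0.2, seed = 2)
  cv <- apply(concentrations(pn), 2, function(x) sd(x) / mean(x))
  expect_true(all(abs(cv - 0.2) / 0.2 < 0.1))
})

test_that("OTU generator produces valid linked structure", {
  tab <- genOtuTable(nOtus = 150, nSamples = 9, nLinked = 10,
                     effectSize = 1.5, depth = 50000, seed = 6)
  expect_equal(unname(colSums(otuCounts(tab))), rep(50000, 9))
  tr <- attr(tab, "truth")
  prop <- relativeAbundance(tab)
  rLinked <- vapply(tr$linked, function(o)
    cor(prop[o, ], tr$covariate), numeric(1))
  expect_gt(mean(abs(rLinked)), 0.9)
  # effectSize 0: linked set indistinguishable from null
  tab0 <- genOtuTable(nOtus = 150, nSamples = 9, nLinked = 10,
                      effectSize = 0, depth = 50000, seed = 6)
  tr0 <- attr(tab0, "truth")
  cvt <- CovariateTable(matrix(tr0$covariate, 9, 1,
                               dimnames = list(names(tr0$covariate), "x")))
  res0 <- correlationScreen(tab0, cvt)
  expect_lt(sum(res0$significant[match(tr0$linked, res0$otu_id)]), 3)
})

test_that("tree/trait generator matches its target covariance", {
  tt0 <- genTreeTraits(40, lambdaTrue = 0, seed = 7)
  C <- phyloCovariance(tt0$tree)
  # lambda 0: traits iid normal with variance = diag -> weak cross-correlation
  many0 <- genTreeTraits(40, lambdaTrue = 0, seed = 8, tree = tt0$tree,
                         nDraws = 500)$traits
  cc <- cor(t(many0))
  expect_lt(mean(abs(cc[upper.tri(cc)])), 0.08)
  # covariance recovery on a fixed 10-tip tree over 2000 replicate draws
  tt <- genTreeTraits(10, lambdaTrue = 0.5, seed = 9)
  draws <- genTreeTraits(10, lambdaTrue = 0.5, seed = 10, tree = tt$tree,
                         nDraws = 2000)$traits
  target <- lambdaTransform(phyloCovariance(tt$tree), 0.5)
  emp <- tcrossprod(draws - rowMeans(draws)) / (ncol(draws) - 1)
  relFrob <- norm(emp - target, "F") / norm(target, "F")
  # expected sampling error of a Wishart covariance estimate:
  # E||S - Sigma||_F^2 = (tr(Sigma^2) + tr(Sigma)^2) / nDraws
  theo <- sqrt((sum(target^2) + sum(diag(target))^2) / 2000) /
    norm(target, "F")
  expect_lt(relFrob, 1.5 * theo)
  expect_lt(relFrob, 0.10)
  expect_error(genTreeTraits(3), "at least 4")
})

test_that("turnover generator follows the exponential decay law", {
  comm <- genTurnoverCommunities(nSites = 20, rate = 2, noise = 0.05,
                                 seed = 11, nOtus = 2000, depth = 200000)
  g <- attr(comm, "truth")$gradient
  bc <- brayCurtis(comm)
  pairs <- t(combn(20, 2))
  dg <- abs(g[pairs[, 1]] - g[pairs[, 2]])
  d <- bc[pairs]
  # same-gradient duplicates are nearly identical; huge separations saturate
  commDup <- genTurnoverCommunities(nSites = 4, gradient = c(0, 0, 5, 5),
                                    rate = 2, noise = 0, seed = 12,
                                    nOtus = 4000, depth = 500000)
  bcd <- brayCurtis(commDup)
  expect_lt(bcd[1, 2], 0.05)
  expect_gt(bcd[1, 3], 0.99)
  # decay-rate recovery within 15% by curve fit
  fit <- stats::nls(d ~ 1 - exp(-r * dg), start = list(r = 1))
  rHat <- coef(fit)[["r"]]
  expect_lt(abs(rHat - 2) / 2, 0.15)
})

test_that("houston9 scenario writes a complete, reloadable bundle", {
  sc <- genHouston9(seed = 1)
  dir <- withr::local_tempdir()
  paths <- writeScenario(sc, dir)
  expect_true(all(file.exists(paths)))
  pan <- readElementPanel(file.path(dir, "elements.csv"))
  expect_equal(concentrations(pan), concentrations(sc$panel),
               tolerance = 1e-10)
  bact <- readOtuTable(file.path(dir, "bacteria.tsv"))
  expect_equal(otuCounts(bact), otuCounts(sc$bacteria))
  tree <- readPhylogeny(file.path(dir, "tree_fungi.nwk"))
  expect_setequal(tree$tip.label, sc$treeTraits$tree$tip.label)
  treeB <- readPhylogeny(file.path(dir, "tree_bacteria.nwk"))
  expect_length(treeB$tip.label, 100)
  # tips resolve to OTU ids in the matching table
  expect_true(all(tree$tip.label %in% otuIDs(sc$fungi)))
  expect_true(all(treeB$tip.label %in% otuIDs(sc$bacteria)))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(truth$scenario$seed, 1)
})
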