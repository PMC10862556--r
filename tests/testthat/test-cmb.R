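test_that("single-source identity: exact profile multiple is recovered", {
  pr <- genSourceProfiles(nSources = 1, seed = 1)
  S <- matrix(10, 1, 1, dimnames = list("A1", sourceNames(pr)))
  pan <- genElementPanel(pr, S, noiseCV = 0, seed = 1)
  fit <- fitCMB(pan, pr)
  expect_equal(unname(sourceContributions(fit)[1, 1]), 10, tolerance = 1e-9)
  expect_lt(max(abs(fit@residuals), na.rm = TRUE), 1e-8)
  expect_equal(unname(fit@rSquared[1]), 1, tolerance = 1e-9)
})

test_that("zero-noise recovery matches the unweighted linear-solve oracle", {
  pr <- genSourceProfiles(nSources = 3, seed = 2)
  Strue <- c(10, 5, 2)
  S <- matrix(Strue, 1, dimnames = list("A1", sourceNames(pr)))
  pan <- genElementPanel(pr, S, noiseCV = 0, seed = 2)
  # equal uncertainties: effective-variance solution must equal plain OLS
  pan2 <- ElementPanel(sampleIDs(pan), concentrations(pan),
                       matrix(1, nrow(concentrations(pan)),
                              ncol(concentrations(pan))))
  prEq <- SourceProfileSet(massFractions(pr),
                           matrix(1e-12, nrow(massFractions(pr)),
                                  ncol(massFractions(pr))))
  fit <- fitCMB(pan2, prEq)
  Fm <- t(massFractions(pr))
  ols <- qr.solve(Fm, concentrations(pan)[1, colnames(massFractions(pr))]) / 1000
  expect_lt(max(abs(sourceContributions(fit)[1, ] - ols)), 1e-8)
  # and recovers the truth to far better than 1e-6 ug/m3
  fitEv <- fitCMB(pan, pr)
  expect_lt(max(abs(sourceContributions(fitEv)[1, ] - Strue)), 1e-6)
})

test_that("zero-noise recovery holds across random well-conditioned profiles", {
  for (seed in 1:5) {
    pr <- genSourceProfiles(nSources = 5, seed = seed)
    set.seed(seed)
    S <- matrix(runif(5, 0.5, 20), 1, dimnames = list("A1", sourceNames(pr)))
    pan <- genElementPanel(pr, S, noiseCV = 0, seed = seed)
    fit <- fitCMB(pan, pr)
    expect_lt(max(abs(sourceContributions(fit) - S)), 1e-6)
  }
})

test_that("fit is scale-equivariant and a fixed point of the iteration", {
  pr <- genSourceProfiles(nSources = 4, seed = 3)
  S <- matrix(c(8, 3, 1, 5), 1, dimnames = list("A1", sourceNames(pr)))
  pan <- genElementPanel(pr, S, noiseCV = 0.1, seed = 3)
  fit <- fitCMB(pan, pr, tol = 1e-10)
  k <- 3.7
  panK <- ElementPanel(sampleIDs(pan), k * concentrations(pan),
                       k * uncertainties(pan))
  fitK <- fitCMB(panK, pr, tol = 1e-10)
  expect_equal(sourceContributions(fitK), k * sourceContributions(fit),
               tolerance = 1e-6)
  # one extra effective-variance update leaves the solution unchanged
  els <- fit@fitElements
  Shat <- 1000 * sourceContributions(fit)[1, ]
  Fm <- t(massFractions(pr)[, els])
  Fu <- t(massFractionUnc(pr)[, els])
  Ve <- uncertainties(pan)[1, els]^2 + drop(Fu^2 %*% Shat^2)
  A <- crossprod(Fm, Fm / Ve)
  b <- crossprod(Fm, concentrations(pan)[1, els] / Ve)
  expect_lt(max(abs(drop(solve(A, b)) - Shat) / pmax(abs(Shat), 1)), 1e-8)
})

test_that("rank-deficient profiles raise an error naming collinear sources", {
  pr <- genSourceProfiles(nSources = 3, seed = 4)
  fr <- massFractions(pr)
  fr[2, ] <- fr[1, ]          # duplicate source composition
  prBad <- SourceProfileSet(fr, massFractionUnc(pr))
  pan <- genElementPanel(pr, matrix(c(5, 5, 5), 1), noiseCV = 0, seed = 4)
  err <- tryCatch(fitCMB(pan, prBad), error = identity)
  expect_match(conditionMessage(err), "collinear")
  expect_match(conditionMessage(err), "African dust")
  expect_match(conditionMessage(err), "local soil")
})

test_that("mineral mass reconstruction matches apportioned crustal mass", {
  pr <- genSourceProfiles(nSources = 3, seed = 5, jitterCV = 0)
  S <- matrix(c(30, 0, 0), 1, dimnames = list("A1", sourceNames(pr)))
  pan <- genElementPanel(pr, S, noiseCV = 0, seed = 5)
  # zero-contribution sources may fit to tiny negatives; that is warned
  fit <- suppressWarnings(fitCMB(pan, pr))
  rm3 <- reconstructMineralMass(fit, sourceNames(pr), panel = pan)
  expect_equal(rm3$apportioned, sum(sourceContributions(fit)),
               tolerance = 1e-8)
  # oxide-weighted RMMM of a purely crustal sample agrees within 15%
  expect_lt(abs(rm3$rmmm - rm3$apportioned) / rm3$apportioned, 0.15)
  expect_equal(reconstructMineralMass(fit, character())$apportioned, 0)
  expect_error(reconstructMineralMass(fit, "nonesuch"), "not in apportionment")
})

test_that("ratio diagnostics reproduce the campaign means", {
  pan <- readElementPanel(dustbiomeExtdata("elements_houston_synthetic.csv"))
  rd <- ratioDiagnostics(pan)
  m <- attr(rd, "means")
  expect_equal(round(unname(m["la_ce"]), 2), 0.55)
  expect_equal(round(unname(m["la_v"]), 2), 0.24)
  # symmetry: La == Ce gives ratio exactly 1
  conc <- matrix(c(2, 2, 5), 1, dimnames = list(NULL, c("La", "Ce", "V")))
  rd2 <- ratioDiagnostics(makePanel(conc))
  expect_equal(unname(attr(rd2, "means")["la_ce"]), 1)
  # zero denominator flagged and excluded
  conc0 <- matrix(c(2, 2, 0, 1, 1, 1), 2, byrow = TRUE,
                  dimnames = list(NULL, c("La", "Ce", "V")))
  expect_warning(rd3 <- ratioDiagnostics(makePanel(conc0)), "zero/missing")
  expect_true(is.na(rd3$la_v[1]))
  expect_equal(unname(attr(rd3, "means")["la_v"]), 1)
})

test_that("dust-day classification reproduces the printed labels", {
  expect_equal(as.character(classifyDustDays(c(65.7, 14.0, 2.0))),
               c("peak", "medium", "low"))
  t1 <- houstonCampaign()
  lab <- classifyDustDays(setNames(t1$saharan_dust, t1$sample_id))
  expect_equal(as.character(lab), t1$dust_label)
  expect_error(classifyDustDays(1, thresholds = c(30, 10)))
})

test_that("percent-contribution summary behaves on edge cases", {
  t1 <- houstonCampaign()
  idx <- t1$sample_id %in% c("S1", "S6", "S7", "S8", "S9")
  s <- summarizeContributions(setNames(t1$saharan_dust, t1$sample_id)[idx],
                              t1$pm10[idx])
  expect_equal(round(s$mean), 12)
  one <- summarizeContributions(5, 50)
  expect_equal(one$sd, 0)
  expect_equal(one$mean, 10)
  z <- summarizeContributions(c(0, 0), c(40, 50))
  expect_equal(z$mean, 0)
  expect_error(summarizeContributions(numeric(0), numeric(0)), "empty")
})

test_that("unapportioned fraction recovers known secondary mass share", {
  pr <- genSourceProfiles(nSources = 4, seed = 6)
  S <- matrix(c(10, 5, 3, 2), 1, dimnames = list("A1", sourceNames(pr)))
  panFull <- genElementPanel(pr, S, noiseCV = 0, seed = 6)
  fitFull <- fitCMB(panFull, pr)
  expect_equal(unapportionedFraction(fitFull)$mean, 0, tolerance = 1e-6)
  pan20 <- genElementPanel(pr, S, noiseCV = 0, seed = 6,
                           secondaryFraction = 0.2)
  expect_equal(unapportionedFraction(fitCMB(pan20, pr))$mean, 20,
               tolerance = 0.5)
  # over-apportionment is reported negative, not clipped
  panNeg <- ElementPanel(sampleIDs(panFull), concentrations(panFull),
                         uncertainties(panFull), pm10 = 0.9 * sum(S))
  fitNeg <- fitCMB(panNeg, pr)
  expect_warning(u <- unapportionedFraction(fitNeg), "over-apportionment")
  expect_lt(u$mean, 0)
})
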