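## Synthetic-data generators with known ground truth for every input
## class: linear source mixtures with multiplicative noise, log-normal
## OTU abundances with covariate-linked subsets, Yule trees with traits at
## known lambda, and communities with exponential distance-decay
## turnover. Every generator is deterministic given (arguments, seed) and
## attaches its ground truth as the `truth` attribute.

.DEFAULT_ELEMENTS <- c("Al", "Si", "Ca", "Fe", "Ti", "K", "Na", "Mg",
                       "S", "Cl", "P", "V", "Cr", "Mn", "Ni", "Cu",
                       "Zn", "As", "Se", "Br", "Rb", "Sr", "Zr", "Mo",
                       "Cd", "Sn", "Sb", "Cs", "Ba", "La", "Ce", "Nd",
                       "Sm", "W", "Pb", "Th")

.DEFAULT_SOURCES <- c("African dust", "local soil", "concrete dust",
                      "road dust", "motor vehicles", "sea salt",
                      "oil combustion")

#' Generate a well-conditioned aerosol source profile set
#'
#' Emulates a seven-source urban profile library over 36 major and trace
#' elements: a crustal long-range dust profile (Al/Si/Ti/rare-earth rich,
#' La/Ce = 0.5), a local soil variant (K/Mn/Rb-enriched, traffic-metal
#' contaminated), concrete dust (Ca/Sr), road dust (brake/tire wear:
#' Fe/Cu/Zn/Zr/Sb/Ba), motor vehicles (S/Zn/Pb/Cu/Br/Ba), sea salt
#' (Na/Cl/Mg/Br) and oil combustion (V/Ni-rich, crude oil's most
#' abundant trace metals, plus S/Se/Mo). Distinct per-source tracer
#' signatures keep the library well separated, mirroring the element
#' panels used in urban receptor modelling. Base fractions are fixed; a
#' small multiplicative jitter (seeded) decorrelates replicate draws.
#' Draws are rejected until the profile matrix condition number on the
#' default fit elements is below `maxCondition`.
#'
#' @param nSources number of sources (1 to 7, taken in the order above).
#' @param elements element set (default 36 elements incl. La/Ce/V/Ni).
#' @param seed RNG seed.
#' @param jitterCV multiplicative jitter CV on nonzero fractions.
#' @param uncCV profile uncertainty CV.
#' @param maxCondition conditioning bound.
#' @return a [SourceProfileSet-class] with a `truth` attribute.
#' @export
genSourceProfiles <- function(nSources = 7, elements = .DEFAULT_ELEMENTS,
                              seed = 1, jitterCV = 0.05, uncCV = 0.1,
                              maxCondition = 100) {
  stopifnot(nSources >= 1, nSources <= length(.DEFAULT_SOURCES))
  mkp <- function(...) {
    v <- c(...)
    out <- setNames(numeric(length(.DEFAULT_ELEMENTS)), .DEFAULT_ELEMENTS)
    out[names(v)] <- v
    out
  }
  base <- rbind(
    "African dust" = mkp(Al = .081, Si = .28, Ca = .025, Fe = .05,
      Ti = .0048, K = .023, Na = .006, Mg = .013, S = .002, Cl = .001,
      P = 7e-4, V = 1.1e-4, Cr = 8e-5, Mn = 8.5e-4, Ni = 5.5e-5,
      Cu = 3e-5, Zn = 9e-5, As = 2e-6, Se = 1e-7, Br = 3e-6, Rb = 9e-5,
      Sr = 2.5e-4, Zr = 2.8e-4, Mo = 8e-7, Cd = 1e-7, Sn = 2e-6,
      Sb = 3e-7, Cs = 5e-6, Ba = 5e-4, La = 3.4e-5, Ce = 6.8e-5,
      Nd = 2.9e-5, Sm = 6e-6, W = 1e-6, Pb = 2e-5, Th = 1.1e-5),
    "local soil" = mkp(Al = .035, Si = .09, Ca = .1, Fe = .022,
      Ti = 8e-4, K = .032, Na = .009, Mg = .006, S = .007, Cl = .002,
      P = .0015, V = 5e-5, Cr = 6e-5, Mn = .003, Ni = 5e-5, Cu = 2.5e-4,
      Zn = 1.1e-3, As = 6e-6, Se = 8e-7, Br = 8e-6, Rb = 2.4e-4,
      Sr = 4e-4, Zr = 6e-5, Mo = 2e-6, Cd = 6e-7, Sn = 8e-6, Sb = 2e-6,
      Cs = 2.2e-5, Ba = 8e-4, La = 1e-5, Ce = 2.1e-5, Nd = 8e-6,
      Sm = 1.6e-6, W = 8e-7, Pb = 3e-4, Th = 3e-6),
    "concrete dust" = mkp(Al = .016, Si = .06, Ca = .31, Fe = .009,
      Ti = 7e-4, K = .005, Na = .003, Mg = .007, S = .007, Cl = .001,
      P = 4e-4, V = 2.5e-5, Cr = 3e-5, Mn = 2.5e-4, Ni = 2e-5, Cu = 4e-5,
      Zn = 1.2e-4, As = 1e-6, Se = 2e-7, Br = 1e-6, Rb = 2.5e-5,
      Sr = 1.6e-3, Zr = 3e-5, Mo = 1e-6, Cd = 1e-7, Sn = 2e-6, Sb = 5e-7,
      Cs = 2e-6, Ba = 3e-4, La = 5e-6, Ce = 1e-5, Nd = 4e-6, Sm = 8e-7,
      W = 5e-7, Pb = 3e-5, Th = 1.5e-6),
    "road dust" = mkp(Al = .025, Si = .08, Ca = .06, Fe = .09,
      Ti = .0012, K = .006, Na = .005, Mg = .005, S = .004, Cl = .003,
      P = 6e-4, V = 8e-5, Cr = 4e-4, Mn = .0012, Ni = 2e-4, Cu = 2.2e-3,
      Zn = 3.2e-3, As = 3e-6, Se = 5e-7, Br = 6e-6, Rb = 3e-5, Sr = 2e-4,
      Zr = 1.1e-3, Mo = 5e-5, Cd = 2e-6, Sn = 1.2e-4, Sb = 3.4e-4,
      Cs = 3e-6, Ba = 3.6e-3, La = 7e-6, Ce = 1.5e-5, Nd = 5e-6,
      Sm = 1e-6, W = 2.5e-5, Pb = 6e-4, Th = 1.2e-6),
    "motor vehicles" = mkp(Al = .003, Si = .01, Ca = .015, Fe = .02,
      Ti = 3e-4, K = .003, Na = .002, Mg = .002, S = .03, Cl = .002,
      P = .004, V = 1.2e-4, Cr = 1.8e-4, Mn = 3.5e-4, Ni = 3.5e-4,
      Cu = 3.8e-3, Zn = .009, As = 4e-6, Se = 2e-6, Br = 1.8e-4,
      Rb = 6e-6, Sr = 8e-5, Zr = 1.5e-4, Mo = 1.4e-4, Cd = 8e-6,
      Sn = 9e-5, Sb = 9e-5, Cs = 1e-6, Ba = .0048, La = 2e-6, Ce = 5e-6,
      Nd = 1.5e-6, Sm = 3e-7, W = 6e-6, Pb = 3e-3, Th = 3e-7),
    "sea salt" = mkp(Al = 3e-4, Si = 1e-3, Ca = .012, Fe = 2e-4,
      Ti = 2e-5, K = .011, Na = .31, Mg = .037, S = .026, Cl = .55,
      P = 1e-5, V = 5e-6, Cr = 1e-6, Mn = 6e-6, Ni = 3e-6, Cu = 6e-6,
      Zn = 3e-5, As = 5e-7, Se = 1e-7, Br = 1.9e-3, Rb = 3.4e-6,
      Sr = 2.2e-3, Zr = 1e-6, Mo = 3e-7, Cd = 3e-8, Sn = 2e-7, Sb = 1e-7,
      Cs = 1e-7, Ba = 2e-5, La = 1e-7, Ce = 2e-7, Nd = 8e-8, Sm = 2e-8,
      W = 1e-8, Pb = 4e-6, Th = 2e-8),
    "oil combustion" = mkp(Al = .002, Si = .004, Ca = .006, Fe = .008,
      Ti = 2e-4, K = .002, Na = .01, Mg = .003, S = .28, Cl = .002,
      P = 3e-4, V = .012, Cr = 2e-4, Mn = 2e-4, Ni = .0046, Cu = 2.6e-4,
      Zn = 5.5e-4, As = 1e-5, Se = 2.5e-5, Br = 2e-5, Rb = 2e-6,
      Sr = 8e-5, Zr = 8e-6, Mo = 9e-5, Cd = 2e-6, Sn = 8e-6, Sb = 4e-6,
      Cs = 3e-7, Ba = 3e-4, La = 6e-6, Ce = 9e-6, Nd = 3e-6, Sm = 6e-7,
      W = 3e-6, Pb = 1.6e-4, Th = 2e-7))
  base <- base[seq_len(nSources), intersect(.DEFAULT_ELEMENTS, elements),
               drop = FALSE]
  set.seed(seed)
  for (attempt in seq_len(1000)) {
    frac <- base * matrix(exp(rnorm(length(base), -jitterCV^2 / 2, jitterCV)),
                          nrow(base))
    frac <- pmin(frac, 1)
    if (nSources == 1) break
    Fn <- t(frac)                               # elements x sources
    Fn <- sweep(Fn, 2, sqrt(colSums(Fn^2)), "/")
    if (kappa(Fn, exact = TRUE) < maxCondition) break
    if (attempt == 1000)
      stop("could not draw a profile set with condition number < ",
           maxCondition, call. = FALSE)
  }
  out <- SourceProfileSet(frac, uncCV * frac)
  attr(out, "truth") <- list(seed = seed, jitterCV = jitterCV,
                             uncCV = uncCV)
  out
}

#' Generate an element panel from known source contributions
#'
#' `C = 1000 * S_true %*% F` (ng/m3 from ug/m3 contributions), perturbed
#' elementwise by multiplicative lognormal noise with coefficient of
#' variation `noiseCV` (mean preserved); uncertainties are set to
#' `noiseCV` times the ideal (noise-free) mixture, floored at a tiny
#' positive fraction when `noiseCV = 0`. Tying the uncertainty to the
#' ideal rather than the realized value keeps the weights of downstream
#' weighted fits independent of the noise, avoiding the systematic
#' downward bias that noise-correlated weights induce.
#'
#' @param profiles a [SourceProfileSet-class].
#' @param S samples x sources matrix of true contributions, ug/m3.
#' @param noiseCV multiplicative noise CV.
#' @param seed RNG seed.
#' @param secondaryFraction fraction of PM10 mass not attributable to the
#'   fitted sources (emulates secondary aerosol); PM10 is set to
#'   `rowSums(S) / (1 - secondaryFraction)`.
#' @return an [ElementPanel-class] with a `truth` attribute carrying `S`.
#' @export
genElementPanel <- function(profiles, S, noiseCV = 0.1, seed = 1,
                            secondaryFraction = 0) {
  S <- as.matrix(S)
  stopifnot(all(S >= 0), ncol(S) == nrow(massFractions(profiles)))
  set.seed(seed)
  Fm <- massFractions(profiles)
  C0 <- 1000 * S %*% Fm
  C <- C0
  if (noiseCV > 0) {
    sdl <- sqrt(log(1 + noiseCV^2))
    C <- C0 * matrix(exp(rnorm(length(C0), -sdl^2 / 2, sdl)), nrow(C0))
  }
  ## uncertainties follow the ideal mixture, not its noisy realization:
  ## sigma correlated with the realized noise would bias any weighted fit
  unc <- pmax(noiseCV, 1e-6) * C0
  ids <- rownames(S) %||% paste0("A", seq_len(nrow(S)))
  pm10 <- rowSums(S) / (1 - secondaryFraction)
  out <- ElementPanel(ids, C, unc, pm10 = pm10)
  attr(out, "truth") <- list(S = S, noiseCV = noiseCV, seed = seed,
                             secondaryFraction = secondaryFraction)
  out
}

#' Generate an OTU table with covariate-linked members
#'
#' Baseline expected abundances are log-normal across OTUs; a chosen
#' subset of `nLinked` OTUs has expected proportions shifted linearly
#' with the standardized covariate (`1 + effectSize * z`, floored at
#' 0.05); counts are drawn multinomially at the given depth per sample.
#'
#' @param nOtus,nSamples table dimensions.
#' @param nLinked number of covariate-linked OTUs (first `nLinked` ids).
#' @param covariate numeric per-sample covariate (length `nSamples`).
#' @param effectSize standardized linear effect (default 1).
#' @param depth sequencing depth per sample.
#' @param seed RNG seed.
#' @param covariateName label recorded in the truth.
#' @return an [OtuTable-class] with a `truth` attribute (`linked`,
#'   `effectSize`, `covariate`).
#' @export
genOtuTable <- function(nOtus = 300, nSamples = 9, nLinked = 20,
                        covariate = NULL, effectSize = 1, depth = 30000,
                        seed = 1, covariateName = "covariate") {
  stopifnot(nLinked <= nOtus)
  set.seed(seed)
  if (is.null(covariate)) covariate <- rnorm(nSamples)
  stopifnot(length(covariate) == nSamples)
  if (depth < nOtus)
    warning("sequencing depth below the number of OTUs", call. = FALSE)
  z <- as.vector(scale(covariate))
  baseline <- rlnorm(nOtus, meanlog = 0, sdlog = 1.5)
  lam <- matrix(baseline, nOtus, nSamples)
  linked <- seq_len(nLinked)
  if (nLinked > 0)
    lam[linked, ] <- baseline[linked] %o% pmax(1 + effectSize * z, 0.05)
  counts <- sapply(seq_len(nSamples), function(s)
    rmultinom(1, depth, lam[, s]))
  rownames(counts) <- sprintf("OTU%04d", seq_len(nOtus))
  colnames(counts) <- sprintf("S%d", seq_len(nSamples))
  tax <- sprintf("Bacteria;Phylum%02d;Class%02d;Order%02d;Family%02d;Genus%03d",
                 (seq_len(nOtus) %% 9) + 1, (seq_len(nOtus) %% 17) + 1,
                 (seq_len(nOtus) %% 23) + 1, (seq_len(nOtus) %% 31) + 1,
                 (seq_len(nOtus) %% 97) + 1)
  out <- OtuTable(counts, tax)
  attr(out, "truth") <- list(linked = rownames(counts)[linked],
                             effectSize = effectSize,
                             covariate = setNames(covariate, colnames(counts)),
                             covariateName = covariateName, seed = seed)
  out
}

#' Generate a Yule tree with traits at known Pagel's lambda
#'
#' Simulates a pure-birth (Yule) tree and draws tip traits from a
#' multivariate normal with covariance `rate *` the lambda-transformed
#' Brownian covariance of the tree.
#'
#' @param nTips number of tips (>= 4); ignored when `tree` is supplied.
#' @param lambdaTrue true lambda in `[0, 1]`.
#' @param rate Brownian rate (trait variance per unit branch length).
#' @param seed RNG seed.
#' @param tree optional fixed `phylo` to draw traits on (skips tree
#'   simulation).
#' @param nDraws number of independent trait replicates (vector when 1,
#'   tips x nDraws matrix otherwise).
#' @return list with `tree` (phylo), `traits`, `truth`.
#' @export
genTreeTraits <- function(nTips, lambdaTrue = 1, rate = 1, seed = 1,
                          tree = NULL, nDraws = 1) {
  stopifnot(lambdaTrue >= 0, lambdaTrue <= 1)
  set.seed(seed)
  if (is.null(tree)) {
    if (nTips < 4) stop("need at least 4 tips", call. = FALSE)
    tree <- ape::rphylo(nTips, birth = 1, death = 0)
  } else {
    validatePhylogeny(tree)
    nTips <- length(tree$tip.label)
  }
  C <- phyloCovariance(tree)
  Cl <- C * lambdaTrue
  diag(Cl) <- diag(C)
  R <- chol(rate * Cl + diag(1e-10, nTips))
  traits <- crossprod(R, matrix(rnorm(nTips * nDraws), nTips))
  rownames(traits) <- tree$tip.label
  if (nDraws == 1) traits <- traits[, 1]
  list(tree = tree, traits = traits,
       truth = list(lambda = lambdaTrue, rate = rate, seed = seed))
}

#' Generate communities with exponential distance-decay turnover
#'
#' Species have Laplace (exponential) niches `exp(-|g - o|/tau)` with
#' optima spaced uniformly along an extended gradient and niche width
#' `tau = 1/(2 rate)`; in the dense-optima limit the expected pairwise
#' Bray-Curtis dissimilarity between sites is exactly
#' `1 - exp(-rate |dg|)`. Multiplicative lognormal noise perturbs
#' abundances, then counts are drawn multinomially at `depth`.
#'
#' @param nSites number of sites.
#' @param gradient numeric gradient values (length `nSites`); default
#'   equally spaced on `[0, 1]`.
#' @param rate turnover rate (> 0) per unit gradient distance.
#' @param noise lognormal noise sd (log scale).
#' @param seed RNG seed.
#' @param nOtus species pool size.
#' @param depth counts per site.
#' @return an [OtuTable-class] with a `truth` attribute (`rate`,
#'   `gradient`).
#' @export
genTurnoverCommunities <- function(nSites = 9, gradient = NULL, rate = 2,
                                   noise = 0.05, seed = 1, nOtus = 600,
                                   depth = 200000) {
  stopifnot(rate > 0)
  set.seed(seed)
  if (is.null(gradient)) gradient <- seq(0, 1, length.out = nSites)
  stopifnot(length(gradient) == nSites)
  tau <- 1 / (2 * rate)
  lo <- min(gradient) - 8 * tau
  hi <- max(gradient) + 8 * tau
  optima <- seq(lo, hi, length.out = nOtus)
  lam <- exp(-abs(outer(optima, gradient, "-")) / tau)
  if (noise > 0)
    lam <- lam * matrix(exp(rnorm(length(lam), 0, noise)), nOtus)
  counts <- sapply(seq_len(nSites), function(s) rmultinom(1, depth, lam[, s]))
  rownames(counts) <- sprintf("OTU%04d", seq_len(nOtus))
  colnames(counts) <- sprintf("G%d", seq_len(nSites))
  out <- OtuTable(counts)
  attr(out, "truth") <- list(rate = rate, gradient = setNames(gradient,
                                                              colnames(counts)),
                             tau = tau, noise = noise, seed = seed)
  out
}

#' Generate the "houston9" demonstration scenario
#'
#' A desk-scale emulation of the study shape: 9 daily samples, 7 sources
#' with a dust-pulse contribution trajectory (low - peak - low), a 36
#' element panel with 10% multiplicative noise, bacterial- and
#' fungal-like OTU tables whose linked members track the dust pulse, a
#' Yule tree with traits at known lambda, and covariates from the true
#' contributions. For demonstrations and qualitative checks, not for
#' quantitative comparison with any field campaign.
#'
#' @param seed RNG seed.
#' @return named list: `profiles`, `Strue`, `panel`, `bacteria`, `fungi`,
#'   `treeTraits` (fungal), `bacterialTreeTraits`, `covariates`, `truth`.
#' @export
genHouston9 <- function(seed = 1) {
  profiles <- genSourceProfiles(seed = seed)
  pulse <- c(3, 25, 66, 54, 42, 12, 2, 14, 2)        # dust, ug/m3
  Strue <- cbind(
    `African dust` = pulse,
    `local soil` = c(6, 5, 7, 8, 6, 7, 9, 6, 5),
    `concrete dust` = c(8, 7, 9, 10, 8, 11, 14, 9, 8),
    `road dust` = c(4, 4, 5, 5, 4, 5, 6, 4, 4),
    `motor vehicles` = c(9, 8, 9, 10, 9, 10, 12, 9, 9),
    `sea salt` = c(3, 3, 4, 3, 3, 3, 4, 3, 3),
    `oil combustion` = c(1.2, 1, 0.9, 1, 1, 1.1, 1.4, 1.1, 1.2))
  rownames(Strue) <- paste0("S", 1:9)
  panel <- genElementPanel(profiles, Strue, noiseCV = 0.1, seed = seed + 1,
                           secondaryFraction = 0.18)
  bacteria <- genOtuTable(nOtus = 848, nSamples = 9, nLinked = 36,
                          covariate = pulse, effectSize = 1,
                          depth = 30000, seed = seed + 2,
                          covariateName = "African dust")
  fungi <- genOtuTable(nOtus = 1345, nSamples = 9, nLinked = 77,
                       covariate = pulse, effectSize = 1,
                       depth = 110000, seed = seed + 3,
                       covariateName = "African dust")
  ## tip labels line up with leading OTU ids so each tree and its OTU
  ## table can be used together for phylogenetic-signal analyses; lambda
  ## levels mirror the weaker bacterial vs stronger fungal signal
  relabel <- function(tt) {
    tt$tree$tip.label <- sprintf("OTU%04d", seq_along(tt$tree$tip.label))
    names(tt$traits) <- tt$tree$tip.label
    tt
  }
  ttFungi <- relabel(genTreeTraits(120, lambdaTrue = 0.3, seed = seed + 4))
  ttBact <- relabel(genTreeTraits(100, lambdaTrue = 0.15, seed = seed + 5))
  covariates <- CovariateTable(Strue)
  list(profiles = profiles, Strue = Strue, panel = panel,
       bacteria = bacteria, fungi = fungi, treeTraits = ttFungi,
       bacterialTreeTraits = ttBact, covariates = covariates,
       truth = list(seed = seed, dustPulse = pulse))
}

#' Write a generated scenario and its ground truth to disk
#'
#' Emits element CSV, profile CSV, two OTU TSVs, two Newick trees,
#' covariate CSV and a JSON truth sidecar into `dir`.
#'
#' @param scenario list from [genHouston9()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeScenario <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    elements = writeElementPanel(scenario$panel, file.path(dir, "elements.csv")),
    profiles = writeSourceProfiles(scenario$profiles, file.path(dir, "profiles.csv")),
    bacteria = writeOtuTable(scenario$bacteria, file.path(dir, "bacteria.tsv")),
    fungi = writeOtuTable(scenario$fungi, file.path(dir, "fungi.tsv")),
    covariates = writeCovariates(scenario$covariates,
                                 file.path(dir, "covariates.csv")))
  ape::write.tree(scenario$treeTraits$tree, file.path(dir, "tree_fungi.nwk"))
  paths["tree_fungi"] <- file.path(dir, "tree_fungi.nwk")
  ape::write.tree(scenario$bacterialTreeTraits$tree,
                  file.path(dir, "tree_bacteria.nwk"))
  paths["tree_bacteria"] <- file.path(dir, "tree_bacteria.nwk")
  truth <- list(scenario = scenario$truth,
                panel = attr(scenario$panel, "truth"),
                bacteria = attr(scenario$bacteria, "truth"),
                fungi = attr(scenario$fungi, "truth"),
                fungalTree = scenario$treeTraits$truth,
                bacterialTree = scenario$bacterialTreeTraits$truth)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths["truth"] <- file.path(dir, "truth.json")
  invisible(paths)
}
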