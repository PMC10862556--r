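## Effective-variance chemical mass balance (CMB) receptor model.
##
## The receptor equation is C_i = sum_j F_ij S_j for element i and source
## j: C_i the ambient concentration (ng/m3), F_ij the source-profile mass
## fraction, S_j the source contribution. The weighted least-squares
## solution uses "effective variance" weights that propagate profile
## uncertainty through the current contribution estimate,
##   V_e,i = sigma_Ci^2 + sum_j S_j^2 sigma_Fij^2,
## and is iterated to a fixed point (Watson's effective-variance scheme).

#' Fit the effective-variance CMB receptor model
#'
#' Estimates per-sample source contributions S (ug/m3) from an element
#' panel and a source profile set by iterated weighted least squares with
#' effective-variance weights. Contributions solve `C = F S` where C is in
#' ng/m3, so the internal solution is rescaled by 1000 at the end.
#'
#' Iteration starts from ordinary weighted LS using the measurement
#' uncertainties only and stops when the maximum relative change in S is
#' below `tol` (default 1e-4) or after `maxIter` iterations (an error is
#' raised on non-convergence, carrying the last iterate in the condition).
#' Negative fitted contributions are reported with a warning; with
#' `dropNegative = TRUE` the most negative source is removed and the
#' sample refit until all remaining contributions are non-negative
#' (standard receptor-modelling practice), the dropped sources reporting 0.
#'
#' Diagnostics: `rSquared` is the weighted explained variance
#' `1 - sum(w r^2) / sum(w (C - wmean(C))^2)`; `chiSquared` is
#' `sum(w r^2) / (n_elements - n_sources)`.
#'
#' @param panel an [ElementPanel-class].
#' @param profiles a [SourceProfileSet-class].
#' @param fitElements elements to fit on; default: all elements shared by
#'   panel and profiles after dropping elements missing (non-finite) in
#'   more than half the samples.
#' @param tol relative convergence tolerance on S.
#' @param maxIter maximum effective-variance iterations.
#' @param dropNegative refit without negative sources (see above).
#' @param maxCondition largest acceptable condition number of the profile
#'   submatrix on the fit elements.
#' @return an [ApportionmentResult-class].
#' @examples
#' pr <- genSourceProfiles(seed = 1)
#' S  <- matrix(c(10, 5, 2, 1, 3, 0.5, 0.2), 1,
#'              dimnames = list("A1", sourceNames(pr)))
#' pan <- genElementPanel(pr, S, noiseCV = 0, seed = 1)
#' fit <- fitCMB(pan, pr)
#' sourceContributions(fit)   # recovers S
#' @export
fitCMB <- function(panel, profiles, fitElements = NULL, tol = 1e-4,
                   maxIter = 50L, dropNegative = FALSE,
                   maxCondition = 1e8) {
  shared <- intersect(elementNames(panel), elementNames(profiles))
  if (is.null(fitElements)) {
    ok <- colMeans(is.finite(panel@conc[, shared, drop = FALSE])) >= 0.5
    fitElements <- shared[ok]
  } else {
    missing <- setdiff(fitElements, shared)
    if (length(missing))
      stop("fit elements not present in both panel and profiles: ",
           paste(missing, collapse = ", "), call. = FALSE)
  }
  Fmat <- t(profiles@frac[, fitElements, drop = FALSE])   # elements x sources
  Func <- t(profiles@fracUnc[, fitElements, drop = FALSE])
  nsrc <- ncol(Fmat)
  if (length(fitElements) < nsrc)
    stop("need at least as many fitted elements as sources", call. = FALSE)
  kap <- kappa(Fmat, exact = TRUE)
  if (!is.finite(kap) || kap > maxCondition) {
    cc <- abs(stats::cor(Fmat))
    diag(cc) <- 0
    worst <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    stop(sprintf(
      "profile matrix is rank-deficient/ill-conditioned on the fit elements (condition %.3g); most collinear sources: '%s' and '%s'",
      kap, colnames(Fmat)[worst[1]], colnames(Fmat)[worst[2]]), call. = FALSE)
  }

  ns <- length(panel@sampleIDs)
  contrib <- contribUnc <- matrix(NA_real_, ns, nsrc,
                                  dimnames = list(panel@sampleIDs, colnames(Fmat)))
  resid <- matrix(NA_real_, ns, length(fitElements),
                  dimnames = list(panel@sampleIDs, fitElements))
  r2 <- chi2 <- numeric(ns)
  iters <- integer(ns)
  negSamples <- character()

  solveOne <- function(C, sC, Fm, Fu) {
    S <- .wlsSolve(Fm, C, 1 / sC^2)
    it <- 0L
    repeat {
      it <- it + 1L
      Ve <- sC^2 + drop(Fu^2 %*% S^2)
      Snew <- .wlsSolve(Fm, C, 1 / Ve)
      delta <- max(abs(Snew - S) / pmax(abs(Snew), 1e-12))
      S <- Snew
      if (delta < tol) break
      if (it >= maxIter)
        stop(structure(class = c("cmbNonConvergence", "error", "condition"),
                       list(message = sprintf(
                         "effective-variance iteration did not converge in %d iterations (last max rel change %.3g)",
                         maxIter, delta),
                         call = NULL, lastIterate = S)))
    }
    Ve <- sC^2 + drop(Fu^2 %*% S^2)
    list(S = S, unc = sqrt(diag(.wlsCov(Fm, 1 / Ve))), Ve = Ve, iter = it)
  }

  for (s in seq_len(ns)) {
    C <- panel@conc[s, fitElements]
    sC <- panel@unc[s, fitElements]
    use <- is.finite(C) & is.finite(sC)
    if (sum(use) < nsrc)
      stop("sample '", panel@sampleIDs[s],
           "': fewer finite fitted elements than sources", call. = FALSE)
    active <- seq_len(nsrc)
    repeat {
      fit <- solveOne(C[use], sC[use], Fmat[use, active, drop = FALSE],
                      Func[use, active, drop = FALSE])
      if (!dropNegative || all(fit$S >= 0) || length(active) == 1L) break
      worst <- which.min(fit$S)
      active <- active[-worst]
    }
    S <- numeric(nsrc)
    Sunc <- rep(NA_real_, nsrc)
    S[active] <- fit$S
    Sunc[active] <- fit$unc
    ## dropped sources: contribution fixed at 0, uncertainty undefined ->
    ## report a tiny positive placeholder so the validity invariant holds
    Sunc[-active] <- if (length(active) < nsrc) .Machine$double.eps else Sunc[-active]
    if (any(S < 0)) negSamples <- c(negSamples, panel@sampleIDs[s])
    Chat <- drop(Fmat[use, active, drop = FALSE] %*% fit$S)
    r <- C[use] - Chat
    w <- 1 / fit$Ve
    wmean <- sum(w * C[use]) / sum(w)
    sst <- sum(w * (C[use] - wmean)^2)
    r2[s] <- if (sst > 0) 1 - sum(w * r^2) / sst else NA_real_
    dof <- sum(use) - length(active)
    chi2[s] <- if (dof > 0) sum(w * r^2) / dof else NA_real_
    resid[s, use] <- r
    contrib[s, ] <- S / 1000        # ng/m3 -> ug/m3
    contribUnc[s, ] <- Sunc / 1000
    contribUnc[s, !is.finite(contribUnc[s, ])] <- .Machine$double.eps
    iters[s] <- fit$iter
  }
  if (length(negSamples))
    warning(sprintf("negative fitted contribution(s) in %d sample(s): %s%s",
                    length(negSamples),
                    paste(head(negSamples, 5), collapse = ", "),
                    if (length(negSamples) > 5) ", ..." else ""),
            call. = FALSE)
  pct <- 100 * rowSums(contrib) / panel@pm10
  new("ApportionmentResult", contrib = contrib, contribUnc = contribUnc,
      rSquared = setNames(r2, panel@sampleIDs),
      chiSquared = setNames(chi2, panel@sampleIDs),
      pctMass = setNames(pct, panel@sampleIDs),
      residuals = resid, fitElements = fitElements,
      pm10 = setNames(panel@pm10, panel@sampleIDs), iterations = iters)
}

## Weighted LS via QR of the weighted design (not normal equations):
## zero-noise panels produce weights spanning many orders of magnitude,
## which the normal matrix cannot survive in double precision.
.wlsSolve <- function(Fm, C, w) {
  sw <- sqrt(w)
  drop(qr.coef(qr(Fm * sw), C * sw))
}

## (F' W F)^{-1} via the same QR route, un-pivoting if needed
.wlsCov <- function(Fm, w) {
  qrF <- qr(Fm * sqrt(w))
  R <- qr.R(qrF)
  Ri <- backsolve(R, diag(ncol(Fm)))
  covp <- tcrossprod(Ri)
  piv <- qrF$pivot
  if (is.null(piv)) return(covp)
  cov <- matrix(0, ncol(Fm), ncol(Fm))
  cov[piv, piv] <- covp
  cov
}

## Conventional crustal oxide multipliers used for the reconstructed
## measured mineral material (RMMM): each crustal element is scaled to its
## common oxide form (Al2O3, SiO2, CaO, Fe2O3, TiO2).
.OXIDE_FACTORS <- c(Al = 1.89, Si = 2.14, Ca = 1.4, Fe = 1.43, Ti = 1.67)

#' Reconstruct mineral mass and compare with apportioned mineral dust
#'
#' Returns, per sample, (i) the sum of the apportioned contributions of
#' the named mineral sources and (ii) the oxide-weighted reconstructed
#' measured mineral material (RMMM) from the crustal elements Al, Si, Ca,
#' Fe, Ti: `RMMM = 1.89 Al + 2.14 Si + 1.4 Ca + 1.43 Fe + 1.67 Ti`
#' (ng/m3, reported in ug/m3). Elements absent from the panel are skipped
#' with a warning.
#'
#' @param result an [ApportionmentResult-class].
#' @param mineralSources character vector of mineral source names (e.g.
#'   African dust, local soil, concrete dust); may be empty (sum 0).
#' @param panel the [ElementPanel-class] used for the fit (needed for the
#'   oxide reconstruction; omit to get the apportioned sum only).
#' @return data.frame with columns `sample_id`, `apportioned` and (when a
#'   panel is given) `rmmm`, both ug/m3.
#' @export
reconstructMineralMass <- function(result, mineralSources, panel = NULL) {
  bad <- setdiff(mineralSources, colnames(result@contrib))
  if (length(bad))
    stop("source(s) not in apportionment result: ",
         paste(bad, collapse = ", "), call. = FALSE)
  apport <- if (length(mineralSources))
    rowSums(result@contrib[, mineralSources, drop = FALSE])
  else rep(0, nrow(result@contrib))
  out <- data.frame(sample_id = rownames(result@contrib),
                    apportioned = unname(apport))
  if (!is.null(panel)) {
    have <- intersect(names(.OXIDE_FACTORS), elementNames(panel))
    if (!length(have))
      stop("panel has none of the crustal elements ",
           paste(names(.OXIDE_FACTORS), collapse = ", "), call. = FALSE)
    if (length(have) < length(.OXIDE_FACTORS))
      warning("crustal elements missing from panel: ",
              paste(setdiff(names(.OXIDE_FACTORS), have), collapse = ", "),
              call. = FALSE)
    out$rmmm <- drop(panel@conc[, have, drop = FALSE] %*%
                       .OXIDE_FACTORS[have]) / 1000
  }
  out
}

#' Elemental ratio and mass-ratio dust diagnostics
#'
#' Per-sample La/Ce, La/V and PM10/PM2.5 ratios plus campaign arithmetic
#' means. La/Ce near 0.5 marks upper-crustal (desert dust) character;
#' depressed La/V marks vanadium-rich industrial oil-combustion aerosol;
#' the PM10/PM2.5 mass ratio drops during long-range dust transport.
#' Ratios with a zero/missing denominator are `NA`, excluded from the
#' mean with a warning. Nothing is rounded.
#'
#' @param panel an [ElementPanel-class] containing La, Ce and V.
#' @return data.frame of per-sample ratios with a `means` attribute
#'   (named vector `la_ce`, `la_v`, `pm_ratio`).
#' @export
ratioDiagnostics <- function(panel) {
  need <- c("La", "Ce", "V")
  miss <- setdiff(need, elementNames(panel))
  if (length(miss))
    stop("panel lacks element(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  safeDiv <- function(num, den, what) {
    bad <- !is.finite(den) | den == 0
    if (any(bad) && !all(bad))
      warning(sprintf("%s: zero/missing denominator for %s; excluded from mean",
                      what, paste(panel@sampleIDs[bad], collapse = ", ")),
              call. = FALSE)
    ifelse(bad, NA_real_, num / den)
  }
  df <- data.frame(
    sample_id = panel@sampleIDs,
    la_ce = safeDiv(panel@conc[, "La"], panel@conc[, "Ce"], "La/Ce"),
    la_v  = safeDiv(panel@conc[, "La"], panel@conc[, "V"], "La/V"),
    pm_ratio = safeDiv(panel@pm10, panel@pm25, "PM10/PM2.5"))
  attr(df, "means") <- c(la_ce = mean(df$la_ce, na.rm = TRUE),
                         la_v = mean(df$la_v, na.rm = TRUE),
                         pm_ratio = mean(df$pm_ratio, na.rm = TRUE))
  df
}

#' Classify sampling days by apportioned dust contribution
#'
#' Labels each sample `low` when the dust contribution is below
#' `thresholds[1]`, `peak` when above `thresholds[2]`, and `medium`
#' otherwise. Defaults (10, 30) ug/m3 reproduce the published nine-day
#' categorization.
#'
#' @param x an [ApportionmentResult-class] plus `source` naming the dust
#'   source, or a numeric vector of dust contributions (ug/m3).
#' @param thresholds ordered pair `(low_max, peak_min)`, ug/m3.
#' @param source dust source name when `x` is an apportionment result.
#' @return named factor with levels `low < medium < peak`.
#' @export
classifyDustDays <- function(x, thresholds = c(10, 30),
                             source = "African dust") {
  stopifnot(length(thresholds) == 2, thresholds[1] < thresholds[2])
  if (is(x, "ApportionmentResult")) {
    if (!source %in% colnames(x@contrib))
      stop("source '", source, "' not in apportionment result", call. = FALSE)
    v <- setNames(x@contrib[, source], rownames(x@contrib))
  } else v <- x
  lab <- ifelse(v < thresholds[1], "low",
                ifelse(v > thresholds[2], "peak", "medium"))
  factor(setNames(lab, names(v)), levels = c("low", "medium", "peak"),
         ordered = TRUE)
}

#' Summarize percent dust contribution to PM10
#'
#' For the chosen samples, computes 100 * S_dust / PM10 and its mean,
#' population standard deviation and range.
#'
#' @param dust numeric dust contributions (ug/m3) or an
#'   [ApportionmentResult-class] (with `source`).
#' @param pm10 gravimetric PM10 masses (ug/m3), same order; taken from the
#'   result when `dust` is an apportionment result.
#' @param samples optional subset of sample names.
#' @param source dust source name for result input.
#' @return list with `percent` (named per-sample vector), `mean`, `sd`
#'   (population), `min`, `max`.
#' @export
summarizeContributions <- function(dust, pm10 = NULL, samples = NULL,
                                   source = "African dust") {
  if (is(dust, "ApportionmentResult")) {
    pm10 <- dust@pm10
    dust <- setNames(dust@contrib[, source], rownames(dust@contrib))
  }
  if (!is.null(samples)) {
    idx <- match(samples, names(dust))
    if (any(is.na(idx))) stop("unknown sample(s) requested", call. = FALSE)
    dust <- dust[idx]
    pm10 <- pm10[idx]
  }
  if (length(dust) == 0) stop("empty sample subset", call. = FALSE)
  if (any(!is.finite(pm10)))
    stop("PM10 missing for some requested samples", call. = FALSE)
  pct <- 100 * dust / pm10
  list(percent = pct, mean = mean(pct),
       sd = sqrt(mean((pct - mean(pct))^2)),
       min = min(pct), max = max(pct))
}

#' Percent of PM10 mass not assigned to any fitted source
#'
#' `100 * (PM10 - sum(S)) / PM10` per sample, plus the campaign mean.
#' Negative values (over-apportionment) are reported, not clipped, with a
#' warning. In the field this residual is read as secondary aerosol not
#' resolvable by elemental analysis.
#'
#' @param result an [ApportionmentResult-class] fitted from a panel with
#'   PM10 masses.
#' @return list with `percent` (per sample) and `mean`.
#' @export
unapportionedFraction <- function(result) {
  if (any(!is.finite(result@pm10)))
    stop("PM10 missing; unapportioned fraction undefined", call. = FALSE)
  pct <- 100 * (result@pm10 - rowSums(result@contrib)) / result@pm10
  if (any(pct < 0))
    warning("over-apportionment (sum S > PM10) for ",
            paste(names(pct)[pct < 0], collapse = ", "), call. = FALSE)
  list(percent = pct, mean = mean(pct))
}
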