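## Central S4 containers. Element concentrations are held in ng/m3 and
## gravimetric PM masses in ug/m3 throughout; converters live at the I/O
## boundary so a silent 1000x unit error cannot propagate.

#' ElementPanel: per-sample element concentrations with uncertainties
#'
#' Holds a samples-by-elements matrix of ambient concentrations (ng/m3),
#' a matching matrix of 1-sigma measurement uncertainties, gravimetric
#' PM10/PM2.5 masses (ug/m3) and sampling dates. Dates are metadata only
#' and never enter a computation.
#'
#' @slot sampleIDs character vector of sample labels (e.g. S1..S9).
#' @slot startDate,endDate character calendar dates, metadata only.
#' @slot pm10,pm25 numeric gravimetric masses, ug/m3 (`NA` allowed for
#'   pm25; pm10 must be positive where present).
#' @slot conc numeric matrix, samples x elements, ng/m3.
#' @slot unc numeric matrix of 1-sigma uncertainties, same shape as
#'   `conc`, strictly positive wherever `conc` is finite.
#'
#' @exportClass ElementPanel
setClass("ElementPanel",
  representation(
    sampleIDs = "character",
    startDate = "character",
    endDate   = "character",
    pm10      = "numeric",
    pm25      = "numeric",
    conc      = "matrix",
    unc       = "matrix"
  )
)

setValidity("ElementPanel", function(object) {
  msg <- character()
  n <- length(object@sampleIDs)
  if (anyDuplicated(object@sampleIDs))
    msg <- c(msg, "duplicate sample ids")
  if (nrow(object@conc) != n)
    msg <- c(msg, "conc must have one row per sample")
  if (!identical(dim(object@conc), dim(object@unc)))
    msg <- c(msg, "conc and unc must have identical shape")
  if (is.null(colnames(object@conc)))
    msg <- c(msg, "conc must carry element names as colnames")
  if (length(object@pm10) != n || length(object@pm25) != n)
    msg <- c(msg, "pm10/pm25 must have one value per sample")
  if (any(!is.na(object@pm10) & object@pm10 <= 0))
    msg <- c(msg, "pm10 masses must be positive")
  bad <- is.finite(object@conc) & (!is.finite(object@unc) | object@unc <= 0)
  if (any(bad)) {
    ij <- which(bad, arr.ind = TRUE)[1, ]
    msg <- c(msg, sprintf("non-positive uncertainty at sample '%s', element '%s'",
                          object@sampleIDs[ij[1]], colnames(object@conc)[ij[2]]))
  }
  neg <- !is.na(object@conc) & object@conc < 0
  if (any(neg)) {
    ij <- which(neg, arr.ind = TRUE)[1, ]
    msg <- c(msg, sprintf("negative concentration at sample '%s', element '%s'",
                          object@sampleIDs[ij[1]], colnames(object@conc)[ij[2]]))
  }
  if (length(msg)) msg else TRUE
})

#' SourceProfileSet: element mass fractions per aerosol source
#'
#' Rows are source categories (e.g. African dust, local soil, concrete
#' dust, road dust, motor vehicles, sea salt, oil combustion), columns are
#' elements. Entries are dimensionless mass fractions per unit emitted
#' source mass, with matching 1-sigma uncertainties. Per-source fraction
#' sums may exceed 1 slightly (up to 1.2) because elements are reported as
#' a subset of total mass plus oxide-bound forms.
#'
#' @slot frac numeric matrix, sources x elements, in `[0, 1]`.
#' @slot fracUnc numeric matrix of 1-sigma uncertainties, same shape.
#'
#' @exportClass SourceProfileSet
setClass("SourceProfileSet",
  representation(frac = "matrix", fracUnc = "matrix")
)

setValidity("SourceProfileSet", function(object) {
  msg <- character()
  if (is.null(rownames(object@frac)) || is.null(colnames(object@frac)))
    msg <- c(msg, "frac must carry source rownames and element colnames")
  if (!identical(dim(object@frac), dim(object@fracUnc)))
    msg <- c(msg, "frac and fracUnc must have identical shape")
  if (any(object@frac < 0 | object@frac > 1, na.rm = TRUE))
    msg <- c(msg, "mass fractions must lie in [0, 1]")
  if (any(object@fracUnc < 0, na.rm = TRUE))
    msg <- c(msg, "fraction uncertainties must be non-negative")
  sums <- rowSums(object@frac, na.rm = TRUE)
  if (any(sums > 1.2))
    msg <- c(msg, sprintf("per-source fraction sum exceeds 1.2 for '%s'",
                          rownames(object@frac)[which.max(sums)]))
  if (length(msg)) msg else TRUE
})

#' OtuTable: OTU counts with taxonomy lineages
#'
#' A non-negative integer matrix of OTU counts (OTUs x samples) together
#' with one semicolon-separated taxonomy lineage string per OTU
#' (kingdom;phylum;...;species; `unclassified` tokens and greengenes-style
#' `p__` prefixes are tolerated). Taxonomy may be empty (length zero) when
#' lineages are unknown.
#'
#' @slot counts numeric matrix of non-negative integers, OTUs x samples,
#'   with OTU ids as rownames and sample ids as colnames.
#' @slot taxonomy character vector of lineage strings, one per OTU, or
#'   length zero.
#'
#' @exportClass OtuTable
setClass("OtuTable",
  representation(counts = "matrix", taxonomy = "character")
)

setValidity("OtuTable", function(object) {
  msg <- character()
  if (is.null(rownames(object@counts)))
    msg <- c(msg, "counts must carry OTU ids as rownames")
  if (anyDuplicated(rownames(object@counts)))
    msg <- c(msg, "duplicate OTU ids")
  if (any(object@counts < 0))
    msg <- c(msg, "counts must be non-negative")
  if (any(object@counts != round(object@counts)))
    msg <- c(msg, "counts must be integers")
  if (length(object@taxonomy) > 0 &&
      length(object@taxonomy) != nrow(object@counts))
    msg <- c(msg, "taxonomy must have one lineage per OTU")
  if (length(msg)) msg else TRUE
})

#' CovariateTable: per-sample covariates for correlation/GDM analyses
#'
#' Samples x covariates matrix; covariates are either element
#' concentrations (ng/m3) or apportioned source contributions (ug/m3).
#'
#' @slot values numeric matrix, samples x covariates, with sample ids as
#'   rownames and covariate names as colnames.
#'
#' @exportClass CovariateTable
setClass("CovariateTable", representation(values = "matrix"))

setValidity("CovariateTable", function(object) {
  msg <- character()
  if (is.null(rownames(object@values)) || is.null(colnames(object@values)))
    msg <- c(msg, "values must carry sample rownames and covariate colnames")
  if (anyDuplicated(rownames(object@values)))
    msg <- c(msg, "duplicate sample ids")
  if (length(msg)) msg else TRUE
})

#' ApportionmentResult: per-sample CMB source contribution estimates
#'
#' @slot contrib numeric matrix, samples x sources, fitted source
#'   contributions in ug/m3 (may be negative; see [fitCMB()]).
#' @slot contribUnc matching 1-sigma uncertainties, ug/m3.
#' @slot rSquared,chiSquared per-sample weighted fit diagnostics.
#' @slot pctMass per-sample 100 * sum(contrib) / PM10 (NA without PM10).
#' @slot residuals numeric matrix, samples x fitted elements, observed
#'   minus reconstructed concentration, ng/m3.
#' @slot fitElements elements used in the fit.
#' @slot pm10 gravimetric PM10 carried over from the panel, ug/m3.
#' @slot iterations effective-variance iterations used per sample.
#'
#' @exportClass ApportionmentResult
setClass("ApportionmentResult",
  representation(
    contrib    = "matrix",
    contribUnc = "matrix",
    rSquared   = "numeric",
    chiSquared = "numeric",
    pctMass    = "numeric",
    residuals  = "matrix",
    fitElements = "character",
    pm10       = "numeric",
    iterations = "integer"
  )
)

setValidity("ApportionmentResult", function(object) {
  msg <- character()
  if (!identical(dim(object@contrib), dim(object@contribUnc)))
    msg <- c(msg, "contrib and contribUnc must have identical shape")
  if (any(object@contribUnc <= 0, na.rm = TRUE))
    msg <- c(msg, "contribution uncertainties must be positive")
  if (ncol(object@residuals) != length(object@fitElements))
    msg <- c(msg, "residuals must have one column per fitted element")
  if (length(msg)) msg else TRUE
})

#' LambdaFit: maximum-likelihood Pagel's lambda with Monte-Carlo p-value
#'
#' @slot lambda ML estimate of the lambda branch-length transform, in
#'   `[0, lambdaMax]`; `NA` when the signal is non-identifiable (star tree).
#' @slot lambdaMax upper search bound (1 for ultrametric trees, else the
#'   largest value keeping the transformed covariance positive definite).
#' @slot sigma2 ML Brownian rate at the optimum.
#' @slot rootState ML root (GLS mean) estimate.
#' @slot logLik,logLik0 log-likelihood at the optimum and at lambda = 0.
#' @slot pValue Monte-Carlo (or likelihood-ratio) p-value for lambda > 0.
#' @slot nSims number of Monte-Carlo permutations used (0 for LR test).
#' @slot identifiable FALSE on a star phylogeny, where the likelihood is
#'   constant in lambda.
#'
#' @exportClass LambdaFit
setClass("LambdaFit",
  representation(
    lambda = "numeric", lambdaMax = "numeric", sigma2 = "numeric",
    rootState = "numeric", logLik = "numeric", logLik0 = "numeric",
    pValue = "numeric", nSims = "integer", identifiable = "logical"
  )
)

setValidity("LambdaFit", function(object) {
  msg <- character()
  if (object@identifiable &&
      object@logLik < object@logLik0 - 1e-6)
    msg <- c(msg, "log-likelihood at the optimum below lambda = 0")
  if (!is.na(object@pValue) &&
      (object@pValue <= 0 || object@pValue > 1))
    msg <- c(msg, "p-value must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' GdmModel: fitted generalized dissimilarity model
#'
#' Monotone regression of pairwise community dissimilarity on I-spline
#' transformed site predictors through the link mu = 1 - exp(-eta).
#'
#' @slot intercept non-negative intercept beta0.
#' @slot coefficients named non-negative vector, one entry per
#'   predictor/spline combination (`pred.1`, `pred.2`, ...).
#' @slot predictors predictor names.
#' @slot knots list of knot vectors (min/median/max quantiles by default),
#'   one per predictor, on the original predictor scale.
#' @slot nullDeviance,residualDeviance binomial-type deviances of the
#'   intercept-only and fitted models.
#' @slot devianceExplained 100 * (1 - residual/null).
#' @slot fitted fitted pairwise dissimilarities, in `[0, 1)`.
#' @slot converged,iterations IRLS convergence state.
#'
#' @exportClass GdmModel
setClass("GdmModel",
  representation(
    intercept = "numeric", coefficients = "numeric",
    predictors = "character", knots = "list",
    nullDeviance = "numeric", residualDeviance = "numeric",
    devianceExplained = "numeric", fitted = "numeric",
    converged = "logical", iterations = "integer"
  )
)

setValidity("GdmModel", function(object) {
  msg <- character()
  if (object@intercept < 0 || any(object@coefficients < 0))
    msg <- c(msg, "intercept and coefficients must be non-negative")
  if (any(object@fitted < 0 | object@fitted >= 1))
    msg <- c(msg, "fitted dissimilarities must lie in [0, 1)")
  if (object@devianceExplained > 100 + 1e-8)
    msg <- c(msg, "deviance explained cannot exceed 100%")
  if (length(msg)) msg else TRUE
})
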