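#' @rdname accessors
#' @export
setMethod("sampleIDs", "ElementPanel", function(x) x@sampleIDs)

#' @rdname accessors
#' @export
setMethod("sampleIDs", "OtuTable", function(x) colnames(x@counts))

#' @rdname accessors
#' @export
setMethod("sampleIDs", "CovariateTable", function(x) rownames(x@values))

#' @rdname accessors
#' @export
setMethod("sampleIDs", "ApportionmentResult", function(x) rownames(x@contrib))

#' @rdname accessors
#' @export
setMethod("elementNames", "ElementPanel", function(x) colnames(x@conc))

#' @rdname accessors
#' @export
setMethod("elementNames", "SourceProfileSet", function(x) colnames(x@frac))

#' @rdname accessors
#' @export
setMethod("concentrations", "ElementPanel", function(x) x@conc)

#' @rdname accessors
#' @export
setMethod("uncertainties", "ElementPanel", function(x) x@unc)

#' @rdname accessors
#' @export
setMethod("pm10Mass", "ElementPanel", function(x) setNames(x@pm10, x@sampleIDs))

#' @rdname accessors
#' @export
setMethod("pm25Mass", "ElementPanel", function(x) setNames(x@pm25, x@sampleIDs))

#' @rdname accessors
#' @export
setMethod("sourceNames", "SourceProfileSet", function(x) rownames(x@frac))

#' @rdname accessors
#' @export
setMethod("sourceNames", "ApportionmentResult", function(x) colnames(x@contrib))

#' @rdname accessors
#' @export
setMethod("massFractions", "SourceProfileSet", function(x) x@frac)

#' @rdname accessors
#' @export
setMethod("massFractionUnc", "SourceProfileSet", function(x) x@fracUnc)

#' @rdname accessors
#' @export
setMethod("otuIDs", "OtuTable", function(x) rownames(x@counts))

#' @rdname accessors
#' @export
setMethod("otuCounts", "OtuTable", function(x) x@counts)

#' @rdname accessors
#' @export
setMethod("taxonomy", "OtuTable", function(x) x@taxonomy)

#' @rdname accessors
#' @export
setMethod("relativeAbundance", "OtuTable", function(x) {
  tot <- colSums(x@counts)
  if (any(tot == 0))
    warning("all-zero sample(s): ",
            paste(colnames(x@counts)[tot == 0], collapse = ", "))
  sweep(x@counts, 2, ifelse(tot > 0, tot, NA_real_), "/")
})

#' @rdname accessors
#' @export
setMethod("covariateValues", "CovariateTable", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("sourceContributions", "ApportionmentResult", function(x) x@contrib)

#' @rdname accessors
#' @export
setMethod("contributionUnc", "ApportionmentResult", function(x) x@contribUnc)

setMethod("show", "ElementPanel", function(object) {
  cat(sprintf("ElementPanel: %d samples x %d elements (ng/m3)\n",
              nrow(object@conc), ncol(object@conc)))
  cat("  samples: ", paste(head(object@sampleIDs, 6), collapse = ", "),
      if (length(object@sampleIDs) > 6) ", ..." else "", "\n", sep = "")
  cat("  elements:", paste(head(colnames(object@conc), 8), collapse = ", "),
      if (ncol(object@conc) > 8) "..." else "", "\n")
  cat(sprintf("  PM10 (ug/m3): %s\n",
              paste(format(object@pm10, digits = 3), collapse = " ")))
})

setMethod("show", "SourceProfileSet", function(object) {
  cat(sprintf("SourceProfileSet: %d sources x %d elements\n",
              nrow(object@frac), ncol(object@frac)))
  cat("  sources:", paste(rownames(object@frac), collapse = ", "), "\n")
})

setMethod("show", "OtuTable", function(object) {
  cat(sprintf("OtuTable: %d OTUs x %d samples, %s taxonomy\n",
              nrow(object@counts), ncol(object@counts),
              if (length(object@taxonomy)) "with" else "no"))
  cat("  total counts per sample:",
      paste(format(colSums(object@counts)), collapse = " "), "\n")
})

setMethod("show", "CovariateTable", function(object) {
  cat(sprintf("CovariateTable: %d samples x %d covariates\n",
              nrow(object@values), ncol(object@values)))
  cat("  covariates:", paste(head(colnames(object@values), 10), collapse = ", "),
      if (ncol(object@values) > 10) "..." else "", "\n")
})

setMethod("show", "ApportionmentResult", function(object) {
  cat(sprintf("ApportionmentResult: %d samples x %d sources (ug/m3)\n",
              nrow(object@contrib), ncol(object@contrib)))
  cat("  sources:", paste(colnames(object@contrib), collapse = ", "), "\n")
  cat(sprintf("  mean %% PM10 apportioned: %.1f ; mean r2: %.3f\n",
              mean(object@pctMass, na.rm = TRUE), mean(object@rSquared)))
})

setMethod("show", "LambdaFit", function(object) {
  if (!object@identifiable) {
    cat("LambdaFit: non-identifiable (star phylogeny; likelihood constant in lambda)\n")
    return(invisible(NULL))
  }
  cat(sprintf("LambdaFit: lambda = %.4f (max %.3f), sigma2 = %.4g\n",
              object@lambda, object@lambdaMax, object@sigma2))
  cat(sprintf("  logL = %.3f (lambda=0: %.3f), p = %.4g (%s)\n",
              object@logLik, object@logLik0, object@pValue,
              if (object@nSims > 0) sprintf("%d permutations", object@nSims)
              else "LR chi-square"))
})

setMethod("show", "GdmModel", function(object) {
  cat(sprintf("GdmModel: %d predictors, deviance explained %.1f%%\n",
              length(object@predictors), object@devianceExplained))
  h <- vapply(object@predictors, function(p) {
    sum(object@coefficients[startsWith(names(object@coefficients),
                                       paste0(p, "."))])
  }, numeric(1))
  cat("  partial curve heights:",
      paste(sprintf("%s=%.3f", names(h), h), collapse = ", "), "\n")
  cat(sprintf("  intercept %.4f; %sconverged in %d IRLS iterations\n",
              object@intercept, if (object@converged) "" else "NOT ",
              object@iterations))
})
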