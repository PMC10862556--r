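## UCC-normalized La-V-Ni ternary mixing analysis. Ambient La, V and Ni
## arise almost entirely from two end-members - upper-crustal (desert
## dust) aerosol and V/Ni-rich oil-combustion aerosol - so after a
## normalization that places the upper continental crust (UCC) at the
## ternary centroid, samples fall on the straight segment joining the two
## end-member points, and their position along it tracks the dust share.

#' Upper continental crust reference abundances (ug/g)
#'
#' Average upper-crustal abundances of La, V and Ni from the Rudnick &
#' Gao (2003) compilation; overridable wherever a `reference` argument is
#' accepted.
#' @format named numeric vector, ug/g.
#' @export
UCC_REFERENCE <- c(La = 31, V = 97, Ni = 47)

#' Centroid-anchoring normalization factors
#'
#' Computes per-element multipliers `factor_e = reference[anchor] /
#' reference[e]` so that the reference composition, scaled and closed,
#' plots at the ternary centroid (1/3, 1/3, 1/3). With the packaged UCC
#' reference and V anchored at 1 the factors are 1 (V), 2.06 (Ni),
#' 3.13 (La).
#'
#' @param reference named vector of three reference abundances (> 0).
#' @param anchor element whose multiplier is fixed at 1.
#' @return list with `factors` (named multipliers) and `reference`.
#' @examples
#' centroidFactors()$factors
#' @export
centroidFactors <- function(reference = UCC_REFERENCE, anchor = "V") {
  if (length(reference) != 3 || is.null(names(reference)))
    stop("reference must be a named vector of three abundances", call. = FALSE)
  if (any(reference <= 0))
    stop("reference abundances must be positive", call. = FALSE)
  if (!anchor %in% names(reference))
    stop("anchor element not in reference", call. = FALSE)
  factors <- reference[[anchor]] / reference
  structure(list(factors = factors, reference = reference),
            class = "ternaryFactors")
}

#' Ternary coordinates of samples under a normalization
#'
#' Scales the three elements by the normalization factors and closes to
#' sum 1. Samples with a non-positive scaled value are flagged (`ok`
#' column FALSE, coordinates NA).
#'
#' @param panel an [ElementPanel-class] containing the three elements, or
#'   a samples x 3 matrix with element colnames.
#' @param factors result of [centroidFactors()].
#' @return matrix, samples x 3 (element-named columns summing to 1), with
#'   logical attribute `ok` per sample.
#' @export
ternaryCoordinates <- function(panel, factors = centroidFactors()) {
  els <- names(factors$factors)
  m <- if (is(panel, "ElementPanel")) {
    miss <- setdiff(els, elementNames(panel))
    if (length(miss))
      stop("panel lacks element(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    concentrations(panel)[, els, drop = FALSE]
  } else as.matrix(panel)[, els, drop = FALSE]
  scaled <- sweep(m, 2, factors$factors[els], "*")
  ok <- apply(scaled, 1, function(r) all(is.finite(r)) && all(r >= 0) &&
                sum(r) > 0)
  if (any(!ok))
    warning("flagged sample(s) with non-positive scaled values: ",
            paste(rownames(m)[!ok], collapse = ", "), call. = FALSE)
  coords <- scaled / rowSums(scaled)
  coords[!ok, ] <- NA_real_
  attr(coords, "ok") <- ok
  coords
}

## Equilateral-triangle embedding of the 2-simplex: vertex order follows
## the coordinate columns (a at origin, b at (1,0), c at (1/2, sqrt(3)/2)).
.simplexToPlane <- function(p) {
  p <- matrix(p, ncol = 3)
  cbind(x = p[, 2] + 0.5 * p[, 3], y = sqrt(3) / 2 * p[, 3])
}

#' Project ternary points onto a two-end-member mixing line
#'
#' Embeds the simplex in the plane (equilateral-triangle coordinates) and
#' orthogonally projects each sample onto the segment joining the two
#' end-member compositions. The mixing fraction is 0 at `endMember1` and
#' 1 at `endMember2`; values outside `[0, 1]` are reported and flagged.
#' The perpendicular deviation is the point-to-line distance in the
#' embedding.
#'
#' @param points samples x 3 ternary coordinate matrix (rows sum to 1).
#' @param endMember1,endMember2 length-3 ternary compositions.
#' @return data.frame with `fraction`, `deviation`, `within` (fraction in
#'   `[0,1]`).
#' @export
mixingLineProjection <- function(points, endMember1, endMember2) {
  e1 <- .simplexToPlane(endMember1 / sum(endMember1))
  e2 <- .simplexToPlane(endMember2 / sum(endMember2))
  d <- e2 - e1
  len2 <- sum(d^2)
  if (len2 < 1e-24)
    stop("end members coincide; mixing line undefined", call. = FALSE)
  xy <- .simplexToPlane(points)
  rel <- sweep(xy, 2, drop(e1))
  frac <- drop(rel %*% drop(d)) / len2
  foot <- outer(frac, drop(d))
  dev <- sqrt(rowSums((rel - foot)^2))
  data.frame(fraction = frac, deviation = dev,
             within = frac >= 0 & frac <= 1,
             row.names = rownames(points))
}
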