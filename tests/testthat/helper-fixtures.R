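# Shared test helpers: tiny in-code fixtures and independent oracles.

# panel with named elements from a concentration matrix
makePanel <- function(conc, unc = NULL, pm10 = NA, pm25 = NA) {
  ElementPanel(rownames(conc) %||% paste0("A", seq_len(nrow(conc))),
               conc, unc, pm10 = pm10, pm25 = pm25)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# Procrustes residual after optimal translation/rotation/reflection/scaling
# of configuration X onto Y (independent of any ordination code).
procrustesResidual <- function(X, Y) {
  X <- scale(X, scale = FALSE)
  Y <- scale(Y, scale = FALSE)
  s <- svd(crossprod(Y, X))
  R <- s$v %*% t(s$u)
  Xr <- X %*% R
  sc <- sum(diag(crossprod(Y, Xr))) / sum(Xr^2)
  sqrt(sum((sc * Xr - Y)^2))
}

# Naive Cox-de Boor B-spline evaluation: the independent oracle for the
# I-spline basis (cumulative-sum identity).
bsplineNaive <- function(x, knots, i, ord) {
  if (ord == 1)
    return(as.numeric(x >= knots[i] &
                        (x < knots[i + 1] |
                           (x == knots[i + 1] &
                              knots[i + 1] == knots[length(knots)]))))
  d1 <- knots[i + ord - 1] - knots[i]
  d2 <- knots[i + ord] - knots[i + 1]
  t1 <- if (d1 > 0) (x - knots[i]) / d1 * bsplineNaive(x, knots, i, ord - 1) else 0
  t2 <- if (d2 > 0) (knots[i + ord] - x) / d2 * bsplineNaive(x, knots, i + 1, ord - 1) else 0
  t1 + t2
}

# a small rooted non-trivial tree used across phylo tests
treeABC <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")
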