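## Alpha/beta diversity, ordination, taxon aggregation and the per-OTU
## covariate correlation screen.

#' Chao1 richness estimate for one sample
#'
#' Classic Chao1: `S_obs + F1^2 / (2 F2)` when doubletons are present,
#' bias-corrected `S_obs + F1 (F1 - 1) / 2` when `F2 = 0` (F1, F2 the
#' singleton and doubleton counts). An all-zero sample is undefined (`NA`
#' with a warning).
#'
#' @param counts non-negative integer counts for one sample.
#' @return list with `chao1`, `S_obs`, `F1`, `F2`.
#' @examples
#' chao1(c(5, 3, 1, 1, 2))$chao1   # S=5, F1=2, F2=1 -> 7
#' @export
chao1 <- function(counts) {
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  S <- sum(counts > 0)
  if (S == 0) {
    warning("all-zero sample: Chao1 undefined", call. = FALSE)
    return(list(chao1 = NA_real_, S_obs = 0L, F1 = 0L, F2 = 0L))
  }
  F1 <- sum(counts == 1)
  F2 <- sum(counts == 2)
  est <- if (F2 > 0) S + F1^2 / (2 * F2) else S + F1 * (F1 - 1) / 2
  list(chao1 = est, S_obs = S, F1 = F1, F2 = F2)
}

#' Shannon entropy (nats) for one sample
#'
#' `-sum(p log p)` over positive proportions, natural log.
#'
#' @param counts non-negative counts (or proportions) for one sample.
#' @export
shannon <- function(counts) {
  stopifnot(all(counts >= 0))
  if (sum(counts) == 0) {
    warning("all-zero sample: Shannon undefined", call. = FALSE)
    return(NA_real_)
  }
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}

#' Per-sample alpha diversity table
#'
#' @param table an [OtuTable-class].
#' @return data.frame with per-sample `S_obs`, `F1`, `F2`, `chao1`,
#'   `shannon` (nats).
#' @export
alphaDiversity <- function(table) {
  cnt <- otuCounts(table)
  res <- lapply(seq_len(ncol(cnt)), function(s) {
    c1 <- chao1(cnt[, s])
    data.frame(sample_id = colnames(cnt)[s], S_obs = c1$S_obs,
               F1 = c1$F1, F2 = c1$F2, chao1 = c1$chao1,
               shannon = shannon(cnt[, s]))
  })
  do.call(rbind, res)
}

#' Bray-Curtis dissimilarity matrix
#'
#' `d(x, y) = sum(|x - y|) / sum(x + y)` over OTUs, on raw counts or
#' per-sample proportions. A pair of all-zero samples is undefined (`NA`,
#' flagged with a warning).
#'
#' @param table an [OtuTable-class] or an OTUs x samples matrix.
#' @param proportions divide each sample by its total first.
#' @return square symmetric matrix with zero diagonal and a `meanOffDiag`
#'   attribute (mean of the upper triangle).
#' @export
brayCurtis <- function(table, proportions = FALSE) {
  m <- if (is(table, "OtuTable")) otuCounts(table) else as.matrix(table)
  if (ncol(m) < 2) stop("need at least 2 samples", call. = FALSE)
  if (proportions) {
    tot <- colSums(m)
    m <- sweep(m, 2, ifelse(tot > 0, tot, 1), "/")
  }
  n <- ncol(m)
  d <- matrix(0, n, n, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    tot <- sum(m[, i] + m[, j])
    d[i, j] <- d[j, i] <- if (tot > 0) sum(abs(m[, i] - m[, j])) / tot
    else NA_real_
  }
  if (anyNA(d))
    warning("pair(s) of all-zero samples: dissimilarity undefined",
            call. = FALSE)
  attr(d, "meanOffDiag") <- mean(d[upper.tri(d)], na.rm = TRUE)
  d
}

#' Principal coordinates analysis (classical MDS)
#'
#' Gower-centered eigen-decomposition of `-d^2/2`; coordinates are
#' eigenvectors scaled by the square root of their (positive)
#' eigenvalues; percent variance explained is taken relative to the sum
#' of positive eigenvalues. Negative eigenvalues are reported but
#' excluded from the denominator.
#'
#' @param d square symmetric dissimilarity matrix.
#' @param nAxes number of axes to return (truncated with a warning if it
#'   exceeds the number of positive eigenvalues).
#' @return list with `coordinates` (samples x axes), `eigenvalues` (all,
#'   non-increasing), `percentExplained` (per returned axis).
#' @export
pcoa <- function(d, nAxes = 3) {
  d <- as.matrix(d)
  n <- nrow(d)
  stopifnot(n == ncol(d), max(abs(d - t(d))) < 1e-8)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (d^2) %*% J
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  pos <- eig$values > max(eig$values) * 1e-12
  npos <- sum(pos)
  if (nAxes > npos) {
    warning(sprintf("only %d positive eigenvalues; truncating axes", npos),
            call. = FALSE)
    nAxes <- npos
  }
  coords <- eig$vectors[, seq_len(nAxes), drop = FALSE] %*%
    diag(sqrt(eig$values[seq_len(nAxes)]), nAxes)
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("PCo", seq_len(nAxes))
  list(coordinates = coords, eigenvalues = eig$values,
       percentExplained = 100 * eig$values[seq_len(nAxes)] /
         sum(eig$values[pos]))
}

.RANKS <- c("kingdom", "phylum", "class", "order", "family", "genus",
            "species")

.rankToken <- function(taxonomy, rank) {
  idx <- match(rank, .RANKS)
  if (is.na(idx)) stop("unknown rank '", rank, "'; use one of ",
                       paste(.RANKS, collapse = ", "), call. = FALSE)
  vapply(strsplit(taxonomy, ";"), function(tok) {
    tok <- trimws(tok)
    tok <- sub("^[a-z]__", "", tok)      # greengenes-style prefixes
    if (length(tok) < idx) return("unclassified")
    t <- tok[idx]
    if (t == "" || tolower(t) == "unclassified") "unclassified" else t
  }, character(1))
}

#' Aggregate relative abundances at a taxonomic rank
#'
#' Converts counts to per-sample proportions, groups OTUs by the lineage
#' token at `rank` (OTUs lacking the rank pooled as `unclassified`),
#' keeps the `topN` groups by campaign-wide mean abundance and pools the
#' remainder as `other`.
#'
#' @param table an [OtuTable-class] with taxonomy.
#' @param rank one of kingdom, phylum, class, order, family, genus,
#'   species.
#' @param topN number of named groups to keep.
#' @return groups x samples matrix of proportions; columns sum to 1.
#' @export
aggregateTaxa <- function(table, rank = "phylum", topN = 30) {
  if (!length(taxonomy(table)))
    stop("OTU table has no taxonomy", call. = FALSE)
  prop <- relativeAbundance(table)
  grp <- .rankToken(taxonomy(table), rank)
  agg <- rowsum(prop, grp)
  named <- setdiff(rownames(agg), "unclassified")
  keep <- named[order(rowMeans(agg[named, , drop = FALSE]),
                      decreasing = TRUE)][seq_len(min(topN, length(named)))]
  rest <- setdiff(named, keep)
  out <- agg[keep, , drop = FALSE]
  if (length(rest))
    out <- rbind(out, other = colSums(agg[rest, , drop = FALSE]))
  if ("unclassified" %in% rownames(agg))
    out <- rbind(out, unclassified = agg["unclassified", ])
  out
}

#' Per-OTU covariate correlation screen
#'
#' Pearson correlation between each OTU's relative abundance and each
#' covariate across samples, with a two-sided t-test p-value (df = n - 2)
#' and uncorrected significance at `alpha` (Benjamini-Hochberg optionally
#' via `adjust = "BH"`). For each OTU, the covariate with the largest
#' |r| among its significant correlations is flagged `strongest`.
#' Constant OTUs are skipped with a note attribute; constant covariates
#' are an error.
#'
#' @param table an [OtuTable-class].
#' @param covariates a [CovariateTable-class] sharing >= 4 samples with
#'   the table, in consistent order.
#' @param alpha significance level (default 0.05, uncorrected).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return data.frame with `otu_id`, `covariate`, `r`, `p`, `significant`,
#'   `sign`, `strongest`; attributes `counts` (per-covariate significant
#'   totals split by sign) and `skipped` (constant OTUs).
#' @export
correlationScreen <- function(table, covariates, alpha = 0.05,
                              adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  shared <- intersect(sampleIDs(table), sampleIDs(covariates))
  if (length(shared) < 4)
    stop("need at least 4 shared samples", call. = FALSE)
  prop <- relativeAbundance(table)[, shared, drop = FALSE]
  X <- covariateValues(covariates)[shared, , drop = FALSE]
  if (any(apply(X, 2, var) == 0))
    stop("constant covariate(s): ",
         paste(colnames(X)[apply(X, 2, var) == 0], collapse = ", "),
         call. = FALSE)
  keep <- apply(prop, 1, var) > 0
  skipped <- rownames(prop)[!keep]
  prop <- prop[keep, , drop = FALSE]
  n <- length(shared)
  ## vectorized Pearson r: standardize rows/cols, r = Z_otu %*% Z_cov / (n-1)
  Zp <- t(scale(t(prop)))
  Zx <- scale(X)
  r <- (Zp %*% Zx) / (n - 1)
  r <- pmin(pmax(r, -1), 1)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-300))
  p <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  res <- data.frame(
    otu_id = rep(rownames(r), times = ncol(r)),
    covariate = rep(colnames(r), each = nrow(r)),
    r = as.vector(r), p = as.vector(p))
  if (adjust == "BH") res$p <- stats::p.adjust(res$p, "BH")
  res$significant <- res$p < alpha
  res$sign <- ifelse(res$r >= 0, "positive", "negative")
  res$strongest <- FALSE
  sig <- res[res$significant, ]
  if (nrow(sig)) {
    best <- tapply(seq_len(nrow(sig)), sig$otu_id,
                   function(ix) ix[which.max(abs(sig$r[ix]))])
    rowsBest <- match(paste(sig$otu_id[best], sig$covariate[best]),
                      paste(res$otu_id, res$covariate))
    res$strongest[rowsBest] <- TRUE
  }
  counts <- do.call(rbind, lapply(colnames(r), function(cv) {
    sub <- res[res$covariate == cv & res$significant, ]
    data.frame(covariate = cv, n_significant = nrow(sub),
               n_positive = sum(sub$sign == "positive"),
               n_negative = sum(sub$sign == "negative"))
  }))
  attr(res, "counts") <- counts
  attr(res, "skipped") <- skipped
  res
}
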