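## Readers/writers for the tabular and tree formats. Concentrations are
## ng/m3 and PM masses ug/m3 on disk and in memory; no unit conversion is
## performed silently.

.numeric_or_stop <- function(x, what, rows) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & x != "" & is.na(out))
  if (length(bad))
    stop(sprintf("non-numeric value '%s' in column '%s', row %d",
                 x[bad[1]], what, rows[bad[1]]), call. = FALSE)
  out
}

#' Construct an ElementPanel
#'
#' @param sampleIDs character sample labels.
#' @param conc samples x elements matrix of concentrations, ng/m3.
#' @param unc matching 1-sigma uncertainty matrix, ng/m3. If `NULL`,
#'   uncertainties are imputed as `uncCV * conc` (floored at the smallest
#'   positive machine-representable fraction of the concentration).
#' @param pm10,pm25 gravimetric masses, ug/m3 (`NA` allowed for pm25).
#' @param startDate,endDate optional calendar dates (metadata only).
#' @param uncCV coefficient of variation used when `unc` is missing.
#' @return a validated [ElementPanel-class] object.
#' @export
ElementPanel <- function(sampleIDs, conc, unc = NULL, pm10 = NA_real_,
                         pm25 = NA_real_, startDate = NA_character_,
                         endDate = NA_character_, uncCV = 0.1) {
  conc <- as.matrix(conc)
  storage.mode(conc) <- "double"
  if (is.null(unc)) {
    if (is.null(uncCV))
      stop("no uncertainties supplied and no uncertainty CV configured",
           call. = FALSE)
    unc <- pmax(uncCV * abs(conc), .Machine$double.eps)
  }
  unc <- as.matrix(unc)
  storage.mode(unc) <- "double"
  dimnames(unc) <- dimnames(conc)
  n <- length(sampleIDs)
  rownames(conc) <- rownames(unc) <- sampleIDs
  new("ElementPanel", sampleIDs = as.character(sampleIDs),
      startDate = rep_len(as.character(startDate), n),
      endDate = rep_len(as.character(endDate), n),
      pm10 = rep_len(as.numeric(pm10), n),
      pm25 = rep_len(as.numeric(pm25), n),
      conc = conc, unc = unc)
}

#' Read / write an element concentration panel (CSV)
#'
#' The CSV has one row per sample with columns `sample_id`, optional
#' `start_date`/`end_date`, optional `pm10`/`pm25` (ug/m3), one column per
#' element (ng/m3) and optionally one paired `<element>_unc` column per
#' element. Elements without an uncertainty column get `uncCV * conc`.
#'
#' @param path CSV file path.
#' @param uncCV coefficient of variation for missing uncertainties
#'   (default 0.1); set `NULL` to require explicit uncertainty columns.
#' @return [readElementPanel()]: an [ElementPanel-class].
#' @export
readElementPanel <- function(path, uncCV = 0.1) {
  raw <- read.csv(path, check.names = FALSE, colClasses = "character",
                  strip.white = TRUE)
  if (!"sample_id" %in% names(raw))
    stop("element panel CSV must have a 'sample_id' column", call. = FALSE)
  meta <- c("sample_id", "start_date", "end_date", "pm10", "pm25")
  rows <- seq_len(nrow(raw)) + 1L    # header is line 1
  getnum <- function(col) {
    if (col %in% names(raw)) .numeric_or_stop(raw[[col]], col, rows)
    else rep(NA_real_, nrow(raw))
  }
  cols <- setdiff(names(raw), meta)
  uncCols <- grep("_unc$", cols, value = TRUE)
  elements <- setdiff(cols, uncCols)
  conc <- sapply(elements, getnum)
  conc <- matrix(conc, nrow = nrow(raw), dimnames = list(NULL, elements))
  unc <- matrix(NA_real_, nrow(raw), length(elements),
                dimnames = list(NULL, elements))
  for (el in elements) {
    uc <- paste0(el, "_unc")
    if (uc %in% uncCols) {
      unc[, el] <- getnum(uc)
    } else {
      if (is.null(uncCV))
        stop(sprintf("no uncertainty column for element '%s' and no CV configured", el),
             call. = FALSE)
      unc[, el] <- pmax(uncCV * abs(conc[, el]), .Machine$double.eps)
    }
  }
  ElementPanel(raw$sample_id, conc, unc,
               pm10 = getnum("pm10"), pm25 = getnum("pm25"),
               startDate = if ("start_date" %in% names(raw)) raw$start_date else NA,
               endDate = if ("end_date" %in% names(raw)) raw$end_date else NA)
}

#' @rdname readElementPanel
#' @param panel an [ElementPanel-class] to serialize.
#' @export
writeElementPanel <- function(panel, path) {
  df <- data.frame(sample_id = panel@sampleIDs,
                   start_date = panel@startDate, end_date = panel@endDate,
                   pm10 = panel@pm10, pm25 = panel@pm25,
                   check.names = FALSE)
  for (el in colnames(panel@conc)) {
    df[[el]] <- panel@conc[, el]
    df[[paste0(el, "_unc")]] <- panel@unc[, el]
  }
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a SourceProfileSet
#'
#' @param frac sources x elements matrix of mass fractions (with source
#'   rownames and element colnames).
#' @param fracUnc matching uncertainty matrix; defaults to `uncCV * frac`.
#' @param uncCV coefficient of variation used when `fracUnc` is missing.
#' @export
SourceProfileSet <- function(frac, fracUnc = NULL, uncCV = 0.1) {
  frac <- as.matrix(frac)
  storage.mode(frac) <- "double"
  if (is.null(fracUnc)) fracUnc <- uncCV * frac
  fracUnc <- as.matrix(fracUnc)
  storage.mode(fracUnc) <- "double"
  dimnames(fracUnc) <- dimnames(frac)
  new("SourceProfileSet", frac = frac, fracUnc = fracUnc)
}

#' Read / write aerosol source profiles (CSV)
#'
#' One row per source: a `source` column, one column per element holding
#' the mass fraction, and optionally `<element>_unc` columns.
#'
#' @param path CSV file path.
#' @param uncCV CV used for elements without an uncertainty column.
#' @export
readSourceProfiles <- function(path, uncCV = 0.1) {
  raw <- read.csv(path, check.names = FALSE, colClasses = "character",
                  strip.white = TRUE)
  if (!"source" %in% names(raw))
    stop("profile CSV must have a 'source' column", call. = FALSE)
  rows <- seq_len(nrow(raw)) + 1L
  cols <- setdiff(names(raw), "source")
  uncCols <- grep("_unc$", cols, value = TRUE)
  elements <- setdiff(cols, uncCols)
  frac <- sapply(elements, function(el) .numeric_or_stop(raw[[el]], el, rows))
  frac <- matrix(frac, nrow = nrow(raw),
                 dimnames = list(raw$source, elements))
  fracUnc <- matrix(NA_real_, nrow(raw), length(elements),
                    dimnames = dimnames(frac))
  for (el in elements) {
    uc <- paste0(el, "_unc")
    fracUnc[, el] <- if (uc %in% uncCols)
      .numeric_or_stop(raw[[uc]], uc, rows) else uncCV * frac[, el]
  }
  SourceProfileSet(frac, fracUnc)
}

#' @rdname readSourceProfiles
#' @param profiles a [SourceProfileSet-class] to serialize.
#' @export
writeSourceProfiles <- function(profiles, path) {
  df <- data.frame(source = rownames(profiles@frac), check.names = FALSE)
  for (el in colnames(profiles@frac)) {
    df[[el]] <- profiles@frac[, el]
    df[[paste0(el, "_unc")]] <- profiles@fracUnc[, el]
  }
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct an OtuTable
#'
#' @param counts OTUs x samples matrix of non-negative integer counts with
#'   OTU ids as rownames.
#' @param taxonomy optional character vector of lineage strings.
#' @export
OtuTable <- function(counts, taxonomy = character()) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  new("OtuTable", counts = counts, taxonomy = as.character(taxonomy))
}

#' Read / write an OTU table (TSV, QIIME-classic dialect)
#'
#' Tab-separated: first column the OTU id (header `#OTU ID` tolerated),
#' one column per sample, optional trailing `taxonomy` column holding
#' semicolon-separated lineages. Counts must be integers.
#'
#' @param path TSV file path.
#' @export
readOtuTable <- function(path) {
  ln1 <- readLines(path, n = 1)
  raw <- read.delim(path, check.names = FALSE, colClasses = "character",
                    comment.char = "", strip.white = TRUE)
  names(raw)[1] <- sub("^#\\s*OTU\\s*ID$", "otu_id", names(raw)[1],
                       ignore.case = TRUE)
  taxcol <- names(raw)[tolower(names(raw)) == "taxonomy"]
  samples <- setdiff(names(raw)[-1], taxcol)
  rows <- seq_len(nrow(raw)) + 1L
  counts <- sapply(samples, function(s) .numeric_or_stop(raw[[s]], s, rows))
  counts <- matrix(counts, nrow = nrow(raw),
                   dimnames = list(raw[[1]], samples))
  if (any(counts != round(counts), na.rm = TRUE)) {
    ij <- which(counts != round(counts), arr.ind = TRUE)[1, ]
    stop(sprintf("non-integer count for OTU '%s', sample '%s'",
                 rownames(counts)[ij[1]], samples[ij[2]]), call. = FALSE)
  }
  taxonomy <- if (length(taxcol)) raw[[taxcol[1]]] else character()
  OtuTable(counts, taxonomy)
}

#' @rdname readOtuTable
#' @param table an [OtuTable-class] to serialize.
#' @export
writeOtuTable <- function(table, path) {
  df <- data.frame(`#OTU ID` = rownames(table@counts), table@counts,
                   check.names = FALSE)
  if (length(table@taxonomy)) df$taxonomy <- table@taxonomy
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a rooted phylogeny (Newick)
#'
#' Thin validated wrapper around [ape::read.tree()]: requires branch
#' lengths, unique tip labels, non-negative edge lengths; polytomies are
#' preserved.
#'
#' @param path Newick file path.
#' @return an [ape::phylo] object.
#' @export
readPhylogeny <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse Newick file", call. = FALSE)
  validatePhylogeny(tree)
}

#' @rdname readPhylogeny
#' @param tree a `phylo` object to validate in place.
#' @export
validatePhylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object", call. = FALSE)
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "), call. = FALSE)
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths", call. = FALSE)
  if (any(is.na(tree$edge.length)))
    stop("missing branch length", call. = FALSE)
  if (any(tree$edge.length < 0))
    stop("negative branch length", call. = FALSE)
  tree
}

#' Construct / read / write a covariate table
#'
#' Per-sample covariates for the correlation screen and GDM: either
#' element concentrations (ng/m3) or apportioned source contributions
#' (ug/m3). CSV layout: `sample_id` column plus one column per covariate.
#'
#' @param values samples x covariates matrix (sample ids as rownames).
#' @export
CovariateTable <- function(values) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  new("CovariateTable", values = values)
}

#' @rdname CovariateTable
#' @param path CSV file path.
#' @export
readCovariates <- function(path) {
  raw <- read.csv(path, check.names = FALSE, colClasses = "character",
                  strip.white = TRUE)
  if (!"sample_id" %in% names(raw))
    stop("covariate CSV must have a 'sample_id' column", call. = FALSE)
  rows <- seq_len(nrow(raw)) + 1L
  cov <- setdiff(names(raw), "sample_id")
  values <- sapply(cov, function(cl) .numeric_or_stop(raw[[cl]], cl, rows))
  values <- matrix(values, nrow = nrow(raw),
                   dimnames = list(raw$sample_id, cov))
  CovariateTable(values)
}

#' @rdname CovariateTable
#' @param covariates a [CovariateTable-class] to serialize.
#' @export
writeCovariates <- function(covariates, path) {
  df <- data.frame(sample_id = rownames(covariates@values),
                   covariates@values, check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
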