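#' Packaged nine-day Houston dust-episode sampling summary
#'
#' Loads the packaged campaign summary for the August 2018 Saharan dust
#' episode in Houston, Texas: nine daily PM10 samples (S1-S9) with
#' gravimetric PM10/PM2.5 masses (ug/m3), the PM10/PM2.5 mass ratio, the
#' CMB-apportioned Saharan dust contribution (ug/m3) with its published
#' low/medium/peak categorization, and the La/Ce and La/V elemental mass
#' ratios.
#'
#' A companion fixture, `elements_houston_synthetic.csv`, carries synthetic
#' La/Ce/V/Ni concentrations constructed to be consistent with these
#' ratios (the full per-element campaign data are not redistributed);
#' load it with [readElementPanel()] via [dustbiomeExtdata()].
#'
#' @return a data.frame with one row per sample and columns `sample_id`,
#'   `start_date`, `end_date`, `pm10`, `pm25`, `pm_ratio`, `saharan_dust`,
#'   `dust_label`, `la_ce`, `la_v`.
#' @examples
#' t1 <- houstonCampaign()
#' mean(t1$la_ce)   # campaign-mean La/Ce
#' @export
houstonCampaign <- function() {
  path <- dustbiomeExtdata("houston_campaign.csv")
  df <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(nrow(df) == 9)
  df
}

#' Path to a packaged example data file
#'
#' @param file file name under the package's `extdata` directory; with no
#'   argument, lists the available files.
#' @export
dustbiomeExtdata <- function(file = NULL) {
  dir <- system.file("extdata", package = "dustbiome")
  if (is.null(file)) return(list.files(dir))
  path <- file.path(dir, file)
  if (!file.exists(path)) stop("no packaged file '", file, "'", call. = FALSE)
  path
}
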