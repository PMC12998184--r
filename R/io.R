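#' Read and write assay time series as CSV
#'
#' The on-disk schema is `time_h,od600,conc_uM,ph` plus an optional
#' `censored` column; assay metadata (analyte, mode, species) travel as
#' arguments because CSV carries no attributes.
#'
#' @param series An [assay_series()].
#' @param path File path.
#' @return `write_assay_csv()` returns `path` invisibly;
#'   `read_assay_csv()` returns an [assay_series()].
#' @export
write_assay_csv <- function(series, path) {
  stopifnot(inherits(series, "assay_series"))
  write.csv(as.data.frame(series), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_assay_csv
#' @param analyte,mode,species Metadata to attach on read.
#' @export
read_assay_csv <- function(path, analyte = "nitrite", mode = "growing",
                           species = NA_character_) {
  d <- read.csv(path)
  need <- c("time_h", "od600", "conc_uM")
  if (!all(need %in% names(d))) {
    stop("assay CSV must have columns ", paste(need, collapse = ", "))
  }
  assay_series(d$time_h, d$od600, d$conc_uM,
               ph = if ("ph" %in% names(d)) d$ph else 7,
               censored = if ("censored" %in% names(d)) d$censored else FALSE,
               analyte = analyte, mode = mode, species = species)
}

#' Read a calibration-standards table (`conc_uM,absorbance`)
#'
#' @param path File path.
#' @return `data.frame` suitable for [fit_calibration()].
#' @export
read_standards_csv <- function(path) {
  d <- read.csv(path)
  if (!all(c("conc_uM", "absorbance") %in% names(d))) {
    stop("standards CSV must have columns conc_uM, absorbance")
  }
  d
}

#' Read a taxon-profile table (TSV: species, abundance, specific_activity)
#'
#' @param path File path.
#' @return List of [taxon_profile()] objects.
#' @export
read_taxon_profiles_tsv <- function(path) {
  d <- read.csv(path, sep = "\t")
  need <- c("species", "abundance", "specific_activity")
  if (!all(need %in% names(d))) {
    stop("profiles TSV must have columns ", paste(need, collapse = ", "))
  }
  lapply(seq_len(nrow(d)), function(i)
    taxon_profile(d$species[i], d$abundance[i], d$specific_activity[i]))
}

#' Write a per-species activity summary as TSV
#'
#' Columns mirror the standard reporting layout: species, activity, sd and
#' the below-threshold flag.
#'
#' @param summary `data.frame` with columns `species`, `activity`, `sd`,
#'   `below_threshold`.
#' @param path File path.
#' @export
write_activity_tsv <- function(summary, path) {
  stopifnot(all(c("species", "activity") %in% names(summary)))
  utils::write.table(summary, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
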