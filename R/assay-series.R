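#' Incubation-assay time series
#'
#' The central data container: one incubation experiment sampled over time,
#' holding optical density, analyte concentration and pH, plus assay
#' metadata. Implemented as a `data.frame` subclass with columns
#' `time_h`, `od600`, `conc_uM`, `ph` and an optional logical `censored`
#' column marking readings below the detection limit.
#'
#' @param time_h Sampling times in h, strictly increasing.
#' @param od600 OD600 readings.
#' @param conc_uM Analyte concentration in uM (`NA` allowed for censored
#'   readings).
#' @param ph pH readings (recycled if scalar).
#' @param censored Logical vector marking below-detection-limit readings.
#' @param analyte `"nitrite"` or `"nitrate"`.
#' @param mode `"growing"` or `"resting"`.
#' @param species Optional species label.
#' @return An object of classes `assay_series` and `data.frame`.
#' @examples
#' assay_series(0:5, od600 = rep(8, 6), conc_uM = 100 - 20 * (0:5),
#'              ph = 7, mode = "resting")
#' @export
assay_series <- function(time_h, od600, conc_uM, ph = 7,
                         censored = FALSE,
                         analyte = c("nitrite", "nitrate"),
                         mode = c("growing", "resting"),
                         species = NA_character_) {
  analyte <- match.arg(analyte)
  mode <- match.arg(mode)
  n <- length(time_h)
  if (n == 0L) stop("time_h must be non-empty")
  if (any(!is.finite(time_h))) stop("time_h must be finite")
  if (n > 1L && any(diff(time_h) <= 0)) stop("time_h must be strictly increasing")
  ph <- rep_len(ph, n)
  censored <- rep_len(as.logical(censored), n)
  if (length(od600) == 1L) od600 <- rep_len(od600, n)
  if (length(od600) != n || length(conc_uM) != n) {
    stop("od600 and conc_uM must have one value per timepoint")
  }
  out <- data.frame(time_h = time_h, od600 = od600, conc_uM = conc_uM,
                    ph = ph, censored = censored)
  structure(out,
            analyte = analyte, mode = mode, species = species,
            class = c("assay_series", "data.frame"))
}

#' @export
print.assay_series <- function(x, ...) {
  cat(sprintf("<assay_series> %s, %s cells%s: %d timepoints over %g h\n",
              attr(x, "analyte"), attr(x, "mode"),
              if (is.na(attr(x, "species"))) "" else
                paste0(" (", attr(x, "species"), ")"),
              nrow(x), max(x$time_h) - min(x$time_h)))
  print.data.frame(utils::head(as.data.frame(x), 8), ...)
  if (nrow(x) > 8) cat("... ", nrow(x) - 8, " more rows\n", sep = "")
  invisible(x)
}

#' Mark readings below the detection limit as censored
#'
#' Concentrations below `lod` (or negative) are flagged and their values set
#' to `NA`: censored readings carry an explicit state rather than a zero, so
#' downstream fits can exclude them.
#'
#' @param series An [assay_series()].
#' @param lod Detection limit in uM (default 10).
#' @return The series with updated `conc_uM` and `censored` columns.
#' @export
apply_detection_limit <- function(series, lod = 10) {
  stopifnot(inherits(series, "assay_series"), lod >= 0)
  cens <- series$censored | (!is.na(series$conc_uM) & series$conc_uM < lod)
  series$censored <- cens
  series$conc_uM[cens] <- NA_real_
  series
}
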