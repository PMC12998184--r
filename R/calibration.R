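#' Construct a colorimetric calibration curve
#'
#' Linear absorbance-to-concentration map for the azo-dye nitrite assay
#' (absorbance read at 540 nm), with a detection limit below which
#' back-calculated concentrations are censored.
#'
#' @param slope Absorbance per uM (> 0).
#' @param intercept Blank absorbance.
#' @param r2 Coefficient of determination of the calibration fit.
#' @param lod Detection limit in uM (default 10).
#' @return An object of class `calibration_curve`.
#' @export
calibration_curve <- function(slope, intercept, r2 = NA_real_, lod = 10) {
  stopifnot(is.numeric(slope), is.finite(slope),
            is.numeric(intercept), is.finite(intercept), lod >= 0)
  if (slope <= 0) stop("calibration slope must be positive")
  if (!is.na(r2) && (r2 < 0 || r2 > 1)) stop("r2 must lie in [0, 1]")
  structure(list(slope = slope, intercept = intercept, r2 = r2, lod = lod),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> A = %.5g * C + %.5g (r2 = %.4f, LOD %g uM)\n",
              x$slope, x$intercept, x$r2, x$lod))
  invisible(x)
}

#' Fit a calibration curve to a standards table
#'
#' Ordinary (unweighted) least squares of absorbance against standard
#' concentration. Requires at least three distinct standard levels; a blank
#' (0 uM) is expected in a well-run series and its absence triggers a
#' warning.
#'
#' @param standards `data.frame` with columns `conc_uM` and `absorbance`.
#' @param lod Detection limit attached to the returned curve, uM.
#' @return A [calibration_curve()].
#' @examples
#' std <- simulate_calibration_standards(seq(0, 100, 25), 0.005, 0.02)
#' fit_calibration(std)
#' @export
fit_calibration <- function(standards, lod = 10) {
  stopifnot(is.data.frame(standards),
            all(c("conc_uM", "absorbance") %in% names(standards)))
  std <- standards[is.finite(standards$conc_uM) & is.finite(standards$absorbance), ]
  if (length(unique(std$conc_uM)) < 3L) {
    stop("need at least 3 distinct standard levels")
  }
  if (!any(std$conc_uM == 0)) {
    warning("standards contain no blank (0 uM)")
  }
  if (sd(std$absorbance) == 0) {
    stop("degenerate standards: all absorbances identical")
  }
  fit <- lm(absorbance ~ conc_uM, data = std)
  slope <- unname(coef(fit)[2])
  if (slope <= 0) stop("fitted calibration slope is not positive")
  r2 <- 1 - sum(residuals(fit)^2) / sum((std$absorbance - mean(std$absorbance))^2)
  calibration_curve(slope, unname(coef(fit)[1]),
                    r2 = min(max(r2, 0), 1), lod = lod)
}

#' Convert absorbance readings to (possibly censored) concentrations
#'
#' Inverts the linear calibration, `C = (A - intercept) / slope`. Estimates
#' below the detection limit - including negative estimates - are returned
#' as censored (`NA` value with `censored = TRUE`) rather than as zero, so
#' downstream fits can exclude them explicitly.
#'
#' @param curve A [calibration_curve()].
#' @param a Absorbance reading(s); must be finite.
#' @return `data.frame` with columns `conc_uM` (NA when censored) and
#'   `censored`, plus the LOD as attribute `lod`.
#' @examples
#' cc <- calibration_curve(0.005, 0.02)
#' absorbance_to_concentration(cc, c(0.52, 0.02))
#' @export
absorbance_to_concentration <- function(curve, a) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (any(!is.finite(a))) stop("absorbance readings must be finite")
  conc <- (a - curve$intercept) / curve$slope
  cens <- conc < curve$lod
  conc[cens] <- NA_real_
  structure(data.frame(conc_uM = conc, censored = cens), lod = curve$lod)
}
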