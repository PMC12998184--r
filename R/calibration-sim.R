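#' Simulate a table of colorimetric calibration standards
#'
#' Generates absorbance readings for a dilution series of nitrite standards
#' (classically 0-100 uM) under a linear Beer-Lambert response
#' `A = slope * C + intercept` plus Gaussian read noise.
#'
#' @param levels Standard concentrations in uM (should include a blank).
#' @param slope Absorbance per uM (> 0).
#' @param intercept Blank absorbance.
#' @param noise A [noise_spec()]; `absorbance_sd` is the read noise.
#' @return `data.frame` with columns `conc_uM`, `absorbance`.
#' @examples
#' simulate_calibration_standards(seq(0, 100, 20), 0.005, 0.02,
#'                                noise_spec(absorbance_sd = 0.005, seed = 1))
#' @export
simulate_calibration_standards <- function(levels, slope = 0.005,
                                           intercept = 0.02,
                                           noise = noise_spec()) {
  stopifnot(is.numeric(levels), length(levels) >= 1L, all(is.finite(levels)),
            all(levels >= 0), inherits(noise, "noise_spec"))
  if (slope <= 0) stop("slope must be positive")
  a <- with_noise_seed(
    noise,
    slope * levels + intercept + rnorm(length(levels), sd = noise$absorbance_sd)
  )
  data.frame(conc_uM = levels, absorbance = a)
}

#' Counting-chamber geometry
#'
#' Geometry and counting protocol of a Thoma-type hemocytometer. The
#' defaults describe a chamber with 0.02 mm cell depth and 0.0025 mm^2
#' small-square area, of which four main squares are counted.
#'
#' @param depth_mm Chamber depth in mm.
#' @param square_area_mm2 Area of one counted square in mm^2.
#' @param squares_counted Number of main squares counted per sample.
#' @param dilution Dilution factor of the counted suspension.
#' @return An object of class `counting_chamber`.
#' @export
counting_chamber <- function(depth_mm = 0.02, square_area_mm2 = 0.0025,
                             squares_counted = 4, dilution = 1) {
  vals <- c(depth_mm, square_area_mm2, squares_counted, dilution)
  if (!all(is.finite(vals)) || any(vals <= 0)) {
    stop("all counting-chamber dimensions must be positive")
  }
  structure(list(depth_mm = depth_mm, square_area_mm2 = square_area_mm2,
                 squares_counted = squares_counted, dilution = dilution),
            class = "counting_chamber")
}

#' Simulate a counting-chamber / dry-weight calibration experiment
#'
#' Emulates the protocol used to link OD600 to cell numbers and dry weight:
#' cultures harvested at several OD levels (at least three, mirroring the
#' protocol) are counted in a hemocytometer and dried for weighing.
#' Expected counts and dry weights scale linearly with OD; `od_cv` noise is
#' applied multiplicatively to both observations.
#'
#' @param per_cell_dw True dry mass of one cell, g.
#' @param cells_per_l_od True cell density per OD unit, cells L^-1 OD^-1.
#' @param ods OD600 levels at which cultures are harvested (>= 3).
#' @param noise A [noise_spec()]; `od_cv` sets the relative noise.
#' @param chamber A [counting_chamber()].
#' @return List with `counts` (`data.frame`: `od`, `square_count`,
#'   `dilution`), `dry_weights` (`data.frame`: `od`, `dw_g_per_l`) and
#'   `truth` (the generating values).
#' @examples
#' sim <- simulate_counting_experiment(1.43e-13, 1.61e12, c(0.5, 1, 2))
#' @export
simulate_counting_experiment <- function(per_cell_dw, cells_per_l_od, ods,
                                         noise = noise_spec(),
                                         chamber = counting_chamber()) {
  stopifnot(per_cell_dw > 0, cells_per_l_od > 0,
            inherits(chamber, "counting_chamber"))
  if (length(ods) < 2L) stop("at least 2 OD levels required for regression")
  if (length(ods) < 3L) {
    warning("fewer than 3 OD levels: protocol calls for a minimum of three")
  }
  square_vol_ml <- chamber$square_area_mm2 * chamber$depth_mm * 1e-3  # mm^3 -> mL
  cells_per_ml <- ods * cells_per_l_od / 1000
  expected_count <- cells_per_ml * square_vol_ml / chamber$dilution
  expected_dw <- ods * cells_per_l_od * per_cell_dw

  obs <- with_noise_seed(noise, {
    list(count = expected_count * (1 + rnorm(length(ods), sd = noise$od_cv)),
         dw = expected_dw * (1 + rnorm(length(ods), sd = noise$od_cv)))
  })
  list(
    counts = data.frame(od = ods, square_count = pmax(obs$count, 0),
                        dilution = chamber$dilution),
    dry_weights = data.frame(od = ods, dw_g_per_l = pmax(obs$dw, 0)),
    truth = list(per_cell_dw = per_cell_dw, cells_per_l_od = cells_per_l_od,
                 chamber = chamber)
  )
}
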