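#' Cell concentration from counting-chamber counts
#'
#' Converts the mean cell count per small square of a Thoma-type chamber to
#' a suspension concentration. With the default geometry one square holds
#' `0.0025 mm^2 x 0.02 mm = 5e-8 mL`, so 20 cells per square in an undiluted
#' sample correspond to 4e8 cells mL^-1.
#'
#' @param mean_count_per_square Mean count per counted square (>= 0).
#' @param chamber A [counting_chamber()] (carries the dilution factor).
#' @return Cell concentration in cells mL^-1.
#' @examples
#' counts_to_concentration(20)  # 4e8
#' @export
counts_to_concentration <- function(mean_count_per_square,
                                    chamber = counting_chamber()) {
  stopifnot(inherits(chamber, "counting_chamber"),
            all(mean_count_per_square >= 0))
  square_vol_ml <- chamber$square_area_mm2 * chamber$depth_mm * 1e-3
  if (square_vol_ml <= 0) stop("chamber dimensions must be positive")
  mean_count_per_square * chamber$dilution / square_vol_ml
}

#' Per-cell dry mass by regression of dry weight on cell number
#'
#' Origin-constrained least-squares slope of dry weight against cell number
#' (zero cells imply zero mass, which fixes the intercept the protocol
#' leaves unstated).
#'
#' @param cell_numbers Cells per unit volume at each harvest (>= 2 distinct
#'   values).
#' @param dry_weights Matching dry weights, g per same volume.
#' @return Dry mass of one cell in g.
#' @examples
#' n <- c(0.5, 1, 2) * 1.61e12
#' per_cell_dw_from_regression(n, 1.43e-13 * n)  # 1.43e-13
#' @export
per_cell_dw_from_regression <- function(cell_numbers, dry_weights) {
  stopifnot(length(cell_numbers) == length(dry_weights),
            length(cell_numbers) >= 2L,
            all(is.finite(cell_numbers)), all(is.finite(dry_weights)))
  if (length(unique(cell_numbers)) < 2L) {
    stop("all cell numbers equal: regression impossible")
  }
  sum(cell_numbers * dry_weights) / sum(cell_numbers^2)
}

#' Average duplicate drying measurements
#'
#' Dry weights are read after 24 h and again after 48 h of drying; the two
#' readings are averaged per sample and flagged when they disagree by more
#' than `tol` (relative), indicating incomplete drying.
#'
#' @param dw_24h,dw_48h Paired dry-weight readings, g.
#' @param tol Relative discrepancy that triggers a flag (default 0.05).
#' @return `data.frame` with `dw_g` (mean) and `flagged`.
#' @export
average_drying_measurements <- function(dw_24h, dw_48h, tol = 0.05) {
  stopifnot(length(dw_24h) == length(dw_48h))
  m <- (dw_24h + dw_48h) / 2
  rel <- ifelse(m > 0, abs(dw_24h - dw_48h) / m, 0)
  data.frame(dw_g = m, flagged = rel > tol)
}

#' Per-species biomass calibration row
#'
#' Combines the two per-OD calibration factors of a species into its
#' per-cell dry mass: `per_cell_dw = dw_per_l_per_od / cells_per_l_per_od`.
#'
#' @param species Species label.
#' @param cells_per_l_per_od Cell density per OD unit, cells L^-1 OD^-1
#'   (> 0).
#' @param dw_per_l_per_od Dry weight per OD unit, g L^-1 OD^-1 (> 0, or NA
#'   when unmeasured).
#' @return An object of class `species_biomass` (also a one-row
#'   `data.frame`).
#' @examples
#' species_biomass_row("Bacteroides xylanisolvens", 2.23e12, 0.36)
#' @export
species_biomass_row <- function(species, cells_per_l_per_od, dw_per_l_per_od) {
  stopifnot(cells_per_l_per_od > 0)
  if (!is.na(dw_per_l_per_od) && dw_per_l_per_od <= 0) {
    stop("dw_per_l_per_od must be positive (or NA when unmeasured)")
  }
  out <- data.frame(
    species = species,
    cells_per_l_per_od = cells_per_l_per_od,
    dw_per_l_per_od = dw_per_l_per_od,
    per_cell_dw = dw_per_l_per_od / cells_per_l_per_od
  )
  class(out) <- c("species_biomass", "data.frame")
  out
}

#' Community-average per-cell dry mass
#'
#' Arithmetic mean and sample sd of the per-cell dry mass over all species
#' with both calibration columns measured; species lacking a dry-weight
#' determination are carried in tables but excluded here.
#'
#' @param rows `data.frame` with a `per_cell_dw` column (e.g. rbind-ed
#'   [species_biomass_row()]s or [gut_cell_mass_table()]).
#' @return List with `mean_per_cell_dw` (g), `sd` (g) and `n_species`.
#' @examples
#' community_average(gut_cell_mass_table())
#' @export
community_average <- function(rows) {
  stopifnot(is.data.frame(rows), "per_cell_dw" %in% names(rows))
  v <- rows$per_cell_dw[is.finite(rows$per_cell_dw)]
  if (length(v) < 2L) stop("need at least 2 species with per-cell dry mass")
  list(mean_per_cell_dw = mean(v), sd = sd(v), n_species = length(v))
}

#' Calibrate biomass factors from a counting experiment
#'
#' Convenience wrapper for the output of [simulate_counting_experiment()]
#' (or equivalently structured real data): converts square counts to cell
#' concentrations, regresses dry weight on cell number for the per-cell dry
#' mass, and regresses cells and dry weight on OD for the per-OD factors.
#'
#' @param counts `data.frame` with `od`, `square_count`, `dilution`.
#' @param dry_weights `data.frame` with `od`, `dw_g_per_l`.
#' @param chamber A [counting_chamber()] (geometry; per-row dilutions are
#'   taken from `counts`).
#' @return List with `per_cell_dw` (g), `cells_per_l_per_od`,
#'   `dw_per_l_per_od`.
#' @export
calibrate_biomass <- function(counts, dry_weights,
                              chamber = counting_chamber()) {
  stopifnot(all(c("od", "square_count", "dilution") %in% names(counts)),
            all(c("od", "dw_g_per_l") %in% names(dry_weights)),
            nrow(counts) == nrow(dry_weights),
            all(counts$od == dry_weights$od))
  cells_per_ml <- vapply(seq_len(nrow(counts)), function(i) {
    ch <- chamber
    ch$dilution <- counts$dilution[i]
    counts_to_concentration(counts$square_count[i], ch)
  }, numeric(1))
  cells_per_l <- cells_per_ml * 1000
  list(
    per_cell_dw = per_cell_dw_from_regression(cells_per_l,
                                              dry_weights$dw_g_per_l),
    cells_per_l_per_od = sum(counts$od * cells_per_l) / sum(counts$od^2),
    dw_per_l_per_od = sum(dry_weights$od * dry_weights$dw_g_per_l) /
      sum(dry_weights$od^2)
  )
}
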