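#' Stool physiology constants for whole-colon extrapolation
#'
#' The handful of literature constants that scale a measured specific
#' activity up to the whole large intestine: the bacterial count per g of
#' dry stool, the colonic stool volume, wet-stool density, water content,
#' and the average dry mass of one gut bacterium.
#'
#' @param cells_per_g_dry_stool Bacteria per g dry stool (default 3.23e11).
#' @param wet_volume_ml Colonic stool content in mL (default 400).
#' @param density_g_per_ml Wet-stool density (default 1.04).
#' @param water_fraction Water content of wet stool (default 0.75).
#' @param per_cell_dw Average dry mass of one gut bacterium in g
#'   (default 2.52e-13, the community average).
#' @return An object of class `stool_physiology`.
#' @export
stool_physiology <- function(cells_per_g_dry_stool = 3.23e11,
                             wet_volume_ml = 400,
                             density_g_per_ml = 1.04,
                             water_fraction = 0.75,
                             per_cell_dw = 2.52e-13) {
  stopifnot(cells_per_g_dry_stool > 0, wet_volume_ml > 0,
            density_g_per_ml > 0, per_cell_dw > 0,
            water_fraction > 0, water_fraction < 1)
  structure(
    list(cells_per_g_dry_stool = cells_per_g_dry_stool,
         wet_volume_ml = wet_volume_ml,
         density_g_per_ml = density_g_per_ml,
         water_fraction = water_fraction,
         per_cell_dw = per_cell_dw),
    class = "stool_physiology"
  )
}

#' Taxon profile: abundance and specific activity
#'
#' @param species Species label.
#' @param abundance Fraction of all cells (0..1), e.g. 0.008 for a taxon at
#'   0.8% abundance.
#' @param specific_activity Specific nitrite (or nitrate) degradation
#'   activity, umol g_DW^-1 h^-1 (>= 0).
#' @return An object of class `taxon_profile`.
#' @export
taxon_profile <- function(species, abundance, specific_activity) {
  stopifnot(abundance >= 0, abundance <= 1, specific_activity >= 0)
  structure(list(species = species, abundance = abundance,
                 specific_activity = specific_activity),
            class = "taxon_profile")
}

#' Dry mass of the colonic stool content
#'
#' `wet_volume * density * (1 - water_fraction)`; with the defaults, 400 mL
#' of wet stool at 1.04 g/mL and 75% water give 104 g dry weight.
#'
#' @param phys A [stool_physiology()].
#' @return Dry mass in g.
#' @examples
#' colon_dry_mass()  # 104
#' @export
colon_dry_mass <- function(phys = stool_physiology()) {
  phys$wet_volume_ml * phys$density_g_per_ml * (1 - phys$water_fraction)
}

#' Taxon cell count per g of dry stool
#'
#' @param profile A [taxon_profile()].
#' @param phys A [stool_physiology()].
#' @return Cells per g dry stool.
#' @export
taxon_cells_per_gds <- function(profile, phys = stool_physiology()) {
  profile$abundance * phys$cells_per_g_dry_stool
}

#' Taxon biomass per g of dry stool
#'
#' @param cells_per_gds Cells per g dry stool.
#' @param phys A [stool_physiology()] (supplies the per-cell dry mass).
#' @return g dry-weight biomass per g dry stool.
#' @export
biomass_per_gds <- function(cells_per_gds, phys = stool_physiology()) {
  cells_per_gds * phys$per_cell_dw
}

#' Whole-colon activity chain for one taxon (or the whole community)
#'
#' Runs the full extrapolation: cells per g dry stool, biomass per g dry
#' stool, dry-stool activity (umol per g dry stool per h), colon dry mass,
#' and total colonic activity (umol h^-1). All intermediates are exposed.
#'
#' @param profile A [taxon_profile()]; `abundance = 1` with the measured
#'   fecal specific activity gives the whole-community chain.
#' @param phys A [stool_physiology()].
#' @return An object of class `colon_activity` (a list of the chain
#'   quantities).
#' @examples
#' ec <- taxon_profile("Escherichia coli", 0.008, 10966)
#' activity_chain(ec)
#' @export
activity_chain <- function(profile, phys = stool_physiology()) {
  stopifnot(inherits(profile, "taxon_profile"),
            inherits(phys, "stool_physiology"))
  cells <- taxon_cells_per_gds(profile, phys)
  biomass <- biomass_per_gds(cells, phys)
  dsa <- profile$specific_activity * biomass
  cdm <- colon_dry_mass(phys)
  structure(
    list(species = profile$species,
         cells_per_gds = cells,
         biomass_g_per_gds = biomass,
         dry_stool_activity = dsa,
         colon_wet_mass_g = phys$wet_volume_ml * phys$density_g_per_ml,
         colon_dry_mass_g = cdm,
         total_activity = dsa * cdm),
    class = "colon_activity"
  )
}

#' @export
print.colon_activity <- function(x, ...) {
  cat(sprintf("<colon_activity> %s\n", x$species))
  cat(sprintf("  cells / g dry stool      : %.3g\n", x$cells_per_gds))
  cat(sprintf("  biomass (gDW/g dry stool): %.3g\n", x$biomass_g_per_gds))
  cat(sprintf("  dry-stool activity       : %.3g umol/g/h\n",
              x$dry_stool_activity))
  cat(sprintf("  colon dry mass           : %.3g g\n", x$colon_dry_mass_g))
  cat(sprintf("  total colonic activity   : %.3g umol/h\n", x$total_activity))
  invisible(x)
}

#' Nitrite amount in a stool bolus
#'
#' @param conc_uM Bolus nitrite concentration, uM.
#' @param volume_ml Bolus volume, mL.
#' @return Amount in umol (`uM * mL / 1e6 * 1e3`... i.e. umol/L * L).
#' @examples
#' bolus_amount(50, 400)  # 20 umol
#' @export
bolus_amount <- function(conc_uM = 50, volume_ml = 400) {
  stopifnot(conc_uM >= 0, volume_ml > 0)
  conc_uM * volume_ml / 1000
}

#' Time to detoxify a nitrite bolus
#'
#' `amount / total_activity`, converted to minutes; assumes zero-order
#' consumption at the measured rate (a capacity argument, not a dynamic
#' model). Zero activity yields `Inf`.
#'
#' @param amount_umol Nitrite amount, umol.
#' @param total_activity_umol_h Total colonic activity, umol h^-1.
#' @return Time in minutes.
#' @examples
#' detox_time(20, 742)  # ~1.6 min
#' @export
detox_time <- function(amount_umol, total_activity_umol_h) {
  stopifnot(amount_umol >= 0, total_activity_umol_h >= 0)
  if (total_activity_umol_h == 0) return(Inf)
  amount_umol / total_activity_umol_h * 60
}

#' Back-estimate a taxon's abundance from community activity
#'
#' If one reference taxon dominates the community activity, its abundance
#' is approximately the ratio of the community-average specific activity to
#' the taxon's own specific activity.
#'
#' @param community_specific_activity Measured community specific activity,
#'   umol g_DW^-1 h^-1.
#' @param reference A [taxon_profile()] with `specific_activity > 0`.
#' @return Estimated abundance as a percentage.
#' @examples
#' back_estimate_abundance(74.4, taxon_profile("E. coli", 0.008, 10966))
#' @export
back_estimate_abundance <- function(community_specific_activity, reference) {
  stopifnot(community_specific_activity >= 0,
            inherits(reference, "taxon_profile"))
  if (reference$specific_activity <= 0) stop("reference activity must be > 0")
  100 * community_specific_activity / reference$specific_activity
}

#' Abundance-weighted community activity of a strain mixture
#'
#' Predicted specific activity of a defined mixture of strains combined
#' according to their intestinal abundance: the abundance-weighted mean of
#' the member activities, with weights renormalized over the included taxa
#' (a synthetic mix contains only the selected strains).
#'
#' @param profiles List of [taxon_profile()]s, or a `data.frame` with
#'   `abundance` and `specific_activity` columns.
#' @return Specific activity in umol g_DW^-1 h^-1.
#' @examples
#' mixture_activity(list(taxon_profile("a", 0.1, 0),
#'                       taxon_profile("b", 0.1, 100)))  # 50
#' @export
mixture_activity <- function(profiles) {
  if (is.data.frame(profiles)) {
    if (!all(c("abundance", "specific_activity") %in% names(profiles))) {
      stop("profile table needs columns abundance and specific_activity")
    }
    ab <- profiles$abundance
    act <- profiles$specific_activity
  } else {
    stopifnot(length(profiles) >= 1L)
    ab <- vapply(profiles, `[[`, numeric(1), "abundance")
    act <- vapply(profiles, `[[`, numeric(1), "specific_activity")
  }
  stopifnot(all(ab >= 0), all(act >= 0))
  if (sum(ab) == 0) stop("all abundances are zero")
  sum(ab * act) / sum(ab)
}
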