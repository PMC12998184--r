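#' Reference biomass calibration of gut bacteria
#'
#' Bundled per-species calibration measurements linking OD600 to cell
#' numbers and dry weight for common gut bacteria: cell density per OD unit
#' (cells L^-1 OD^-1), dry weight per OD unit (g L^-1 OD^-1), and the
#' per-cell dry mass printed alongside them. One species (*Anaerostipes
#' hadrus*) lacks a dry-weight determination and is excluded from averages.
#' The community average per-cell dry mass over these measurements is
#' 2.52e-13 g.
#'
#' @return `data.frame` with columns `species`, `cells_per_l_per_od`,
#'   `dw_per_l_per_od`, `per_cell_dw`.
#' @seealso [community_average()], [species_biomass_row()]
#' @export
gut_cell_mass_table <- function() {
  data.frame(
    species = c(
      "Agathobacter rectalis", "Akkermansia muciniphila",
      "Anaerostipes hadrus", "Bacteroides cellulosilyticus",
      "Bacteroides xylanisolvens", "Bifidobacterium adolescentis",
      "Blautia faecis", "Escherichia coli", "Faecalibacterium prausnitzii",
      "Mediterraneibacter gnavus", "Parabacteroides johnsonii",
      "Phocaeicola dorei", "Phocaeicola vulgatus", "Segatella copri"
    ),
    cells_per_l_per_od = c(
      1.85e12, 2.55e12, 6.95e11, 1.14e12, 2.23e12, 1.41e12, 1.69e12,
      8.00e11, 1.17e12, 9.78e11, 1.52e12, 1.61e12, 1.03e12, 1.44e12
    ),
    dw_per_l_per_od = c(
      0.41, 0.41, NA, 0.31, 0.36, 0.42, 0.45, 0.22, 0.41, 0.25, 0.40,
      0.23, 0.36, 0.40
    ),
    per_cell_dw = c(
      2.19e-13, 1.62e-13, NA, 2.72e-13, 1.61e-13, 2.98e-13, 2.63e-13,
      2.80e-13, 3.51e-13, 2.56e-13, 2.63e-13, 1.43e-13, 3.50e-13, 2.78e-13
    )
  )
}

#' Reference nitrite degradation activities of colon bacteria
#'
#' Bundled measured specific nitrite-degradation activities
#' (umol g_DW^-1 h^-1, mean and sd over replicate assays) of highly
#' abundant large-intestine species, together with their prevalence and
#' mean relative abundance (%) in the colon. Activities below the
#' reporting threshold carry `below_threshold = TRUE` with the threshold in
#' `activity` treated as an upper bound.
#'
#' @return `data.frame` with columns `species`, `activity`, `sd`,
#'   `below_threshold`, `prevalence_pct`, `abundance_pct`.
#' @export
colon_nitrite_activities <- function() {
  data.frame(
    species = c(
      "Agathobacter rectalis", "Akkermansia muciniphila",
      "Bacteroides cellulosilyticus", "Bacteroides xylanisolvens",
      "Bifidobacterium longum", "Escherichia coli K-12",
      "Faecalibacterium prausnitzii", "Hominimerdicola aceti",
      "Phocaeicola dorei", "Phocaeicola vulgatus", "Roseburia intestinalis"
    ),
    activity = c(1, 1, 26.9, 110.4, 2.2, 10770, 2, 1, 10.6, 55.3, 29.3),
    sd = c(NA, NA, 12.2, 27.5, 0.2, 2183, NA, NA, 6.2, 32.2, 10.9),
    below_threshold = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE,
                        FALSE, FALSE, FALSE),
    prevalence_pct = c(88.0, 44.5, 51.3, 73.3, 74.7, 64.2, 86.8, 65.0,
                       69.1, 90.3, 67.1),
    abundance_pct = c(6.2, 0.7, 3.4, 4.9, 0.7, 0.8, 3.5, 2.5, 17.4, 15.0,
                      1.1)
  )
}

#' Reference nitrite activities of small-intestine bacteria
#'
#' Measured specific nitrite-degradation activities of lactic acid bacteria
#' and species of the genera *Streptococcus* and *Veillonella*
#' (umol g_DW^-1 h^-1).
#'
#' @return `data.frame` with columns `species`, `activity`, `sd`,
#'   `below_threshold`.
#' @export
small_intestine_nitrite_activities <- function() {
  data.frame(
    species = c(
      "Lacticaseibacillus casei", "Limosilactobacillus balticus",
      "Limosilactobacillus fermentum", "Limosilactobacillus reuteri",
      "Streptococcus hyointestinalis", "Streptococcus thermophilus",
      "Streptococcus vestibularis", "Veillonella atypica",
      "Veillonella magna", "Veillonella ratti"
    ),
    activity = c(2, 890, 3529, 1070, 2, 2, 420, 327, 771, 922),
    sd = c(NA, 167, 255, 471, NA, NA, 122, 28, 232, 53),
    below_threshold = c(TRUE, FALSE, FALSE, FALSE, TRUE, TRUE, FALSE,
                        FALSE, FALSE, FALSE)
  )
}

#' Reference nitrate degradation activities
#'
#' Measured specific nitrate-reduction activities (umol g_DW^-1 h^-1) of
#' intestinal bacteria; most species show none.
#'
#' @return `data.frame` with columns `species`, `intestine`, `activity`,
#'   `sd`.
#' @export
nitrate_activities <- function() {
  data.frame(
    species = c(
      "Agathobacter rectalis", "Akkermansia muciniphila",
      "Bacteroides cellulosilyticus", "Bacteroides xylanisolvens",
      "Bifidobacterium longum", "Escherichia coli K-12",
      "Faecalibacterium prausnitzii", "Phocaeicola dorei",
      "Phocaeicola vulgatus", "Roseburia intestinalis",
      "Limosilactobacillus reuteri", "Streptococcus vestibularis",
      "Veillonella atypica"
    ),
    intestine = c(rep("large", 10), rep("small", 3)),
    activity = c(0, 0, 0, 0, 0, 487, 0, 0, 0, 0, 0, 0, 208),
    sd = c(NA, NA, NA, NA, NA, 177, NA, NA, NA, NA, NA, NA, 52)
  )
}
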