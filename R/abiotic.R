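#' Abiotic nitrite-loss model
#'
#' Nitrite is lost from incubation media by two purely chemical routes that
#' must be separated from enzymatic degradation: (i) an effectively
#' instantaneous scavenging by the reducing agent L-cysteine at the start of
#' the assay, and (ii) a slow first-order decay whose rate depends on pH
#' (protonation to HNO2/NO+ below pH 5.8, plus a small background loss of
#' about 10% over 24 h at higher pH).
#'
#' The default scavenging magnitude (100/3 uM per mM cysteine) is anchored to
#' the standard assay condition in which 1.5 mM cysteine drops a nominal
#' 150 uM nitrite spike to an effective 100 uM within seconds.
#'
#' @param cysteine_mM Cysteine concentration in the medium, mM.
#' @param cysteine_loss_per_mM Instantaneous nitrite loss per mM cysteine,
#'   uM mM^-1.
#' @param ph_decay_table `data.frame` with columns `ph` and `rate_per_h`
#'   giving the first-order abiotic decay rate at each pH; rates between
#'   tabulated pH values are linearly interpolated. The default table covers
#'   only the plateau at pH >= 5.8; rates for acidic media must be supplied
#'   by the user.
#' @return An object of class `abiotic_params`.
#' @examples
#' abiotic_params()  # standard assay: 1.5 mM cysteine, neutral-pH background
#' @export
abiotic_params <- function(cysteine_mM = 1.5,
                           cysteine_loss_per_mM = 100 / 3,
                           ph_decay_table = default_ph_decay_table()) {
  stopifnot(
    is.numeric(cysteine_mM), cysteine_mM >= 0,
    is.numeric(cysteine_loss_per_mM), cysteine_loss_per_mM >= 0,
    is.data.frame(ph_decay_table),
    all(c("ph", "rate_per_h") %in% names(ph_decay_table)),
    nrow(ph_decay_table) >= 1,
    all(is.finite(ph_decay_table$ph)),
    all(is.finite(ph_decay_table$rate_per_h)),
    all(ph_decay_table$rate_per_h >= 0)
  )
  ph_decay_table <- ph_decay_table[order(ph_decay_table$ph), , drop = FALSE]
  structure(
    list(cysteine_mM = cysteine_mM,
         cysteine_loss_per_mM = cysteine_loss_per_mM,
         ph_decay_table = ph_decay_table),
    class = "abiotic_params"
  )
}

#' Default pH-dependent abiotic decay table
#'
#' Above pH 5.8 chemical nitrite loss plateaus at a background of roughly
#' 10% over 24 h; under first-order kinetics that is a rate of
#' `-log(0.9)/24` ~ 0.0044 h^-1. Decay accelerates sharply in acidic media,
#' but those rates are medium-specific and must be supplied by the user.
#'
#' @param background_loss_24h Fractional loss over 24 h on the plateau
#'   (default 0.10).
#' @return `data.frame` with columns `ph`, `rate_per_h`.
#' @export
default_ph_decay_table <- function(background_loss_24h = 0.10) {
  rate <- -log(1 - background_loss_24h) / 24
  data.frame(ph = c(5.8, 9.0), rate_per_h = c(rate, rate))
}

#' @export
print.abiotic_params <- function(x, ...) {
  cat(sprintf(
    "<abiotic_params> cysteine %g mM x %.3g uM/mM; pH table %g..%g\n",
    x$cysteine_mM, x$cysteine_loss_per_mM,
    min(x$ph_decay_table$ph), max(x$ph_decay_table$ph)
  ))
  invisible(x)
}

#' Effective initial nitrite after cysteine scavenging
#'
#' The reducing agent cysteine consumes part of a nitrite spike within
#' seconds of addition, so the concentration the cells actually see is lower
#' than the nominal spike. Under the default model a nominal 150 uM spike in
#' 1.5 mM cysteine medium yields an effective 100 uM.
#'
#' @param nominal Nominal spiked concentration, uM (>= 0).
#' @param cysteine_mM Cysteine concentration, mM; defaults to the value in
#'   `corr`.
#' @param corr An [abiotic_params()] object.
#' @return Effective initial concentration in uM, floored at 0.
#' @examples
#' effective_initial_nitrite(150, 1.5)  # 100
#' @export
effective_initial_nitrite <- function(nominal, cysteine_mM = corr$cysteine_mM,
                                      corr = abiotic_params()) {
  stopifnot(is.numeric(nominal), all(nominal >= 0), cysteine_mM >= 0)
  pmax(nominal - corr$cysteine_loss_per_mM * cysteine_mM, 0)
}

#' First-order abiotic nitrite decay rate at a given pH
#'
#' Linearly interpolates the decay-rate table of an abiotic-loss model. At
#' or above the highest/lowest tabulated pH within the table's span, the
#' nearest tabulated rate is used, so all pH values on the >= 5.8 plateau
#' share the same background rate.
#'
#' @param ph pH value(s), must lie within `[3, 9]` and within the span
#'   covered by the table (acidic pH requires user-supplied rates).
#' @param corr An [abiotic_params()] object.
#' @return Decay rate(s) in h^-1.
#' @examples
#' abiotic_decay_rate(7)  # background: -log(0.9)/24
#' @export
abiotic_decay_rate <- function(ph, corr = abiotic_params()) {
  if (any(!is.finite(ph))) stop("pH must be finite")
  if (any(ph < 3 | ph > 9)) stop("pH outside [3, 9]")
  tab <- corr$ph_decay_table
  below <- ph < min(tab$ph) - 1e-9
  if (any(below)) {
    stop(sprintf(
      "pH %.2f below the decay table range (%.2f); supply acidic rates in ph_decay_table",
      min(ph[below]), min(tab$ph)
    ))
  }
  if (nrow(tab) == 1L) return(rep(tab$rate_per_h, length(ph)))
  approx(tab$ph, tab$rate_per_h, xout = ph, rule = 2)$y
}

#' Remove the abiotic first-order component from a measured series
#'
#' Inverts the pH-dependent chemical decay so that downstream rate
#' calculations reflect enzymatic activity only: each concentration is
#' multiplied by `exp(K(t))` where `K(t)` is the cumulative (trapezoidal)
#' integral of the abiotic decay rate along the recorded pH trace. A series
#' generated by pure abiotic decay is restored to a constant; when all rates
#' are zero the series is returned unchanged.
#'
#' @param series An [assay_series()] with pH recorded at every timepoint.
#' @param corr An [abiotic_params()] object.
#' @return The corrected series (censored readings stay censored).
#' @export
subtract_abiotic <- function(series, corr = abiotic_params()) {
  stopifnot(inherits(series, "assay_series"))
  if (any(is.na(series$ph))) stop("pH must be recorded at every timepoint")
  k <- abiotic_decay_rate(series$ph, corr)
  t <- series$time_h
  n <- length(t)
  # cumulative trapezoidal integral of k over time
  K <- c(0, cumsum(diff(t) * (utils::head(k, -1) + utils::tail(k, -1)) / 2))
  series$conc_uM <- series$conc_uM * exp(K)
  series
}
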