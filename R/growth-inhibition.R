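#' Extract growth parameters from an OD600 curve
#'
#' Estimates the three parameters used to phenotype growth under nitrite
#' stress. The maximum specific growth rate is the steepest slope of
#' log(OD) over a sliding window (default 5 points), the doubling time is
#' `log(2)` over that rate, the lag is found by the tangent-intercept
#' method (intersection of the steepest log-linear fit with the initial
#' log-OD), and the maximum OD is the peak of a running-median-smoothed
#' curve. Curves whose smoothed maximum stays within `no_growth_delta` of
#' the initial OD are flagged `no_growth`.
#'
#' @param curve `data.frame` with columns `time_h` and `od600`
#'   (>= 8 timepoints, background OD already subtracted so all ODs are
#'   positive).
#' @param window Sliding-window length in points for the log-linear fit.
#' @param no_growth_delta Minimum OD rise to count as growth (default
#'   0.05).
#' @return An object of class `growth_parameters`: list with `lag_h`,
#'   `doubling_time_h`, `mu_max`, `od_max`, `od_initial`, `r2` (of the
#'   steepest window) and `no_growth`.
#' @examples
#' t <- seq(0, 24, 0.25)
#' od <- simulate_growth(growth_params(0.05, 0.6, log(2) / 1.1, lag = 5), t)
#' fit_growth_parameters(data.frame(time_h = t, od600 = od))
#' @export
fit_growth_parameters <- function(curve, window = 5, no_growth_delta = 0.05) {
  stopifnot(is.data.frame(curve),
            all(c("time_h", "od600") %in% names(curve)),
            window >= 3)
  t <- curve$time_h
  od <- curve$od600
  if (length(t) < 8L) stop("need at least 8 timepoints")
  if (any(od <= 0)) stop("non-positive OD after background subtraction")

  sm <- runmed(od, k = min(5L, length(od) - (1 - length(od) %% 2)))
  od_initial <- median(sm[seq_len(min(3L, length(sm)))])
  od_max <- max(sm)

  res <- list(lag_h = NA_real_, doubling_time_h = NA_real_,
              mu_max = NA_real_, od_max = od_max, od_initial = od_initial,
              r2 = NA_real_, no_growth = FALSE)
  if (od_max < od_initial + no_growth_delta) {
    res$no_growth <- TRUE
    return(structure(res, class = "growth_parameters"))
  }

  y <- log(od)
  w <- as.integer(window)
  Ty <- embed(y, w)
  Tt <- embed(t, w)
  dT <- Tt - rowMeans(Tt)
  dY <- Ty - rowMeans(Ty)
  sxx <- rowSums(dT^2)
  syy <- rowSums(dY^2)
  slope <- rowSums(dT * dY) / sxx
  i <- which.max(slope)
  mu <- slope[i]
  if (!is.finite(mu) || mu <= 0) {
    res$no_growth <- TRUE
    return(structure(res, class = "growth_parameters"))
  }
  intercept <- mean(Ty[i, ]) - mu * mean(Tt[i, ])
  res$mu_max <- mu
  res$doubling_time_h <- log(2) / mu
  res$lag_h <- max((log(od_initial) - intercept) / mu, 0)
  res$r2 <- if (syy[i] > 0) (rowSums(dT * dY)[i])^2 / (sxx[i] * syy[i]) else 0
  structure(res, class = "growth_parameters")
}

#' @export
print.growth_parameters <- function(x, ...) {
  if (x$no_growth) {
    cat("<growth_parameters> no growth detected\n")
  } else {
    cat(sprintf(
      "<growth_parameters> lag %.2f h, t_d %.2f h (mu %.3f /h), od_max %.3f\n",
      x$lag_h, x$doubling_time_h, x$mu_max, x$od_max
    ))
  }
  invisible(x)
}

#' Build a dose-response inhibition profile from growth curves
#'
#' Fits growth parameters for every nitrite concentration of a plate
#' experiment. A curve at 0 uM must be present as reference.
#'
#' @param curves Named list of `data.frame(time_h, od600)` where names are
#'   nitrite concentrations in uM, or the output of
#'   [simulate_inhibition_profile()].
#' @param ... Passed to [fit_growth_parameters()].
#' @return An object of classes `inhibition_profile` and `data.frame`:
#'   one row per concentration with `conc_uM`, `lag_h`, `doubling_time_h`,
#'   `mu_max`, `od_max`, `no_growth`.
#' @export
build_profile <- function(curves, ...) {
  if (is.list(curves) && !is.null(curves$curves)) curves <- curves$curves
  stopifnot(is.list(curves), !is.null(names(curves)))
  conc <- suppressWarnings(as.numeric(names(curves)))
  if (any(is.na(conc))) stop("curve names must be nitrite concentrations in uM")
  if (!0 %in% conc) stop("a 0 uM reference concentration is required")
  rows <- lapply(seq_along(curves), function(i) {
    p <- fit_growth_parameters(curves[[i]], ...)
    data.frame(conc_uM = conc[i], lag_h = p$lag_h,
               doubling_time_h = p$doubling_time_h, mu_max = p$mu_max,
               od_max = p$od_max, no_growth = p$no_growth)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$conc_uM), ]
  rownames(out) <- NULL
  structure(out, class = c("inhibition_profile", "data.frame"))
}

#' Classify the nitrite-inhibition phenotype of a dose-response profile
#'
#' Compares each concentration's growth parameters with the 0 uM reference
#' and assigns exactly one phenotype class, by precedence:
#'
#' 1. `complete_inhibition_above_threshold` - any concentration shows no
#'    growth; the threshold is the lowest such concentration.
#' 2. `capacity_loss` - the maximum OD declines by at least
#'    `rel_threshold` at some concentration.
#' 3. `lag_extension` - lag and/or doubling time increase by at least
#'    `rel_threshold` while the maximum OD does not decline by that much.
#' 4. `insensitive` - no parameter shifts by `rel_threshold`.
#'
#' @param profile An [build_profile()] result with >= 3 concentrations.
#' @param rel_threshold Relative-change threshold (default 0.25).
#' @return An object of class `phenotype_class`: list with `class`,
#'   `threshold_conc_uM` (lowest no-growth concentration, or `NA`), and
#'   the per-concentration relative changes.
#' @export
classify_phenotype <- function(profile, rel_threshold = 0.25) {
  stopifnot(inherits(profile, "inhibition_profile") ||
              is.data.frame(profile))
  if (nrow(profile) < 3L) stop("profile needs at least 3 concentrations")
  ref <- profile[profile$conc_uM == 0, ]
  if (nrow(ref) != 1L) stop("exactly one 0 uM reference row required")
  if (ref$no_growth) stop("reference culture shows no growth")

  other <- profile[profile$conc_uM > 0, , drop = FALSE]
  rel <- data.frame(
    conc_uM = other$conc_uM,
    d_lag = (other$lag_h - ref$lag_h) / max(ref$lag_h, 0.5),
    d_doubling = (other$doubling_time_h - ref$doubling_time_h) /
      ref$doubling_time_h,
    d_od_max = (other$od_max - ref$od_max) / ref$od_max,
    no_growth = other$no_growth
  )

  cls <- if (any(other$no_growth)) {
    "complete_inhibition_above_threshold"
  } else if (any(rel$d_od_max <= -rel_threshold)) {
    "capacity_loss"
  } else if (any(rel$d_lag >= rel_threshold, na.rm = TRUE) ||
             any(rel$d_doubling >= rel_threshold, na.rm = TRUE)) {
    "lag_extension"
  } else {
    "insensitive"
  }
  structure(
    list(class = cls,
         threshold_conc_uM = if (any(other$no_growth))
           min(other$conc_uM[other$no_growth]) else NA_real_,
         changes = rel, rel_threshold = rel_threshold),
    class = "phenotype_class"
  )
}

#' @export
print.phenotype_class <- function(x, ...) {
  cat(sprintf("<phenotype_class> %s%s\n", x$class,
              if (is.na(x$threshold_conc_uM)) "" else
                sprintf(" (no growth from %g uM)", x$threshold_conc_uM)))
  invisible(x)
}
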