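#' Pair instantaneous depletion rates with biomass
#'
#' Evaluates the fitted depletion rate at each sampled timepoint and pairs
#' it with the dry-weight biomass implied by the OD reading
#' (`x_dw = od600 * g_dw_per_l_per_od`). Censored readings are excluded,
#' and the first censored timepoint (substrate below the detection limit)
#' defines a terminal time after which rates are not evaluated.
#'
#' @param fit A [fit_concentration_course()] result.
#' @param series The [assay_series()] the fit came from (OD required at
#'   every retained timepoint).
#' @param g_dw_per_l_per_od Biomass conversion, g L^-1 per OD600 unit
#'   (default 0.36, the community average).
#' @return `data.frame` with columns `time_h`, `x_dw` (g L^-1) and `rate`
#'   (uM h^-1), ordered by time.
#' @export
rate_vs_biomass <- function(fit, series, g_dw_per_l_per_od = 0.36) {
  stopifnot(inherits(fit, "depletion_fit"),
            is.data.frame(series),
            all(c("time_h", "od600") %in% names(series)),
            g_dw_per_l_per_od > 0)
  cens <- if ("censored" %in% names(series)) series$censored else
    rep(FALSE, nrow(series))
  terminal <- if (any(cens)) min(series$time_h[cens]) else Inf
  keep <- !cens & series$time_h < terminal &
    series$time_h >= fit$trange[1] & series$time_h <= fit$trange[2]
  s <- series[keep, , drop = FALSE]
  if (any(!is.finite(s$od600))) stop("OD600 missing at retained timepoints")
  data.frame(
    time_h = s$time_h,
    x_dw = s$od600 * g_dw_per_l_per_od,
    rate = instantaneous_rate(fit, s$time_h)
  )[order(s$time_h), ]
}

# Coefficient of determination of a through-origin fit of y on x
# (uncentered: 1 - SSres / sum(y^2)); defined as 1 when y is essentially 0.
origin_r2 <- function(x, y) {
  ssy <- sum(y^2)
  if (ssy <= .Machine$double.eps * length(y)) return(1)
  b <- if (sum(x^2) > 0) sum(x * y) / sum(x^2) else 0
  1 - sum((y - b * x)^2) / ssy
}

#' Locate the initial linear portion of the rate-biomass relation
#'
#' Finds the longest prefix of the rate-versus-biomass pairs (minimum
#' `min_points`) over which the rate is proportional to biomass, judged by
#' the through-origin coefficient of determination. If no prefix reaches
#' `r2_min`, the first `min_points` pairs are returned with
#' `proportional = FALSE` - a warning flag that the measured depletion
#' cannot be attributed to biomass.
#'
#' @param pairs Output of [rate_vs_biomass()] (>= 3 rows).
#' @param r2_min Linearity threshold on the through-origin R^2
#'   (default 0.95).
#' @param min_points Minimum window size (default 3).
#' @return List with `indices`, `r2`, and logical `proportional`.
#' @export
initial_linear_window <- function(pairs, r2_min = 0.95, min_points = 3) {
  stopifnot(is.data.frame(pairs), all(c("x_dw", "rate") %in% names(pairs)))
  n <- nrow(pairs)
  if (n < min_points) stop("need at least ", min_points, " rate-biomass pairs")
  r2s <- vapply(min_points:n, function(k)
    origin_r2(pairs$x_dw[1:k], pairs$rate[1:k]), numeric(1))
  hits <- which(r2s >= r2_min)
  if (length(hits) == 0L) {
    return(list(indices = 1:min_points,
                r2 = r2s[1], proportional = FALSE))
  }
  k <- (min_points:n)[max(hits)]
  list(indices = 1:k, r2 = r2s[max(hits)], proportional = TRUE)
}

#' Specific activity from the initial linear window
#'
#' Origin-constrained least-squares slope of depletion rate (uM h^-1, i.e.
#' umol L^-1 h^-1) against dry-weight biomass (g L^-1) within the window;
#' the slope is therefore directly in umol g_DW^-1 h^-1. Using the whole
#' initial linear portion rather than a single-point ratio makes the
#' estimate robust to individual noisy timepoints.
#'
#' @param pairs Output of [rate_vs_biomass()].
#' @param window Output of [initial_linear_window()] (or an index vector).
#' @return Specific activity in umol g_DW^-1 h^-1, with the through-origin
#'   standard error as attribute `se`.
#' @export
specific_activity <- function(pairs, window = initial_linear_window(pairs)) {
  idx <- if (is.list(window)) window$indices else window
  if (length(idx) < 2L) stop("window of size < 2 after censoring")
  x <- pairs$x_dw[idx]
  y <- pairs$rate[idx]
  if (sum(x^2) == 0) stop("zero biomass throughout the window")
  b <- sum(x * y) / sum(x^2)
  se <- if (length(idx) > 2L) {
    sqrt(sum((y - b * x)^2) / (length(idx) - 1) / sum(x^2))
  } else 0
  structure(max(b, 0), se = se)
}

#' Full specific-activity pipeline for one assay
#'
#' Runs the complete kinetic procedure on a single incubation series:
#' detection-limit censoring, depletion-course fitting, analytic
#' differentiation, rate-biomass pairing, initial-linear-window search and
#' origin-constrained activity estimation.
#'
#' @param series An [assay_series()].
#' @param g_dw_per_l_per_od Biomass conversion, g L^-1 OD^-1.
#' @param lod Detection limit in uM.
#' @param r2_min,min_points Window parameters, see
#'   [initial_linear_window()].
#' @return An object of class `kinetics_result`: list with `fit`, `pairs`,
#'   `window`, `specific_activity` (umol g_DW^-1 h^-1), `se`,
#'   `proportional`, `window_fraction`, `analyte`, `species`.
#' @examples
#' g <- data.frame(time_h = seq(0, 24, 0.5), od600 = 0.139)  # 0.05 g/L
#' sim <- simulate_depletion(g, consumption_params(100, km = 0),
#'                           abiotic_params(cysteine_mM = 0,
#'                             ph_decay_table = data.frame(ph = 7, rate_per_h = 0)),
#'                           100)
#' res <- assay_specific_activity(sim$series)
#' res$specific_activity  # ~ 100
#' @export
assay_specific_activity <- function(series, g_dw_per_l_per_od = 0.36,
                                    lod = 10, r2_min = 0.95, min_points = 3) {
  stopifnot(inherits(series, "assay_series"))
  series <- apply_detection_limit(series, lod)
  fit <- fit_concentration_course(series)
  pairs <- rate_vs_biomass(fit, series, g_dw_per_l_per_od)
  win <- initial_linear_window(pairs, r2_min = r2_min, min_points = min_points)
  act <- specific_activity(pairs, win)
  structure(
    list(fit = fit, pairs = pairs, window = win,
         specific_activity = as.numeric(act), se = attr(act, "se"),
         proportional = win$proportional,
         window_fraction = length(win$indices) / nrow(pairs),
         analyte = attr(series, "analyte"), species = attr(series, "species")),
    class = "kinetics_result"
  )
}

#' @export
print.kinetics_result <- function(x, ...) {
  cat(sprintf(
    "<kinetics_result> %s: %.4g umol/gDW/h (se %.3g, %s fit, window %d/%d%s)\n",
    x$analyte, x$specific_activity, x$se, x$fit$form,
    length(x$window$indices), nrow(x$pairs),
    if (x$proportional) "" else ", NOT proportional to biomass"
  ))
  invisible(x)
}

#' Aggregate replicate activity estimates
#'
#' @param activities Numeric vector of per-replicate specific activities.
#' @return Named vector: `mean`, `sd`, `n`.
#' @export
aggregate_activity <- function(activities) {
  stopifnot(is.numeric(activities), length(activities) >= 1L)
  c(mean = mean(activities),
    sd = if (length(activities) > 1L) sd(activities) else 0,
    n = length(activities))
}

#' Classify an activity as below a reporting threshold
#'
#' Activities whose upper confidence bound (estimate + sd) falls strictly
#' below the threshold are reported as "< threshold" rather than as a point
#' estimate. In addition, an activity is reported below threshold when the
#' depletion rate could not be attributed to biomass: no proportional
#' initial window exists, or the proportional window covers less than
#' `min_window_fraction` of the pre-depletion assay (the signature of
#' stationary-phase losses uncorrelated with the optical density).
#'
#' @param result A `kinetics_result`, or a numeric activity estimate.
#' @param threshold Reporting threshold in umol g_DW^-1 h^-1 (default 1).
#' @param sd Uncertainty to add to the estimate; for a `kinetics_result`
#'   defaults to its regression `se`, for replicate means pass the
#'   replicate sd.
#' @param min_window_fraction Minimum fraction of pairs the proportional
#'   window must cover for the activity to be attributable (default 0.25).
#' @return List with `below` (logical), `label` (e.g. `"< 1"` or the
#'   formatted estimate), `estimate`, `threshold`.
#' @examples
#' classify_below_threshold(0.3, threshold = 1, sd = 0.2)$label   # "< 1"
#' classify_below_threshold(26.9, threshold = 1, sd = 12.2)$label # "26.9"
#' @export
classify_below_threshold <- function(result, threshold = 1, sd = NULL,
                                     min_window_fraction = 0.25) {
  if (inherits(result, "kinetics_result")) {
    est <- result$specific_activity
    unc <- if (is.null(sd)) result$se else sd
    attributable <- result$proportional &&
      result$window_fraction >= min_window_fraction
  } else {
    est <- as.numeric(result)
    unc <- if (is.null(sd)) 0 else sd
    attributable <- TRUE
  }
  below <- (est + unc) < threshold || !attributable
  list(
    below = below,
    label = if (below) paste("<", format(threshold)) else format(signif(est, 3)),
    estimate = est,
    threshold = threshold
  )
}
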