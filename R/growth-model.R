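#' Growth-curve model parameters
#'
#' Parameters of the lag + logistic growth model used by the simulators:
#' the culture sits at `od_initial` until the end of the lag phase, then
#' rises logistically toward `od_max`. The model is parameterized so that
#' the maximum specific growth rate equals `mu_max` exactly, hence the
#' doubling time is `log(2) / mu_max`.
#'
#' @param od_initial Initial optical density (OD600), > 0.
#' @param od_max Carrying-capacity OD600, >= `od_initial`.
#' @param mu_max Maximum specific growth rate in h^-1, >= 0.
#' @param lag Lag-phase duration in h, >= 0.
#' @return An object of class `growth_params`.
#' @seealso [simulate_growth()]
#' @examples
#' # 5 h lag, 1.1 h doubling time, plateau at OD 0.6
#' growth_params(0.05, 0.6, log(2) / 1.1, lag = 5)
#' @export
growth_params <- function(od_initial, od_max, mu_max, lag = 0) {
  vals <- c(od_initial = od_initial, od_max = od_max, mu_max = mu_max, lag = lag)
  if (!all(is.finite(vals))) stop("growth parameters must be finite")
  if (od_initial <= 0) stop("od_initial must be > 0")
  if (od_max < od_initial) stop("od_max must be >= od_initial")
  if (mu_max < 0) stop("mu_max must be >= 0")
  if (lag < 0) stop("lag must be >= 0")
  structure(as.list(vals), class = "growth_params")
}

#' @export
print.growth_params <- function(x, ...) {
  cat(sprintf(
    "<growth_params> od0=%g od_max=%g mu_max=%g /h (t_d=%.3g h) lag=%g h\n",
    x$od_initial, x$od_max, x$mu_max,
    if (x$mu_max > 0) log(2) / x$mu_max else Inf, x$lag
  ))
  invisible(x)
}

#' Simulate a bacterial growth curve
#'
#' Evaluates the lag + logistic growth model at the requested times.
#' For `t <= lag` the OD stays at `od_initial`; afterwards it follows a
#' logistic rise toward `od_max` whose maximum specific growth rate is
#' `mu_max` (attained immediately after the lag phase, when the culture is
#' farthest from carrying capacity). The curve is monotone non-decreasing.
#'
#' @param params A [growth_params()] object.
#' @param times Sampling times in h, strictly increasing, non-negative.
#' @return Numeric vector of OD600 values, one per time.
#' @examples
#' t <- seq(0, 24, 0.5)
#' od <- simulate_growth(growth_params(0.05, 0.6, log(2) / 1.1, lag = 5), t)
#' @export
simulate_growth <- function(params, times) {
  stopifnot(inherits(params, "growth_params"))
  if (length(times) == 0L) stop("times must be non-empty")
  if (!all(is.finite(times)) || any(times < 0)) {
    stop("times must be finite and non-negative")
  }
  if (length(times) > 1L && any(diff(times) <= 0)) {
    stop("times must be strictly increasing")
  }
  od0 <- params$od_initial
  K <- params$od_max
  mu <- params$mu_max
  if (mu == 0 || K == od0) return(rep(od0, length(times)))
  # scale the logistic rate so the initial per-capita rate is exactly mu_max
  r <- mu / (1 - od0 / K)
  s <- pmax(times - params$lag, 0)
  e <- exp(r * s)
  K * od0 * e / (K - od0 + od0 * e)
}
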