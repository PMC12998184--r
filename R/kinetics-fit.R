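#' Fit a functional form to a substrate-depletion course
#'
#' Reproduces the classical kinetic workflow - fit a functional equation to
#' the concentration-versus-time data, then differentiate it analytically -
#' with automatic model selection instead of interactive curve fitting.
#' A small family of candidate forms is fitted to the uncensored readings:
#'
#' * constant `C = c`
#' * linear `C = c0 + b t`
#' * exponential-plus-offset `C = c_inf + (c0 - c_inf) exp(-k t)`
#' * logistic decline `C = c0 / (1 + exp((t - t0)/s))`
#'
#' The winner is chosen by small-sample-corrected AIC among the candidates
#' whose fitted curve is monotone non-increasing over the data range; if no
#' parametric candidate qualifies, a monotone cubic spline (after an
#' antitonic projection of the data) is used as fallback.
#'
#' @param series An [assay_series()] (or `data.frame` with `time_h`,
#'   `conc_uM` and optional `censored`).
#' @return An object of class `depletion_fit` with elements `form`,
#'   `coefficients`, `fn(t)`, `dfn(t)` (analytic derivative), `trange`,
#'   `aicc`, and the fitted data.
#' @examples
#' s <- assay_series(0:10, od600 = 1, conc_uM = 100 - 5 * (0:10))
#' fit <- fit_concentration_course(s)
#' fit$form  # "linear"
#' @export
fit_concentration_course <- function(series) {
  stopifnot(is.data.frame(series), all(c("time_h", "conc_uM") %in% names(series)))
  cens <- if ("censored" %in% names(series)) series$censored else FALSE
  keep <- !cens & is.finite(series$conc_uM) & is.finite(series$time_h)
  t <- series$time_h[keep]
  y <- series$conc_uM[keep]
  if (length(t) == 0L) stop("all points censored: nothing to fit")
  if (length(t) < 4L) stop("need at least 4 uncensored points to fit")

  n <- length(t)
  scale <- max(abs(y), 1e-12)
  cand <- list()

  aicc <- function(fit, npar) {
    k <- npar + 1  # + residual variance
    a <- AIC(fit)
    if (n - k - 1 > 0) a + 2 * k * (k + 1) / (n - k - 1) else Inf
  }

  # constant
  f <- lm(y ~ 1)
  c0 <- unname(coef(f)[1])
  cand$constant <- list(
    form = "constant", coefficients = c(c = c0),
    fn = local({ cc <- c0; function(t) rep(cc, length(t)) }),
    dfn = function(t) rep(0, length(t)),
    aicc = aicc(f, 1)
  )

  # linear
  f <- lm(y ~ t)
  b0 <- unname(coef(f)[1]); b1 <- unname(coef(f)[2])
  cand$linear <- list(
    form = "linear", coefficients = c(c0 = b0, slope = b1),
    fn = local({ a0 <- b0; a1 <- b1; function(t) a0 + a1 * t }),
    dfn = local({ a1 <- b1; function(t) rep(a1, length(t)) }),
    aicc = aicc(f, 2), slope = b1
  )

  # exponential-plus-offset
  st <- list(cinf = max(min(y), 0), c0 = max(y),
             k = 1 / max(diff(range(t)) / 3, 1e-3))
  f <- tryCatch(
    minpack.lm::nlsLM(
      y ~ cinf + (c0 - cinf) * exp(-k * t),
      start = st, lower = c(cinf = 0, c0 = 0, k = 1e-8),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (!is.null(f)) {
    p <- coef(f)
    cand$exp_offset <- list(
      form = "exp_offset",
      coefficients = c(c0 = unname(p["c0"]), c_inf = unname(p["cinf"]),
                       k = unname(p["k"])),
      fn = local({ p <- p; function(t)
        p["cinf"] + (p["c0"] - p["cinf"]) * exp(-p["k"] * t) }),
      dfn = local({ p <- p; function(t)
        -(p["c0"] - p["cinf"]) * p["k"] * exp(-p["k"] * t) }),
      aicc = aicc(f, 3)
    )
  }

  # logistic decline
  half <- min(y) + diff(range(y)) / 2
  t0_guess <- if (any(y <= half)) t[which(y <= half)[1]] else max(t)
  f <- tryCatch(
    minpack.lm::nlsLM(
      y ~ c0 / (1 + exp((t - t0) / s)),
      start = list(c0 = max(y), t0 = t0_guess,
                   s = max(diff(range(t)) / 10, 1e-3)),
      lower = c(c0 = 0, t0 = -Inf, s = 1e-6),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (!is.null(f)) {
    p <- coef(f)
    cand$logistic <- list(
      form = "logistic",
      coefficients = c(c0 = unname(p["c0"]), t0 = unname(p["t0"]),
                       s = unname(p["s"])),
      fn = local({ p <- p; function(t) p["c0"] / (1 + exp((t - p["t0"]) / p["s"])) }),
      dfn = local({ p <- p; function(t) {
        e <- exp((t - p["t0"]) / p["s"])
        -p["c0"] * e / (p["s"] * (1 + e)^2)
      } }),
      aicc = aicc(f, 3)
    )
  }

  # keep only monotone non-increasing candidates
  grid <- seq(min(t), max(t), length.out = 201)
  ok <- vapply(cand, function(m) {
    v <- m$fn(grid)
    all(diff(v) <= 1e-8 * scale) && all(is.finite(v))
  }, logical(1))
  cand <- cand[ok]

  if (length(cand) == 0L) {
    best <- monotone_spline_fit(t, y)
  } else {
    best <- cand[[which.min(vapply(cand, `[[`, numeric(1), "aicc"))]]
  }

  best$trange <- range(t)
  best$data <- data.frame(time_h = t, conc_uM = y)
  class(best) <- "depletion_fit"
  best
}

# Antitonic projection of the data followed by a monotone (Hyman) cubic
# spline; used when no parametric form is admissible.
monotone_spline_fit <- function(t, y) {
  iso <- -stats::isoreg(t, -y)$yf  # non-increasing projection
  keep <- !duplicated(iso) | c(TRUE, diff(t) > 0)
  sf <- splinefun(t, iso, method = "hyman")
  list(form = "spline", coefficients = NULL,
       fn = sf, dfn = function(x) sf(x, deriv = 1), aicc = NA_real_)
}

#' @export
print.depletion_fit <- function(x, ...) {
  cat(sprintf("<depletion_fit> form=%s over t in [%g, %g] h\n",
              x$form, x$trange[1], x$trange[2]))
  if (!is.null(x$coefficients)) print(x$coefficients)
  invisible(x)
}

#' Instantaneous depletion rate from a fitted course
#'
#' Analytic derivative of the fitted concentration function, sign-flipped
#' so that depletion is positive. Evaluation outside the fitted data range
#' is refused (no extrapolation).
#'
#' @param fit A [fit_concentration_course()] result.
#' @param t Time(s) in h, inside the fitted range.
#' @return Depletion rate(s) in uM h^-1.
#' @export
instantaneous_rate <- function(fit, t) {
  stopifnot(inherits(fit, "depletion_fit"))
  tol <- 1e-9 * max(abs(fit$trange), 1)
  if (any(t < fit$trange[1] - tol | t > fit$trange[2] + tol)) {
    stop("rate requested outside the fitted time range")
  }
  as.numeric(-fit$dfn(t))
}
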