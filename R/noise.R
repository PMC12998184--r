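#' Measurement-noise specification for the simulators
#'
#' Bundles the noise magnitudes applied by the synthetic-data generators and
#' the random seed that makes them reproducible. All magnitudes default to
#' zero (noise off).
#'
#' @param od_cv Fractional (coefficient-of-variation) noise on optical
#'   density readings.
#' @param conc_sd Additive Gaussian noise on concentration readings, in uM.
#' @param absorbance_sd Additive Gaussian noise on absorbance readings
#'   (dimensionless).
#' @param seed Integer seed; identical seeds give byte-identical simulator
#'   output. `NULL` uses (and advances) the session RNG.
#' @return An object of class `noise_spec`.
#' @examples
#' noise_spec(conc_sd = 2, seed = 1)
#' @export
noise_spec <- function(od_cv = 0, conc_sd = 0, absorbance_sd = 0, seed = NULL) {
  stopifnot(
    is.numeric(od_cv), length(od_cv) == 1L, is.finite(od_cv), od_cv >= 0,
    is.numeric(conc_sd), length(conc_sd) == 1L, is.finite(conc_sd), conc_sd >= 0,
    is.numeric(absorbance_sd), length(absorbance_sd) == 1L,
    is.finite(absorbance_sd), absorbance_sd >= 0
  )
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    seed <- as.integer(seed)
  }
  structure(
    list(od_cv = od_cv, conc_sd = conc_sd, absorbance_sd = absorbance_sd,
         seed = seed),
    class = "noise_spec"
  )
}

# Evaluate `expr` under the spec's seed without disturbing the caller's RNG
# stream (no-op passthrough when seed is NULL).
with_noise_seed <- function(noise, expr) {
  if (is.null(noise$seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(noise$seed)
  expr
}

#' @export
print.noise_spec <- function(x, ...) {
  cat(sprintf(
    "<noise_spec> od_cv=%g conc_sd=%g uM absorbance_sd=%g seed=%s\n",
    x$od_cv, x$conc_sd, x$absorbance_sd,
    if (is.null(x$seed)) "none" else x$seed
  ))
  invisible(x)
}
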