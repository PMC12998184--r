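# Shared fixtures: abiotic model with all chemical sinks switched off, and a
# resting-cell growth table (constant OD).

abiotic_off <- function() {
  abiotic_params(cysteine_mM = 0,
                 ph_decay_table = data.frame(ph = 7, rate_per_h = 0))
}

resting_growth <- function(od, times = seq(0, 24, 0.5)) {
  data.frame(time_h = times, od600 = od)
}

# Resting-cell recovery simulation at specific activity `a`: cell density is
# scaled so the zero-order depletion rate is ~40 uM/h regardless of `a`.
recovery_sim <- function(a, seed, conc_sd = 2) {
  x_dw <- 40 / a
  g <- resting_growth(x_dw / 0.36, times = seq(0, 4, 0.1))
  simulate_depletion(g, consumption_params(a, km = 0), abiotic_off(),
                     c_nominal = 100,
                     noise = noise_spec(conc_sd = conc_sd, seed = seed))
}
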