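# Independent oracles used across tests. These deliberately avoid the
# package's own code paths: fixed-step Euler for the ODE, exhaustive pair
# enumeration for the MSD, closed-form regression for the log-linear fit.

# Fixed-step Euler integration of the cascade (constant or depleting glucose).
euler_cascade <- function(model, catalyst_conc, glucose0, h2o2_0, t_end,
                          dt = 1e-3, glucose_depletion = TRUE) {
  prod <- model$production
  dec <- model$decomposition
  rp <- (catalyst_conc / prod$ref_catalyst_conc)^model$production_catalyst_exponent
  rd <- (catalyst_conc / dec$ref_catalyst_conc)^model$decomposition_catalyst_exponent
  n <- ceiling(t_end / dt)
  g <- glucose0; h <- h2o2_0
  for (i in seq_len(n)) {
    p <- prod$v_max * g / (prod$k_m + g) * rp
    d <- dec$v_max * h^dec$hill_h /
      (dec$k_half^dec$hill_h + h^dec$hill_h) * rd
    if (glucose_depletion) g <- max(g - dt * p, 0)
    h <- max(h + dt * (p - d), 0)
  }
  c(glucose = g, h2o2 = h)
}

# Exhaustive O(n^2) time-averaged MSD for one track at every available lag.
msd_pairs_oracle <- function(x, y, n_lags) {
  n <- length(x)
  vapply(seq_len(n_lags), function(k) {
    if (k >= n) return(NA_real_)
    acc <- 0
    cnt <- 0L
    for (i in seq_len(n - k)) {
      acc <- acc + (x[i + k] - x[i])^2 + (y[i + k] - y[i])^2
      cnt <- cnt + 1L
    }
    acc / cnt
  }, 0)
}

# Closed-form simple-regression slope of log2(value) on time.
log2_slope_oracle <- function(time, value) {
  yt <- log2(value)
  sum((time - mean(time)) * (yt - mean(yt))) / sum((time - mean(time))^2)
}

# A small reference cascade used in several tests: glucose-oxidation
# Km at 2.9 mM, decomposition half-saturation at 155.1 mM.
ref_cascade <- function(hill_h = 1, prod_vmax = 0.5, dec_vmax = 5,
                        prod_exp = 1, dec_exp = 0.5) {
  cascade_model(
    mm_kinetics(v_max = prod_vmax, k_m = 2.9, ref_catalyst_conc = 0.1),
    hill_kinetics(v_max = dec_vmax, k_half = 155.1, hill_h = hill_h,
                  ref_catalyst_conc = 0.1),
    production_catalyst_exponent = prod_exp,
    decomposition_catalyst_exponent = dec_exp
  )
}
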