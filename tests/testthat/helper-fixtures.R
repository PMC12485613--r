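# Small in-code fixtures shared across test files.

# A bottle whose rate is hand-computable from the tracer equation:
# (0.3763 - 0.3663)/(1.41 - 0.3663) * 0.5 / 1 * 1000 = 4.790649...
hand_bottle <- list(a_pn_initial = 0.3663, a_pn_final = 0.3763,
                    a_n2 = 1.41, pn_conc = 0.5, duration = 1)

# tiny perfect dilution series (slope -3.3219, intercept 38)
perfect_standards <- function(levels = 10^(1:5), intercept = 38,
                              slope = -3.3219, nrep = 3) {
  cps <- rep(levels, each = nrep)
  data.frame(copies_per_well = cps, ct = intercept + slope * log10(cps))
}

# a small fitted niche model on a noiseless synthetic database
noiseless_fit <- function(seed = 11, n = 300) {
  cfg <- sim_config(seed = seed, n_db_records = n)
  db <- simulate_global_database(cfg, list(ucynb_truth(noise_sd = 0)))
  niche_gam(db$records, taxon = "UCYN-B")
}

# centered true partial response of a niche_truth for one covariate:
# the truth's additive term minus its mean over the training values,
# evaluated on a grid (comparable to mgcv's centered smooths)
centered_truth <- function(truth, covariate, grid, train_values) {
  f <- switch(covariate, sst = truth$response_sst,
              dfe = truth$response_dfe, p = truth$response_p)
  f(grid) - mean(f(train_values))
}
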