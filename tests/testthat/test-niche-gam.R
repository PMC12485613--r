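test_that("noiseless synthetic niche is recovered almost perfectly", {
  # the bump/saturation/peak truth is not inside a small spline basis,
  # so near-exact recovery requires an adequate basis dimension
  cfg <- sim_config(seed = 11, n_db_records = 300)
  db <- simulate_global_database(cfg, list(ucynb_truth(noise_sd = 0)))
  fit <- suppressWarnings(niche_gam(db$records, taxon = "UCYN-B",
                                    k = 12))
  expect_gt(fit$deviance_explained, 99)
  expect_gt(fit$r_squared, 0.99)
  # a truth inside the model span round-trips to machine precision
  lin <- niche_truth("lin", function(s) 0.1 * s, function(d) 0.8 * d,
                     function(p) -0.5 * p, intercept = 5, noise_sd = 0)
  db2 <- simulate_global_database(cfg, list(lin))
  fit2 <- suppressWarnings(niche_gam(db2$records, taxon = "lin"))
  pred <- predict(fit2, db2$records)
  expect_equal(as.numeric(pred), log10(db2$records$nifh_areal),
               tolerance = 1e-6)
})

test_that("pure-noise response yields near-zero deviance explained", {
  cfg <- sim_config(seed = 21, n_db_records = 600)
  db <- simulate_global_database(cfg, list(ucynb_truth()))
  rec <- db$records
  set.seed(1)
  rec$nifh_areal <- 10^rnorm(nrow(rec), 5, 0.5)  # decoupled from covariates
  fit <- niche_gam(rec, taxon = "UCYN-B")
  expect_lt(fit$deviance_explained, 5)
})

test_that("fit statistics match textbook definitions on the fitted data", {
  fit <- noiseless_fit(seed = 13, n = 120)
  y <- fit$fit$y
  res <- residuals(fit)
  # fraction of null deviance explained, computed from first principles
  dev_expl <- 1 - sum(res^2) / sum((y - mean(y))^2)
  expect_equal(fit$deviance_explained, 100 * dev_expl, tolerance = 1e-8)
  expect_true(fit$deviance_explained >= 0 &&
                fit$deviance_explained <= 100)
  # adjusted R^2 is bounded by the unadjusted fraction from above
  expect_lte(fit$r_squared, dev_expl + 1e-8)
})

test_that("fit is invariant to record order", {
  cfg <- sim_config(seed = 31, n_db_records = 200)
  db <- simulate_global_database(cfg, list(ucynb_truth(noise_sd = 0.3)))
  f1 <- niche_gam(db$records, taxon = "UCYN-B")
  set.seed(2)
  f2 <- niche_gam(db$records[sample(nrow(db$records)), ],
                  taxon = "UCYN-B")
  expect_equal(f1$r_squared, f2$r_squared, tolerance = 1e-8)
  nd <- data.frame(sst = c(24, 27.5), dfe = c(0.3, 0.6),
                   p = c(0.1, 0.4))
  expect_equal(as.numeric(predict(f1, nd)),
               as.numeric(predict(f2, nd)), tolerance = 1e-8)
})

test_that("partial responses recover a known bump within tolerance", {
  cfg <- sim_config(seed = 41, n_db_records = 600)
  truth <- ucynb_truth(noise_sd = 0.5)
  db <- simulate_global_database(cfg, list(truth))
  fit <- niche_gam(db$records, taxon = "UCYN-B")
  rc <- partial_response(fit, "sst", n_grid = 200)
  # argmax of the temperature response within 1 degC of the true 27.5
  expect_lt(abs(rc$x[which.max(rc$effect)] - 27.5), 1)
  # RMSE against the centered truth over the central 90% of the range
  train <- fit$hull$sst$values
  qs <- quantile(train, c(0.05, 0.95))
  sel <- rc$x >= qs[1] & rc$x <= qs[2]
  tr <- centered_truth(truth, "sst", rc$x[sel], train)
  rmse <- sqrt(mean((rc$effect[sel] - tr)^2))
  expect_lt(rmse, 0.3)
  # the iron response declines sharply below its half-saturation
  rd <- partial_response(fit, "dfe", n_grid = 200)
  low <- rd$effect[rd$x < 0.1]
  high <- rd$effect[rd$x > 0.4]
  expect_lt(max(low), min(high))
})

test_that("flat truth produces a response within its confidence band of zero", {
  flat <- niche_truth("flat", function(s) 0 * s, function(d) 0 * d,
                      function(p) 0 * p, intercept = 5, noise_sd = 0.4)
  cfg <- sim_config(seed = 51, n_db_records = 600)
  db <- simulate_global_database(cfg, list(flat))
  fit <- niche_gam(db$records, taxon = "flat")
  rc <- partial_response(fit, "sst")
  expect_true(all(rc$lower <= 0 & rc$upper >= 0))
})

test_that("prediction clamps out-of-hull covariates and flags them", {
  fit <- noiseless_fit(seed = 61, n = 200)
  r <- fit$hull$sst$range
  inside <- data.frame(sst = r[2], dfe = fit$hull$dfe$median,
                       p = fit$hull$p$median)
  beyond <- inside; beyond$sst <- r[2] + 5
  p_in <- predict(fit, inside)
  p_out <- predict(fit, beyond)
  expect_equal(as.numeric(p_in), as.numeric(p_out), tolerance = 1e-10)
  expect_false(attr(p_in, "extrapolated"))
  expect_true(attr(p_out, "extrapolated"))
  expect_error(predict(fit, data.frame(sst = 27)), "lacks covariates")
})

test_that("prediction at the medians equals constant plus centered effects", {
  fit <- noiseless_fit(seed = 71, n = 200)
  med <- data.frame(sst = fit$hull$sst$median,
                    dfe = fit$hull$dfe$median,
                    p = fit$hull$p$median)
  pr <- as.numeric(predict(fit, med))
  eff <- vapply(fit$covariates, function(cv) {
    rc <- partial_response(fit, cv, n_grid = 401)
    approx(rc$x, rc$effect, xout = med[[cv]])$y
  }, numeric(1))
  const <- pr - sum(eff)
  # rebuild a prediction elsewhere from constant + interpolated effects
  nd <- data.frame(sst = 26, dfe = 0.5, p = 0.2)
  eff2 <- vapply(fit$covariates, function(cv) {
    rc <- partial_response(fit, cv, n_grid = 401)
    approx(rc$x, rc$effect, xout = nd[[cv]])$y
  }, numeric(1))
  expect_equal(const + sum(eff2), as.numeric(predict(fit, nd)),
               tolerance = 1e-3)
})

test_that("zero-abundance handling drops or floors as configured", {
  cfg <- sim_config(seed = 81, n_db_records = 200)
  db <- simulate_global_database(cfg, list(ucynb_truth(noise_sd = 0.3)))
  rec <- db$records
  rec$nifh_areal[1:40] <- 0
  f_drop <- niche_gam(rec, taxon = "UCYN-B")
  expect_equal(f_drop$n_used, 160)
  expect_equal(f_drop$n_zero_dropped, 40)
  f_floor <- niche_gam(rec, taxon = "UCYN-B", zero_handling = "floor",
                       floor_value = 1e3)
  expect_equal(f_floor$n_used, 200)
  expect_error(niche_gam(rec, taxon = "UCYN-B",
                         zero_handling = "floor"), "floor_value")
  expect_error(niche_gam(rec[1:30, ], taxon = "UCYN-B"), "usable records")
})

test_that("model methods behave like a classed fit object", {
  fit <- noiseless_fit(seed = 91, n = 120)
  expect_s3_class(fit, "niche_gam")
  expect_output(print(fit), "Diazotroph niche GAM")
  expect_output(print(summary(fit)), "Smooth terms")
  expect_true(length(coef(fit)) > 3)
  expect_equal(length(fitted(fit)), fit$n_used)
  expect_equal(length(residuals(fit)), fit$n_used)
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_equal(dim(sims), c(fit$n_used, 2L))
  expect_error(partial_response(fit, "chlorophyll"), "unknown covariate")
})
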