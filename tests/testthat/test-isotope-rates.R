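test_that("tracer rate equation matches hand evaluation and is linear in PN", {
  b <- hand_bottle
  r <- n2_fixation_rate(b$a_pn_initial, b$a_pn_final, b$a_n2,
                        b$pn_conc, b$duration)
  expect_equal(as.numeric(r), (0.01 / 1.0437) * 0.5 * 1000,
               tolerance = 1e-12)
  # no enrichment -> zero rate
  expect_equal(as.numeric(
    n2_fixation_rate(0.3663, 0.3663, 1.41, 0.5, 1)), 0)
  # doubling PN doubles the rate
  r2 <- n2_fixation_rate(b$a_pn_initial, b$a_pn_final, b$a_n2,
                         2 * b$pn_conc, b$duration)
  expect_equal(as.numeric(r2), 2 * as.numeric(r), tolerance = 1e-12)
})

test_that("negative enrichment clips to zero with a flag; bad tracer errors", {
  r <- n2_fixation_rate(0.3663, 0.3600, 1.41, 0.5, 1)
  expect_equal(as.numeric(r), 0)
  expect_true(attr(r, "clipped"))
  expect_error(n2_fixation_rate(0.3663, 0.3763, 0.3, 0.5, 1),
               "undefined tracer")
  expect_error(n2_fixation_rate(0.3663, 0.3763, 1.41, -1, 1), "pn_conc")
})

test_that("min_delta_apn is 3 x sd, matching the reported worked value", {
  expect_equal(min_delta_apn(0.00017), 0.00051)
  expect_equal(signif(min_delta_apn(0.00017), 1), 5e-4)
  expect_equal(min_delta_apn(0), 0)
  expect_equal(min_delta_apn(0.001), 0.003)
})

test_that("LOD-1 substitutes min_dA into the rate equation and is linear", {
  b <- hand_bottle
  l <- lod1_rate(b$a_pn_initial, b$a_n2, b$pn_conc, b$duration)
  expect_equal(as.numeric(l), (0.00146 / 1.0437) * 0.5 * 1000,
               tolerance = 1e-12)
  expect_equal(as.numeric(
    lod1_rate(b$a_pn_initial, b$a_n2, b$pn_conc, b$duration, min_da = 0)),
    0)
  l2 <- lod1_rate(b$a_pn_initial, b$a_n2, b$pn_conc, b$duration,
                  min_da = 2 * 0.00146)
  expect_equal(as.numeric(l2), 2 * as.numeric(l), tolerance = 1e-12)
})

test_that("delta-method LOD-2 is zero for identical duplicates and grows with sd_a_n2", {
  p <- lod2_rate(c(0.38, 0.38), c(0.5, 0.5), 0.3663, 1.41, 1,
                 sd_a_n2 = 0)
  expect_equal(p$sd, 0)
  expect_equal(p$lod2, 0)
  sds <- vapply(c(0, 0.05, 0.083, 0.2), function(s)
    lod2_rate(c(0.377, 0.379), c(0.48, 0.52), 0.3663, 1.41, 1,
              sd_a_n2 = s)$sd, numeric(1))
  expect_true(all(diff(sds) >= 0))
  # multiplier convention
  p2 <- lod2_rate(c(0.377, 0.379), c(0.48, 0.52), 0.3663, 1.41, 1)
  expect_equal(p2$lod2, 3 * p2$sd)
  expect_error(lod2_rate(c(0.38, 0.38, 0.38), c(0.5, 0.5, 0.5),
                         0.3663, 1.41, 1), "duplicate")
})

test_that("delta-method sd agrees with a Monte-Carlo oracle within 5%", {
  a_t <- c(0.377, 0.379); pn <- c(0.48, 0.52)
  a0 <- 0.3663; an2 <- 1.41; dt <- 1; s_an2 <- 0.083
  prop <- lod2_rate(a_t, pn, a0, an2, dt, sd_a_n2 = s_an2)
  set.seed(42)
  n <- 1e5
  draws <- (rnorm(n, mean(a_t), sd(a_t)) - a0) /
    (rnorm(n, an2, s_an2) - a0) *
    rnorm(n, mean(pn), sd(pn)) / dt * 1000
  expect_equal(prop$sd, sd(draws), tolerance = 0.05)
})

test_that("trapezoidal depth integration matches closed forms and ignores row order", {
  # constant 1 nmol L-1 d-1 over 0..100 m -> 100 umol m-2 d-1
  expect_equal(depth_integrate(c(0, 50, 100), c(1, 1, 1)), 100)
  # linear 2 -> 0 over 0..100 m -> 100
  expect_equal(depth_integrate(c(0, 100), c(2, 0)), 100)
  # surface extension: shallowest value extended to 0 m
  expect_equal(depth_integrate(c(10, 100), c(1, 1)), 100)
  # order invariance
  expect_equal(depth_integrate(c(100, 0, 50), c(0, 2, 1)),
               depth_integrate(c(0, 50, 100), c(2, 1, 0)))
  expect_error(depth_integrate(5, 1), "two depths")
  # exact on piecewise-linear profiles: compare with pracma's trapezoid
  skip_if_not_installed("pracma")
  d <- c(0, 7, 23, 55, 80, 120)
  v <- c(6, 5.2, 3.1, 1.4, 0.5, 0.1)
  expect_equal(depth_integrate(d, v), pracma::trapz(d, v))
})

test_that("rate_table aggregates duplicates, flags below-LOD and low PN mass", {
  sim <- simulate_incubations(sim_config(seed = 5, n_stations = 3))
  rt <- rate_table(sim$samples)
  expect_equal(nrow(rt), 3 * 6)
  expect_true(all(rt$n_bottles == 2))
  expect_true(all(rt$flag %in% c("ok", "below_lod1", "below_lod2")))
  expect_true(all(rt$lod1 > 0))
  # null-signal bottles: recovered rates sit below the detection limit
  cfg0 <- sim_config(seed = 6, n_stations = 2)
  sim0 <- simulate_incubations(cfg0, true_surface_rates = c(0, 0))
  rt0 <- rate_table(sim0$samples)
  expect_true(all(rt0$flag != "ok"))
  # low-mass flag fires when PN mass drops below the gate
  low <- sim$samples
  low$pn_mass <- 5
  expect_true(all(rate_table(low)$low_pn_mass))
})

test_that("station profiles integrate to areal rates with below-LOD zeroed", {
  rt <- data.frame(station = "S1", depth = c(5, 50, 100),
                   fraction = "bulk", n_bottles = 2,
                   rate = c(4, 2, 1), sd = NA, lod1 = 0.5, lod2 = NA,
                   flag = c("ok", "ok", "below_lod1"),
                   low_pn_mass = FALSE)
  ar <- integrate_rate_profiles(rt)
  # surface extension of 4, trapezoid 5..50..100, deepest zeroed
  expect_equal(ar$areal_rate,
               depth_integrate(c(5, 50, 100), c(4, 2, 0)))
})
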