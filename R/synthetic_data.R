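#' Simulation configuration for the synthetic pipeline inputs
#'
#' Bundles the sizes, covariate ranges, noise levels and plate layout
#' used by every `simulate_*()` generator. A fixed `seed` makes each
#' generator bit-reproducible.
#'
#' Defaults mirror the field campaign the package models: stations
#' sampled at six light depths (100/50/25/10/1/0.1% surface PAR) with
#' duplicate bulk bottles, qPCR standards spanning 1 to 1e6 copies per
#' well in triplicate, and a global niche database of 600 stations over
#' tropical-to-temperate covariate ranges.
#'
#' @param seed integer RNG seed.
#' @param n_stations incubation stations to simulate.
#' @param n_depths light depths per station (>= 2).
#' @param n_replicates duplicate bottles per depth.
#' @param depths_m sampling depths (m) corresponding to the PAR levels.
#' @param par_levels percent surface PAR labels for the depths.
#' @param apn_noise_sd measurement noise on final PN atom%, atom%.
#' @param pn_cv lognormal coefficient of variation of PN concentration
#'   between duplicates.
#' @param a_n2_mean,a_n2_sd dissolved-N2 labelling distribution, atom%
#'   (bulk defaults 1.41 / 0.083; the <10 um fraction uses 1.56 / 0.077).
#' @param a_pn_initial natural-abundance initial atom%.
#' @param duration_d incubation length, days.
#' @param standard_levels qPCR standard copies per well.
#' @param ct_noise_sd replicate Ct noise, cycles.
#' @param qpcr_slope,qpcr_intercept true standard-curve parameters.
#' @param n_db_records rows of the synthetic global niche database.
#' @param sst_range,dfe_range,p_range covariate ranges (degC, nM, uM).
#' @param rate_fraction fraction of database records carrying an areal
#'   rate observation and a method tag.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_stations = 12L, n_depths = 6L,
                       n_replicates = 2L,
                       depths_m = c(5, 20, 40, 60, 90, 120),
                       par_levels = c(100, 50, 25, 10, 1, 0.1),
                       apn_noise_sd = 2e-4, pn_cv = 0.05,
                       a_n2_mean = 1.41, a_n2_sd = 0.083,
                       a_pn_initial = 0.3663, duration_d = 1,
                       standard_levels = 10^(0:6), ct_noise_sd = 0.1,
                       qpcr_slope = -3.3219, qpcr_intercept = 38,
                       n_db_records = 600L,
                       sst_range = c(10, 31), dfe_range = c(0.01, 1.2),
                       p_range = c(0.01, 1.5), rate_fraction = 0.5) {
  if (n_depths < 2L) stop("n_depths must be >= 2", call. = FALSE)
  if (length(depths_m) < n_depths || length(par_levels) < n_depths)
    stop("need depths_m and par_levels for every depth", call. = FALSE)
  cfg <- as.list(environment())
  cfg$depths_m <- depths_m[seq_len(n_depths)]
  cfg$par_levels <- par_levels[seq_len(n_depths)]
  structure(cfg, class = "sim_config")
}

#' Prescribed niche truth for one phylotype
#'
#' The data-generating process behind the synthetic global database:
#' log10 areal nifH abundance is `intercept` plus one smooth additive
#' response per covariate plus Gaussian noise.
#'
#' @param taxon phylotype name.
#' @param response_sst,response_dfe,response_p vectorized functions of
#'   one covariate returning its additive contribution, log10 units.
#' @param intercept baseline log10 copies m-2.
#' @param noise_sd Gaussian noise SD on the log10 scale (>= 0).
#' @return List of class `niche_truth`.
#' @seealso [ucynb_truth()] for a ready-made warm-oligotroph truth.
#' @export
niche_truth <- function(taxon, response_sst, response_dfe, response_p,
                        intercept, noise_sd) {
  stopifnot(is.function(response_sst), is.function(response_dfe),
            is.function(response_p))
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(list(taxon = taxon, response_sst = response_sst,
                 response_dfe = response_dfe, response_p = response_p,
                 intercept = intercept, noise_sd = noise_sd),
            class = "niche_truth")
}

#' A UCYN-B-like prescribed niche
#'
#' Warm-water unicellular diazotroph truth: a Gaussian temperature
#' optimum at 27.5 degC (scale 2 degC), a saturating dissolved-iron
#' response with half-saturation near 0.2 nM (declining sharply below),
#' and a phosphate response peaking near 0.1 uM and declining toward
#' high-P (upwelling-like) waters.
#'
#' @param intercept baseline log10 copies m-2 (default 5).
#' @param noise_sd log10-scale noise SD (default 0.5).
#' @return A [niche_truth()] object.
#' @export
ucynb_truth <- function(intercept = 5, noise_sd = 0.5) {
  niche_truth(
    taxon = "UCYN-B",
    response_sst = function(sst) 2.5 * exp(-((sst - 27.5)^2) / (2 * 2^2)),
    response_dfe = function(dfe) 1.5 * dfe / (dfe + 0.2),
    response_p = function(p)
      1.5 * exp(-((log10(p) - log10(0.1))^2) / (2 * 0.35^2)),
    intercept = intercept, noise_sd = noise_sd)
}

#' Evaluate a niche truth's noiseless log10 abundance
#'
#' @param truth a [niche_truth()].
#' @param sst,dfe,p covariate vectors.
#' @return log10 copies m-2 without noise.
#' @export
truth_log_abundance <- function(truth, sst, dfe, p) {
  stopifnot(inherits(truth, "niche_truth"))
  out <- truth$intercept + truth$response_sst(sst) +
    truth$response_dfe(dfe) + truth$response_p(p)
  if (any(!is.finite(out)))
    stop("niche truth is non-finite over the requested range",
         call. = FALSE)
  out
}

#' Simulate an incubation bottle table with known true rates
#'
#' Draws a surface-intensified true volumetric rate profile per station,
#' inverts the tracer rate equation to obtain the final PN atom% each
#' bottle would show, and adds measurement noise on the atom% and PN
#' concentration. Duplicate bottles share the station/depth true rate.
#' The hidden truth is returned alongside, never inside, the bottle
#' table.
#'
#' @param config a [sim_config()].
#' @param true_surface_rates optional per-station surface rates
#'   (nmol N L-1 d-1); by default lognormal around 5.
#' @param decay_scale_m e-folding depth of the rate profile (default
#'   40 m).
#' @return List with `samples` (the bottle table, see
#'   [diazo_schemas()]) and `truth` (station/depth true rates).
#' @export
simulate_incubations <- function(config = sim_config(),
                                 true_surface_rates = NULL,
                                 decay_scale_m = 40) {
  set.seed(config$seed)
  ns <- config$n_stations
  if (is.null(true_surface_rates))
    true_surface_rates <- stats::rlnorm(ns, log(5), 0.5)
  stations <- sprintf("ST%02d", seq_len(ns))

  grid <- expand.grid(replicate = seq_len(config$n_replicates),
                      depth_ix = seq_len(config$n_depths),
                      station_ix = seq_len(ns))
  depth <- config$depths_m[grid$depth_ix]
  true_rate <- true_surface_rates[grid$station_ix] *
    exp(-depth / decay_scale_m)

  n <- nrow(grid)
  a_n2 <- stats::rnorm(n, config$a_n2_mean, config$a_n2_sd)
  # one A_N2 per bottle condition is physical: duplicates share the bag
  cond <- (grid$station_ix - 1L) * config$n_depths + grid$depth_ix
  a_n2 <- a_n2[match(cond, cond)]
  pn_true <- 0.3 * exp(-depth / 150)
  pn_conc <- pn_true * stats::rlnorm(n, -config$pn_cv^2 / 2, config$pn_cv)

  # invert rho = (a_t - a0)/(a_n2 - a0) * pn * 1000 / dt for a_t
  a0 <- config$a_pn_initial
  a_final <- a0 + true_rate * config$duration_d * (a_n2 - a0) /
    (pn_conc * 1000)
  a_final <- a_final + stats::rnorm(n, 0, config$apn_noise_sd)

  samples <- data.frame(
    station = stations[grid$station_ix],
    depth = depth,
    par_level = config$par_levels[grid$depth_ix],
    fraction = "bulk",
    replicate = grid$replicate,
    a_pn_initial = a0,
    a_pn_final = a_final,
    a_n2 = a_n2,
    pn_conc = pn_conc,
    pn_mass = pn_conc * 4.5 * 14.007,   # 4.5 L filtered, ug N
    duration = config$duration_d,
    stringsAsFactors = FALSE)
  truth <- data.frame(
    station = stations[grid$station_ix],
    depth = depth,
    replicate = grid$replicate,
    true_rate = true_rate,
    stringsAsFactors = FALSE)
  truth <- unique(truth[truth$replicate == 1L,
                        c("station", "depth", "true_rate")])
  list(samples = samples, truth = truth)
}

#' Simulate a qPCR plate with standards and unknowns
#'
#' Ct values are generated from a prescribed linear standard curve plus
#' Gaussian replicate noise: `Ct = intercept + slope * log10(copies)`.
#'
#' @param config a [sim_config()] (supplies curve parameters, standard
#'   levels, replicate count and Ct noise).
#' @param true_copies_per_well named numeric vector: true template
#'   copies per well of each unknown sample.
#' @param ct_noise_sd override for the config's Ct noise SD.
#' @return List with `standards` (long table: copies_per_well, ct),
#'   `unknowns` (sample_id, ct replicate columns) and `truth`.
#' @export
simulate_qpcr_plate <- function(config = sim_config(),
                                true_copies_per_well = c(U1 = 1000),
                                ct_noise_sd = NULL) {
  if (any(config$standard_levels <= 0))
    stop("standard copies must be positive", call. = FALSE)
  if (any(true_copies_per_well <= 0))
    stop("unknown true copies must be positive", call. = FALSE)
  if (is.null(ct_noise_sd)) ct_noise_sd <- config$ct_noise_sd
  set.seed(config$seed + 1L)
  nrep <- 3L
  cps <- rep(config$standard_levels, each = nrep)
  ct_std <- config$qpcr_intercept + config$qpcr_slope * log10(cps) +
    stats::rnorm(length(cps), 0, ct_noise_sd)
  standards <- data.frame(copies_per_well = cps, ct = ct_std)

  ct_unk <- vapply(true_copies_per_well, function(cp)
    config$qpcr_intercept + config$qpcr_slope * log10(cp) +
      stats::rnorm(nrep, 0, ct_noise_sd), numeric(nrep))
  unknowns <- data.frame(sample_id = names(true_copies_per_well),
                         ct1 = ct_unk[1, ], ct2 = ct_unk[2, ],
                         ct3 = ct_unk[3, ], stringsAsFactors = FALSE,
                         row.names = NULL)
  list(standards = standards, unknowns = unknowns,
       truth = true_copies_per_well)
}

#' Simulate a global diazotroph niche database
#'
#' Samples covariates uniformly over the configured ranges, evaluates
#' each phylotype's prescribed niche truth, adds Gaussian log10-scale
#' noise, and attaches areal rate observations with measurement-method
#' tags to a configurable fraction of records.
#'
#' @param config a [sim_config()].
#' @param truths list of [niche_truth()] objects (>= 1).
#' @return List with `records` (the analysis-facing database, one row
#'   per station x taxon; see [diazo_schemas()]) and `truth` (the niche
#'   truths plus per-record noiseless log10 abundance).
#' @export
simulate_global_database <- function(config = sim_config(),
                                     truths = list(ucynb_truth())) {
  if (!length(truths)) stop("need at least one niche truth", call. = FALSE)
  set.seed(config$seed + 2L)
  n <- config$n_db_records
  sst <- stats::runif(n, config$sst_range[1], config$sst_range[2])
  dfe <- stats::runif(n, config$dfe_range[1], config$dfe_range[2])
  p <- stats::runif(n, config$p_range[1], config$p_range[2])
  lat <- stats::runif(n, -60, 60)
  lon <- stats::runif(n, -180, 180)

  per_taxon <- lapply(truths, function(tr) {
    mu <- truth_log_abundance(tr, sst, dfe, p)
    log_ab <- mu + stats::rnorm(n, 0, tr$noise_sd)
    has_rate <- stats::runif(n) < config$rate_fraction
    rate <- ifelse(has_rate,
                   stats::rlnorm(n, log(150), 0.6), NA_real_)
    method <- ifelse(has_rate,
                     sample(c("dissolution", "bubble", "ARA"), n,
                            replace = TRUE, prob = c(0.6, 0.25, 0.15)),
                     NA_character_)
    list(records = data.frame(lat = lat, lon = lon, taxon = tr$taxon,
                              nifh_areal = 10^log_ab, sst = sst,
                              dfe = dfe, p = p, rate = rate,
                              method = method, stringsAsFactors = FALSE),
         mu = mu)
  })
  records <- do.call(rbind, lapply(per_taxon, `[[`, "records"))
  rownames(records) <- NULL
  list(records = records,
       truth = list(niches = truths,
                    log10_noiseless = lapply(per_taxon, `[[`, "mu")))
}

#' Simulate monthly gridded environmental climatologies
#'
#' Deterministic smooth fields on a regular grid: SST follows a
#' latitudinal Gaussian with a seasonally migrating thermal equator,
#' dissolved iron a subtropical maximum with a zonal gradient, and
#' phosphate a poleward increase. A synthetic land mask (rectangular
#' continents) is included so missing-value propagation is exercised.
#' The fields are climatologies, not draws: they do not depend on the
#' seed.
#'
#' @param config a [sim_config()] (unused except for interface symmetry).
#' @param nlat,nlon grid size; defaults 180 x 360 (1 degree).
#' @param constant_fields if `TRUE`, every field is spatially and
#'   monthly constant (median of its range) — a degenerate grid for
#'   invariance tests.
#' @return An [env_grid()].
#' @export
simulate_env_grids <- function(config = sim_config(), nlat = 180L,
                               nlon = 360L, constant_fields = FALSE) {
  lat <- seq(-90 + 180 / nlat / 2, 90 - 180 / nlat / 2,
             length.out = nlat)
  lon <- seq(-180 + 360 / nlon / 2, 180 - 360 / nlon / 2,
             length.out = nlon)
  sst <- dfe <- p <- array(NA_real_, c(12L, nlat, nlon))
  latm <- matrix(lat, nlat, nlon)
  lonm <- matrix(lon, nlat, nlon, byrow = TRUE)

  # synthetic continents: three rectangles
  land <- (lonm > -80 & lonm < -35 & latm > -55 & latm < 10) |
    (lonm > -15 & lonm < 50 & latm > -35 & latm < 35) |
    (lonm > 70 & lonm < 140 & latm > 20 & latm < 70)
  mask <- !land

  for (m in 1:12) {
    if (constant_fields) {
      sst[m, , ] <- 27
      dfe[m, , ] <- 0.4
      p[m, , ] <- 0.2
    } else {
      eq <- 8 * sin(2 * pi * (m - 3) / 12)   # migrating thermal equator
      sst[m, , ] <- 29.5 * exp(-((latm - eq) / 32)^2)
      dfe[m, , ] <- 0.05 + 0.9 * exp(-((latm - 15) / 25)^2) *
        (0.6 + 0.4 * cos(pi * lonm / 180))
      p[m, , ] <- 0.03 + 1.4 * (abs(latm) / 90)^1.5 +
        0.1 * cos(2 * pi * (m - 1) / 12) * (abs(latm) / 90)
    }
    sst[m, , ][land] <- NA
    dfe[m, , ][land] <- NA
    p[m, , ][land] <- NA
  }
  env_grid(lat, lon, sst, dfe, p, mask)
}
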