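#' Volumetric N2 fixation rate from a 15N2 dissolution incubation
#'
#' Computes the isotope mass-balance rate for a single incubation bottle:
#' the fractional transfer of 15N tracer into particulate nitrogen (PN),
#' normalized by the labelling of the dissolved N2 source pool, scaled by
#' the PN standing stock and the incubation time,
#' \deqn{\rho = \frac{A_{PN}(t) - A_{PN}(0)}{A_{N_2} - A_{PN}(0)}
#'       \times \frac{[PN]}{\Delta t} \times 1000}
#' with atom% values for the isotopic abundances, `pn_conc` in
#' \eqn{\mu}mol N L\eqn{^{-1}} and `duration` in days, giving a rate in
#' nmol N L\eqn{^{-1}} d\eqn{^{-1}}.
#'
#' A final atom% below the initial one (possible through measurement
#' noise at very low rates) would produce a negative rate; by default such
#' rates are clipped to zero and recorded in the `"clipped"` attribute,
#' since negative fixation is not physically meaningful and must not
#' propagate into depth integrals.
#'
#' @param a_pn_initial atom% 15N of PN at the start of the incubation
#'   (natural abundance is 0.3663 atom%).
#' @param a_pn_final atom% 15N of PN at the end of the incubation.
#' @param a_n2 atom% 15N of the dissolved N2 pool during the incubation
#'   (e.g. 1.41 for bulk, 1.56 for <10 um incubations with the
#'   dissolution method).
#' @param pn_conc particulate nitrogen concentration, umol N L-1.
#' @param duration incubation length, days.
#' @param clip_negative clip negative rates to zero? Default `TRUE`.
#' @return Numeric vector of rates in nmol N L-1 d-1, with a logical
#'   attribute `"clipped"` marking bottles whose negative raw rate was
#'   clipped to zero.
#' @seealso [lod1_rate()], [lod2_rate()], [depth_integrate()]
#' @export
#' @examples
#' n2_fixation_rate(0.3663, 0.3763, 1.41, pn_conc = 0.5, duration = 1)
n2_fixation_rate <- function(a_pn_initial, a_pn_final, a_n2, pn_conc,
                             duration, clip_negative = TRUE) {
  check_atom_pct(a_pn_initial, "a_pn_initial")
  check_atom_pct(a_pn_final, "a_pn_final")
  check_atom_pct(a_n2, "a_n2")
  if (any(a_n2 <= a_pn_initial))
    stop("undefined tracer: a_n2 must exceed a_pn_initial", call. = FALSE)
  if (any(duration <= 0)) stop("duration must be positive", call. = FALSE)
  if (any(pn_conc <= 0)) stop("pn_conc must be positive", call. = FALSE)

  rate <- (a_pn_final - a_pn_initial) / (a_n2 - a_pn_initial) *
    pn_conc / duration * 1000
  clipped <- rate < 0
  if (clip_negative) rate[clipped] <- 0
  attr(rate, "clipped") <- clipped & clip_negative
  rate
}

check_atom_pct <- function(x, name) {
  if (any(!is.finite(x)) || any(x <= 0) || any(x >= 100))
    stop(sprintf("%s must be finite atom%% in (0, 100)", name),
         call. = FALSE)
  invisible(x)
}

#' Minimal detectable atom-percent difference of the mass spectrometer
#'
#' The smallest enrichment of PN that the elemental-analyzer IRMS can
#' resolve, taken as three standard deviations of repeated atom%
#' measurements of N standards at the relevant PN mass.
#'
#' @param sd_standards standard deviation (atom%) of replicate A_PN
#'   measurements of the reference material.
#' @return 3 x `sd_standards`, in atom%.
#' @export
#' @examples
#' min_delta_apn(0.00017)  # 0.00051, i.e. 0.0005 at one significant figure
min_delta_apn <- function(sd_standards) {
  if (any(sd_standards < 0)) stop("sd_standards must be >= 0", call. = FALSE)
  3 * sd_standards
}

#' Instrument-resolution detection limit (LOD-1) for a fixation rate
#'
#' Substitutes the minimal resolvable enrichment `min_da` for the observed
#' PN enrichment in the rate equation, giving the smallest rate the
#' instrument could have detected for this bottle's PN stock, labelling
#' and duration. The generic value 0.00146 atom% is the default.
#'
#' @inheritParams n2_fixation_rate
#' @param min_da minimal detectable A_PN difference, atom%.
#' @return LOD-1 in nmol N L-1 d-1 (linear in `min_da` and `pn_conc`).
#' @export
lod1_rate <- function(a_pn_initial, a_n2, pn_conc, duration,
                      min_da = 0.00146) {
  if (any(min_da < 0)) stop("min_da must be >= 0", call. = FALSE)
  n2_fixation_rate(a_pn_initial, a_pn_initial + min_da, a_n2,
                   pn_conc, duration)
}

#' Replicate-propagated uncertainty and detection limit (LOD-2)
#'
#' First-order (delta-method) propagation of the between-duplicate
#' variability of the final PN atom% and of the PN concentration,
#' together with a fixed uncertainty on the dissolved-N2 labelling,
#' through the rate equation. The detection limit is a multiple
#' (default 3) of the propagated standard deviation, mirroring the
#' 3-sigma convention of [min_delta_apn()].
#'
#' With \eqn{\rho(A_t, A_{N_2}, P)} the rate equation evaluated at the
#' duplicate means, the propagated variance is
#' \deqn{\sigma_\rho^2 =
#'   \left(\frac{\partial\rho}{\partial A_t}\right)^2 s_{A_t}^2 +
#'   \left(\frac{\partial\rho}{\partial A_{N_2}}\right)^2 s_{A_{N_2}}^2 +
#'   \left(\frac{\partial\rho}{\partial P}\right)^2 s_P^2.}
#'
#' @param a_pn_final_dup length-2 numeric: final PN atom% of the two
#'   duplicate bottles.
#' @param pn_conc_dup length-2 numeric: PN concentrations (umol N L-1) of
#'   the duplicates.
#' @param a_pn_initial shared initial PN atom%.
#' @param a_n2 shared dissolved-N2 atom% (duplicate mean if measured).
#' @param duration incubation length, days.
#' @param sd_a_n2 standard deviation of the N2-pool atom%; default 0.083,
#'   the observed variability of MIMS-measured enrichment across bulk
#'   incubations.
#' @param multiplier LOD-2 = `multiplier` x propagated sd; default 3.
#' @return List with `sd` (propagated rate sd, nmol N L-1 d-1) and
#'   `lod2`.
#' @export
lod2_rate <- function(a_pn_final_dup, pn_conc_dup, a_pn_initial, a_n2,
                      duration, sd_a_n2 = 0.083, multiplier = 3) {
  if (length(a_pn_final_dup) != 2L || length(pn_conc_dup) != 2L)
    stop("lod2_rate requires exactly two duplicate bottles", call. = FALSE)
  if (sd_a_n2 < 0) stop("sd_a_n2 must be >= 0", call. = FALSE)
  a_t <- mean(a_pn_final_dup)
  p <- mean(pn_conc_dup)
  s_at <- stats::sd(a_pn_final_dup)
  s_p <- stats::sd(pn_conc_dup)
  denom <- a_n2 - a_pn_initial
  if (denom <= 0)
    stop("undefined tracer: a_n2 must exceed a_pn_initial", call. = FALSE)

  # partial derivatives of rho = (a_t - a0)/(a_n2 - a0) * p * 1000 / dt
  d_at <- p * 1000 / (duration * denom)
  d_an2 <- -(a_t - a_pn_initial) * p * 1000 / (duration * denom^2)
  d_p <- (a_t - a_pn_initial) * 1000 / (duration * denom)

  v <- d_at^2 * s_at^2 + d_an2^2 * sd_a_n2^2 + d_p^2 * s_p^2
  sd_rate <- sqrt(v)
  list(sd = sd_rate, lod2 = multiplier * sd_rate)
}

#' Trapezoidal depth integration of a volumetric profile
#'
#' Integrates a profile of volumetric values over depth by the trapezoid
#' rule. The shallowest measured value is extended unchanged to the
#' surface (0 m) and the integral is truncated at the deepest sampled
#' depth. For fixation rates in nmol N L-1 d-1 (= umol N m-3 d-1) the
#' result is in umol N m-2 d-1 with no further conversion.
#'
#' @param depth sampling depths in m (any order; must be distinct).
#' @param value volumetric values at those depths.
#' @param extend_surface extend the shallowest value to 0 m? Default TRUE.
#' @return The depth integral (value units x m).
#' @export
#' @examples
#' depth_integrate(c(5, 100), c(1, 1))   # 100
depth_integrate <- function(depth, value, extend_surface = TRUE) {
  if (length(depth) != length(value))
    stop("depth and value lengths differ", call. = FALSE)
  if (length(depth) < 2L)
    stop("need at least two depths to integrate", call. = FALSE)
  if (anyDuplicated(depth))
    stop("duplicate depths in profile", call. = FALSE)
  ord <- order(depth)
  d <- depth[ord]
  v <- value[ord]
  if (extend_surface && d[1] > 0) {
    d <- c(0, d)
    v <- c(v[1], v)
  }
  n <- length(d)
  sum(diff(d) * (v[-1] + v[-n]) / 2)
}

#' Per-bottle rates, detection limits and flags for an incubation table
#'
#' Applies [n2_fixation_rate()], [lod1_rate()] and (where duplicates
#' exist) [lod2_rate()] to a table of incubation bottles, aggregating
#' duplicates of the same station/depth/fraction condition.
#'
#' Bottles with a PN mass below `pn_mass_gate` (default 10 ug) are flagged
#' `low_pn_mass` but kept: small filter loads degrade the atom%
#' precision but do not invalidate the rate. Missing `a_pn_initial`
#' values fall back to `default_a_pn_initial` (natural abundance).
#'
#' @param bottles data.frame with columns `station`, `depth`, `fraction`,
#'   `a_pn_initial`, `a_pn_final`, `a_n2`, `pn_conc`, `pn_mass`,
#'   `duration`, `replicate` (see [diazo_schemas()]).
#' @param min_da minimal detectable A_PN difference for LOD-1.
#' @param sd_a_n2 fixed N2-pool atom% sd for LOD-2 propagation.
#' @param lod2_multiplier multiplier on the propagated sd.
#' @param pn_mass_gate low-PN-mass flag threshold, ug N.
#' @param default_a_pn_initial substitute when `a_pn_initial` is `NA`.
#' @return data.frame with one row per station/depth/fraction condition:
#'   mean rate, between-duplicate sd, `lod1`, `lod2`, and `flag` in
#'   `ok`, `below_lod1`, `below_lod2`; plus `low_pn_mass`.
#' @export
rate_table <- function(bottles, min_da = 0.00146, sd_a_n2 = 0.083,
                       lod2_multiplier = 3, pn_mass_gate = 10,
                       default_a_pn_initial = 0.3663) {
  required <- c("station", "depth", "fraction", "a_pn_initial",
                "a_pn_final", "a_n2", "pn_conc", "pn_mass", "duration")
  missing_cols <- setdiff(required, names(bottles))
  if (length(missing_cols))
    stop("bottles table lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)

  bottles$a_pn_initial[is.na(bottles$a_pn_initial)] <- default_a_pn_initial
  key <- interaction(bottles$station, bottles$depth, bottles$fraction,
                     drop = TRUE)
  out <- lapply(split(bottles, key), function(b) {
    r <- n2_fixation_rate(b$a_pn_initial, b$a_pn_final, b$a_n2,
                          b$pn_conc, b$duration)
    lod1 <- mean(lod1_rate(b$a_pn_initial, b$a_n2, b$pn_conc, b$duration,
                           min_da = min_da))
    if (nrow(b) == 2L) {
      prop <- lod2_rate(b$a_pn_final, b$pn_conc, mean(b$a_pn_initial),
                        mean(b$a_n2), mean(b$duration),
                        sd_a_n2 = sd_a_n2, multiplier = lod2_multiplier)
      sd_rate <- prop$sd
      lod2 <- prop$lod2
    } else {
      sd_rate <- NA_real_
      lod2 <- NA_real_
    }
    rate <- mean(r)
    flag <- if (rate < lod1) "below_lod1"
            else if (!is.na(lod2) && rate < lod2) "below_lod2"
            else "ok"
    data.frame(station = b$station[1], depth = b$depth[1],
               fraction = b$fraction[1], n_bottles = nrow(b),
               rate = rate, sd = sd_rate, lod1 = lod1, lod2 = lod2,
               flag = flag,
               low_pn_mass = any(b$pn_mass < pn_mass_gate),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$station, res$fraction, res$depth), , drop = FALSE]
}

#' Depth-integrated areal rates per station
#'
#' Trapezoid-integrates the per-depth rates of [rate_table()] output into
#' areal rates (umol N m-2 d-1), station by station and fraction by
#' fraction. Rates flagged below LOD-1 enter as zero.
#'
#' @param rates data.frame from [rate_table()].
#' @return data.frame with `station`, `fraction`, `areal_rate`
#'   (umol N m-2 d-1) and `n_depths`.
#' @export
integrate_rate_profiles <- function(rates) {
  key <- interaction(rates$station, rates$fraction, drop = TRUE)
  out <- lapply(split(rates, key), function(p) {
    v <- ifelse(p$flag == "below_lod1", 0, p$rate)
    data.frame(station = p$station[1], fraction = p$fraction[1],
               areal_rate = depth_integrate(p$depth, v),
               n_depths = nrow(p), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
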