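#' Fit a qPCR standard curve
#'
#' Ordinary least squares of mean threshold cycle (Ct) on log10 template
#' copies per well, over a dilution series of plasmid standards.
#' Amplification efficiency follows from the slope as
#' \eqn{E = (10^{-1/slope} - 1) \times 100%}; a slope of -3.3219
#' (= -1/log10(2)) corresponds to perfect doubling, i.e. 100%.
#'
#' @param copies_per_well template copies per well for each standard
#'   reaction (replicates repeated); must be positive and span at least
#'   three dilution levels.
#' @param ct observed Ct for each reaction, aligned with
#'   `copies_per_well`. `NA` marks non-amplified wells and is dropped.
#' @return An object of class `standard_curve`: list with `slope`,
#'   `intercept` (Ct at 1 copy per well), `efficiency` (%), `r_squared`,
#'   `n_levels`, and the level means used for the fit.
#' @export
#' @examples
#' cps <- rep(10^(1:5), each = 3)
#' ct <- 38 - 3.3219 * log10(cps)
#' fit_standard_curve(cps, ct)
fit_standard_curve <- function(copies_per_well, ct) {
  if (length(copies_per_well) != length(ct))
    stop("copies_per_well and ct lengths differ", call. = FALSE)
  keep <- !is.na(ct)
  copies_per_well <- copies_per_well[keep]
  ct <- ct[keep]
  if (any(copies_per_well <= 0))
    stop("standard copies must be positive", call. = FALSE)
  if (any(ct <= 0)) stop("Ct values must be positive", call. = FALSE)

  lc <- log10(copies_per_well)
  mean_ct <- tapply(ct, lc, mean)
  x <- as.numeric(names(mean_ct))
  y <- as.numeric(mean_ct)
  if (length(x) < 3L)
    stop("need standards at >= 3 dilution levels", call. = FALSE)

  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope)) stop("singular standard-curve fit", call. = FALSE)
  if (slope >= 0)
    stop("assay failure: standard-curve slope must be negative",
         call. = FALSE)
  # direct R^2: summary.lm warns on a numerically perfect dilution series
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
  structure(
    list(slope = slope,
         intercept = unname(stats::coef(fit)[1]),
         efficiency = qpcr_efficiency(slope),
         r_squared = r2,
         n_levels = length(x),
         level_log10_copies = x,
         level_mean_ct = y),
    class = "standard_curve")
}

#' Amplification efficiency implied by a standard-curve slope
#'
#' @param slope Ct change per log10 copies (negative).
#' @return Efficiency in percent; 100 at slope -1/log10(2).
#' @export
qpcr_efficiency <- function(slope) {
  if (any(slope >= 0)) stop("slope must be negative", call. = FALSE)
  (10^(-1 / slope) - 1) * 100
}

#' @export
print.standard_curve <- function(x, ...) {
  cat("qPCR standard curve\n")
  cat(sprintf("  Ct = %.3f %+.4f x log10(copies/well)\n",
              x$intercept, x$slope))
  cat(sprintf("  efficiency %.1f%%, R^2 = %.4f, %d dilution levels\n",
              x$efficiency, x$r_squared, x$n_levels))
  invisible(x)
}

#' Absolute quantification of an unknown from its Ct replicates
#'
#' Inverts a fitted standard curve for a triplicate of Ct values and
#' converts copies per well to copies per liter of seawater filtered:
#' `copies/L = 10^((mean Ct - intercept)/slope) * scaling / volume_l`.
#'
#' Non-amplified wells (`NA` Ct) are dropped before averaging. If no well
#' amplified, the result is 0 copies per liter flagged `<LOD`. Results
#' below `loq` copies per liter are flagged `<LOQ`, below `lod` copies
#' per liter `<LOD`; a single amplified well is never rated better than
#' `<LOQ` because the replicate criterion is not met.
#'
#' @param ct numeric vector of replicate Ct values (typically 3), `NA`
#'   for no amplification.
#' @param curve a [fit_standard_curve()] object.
#' @param volume_l seawater volume filtered, liters.
#' @param scaling copies-per-well to copies-per-sample factor: elution
#'   volume divided by template volume per reaction. No default: the
#'   conversion is meaningless without it.
#' @param lod,loq detection and quantification limits, copies per liter;
#'   defaults 25 and 250.
#' @return data.frame with `copies_per_l`, `flag` (`ok`, `<LOQ`, `<LOD`)
#'   and `n_amplified`.
#' @export
quantify <- function(ct, curve, volume_l, scaling, lod = 25, loq = 250) {
  stopifnot(inherits(curve, "standard_curve"))
  if (volume_l <= 0) stop("volume_l must be positive", call. = FALSE)
  if (scaling <= 0) stop("scaling must be positive", call. = FALSE)
  n_amp <- sum(!is.na(ct))
  if (n_amp == 0L) {
    return(data.frame(copies_per_l = 0, flag = "<LOD", n_amplified = 0L,
                      stringsAsFactors = FALSE))
  }
  mean_ct <- mean(ct, na.rm = TRUE)
  copies_well <- 10^((mean_ct - curve$intercept) / curve$slope)
  copies_l <- copies_well * scaling / volume_l
  flag <- if (copies_l < lod) "<LOD"
          else if (copies_l < loq || n_amp < 2L) "<LOQ"
          else "ok"
  data.frame(copies_per_l = copies_l, flag = flag, n_amplified = n_amp,
             stringsAsFactors = FALSE)
}

#' Depth-integrated nifH gene abundance
#'
#' Trapezoid integration of a copies-per-liter profile into copies per
#' square meter (1 copy L-1 = 1000 copies m-3), with the same edge rules
#' as [depth_integrate()]: surface extension of the shallowest value and
#' truncation at the deepest sampled depth.
#'
#' Values flagged `<LOD` enter the integral as `lod_substitution`
#' (default 0); `<LOQ` values enter at face value. Both behaviours
#' follow from the detection/quantification semantics: below the LOD
#' nothing can be asserted, between LOD and LOQ the estimate is noisy but
#' unbiased.
#'
#' @param depth sampling depths, m.
#' @param copies_per_l nifH copies per liter at those depths.
#' @param flag optional character vector of qc flags (`ok`, `<LOQ`,
#'   `<LOD`).
#' @param lod_substitution value (copies per liter) substituted for
#'   `<LOD` entries.
#' @return Depth-integrated abundance, copies m-2.
#' @export
#' @examples
#' depth_integrate_nifh(c(0, 100), c(1e3, 1e3))  # 1e8 copies m-2
depth_integrate_nifh <- function(depth, copies_per_l, flag = NULL,
                                 lod_substitution = 0) {
  if (any(copies_per_l < 0)) stop("copies must be >= 0", call. = FALSE)
  v <- copies_per_l
  if (!is.null(flag)) v[flag == "<LOD"] <- lod_substitution
  depth_integrate(depth, v * 1000)
}

#' Community composition shares from per-taxon abundances
#'
#' @param abundances named non-negative numeric vector, one entry per
#'   phylotype.
#' @return Vector of fractions summing to 1. If every abundance is zero
#'   the shares are undefined: all-`NA` with attribute
#'   `undefined = TRUE`.
#' @export
#' @examples
#' community_shares(c(UCYN_B = 3e8, Trichodesmium = 6e7, UCYN_A = 4e7))
community_shares <- function(abundances) {
  if (length(abundances) == 0L)
    stop("need at least one abundance", call. = FALSE)
  if (any(abundances < 0))
    stop("abundances must be non-negative", call. = FALSE)
  total <- sum(abundances)
  if (total == 0) {
    out <- rep(NA_real_, length(abundances))
    names(out) <- names(abundances)
    attr(out, "undefined") <- TRUE
    return(out)
  }
  abundances / total
}
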