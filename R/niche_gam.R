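#' Fit an ecological niche model for a diazotroph phylotype
#'
#' Models log10 depth-integrated nifH gene abundance as an additive
#' Gaussian function of sea-surface temperature, dissolved iron and
#' phosphate,
#' \deqn{\log_{10} N \sim s(SST) + s(dFe) + s(P),}
#' with one univariate penalized cubic regression spline per covariate,
#' fitted with \pkg{mgcv}. Smoothing parameters are selected by REML by
#' default (GCV available). This is the niche form used throughout the
#' package to project diazotroph biogeography from environmental fields.
#'
#' Records with zero (non-detect) abundance have no defined log10
#' response. By default they are dropped before fitting
#' (`zero_handling = "drop"`); alternatively they are floored at a
#' detection-limit abundance (`zero_handling = "floor"` with
#' `floor_value`), which keeps absences in the fit at the price of a
#' substitution artefact.
#'
#' @param data data.frame of station records with an abundance column
#'   `nifh_areal` (copies m-2) and the covariate columns; see
#'   [diazo_schemas()] for the database layout.
#' @param taxon optional phylotype name; if given and `data` has a
#'   `taxon` column, the data are filtered to it.
#' @param covariates names of the covariate columns; default
#'   `c("sst", "dfe", "p")`.
#' @param k basis dimension of each smooth (default 6).
#' @param bs spline basis (default `"cr"`, cubic regression).
#' @param method smoothing-parameter selection: `"REML"` (default) or
#'   `"GCV.Cp"`.
#' @param zero_handling `"drop"` (default) or `"floor"`.
#' @param floor_value abundance substituted for zeros when flooring.
#' @param min_records minimum usable records (default 50).
#' @return An object of class `niche_gam`: the mgcv fit plus the taxon,
#'   covariate hull (ranges and medians of the training data), `n_used`,
#'   `r_squared` (adjusted) and `deviance_explained` (%). Supports
#'   [print()], [summary()], [coef()], [predict()][predict.niche_gam],
#'   [plot()][plot.niche_gam], [residuals()], [fitted()] and
#'   [simulate()][simulate.niche_gam].
#' @seealso [partial_response()], [project_taxon()]
#' @export
niche_gam <- function(data, taxon = NULL,
                      covariates = c("sst", "dfe", "p"),
                      k = 6, bs = "cr", method = c("REML", "GCV.Cp"),
                      zero_handling = c("drop", "floor"),
                      floor_value = NULL, min_records = 50) {
  method <- match.arg(method)
  zero_handling <- match.arg(zero_handling)
  if (!is.null(taxon) && "taxon" %in% names(data))
    data <- data[data$taxon == taxon, , drop = FALSE]
  missing_cols <- setdiff(c("nifh_areal", covariates), names(data))
  if (length(missing_cols))
    stop("data lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)

  keep <- stats::complete.cases(data[, c("nifh_areal", covariates)])
  data <- data[keep, , drop = FALSE]
  if (any(data$nifh_areal < 0))
    stop("negative abundances", call. = FALSE)
  zero <- data$nifh_areal == 0
  n_zero <- sum(zero)
  if (zero_handling == "drop") {
    data <- data[!zero, , drop = FALSE]
  } else {
    if (is.null(floor_value) || floor_value <= 0)
      stop("zero_handling = 'floor' needs a positive floor_value",
           call. = FALSE)
    data$nifh_areal[zero] <- floor_value
  }
  if (nrow(data) < min_records)
    stop(sprintf("only %d usable records (< %d)", nrow(data), min_records),
         call. = FALSE)
  if (all(data$nifh_areal == data$nifh_areal[1]))
    stop("constant response: nothing to fit", call. = FALSE)

  data$.log10_abund <- log10(data$nifh_areal)
  terms <- sprintf("s(%s, bs = \"%s\", k = %d)", covariates, bs, k)
  fml <- stats::as.formula(paste(".log10_abund ~",
                                 paste(terms, collapse = " + ")))
  fit <- mgcv::gam(fml, data = data, method = method)
  sm <- summary(fit)

  hull <- lapply(covariates, function(cv)
    list(range = range(data[[cv]]), median = stats::median(data[[cv]]),
         values = data[[cv]]))
  names(hull) <- covariates

  structure(
    list(fit = fit, taxon = taxon, covariates = covariates,
         k = k, bs = bs, method = method,
         zero_handling = zero_handling, n_zero_dropped = n_zero,
         hull = hull, n_used = nrow(data),
         r_squared = unname(sm$r.sq),
         deviance_explained = unname(sm$dev.expl) * 100,
         p_values = sm$s.table[, "p-value"],
         call = match.call()),
    class = "niche_gam")
}

#' @export
print.niche_gam <- function(x, ...) {
  cat("Diazotroph niche GAM",
      if (!is.null(x$taxon)) paste0("for ", x$taxon), "\n")
  cat(sprintf("  log10(nifH m^-2) ~ %s\n",
              paste(sprintf("s(%s)", x$covariates), collapse = " + ")))
  cat(sprintf("  n = %d, adj. R^2 = %.3f, deviance explained = %.1f%%\n",
              x$n_used, x$r_squared, x$deviance_explained))
  invisible(x)
}

#' @export
summary.niche_gam <- function(object, ...) {
  out <- list(model = object, mgcv = summary(object$fit))
  class(out) <- "summary.niche_gam"
  out
}

#' @export
print.summary.niche_gam <- function(x, ...) {
  print(x$model)
  cat("\nSmooth terms (mgcv):\n")
  stats::printCoefmat(x$mgcv$s.table, has.Pvalue = TRUE)
  invisible(x)
}

#' @export
coef.niche_gam <- function(object, ...) stats::coef(object$fit)

#' @export
fitted.niche_gam <- function(object, ...) stats::fitted(object$fit)

#' @export
residuals.niche_gam <- function(object, ...)
  stats::residuals(object$fit, ...)

#' Predict log10 nifH abundance from a fitted niche model
#'
#' Additive prediction on the log10 copies m-2 scale. Covariate values
#' outside the training hull are, by default, clamped to the hull
#' boundary (so the smooths are never evaluated beyond the data) and
#' marked in the `"extrapolated"` attribute. Free spline extrapolation is
#' available with `clamp = FALSE` but is unsafe for projection.
#'
#' @param object a [niche_gam()] fit.
#' @param newdata data.frame with the model's covariate columns.
#' @param clamp clamp out-of-hull covariates to the hull boundary?
#' @param se.fit also return pointwise standard errors?
#' @param ... unused.
#' @return Numeric vector of predicted log10 copies m-2 (or a list with
#'   `fit` and `se.fit`), with logical attribute `"extrapolated"`.
#' @export
predict.niche_gam <- function(object, newdata, clamp = TRUE,
                              se.fit = FALSE, ...) {
  missing_cols <- setdiff(object$covariates, names(newdata))
  if (length(missing_cols))
    stop("newdata lacks covariates: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  extrap <- rep(FALSE, nrow(newdata))
  for (cv in object$covariates) {
    r <- object$hull[[cv]]$range
    x <- newdata[[cv]]
    if (any(!is.finite(x)))
      stop("non-finite covariate values in newdata", call. = FALSE)
    out <- x < r[1] | x > r[2]
    extrap <- extrap | out
    if (clamp) newdata[[cv]] <- pmin(pmax(x, r[1]), r[2])
  }
  pred <- mgcv::predict.gam(object$fit, newdata = newdata,
                            se.fit = se.fit)
  if (se.fit) {
    pred$fit <- as.numeric(pred$fit)
    pred$se.fit <- as.numeric(pred$se.fit)
    attr(pred$fit, "extrapolated") <- extrap
  } else {
    pred <- as.numeric(pred)
    attr(pred, "extrapolated") <- extrap
  }
  pred
}

#' @export
simulate.niche_gam <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- stats::fitted(object$fit)
  sigma <- sqrt(object$fit$sig2)
  out <- as.data.frame(
    replicate(nsim, stats::rnorm(length(mu), mu, sigma)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Partial response curve of one covariate
#'
#' The centered additive contribution of one covariate's smooth to log10
#' abundance, evaluated on a grid across the training range with the
#' other covariates held at their training medians, together with a
#' pointwise confidence band from the Bayesian posterior covariance of
#' the spline coefficients.
#'
#' @param object a [niche_gam()] fit.
#' @param covariate one of the model's covariate names.
#' @param n_grid grid resolution (default 100).
#' @param level confidence level for the band (default 0.95).
#' @return A data.frame of class `response_curve` with columns `x`,
#'   `effect`, `lower`, `upper`; attributes `covariate`, `taxon` and
#'   `rug` (the observed covariate values).
#' @export
partial_response <- function(object, covariate, n_grid = 100,
                             level = 0.95) {
  stopifnot(inherits(object, "niche_gam"))
  if (!covariate %in% object$covariates)
    stop("unknown covariate: ", covariate, call. = FALSE)
  r <- object$hull[[covariate]]$range
  nd <- data.frame(x = seq(r[1], r[2], length.out = n_grid))
  names(nd) <- covariate
  for (cv in setdiff(object$covariates, covariate))
    nd[[cv]] <- object$hull[[cv]]$median
  tm <- mgcv::predict.gam(object$fit, newdata = nd, type = "terms",
                          se.fit = TRUE)
  col <- grep(sprintf("s\\(%s\\)", covariate), colnames(tm$fit))
  if (length(col) != 1L)
    stop("could not locate smooth term for ", covariate, call. = FALSE)
  z <- stats::qnorm(1 - (1 - level) / 2)
  eff <- tm$fit[, col]
  se <- tm$se.fit[, col]
  out <- data.frame(x = nd[[covariate]], effect = eff,
                    lower = eff - z * se, upper = eff + z * se)
  attr(out, "covariate") <- covariate
  attr(out, "taxon") <- object$taxon
  attr(out, "rug") <- object$hull[[covariate]]$values
  class(out) <- c("response_curve", "data.frame")
  out
}

#' @export
plot.niche_gam <- function(x, n_grid = 100, ...) {
  p <- length(x$covariates)
  old <- graphics::par(mfrow = c(1, p))
  on.exit(graphics::par(old))
  for (cv in x$covariates) {
    rc <- partial_response(x, cv, n_grid = n_grid)
    graphics::plot(rc$x, rc$effect, type = "l",
                   ylim = range(rc$lower, rc$upper),
                   xlab = cv, ylab = "partial effect (log10 copies m^-2)",
                   main = if (!is.null(x$taxon)) x$taxon else "", ...)
    graphics::lines(rc$x, rc$lower, lty = 2)
    graphics::lines(rc$x, rc$upper, lty = 2)
    graphics::rug(attr(rc, "rug"))
    graphics::abline(h = 0, col = "grey")
  }
  invisible(x)
}
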