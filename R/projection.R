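#' Construct a gridded monthly environmental field set
#'
#' Container for monthly sea-surface temperature, dissolved iron and
#' phosphate climatologies on a regular lat/lon grid (1 degree in the
#' global default), with a common land/missing mask.
#'
#' @param lat,lon cell-center coordinates, degrees; lon in -180..180.
#' @param sst,dfe,p arrays of dimension (12, length(lat), length(lon)):
#'   SST degC, dissolved Fe nM, phosphate uM.
#' @param mask logical matrix (lat x lon), `TRUE` for ocean cells.
#' @return Object of class `env_grid`.
#' @export
env_grid <- function(lat, lon, sst, dfe, p, mask) {
  dims <- c(12L, length(lat), length(lon))
  for (nm in c("sst", "dfe", "p")) {
    a <- get(nm)
    if (!identical(dim(a), dims))
      stop(sprintf("%s must have dim (12, nlat, nlon)", nm), call. = FALSE)
  }
  if (!identical(dim(mask), dims[2:3]))
    stop("mask must be nlat x nlon", call. = FALSE)
  if (any(lon < -180 | lon > 180))
    stop("lon centers must lie in -180..180", call. = FALSE)
  structure(list(lat = lat, lon = lon, sst = sst, dfe = dfe, p = p,
                 mask = mask),
            class = "env_grid")
}

#' @export
print.env_grid <- function(x, ...) {
  cat(sprintf("env_grid: 12 months x %d lat x %d lon, %d ocean cells\n",
              length(x$lat), length(x$lon), sum(x$mask)))
  invisible(x)
}

#' Project a fitted niche onto gridded environmental fields
#'
#' Predicts log10 nifH abundance cell-by-cell for each month from a
#' fitted [niche_gam()], back-transforms to copies m-2, and annualizes.
#' The default annualization averages the 12 monthly abundances in
#' linear space, since abundance (not its logarithm) is the mapped and
#' budgeted quantity; geometric (log-space) averaging is available.
#' Out-of-hull covariates are clamped by [predict.niche_gam()] and the
#' cells flagged.
#'
#' @param fit a [niche_gam()] object.
#' @param env an [env_grid()].
#' @param annualize `"linear"` (default) or `"log"`.
#' @return Object of class `abundance_map`: `lat`, `lon`, `abundance`
#'   matrix (copies m-2, `NA` over land), `extrapolated` logical matrix
#'   (any month clamped), `monthly` array (12 x nlat x nlon), `taxon`.
#' @export
project_taxon <- function(fit, env, annualize = c("linear", "log")) {
  stopifnot(inherits(fit, "niche_gam"), inherits(env, "env_grid"))
  annualize <- match.arg(annualize)
  missing_cov <- setdiff(fit$covariates, c("sst", "dfe", "p"))
  if (length(missing_cov))
    stop("env grids lack covariate fields: ",
         paste(missing_cov, collapse = ", "), call. = FALSE)
  nlat <- length(env$lat); nlon <- length(env$lon)
  ocean <- which(env$mask)
  monthly <- array(NA_real_, c(12L, nlat, nlon))
  extrap <- matrix(FALSE, nlat, nlon)
  for (m in 1:12) {
    nd <- data.frame(sst = env$sst[m, , ][ocean],
                     dfe = env$dfe[m, , ][ocean],
                     p = env$p[m, , ][ocean])
    pr <- predict(fit, nd)
    slice <- matrix(NA_real_, nlat, nlon)
    slice[ocean] <- 10^as.numeric(pr)
    monthly[m, , ] <- slice
    ex <- matrix(FALSE, nlat, nlon)
    ex[ocean] <- attr(pr, "extrapolated")
    extrap <- extrap | ex
  }
  ann <- if (annualize == "linear") apply(monthly, c(2, 3), mean)
         else 10^apply(log10(monthly), c(2, 3), mean)
  structure(list(taxon = fit$taxon, lat = env$lat, lon = env$lon,
                 abundance = ann, extrapolated = extrap,
                 monthly = monthly, annualize = annualize),
            class = "abundance_map")
}

#' @export
print.abundance_map <- function(x, ...) {
  cat(sprintf("abundance_map%s: %d x %d, ocean median %.3g copies m^-2\n",
              if (!is.null(x$taxon)) paste0(" (", x$taxon, ")") else "",
              length(x$lat), length(x$lon),
              stats::median(x$abundance, na.rm = TRUE)))
  invisible(x)
}

#' Classify taxon-dominance regions from projected abundance maps
#'
#' A cell is assigned to taxon t iff t's share of the summed abundance
#' strictly exceeds `share_threshold` and the summed abundance strictly
#' exceeds `abundance_threshold`; otherwise `"none"`. Both inequalities
#' are strict, matching the ">75%" / ">10^x copies m^-2" definitions.
#' Two abundance-floor presets are kept: `"dominance-map"` (10^4 copies
#' m-2, the global dominance cartography) and `"hotspot"` (10^8 copies
#' m-2, the high-fixation region delineation).
#'
#' @param maps named list of [project_taxon()] maps on one common grid
#'   (typically the four surveyed phylotypes).
#' @param share_threshold dominance share cut, default 0.75.
#' @param abundance_threshold total-abundance floor, copies m-2; default
#'   taken from `preset`.
#' @param preset `"dominance-map"` (1e4) or `"hotspot"` (1e8).
#' @return Object of class `dominance_mask`: `taxon` character matrix
#'   (`NA` over land, `"none"` where no taxon qualifies), `total`
#'   abundance matrix, grid coordinates and the thresholds used.
#' @export
dominance <- function(maps, share_threshold = 0.75,
                      abundance_threshold = NULL,
                      preset = c("dominance-map", "hotspot")) {
  preset <- match.arg(preset)
  if (is.null(abundance_threshold))
    abundance_threshold <- switch(preset, "dominance-map" = 1e4,
                                  "hotspot" = 1e8)
  if (length(maps) < 1L) stop("need at least one map", call. = FALSE)
  if (is.null(names(maps)) || any(!nzchar(names(maps))))
    stop("maps must be a named list", call. = FALSE)
  ref <- maps[[1]]
  for (m in maps) {
    if (!identical(m$lat, ref$lat) || !identical(m$lon, ref$lon))
      stop("maps are not on a common grid", call. = FALSE)
  }
  ab <- vapply(maps, function(m) m$abundance,
               matrix(0, length(ref$lat), length(ref$lon)))
  total <- apply(ab, c(1, 2), sum)
  winner_ix <- apply(ab, c(1, 2), function(v)
    if (all(is.na(v))) NA_integer_ else which.max(v))
  winner_share <- apply(ab, c(1, 2), function(v)
    if (all(is.na(v))) NA_real_ else max(v)) / total

  taxon <- matrix(NA_character_, length(ref$lat), length(ref$lon))
  ocean <- !is.na(total)
  taxon[ocean] <- "none"
  qual <- ocean & winner_share > share_threshold &
    total > abundance_threshold
  qual[is.na(qual)] <- FALSE
  taxon[qual] <- names(maps)[winner_ix[qual]]
  structure(list(taxon = taxon, total = total,
                 lat = ref$lat, lon = ref$lon,
                 share_threshold = share_threshold,
                 abundance_threshold = abundance_threshold),
            class = "dominance_mask")
}

#' @export
print.dominance_mask <- function(x, ...) {
  tab <- table(x$taxon)
  cat(sprintf("dominance_mask (share > %g, total > %g copies m^-2)\n",
              x$share_threshold, x$abundance_threshold))
  print(tab)
  invisible(x)
}

#' Spherical grid-cell areas by latitude band
#'
#' Area of a lat/lon cell on a sphere of radius `radius_km`:
#' \eqn{A = R^2 \Delta\lambda (\sin\phi_2 - \sin\phi_1)} with cell edges
#' at +/- half a cell width around the center. The global sum over a
#' full grid is 4 pi R^2 exactly (to rounding).
#'
#' @param lat cell-center latitudes, degrees.
#' @param dlat,dlon cell sizes in degrees (default 1).
#' @param radius_km sphere radius; default 6371 km.
#' @return Vector of areas in km^2, one per latitude.
#' @export
cell_areas <- function(lat, dlat = 1, dlon = 1, radius_km = 6371) {
  phi1 <- (lat - dlat / 2) * pi / 180
  phi2 <- (lat + dlat / 2) * pi / 180
  radius_km^2 * (dlon * pi / 180) * (sin(phi2) - sin(phi1))
}

#' Connected hotspot regions of a dominance mask
#'
#' Labels the connected components (8-connectivity, with wrap across the
#' antimeridian but not over the poles) of cells that pass the dominance
#' classification — optionally restricted to one taxon and to cells where
#' `rate_mask` is `TRUE` (e.g. predicted areal fixation above
#' 100 umol N m-2 d-1) — and reports the area of each component from
#' latitude-weighted spherical cell areas.
#'
#' @param mask a [dominance()] object.
#' @param taxon restrict to this taxon's cells (default: any taxon,
#'   i.e. every cell not `"none"`).
#' @param rate_mask optional logical matrix on the same grid; only cells
#'   that are `TRUE` qualify.
#' @param dlat,dlon,radius_km passed to [cell_areas()].
#' @return data.frame with one row per region: `region`, `taxon`
#'   (majority taxon of the component), `n_cells`, `area_1e6_km2`;
#'   the integer label matrix is attached as attribute `"labels"`.
#'   Zero rows when no cell qualifies.
#' @export
hotspot_regions <- function(mask, taxon = NULL, rate_mask = NULL,
                            dlat = 1, dlon = 1, radius_km = 6371) {
  stopifnot(inherits(mask, "dominance_mask"))
  qual <- !is.na(mask$taxon) & mask$taxon != "none"
  if (!is.null(taxon)) qual <- qual & mask$taxon == taxon
  if (!is.null(rate_mask)) {
    if (!identical(dim(rate_mask), dim(mask$taxon)))
      stop("rate_mask grid mismatch", call. = FALSE)
    qual <- qual & rate_mask & !is.na(rate_mask)
  }
  nlat <- nrow(qual); nlon <- ncol(qual)
  labels <- matrix(0L, nlat, nlon)
  current <- 0L
  area_by_lat <- cell_areas(mask$lat, dlat, dlon, radius_km)

  for (start in which(qual & labels == 0L)) {
    if (labels[start] != 0L) next
    current <- current + 1L
    queue <- start
    labels[start] <- current
    while (length(queue)) {
      cell <- queue[length(queue)]
      queue <- queue[-length(queue)]
      i <- (cell - 1L) %% nlat + 1L
      j <- (cell - 1L) %/% nlat + 1L
      for (di in -1:1) for (dj in -1:1) {
        if (di == 0L && dj == 0L) next
        ii <- i + di
        if (ii < 1L || ii > nlat) next        # no wrap over poles
        jj <- (j + dj - 1L) %% nlon + 1L       # antimeridian wrap
        nb <- (jj - 1L) * nlat + ii
        if (qual[nb] && labels[nb] == 0L) {
          labels[nb] <- current
          queue <- c(queue, nb)
        }
      }
    }
  }

  if (current == 0L) {
    out <- data.frame(region = integer(0), taxon = character(0),
                      n_cells = integer(0), area_1e6_km2 = numeric(0),
                      stringsAsFactors = FALSE)
    attr(out, "labels") <- labels
    return(out)
  }
  rows <- lapply(seq_len(current), function(lab) {
    cells <- which(labels == lab)
    ii <- (cells - 1L) %% nlat + 1L
    tax <- mask$taxon[cells]
    data.frame(region = lab,
               taxon = names(which.max(table(tax))),
               n_cells = length(cells),
               area_1e6_km2 = sum(area_by_lat[ii]) / 1e6,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "labels") <- labels
  out
}
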