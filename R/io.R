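#' Column schemas of the package's CSV tables
#'
#' Named list of schemas, one per table kind: `bottles` (incubation
#' samples), `rates` (per-condition rate results), `qpcr_standards`,
#' `qpcr_unknowns`, `database` (global diazotroph records), `profiles`
#' (nifH depth profiles) and `regions` (budget regions). Each schema
#' maps column name to expected type (`"numeric"` or `"character"`);
#' names suffixed `?` are optional.
#'
#' @return Named list of named character vectors.
#' @export
diazo_schemas <- function() {
  list(
    bottles = c(station = "character", depth = "numeric",
                par_level = "numeric", fraction = "character",
                replicate = "numeric", a_pn_initial = "numeric",
                a_pn_final = "numeric", a_n2 = "numeric",
                pn_conc = "numeric", pn_mass = "numeric",
                duration = "numeric"),
    rates = c(station = "character", depth = "numeric",
              fraction = "character", n_bottles = "numeric",
              rate = "numeric", `sd?` = "numeric", lod1 = "numeric",
              `lod2?` = "numeric", flag = "character",
              low_pn_mass = "character"),
    qpcr_standards = c(copies_per_well = "numeric", ct = "numeric"),
    qpcr_unknowns = c(sample_id = "character", ct1 = "numeric",
                      ct2 = "numeric", ct3 = "numeric",
                      `volume_l?` = "numeric", `scaling?` = "numeric"),
    database = c(lat = "numeric", lon = "numeric", taxon = "character",
                 nifh_areal = "numeric", sst = "numeric",
                 dfe = "numeric", p = "numeric", `rate?` = "numeric",
                 `method?` = "character"),
    profiles = c(station = "character", phylotype = "character",
                 depth = "numeric", copies_per_l = "numeric",
                 flag = "character"),
    regions = c(name = "character", area = "numeric",
                `comparison_geometric?` = "numeric",
                `comparison_arithmetic?` = "numeric"))
}

#' Read a schema-validated CSV table
#'
#' Reads a comma-separated, UTF-8, dot-decimal table and validates it
#' against one of the package schemas: missing required columns are an
#' error naming the columns; values that fail numeric coercion are an
#' error naming the rows. No silent coercion.
#'
#' @param path CSV file path.
#' @param schema schema name (see [diazo_schemas()]) or a named type
#'   vector of the same form.
#' @return data.frame with validated types.
#' @export
read_diazo_table <- function(path, schema) {
  if (!file.exists(path))
    stop("input file not found: ", path, call. = FALSE)
  if (is.character(schema) && length(schema) == 1L) {
    schemas <- diazo_schemas()
    if (!schema %in% names(schemas))
      stop("unknown schema: ", schema, call. = FALSE)
    schema <- schemas[[schema]]
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  required <- names(schema)[!endsWith(names(schema), "?")]
  optional <- sub("\\?$", "", names(schema)[endsWith(names(schema), "?")])
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("schema error in ", path, ": missing required column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  types <- schema
  names(types) <- sub("\\?$", "", names(schema))
  for (cl in intersect(names(df), c(required, optional))) {
    if (types[[cl]] == "numeric") {
      raw <- df[[cl]]
      val <- suppressWarnings(as.numeric(raw))
      bad <- which(!is.na(raw) & raw != "" & raw != "NA" & is.na(val))
      if (length(bad))
        stop(sprintf("schema error in %s: column '%s' non-numeric at row(s) %s",
                     path, cl,
                     paste(utils::head(bad, 5), collapse = ", ")),
             call. = FALSE)
      df[[cl]] <- val
    }
  }
  df
}

#' Write a CSV table, optionally checking it against a schema
#'
#' @param df data.frame to write.
#' @param path output CSV path.
#' @param schema optional schema name or type vector; when given, the
#'   required columns must all be present.
#' @return `path`, invisibly.
#' @export
write_diazo_table <- function(df, path, schema = NULL) {
  if (!is.null(schema)) {
    if (is.character(schema) && length(schema) == 1L)
      schema <- diazo_schemas()[[schema]]
    required <- sub("\\?$", "",
                    names(schema)[!endsWith(names(schema), "?")])
    missing_cols <- setdiff(required, names(df))
    if (length(missing_cols))
      stop("refusing to write: missing required column(s) ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write an environmental grid (or abundance map) to netCDF
#'
#' CF-style layout: dimensions `lon`, `lat` and, for an [env_grid()],
#' `month`; double precision so values round-trip bitwise. Land/missing
#' cells are stored as the variable's `NA` fill value.
#'
#' @param x an [env_grid()] or an `abundance_map` from
#'   [project_taxon()].
#' @param path output `.nc` path.
#' @return `path`, invisibly.
#' @export
write_env_grid <- function(x, path) {
  dlat <- ncdf4::ncdim_def("lat", "degrees_north", x$lat)
  dlon <- ncdf4::ncdim_def("lon", "degrees_east", x$lon)
  fill <- -9.96921e36
  if (inherits(x, "env_grid")) {
    dmon <- ncdf4::ncdim_def("month", "month of year", 1:12)
    vars <- list(
      sst = ncdf4::ncvar_def("sst", "degC", list(dmon, dlat, dlon),
                             fill, prec = "double"),
      dfe = ncdf4::ncvar_def("dfe", "nmol L-1", list(dmon, dlat, dlon),
                             fill, prec = "double"),
      p = ncdf4::ncvar_def("p", "umol L-1", list(dmon, dlat, dlon),
                           fill, prec = "double"))
    nc <- ncdf4::nc_create(path, vars)
    on.exit(ncdf4::nc_close(nc))
    for (nm in names(vars)) {
      # substitute the fill value on a local copy: ncvar_put would
      # otherwise overwrite NA cells in the caller's array in place
      a <- x[[nm]]
      a[is.na(a)] <- fill
      ncdf4::ncvar_put(nc, vars[[nm]], a)
    }
  } else if (inherits(x, "abundance_map")) {
    v <- ncdf4::ncvar_def("abundance", "copies m-2", list(dlat, dlon),
                          fill, prec = "double")
    e <- ncdf4::ncvar_def("extrapolated", "flag", list(dlat, dlon),
                          prec = "integer")
    nc <- ncdf4::nc_create(path, list(v, e))
    on.exit(ncdf4::nc_close(nc))
    a <- x$abundance
    a[is.na(a)] <- fill
    ncdf4::ncvar_put(nc, v, a)
    ncdf4::ncvar_put(nc, e, x$extrapolated * 1L)
  } else stop("unsupported object", call. = FALSE)
  invisible(path)
}

#' Read an environmental grid from netCDF
#'
#' Accepts `(month, lat, lon)` variables `sst`, `dfe`, `p`. Longitudes
#' on a 0..360 convention are rotated to -180..180 with the data
#' reordered accordingly; missing cells become the land mask.
#'
#' @param path `.nc` file with the layout of [write_env_grid()].
#' @return An [env_grid()].
#' @export
read_env_grid <- function(path) {
  if (!file.exists(path))
    stop("input file not found: ", path, call. = FALSE)
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  lat <- as.numeric(ncdf4::ncvar_get(nc, "lat"))
  lon <- as.numeric(ncdf4::ncvar_get(nc, "lon"))
  get3 <- function(nm) {
    a <- ncdf4::ncvar_get(nc, nm, collapse_degen = FALSE)
    aperm(a, c(1, 2, 3))  # stored (month, lat, lon)
  }
  sst <- get3("sst"); dfe <- get3("dfe"); p <- get3("p")
  if (any(lon > 180)) {
    lon2 <- ifelse(lon > 180, lon - 360, lon)
    ord <- order(lon2)
    lon <- lon2[ord]
    sst <- sst[, , ord, drop = FALSE]
    dfe <- dfe[, , ord, drop = FALSE]
    p <- p[, , ord, drop = FALSE]
  }
  mask <- !is.na(sst[1, , ])
  env_grid(lat, lon, sst, dfe, p, mask)
}

#' Serialize a fitted niche model to portable JSON
#'
#' Writes a self-contained text representation of a [niche_gam()] fit:
#' the intercept-level prediction at the covariate medians, the
#' covariate hull, and each smooth as a dense piecewise-linear curve
#' (`n_grid` points over the training range). Predictions from the
#' serialized form reproduce the model to linear-interpolation error —
#' well below the fit's own uncertainty at the default resolution —
#' without requiring the fitting machinery at projection time.
#'
#' @param object a [niche_gam()] fit.
#' @param path output `.json` path.
#' @param n_grid curve resolution per covariate (default 512).
#' @return `path`, invisibly.
#' @seealso [read_niche_gam()]
#' @export
write_niche_gam <- function(object, path, n_grid = 512) {
  stopifnot(inherits(object, "niche_gam"))
  curves <- lapply(object$covariates, function(cv) {
    rc <- partial_response(object, cv, n_grid = n_grid)
    list(x = rc$x, effect = rc$effect)
  })
  names(curves) <- object$covariates
  # constant part: prediction at medians minus the partial effects there
  med <- as.data.frame(lapply(object$hull, `[[`, "median"))
  names(med) <- object$covariates
  base <- as.numeric(predict(object, med)) -
    sum(vapply(object$covariates, function(cv)
      stats::approx(curves[[cv]]$x, curves[[cv]]$effect,
                    xout = med[[cv]])$y, numeric(1)))
  payload <- list(
    format = "diazoflux-niche-gam",
    version = 1L,
    taxon = object$taxon,
    covariates = object$covariates,
    constant = base,
    hull = lapply(object$hull, function(h)
      list(min = h$range[1], max = h$range[2], median = h$median)),
    curves = curves,
    n_used = object$n_used,
    r_squared = object$r_squared,
    deviance_explained = object$deviance_explained)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a serialized niche model
#'
#' @param path a file written by [write_niche_gam()].
#' @return Object of class `niche_gam_serialized`, supporting
#'   [predict()][predict.niche_gam_serialized].
#' @export
read_niche_gam <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "diazoflux-niche-gam"))
    stop("not a serialized niche model: ", path, call. = FALSE)
  class(obj) <- "niche_gam_serialized"
  obj
}

#' Predict log10 abundance from a serialized niche model
#'
#' Covariates are clamped to the stored hull (the curves are not defined
#' beyond it) and interpolated linearly on each stored curve.
#'
#' @param object a [read_niche_gam()] object.
#' @param newdata data.frame with the covariate columns.
#' @param ... unused.
#' @return Numeric vector of log10 copies m-2 with attribute
#'   `"extrapolated"`.
#' @export
predict.niche_gam_serialized <- function(object, newdata, ...) {
  out <- rep(object$constant, nrow(newdata))
  extrap <- rep(FALSE, nrow(newdata))
  for (cv in object$covariates) {
    x <- newdata[[cv]]
    if (is.null(x)) stop("newdata lacks covariate ", cv, call. = FALSE)
    h <- object$hull[[cv]]
    extrap <- extrap | x < h$min | x > h$max
    x <- pmin(pmax(x, h$min), h$max)
    out <- out + stats::approx(object$curves[[cv]]$x,
                               object$curves[[cv]]$effect, xout = x)$y
  }
  attr(out, "extrapolated") <- extrap
  out
}
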