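make_tiny_env <- function(nlat = 6, nlon = 8, constant = TRUE) {
  simulate_env_grids(nlat = nlat, nlon = nlon, constant_fields = constant)
}

test_that("constant environmental fields project to a spatially constant map", {
  fit <- noiseless_fit(seed = 101, n = 200)
  env <- make_tiny_env()
  m <- project_taxon(fit, env)
  vals <- m$abundance[env$mask]
  expect_equal(max(vals) - min(vals), 0, tolerance = 1e-9 * max(vals))
  expect_true(all(is.na(m$abundance[!env$mask])))
})

test_that("map values equal brute-force single-cell predictions", {
  fit <- noiseless_fit(seed = 103, n = 200)
  env <- simulate_env_grids(nlat = 10, nlon = 16)
  m <- project_taxon(fit, env)
  ocean <- which(env$mask)
  set.seed(7)
  for (cell in sample(ocean, 20)) {
    monthly <- vapply(1:12, function(mo) {
      nd <- data.frame(sst = env$sst[mo, , ][cell],
                       dfe = env$dfe[mo, , ][cell],
                       p = env$p[mo, , ][cell])
      10^as.numeric(predict(fit, nd))
    }, numeric(1))
    expect_equal(m$abundance[cell], mean(monthly), tolerance = 1e-10)
  }
})

test_that("annualized map is bounded by the monthly extremes cellwise", {
  fit <- noiseless_fit(seed = 105, n = 200)
  env <- simulate_env_grids(nlat = 8, nlon = 12)
  m <- project_taxon(fit, env)
  lo <- apply(m$monthly, c(2, 3), min)
  hi <- apply(m$monthly, c(2, 3), max)
  ocean <- env$mask
  expect_true(all(m$abundance[ocean] >= lo[ocean] - 1e-12))
  expect_true(all(m$abundance[ocean] <= hi[ocean] + 1e-12))
  # log-space annualization is the cellwise geometric mean
  mg <- project_taxon(fit, env, annualize = "log")
  expect_true(all(mg$abundance[ocean] <= m$abundance[ocean] + 1e-9))
})

fake_map <- function(values, lat, lon, taxon = "t") {
  structure(list(taxon = taxon, lat = lat, lon = lon,
                 abundance = values,
                 extrapolated = matrix(FALSE, length(lat), length(lon))),
            class = "abundance_map")
}

test_that("dominance classification matches an exhaustive per-cell oracle", {
  lat <- seq(-2, 2); lon <- seq(10, 14)
  set.seed(11)
  for (trial in 1:200) {
    maps <- lapply(1:4, function(i)
      fake_map(matrix(10^runif(25, 2, 9), 5, 5), lat, lon))
    names(maps) <- c("UCYN-B", "Trichodesmium", "UCYN-A", "Richelia")
    thr <- 10^runif(1, 3, 8)
    mask <- dominance(maps, abundance_threshold = thr)
    for (cell in seq_len(25)) {
      ab <- vapply(maps, function(m) m$abundance[cell], numeric(1))
      tot <- sum(ab)
      expected <- "none"
      for (nm in names(ab)) {
        if (ab[nm] / tot > 0.75 && tot > thr) expected <- nm
      }
      expect_identical(mask$taxon[cell], expected)
    }
  }
})

test_that("dominance tie rule is strict and rescaling invariance holds", {
  lat <- 0; lon <- c(0, 1)
  a <- fake_map(matrix(c(75, 75), 1, 2), lat, lon)
  b <- fake_map(matrix(c(25, 25), 1, 2), lat, lon)
  # share exactly 0.75 -> none (strict inequality)
  mask <- dominance(list(A = a, B = b), abundance_threshold = 10)
  expect_identical(unique(as.vector(mask$taxon)), "none")
  # common rescaling with matching threshold leaves the mask unchanged
  set.seed(3)
  maps <- lapply(1:3, function(i)
    fake_map(matrix(10^runif(8, 2, 7), 2, 4), 1:2, 1:4))
  names(maps) <- c("a", "b", "c")
  m1 <- dominance(maps, abundance_threshold = 1e4)
  scaled <- lapply(maps, function(m) {
    m$abundance <- m$abundance * 137; m
  })
  m2 <- dominance(scaled, abundance_threshold = 1e4 * 137)
  expect_identical(m1$taxon, m2$taxon)
})

test_that("a single dominant taxon claims every ocean cell above threshold", {
  env <- make_tiny_env()
  lat <- env$lat; lon <- env$lon
  hot <- fake_map(matrix(1e9, length(lat), length(lon)), lat, lon)
  cold <- fake_map(matrix(0, length(lat), length(lon)), lat, lon)
  hot$abundance[!env$mask] <- NA
  cold$abundance[!env$mask] <- NA
  mask <- dominance(list(B = hot, A = cold), preset = "hotspot")
  expect_true(all(mask$taxon[env$mask] == "B"))
  expect_true(all(is.na(mask$taxon[!env$mask])))
})

test_that("spherical cell areas sum to the area of the sphere", {
  lat <- seq(-89.5, 89.5, by = 1)
  total <- sum(cell_areas(lat)) * 360
  expect_equal(total, 4 * pi * 6371^2, tolerance = 1e-4)
  # single 1-degree cell at the equator
  expect_equal(cell_areas(0), 6371^2 * (pi / 180) * 2 * sin(pi / 360),
               tolerance = 1e-12)
  expect_equal(cell_areas(0), 1.236e4, tolerance = 1e-3)
})

test_that("hotspot regions use 8-connectivity with antimeridian wrap", {
  lat <- seq(-2.5, 2.5); lon <- seq(-179.5, 179.5)
  nlat <- length(lat); nlon <- length(lon)
  tx <- matrix(NA_character_, nlat, nlon)
  tx[] <- "none"
  # two cells straddling the date line on the same row
  tx[3, 1] <- "B"; tx[3, nlon] <- "B"
  # a diagonal pair elsewhere (8-connectivity joins them)
  tx[1, 100] <- "B"; tx[2, 101] <- "B"
  # an isolated cell
  tx[5, 200] <- "B"
  mask <- structure(list(taxon = tx, total = matrix(1e9, nlat, nlon),
                         lat = lat, lon = lon,
                         share_threshold = 0.75,
                         abundance_threshold = 1e8),
                    class = "dominance_mask")
  regions <- hotspot_regions(mask)
  expect_equal(nrow(regions), 3)
  expect_setequal(regions$n_cells, c(2, 2, 1))
  # date-line pair is one region
  labels <- attr(regions, "labels")
  expect_equal(labels[3, 1], labels[3, nlon])
  # areas come from the latitude-weighted cell formula
  one_cell <- regions[regions$n_cells == 1, "area_1e6_km2"]
  expect_equal(one_cell, cell_areas(lat[5]) / 1e6, tolerance = 1e-12)
})

test_that("an empty qualifying set yields an empty region table", {
  tx <- matrix("none", 3, 4)
  mask <- structure(list(taxon = tx, total = matrix(0, 3, 4),
                         lat = 1:3, lon = 1:4, share_threshold = 0.75,
                         abundance_threshold = 1e8),
                    class = "dominance_mask")
  regions <- hotspot_regions(mask)
  expect_equal(nrow(regions), 0)
  # rate mask filtering drops cells below the rate threshold
  tx[2, 2] <- "B"
  mask$taxon <- tx
  rm_false <- matrix(FALSE, 3, 4)
  expect_equal(nrow(hotspot_regions(mask, rate_mask = rm_false)), 0)
})

test_that("grid mismatch between maps is an error", {
  a <- fake_map(matrix(1, 2, 2), 1:2, 1:2)
  b <- fake_map(matrix(1, 2, 3), 1:2, 1:3)
  expect_error(dominance(list(a = a, b = b)), "common grid")
})
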