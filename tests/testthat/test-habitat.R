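R_KM <- 6371.0088

test_that("cell areas reproduce spherical closed forms", {
  # whole sphere at 2-degree resolution
  syn <- make_synthetic_bathymetry(data.frame(lat_min = -90, lat_max = 90,
                                              elevation_m = -5000),
                                   resolution = 2)
  areas <- cell_area_grid(syn$grid)
  expect_equal(sum(areas), 4 * pi * R_KM^2, tolerance = 1e-9)

  # one cell spanning lon 0-360, lat 0-30: the spherical zone formula
  cell <- bathy_grid(lat = 15, lon = 0, elevation = matrix(-5000, 1, 1),
                     dlat = 30, dlon = 360)
  expect_equal(cell_area_grid(cell)[1, 1], pi * R_KM^2, tolerance = 1e-9)

  # halving the resolution leaves the total unchanged
  syn2 <- make_synthetic_bathymetry(data.frame(lat_min = -90, lat_max = 90,
                                               elevation_m = -5000),
                                    resolution = 1)
  expect_equal(sum(cell_area_grid(syn2$grid)), sum(areas), tolerance = 1e-9)
})

test_that("cells crossing a pole are clamped with a warning", {
  g <- bathy_grid(lat = c(-90, 0, 90), lon = c(-120, 0, 120),
                  elevation = matrix(-1000, 3, 3), dlat = 60, dlon = 120)
  expect_warning(areas <- cell_area_grid(g),
                 class = "hadalrange_pole_clamp")
  # rows clamp to [-90,-60], [-30,30], [60,90]
  expect_equal(sum(areas),
               2 * pi * R_KM^2 * (3 - 2 * sin(pi / 3)),
               tolerance = 1e-9)
})

test_that("envelope mask uses the closed depth interval and excludes land", {
  env <- depth_envelope(3890, 8931)
  g <- bathy_grid(lat = c(-10, 10), lon = c(0, 90),
                  elevation = matrix(c(-5000, -100, 200, -3890), 2, 2))
  m <- envelope_mask(g, env)
  expect_identical(m, matrix(c(TRUE, FALSE, FALSE, TRUE), 2, 2))
  g$elevation[1, 1] <- NA
  expect_false(envelope_mask(g, env)[1, 1])
})

test_that("habitat report: all-suitable basin is 100%, zone band is 50%", {
  env <- depth_envelope(3890, 8931)
  allin <- make_synthetic_bathymetry(data.frame(lat_min = -90, lat_max = 90,
                                                elevation_m = -5000),
                                     resolution = 2)
  r <- habitat_report(allin$grid, allin$basin_mask, env)
  expect_equal(r$percent[r$basin == "Pacific"], 100)

  # ocean = northern hemisphere; suitable depths only in the 0-30 zone:
  # percent = 100 * sin(30 deg) = 50.00
  zoned <- make_synthetic_bathymetry(
    data.frame(lat_min = c(-90, 0, 30), lat_max = c(0, 30, 90),
               elevation_m = c(200, -5000, -2000)),
    resolution = 1)
  rz <- habitat_report(zoned$grid, zoned$basin_mask, env)
  expect_equal(rz$percent[rz$basin == "Pacific"], 50)
  expect_equal(rz$envelope_area_km2[rz$basin == "Pacific"],
               pi * R_KM^2, tolerance = 1e-9)
})

test_that("report invariants: monotone in envelope, basins partition the ocean", {
  set.seed(5)
  lat <- seq(-89.5, 89.5, by = 1); lon <- seq(-179.5, 179.5, by = 1)
  elev <- matrix(runif(length(lat) * length(lon), -9000, 1000),
                 length(lat), length(lon))
  g <- bathy_grid(lat, lon, elev)
  mask <- matrix(ifelse(rep(lon, each = length(lat)) < 0, "Pacific",
                        "Atlantic"), length(lat), length(lon))
  small <- habitat_report(g, mask, depth_envelope(4000, 6000))
  big <- habitat_report(g, mask, depth_envelope(3000, 8000))
  expect_true(all(big$envelope_area_km2 >= small$envelope_area_km2))

  ocean_total <- sum(cell_area_grid(g)[elev < 0])
  expect_equal(sum(small$total_area_km2[small$basin != "Global"]),
               ocean_total, tolerance = 1e-9)
  expect_equal(small$envelope_area_km2[small$basin == "Global"],
               sum(small$envelope_area_km2[small$basin != "Global"]))
})

test_that("a basin with no ocean is flagged", {
  g <- bathy_grid(c(-45, 45), c(-90, 90),
                  elevation = matrix(c(-5000, -5000, 200, 200), 2, 2))
  mask <- matrix(c("Pacific", "Pacific", "Arctic", "Arctic"), 2, 2)
  expect_warning(r <- habitat_report(g, mask, depth_envelope(3890, 8931)),
                 class = "hadalrange_empty_basin")
  expect_true(is.na(r$percent[r$basin == "Arctic"]))
})

test_that("percentage arithmetic on an external area table", {
  tab <- data.frame(basin = c("Pacific", "Indian"),
                    envelope_area_km2 = c(50, 25),
                    total_area_km2 = c(100, 100))
  r <- report_from_areas(tab)
  expect_equal(r$percent, c(50, 25, 37.5))
  expect_equal(r$envelope_area_km2[3], 75)
  expect_error(report_from_areas(tab[, 1:2]),
               class = "hadalrange_config_error")
})

test_that("ASCII grid and basin mask round-trip through text files", {
  syn <- make_synthetic_bathymetry(
    data.frame(lat_min = c(-90, 0), lat_max = c(0, 90),
               elevation_m = c(-4000, 100)),
    basins = data.frame(name = c("Pacific", "Atlantic"),
                        lon_min = c(-180, 0), lon_max = c(0, 180)),
    resolution = 10)
  gp <- tempfile(fileext = ".asc"); mp <- tempfile(fileext = ".asc")
  write_ascii_grid(syn$grid, gp)
  write_basin_mask(syn$basin_mask, syn$grid, mp)
  g2 <- read_ascii_grid(gp)
  expect_equal(sort(g2$lat), sort(syn$grid$lat))
  ord <- order(-syn$grid$lat)
  expect_equal(g2$elevation, syn$grid$elevation[ord, ], ignore_attr = TRUE)
  m2 <- read_basin_mask(mp)
  expect_equal(m2, syn$basin_mask[ord, ])
})
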