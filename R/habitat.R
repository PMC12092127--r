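#' Construct a regular lat-lon bathymetry grid
#'
#' @param lat,lon strictly monotone cell-centre coordinates in degrees.
#' @param elevation matrix (length(lat) x length(lon)) of elevations in
#'   metres, negative below sea level (GEBCO convention); `NA` = no data.
#' @param dlat,dlon cell sizes in degrees; inferred from the coordinate
#'   spacing when possible, otherwise (single row/column) they default to
#'   the full 180/360-degree span and can be overridden here.
#' @return An object of class `bathy_grid`.
#' @export
bathy_grid <- function(lat, lon, elevation, dlat = NULL, dlon = NULL) {
  if (length(lat) < 1 || length(lon) < 1) stop_validation("empty grid")
  if (any(abs(lat) > 90)) stop_validation("latitudes must lie in [-90, 90]")
  dl <- diff(lat); dn <- diff(lon)
  if (length(dl) > 0 && !(all(dl > 0) || all(dl < 0))) {
    stop_validation("latitudes must be strictly monotone")
  }
  if (length(dn) > 0 && !(all(dn > 0) || all(dn < 0))) {
    stop_validation("longitudes must be strictly monotone")
  }
  if (!all(dim(elevation) == c(length(lat), length(lon)))) {
    stop_validation("elevation must be length(lat) x length(lon)")
  }
  if (is.null(dlat)) dlat <- if (length(lat) > 1) abs(lat[2] - lat[1]) else 180
  if (is.null(dlon)) dlon <- if (length(lon) > 1) abs(lon[2] - lon[1]) else 360
  structure(list(lat = lat, lon = lon, dlat = dlat, dlon = dlon,
                 elevation = elevation),
            class = "bathy_grid")
}

#' @export
print.bathy_grid <- function(x, ...) {
  cat(sprintf("Bathymetry grid: %d x %d cells (%.4g x %.4g deg)\n",
              length(x$lat), length(x$lon), x$dlat, x$dlon))
  invisible(x)
}

#' Spherical cell areas of a lat-lon grid
#'
#' Exact equal-area accounting on the authalic sphere (R = 6371.0088 km):
#' a cell with longitudinal width \eqn{\Delta\lambda} between latitudes
#' \eqn{\phi_1 < \phi_2} has area
#' \eqn{R^2 \Delta\lambda_{rad} (\sin\phi_2 - \sin\phi_1)}. Cells whose
#' bounds cross a pole are clamped at +/-90 degrees with a warning. This
#' is numerically equivalent to measuring in any equal-area map projection
#' (e.g. world Mollweide) but has a closed form.
#'
#' @param grid a `bathy_grid`.
#' @return Matrix of per-cell areas in km^2, same shape as the elevation.
#' @export
cell_area_grid <- function(grid) {
  top <- grid$lat + grid$dlat / 2
  bot <- grid$lat - grid$dlat / 2
  if (any(top > 90 + 1e-9) || any(bot < -90 - 1e-9)) {
    warn_flag("cell bounds cross a pole; clamped at +/-90 degrees",
              class = "hadalrange_pole_clamp")
  }
  top <- pmin(top, 90); bot <- pmax(bot, -90)
  band <- EARTH_RADIUS_KM^2 * (grid$dlon * pi / 180) *
    (sin(top * pi / 180) - sin(bot * pi / 180))
  matrix(band, nrow = length(grid$lat), ncol = length(grid$lon))
}

#' Depth-envelope suitability mask
#'
#' A cell is suitable when its depth (= negative elevation) falls inside
#' the closed interval of the envelope. Land (elevation >= 0) and no-data
#' cells are unsuitable.
#'
#' @param grid a `bathy_grid`.
#' @param envelope a `depth_envelope`.
#' @return Logical matrix, same shape as the elevation.
#' @export
envelope_mask <- function(grid, envelope) {
  depth <- -grid$elevation
  m <- !is.na(depth) & depth >= envelope$d_min_m & depth <= envelope$d_max_m
  m
}

#' Per-basin habitat areas and percentages
#'
#' Projects a species depth envelope onto gridded bathymetry: for each
#' ocean basin, sums the spherical areas of suitable cells (depth within
#' the envelope) and of all ocean cells (elevation < 0), and reports the
#' suitable percentage. A global row sums the basins. Percentages are
#' rounded half-to-even at two decimals.
#'
#' @param grid a `bathy_grid`.
#' @param basin_mask character (or factor) matrix co-registered with the
#'   grid: basin label per cell (`NA` or `"none"` = unassigned).
#' @param envelope a `depth_envelope`.
#' @return A data frame of class `habitat_report`: `basin`,
#'   `envelope_area_km2`, `total_area_km2`, `percent`, with a final
#'   `"Global"` row. A basin with zero ocean area gets `NA` percent and a
#'   warning.
#' @export
habitat_report <- function(grid, basin_mask, envelope) {
  if (!all(dim(basin_mask) == dim(grid$elevation))) {
    stop_validation("basin mask shape does not match the grid")
  }
  areas <- cell_area_grid(grid)
  suitable <- envelope_mask(grid, envelope)
  ocean <- !is.na(grid$elevation) & grid$elevation < 0
  labels <- BASIN_LEVELS[BASIN_LEVELS %in% basin_mask]
  env_area <- vapply(labels, function(b) {
    sum(areas[suitable & !is.na(basin_mask) & basin_mask == b])
  }, 0)
  tot_area <- vapply(labels, function(b) {
    sum(areas[ocean & !is.na(basin_mask) & basin_mask == b])
  }, 0)
  if (any(tot_area == 0)) {
    warn_flag(sprintf("basin(s) with zero ocean area: %s",
                      paste(labels[tot_area == 0], collapse = ", ")),
              class = "hadalrange_empty_basin")
  }
  report_from_areas(data.frame(basin = labels,
                               envelope_area_km2 = unname(env_area),
                               total_area_km2 = unname(tot_area),
                               stringsAsFactors = FALSE))
}

#' Habitat percentages from per-basin areas
#'
#' The reporting arithmetic of [habitat_report()] applied to an existing
#' per-basin area table (e.g. one computed elsewhere from a published
#' bathymetry product): percent suitable per basin and a global row that
#' sums basins.
#'
#' @param areas data frame with columns `basin`, `envelope_area_km2`,
#'   `total_area_km2`.
#' @return A `habitat_report` data frame.
#' @export
report_from_areas <- function(areas) {
  req <- c("basin", "envelope_area_km2", "total_area_km2")
  if (!all(req %in% names(areas))) {
    stop_config(sprintf("area table needs columns: %s",
                        paste(req, collapse = ", ")))
  }
  out <- areas[req]
  out <- rbind(out, data.frame(basin = "Global",
                               envelope_area_km2 = sum(out$envelope_area_km2),
                               total_area_km2 = sum(out$total_area_km2)))
  out$percent <- ifelse(out$total_area_km2 > 0,
                        round(100 * out$envelope_area_km2 /
                                out$total_area_km2, 2),
                        NA_real_)
  class(out) <- c("habitat_report", "data.frame")
  out
}

#' @export
print.habitat_report <- function(x, ...) {
  cat("Depth-envelope habitat report (areas in km^2):\n")
  print.data.frame(x, row.names = FALSE, digits = 10)
  invisible(x)
}

#' Write a habitat report to CSV
#'
#' @param report a `habitat_report`.
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
write_habitat_report <- function(report, path) {
  write.csv(as.data.frame(report), path, row.names = FALSE)
  invisible(path)
}
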