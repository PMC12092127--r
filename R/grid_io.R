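## Plain-text grid exchange: ESRI ASCII grid for elevation / integer
## label rasters, with a JSON legend for basin labels.  (No GeoTIFF/netCDF
## backend is provided; those readers are not available in this stack, and
## the ASCII grid is the GDAL-standard text equivalent.)

#' Write a bathymetry grid as an ESRI ASCII grid
#'
#' @param grid a `bathy_grid`.
#' @param path output `.asc` path.
#' @param nodata no-data sentinel written for `NA` cells.
#' @return The path, invisibly.
#' @export
write_ascii_grid <- function(grid, path, nodata = -9999) {
  lat_desc <- if (length(grid$lat) > 1 && grid$lat[2] > grid$lat[1])
    rev(grid$lat) else grid$lat
  elev <- grid$elevation
  if (length(grid$lat) > 1 && grid$lat[2] > grid$lat[1]) {
    elev <- elev[rev(seq_len(nrow(elev))), , drop = FALSE]
  }
  elev[is.na(elev)] <- nodata
  hdr <- c(sprintf("ncols %d", length(grid$lon)),
           sprintf("nrows %d", length(grid$lat)),
           sprintf("xllcorner %.10g", min(grid$lon) - grid$dlon / 2),
           sprintf("yllcorner %.10g", min(grid$lat) - grid$dlat / 2),
           sprintf("cellsize %.10g", grid$dlon),
           sprintf("NODATA_value %g", nodata))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(apply(elev, 1, paste, collapse = " "), con)
  invisible(path)
}

#' Read an ESRI ASCII grid as a bathymetry grid
#'
#' Requires square cells (`cellsize` applies to both axes, as in the
#' format definition).
#'
#' @param path path to a `.asc` file.
#' @return A `bathy_grid` with latitudes descending (north first).
#' @export
read_ascii_grid <- function(path) {
  if (!file.exists(path)) stop_config(sprintf("grid file not found: %s", path))
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (i <= length(lines) && grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr))) {
    stop_validation(sprintf("ASCII grid header incomplete in %s", path))
  }
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  nr <- hdr$nrows; nc <- hdr$ncols; cs <- hdr$cellsize
  if (length(vals) != nr * nc) {
    stop_validation("ASCII grid body size does not match header")
  }
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  lat <- hdr$yllcorner + cs * (nr - seq_len(nr) + 0.5)
  lon <- hdr$xllcorner + cs * (seq_len(nc) - 0.5)
  bathy_grid(lat = lat, lon = lon, elevation = m)
}

#' Write a basin-label mask as an integer ASCII grid plus JSON legend
#'
#' @param basin_mask character matrix of basin labels (`NA` = none).
#' @param grid the co-registered `bathy_grid` (for coordinates).
#' @param path output `.asc` path; the legend goes to `<path>.legend.json`.
#' @return The path, invisibly.
#' @export
write_basin_mask <- function(basin_mask, grid, path) {
  labels <- BASIN_LEVELS[BASIN_LEVELS %in% basin_mask]
  codes <- matrix(match(basin_mask, labels), nrow = nrow(basin_mask))
  g <- grid
  g$elevation <- codes
  write_ascii_grid(g, path, nodata = 0)
  jsonlite::write_json(as.list(setNames(labels, seq_along(labels))),
                       paste0(path, ".legend.json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a basin-label mask written by [write_basin_mask()]
#'
#' @param path `.asc` path (expects `<path>.legend.json` alongside).
#' @return Character matrix of basin labels.
#' @export
read_basin_mask <- function(path) {
  g <- read_ascii_grid(path)
  legend_path <- paste0(path, ".legend.json")
  if (!file.exists(legend_path)) {
    stop_config(sprintf("legend file not found: %s", legend_path))
  }
  legend <- jsonlite::read_json(legend_path, simplifyVector = TRUE)
  lab <- unlist(legend)[as.character(g$elevation)]
  matrix(unname(lab), nrow = nrow(g$elevation))
}
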