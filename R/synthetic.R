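#' Simulate an alignment under the standard neutral coalescent
#'
#' Kingman coalescent without recombination: with `k` lineages the time to
#' the next coalescence is exponential with rate `choose(k, 2)`; mutations
#' are Poisson with rate `theta/2` per unit of total branch length, placed
#' uniformly on the tree, and assigned (infinite-sites style) to distinct
#' columns of a fixed-length alignment, each substituting a base different
#' from the ancestral one. Under this model the expected number of
#' segregating sites is `theta * a1` (Watterson) and the expected mean
#' pairwise difference is `theta`, which makes the simulator a calibrated
#' neutral null for Tajima's D.
#'
#' @param n sample size (>= 2).
#' @param L alignment length in sites; mutations exceeding `L` abort with
#'   advice to enlarge `L`.
#' @param theta scaled mutation rate per locus (> 0).
#' @param seed integer seed; output is byte-identical across repeats.
#' @param locus locus tag for the resulting alignment.
#' @param regions locality labels recycled over the sample (default 14
#'   a-priori geographic regions).
#' @return A `dna_alignment` with a `sim_config` attribute recording the
#'   generating parameters.
#' @export
simulate_coalescent_alignment <- function(n, L, theta, seed = 1,
                                          locus = "other",
                                          regions = sprintf("R%02d", 1:14)) {
  if (n < 2) stop_validation("coalescent simulation needs n >= 2")
  if (L < 1) stop_validation("L must be >= 1")
  if (!is.finite(theta) || theta <= 0) stop_validation("theta must be > 0")
  with_seed(seed, {
    lineages <- as.list(seq_len(n))
    epochs <- vector("list", n - 1)
    k <- n
    while (k > 1) {
      epochs[[n - k + 1]] <- list(k = k,
                                  dur = rexp(1, rate = choose(k, 2)),
                                  tipsets = lineages)
      pair <- sort(sample.int(k, 2))
      merged <- c(lineages[[pair[1]]], lineages[[pair[2]]])
      lineages <- c(lineages[-pair], list(merged))
      k <- k - 1
    }
    lens <- vapply(epochs, function(e) e$k * e$dur, 0)
    n_mut <- rpois(1, theta * sum(lens) / 2)
    if (n_mut > L) {
      stop_validation(sprintf(
        "%d mutations exceed L = %d sites; increase L for infinite-sites placement",
        n_mut, L))
    }
    bases <- c("A", "C", "G", "T")
    anc <- sample(bases, L, replace = TRUE)
    mat <- matrix(rep(anc, each = n), nrow = n, ncol = L)
    if (n_mut > 0) {
      cols <- sample.int(L, n_mut)
      which_epoch <- sample.int(length(epochs), n_mut, replace = TRUE,
                                prob = lens)
      for (m in seq_len(n_mut)) {
        e <- epochs[[which_epoch[m]]]
        tips <- e$tipsets[[sample.int(e$k, 1)]]
        derived <- sample(setdiff(bases, anc[cols[m]]), 1)
        mat[tips, cols[m]] <- derived
      }
    }
    rownames(mat) <- sprintf("seq%03d", seq_len(n))
    locality <- setNames(rep_len(regions, n), rownames(mat))
    aln <- dna_alignment(mat, locus = locus, locality = locality)
    attr(aln, "sim_config") <- list(n = n, L = L, theta = theta,
                                    seed = seed, n_mutations = n_mut)
    aln
  })
}

#' Write an alignment to FASTA
#'
#' @param alignment a `dna_alignment`.
#' @param path output FASTA path.
#' @return The path, invisibly.
#' @export
write_alignment_fasta <- function(alignment, path) {
  seqs <- apply(alignment$matrix, 1, paste, collapse = "")
  writeLines(paste0(">", alignment$ids, "\n", seqs), path)
  invisible(path)
}

#' Synthetic bathymetry with closed-form areas
#'
#' Builds a regular grid whose elevation is constant inside prescribed
#' latitude bands, with ocean basins as longitude sectors, so every area
#' the habitat projection can compute has an exact spherical closed form
#' (band area \eqn{2\pi R^2(\sin\phi_2 - \sin\phi_1)} times the sector
#' fraction). Band and sector boundaries must fall on cell edges
#' (multiples of `resolution`) so grid sums reproduce the closed forms to
#' rounding error.
#'
#' @param bands data frame with `lat_min`, `lat_max` (degrees) and
#'   `elevation_m` (negative = ocean); must tile \[-90, 90\] without
#'   overlap.
#' @param basins data frame with `name`, `lon_min`, `lon_max` tiling
#'   \[-180, 180\]; default a single all-longitude `"Pacific"` sector.
#' @param resolution cell size in degrees (must divide the band/sector
#'   bounds).
#' @return List with `grid` (a `bathy_grid`), `basin_mask` (character
#'   matrix) and `expected` (data frame of analytic per-basin, per-band
#'   areas in km^2).
#' @export
make_synthetic_bathymetry <- function(bands,
                                      basins = data.frame(
                                        name = "Pacific",
                                        lon_min = -180, lon_max = 180),
                                      resolution = 1) {
  b <- bands[order(bands$lat_min), , drop = FALSE]
  if (b$lat_min[1] != -90 || b$lat_max[nrow(b)] != 90) {
    stop_validation("bands must cover latitudes -90 to 90")
  }
  if (nrow(b) > 1) {
    gaps <- b$lat_min[-1] - b$lat_max[-nrow(b)]
    if (any(gaps < 0)) stop_validation("overlapping latitude bands")
    if (any(gaps > 0)) stop_validation("latitude bands leave gaps")
  }
  edges <- c(b$lat_min, b$lat_max, basins$lon_min, basins$lon_max)
  if (any(abs(edges / resolution - round(edges / resolution)) > 1e-9)) {
    stop_validation("band and sector bounds must be multiples of the resolution")
  }
  lat <- seq(-90 + resolution / 2, 90 - resolution / 2, by = resolution)
  lon <- seq(-180 + resolution / 2, 180 - resolution / 2, by = resolution)
  elev <- matrix(NA_real_, length(lat), length(lon))
  for (i in seq_len(nrow(b))) {
    sel <- lat >= b$lat_min[i] & lat <= b$lat_max[i]
    elev[sel, ] <- b$elevation_m[i]
  }
  mask <- matrix(NA_character_, length(lat), length(lon))
  for (i in seq_len(nrow(basins))) {
    sel <- lon >= basins$lon_min[i] & lon <= basins$lon_max[i]
    mask[, sel] <- basins$name[i]
  }
  grid <- bathy_grid(lat, lon, elev)

  zone <- function(p1, p2) {
    2 * pi * EARTH_RADIUS_KM^2 * (sin(p2 * pi / 180) - sin(p1 * pi / 180))
  }
  expected <- do.call(rbind, lapply(seq_len(nrow(basins)), function(s) {
    frac <- (basins$lon_max[s] - basins$lon_min[s]) / 360
    data.frame(basin = basins$name[s],
               lat_min = b$lat_min, lat_max = b$lat_max,
               elevation_m = b$elevation_m,
               area_km2 = zone(b$lat_min, b$lat_max) * frac,
               stringsAsFactors = FALSE)
  }))
  list(grid = grid, basin_mask = mask, expected = expected)
}

#' Synthetic occurrence records with forced depth extremes
#'
#' Generates a parametric record table shaped like a compiled observation/
#' collection dataset: `n_sites` named sites spread over seafloor
#' features, `n_records` records with depths uniform inside the requested
#' range whose endpoints are forced to be present, so the derived depth
#' envelope equals `depth_range` exactly. Deterministic given `seed`.
#'
#' @param n_records number of records (>= n_sites).
#' @param n_sites number of distinct sites.
#' @param depth_range numeric `c(min, max)` in metres.
#' @param seed integer seed.
#' @param basin_weights named numeric vector of basin sampling weights;
#'   the default emulates a strongly Pacific-skewed deep-sea record set.
#' @return An `occurrence_records` data frame.
#' @export
make_synthetic_records <- function(n_records, n_sites, depth_range,
                                   seed = 1,
                                   basin_weights = c(Pacific = 67,
                                                     Atlantic = 4,
                                                     Indian = 4)) {
  if (n_sites < 1 || n_records < n_sites) {
    stop_validation("need 1 <= n_sites <= n_records")
  }
  if (length(depth_range) != 2 || any(!is.finite(depth_range)) ||
      depth_range[1] <= 0 || depth_range[2] < depth_range[1]) {
    stop_validation("depth_range must be positive and ordered")
  }
  with_seed(seed, {
    features <- c("trench", "fracture zone", "abyssal plain", "seamount",
                  "plateau")
    site_ids <- sprintf("S%03d", seq_len(n_sites))
    site_basin <- sample(names(basin_weights), n_sites, replace = TRUE,
                         prob = basin_weights)
    site_feature <- sprintf("%s %s", sample(features, n_sites, TRUE),
                            seq_len(n_sites))
    site_lat <- runif(n_sites, -60, 60)
    site_lon <- runif(n_sites, -180, 180)
    site <- c(seq_len(n_sites),
              sample.int(n_sites, n_records - n_sites, replace = TRUE))
    depth <- runif(n_records, depth_range[1], depth_range[2])
    depth[1] <- depth_range[1]
    depth[min(2, n_records)] <- depth_range[2]
    rec_type <- sample(c("observation", "collection", "both"), n_records,
                       replace = TRUE, prob = c(0.55, 0.35, 0.10))
    df <- data.frame(site_id = site_ids[site],
                     feature = site_feature[site],
                     basin = site_basin[site],
                     lat = site_lat[site],
                     lon = site_lon[site],
                     depth_m = round(depth),
                     record_type = rec_type,
                     source_ref = sprintf("ref%02d", sample.int(18, n_records,
                                                                TRUE)),
                     n_individuals = ifelse(runif(n_records) < 0.3,
                                            NA_integer_,
                                            1L + rpois(n_records, 2)),
                     stringsAsFactors = FALSE)
    # rounding must not break the forced extremes
    df$depth_m[1] <- depth_range[1]
    df$depth_m[min(2, n_records)] <- depth_range[2]
    as_occurrence_records(df)
  })
}
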