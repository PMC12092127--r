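#' Read occurrence records from CSV
#'
#' Reads a table of georeferenced occurrence records (in-situ observations
#' and/or physical collections) of a deep-sea species. Each row is one
#' record at a named site on a seafloor feature (trench, fracture zone,
#' plateau, ...), with coordinates and a depth in metres (positive
#' downward).
#'
#' Required columns (after optional renaming through `col_map`):
#' `site_id`, `feature`, `basin`, `lat`, `lon`, `depth_m`, `record_type`.
#' Optional columns: `source_ref`, `n_individuals` (`NA` = unknown, as in
#' many historical records).
#'
#' @param path path to a UTF-8 CSV file with a header row.
#' @param col_map optional named character vector mapping required column
#'   names to the names actually used in the file, e.g.
#'   `c(lat = "latitude_dd")`.
#' @param ... further arguments passed to [utils::read.csv()].
#' @return A data frame of class `occurrence_records` with validated
#'   columns.
#' @details Rows violating the field invariants (latitude outside
#'   \[-90, 90\], longitude outside \[-180, 180\], non-positive depth, empty
#'   `site_id`, unknown basin or record type) abort with a validation error
#'   listing the offending row numbers. A missing required column is a
#'   configuration error.
#' @seealso [summarize_records()], [envelope_from_records()]
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.csv(data.frame(site_id = c("KT1", "KT1", "MFZ2"),
#'                      feature = c("Kermadec", "Kermadec", "Murray FZ"),
#'                      basin = c("Pacific", "Pacific", "Pacific"),
#'                      lat = c(-32.1, -32.1, 30.5), lon = c(-177.4, -177.4, -140.2),
#'                      depth_m = c(7000, 6265, 6746),
#'                      record_type = c("collection", "observation", "both")),
#'           f, row.names = FALSE)
#' recs <- read_records(f)
#' summarize_records(recs)
read_records <- function(path, col_map = NULL, ...) {
  if (!file.exists(path)) stop_config(sprintf("record file not found: %s", path))
  df <- read.csv(path, stringsAsFactors = FALSE, ...)
  required <- c("site_id", "feature", "basin", "lat", "lon", "depth_m",
                "record_type")
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      idx <- match(col_map[[canon]], names(df))
      if (!is.na(idx)) names(df)[idx] <- canon
    }
  }
  as_occurrence_records(df)
}

#' Validate a data frame of occurrence records
#'
#' @param df data frame with the columns documented in [read_records()].
#' @return The data frame, classed `occurrence_records`.
#' @export
as_occurrence_records <- function(df) {
  required <- c("site_id", "feature", "basin", "lat", "lon", "depth_m",
                "record_type")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop_config(sprintf("missing required column(s): %s",
                        paste(missing, collapse = ", ")))
  }
  if (!"source_ref" %in% names(df)) df$source_ref <- NA_character_
  if (!"n_individuals" %in% names(df)) df$n_individuals <- NA_integer_
  num <- function(x) suppressWarnings(as.numeric(x))
  lat <- num(df$lat); lon <- num(df$lon); depth <- num(df$depth_m)
  bad <- is.na(lat) | lat < -90 | lat > 90
  bad <- bad | is.na(lon) | lon < -180 | lon > 180
  bad <- bad | is.na(depth) | depth <= 0
  bad <- bad | is.na(df$site_id) | !nzchar(trimws(df$site_id))
  bad <- bad | !(df$basin %in% BASIN_LEVELS)
  bad <- bad | !(df$record_type %in% c("observation", "collection", "both"))
  if (any(bad)) {
    stop_validation("invalid occurrence record(s)", rows = which(bad))
  }
  df$lat <- lat; df$lon <- lon; df$depth_m <- depth
  df$n_individuals <- suppressWarnings(as.integer(df$n_individuals))
  class(df) <- c("occurrence_records", "data.frame")
  df
}

#' Summarize occurrence records
#'
#' Counts records and distinct sites, tabulates features and basins, and
#' reports the observed depth extremes. A record flagged `"both"`
#' (observation and collection at once) counts once. Sites are distinct by
#' `site_id` string; no coordinate fuzzing is applied.
#'
#' @param records an `occurrence_records` data frame.
#' @return A list of class `record_summary`: `n_records`, `n_sites`,
#'   `depth_min_m`, `depth_max_m`, `counts_per_feature`, `counts_per_basin`.
#' @export
summarize_records <- function(records) {
  if (is.null(records) || nrow(records) == 0) {
    stop_validation("cannot summarize an empty record set")
  }
  out <- list(
    n_records = nrow(records),
    n_sites = length(unique(records$site_id)),
    depth_min_m = min(records$depth_m),
    depth_max_m = max(records$depth_m),
    counts_per_feature = table(records$feature),
    counts_per_basin = table(factor(records$basin, levels = BASIN_LEVELS))
  )
  structure(out, class = "record_summary")
}

#' @export
print.record_summary <- function(x, ...) {
  cat(sprintf("Occurrence records: %d records at %d sites\n",
              x$n_records, x$n_sites))
  cat(sprintf("Depth range: %g-%g m\n", x$depth_min_m, x$depth_max_m))
  nz <- x$counts_per_basin[x$counts_per_basin > 0]
  cat("Records per basin:",
      paste(sprintf("%s=%d", names(nz), as.integer(nz)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Depth envelope of a record set
#'
#' The closed depth interval \[min, max\] over all record depths: the
#' one-dimensional habitat model used by [habitat_report()]. A single
#' record (or identical depths) yields a degenerate envelope and a warning.
#'
#' @param records an `occurrence_records` data frame.
#' @return A list of class `depth_envelope` with `d_min_m`, `d_max_m` and a
#'   logical `degenerate` flag.
#' @export
envelope_from_records <- function(records) {
  if (is.null(records) || nrow(records) == 0) {
    stop_validation("cannot derive an envelope from an empty record set")
  }
  depth_envelope(min(records$depth_m), max(records$depth_m))
}

#' Construct a depth envelope directly
#'
#' @param d_min_m,d_max_m envelope bounds in metres, positive downward.
#' @return A `depth_envelope` object.
#' @export
depth_envelope <- function(d_min_m, d_max_m) {
  if (!is.finite(d_min_m) || !is.finite(d_max_m) || d_min_m <= 0 ||
      d_max_m < d_min_m) {
    stop_validation("envelope bounds must satisfy 0 < d_min <= d_max")
  }
  degenerate <- d_min_m == d_max_m
  if (degenerate) {
    warn_flag("degenerate depth envelope: d_min == d_max",
              class = "hadalrange_degenerate_envelope")
  }
  structure(list(d_min_m = d_min_m, d_max_m = d_max_m,
                 degenerate = degenerate),
            class = "depth_envelope")
}

#' @export
print.depth_envelope <- function(x, ...) {
  cat(sprintf("Depth envelope: %g-%g m%s\n", x$d_min_m, x$d_max_m,
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}
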