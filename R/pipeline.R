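## Stage orchestration: records -> popgen -> distances -> network ->
## delimitation -> habitat, driven by a plain key=value config, with a
## JSON run manifest (input hashes, seed, versions, per-stage outputs).

log_info <- function(fmt, ...) {
  message(sprintf("[%s] INFO %s", format(Sys.time(), "%H:%M:%S"),
                  sprintf(fmt, ...)))
}

#' Read a plain-text pipeline configuration
#'
#' One `key = value` pair per line; `#` comments and blank lines are
#' ignored. See [run_pipeline()] for the recognised keys.
#'
#' @param path path to the config file.
#' @return Named list of character values.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_config(sprintf("config file not found: %s", path))
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2
  if (any(bad)) stop_config(sprintf("malformed config line(s): %s",
                                    paste(lines[bad], collapse = "; ")))
  setNames(lapply(kv, `[[`, 2), vapply(kv, `[[`, "", 1))
}

cfg_get <- function(config, key, default = NULL) {
  if (!is.null(config[[key]])) config[[key]] else default
}

cfg_num <- function(config, key, default = NULL) {
  v <- cfg_get(config, key, default)
  if (is.null(v)) NULL else as.numeric(v)
}

cfg_path <- function(config, key, required = FALSE) {
  p <- cfg_get(config, key)
  if (is.null(p)) {
    if (required) stop_config(sprintf("config key '%s' is required", key))
    return(NULL)
  }
  if (!file.exists(p)) stop_config(sprintf("'%s' path does not exist: %s", key, p))
  p
}

run_stage <- function(name, expr) {
  t0 <- Sys.time()
  out <- tryCatch(expr, error = function(e) {
    hr_stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
            "hadalrange_stage_error", stage = name)
  })
  log_info("stage %s done in %.2f s", name,
           as.numeric(difftime(Sys.time(), t0, units = "secs")))
  out
}

#' Run the analysis pipeline
#'
#' Executes the requested stages and writes their outputs plus a
#' `manifest.json` recording input hashes, the seed, the package version
#' and per-stage output paths, so a rerun with the same inputs and seed
#' is bitwise reproducible.
#'
#' Recognised config keys: `stages` (comma list among `records`,
#' `popgen`, `distances`, `network`, `delimit`, `habitat`; default all
#' whose inputs are present), `records_csv`, `alignment_fasta`, `locus`,
#' `locality_csv` (two columns: id, locality), `distance_model`
#' (`JC69`/`F81`/`raw`), `base_freqs` (four comma-separated A,C,G,T
#' proportions; required for F81), `network_threshold` (default 0.95),
#' `mc_reps` (default 10000), `seed` (default 1), `bathymetry_asc`,
#' `basin_mask_asc`, `envelope_min_m`/`envelope_max_m` (override the
#' record-derived envelope).
#'
#' @param config named list (or path to a key=value file, see
#'   [read_run_config()]).
#' @param out_dir output directory (created if missing).
#' @return The manifest, invisibly (list with `seed`, `inputs`,
#'   `stages`).
#' @export
run_pipeline <- function(config, out_dir = cfg_get(config, "out_dir", ".")) {
  if (is.character(config) && length(config) == 1) {
    config <- read_run_config(config)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(cfg_num(config, "seed", 1))
  out <- function(f) file.path(out_dir, f)

  records_csv <- cfg_path(config, "records_csv")
  fasta <- cfg_path(config, "alignment_fasta")
  bathy <- cfg_path(config, "bathymetry_asc")
  basin <- cfg_path(config, "basin_mask_asc")

  stages <- cfg_get(config, "stages")
  if (is.null(stages)) {
    stages <- c(if (!is.null(records_csv)) "records",
                if (!is.null(fasta)) c("popgen", "distances", "network",
                                       "delimit"),
                if (!is.null(bathy)) "habitat")
  } else {
    stages <- trimws(strsplit(stages, ",")[[1]])
  }
  known <- c("records", "popgen", "distances", "network", "delimit",
             "habitat")
  if (length(setdiff(stages, known)) > 0) {
    stop_config(sprintf("unknown stage(s): %s",
                        paste(setdiff(stages, known), collapse = ", ")))
  }
  log_info("running stages: %s (seed %d)", paste(stages, collapse = ", "),
           seed)

  manifest <- list(seed = seed,
                   package = "hadalrange",
                   version = as.character(packageVersion("hadalrange")),
                   inputs = list(), stages = list())
  for (p in c(records_csv, fasta, bathy, basin)) {
    manifest$inputs[[basename(p)]] <- unname(md5sum(p))
  }

  envelope <- NULL
  if (!is.null(cfg_num(config, "envelope_min_m"))) {
    envelope <- depth_envelope(cfg_num(config, "envelope_min_m"),
                               cfg_num(config, "envelope_max_m"))
  }

  records <- NULL
  if ("records" %in% stages) {
    manifest$stages$records <- run_stage("records", {
      records <- read_records(records_csv)
      s <- summarize_records(records)
      write.csv(data.frame(n_records = s$n_records, n_sites = s$n_sites,
                           depth_min_m = s$depth_min_m,
                           depth_max_m = s$depth_max_m),
                out("record_summary.csv"), row.names = FALSE)
      list(outputs = "record_summary.csv",
           n_records = s$n_records, n_sites = s$n_sites)
    })
    if (is.null(envelope)) envelope <- envelope_from_records(records)
  }

  aln <- filt <- hap <- dist_raw <- dist_cor <- NULL
  if (any(c("popgen", "distances", "network", "delimit") %in% stages)) {
    if (is.null(fasta)) stop_config("sequence stages need 'alignment_fasta'")
    locality <- NULL
    loc_csv <- cfg_path(config, "locality_csv")
    if (!is.null(loc_csv)) {
      ldf <- read.csv(loc_csv, stringsAsFactors = FALSE)
      locality <- setNames(ldf[[2]], ldf[[1]])
    }
    aln <- read_alignment(fasta, locus = cfg_get(config, "locus", "other"),
                          locality_map = locality)
    filt <- complete_deletion(aln)
    hap <- collapse_haplotypes(aln, filt)
  }

  if ("popgen" %in% stages) {
    manifest$stages$popgen <- run_stage("popgen", {
      stats <- diversity_summary(aln, filt, hap)
      write_diversity_stats(stats, out("diversity_stats.csv"))
      write_haplotype_table(hap, out("haplotypes.csv"))
      list(outputs = c("diversity_stats.csv", "haplotypes.csv"),
           n = stats$n, H = stats$H)
    })
  }

  if (any(c("distances", "delimit") %in% stages)) {
    dist_raw <- p_distance_matrix(aln)
    model <- cfg_get(config, "distance_model", "JC69")
    dist_cor <- if (model == "raw") dist_raw else {
      freqs <- NULL
      if (!is.null(cfg_get(config, "base_freqs"))) {
        f <- as.numeric(strsplit(cfg_get(config, "base_freqs"), ",")[[1]])
        freqs <- base_freqs(f[1], f[2], f[3], f[4])
      }
      correct_distances(dist_raw, model = model, freqs = freqs)
    }
  }

  if ("distances" %in% stages) {
    manifest$stages$distances <- run_stage("distances", {
      write_distances(dist_cor, out("distances.csv"),
                      long_path = out("distances_long.csv"))
      r <- distance_range(dist_cor)
      list(outputs = c("distances.csv", "distances_long.csv"),
           model = dist_cor$model, min = r[[1]], max = r[[2]])
    })
  }

  if ("network" %in% stages) {
    manifest$stages$network <- run_stage("network", {
      threshold <- cfg_num(config, "network_threshold", 0.95)
      mc_reps <- as.integer(cfg_num(config, "mc_reps", 10000))
      limit <- connection_limit(filt$L_retained, threshold = threshold,
                                mc_reps = mc_reps, seed = seed)
      net <- build_network(hap, limit = limit)
      write_network(net, out("network_edges.csv"),
                    nodes_path = out("network_nodes.csv"),
                    graphml_path = out("network.graphml"))
      list(outputs = c("network_edges.csv", "network_nodes.csv",
                       "network.graphml"),
           connection_limit = limit,
           components = length(unique(net$components)))
    })
  }

  if ("delimit" %in% stages) {
    manifest$stages$delimit <- run_stage("delimit", {
      choice <- best_partition(linkage_sweep(dist_cor))
      write_partition_report(choice, out("partition_sweep.csv"),
                             membership_path = out("partition_groups.csv"))
      list(outputs = c("partition_sweep.csv", "partition_groups.csv"),
           n_groups = choice$n_groups, gap = choice$gap)
    })
  }

  if ("habitat" %in% stages) {
    manifest$stages$habitat <- run_stage("habitat", {
      if (is.null(envelope)) {
        stop_config("habitat stage needs an envelope (records or override)")
      }
      grid <- read_ascii_grid(bathy)
      mask <- read_basin_mask(basin)
      report <- habitat_report(grid, mask, envelope)
      write_habitat_report(report, out("habitat_report.csv"))
      list(outputs = "habitat_report.csv",
           envelope = c(envelope$d_min_m, envelope$d_max_m),
           global_percent = report$percent[report$basin == "Global"])
    })
  }

  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  log_info("manifest written to %s", out("manifest.json"))
  invisible(manifest)
}
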