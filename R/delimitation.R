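#' Single-linkage partition sweep over a distance matrix
#'
#' Ascending hierarchical (single-linkage) clustering of sequences by
#' pairwise genetic distance, evaluated at every distinct merge height.
#' At threshold `t` the groups are exactly the connected components of the
#' graph whose edges join pairs at distance `<= t`. Each candidate
#' partition is scored by its barcode gap: the smallest between-group
#' distance minus the largest within-group distance.
#'
#' @param dist a complete `gen_dist` (no missing entries; use complete
#'   deletion).
#' @return An object of class `partition_sweep`: data frame `summary`
#'   (threshold, n_groups, max_intra, min_inter, gap) and a list
#'   `partitions` of group-membership vectors (named by sequence id), one
#'   per summary row, ordered by increasing threshold.
#' @export
linkage_sweep <- function(dist) {
  m <- dist$matrix
  if (any(!is.finite(m))) {
    stop_validation("distance matrix has missing entries; use complete-deletion distances")
  }
  n <- length(dist$ids)
  if (n == 1) {
    part <- setNames(1L, dist$ids)
    return(structure(list(
      summary = data.frame(threshold = 0, n_groups = 1L, max_intra = 0,
                           min_inter = NA_real_, gap = NA_real_),
      partitions = list(part), ids = dist$ids),
      class = "partition_sweep"))
  }
  hc <- hclust(as.dist(m), method = "single")
  heights <- sort(unique(c(0, hc$height)))
  partitions <- list()
  rows <- list()
  for (t in heights) {
    grp <- cutree(hc, h = t)
    names(grp) <- dist$ids
    off <- upper.tri(m)
    same <- outer(grp, grp, "==")[off]
    dvals <- m[off]
    # a partition with no within-group pair has no intraspecific
    # distance distribution, hence no defined barcode gap
    max_intra <- if (any(same)) max(dvals[same]) else NA_real_
    min_inter <- if (any(!same)) min(dvals[!same]) else NA_real_
    rows[[length(rows) + 1]] <- data.frame(
      threshold = t, n_groups = length(unique(grp)),
      max_intra = max_intra, min_inter = min_inter,
      gap = min_inter - max_intra)
    partitions[[length(rows)]] <- grp
  }
  structure(list(summary = do.call(rbind, rows), partitions = partitions,
                 ids = dist$ids),
            class = "partition_sweep")
}

#' Best partition by barcode gap
#'
#' Ranks the sweep's candidate partitions by descending barcode gap,
#' breaking ties in favour of fewer groups, and returns the top-ranked
#' partition together with the full ranked list (never a silent single
#' answer). When no partition achieves a positive gap the one-group
#' partition is returned with a warning.
#'
#' Note: this gap-rank criterion is deliberately simpler than published
#' automatic-partitioning tools (e.g. ASAP's composite score and
#' panmixia p-value); treat the ranking as a screening aid, not a
#' probability statement.
#'
#' @param sweep a `partition_sweep`.
#' @return A list of class `partition_choice`: `partition` (named
#'   membership vector), `gap`, `n_groups`, and `ranking` (the summary
#'   data frame with a `rank` column, gap-ranked rows first).
#' @export
best_partition <- function(sweep) {
  s <- sweep$summary
  scored <- which(!is.na(s$gap) & s$gap > 0)
  if (length(scored) == 0) {
    warn_flag("no positive barcode gap; returning the one-group partition",
              class = "hadalrange_no_gap")
    idx <- which(s$n_groups == 1)[1]
    if (is.na(idx)) idx <- nrow(s)
    ranking <- s
    ranking$rank <- NA_integer_
    return(structure(list(partition = sweep$partitions[[idx]],
                          gap = NA_real_, n_groups = s$n_groups[idx],
                          ranking = ranking),
                     class = "partition_choice"))
  }
  ord <- scored[order(-s$gap[scored], s$n_groups[scored])]
  ranking <- s
  ranking$rank <- NA_integer_
  ranking$rank[ord] <- seq_along(ord)
  best <- ord[1]
  structure(list(partition = sweep$partitions[[best]],
                 gap = s$gap[best], n_groups = s$n_groups[best],
                 ranking = ranking[order(ranking$rank, na.last = TRUE), ]),
            class = "partition_choice")
}

#' @export
print.partition_choice <- function(x, ...) {
  cat(sprintf("Best partition: %d group(s), barcode gap = %s\n",
              x$n_groups,
              if (is.na(x$gap)) "none" else format(x$gap, digits = 4)))
  cat("(gap-rank criterion; simpler than ASAP-style composite scoring)\n")
  invisible(x)
}

#' Write a partition sweep report
#'
#' @param choice a `partition_choice`.
#' @param summary_path CSV path for the ranked threshold table.
#' @param membership_path optional CSV path for the best partition's group
#'   membership.
#' @return `summary_path`, invisibly.
#' @export
write_partition_report <- function(choice, summary_path,
                                   membership_path = NULL) {
  write.csv(choice$ranking, summary_path, row.names = FALSE)
  if (!is.null(membership_path)) {
    write.csv(data.frame(id = names(choice$partition),
                         group = as.integer(choice$partition)),
              membership_path, row.names = FALSE)
  }
  invisible(summary_path)
}
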