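#' Base frequency set for distance corrections
#'
#' @param piA,piC,piG,piT nucleotide proportions; must each lie in (0, 1).
#'   Published frequency sets are often rounded to three decimals and may
#'   miss 1 by up to 0.005 (e.g. a printed set summing to 0.999); such
#'   sets are renormalized to sum exactly 1, with a warning. Larger
#'   deviations are configuration errors.
#' @return Named numeric vector of class `base_freqs`.
#' @export
base_freqs <- function(piA, piC, piG, piT) {
  f <- c(A = piA, C = piC, G = piG, T = piT)
  if (any(!is.finite(f)) || any(f <= 0) || any(f >= 1) ||
      abs(sum(f) - 1) > 5e-3) {
    stop_config("base frequencies must lie in (0,1) and sum to 1")
  }
  if (abs(sum(f) - 1) > 1e-6) {
    warn_flag(sprintf("base frequencies sum to %.4f; renormalized", sum(f)),
              class = "hadalrange_freqs_renormalized")
  }
  structure(f / sum(f), class = "base_freqs")
}

#' Empirical base frequencies of an alignment
#'
#' Proportions of A/C/G/T over the retained columns, for use when no
#' externally specified frequencies are available.
#'
#' @inheritParams segregating_sites
#' @return A `base_freqs` vector.
#' @export
empirical_base_freqs <- function(alignment, filter = NULL) {
  m <- filtered_matrix(alignment, filter)
  counts <- table(factor(m, levels = c("A", "C", "G", "T")))
  f <- as.numeric(counts) / sum(counts)
  base_freqs(f[1], f[2], f[3], f[4])
}

#' Uncorrected p-distance matrix
#'
#' Pairwise proportion of differing sites. Under `"complete"` deletion all
#' pairs are compared on the common retained-column universe; under
#' `"pairwise"` deletion each pair is compared on the columns where both
#' sequences carry an unambiguous base, and a pair with zero comparable
#' sites yields a flagged `NA` entry.
#'
#' @param alignment a `dna_alignment` with n >= 2.
#' @param deletion `"complete"` (default) or `"pairwise"`.
#' @return An object of class `gen_dist`: `ids`, symmetric `matrix`,
#'   `model = "raw"`, `deletion`.
#' @export
p_distance_matrix <- function(alignment, deletion = c("complete", "pairwise")) {
  deletion <- match.arg(deletion)
  n <- length(alignment$ids)
  if (n < 2) stop_validation("distance matrix undefined for n < 2")
  d <- matrix(0, n, n, dimnames = list(alignment$ids, alignment$ids))
  if (deletion == "complete") {
    m <- filtered_matrix(alignment, complete_deletion(alignment))
    L <- ncol(m)
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        d[i, j] <- d[j, i] <- sum(m[i, ] != m[j, ]) / L
      }
    }
  } else {
    m <- alignment$matrix
    good <- m %in% c("A", "C", "G", "T")
    dim(good) <- dim(m)
    any_na <- FALSE
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        comp <- good[i, ] & good[j, ]
        nc <- sum(comp)
        if (nc == 0) {
          d[i, j] <- d[j, i] <- NA_real_
          any_na <- TRUE
        } else {
          d[i, j] <- d[j, i] <- sum(m[i, comp] != m[j, comp]) / nc
        }
      }
    }
    if (any_na) {
      warn_flag("some pairs share no comparable sites; entries set to NA",
                class = "hadalrange_incomparable_pair")
    }
  }
  structure(list(ids = alignment$ids, matrix = d, model = "raw",
                 freqs = NULL, deletion = deletion),
            class = "gen_dist")
}

#' Correct a raw distance matrix under JC69 or F81
#'
#' JC69: \eqn{d = -\frac{3}{4}\ln(1 - \frac{4}{3}p)}. F81:
#' \eqn{d = -B \ln(1 - p/B)} with \eqn{B = 1 - \sum_i \pi_i^2} computed
#' from externally specified base frequencies. At uniform frequencies
#' (B = 3/4) F81 reduces exactly to JC69. Saturated entries (log argument
#' \eqn{\le 0}) become `NaN` with a warning rather than `Inf`, so
#' downstream summaries skip them.
#'
#' @param dist a `gen_dist` with `model = "raw"`.
#' @param model `"JC69"` or `"F81"`.
#' @param freqs a `base_freqs` vector; required for F81.
#' @return A corrected `gen_dist`.
#' @export
correct_distances <- function(dist, model = c("JC69", "F81"), freqs = NULL) {
  model <- match.arg(model)
  if (dist$model != "raw") stop_config("correction requires a raw p-distance matrix")
  if (model == "F81") {
    if (is.null(freqs)) stop_config("F81 correction requires base frequencies")
    B <- 1 - sum(freqs^2)
  } else {
    B <- 3 / 4
  }
  p <- dist$matrix
  arg <- 1 - p / B
  out <- suppressWarnings(-B * log(arg))  # negatives handled as saturation
  sat <- !is.na(arg) & arg <= 0
  if (any(sat)) {
    out[sat] <- NaN
    warn_flag(sprintf("%d saturated pair(s): correction undefined (p >= %g)",
                      sum(sat) / 2, B),
              class = "hadalrange_saturated_distance")
  }
  diag(out) <- 0
  structure(list(ids = dist$ids, matrix = out, model = model,
                 freqs = if (model == "F81") freqs else NULL,
                 deletion = dist$deletion),
            class = "gen_dist")
}

#' Range of off-diagonal distances
#'
#' @param dist a `gen_dist`.
#' @return Numeric `c(min, max)` over finite off-diagonal entries.
#' @export
distance_range <- function(dist) {
  v <- dist$matrix[upper.tri(dist$matrix)]
  v <- v[is.finite(v)]
  if (length(v) == 0) stop_validation("no finite off-diagonal distances")
  c(min = min(v), max = max(v))
}

#' @export
print.gen_dist <- function(x, ...) {
  r <- tryCatch(distance_range(x), error = function(e) c(NA, NA))
  cat(sprintf("Genetic distances (%s, %s deletion): %d sequences, range %.4g-%.4g\n",
              x$model, x$deletion, length(x$ids), r[1], r[2]))
  invisible(x)
}

#' Write a distance matrix to CSV
#'
#' @param dist a `gen_dist`.
#' @param path output path for the square-matrix CSV.
#' @param long_path optional path for a long-format (id1, id2, model,
#'   distance) CSV.
#' @return `path`, invisibly.
#' @export
write_distances <- function(dist, path, long_path = NULL) {
  write.csv(data.frame(id = dist$ids, dist$matrix, check.names = FALSE),
            path, row.names = FALSE)
  if (!is.null(long_path)) {
    pairs <- which(upper.tri(dist$matrix), arr.ind = TRUE)
    long <- data.frame(id1 = dist$ids[pairs[, 1]],
                       id2 = dist$ids[pairs[, 2]],
                       model = dist$model,
                       distance = dist$matrix[pairs],
                       stringsAsFactors = FALSE)
    write.csv(long, long_path, row.names = FALSE)
  }
  invisible(path)
}
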