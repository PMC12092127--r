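#' Number of segregating sites
#'
#' Counts retained alignment columns carrying more than one distinct base.
#'
#' @param alignment a `dna_alignment` with at least two sequences.
#' @param filter a `site_filter`; defaults to [complete_deletion()].
#' @return Integer count of polymorphic columns.
#' @export
segregating_sites <- function(alignment, filter = NULL) {
  m <- filtered_matrix(alignment, filter)
  if (nrow(m) < 2) stop_validation("segregating sites undefined for n < 2")
  sum(apply(m, 2, function(col) length(unique(col)) > 1))
}

#' Nucleotide diversity and mean pairwise differences
#'
#' `k_hat` is the mean number of differing retained columns over all
#' \eqn{\binom{n}{2}} sequence pairs; `pi` is `k_hat` divided by the number
#' of retained columns (per-site nucleotide diversity). Computed on the
#' complete-deletion site universe so that `pi` equals the mean of the raw
#' pairwise p-distance matrix under the same deletion mode.
#'
#' @inheritParams segregating_sites
#' @return List with `pi` and `k_hat`.
#' @export
nucleotide_diversity <- function(alignment, filter = NULL) {
  m <- filtered_matrix(alignment, filter)
  n <- nrow(m)
  if (n < 2) stop_validation("nucleotide diversity undefined for n < 2")
  L <- ncol(m)
  total <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      total <- total + sum(m[i, ] != m[j, ])
    }
  }
  k_hat <- total / choose(n, 2)
  list(pi = k_hat / L, k_hat = k_hat)
}

#' Nei's unbiased haplotype diversity
#'
#' \eqn{h = \frac{n}{n-1}\left(1 - \sum_i (n_i/n)^2\right)}: the
#' (sample-size corrected) probability that two sequences drawn without
#' replacement carry different haplotypes.
#'
#' @param table a `haplotype_table` with `n >= 2`.
#' @return Numeric `h` in \[0, 1\].
#' @export
haplotype_diversity <- function(table) {
  n <- table$n
  if (n < 2) stop_validation("haplotype diversity undefined for n < 2")
  freqs <- table$haplotypes$frequency / n
  (n / (n - 1)) * (1 - sum(freqs^2))
}

#' Tajima's constants for a sample of size n
#'
#' The a1, a2, b1, b2, c1, c2, e1, e2 coefficients from the 1989
#' formulation, which standardize the difference between the
#' pairwise-difference and segregating-sites estimators of theta.
#'
#' @param n number of sequences (n >= 2; n >= 4 recommended for the test).
#' @return List of class `tajima_components`.
#' @export
tajima_components <- function(n) {
  if (n < 2) stop_validation("Tajima components undefined for n < 2")
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  structure(list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
                 e1 = e1, e2 = e2, n = n),
            class = "tajima_components")
}

#' Tajima's D
#'
#' \eqn{D = (\hat{k} - ss/a_1) / \sqrt{e_1 ss + e_2 ss(ss-1)}}. Negative
#' values indicate an excess of low-frequency variants relative to the
#' neutral equilibrium expectation (population growth, purifying selection
#' or a sweep); positive values indicate an excess of intermediate
#' frequencies.
#'
#' @param ss number of segregating sites.
#' @param k_hat mean pairwise differences.
#' @param n number of sequences.
#' @return List with `D` (`NaN` with `undefined = TRUE` when `ss = 0`) and
#'   the `tajima_components`.
#' @export
tajimas_d <- function(ss, k_hat, n) {
  comp <- tajima_components(n)
  if (n < 4) warn_flag("Tajima's D with n < 4 is unreliable")
  if (ss < 0) stop_validation("ss must be nonnegative")
  if (ss == 0) {
    return(list(D = NaN, undefined = TRUE, components = comp))
  }
  V <- comp$e1 * ss + comp$e2 * ss * (ss - 1)
  D <- (k_hat - ss / comp$a1) / sqrt(V)
  list(D = D, undefined = FALSE, components = comp)
}

#' Significance of Tajima's D by the beta approximation
#'
#' Under neutrality D is treated as a generalized beta variate with mean 0
#' and variance 1 on the support \[Dmin, Dmax\], where
#' `Dmin = (2/n - 1/a1)/sqrt(e2)` and `Dmax = ((n+1)/(2n) - 1/a1)/sqrt(e2)`
#' (the most extreme site-frequency configurations). The two-sided p-value
#' is `2 * min(F(D), 1 - F(D))`. A D outside the support is clamped with a
#' warning. An alternative to this analytic approximation is coalescent
#' simulation of the null (see [simulate_coalescent_alignment()]).
#'
#' @param D Tajima's D statistic (finite).
#' @param n number of sequences.
#' @return List with `p_value`, `stars` (`"ns"`, `"*"`, `"**"`, `"***"` at
#'   0.05 / 0.01 / 0.001) and the support bounds.
#' @export
tajima_p_value <- function(D, n) {
  if (!is.finite(D)) stop_validation("D must be finite for the beta test")
  comp <- tajima_components(n)
  d_min <- (2 / n - 1 / comp$a1) / sqrt(comp$e2)
  d_max <- ((n + 1) / (2 * n) - 1 / comp$a1) / sqrt(comp$e2)
  if (D < d_min || D > d_max) {
    warn_flag(sprintf("D = %.5f outside beta support [%.5f, %.5f]; clamped",
                      D, d_min, d_max),
              class = "hadalrange_clamped_D")
    D <- min(max(D, d_min), d_max)
  }
  # shape parameters giving mean 0 and variance 1 on [d_min, d_max]
  alpha <- -(1 + d_min * d_max) * d_max / (d_max - d_min)
  beta <- (1 + d_min * d_max) * d_min / (d_max - d_min)
  Fd <- pbeta((D - d_min) / (d_max - d_min), shape1 = beta, shape2 = alpha)
  p <- 2 * min(Fd, 1 - Fd)
  p <- min(p, 1)
  stars <- if (p <= 0.001) "***" else if (p <= 0.01) "**" else
    if (p <= 0.05) "*" else "ns"
  list(p_value = p, stars = stars, d_min = d_min, d_max = d_max)
}

#' Per-locus diversity summary
#'
#' Assembles the standard per-locus summary row: n, haplotype count and
#' diversity, nucleotide diversity, segregating sites, mean pairwise
#' differences, and Tajima's D with its beta-approximation significance.
#'
#' @param alignment a `dna_alignment` (n >= 2).
#' @param filter optional `site_filter` (default complete deletion).
#' @param table optional precomputed `haplotype_table`.
#' @return A list of class `diversity_stats` with fields `n`, `H`, `h`,
#'   `pi`, `ss`, `k_hat`, `D`, `p_value`, `stars`.
#' @export
diversity_summary <- function(alignment, filter = NULL, table = NULL) {
  if (is.null(filter)) filter <- complete_deletion(alignment)
  if (is.null(table)) table <- collapse_haplotypes(alignment, filter)
  ss <- segregating_sites(alignment, filter)
  nd <- nucleotide_diversity(alignment, filter)
  h <- haplotype_diversity(table)
  td <- tajimas_d(ss, nd$k_hat, table$n)
  if (td$undefined) {
    p <- NA_real_; stars <- "ns"
  } else {
    tp <- tajima_p_value(td$D, table$n)
    p <- tp$p_value; stars <- tp$stars
  }
  structure(list(locus = alignment$locus, n = table$n, H = table$H, h = h,
                 pi = nd$pi, ss = ss, k_hat = nd$k_hat, D = td$D,
                 D_undefined = td$undefined, p_value = p, stars = stars),
            class = "diversity_stats")
}

#' @export
print.diversity_stats <- function(x, ...) {
  cat(sprintf("Diversity (%s): n = %d, H = %d\n", x$locus, x$n, x$H))
  cat(sprintf("  h  = %.5f\n  pi = %.5f\n  ss = %d\n", x$h, x$pi, x$ss))
  if (x$D_undefined) {
    cat("  Tajima's D undefined (no segregating sites)\n")
  } else {
    # D printed at 5 decimals to match conventional reporting
    cat(sprintf("  Tajima's D = %.5f (p = %.4g) %s\n", x$D, x$p_value,
                x$stars))
  }
  invisible(x)
}

#' Write per-locus diversity summaries to CSV
#'
#' @param stats_list a `diversity_stats` object or list of them.
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
write_diversity_stats <- function(stats_list, path) {
  if (inherits(stats_list, "diversity_stats")) stats_list <- list(stats_list)
  rows <- lapply(stats_list, function(s) {
    data.frame(locus = s$locus, n = s$n, H = s$H,
               h = round(s$h, 5), pi = signif(s$pi, 5), ss = s$ss,
               k_hat = round(s$k_hat, 5),
               tajimas_D = round(s$D, 5), p_value = s$p_value,
               significance = s$stars, stringsAsFactors = FALSE)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
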