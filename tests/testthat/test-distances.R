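test_that("p-distances match inspection and the brute-force oracle", {
  aln <- dna_alignment(c(a = "ACGT", b = "ACGA"))
  d <- p_distance_matrix(aln)
  expect_equal(d$matrix["a", "b"], 0.25)
  expect_equal(diag(d$matrix), c(a = 0, b = 0))

  same <- dna_alignment(c(a = "ACGT", b = "ACGT"))
  expect_equal(p_distance_matrix(same)$matrix["a", "b"], 0)

  for (seed in c(4, 17)) {
    aln <- simulate_coalescent_alignment(9, 80, 5, seed = seed)
    m <- aln$matrix
    set.seed(seed)
    m[runif(length(m)) < 0.05] <- "N"
    masked <- dna_alignment(m)
    for (mode in c("complete", "pairwise")) {
      d <- p_distance_matrix(masked, deletion = mode)
      expect_equal(unname(d$matrix),
                   brute_p_dist(m, complete = mode == "complete"))
    }
  }
})

test_that("p-distances agree with ape::dist.dna under complete deletion", {
  aln <- simulate_coalescent_alignment(10, 120, 5, seed = 31)
  bin <- ape::as.DNAbin(aln$matrix)
  expect_equal(unname(p_distance_matrix(aln)$matrix),
               unname(as.matrix(ape::dist.dna(bin, model = "raw"))),
               tolerance = 1e-12)
  jc <- correct_distances(p_distance_matrix(aln), "JC69")
  expect_equal(unname(jc$matrix),
               unname(as.matrix(ape::dist.dna(bin, model = "JC69"))),
               tolerance = 1e-12)
})

test_that("a pair with no comparable sites is flagged NA in pairwise mode", {
  aln <- dna_alignment(c(a = "AC--", b = "--GT", c = "ACGT"))
  expect_warning(d <- p_distance_matrix(aln, deletion = "pairwise"),
                 class = "hadalrange_incomparable_pair")
  expect_true(is.na(d$matrix["a", "b"]))
  expect_false(is.na(d$matrix["a", "c"]))
})

test_that("JC69/F81 corrections follow the closed forms", {
  aln <- dna_alignment(c(a = "ACGT", b = "ACGT"))
  raw <- p_distance_matrix(aln)
  expect_equal(correct_distances(raw, "JC69")$matrix["a", "b"], 0)

  # scalar check: p = 0.03 under JC69
  raw2 <- raw
  raw2$matrix[1, 2] <- raw2$matrix[2, 1] <- 0.03
  expect_equal(correct_distances(raw2, "JC69")$matrix[1, 2],
               -0.75 * log(1 - 0.04), tolerance = 1e-12)

  # F81 with a published 16S frequency set (prints sum 0.999, hence the
  # renormalization warning)
  expect_warning(f16 <- base_freqs(0.276, 0.118, 0.261, 0.344),
                 class = "hadalrange_freqs_renormalized")
  B <- 1 - sum(f16^2)
  expect_equal(correct_distances(raw2, "F81", f16)$matrix[1, 2],
               -B * log(1 - 0.03 / B), tolerance = 1e-12)

  expect_error(correct_distances(raw2, "F81"),
               class = "hadalrange_config_error")
  expect_error(correct_distances(correct_distances(raw2, "JC69"), "JC69"),
               class = "hadalrange_config_error")
})

test_that("F81 equals JC69 at uniform frequencies; corrections dominate p", {
  aln <- simulate_coalescent_alignment(10, 100, 8, seed = 8)
  raw <- p_distance_matrix(aln)
  jc <- correct_distances(raw, "JC69")
  f81 <- correct_distances(raw, "F81", base_freqs(0.25, 0.25, 0.25, 0.25))
  expect_equal(jc$matrix, f81$matrix, tolerance = 1e-12)
  off <- upper.tri(raw$matrix)
  expect_true(all(jc$matrix[off] >= raw$matrix[off]))
  expect_true(all((jc$matrix[off] > raw$matrix[off]) ==
                    (raw$matrix[off] > 0)))
  # strictly increasing on the domain
  p <- seq(0, 0.7, by = 0.01)
  d <- -0.75 * log(1 - 4 * p / 3)
  expect_true(all(diff(d) > 0))
})

test_that("saturated pairs become NaN and are skipped by summaries", {
  aln <- dna_alignment(c(a = "ACGT", b = "ACGT", c = "ACGT"))
  raw <- p_distance_matrix(aln)
  raw$matrix[1, 2] <- raw$matrix[2, 1] <- 0.8  # beyond 3/4
  raw$matrix[1, 3] <- raw$matrix[3, 1] <- 0.1
  expect_warning(cor <- correct_distances(raw, "JC69"),
                 class = "hadalrange_saturated_distance")
  expect_true(is.nan(cor$matrix[1, 2]))
  d01 <- -0.75 * log(1 - 0.4 / 3)
  expect_equal(distance_range(cor), c(min = 0, max = d01))
})

test_that("distance_range scans off-diagonal finite entries", {
  aln <- simulate_coalescent_alignment(8, 90, 5, seed = 14)
  d <- p_distance_matrix(aln)
  v <- d$matrix[upper.tri(d$matrix)]
  expect_equal(distance_range(d), c(min = min(v), max = max(v)))

  const <- d
  const$matrix[] <- 0.2; diag(const$matrix) <- 0
  expect_equal(unname(distance_range(const)), c(0.2, 0.2))

  empty <- d
  empty$matrix[] <- NaN
  expect_error(distance_range(empty), class = "hadalrange_validation_error")
})
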