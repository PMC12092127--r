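# Frozen oracle values computed with an independent implementation
# (dendropy popgenstat) on alignments regenerated deterministically by
# the coalescent simulator at the given seeds.
DENDROPY_ORACLE <- list(
  list(n = 10, L = 200, theta = 3, seed = 11,
       ss = 8, pi = 0.019333333333333345, D = 1.58481814752355),
  list(n = 20, L = 600, theta = 5, seed = 42,
       ss = 10, pi = 0.004745614035087726, D = 0.035571412581415635),
  list(n = 12, L = 300, theta = 8, seed = 5,
       ss = 37, pi = 0.05085858585858587, D = 1.1138805505269889)
)

test_that("segregating sites counts polymorphic retained columns", {
  expect_equal(segregating_sites(dna_alignment(c(a = "AAT", b = "AAT"))), 0)
  expect_equal(segregating_sites(dna_alignment(c(a = "AAT", b = "AAG",
                                                 c = "ACG"))), 2)
  expect_error(segregating_sites(dna_alignment(c(a = "AAT"))),
               class = "hadalrange_validation_error")
})

test_that("nucleotide diversity matches hand enumeration", {
  aln <- dna_alignment(c(a = "AAT", b = "AAG", c = "ACG"))
  nd <- nucleotide_diversity(aln)
  expect_equal(nd$k_hat, 4 / 3)  # pairs differ by 1, 2, 1 sites
  expect_equal(nd$pi, 4 / 9)
  mono <- dna_alignment(c(a = "ACG", b = "ACG"))
  expect_equal(nucleotide_diversity(mono)$pi, 0)
})

test_that("pi equals the mean raw pairwise p-distance", {
  for (seed in c(2, 13)) {
    aln <- simulate_coalescent_alignment(12, 150, 6, seed = seed)
    nd <- nucleotide_diversity(aln)
    d <- p_distance_matrix(aln)
    expect_equal(nd$pi, mean(d$matrix[upper.tri(d$matrix)]),
                 tolerance = 1e-12)
  }
})

test_that("haplotype diversity follows Nei's unbiased formula", {
  tab <- collapse_haplotypes(dna_alignment(c(a = "AAT", b = "AAT",
                                             c = "AAG", d = "ACG")))
  expect_equal(haplotype_diversity(tab), 5 / 6)  # (4/3)(1 - 0.375)
  single <- collapse_haplotypes(dna_alignment(c(a = "AAA", b = "AAA")))
  expect_equal(haplotype_diversity(single), 0)
  distinct <- collapse_haplotypes(dna_alignment(c(a = "AAA", b = "AAC",
                                                  c = "AAG")))
  expect_equal(haplotype_diversity(distinct), 1)
})

test_that("haplotype diversity is permutation-invariant and maximal at equal frequencies", {
  mk <- function(freqs) {
    # synthetic table with the requested haplotype frequencies
    list(n = sum(freqs),
         haplotypes = data.frame(frequency = freqs))
  }
  expect_equal(haplotype_diversity(mk(c(5, 2, 1))),
               haplotype_diversity(mk(c(1, 5, 2))))
  expect_gt(haplotype_diversity(mk(c(3, 3, 3))),
            haplotype_diversity(mk(c(7, 1, 1))))
})

test_that("Tajima's D and components match the independent oracle to 1e-12", {
  for (o in DENDROPY_ORACLE) {
    aln <- simulate_coalescent_alignment(o$n, o$L, o$theta, seed = o$seed)
    filt <- complete_deletion(aln)
    ss <- segregating_sites(aln, filt)
    nd <- nucleotide_diversity(aln, filt)
    expect_equal(ss, o$ss)
    expect_equal(nd$pi, o$pi, tolerance = 1e-12)
    td <- tajimas_d(ss, nd$k_hat, o$n)
    expect_equal(td$D, o$D, tolerance = 1e-12)
  }
})

test_that("Tajima's D is flagged undefined when there is no polymorphism", {
  td <- tajimas_d(0, 0, 10)
  expect_true(td$undefined)
  expect_true(is.nan(td$D))
})

test_that("beta-approximation p-value behaves at the centre and clamps at the edges", {
  p0 <- tajima_p_value(0, 26)
  expect_gt(p0$p_value, 0.5)
  expect_identical(p0$stars, "ns")
  expect_warning(pc <- tajima_p_value(-10, 26),
                 class = "hadalrange_clamped_D")
  expect_lte(pc$p_value, 1)
})

test_that("diversity_summary agrees with individually called operations", {
  aln <- simulate_coalescent_alignment(15, 300, 6, seed = 21,
                                       locus = "16S")
  filt <- complete_deletion(aln)
  tab <- collapse_haplotypes(aln, filt)
  s <- diversity_summary(aln, filt, tab)
  expect_equal(s$ss, segregating_sites(aln, filt))
  expect_equal(s$pi, nucleotide_diversity(aln, filt)$pi)
  expect_equal(s$h, haplotype_diversity(tab))
  expect_equal(s$H, tab$H)
  expect_equal(s$D, tajimas_d(s$ss, s$k_hat, s$n)$D)
  expect_equal(s$p_value, tajima_p_value(s$D, s$n)$p_value)
})
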