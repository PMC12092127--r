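test_that("parsimony probability is 1 at j = 0 and deterministic by seed", {
  p0 <- parsimony_probability(0, 600, mc_reps = 2000, seed = 1)
  expect_identical(p0$P_pars, 1)
  a <- parsimony_probability(3, 400, mc_reps = 2000, seed = 7)
  b <- parsimony_probability(3, 400, mc_reps = 2000, seed = 7)
  expect_identical(a$P_pars, b$P_pars)
  expect_error(parsimony_probability(11, 10, mc_reps = 2000),
               class = "hadalrange_validation_error")
  expect_error(parsimony_probability(1, 100, mc_reps = 10),
               class = "hadalrange_config_error")
})

test_that("one observed difference on a long locus is almost surely one step", {
  est <- parsimony_probability(1, 600, mc_reps = 1e5, seed = 2)
  expect_gte(est$P_pars, 0.99)
})

test_that("connection limit honours degenerate thresholds and grows with L", {
  expect_equal(connection_limit(50, threshold = 0), 50L)
  expect_gte(connection_limit(200, threshold = 1, mc_reps = 2000, seed = 3), 1L)
  lims <- vapply(c(100, 300, 600, 1000), function(L) {
    connection_limit(L, mc_reps = 2000, seed = 4)
  }, 1L)
  expect_true(all(diff(lims) >= 0))
})

test_that("build_network produces hand-checkable minimum spanning networks", {
  single <- collapse_haplotypes(dna_alignment(c(a = "ACGT", b = "ACGT")))
  net1 <- build_network(single)
  expect_equal(nrow(net1$nodes), 1)
  expect_equal(nrow(net1$edges), 0)

  # distances: h1-h2 = 1, h1-h3 = 1, h2-h3 = 2 -> star centred on h1
  tri <- collapse_haplotypes(dna_alignment(c(x = "AAAA", y = "AAAT",
                                             z = "AAGA")))
  net3 <- build_network(tri, limit = 10)
  expect_equal(nrow(net3$edges), 2)
  expect_false(any(net3$nodes$latent))
  deg <- table(c(net3$edges$from, net3$edges$to))
  expect_equal(unname(deg[["H1"]]), 2)

  # two haplotypes three steps apart -> path through 2 latent nodes
  far <- collapse_haplotypes(dna_alignment(c(p = "AAAA", q = "TTTA")))
  netf <- build_network(far, limit = 5)
  expect_equal(sum(netf$nodes$latent), 2)
  expect_equal(nrow(netf$edges), 3)
  expect_true(all(grepl("-step-", netf$nodes$id[netf$nodes$latent])))
  deg <- table(c(netf$edges$from, netf$edges$to))
  expect_true(all(deg[netf$nodes$id[netf$nodes$latent]] >= 2))
})

test_that("connection limit controls components; frequencies are conserved", {
  aln <- simulate_coalescent_alignment(18, 120, 7, seed = 6)
  tab <- collapse_haplotypes(aln)
  full <- build_network(tab, limit = Inf)
  expect_equal(length(unique(full$components[tab$haplotypes$haplotype_id])), 1)
  expect_equal(sum(full$nodes$frequency), tab$n)

  none <- build_network(tab, limit = 0)
  expect_equal(nrow(none$edges), 0)
  expect_equal(length(unique(none$components)), tab$H)
})

test_that("network edges are independent of input row order", {
  aln <- simulate_coalescent_alignment(16, 150, 9, seed = 12)
  tab <- collapse_haplotypes(aln)
  net <- build_network(tab, limit = Inf)
  set.seed(1)
  perm <- sample(seq_along(aln$ids))
  tab2 <- collapse_haplotypes(dna_alignment(aln$matrix[perm, ],
                                            locality = aln$locality))
  net2 <- build_network(tab2, limit = Inf)
  expect_equal(network_signature(net2, tab2), network_signature(net, tab))
})

test_that("classify_haplotypes splits shared from private localities", {
  loc <- c(a = "Kermadec", b = "Japan", c = "Kermadec", d = "Kermadec")
  aln <- dna_alignment(c(a = "AAT", b = "AAT", c = "AAG", d = "ACG"),
                       locality = loc)
  cls <- classify_haplotypes(collapse_haplotypes(aln))
  expect_equal(unname(cls), c("shared", "private", "private"))

  part <- dna_alignment(c(a = "AAT", b = "AAT"),
                        locality = c(a = "Kermadec"))
  err <- expect_error(classify_haplotypes(collapse_haplotypes(part)),
                      class = "hadalrange_validation_error")
  expect_match(conditionMessage(err), "b")
})

test_that("network export writes edge list, node table and GraphML", {
  tab <- collapse_haplotypes(dna_alignment(c(x = "AAAA", y = "AATT")))
  net <- build_network(tab, limit = 5)
  e <- tempfile(fileext = ".csv"); n <- tempfile(fileext = ".csv")
  g <- tempfile(fileext = ".graphml")
  write_network(net, e, nodes_path = n, graphml_path = g)
  expect_equal(nrow(utils::read.csv(e)), nrow(net$edges))
  expect_equal(nrow(utils::read.csv(n)), nrow(net$nodes))
  skip_if_not_installed("igraph")
  gg <- igraph::read_graph(g, format = "graphml")
  expect_equal(igraph::gorder(gg), nrow(net$nodes))
  expect_equal(igraph::gsize(gg), nrow(net$edges))
})
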