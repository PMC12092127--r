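# Shared in-code fixtures.  Everything is built programmatically so the
# suite carries no binary data.

# 5 sequences, 10 sites, 3 segregating sites; reference statistics for
# this alignment were frozen from an independent implementation
# (dendropy popgenstat): ss = 3, pi = 0.16, D = 0.6989953896984744.
toy_alignment <- function(locality = NULL) {
  seqs <- c(s1 = "AATAAAAAAA", s2 = "AATAAAAAAA", s3 = "AAGAAAAAAA",
            s4 = "ACGAAAAAAA", s5 = "ACGAAAATAA")
  dna_alignment(seqs, locus = "other", locality = locality)
}

# Two groups of identical sequences separated by exactly one differing
# site out of 10 (p-distance 0.1 between groups, 0 within).
two_cluster_alignment <- function() {
  seqs <- c(a1 = "AAAAAAAAAA", a2 = "AAAAAAAAAA", a3 = "AAAAAAAAAA",
            b1 = "AAAAAAAAAT", b2 = "AAAAAAAAAT")
  dna_alignment(seqs)
}

write_records_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

toy_records_df <- function() {
  data.frame(site_id = c("KT1", "KT1", "MFZ2"),
             feature = c("Kermadec", "Kermadec", "Murray FZ"),
             basin = c("Pacific", "Pacific", "Pacific"),
             lat = c(-32.1, -32.1, 30.5),
             lon = c(-177.4, -177.4, -140.2),
             depth_m = c(4000, 5000, 6000),
             record_type = c("collection", "observation", "both"),
             stringsAsFactors = FALSE)
}

write_fasta <- function(seqs, path = tempfile(fileext = ".fasta")) {
  writeLines(paste0(">", names(seqs), "\n", seqs), path)
  path
}

# Independent per-pair, per-column p-distance (brute force oracle).
brute_p_dist <- function(mat, complete = TRUE) {
  good <- matrix(mat %in% c("A", "C", "G", "T"), nrow(mat))
  if (complete) {
    keep <- apply(good, 2, all)
    mat <- mat[, keep, drop = FALSE]
    good <- good[, keep, drop = FALSE]
  }
  n <- nrow(mat)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    comp <- good[i, ] & good[j, ]
    d[i, j] <- if (sum(comp) == 0) NA_real_ else
      sum(mat[i, comp] != mat[j, comp]) / sum(comp)
  }
  d
}

# Graph-threshold components: BFS over edges {distance <= t}.
graph_components <- function(m, t) {
  n <- nrow(m)
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    queue <- s
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cur
      queue <- c(queue, which(m[v, ] <= t & is.na(comp)))
    }
  }
  comp
}

# Label-invariant network signature: the multiset of accepted haplotype
# connections, each keyed by the (sorted) representative sequences of its
# two sampled endpoints and its step count (latent chains contracted).
network_signature <- function(net, table) {
  seq_of <- stats::setNames(table$haplotypes$sequence,
                            table$haplotypes$haplotype_id)
  anchor <- function(id) {
    if (id %in% names(seq_of)) return(c(seq_of[[id]], NA))
    parts <- regmatches(id, regexec("^(H\\d+)-(H\\d+)-step-\\d+$", id))[[1]]
    c(seq_of[[parts[2]]], seq_of[[parts[3]]])
  }
  links <- character(0)
  # direct sampled-sampled edges are single steps
  for (i in seq_len(nrow(net$edges))) {
    a <- net$edges$from[i]; b <- net$edges$to[i]
    if (a %in% names(seq_of) && b %in% names(seq_of)) {
      ends <- sort(c(seq_of[[a]], seq_of[[b]]))
      links <- c(links, paste(ends[1], ends[2], 1, sep = "|"))
    }
  }
  # latent chains: steps = latent-node count for that source edge + 1
  lat <- net$nodes$id[net$nodes$latent]
  if (length(lat) > 0) {
    prefix <- sub("-step-\\d+$", "", lat)
    for (p in unique(prefix)) {
      ends <- sort(anchor(lat[prefix == p][1]))
      links <- c(links, paste(ends[1], ends[2],
                              sum(prefix == p) + 1, sep = "|"))
    }
  }
  sort(links)
}
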