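## Run code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## Monte-Carlo histogram of observed differences after k substitutions
## placed uniformly over L sites, each substitution replacing the current
## base by one of the other three uniformly (Jukes-Cantor steps).  Given h
## hits at one site, the final base differs from the original with
## probability (3/4)(1 - (-1/3)^h); sites are independent given hit
## counts, so we draw the hit multiset and per-site Bernoulli outcomes.
## Returns P(observed == j) estimated over `reps` replicates.
mc_obs_prob <- function(L, k, j, reps) {
  if (k == 0) return(as.numeric(j == 0))
  if (j > k) return(0)
  site <- sample.int(L, reps * k, replace = TRUE)
  key <- (rep(seq_len(reps), each = k) - 1) * L + site
  r <- rle(sort(key))
  h <- r$lengths
  rep_of <- (r$values - 1) %/% L + 1
  p_diff <- 0.75 * (1 - (-1 / 3)^h)
  differs <- runif(length(h)) < p_diff
  obs <- tabulate(rep_of[differs], nbins = reps)
  mean(obs == j)
}

#' Parsimony probability of a mutational step count
#'
#' Estimates the probability that an observed difference of `j` sites
#' between two sequences of aligned length `L` reflects exactly `j`
#' substitutions (no hidden multiple hits) — the quantity statistical
#' parsimony thresholds at 95% when deciding whether haplotypes may be
#' connected. Computed as \eqn{P(j) = w_j / \sum_{k \ge j} w_k}, where
#' `w_k` is the Monte-Carlo probability that `k` substitutions placed
#' uniformly over `L` sites (Jukes-Cantor style base changes) produce
#' exactly `j` visible differences; the sum is truncated at the first `k`
#' whose contribution falls below 1e-4. Deterministic given `seed`.
#'
#' @param j observed number of differing sites (0 <= j <= L).
#' @param L alignment length (retained sites).
#' @param mc_reps Monte-Carlo replicates per step count (>= 1000).
#' @param seed integer seed.
#' @return An object of class `parsimony_estimate` with `j`, `L`,
#'   `P_pars`, `mc_reps`, `seed`.
#' @export
parsimony_probability <- function(j, L, mc_reps = 10000, seed = 1) {
  if (j > L) stop_validation("j cannot exceed the alignment length")
  if (mc_reps < 1000) stop_config("mc_reps must be at least 1000")
  P <- with_seed(seed, {
    w <- numeric(0)
    k <- j
    repeat {
      wk <- mc_obs_prob(L, k, j, mc_reps)
      if (k > j && wk < 1e-4) break
      w <- c(w, wk)
      k <- k + 1
      if (k > j + 60) break  # safety cap; contributions are negligible here
    }
    if (sum(w) == 0) 0 else w[1] / sum(w)
  })
  structure(list(j = j, L = L, P_pars = P, mc_reps = mc_reps, seed = seed),
            class = "parsimony_estimate")
}

#' 95% connection limit for a statistical-parsimony network
#'
#' The largest step count `j` whose parsimony probability stays at or
#' above `threshold` (by default 0.95), but at least 1. Haplotype pairs
#' farther apart than this limit are left unconnected in
#' [build_network()].
#'
#' @param L alignment length.
#' @param threshold probability threshold in \[0, 1\] (default 0.95).
#' @param mc_reps,seed passed to [parsimony_probability()].
#' @return Integer step limit `j*`.
#' @export
connection_limit <- function(L, threshold = 0.95, mc_reps = 10000, seed = 1) {
  if (L < 1) stop_validation("L must be >= 1")
  if (threshold <= 0) return(as.integer(L))
  j_star <- 1L
  for (j in seq_len(L)) {
    est <- parsimony_probability(j, L, mc_reps = mc_reps, seed = seed)
    if (est$P_pars >= threshold) j_star <- as.integer(j) else break
  }
  j_star
}

#' @export
print.parsimony_estimate <- function(x, ...) {
  cat(sprintf("P_pars(j = %d | L = %d) = %.4f (%d MC reps, seed %d)\n",
              x$j, x$L, x$P_pars, x$mc_reps, x$seed))
  invisible(x)
}

## Hamming distances between haplotype representative strings.
hap_step_matrix <- function(seqs) {
  mats <- do.call(rbind, strsplit(seqs, ""))
  H <- length(seqs)
  d <- matrix(0L, H, H)
  if (H > 1) {
    for (i in seq_len(H - 1)) {
      for (j in seq(i + 1, H)) {
        d[i, j] <- d[j, i] <- sum(mats[i, ] != mats[j, ])
      }
    }
  }
  d
}

#' Build a statistical-parsimony haplotype network
#'
#' Connects haplotypes by unit mutational steps up to a connection limit,
#' as a minimum spanning network: candidate pairs are taken in increasing
#' distance order and a pair is linked when its two endpoints lay in
#' different components at the start of that distance level, so all
#' equally-short alternative connections (reticulations) are retained.
#' Links longer than one step are expanded through latent (unsampled,
#' frequency-0) intermediate nodes named `<id1>-<id2>-step-<k>`.
#' Haplotype pairs beyond the limit stay in separate components.
#'
#' @param table a `haplotype_table`.
#' @param limit connection limit in mutational steps (e.g. from
#'   [connection_limit()]); `Inf` connects everything.
#' @return An object of class `haplo_network`: `nodes` data frame (id,
#'   frequency, latent, localities), `edges` data frame (from, to) of unit
#'   steps, `connection_limit`, `components` (named membership vector).
#' @export
build_network <- function(table, limit = Inf) {
  df <- table$haplotypes
  H <- nrow(df)
  d <- hap_step_matrix(df$sequence)
  ids <- df$haplotype_id

  parent <- seq_len(H)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }

  pairs <- which(upper.tri(d), arr.ind = TRUE)
  if (nrow(pairs) > 0) {
    pd <- d[pairs]
    ord <- order(pd, ids[pairs[, 1]], ids[pairs[, 2]])
    pairs <- pairs[ord, , drop = FALSE]
    pd <- pd[ord]
  } else {
    pd <- integer(0)
  }

  accepted <- list()
  for (lev in unique(pd)) {
    if (lev > limit) break
    sel <- which(pd == lev)
    comp_start <- vapply(seq_len(H), find, 1L)
    for (s in sel) {
      i <- pairs[s, 1]; j <- pairs[s, 2]
      if (comp_start[i] != comp_start[j]) {
        accepted[[length(accepted) + 1]] <- c(i, j, lev)
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }

  nodes <- data.frame(id = ids, frequency = df$frequency, latent = FALSE,
                      stringsAsFactors = FALSE)
  nodes$localities <- df$localities
  edges <- data.frame(from = character(0), to = character(0),
                      stringsAsFactors = FALSE)
  node_comp <- vapply(seq_len(H), find, 1L)
  comp_of <- setNames(match(node_comp, unique(node_comp)), ids)

  for (e in accepted) {
    i <- e[1]; j <- e[2]; steps <- e[3]
    a <- ids[i]; b <- ids[j]
    if (a > b) { tmp <- a; a <- b; b <- tmp }
    path <- a
    if (steps > 1) {
      lat <- sprintf("%s-%s-step-%d", a, b, seq_len(steps - 1))
      nodes <- rbind(nodes, data.frame(id = lat, frequency = 0L,
                                       latent = TRUE,
                                       localities = I(rep(list(character(0)),
                                                          length(lat))),
                                       stringsAsFactors = FALSE))
      comp_of[lat] <- comp_of[[ids[i]]]
      path <- c(path, lat)
    }
    path <- c(path, b)
    edges <- rbind(edges, data.frame(from = path[-length(path)],
                                     to = path[-1],
                                     stringsAsFactors = FALSE))
  }
  structure(list(nodes = nodes, edges = edges,
                 connection_limit = limit,
                 components = comp_of),
            class = "haplo_network")
}

#' @export
print.haplo_network <- function(x, ...) {
  cat(sprintf("Haplotype network: %d sampled + %d latent nodes, %d unit edges, %d component(s) (limit %s steps)\n",
              sum(!x$nodes$latent), sum(x$nodes$latent), nrow(x$edges),
              length(unique(x$components)),
              format(x$connection_limit)))
  invisible(x)
}

#' Classify haplotypes as shared or private
#'
#' A haplotype is private when all its members were sampled at a single
#' locality, shared when its locality set spans two or more.
#'
#' @param table a `haplotype_table` built from an alignment with locality
#'   labels.
#' @return Named character vector (`"shared"`/`"private"`) over haplotype
#'   ids.
#' @export
classify_haplotypes <- function(table) {
  df <- table$haplotypes
  missing <- unlist(lapply(seq_len(nrow(df)), function(i) {
    if (length(df$localities[[i]]) == 0) df$members[[i]] else
      df$unlocalized[[i]]
  }))
  if (length(missing) > 0) {
    stop_validation(sprintf("members lack locality labels: %s",
                            paste(missing, collapse = ", ")))
  }
  setNames(ifelse(lengths(df$localities) == 1, "private", "shared"),
           df$haplotype_id)
}

#' Export a haplotype network
#'
#' Writes a plain edge-list CSV, a node-attribute CSV, and (optionally) a
#' GraphML file.
#'
#' @param network a `haplo_network`.
#' @param edges_path path for the edge-list CSV.
#' @param nodes_path optional path for the node attribute CSV.
#' @param graphml_path optional path for a GraphML export.
#' @return `edges_path`, invisibly.
#' @export
write_network <- function(network, edges_path, nodes_path = NULL,
                          graphml_path = NULL) {
  write.csv(network$edges, edges_path, row.names = FALSE)
  nd <- data.frame(id = network$nodes$id,
                   frequency = network$nodes$frequency,
                   latent = network$nodes$latent,
                   localities = vapply(network$nodes$localities, paste, "",
                                       collapse = ";"),
                   component = network$components[network$nodes$id],
                   stringsAsFactors = FALSE)
  if (!is.null(nodes_path)) write.csv(nd, nodes_path, row.names = FALSE)
  if (!is.null(graphml_path)) {
    con <- file(graphml_path, "w")
    on.exit(close(con))
    writeLines(c(
      '<?xml version="1.0" encoding="UTF-8"?>',
      '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
      '<key id="freq" for="node" attr.name="frequency" attr.type="int"/>',
      '<key id="lat" for="node" attr.name="latent" attr.type="boolean"/>',
      '<graph edgedefault="undirected">'), con)
    writeLines(sprintf(
      '<node id="%s"><data key="freq">%d</data><data key="lat">%s</data></node>',
      nd$id, nd$frequency, tolower(as.character(nd$latent))), con)
    if (nrow(network$edges) > 0) {
      writeLines(sprintf('<edge source="%s" target="%s"/>',
                         network$edges$from, network$edges$to), con)
    }
    writeLines(c('</graph>', '</graphml>'), con)
  }
  invisible(edges_path)
}
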