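# Independent oracles and graph fixtures used across the suite. The
# oracles deliberately avoid the code paths they check: scores come from
# explicit shortest-path enumeration, distances from Floyd-Warshall,
# cliques from exhaustive subset enumeration, hypergeometric tails from
# direct probability summation.

rand_graph <- function(n, p, seed) {
  withr::with_seed(seed, {
    g <- igraph::sample_gnp(n, p)
    igraph::V(g)$name <- sprintf("v%03d", seq_len(n))
    igraph::simplify(g)
  })
}

# S2B by explicit enumeration of every shortest path of every retained
# seed pair, testing node membership per path.
s2b_path_oracle <- function(net, seeds, avgd) {
  nodes <- igraph::V(net)$name
  numer <- stats::setNames(numeric(length(nodes)), nodes)
  den <- stats::setNames(numeric(length(nodes)), nodes)
  for (i in seeds$seeds_a) {
    for (j in seeds$seeds_b) {
      dij <- igraph::distances(net, v = i, to = j)[1, 1]
      if (!is.finite(dij) || dij > avgd) next
      paths <- igraph::all_shortest_paths(net, from = i, to = j)$vpaths
      on_any <- unique(nodes[unlist(lapply(paths, as.integer))])
      contrib <- setdiff(nodes, j)   # the j != k summation limit
      den[contrib] <- den[contrib] + 1
      hit <- intersect(on_any, contrib)
      numer[hit] <- numer[hit] + 1
    }
  }
  score <- ifelse(den > 0, numer / den, 0)
  score[seeds$shared_discarded] <- NA_real_
  score
}

# All-pairs hop distances by Floyd-Warshall on the adjacency matrix.
fw_distances <- function(net) {
  n <- igraph::vcount(net)
  a <- igraph::as_adjacency_matrix(net, sparse = FALSE)
  d <- matrix(Inf, n, n, dimnames = dimnames(a))
  d[a > 0] <- 1
  diag(d) <- 0
  for (k in seq_len(n)) {
    d <- pmin(d, outer(d[, k], d[k, ], `+`))
  }
  d
}

# Maximal cliques of size >= min_size by exhaustive subset enumeration.
clique_oracle <- function(net, min_size = 4) {
  nodes <- sort(igraph::V(net)$name)
  a <- igraph::as_adjacency_matrix(net, sparse = FALSE)[nodes, nodes]
  out <- list()
  for (s in min_size:length(nodes)) {
    found <- FALSE
    combs <- utils::combn(nodes, s)
    for (ci in seq_len(ncol(combs))) {
      mem <- combs[, ci]
      if (sum(a[mem, mem]) != s * (s - 1)) next
      found <- TRUE
      others <- setdiff(nodes, mem)
      maximal <- !any(colSums(a[mem, others, drop = FALSE]) == s)
      if (maximal) out[[length(out) + 1L]] <- mem
    }
    if (!found) break
  }
  key <- vapply(out, paste, character(1), collapse = "\r")
  out[order(-lengths(out), key)]
}

# Upper hypergeometric tail by direct summation of the pmf.
hyper_tail_oracle <- function(ks, k, s0, n) {
  sum(vapply(ks:min(k, s0), function(x) {
    choose(s0, x) * choose(n - s0, k - x) / choose(n, k)
  }, numeric(1)))
}

# A deterministic two-block graph with a bridge, handy for small fixtures.
two_triangle_bridge <- function() {
  igraph::make_graph(~ A - B, B - C, C - A, C - D, D - E, E - F, F - D)
}
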