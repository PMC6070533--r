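# Structural analysis of the candidate-induced subnetwork: maximal cliques
# and clustering of candidates by co-occurrence on the retained shortest
# paths that generated their scores.

#' Subnetwork induced by a candidate set
#'
#' @param net Undirected igraph object.
#' @param candidates Character vector of candidate node names (must be
#'   network nodes).
#' @return Object of class `candidate_subnetwork`: the induced `graph` and
#'   a `components` table of connected-component sizes.
#' @export
induced_subnetwork <- function(net, candidates) {
  net <- as_s2b_network(net)
  nodes <- igraph::V(net)$name
  if (!all(candidates %in% nodes)) {
    stop(sum(!candidates %in% nodes), " candidate(s) are not network nodes")
  }
  g <- igraph::induced_subgraph(net, candidates)
  comp <- igraph::components(g)
  structure(
    list(graph = g,
         components = data.frame(component = seq_along(comp$csize),
                                 size = as.integer(comp$csize))),
    class = "candidate_subnetwork"
  )
}

#' @export
print.candidate_subnetwork <- function(x, ...) {
  cat("candidate subnetwork:", igraph::vcount(x$graph), "nodes,",
      igraph::ecount(x$graph), "edges,", nrow(x$components),
      "component(s)\n")
  invisible(x)
}

#' Maximal cliques of the candidate subnetwork
#'
#' All maximal cliques with at least `min_size` members (sub-cliques of a
#' larger clique are not reported). Deterministic ordering: size
#' descending, then lexicographic membership.
#'
#' @param sub A [induced_subnetwork()] object (or an igraph object).
#' @param min_size Minimum clique size (the reference analysis highlights
#'   cliques of 4 or more proteins).
#' @return List of character vectors, each a maximal clique.
#' @export
find_cliques <- function(sub, min_size = 4) {
  g <- if (inherits(sub, "candidate_subnetwork")) sub$graph else
    as_s2b_network(sub)
  stopifnot(min_size >= 3)
  cl <- igraph::max_cliques(g, min = min_size)
  cl <- lapply(cl, function(v) sort(igraph::V(g)$name[as.integer(v)]))
  key <- vapply(cl, paste, character(1), collapse = "\r")
  cl[order(-lengths(cl), key)]
}

#' Candidate co-occurrence on retained shortest paths
#'
#' Enumerates, for every retained seed pair (distance at most `avgd`), all
#' shortest paths between the two seeds and counts how often each
#' unordered pair of candidates appears together on a path. Path
#' enumeration is capped per seed pair; hitting the cap is reported via
#' the `"capped_pairs"` attribute.
#'
#' @param net Undirected igraph object.
#' @param seeds A [make_seed_pair()] object (the same used for scoring).
#' @param candidates Character vector of candidate nodes.
#' @param avgd Path-length cutoff used for scoring.
#' @param max_paths_per_pair Enumeration cap per seed pair.
#' @return Symmetric integer matrix of co-occurrence counts over
#'   `candidates`, with attribute `"capped_pairs"` (number of seed pairs
#'   whose enumeration hit the cap).
#' @export
path_cooccurrence <- function(net, seeds, candidates, avgd,
                              max_paths_per_pair = 100) {
  net <- as_s2b_network(net)
  stopifnot(inherits(seeds, "s2b_seed_pair"), length(candidates) > 0)
  candidates <- sort(unique(candidates))
  counts <- matrix(0L, length(candidates), length(candidates),
                   dimnames = list(candidates, candidates))
  capped <- 0L
  for (i in seeds$seeds_a) {
    d <- igraph::distances(net, v = i, to = seeds$seeds_b)[1, ]
    targets <- seeds$seeds_b[is.finite(d) & d <= avgd]
    if (!length(targets)) next
    asp <- igraph::all_shortest_paths(net, from = i, to = targets)$vpaths
    ends <- vapply(asp, function(p) igraph::V(net)$name[as.integer(p[length(p)])],
                   character(1))
    for (j in unique(ends)) {
      paths <- asp[ends == j]
      if (length(paths) > max_paths_per_pair) {
        capped <- capped + 1L
        paths <- paths[seq_len(max_paths_per_pair)]
      }
      for (p in paths) {
        on_path <- intersect(igraph::V(net)$name[as.integer(p)], candidates)
        if (length(on_path) >= 2) {
          idx <- match(on_path, candidates)
          pr <- utils::combn(sort(idx), 2)
          for (q in seq_len(ncol(pr))) {
            counts[pr[1, q], pr[2, q]] <- counts[pr[1, q], pr[2, q]] + 1L
            counts[pr[2, q], pr[1, q]] <- counts[pr[2, q], pr[1, q]] + 1L
          }
        }
      }
    }
  }
  if (capped > 0) {
    message(capped, " seed pair(s) hit the path enumeration cap (",
            max_paths_per_pair, ")")
  }
  attr(counts, "capped_pairs") <- capped
  counts
}

# Mean silhouette width of a labelling under a distance matrix.
mean_silhouette <- function(dmat, labels) {
  n <- length(labels)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    own[i] <- FALSE
    if (!any(own)) { s[i] <- 0; next }   # singleton
    a <- mean(dmat[i, own])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(dmat[i, labels == l]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' Cluster candidates by path co-occurrence
#'
#' Average-linkage hierarchical clustering on the distance
#' `1 - count / max(count)`. The tree is cut at `k` clusters when given;
#' otherwise `k` is chosen by maximum mean silhouette width over
#' `2..max_k`. Labels are deterministic (candidates are processed in
#' lexicographic order).
#'
#' @param cooccurrence Matrix from [path_cooccurrence()].
#' @param k Number of clusters, or `NULL` to choose by silhouette.
#' @param max_k Largest `k` tried when choosing automatically.
#' @param method Clustering method; only `"hierarchical_average"` is
#'   provided.
#' @return Named integer vector of cluster labels.
#' @export
cluster_candidates <- function(cooccurrence, k = NULL, max_k = 10,
                               method = "hierarchical_average") {
  method <- match.arg(method, "hierarchical_average")
  stopifnot(is.matrix(cooccurrence),
            nrow(cooccurrence) == ncol(cooccurrence))
  mx <- max(cooccurrence)
  if (mx <= 0) stop("empty co-occurrence data: no candidate pair shares a path")
  ord <- order(rownames(cooccurrence))
  cm <- cooccurrence[ord, ord]
  dmat <- 1 - cm / mx
  diag(dmat) <- 0
  n <- nrow(dmat)
  if (!is.null(k) && k == 1) {
    return(stats::setNames(rep(1L, n), rownames(dmat)))
  }
  hc <- stats::hclust(stats::as.dist(dmat), method = "average")
  if (is.null(k)) {
    ks <- seq(2L, max(2L, min(max_k, n - 1L)))
    sil <- vapply(ks, function(kk) {
      mean_silhouette(dmat, stats::cutree(hc, kk))
    }, numeric(1))
    k <- ks[which.max(sil)]
  }
  labels <- stats::cutree(hc, k)
  stats::setNames(as.integer(labels), rownames(dmat))
}

#' Export an annotated candidate subnetwork as GraphML
#'
#' Writes the candidate-induced subgraph with per-node attributes (S2B
#' score, specificity scores, cluster label, clique membership, seed
#' flags) for network viewers.
#'
#' @param sub A [induced_subnetwork()] object.
#' @param result An [s2b_run()] result.
#' @param path Output file path.
#' @param clusters Optional labels from [cluster_candidates()].
#' @param cliques Optional clique list from [find_cliques()].
#' @return `path`, invisibly.
#' @export
write_candidate_graphml <- function(sub, result, path, clusters = NULL,
                                    cliques = NULL) {
  stopifnot(inherits(sub, "candidate_subnetwork"),
            inherits(result, "s2b_result"))
  g <- sub$graph
  nm <- igraph::V(g)$name
  g <- igraph::set_vertex_attr(g, "s2b", value = unname(result$score[nm]))
  if (!is.null(result$ss1)) {
    g <- igraph::set_vertex_attr(g, "ss1", value = unname(result$ss1[nm]))
  }
  if (!is.null(result$ss2)) {
    g <- igraph::set_vertex_attr(g, "ss2", value = unname(result$ss2[nm]))
  }
  if (!is.null(clusters)) {
    g <- igraph::set_vertex_attr(g, "cluster",
                                 value = as.integer(clusters[nm]))
  }
  g <- igraph::set_vertex_attr(
    g, "in_clique",
    value = nm %in% unique(unlist(cliques %||% list()))
  )
  g <- igraph::set_vertex_attr(g, "is_seed_a",
                               value = nm %in% result$seed_pair$seeds_a)
  g <- igraph::set_vertex_attr(g, "is_seed_b",
                               value = nm %in% result$seed_pair$seeds_b)
  write_graphml(g, path)
}
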