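# Network input/output, distance infrastructure and degree-preserving
# rewiring null models. Networks are undirected, unweighted igraph objects
# with character vertex names; identifiers are opaque and case-sensitive.

# Validate/normalize a network argument.
as_s2b_network <- function(net) {
  if (!igraph::is_igraph(net)) stop("`net` must be an igraph object")
  if (igraph::is_directed(net)) stop("`net` must be undirected")
  if (is.null(igraph::V(net)$name)) {
    igraph::V(net)$name <- as.character(seq_len(igraph::vcount(net)))
  }
  if (igraph::any_loop(net) || igraph::any_multiple(net)) {
    net <- igraph::simplify(net)
  }
  net
}

#' Read an undirected network from an edge-list file
#'
#' Reads a two-column whitespace/tab separated edge list, or a SIF file
#' (`source relation target [target ...]`, one-to-many rows expanded).
#' Self-loops are dropped and duplicate edges collapsed, with counts
#' reported via [message()]. Blank lines are ignored.
#'
#' The dialect is auto-detected from the column count: files whose rows all
#' have two tokens are read as TSV, rows of four or more tokens imply SIF.
#' Files containing three-token rows are ambiguous (weighted TSV versus a
#' one-target SIF row) and require an explicit `dialect`. In SIF mode a
#' single-token row declares an isolated node.
#'
#' @param path Path to the edge-list file.
#' @param dialect One of `"auto"`, `"tsv"`, `"sif"`.
#' @return An undirected, simple igraph object with named vertices.
#' @export
#' @examples
#' f <- tempfile()
#' writeLines(c("A\tB", "B\tC"), f)
#' g <- read_edge_list(f)
#' igraph::vcount(g)
read_edge_list <- function(path, dialect = c("auto", "tsv", "sif")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("network file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  if (!any(keep)) stop("empty edge-list file: ", path)
  lineno <- which(keep)
  tokens <- strsplit(trimws(lines[keep]), "[ \t]+")
  nt <- lengths(tokens)

  if (dialect == "auto") {
    if (all(nt == 2)) {
      dialect <- "tsv"
    } else if (any(nt >= 4) && all(nt != 2)) {
      dialect <- "sif"
    } else if (all(nt == 3)) {
      stop("ambiguous 3-column file; pass dialect = \"tsv\" or \"sif\"")
    } else {
      stop("cannot auto-detect dialect (mixed column counts); ",
           "pass dialect = \"tsv\" or \"sif\"")
    }
  }

  isolated <- character(0)
  if (dialect == "tsv") {
    bad <- which(nt < 2)
    if (length(bad)) {
      stop("malformed edge-list line ", lineno[bad[1]], ": fewer than 2 columns")
    }
    edges <- t(vapply(tokens, function(x) x[1:2], character(2)))
  } else {
    bad <- which(nt == 2)
    if (length(bad)) {
      stop("malformed SIF line ", lineno[bad[1]],
           ": source and relation but no target")
    }
    isolated <- unlist(lapply(tokens[nt == 1], `[`, 1))
    tk <- tokens[nt >= 3]
    edges <- do.call(rbind, lapply(tk, function(x) {
      cbind(x[1], x[seq(3, length(x))])
    }))
    if (is.null(edges)) edges <- matrix(character(0), ncol = 2)
  }

  nodes <- unique(c(edges[, 1], edges[, 2], isolated))
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges[, 1], to = edges[, 2], stringsAsFactors = FALSE),
    directed = FALSE, vertices = nodes
  )
  n_loop <- sum(igraph::which_loop(g))
  gs <- igraph::simplify(g)
  n_dup <- igraph::ecount(g) - n_loop - igraph::ecount(gs)
  if (n_loop > 0) message("dropped ", n_loop, " self-loop(s)")
  if (n_dup > 0) message("collapsed ", n_dup, " duplicate edge(s)")
  gs
}

#' Read a node list (one identifier per line)
#'
#' Text after `#` is treated as a comment; blank lines are skipped.
#'
#' @param path Path to the node-list file.
#' @return Character vector of node identifiers.
#' @export
read_node_list <- function(path) {
  if (!file.exists(path)) stop("node-list file not found: ", path)
  lines <- sub("#.*$", "", readLines(path, warn = FALSE))
  lines <- trimws(lines)
  lines[nzchar(lines)]
}

#' Write a network as a two-column TSV edge list
#'
#' @param net Undirected igraph object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  net <- as_s2b_network(net)
  el <- igraph::as_edgelist(net)
  utils::write.table(el, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a network as GraphML
#'
#' Vertex attributes present on the graph (scores, cluster labels, seed
#' flags) are carried along, which makes the file directly usable in
#' network viewers such as Cytoscape.
#'
#' @inheritParams write_edge_list
#' @return `path`, invisibly.
#' @export
write_graphml <- function(net, path) {
  igraph::write_graph(net, path, format = "graphml")
  invisible(path)
}

#' Breadth-first hop distances from one node
#'
#' @param net Undirected igraph object.
#' @param source Name of the source node.
#' @return Named integer vector of hop counts for all nodes reachable from
#'   `source` (the source itself has distance 0). Unreachable nodes are
#'   absent.
#' @export
#' @examples
#' g <- igraph::make_graph(~ A - B - C)
#' bfs_distances(g, "A")
bfs_distances <- function(net, source) {
  net <- as_s2b_network(net)
  if (!source %in% igraph::V(net)$name) stop("unknown source node: ", source)
  d <- igraph::distances(net, v = source)[1, ]
  d <- d[is.finite(d)]
  stats::setNames(as.integer(d), names(d))
}

#' Average shortest path length
#'
#' Mean hop distance over connected ordered pairs of distinct nodes; pairs
#' in different components are excluded. With `sample_pairs` the mean is a
#' Monte-Carlo estimate: source nodes are drawn at random and all distances
#' from each drawn source contribute, until at least `sample_pairs` ordered
#' pairs have been seen.
#'
#' @param net Undirected igraph object.
#' @param sample_pairs Optional number of sampled ordered pairs; `NULL`
#'   (default) computes the exact mean over all pairs.
#' @param rng_seed Optional integer seed for the pair sampling.
#' @return The average shortest path length (a single number).
#' @export
#' @examples
#' average_path_length(igraph::make_full_graph(4))  # 1
average_path_length <- function(net, sample_pairs = NULL, rng_seed = NULL) {
  net <- as_s2b_network(net)
  n <- igraph::vcount(net)
  if (n < 2) stop("network needs at least two nodes")
  if (is.null(sample_pairs)) {
    avgd <- igraph::mean_distance(net, directed = FALSE, unconnected = TRUE)
    if (!is.finite(avgd)) stop("network has no connected node pair")
    return(avgd)
  }
  stopifnot(sample_pairs >= 1)
  with_seed(rng_seed, {
    n_src <- min(n, max(1L, ceiling(sample_pairs / (n - 1))))
    src <- sample(igraph::V(net)$name, n_src)
    d <- igraph::distances(net, v = src)
    d <- d[is.finite(d) & d > 0]
    if (!length(d)) stop("network has no connected node pair")
    mean(d)
  })
}

# avgd policy used by the higher-level drivers: exact up to `exact_limit`
# nodes, Monte-Carlo above it (all-pairs BFS on interactome-scale networks
# buys nothing for a coarse path-length filter).
default_avgd <- function(net, rng_seed = NULL, exact_limit = 2000,
                         sample_pairs = 1e5) {
  if (igraph::vcount(net) <= exact_limit) {
    average_path_length(net)
  } else {
    average_path_length(net, sample_pairs = sample_pairs, rng_seed = rng_seed)
  }
}

canonical_edge_ids <- function(net) {
  el <- igraph::as_edgelist(net)
  lo <- pmin(el[, 1], el[, 2])
  hi <- pmax(el[, 1], el[, 2])
  paste(lo, hi, sep = "\r")
}

#' Degree-preserving edge rewiring
#'
#' Randomizes the edges of a network by attempted double-edge swaps while
#' keeping every node's degree fixed; swaps that would create a self-loop
#' or duplicate edge are rejected. This is the null model behind the
#' network-specificity score: node degrees (hence hub status) survive, the
#' wiring pattern does not.
#'
#' @param net Undirected igraph object.
#' @param swap_multiplier Attempted swaps as a multiple of the edge count.
#' @param rng_seed Optional integer seed.
#' @return A rewired igraph object with the same nodes and degree sequence.
#'   If no swap could be applied (e.g. a star graph) the network is
#'   returned unchanged with a warning.
#' @export
rewire_degree_preserving <- function(net, swap_multiplier = 10,
                                     rng_seed = NULL) {
  net <- as_s2b_network(net)
  stopifnot(swap_multiplier > 0)
  ne <- igraph::ecount(net)
  if (ne < 2) {
    warning("fewer than two edges; returning the network unchanged")
    return(net)
  }
  niter <- max(1L, ceiling(swap_multiplier * ne))
  out <- with_seed(rng_seed,
    igraph::rewire(net, igraph::keeping_degseq(loops = FALSE, niter = niter))
  )
  if (setequal(canonical_edge_ids(out), canonical_edge_ids(net))) {
    warning("no degree-preserving swap was applied; network unchanged")
  }
  out
}

#' Rewire approximately a given fraction of edges
#'
#' Applies degree-preserving double-edge swaps in batches until about
#' `fraction` of the original edges have been displaced (used to emulate
#' false-positive interactions in robustness experiments). The achieved
#' number of moved edges is recorded in the graph attribute `"edges_moved"`.
#'
#' @param net Undirected igraph object.
#' @param fraction Fraction of edges to displace, in `[0, 1]`.
#' @param rng_seed Optional integer seed.
#' @param max_rounds Safety cap on swap batches.
#' @return A rewired igraph object with identical degree sequence.
#' @export
rewire_fraction <- function(net, fraction, rng_seed = NULL, max_rounds = 50) {
  net <- as_s2b_network(net)
  stopifnot(fraction >= 0, fraction <= 1)
  orig <- canonical_edge_ids(net)
  target <- round(fraction * length(orig))
  out <- net
  if (target > 0) {
    out <- with_seed(rng_seed, {
      cur <- net
      moved <- 0L
      for (round in seq_len(max_rounds)) {
        need <- target - moved
        if (need <= 0) break
        cur <- igraph::rewire(
          cur, igraph::keeping_degseq(loops = FALSE,
                                      niter = max(1L, ceiling(need / 2)))
        )
        moved <- sum(!canonical_edge_ids(cur) %in% orig)
      }
      cur
    })
  }
  igraph::set_graph_attr(out, "edges_moved",
                         sum(!canonical_edge_ids(out) %in% orig))
}
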