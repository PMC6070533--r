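# Artificial module benchmark generators: a scale-free surrogate base
# network, three module-growth models (shell, conn, rwr) with controlled
# pairwise overlap, and seed sampling with optional contamination.

#' Generate a scale-free surrogate base network
#'
#' Preferential attachment at interactome-like density, restricted to its
#' largest connected component; a download-free stand-in for a real
#' protein-interaction network in the artificial-module benchmarks.
#'
#' @param n_nodes Number of nodes (at least 100).
#' @param mean_degree Target mean degree (attachment parameter is
#'   `round(mean_degree / 2)` edges per incoming node).
#' @param model Base-network model; only `"scale_free"` is provided.
#' @param rng_seed Optional integer seed.
#' @return Undirected, connected igraph object with node names
#'   `n00001, n00002, ...`.
#' @export
#' @examples
#' g <- make_base_network(200, 6, rng_seed = 1)
#' igraph::vcount(g)
make_base_network <- function(n_nodes, mean_degree = 8,
                              model = "scale_free", rng_seed = NULL) {
  model <- match.arg(model, "scale_free")
  if (n_nodes < 100) stop("n_nodes must be at least 100")
  m <- round(mean_degree / 2)
  if (m < 1) stop("mean_degree too small for a connected network")
  g <- with_seed(rng_seed,
                 igraph::sample_pa(n_nodes, m = m, directed = FALSE))
  igraph::V(g)$name <- sprintf("n%05d", seq_len(n_nodes))
  g <- igraph::simplify(g)
  comp <- igraph::components(g)
  igraph::induced_subgraph(g, which(comp$membership == which.max(comp$csize)))
}

# Shared engine for connectivity-significance growth (conn modules and the
# DIAMOnD baseline). At each step every outside node with at least one link
# into the module is scored by the hypergeometric tail probability of its
# link count given its degree, the module size and the network size; the
# lowest p is added. Ties: random when `tie_random` (consumes R's RNG),
# otherwise highest degree then lexicographic name. The iteration itself
# lives in compiled code (connectivity_expand_cpp).
connectivity_expand <- function(net, seed_idx, n_iter, tie_random = FALSE) {
  csr <- adjacency_csr(net)
  nodes <- igraph::V(net)$name
  res <- connectivity_expand_cpp(
    csr$ptr, csr$idx, csr$deg, as.integer(seed_idx) - 1L,
    as.integer(n_iter), tie_random,
    tie_rank = match(nodes, sort(nodes))
  )
  list(added = res$added + 1L, p = res$p)
}

# 0-based CSR adjacency of an igraph object, memoized per graph (the
# benchmark expands hundreds of modules on one base network).
.s2b_cache <- new.env(parent = emptyenv())

adjacency_csr <- function(net) {
  id <- as.character(igraph::graph_id(net))
  hit <- get0(id, envir = .s2b_cache, inherits = FALSE)
  if (!is.null(hit)) return(hit)
  n <- igraph::vcount(net)
  el <- igraph::as_edgelist(net, names = FALSE)
  from <- c(el[, 1], el[, 2])
  to <- c(el[, 2], el[, 1])
  o <- order(from)
  csr <- list(
    ptr = c(0L, as.integer(cumsum(tabulate(from, n)))),
    idx = as.integer(to[o] - 1L),
    deg = tabulate(from, n)
  )
  if (length(ls(.s2b_cache)) > 16) rm(list = ls(.s2b_cache),
                                      envir = .s2b_cache)
  assign(id, csr, envir = .s2b_cache)
  csr
}

#' Grow one artificial module
#'
#' Three growth models around a start node:
#' \describe{
#'   \item{shell}{the start plus successive breadth-first neighborhood
#'     shells; the last shell is randomly subsampled to hit `target_size`.}
#'   \item{conn}{iterative connectivity-significance growth (the same rule
#'     the DIAMOnD baseline uses for prediction), random tie-break.}
#'   \item{rwr}{random walk with restart from the start node (restart
#'     probability `restart_prob`); the `target_size` nodes with highest
#'     stationary visit frequency, within the start's component.}
#' }
#'
#' @param net Undirected igraph object.
#' @param model `"shell"`, `"conn"` or `"rwr"`.
#' @param target_size Module size.
#' @param start Name of the start node.
#' @param rng_seed Optional integer seed.
#' @param restart_prob Restart probability of the rwr walk.
#' @return Character vector of module members (always contains `start`).
#' @export
make_module <- function(net, model = c("shell", "conn", "rwr"), target_size,
                        start, rng_seed = NULL, restart_prob = 0.5) {
  net <- as_s2b_network(net)
  model <- match.arg(model)
  nodes <- igraph::V(net)$name
  if (!start %in% nodes) stop("start node not in network")
  if (target_size >= length(nodes)) stop("target_size must be below network size")
  comp <- igraph::components(net)
  cid <- comp$membership[match(start, nodes)]
  if (comp$csize[cid] < target_size) {
    stop("component containing the start node has fewer than target_size nodes")
  }
  with_seed(rng_seed, switch(model,
    shell = grow_shell(net, start, target_size),
    conn = {
      si <- match(start, nodes)
      idx <- connectivity_expand(net, si, target_size - 1L,
                                 tie_random = TRUE)$added
      nodes[c(si, idx)]
    },
    rwr = {
      reset <- as.numeric(nodes == start)
      pr <- igraph::page_rank(net, damping = 1 - restart_prob,
                              personalized = reset)$vector
      incomp <- comp$membership == cid
      ord <- order(-pr, nodes)
      nodes[ord[incomp[ord]][seq_len(target_size)]]
    }
  ))
}

# Shell growth: full breadth-first rings around the start; the ring that
# crosses the target size is randomly subsampled.
grow_shell <- function(net, start, target_size) {
  d <- igraph::distances(net, v = start)[1, ]
  d <- d[is.finite(d)]
  ring_of <- split(names(d), d)
  mod <- character(0)
  for (ring in ring_of) {
    if (length(mod) + length(ring) >= target_size) {
      return(c(mod, sample(ring, target_size - length(mod))))
    }
    mod <- c(mod, ring)
  }
  mod
}

#' Generate a pair of overlapping artificial modules
#'
#' Draws a first module from a random start, then repeatedly grows a second
#' module of the same model from a start chosen uniformly inside the first,
#' rejecting pairs whose overlap size falls outside `overlap_bounds` (or
#' whose induced subgraphs are not connected), up to `max_tries` second-
#' module draws. Shell module sizes are drawn uniformly from `size_range`;
#' conn and rwr modules have fixed size `module_size`.
#'
#' @param net Undirected igraph object.
#' @param model `"shell"`, `"conn"` or `"rwr"`.
#' @param overlap_bounds Inclusive bounds on the overlap size.
#' @param size_range Shell module size range.
#' @param module_size Fixed conn/rwr module size.
#' @param rng_seed Optional integer seed.
#' @param max_tries Total second-module draws before giving up.
#' @param inner_tries Second-module draws per first module.
#' @param restart_prob Restart probability for rwr modules.
#' @return An object of class `module_pair_truth`: `module_a`, `module_b`,
#'   `overlap`, `model`, and `base_net`.
#' @export
make_module_pair <- function(net, model = c("shell", "conn", "rwr"),
                             overlap_bounds = c(50, 125),
                             size_range = c(200, 400), module_size = 250,
                             rng_seed = NULL, max_tries = 200,
                             inner_tries = 8, restart_prob = 0.5) {
  net <- as_s2b_network(net)
  model <- match.arg(model)
  nodes <- igraph::V(net)$name
  draw_size <- function() {
    if (model == "shell") sample(size_range[1]:size_range[2], 1) else module_size
  }
  with_seed(rng_seed, {
    tries <- 0L
    achieved <- integer(0)
    while (tries < max_tries) {
      A <- make_module(net, model, draw_size(), sample(nodes, 1),
                       restart_prob = restart_prob)
      for (i in seq_len(inner_tries)) {
        tries <- tries + 1L
        if (tries > max_tries) break
        B <- make_module(net, model, draw_size(), sample(A, 1),
                         restart_prob = restart_prob)
        ov <- intersect(A, B)
        achieved <- c(achieved, length(ov))
        if (length(ov) >= overlap_bounds[1] && length(ov) <= overlap_bounds[2] &&
            igraph::is_connected(igraph::induced_subgraph(net, A)) &&
            igraph::is_connected(igraph::induced_subgraph(net, B))) {
          return(structure(
            list(module_a = A, module_b = B, overlap = ov,
                 model = model, base_net = net),
            class = "module_pair_truth"
          ))
        }
      }
    }
    stop("no module pair with overlap in [", overlap_bounds[1], ", ",
         overlap_bounds[2], "] after ", max_tries, " tries (achieved ",
         min(achieved), "-", max(achieved), ")")
  })
}

#' @export
print.module_pair_truth <- function(x, ...) {
  cat("module pair (", x$model, "): |A| = ", length(x$module_a),
      ", |B| = ", length(x$module_b), ", overlap = ", length(x$overlap),
      "\n", sep = "")
  invisible(x)
}

#' Sample seed lists from a module pair
#'
#' Takes a uniform `fraction` sample of each module (floor convention) as
#' seeds; with `contamination > 0` a `floor(contamination * sample size)`
#' subset of each sample is replaced by uniform random network nodes
#' outside the module (emulating false disease-gene associations).
#'
#' @param truth A [make_module_pair()] object.
#' @param fraction Fraction of each module used as seeds, in `(0, 1]`.
#' @param contamination Fraction of each seed sample replaced by random
#'   nodes, in `[0, 1)`.
#' @param rng_seed Optional integer seed.
#' @return List with character vectors `raw_a` and `raw_b`.
#' @export
sample_seeds <- function(truth, fraction = 0.5, contamination = 0,
                         rng_seed = NULL) {
  stopifnot(inherits(truth, "module_pair_truth"),
            fraction > 0, fraction <= 1,
            contamination >= 0, contamination < 1)
  nodes <- igraph::V(truth$base_net)$name
  with_seed(rng_seed, {
    draw <- function(module) {
      ns <- floor(fraction * length(module))
      if (ns < 1) stop("empty seed sample; increase `fraction`")
      s <- sample(module, ns)
      nc <- floor(contamination * ns)
      if (nc > 0) {
        out <- sample(setdiff(nodes, module), nc)
        s[sample.int(ns, nc)] <- out
      }
      s
    }
    list(raw_a = draw(truth$module_a), raw_b = draw(truth$module_b))
  })
}
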