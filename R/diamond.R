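# DIAMOnD baseline: iterative module expansion by hypergeometric
# connectivity significance, and the two-module intersection protocol used
# to benchmark cross-module prediction.

#' Expand a seed set with the DIAMOnD algorithm
#'
#' Starting from the seeds, iteratively adds the node whose number of links
#' into the current module is most significant under a hypergeometric tail
#' test given its degree, the module size and the network size. Ties are
#' broken toward higher degree, then lexicographic identifier, which makes
#' the run deterministic. Seed weighting is fixed at 1.
#'
#' @param net Undirected igraph object.
#' @param seeds Character vector of seed identifiers (must be network
#'   nodes).
#' @param n_iter Number of expansion iterations (250 in the reference
#'   protocol).
#' @return Object of class `diamond_run`: `added`, a data frame with
#'   columns `node` and `p_value` in addition order, and `seeds`. If the
#'   module boundary is exhausted early the run is truncated with a
#'   warning. Added p-values are not monotone across iterations (the
#'   module size changes every step).
#' @export
diamond_expand <- function(net, seeds, n_iter) {
  net <- as_s2b_network(net)
  stopifnot(n_iter >= 1)
  nodes <- igraph::V(net)$name
  seeds <- unique(as.character(seeds))
  if (!all(seeds %in% nodes)) {
    stop(sum(!seeds %in% nodes), " seed(s) are not network nodes")
  }
  if (!length(seeds)) stop("empty seed set")
  res <- connectivity_expand(net, match(seeds, nodes), n_iter)
  if (length(res$added) < n_iter) {
    warning("module boundary exhausted after ", length(res$added),
            " of ", n_iter, " iterations")
  }
  structure(
    list(added = data.frame(node = nodes[res$added], p_value = res$p,
                            stringsAsFactors = FALSE),
         seeds = seeds),
    class = "diamond_run"
  )
}

#' @export
print.diamond_run <- function(x, ...) {
  cat("DIAMOnD run:", length(x$seeds), "seeds,", nrow(x$added),
      "nodes added\n")
  invisible(x)
}

#' Cross-module candidates from two DIAMOnD expansions
#'
#' Runs DIAMOnD separately from each seed set and returns the intersection
#' of the two added-node lists — the single-disease-method surrogate for
#' predicting nodes shared by two modules.
#'
#' @param net Undirected igraph object.
#' @param seeds_a,seeds_b Character vectors of seeds for the two modules.
#' @param n_iter Iterations per expansion.
#' @return Character vector of nodes added in both runs (order of the
#'   first run).
#' @export
diamond_overlap_candidates <- function(net, seeds_a, seeds_b, n_iter) {
  ra <- diamond_expand(net, seeds_a, n_iter)
  rb <- diamond_expand(net, seeds_b, n_iter)
  intersect(ra$added$node, rb$added$node)
}
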