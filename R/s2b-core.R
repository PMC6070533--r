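# The S2B score: fraction of retained shortest paths linking the two seed
# sets that pass through a node, plus its L-curve threshold and candidate
# selection.

#' Build a seed pair from two raw seed lists
#'
#' Seeds absent from the network are dropped (with a message); seeds present
#' in both lists by definition already belong to the module overlap, so they
#' are discarded from both sets and recorded in `shared_discarded` —
#' shortest paths starting from them would diverge from the overlap region.
#'
#' @param net Undirected igraph object.
#' @param raw_a,raw_b Character vectors of seed identifiers for the two
#'   modules.
#' @return An object of class `s2b_seed_pair` with elements `seeds_a`,
#'   `seeds_b` (disjoint, present in the network) and `shared_discarded`.
#' @export
#' @examples
#' g <- igraph::make_graph(~ X - Y - Z)
#' make_seed_pair(g, c("X", "Y"), c("Y", "Z"))
make_seed_pair <- function(net, raw_a, raw_b) {
  net <- as_s2b_network(net)
  nodes <- igraph::V(net)$name
  raw_a <- unique(as.character(raw_a))
  raw_b <- unique(as.character(raw_b))
  miss <- setdiff(union(raw_a, raw_b), nodes)
  if (length(miss)) {
    message(length(miss), " seed(s) absent from the network were dropped")
  }
  a <- intersect(raw_a, nodes)
  b <- intersect(raw_b, nodes)
  shared <- intersect(a, b)
  a <- setdiff(a, shared)
  b <- setdiff(b, shared)
  if (!length(a) || !length(b)) {
    stop("a seed set is empty after dropping absent and shared seeds")
  }
  structure(
    list(seeds_a = a, seeds_b = b, shared_discarded = shared),
    class = "s2b_seed_pair"
  )
}

#' @export
print.s2b_seed_pair <- function(x, ...) {
  cat("S2B seed pair:", length(x$seeds_a), "A-seeds,",
      length(x$seeds_b), "B-seeds,",
      length(x$shared_discarded), "shared seed(s) discarded\n")
  invisible(x)
}

#' Compute S2B scores
#'
#' For every node k, S2B is the fraction of retained seed pairs (i in a,
#' j in b, j != k) whose shortest-path distance satisfies
#' d(i,k) + d(k,j) = d(i,j), i.e. k lies on at least one shortest path
#' between i and j. A seed pair is retained when d(i,j) <= `avgd`, the
#' average shortest path length of the network — the path-length filter
#' that removes loosely related seed pairs. Nodes discarded as shared seeds
#' receive `NA`; nodes for which no pair is retained score 0.
#'
#' @param net Undirected igraph object.
#' @param seeds An [make_seed_pair()] object.
#' @param avgd Positive path-length cutoff, normally
#'   [average_path_length()] of `net`.
#' @return Named numeric vector of scores in `[0, 1]` over all network
#'   nodes (`NA` for discarded shared seeds).
#' @export
compute_s2b <- function(net, seeds, avgd) {
  net <- as_s2b_network(net)
  stopifnot(inherits(seeds, "s2b_seed_pair"))
  if (!is.numeric(avgd) || length(avgd) != 1 || avgd <= 0) {
    stop("`avgd` must be a positive number")
  }
  nodes <- igraph::V(net)$name
  if (!all(c(seeds$seeds_a, seeds$seeds_b) %in% nodes)) {
    stop("seed pair does not match this network")
  }
  Da <- dist_matrix_int(net, seeds$seeds_a)
  Db <- dist_matrix_int(net, seeds$seeds_b)
  b_idx <- match(seeds$seeds_b, nodes) - 1L
  score <- s2b_kernel(Da, Db, b_idx, avgd)
  names(score) <- nodes
  score[seeds$shared_discarded] <- NA_real_
  score
}

# Integer hop-distance matrix (sources x all nodes), -1 for unreachable.
dist_matrix_int <- function(net, sources) {
  d <- igraph::distances(net, v = sources)
  d[!is.finite(d)] <- -1
  storage.mode(d) <- "integer"
  d
}

#' S2B score threshold from the L-shaped score/quantile curve
#'
#' Plotting S2B against `1 - quantile(S2B)` gives an L-shaped curve because
#' only few nodes reach high scores. The threshold is the observed score
#' minimizing the squared distance to the origin of that curve,
#' `(s / max)^2 + (1 - quantile(s))^2`, where `quantile(s)` is the fraction
#' of evaluated nodes (zeros included) scoring at most `s`. Ties go to the
#' smaller score.
#'
#' @param scores Numeric vector of S2B scores (`NA`s ignored).
#' @return The threshold, always one of the observed scores.
#' @export
s2b_threshold <- function(scores) {
  s <- scores[!is.na(scores)]
  if (!length(s) || max(s) <= 0) stop("no positive S2B score")
  vals <- sort(unique(s))
  q <- stats::ecdf(s)(vals)
  obj <- (vals / max(s))^2 + (1 - q)^2
  vals[which.min(obj)]  # which.min takes the first, i.e. smallest, score
}

#' Seed-set specificity score (SS1)
#'
#' Probability that the observed S2B of a node is at least as large as its
#' S2B under random seed sets of the same sizes. Each randomization draws
#' disjoint sets `a_R`, `b_R` uniformly from all network nodes and
#' contributes to the score of every node simultaneously.
#'
#' @param net Undirected igraph object.
#' @param seeds An [make_seed_pair()] object (defines the set sizes).
#' @param scores Observed scores from [compute_s2b()].
#' @param avgd Path-length cutoff used for the observed scores.
#' @param n_random Number of randomizations (200 in the reference
#'   protocol).
#' @param rng_seed Optional integer seed.
#' @return Named numeric vector of SS1 values in `[0, 1]` (`NA` where
#'   `scores` is `NA`).
#' @export
specificity_seeds <- function(net, seeds, scores, avgd, n_random = 200,
                              rng_seed = NULL) {
  net <- as_s2b_network(net)
  stopifnot(n_random >= 1)
  nodes <- igraph::V(net)$name
  hits <- numeric(length(nodes))
  with_seed(rng_seed, {
    for (r in seq_len(n_random)) {
      rp <- draw_random_seed_pair(nodes, length(seeds$seeds_a),
                                  length(seeds$seeds_b))
      rs <- compute_s2b(net, rp, avgd)
      hits <- hits + as.numeric(scores >= rs)
    }
  })
  ss <- hits / n_random
  names(ss) <- nodes
  ss[is.na(scores)] <- NA_real_
  ss
}

# Disjoint uniform random seed sets of the given sizes.
draw_random_seed_pair <- function(nodes, na, nb) {
  a <- sample(nodes, na)
  b <- sample(setdiff(nodes, a), nb)
  structure(list(seeds_a = a, seeds_b = b, shared_discarded = character(0)),
            class = "s2b_seed_pair")
}

#' Network specificity score (SS2)
#'
#' Probability that the observed S2B of a node is at least as large as its
#' S2B on a degree-preserving rewired network (same seeds). High SS2 means
#' the score reflects the actual wiring rather than the node's centrality.
#' The path-length cutoff is recomputed on every rewired network.
#'
#' @inheritParams specificity_seeds
#' @param swap_multiplier Attempted swaps per edge for each rewiring.
#' @return Named numeric vector of SS2 values in `[0, 1]`.
#' @export
specificity_network <- function(net, seeds, scores, n_random = 200,
                                swap_multiplier = 10, rng_seed = NULL) {
  net <- as_s2b_network(net)
  stopifnot(n_random >= 1)
  nodes <- igraph::V(net)$name
  hits <- numeric(length(nodes))
  with_seed(rng_seed, {
    for (r in seq_len(n_random)) {
      gr <- suppressWarnings(
        rewire_degree_preserving(net, swap_multiplier = swap_multiplier)
      )
      avgd_r <- default_avgd(gr)
      rs <- compute_s2b(gr, seeds, avgd_r)
      hits <- hits + as.numeric(scores >= rs)
    }
  })
  ss <- hits / n_random
  names(ss) <- nodes
  ss[is.na(scores)] <- NA_real_
  ss
}

#' Select S2B candidates
#'
#' Candidates score strictly above the threshold and have both specificity
#' scores strictly above `ss_cut`; shared discarded seeds are excluded.
#' Ordered by score (descending), ties by identifier.
#'
#' @param result An [s2b_run()] result.
#' @param ss_cut Specificity cutoff (reference protocol: 0.90).
#' @return Character vector of candidate node identifiers.
#' @export
select_candidates <- function(result, ss_cut = 0.90) {
  stopifnot(inherits(result, "s2b_result"), ss_cut >= 0, ss_cut <= 1)
  sc <- result$score
  ok <- !is.na(sc) & sc > result$threshold
  if (!is.null(result$ss1)) ok <- ok & !is.na(result$ss1) & result$ss1 > ss_cut
  if (!is.null(result$ss2)) ok <- ok & !is.na(result$ss2) & result$ss2 > ss_cut
  cand <- names(sc)[ok]
  cand[order(-sc[cand], cand)]
}

#' Run the full S2B analysis for two seed lists
#'
#' Convenience driver: builds the seed pair, computes the path-length
#' cutoff (exact for networks of at most 2,000 nodes, sampled above),
#' scores all nodes, derives the threshold and, optionally, both
#' specificity scores, then selects candidates.
#'
#' @param net Undirected igraph object.
#' @param raw_a,raw_b Character vectors of seed identifiers.
#' @param n_random Randomizations per specificity score.
#' @param ss_cut Specificity cutoff for candidate selection.
#' @param swap_multiplier Attempted swaps per edge in SS2 rewiring.
#' @param specificity Compute SS1/SS2? (Disable for large benchmark runs.)
#' @param avgd Optional path-length cutoff override.
#' @param rng_seed Optional integer seed governing all randomizations.
#' @return An object of class `s2b_result`: scores, `ss1`, `ss2`,
#'   `threshold`, `n_random`, ordered `candidates`, and the `seed_pair`.
#'   `as.data.frame()` yields the per-node table (node, s2b, ss1, ss2,
#'   rank, is_candidate, is_seed_a, is_seed_b).
#' @export
s2b_run <- function(net, raw_a, raw_b, n_random = 200, ss_cut = 0.90,
                    swap_multiplier = 10, specificity = TRUE, avgd = NULL,
                    rng_seed = NULL) {
  net <- as_s2b_network(net)
  seeds <- make_seed_pair(net, raw_a, raw_b)
  avgd <- avgd %||% default_avgd(net, rng_seed = substream_seed(rng_seed %||% 0, "avgd"))
  score <- compute_s2b(net, seeds, avgd)
  ss1 <- ss2 <- NULL
  if (specificity) {
    ss1 <- specificity_seeds(net, seeds, score, avgd, n_random = n_random,
                             rng_seed = substream_seed(rng_seed %||% 0, "ss1"))
    ss2 <- specificity_network(net, seeds, score, n_random = n_random,
                               swap_multiplier = swap_multiplier,
                               rng_seed = substream_seed(rng_seed %||% 0, "ss2"))
  }
  thr <- if (any(score > 0, na.rm = TRUE)) s2b_threshold(score) else {
    message("all S2B scores are zero (no retained seed pair); ",
            "no candidate can be selected")
    0
  }
  res <- structure(
    list(score = score, ss1 = ss1, ss2 = ss2,
         threshold = thr,
         n_random = if (specificity) n_random else 0L,
         avgd = avgd, seed_pair = seeds),
    class = "s2b_result"
  )
  res$candidates <- select_candidates(res, ss_cut = ss_cut)
  res
}

#' @export
print.s2b_result <- function(x, ...) {
  cat("S2B result:", sum(!is.na(x$score)), "scored nodes, threshold",
      signif(x$threshold, 4), "->", length(x$candidates), "candidate(s)\n")
  invisible(x)
}

#' @export
as.data.frame.s2b_result <- function(x, ...) {
  node <- names(x$score)
  rank <- rep(NA_integer_, length(node))
  ranked <- rank_candidates(x$score, exclude = x$seed_pair$shared_discarded)
  rank[match(ranked, node)] <- seq_along(ranked)
  df <- data.frame(
    node = node,
    s2b = unname(x$score),
    ss1 = if (is.null(x$ss1)) NA_real_ else unname(x$ss1),
    ss2 = if (is.null(x$ss2)) NA_real_ else unname(x$ss2),
    rank = rank,
    is_candidate = node %in% x$candidates,
    is_seed_a = node %in% x$seed_pair$seeds_a,
    is_seed_b = node %in% x$seed_pair$seeds_b,
    stringsAsFactors = FALSE
  )
  df[order(df$rank, df$node, na.last = TRUE), , drop = FALSE]
}
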