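# Benchmark metrics on artificial module pairs: rank-resolved precision /
# neighbor precision / recall curves, DIAMOnD-matched precision, and the
# benchmark driver orchestrating module generation, seed sampling, network
# perturbation, scoring and evaluation.

#' Rank nodes by S2B score
#'
#' @param scores Named numeric score vector (`NA`s dropped).
#' @param exclude Nodes to remove from the ranking (e.g. shared seeds, or
#'   all input seeds).
#' @return Character vector of node names, score descending, ties by
#'   identifier.
#' @export
rank_candidates <- function(scores, exclude = character(0)) {
  if (!length(scores)) stop("empty score vector")
  s <- scores[!is.na(scores)]
  s <- s[!names(s) %in% exclude]
  names(s)[order(-s, names(s))]
}

# Centered moving average with shrinking windows at the ends.
moving_average <- function(x, window) {
  if (window <= 1 || length(x) < 2) return(x)
  h <- (window - 1) %/% 2
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Rank-resolved overlap metrics for one ranked candidate list
#'
#' For each candidate rank: the indicator of true-overlap membership and of
#' direct adjacency to the overlap (both also reported smoothed with a
#' centered moving average over `window` consecutive ranks), and the
#' cumulative recall — the fraction of overlap nodes ranked at or above
#' that rank.
#'
#' @param ranked Character vector from [rank_candidates()].
#' @param truth A [make_module_pair()] object.
#' @param net Network on which adjacency is evaluated (defaults to the
#'   truth's base network).
#' @param window Smoothing window (3 in the reference figures).
#' @return Data frame with columns `rank`, `in_overlap`, `neighbor_hit`,
#'   `precision`, `neighbor_precision`, `recall`.
#' @export
overlap_metrics <- function(ranked, truth, net = truth$base_net, window = 3) {
  stopifnot(length(ranked) > 0, inherits(truth, "module_pair_truth"))
  net <- as_s2b_network(net)
  ov <- truth$overlap
  in_ov <- ranked %in% ov
  near <- igraph::V(net)$name[unique(unlist(
    igraph::adjacent_vertices(net, intersect(ov, igraph::V(net)$name))
  ))]
  nb_hit <- ranked %in% near
  data.frame(
    rank = seq_along(ranked),
    in_overlap = in_ov,
    neighbor_hit = nb_hit,
    precision = moving_average(as.numeric(in_ov), window),
    neighbor_precision = moving_average(as.numeric(nb_hit), window),
    recall = cumsum(in_ov) / length(ov)
  )
}

#' DIAMOnD-matched precision
#'
#' Compares the two methods at equal list length: the DIAMOnD candidate
#' set against the same number of top S2B-ranked nodes.
#'
#' @param s2b_ranked Ranked S2B candidate list.
#' @param diamond_candidates Character vector from
#'   [diamond_overlap_candidates()].
#' @param truth A [make_module_pair()] object.
#' @return List with `precision_s2b`, `precision_diamond` and `n_matched`;
#'   the precisions are `NA` when DIAMOnD returns no candidate (such pairs
#'   are excluded from benchmark medians).
#' @export
matched_precision <- function(s2b_ranked, diamond_candidates, truth) {
  stopifnot(inherits(truth, "module_pair_truth"))
  n <- length(diamond_candidates)
  if (n == 0) {
    return(list(precision_s2b = NA_real_, precision_diamond = NA_real_,
                n_matched = 0L))
  }
  list(
    precision_s2b = mean(utils::head(s2b_ranked, n) %in% truth$overlap),
    precision_diamond = mean(diamond_candidates %in% truth$overlap),
    n_matched = n
  )
}

#' Benchmark configuration
#'
#' Collects every tunable of the artificial-module benchmark with the
#' reference defaults: a 5,000-node scale-free base network of mean degree
#' 8; 50 module pairs per model; shell sizes 200-400, conn/rwr size 250;
#' overlap between 50 and 125 nodes; 50% of each module sampled as seeds;
#' 250 DIAMOnD iterations.
#'
#' @param models Module models to run.
#' @param n_pairs Module pairs per model.
#' @param n_nodes,mean_degree Base-network size and density.
#' @param seed_fraction Fraction of each module used as seeds.
#' @param contamination Fraction of seeds replaced by random nodes.
#' @param rewire_fraction Fraction of network edges rewired before scoring.
#' @param diamond_iters DIAMOnD iterations per module.
#' @param overlap_bounds,size_range,module_size,restart_prob Module
#'   generation parameters, see [make_module_pair()].
#' @param top_k Fixed-depth precision also reported per pair.
#' @param window Rank smoothing window.
#' @param exclude_seeds Exclude all input seeds from the S2B ranking
#'   (default keeps single-module seeds rankable and excludes only shared
#'   seeds, as in the reference protocol).
#' @param specificity Apply threshold + specificity filtering before
#'   ranking (off in the artificial benchmarks; module pairs are not
#'   selected for hub content, so the filters are not needed there).
#' @param max_tries Rejection-sampling budget per module pair.
#' @param rng_seed Integer seed; every stage derives a substream from it.
#' @return A list of class `benchmark_config`.
#' @export
benchmark_config <- function(models = c("shell", "conn", "rwr"), n_pairs = 50,
                             n_nodes = 5000, mean_degree = 8,
                             seed_fraction = 0.5, contamination = 0,
                             rewire_fraction = 0, diamond_iters = 250,
                             overlap_bounds = c(50, 125),
                             size_range = c(200, 400), module_size = 250,
                             restart_prob = 0.5, top_k = 20, window = 3,
                             exclude_seeds = FALSE, specificity = FALSE,
                             max_tries = 400, rng_seed = 1) {
  cfg <- as.list(environment())
  cfg$models <- match.arg(models, c("shell", "conn", "rwr"), several.ok = TRUE)
  structure(cfg, class = "benchmark_config")
}

#' Run the artificial-module benchmark
#'
#' For each model and pair: generate a module pair with known overlap,
#' sample (possibly contaminated) seeds, optionally rewire a fraction of
#' the network edges, score all nodes with S2B, expand both seed sets with
#' DIAMOnD and evaluate matched precision, fixed-depth precision and the
#' top-of-ranking hits. Fully reproducible from the config seed; pairs
#' whose generation fails are skipped and counted.
#'
#' @param config A [benchmark_config()] object (or arguments for it).
#' @param base_net Optional pre-built base network (otherwise generated
#'   from the config).
#' @param progress Emit one message per completed pair.
#' @return List of class `benchmark_result` with elements `pairs` (one row
#'   per evaluated pair), `summary` (per-model medians and quartiles,
#'   type-7), `avgd`, `n_failed` and the `config`.
#' @export
run_benchmark <- function(config = benchmark_config(), base_net = NULL,
                          progress = FALSE) {
  stopifnot(inherits(config, "benchmark_config"))
  cfg <- config
  net <- base_net %||% make_base_network(
    cfg$n_nodes, cfg$mean_degree,
    rng_seed = substream_seed(cfg$rng_seed, "base_net")
  )
  net <- as_s2b_network(net)
  avgd <- default_avgd(net, rng_seed = substream_seed(cfg$rng_seed, "avgd"))

  rows <- list()
  n_failed <- 0L
  for (model in cfg$models) {
    for (p in seq_len(cfg$n_pairs)) {
      seed_p <- substream_seed(cfg$rng_seed, model, p)
      row <- tryCatch(
        benchmark_pair(net, avgd, model, seed_p, cfg),
        error = function(e) {
          warning("pair ", p, " (", model, ") skipped: ",
                  conditionMessage(e))
          NULL
        }
      )
      if (is.null(row)) {
        n_failed <- n_failed + 1L
      } else {
        row$model <- model
        row$pair <- p
        rows[[length(rows) + 1L]] <- row
      }
      if (progress) message(model, " pair ", p, " done")
    }
  }
  pairs <- do.call(rbind, lapply(rows, as.data.frame))
  structure(
    list(pairs = pairs, summary = summarize_benchmark(pairs),
         avgd = avgd, n_failed = n_failed, config = cfg),
    class = "benchmark_result"
  )
}

benchmark_pair <- function(net, avgd, model, seed_p, cfg) {
  truth <- make_module_pair(
    net, model, overlap_bounds = cfg$overlap_bounds,
    size_range = cfg$size_range, module_size = cfg$module_size,
    rng_seed = substream_seed(seed_p, "pair"), max_tries = cfg$max_tries,
    restart_prob = cfg$restart_prob
  )
  raw <- sample_seeds(truth, cfg$seed_fraction, cfg$contamination,
                      rng_seed = substream_seed(seed_p, "seeds"))
  score_net <- net
  score_avgd <- avgd
  if (cfg$rewire_fraction > 0) {
    score_net <- rewire_fraction(net, cfg$rewire_fraction,
                                 rng_seed = substream_seed(seed_p, "rewire"))
    score_avgd <- default_avgd(score_net,
                               rng_seed = substream_seed(seed_p, "avgd"))
  }
  seeds <- make_seed_pair(score_net, raw$raw_a, raw$raw_b)
  score <- compute_s2b(score_net, seeds, score_avgd)
  if (cfg$specificity) {
    ss1 <- specificity_seeds(score_net, seeds, score, score_avgd,
                             rng_seed = substream_seed(seed_p, "ss1"))
    ss2 <- specificity_network(score_net, seeds, score,
                               rng_seed = substream_seed(seed_p, "ss2"))
    keep <- !is.na(score) & ss1 > 0.9 & ss2 > 0.9
    score[!keep] <- NA_real_
  }
  excl <- if (cfg$exclude_seeds) union(raw$raw_a, raw$raw_b)
          else seeds$shared_discarded
  ranked <- rank_candidates(score, exclude = excl)
  dia <- diamond_overlap_candidates(score_net, raw$raw_a, raw$raw_b,
                                    cfg$diamond_iters)
  mp <- matched_precision(ranked, dia, truth)
  metrics <- overlap_metrics(ranked, truth, net = net, window = cfg$window)
  topk <- utils::head(metrics$in_overlap, cfg$top_k)
  top3 <- utils::head(metrics$in_overlap, 3L)
  list(
    size_a = length(truth$module_a), size_b = length(truth$module_b),
    overlap = length(truth$overlap),
    n_shared_seeds = length(seeds$shared_discarded),
    n_diamond = mp$n_matched,
    prec_diamond = mp$precision_diamond,
    prec_s2b_matched = mp$precision_s2b,
    prec_s2b_topk = mean(topk),
    top3_hits = sum(top3), top3_n = length(top3),
    recall_topk = metrics$recall[min(cfg$top_k, nrow(metrics))]
  )
}

summarize_benchmark <- function(pairs) {
  if (is.null(pairs) || !nrow(pairs)) return(NULL)
  do.call(rbind, lapply(split(pairs, pairs$model), function(d) {
    q <- function(x) stats::quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE,
                                     names = FALSE, type = 7)
    qn <- q(d$n_diamond)
    qd <- q(d$prec_diamond)
    qs <- q(d$prec_s2b_matched)
    qk <- q(d$prec_s2b_topk)
    data.frame(
      model = d$model[1], n_pairs = nrow(d),
      n_diamond_q1 = qn[1], n_diamond_median = qn[2], n_diamond_q3 = qn[3],
      prec_diamond_q1 = qd[1], prec_diamond_median = qd[2],
      prec_diamond_q3 = qd[3],
      prec_s2b_matched_q1 = qs[1], prec_s2b_matched_median = qs[2],
      prec_s2b_matched_q3 = qs[3],
      prec_s2b_topk_q1 = qk[1], prec_s2b_topk_median = qk[2],
      prec_s2b_topk_q3 = qk[3],
      top_frac = sum(d$top3_hits) / sum(d$top3_n),
      stringsAsFactors = FALSE, row.names = NULL
    )
  }))
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat("artificial-module benchmark:", nrow(x$pairs), "pairs (",
      x$n_failed, "failed ), avgd =", signif(x$avgd, 4), "\n")
  if (!is.null(x$summary)) print(x$summary, row.names = FALSE)
  invisible(x)
}
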