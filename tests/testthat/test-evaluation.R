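test_that("candidate ranking is ordered, tie-broken and exclusion-aware", {
  expect_equal(rank_candidates(c(A = 0.2, B = 0.9)), c("B", "A"))
  expect_equal(rank_candidates(c(B = 0.5, A = 0.5, C = 0.5)),
               c("A", "B", "C"))
  expect_equal(rank_candidates(c(A = 0.2, B = 0.9, C = 0.7), exclude = "B"),
               c("C", "A"))
  expect_equal(rank_candidates(c(A = 0.2, B = NA)), "A")
})

make_toy_truth <- function(net, A, B) {
  structure(list(module_a = A, module_b = B, overlap = intersect(A, B),
                 model = "shell", base_net = net),
            class = "module_pair_truth")
}

test_that("overlap metrics match a hand-computed fixture", {
  # path P1-...-P10; overlap = {P3, P4}; candidates ranked P3,P4,P7,P5,P10
  g <- igraph::make_ring(10, circular = FALSE)
  igraph::V(g)$name <- paste0("P", 1:10)
  tr <- make_toy_truth(g, paste0("P", 1:4), paste0("P", 3:8))
  ranked <- c("P3", "P4", "P7", "P5", "P10")
  m <- overlap_metrics(ranked, tr, window = 3)

  expect_equal(m$in_overlap, c(TRUE, TRUE, FALSE, FALSE, FALSE))
  # neighbors of {P3,P4}: P2,P3,P4,P5 are adjacent to the overlap
  expect_equal(m$neighbor_hit, c(TRUE, TRUE, FALSE, TRUE, FALSE))
  expect_equal(m$recall, c(0.5, 1, 1, 1, 1))
  # centered window-3 means with shrinking ends, computed by hand
  expect_equal(m$precision, c(1, 2/3, 1/3, 0, 0))
  expect_equal(m$neighbor_precision, c(1, 2/3, 2/3, 1/3, 1/2))
})

test_that("degenerate rankings give all-or-nothing curves", {
  g <- igraph::make_full_graph(6)
  igraph::V(g)$name <- paste0("N", 1:6)
  tr <- make_toy_truth(g, c("N1", "N2", "N3"), c("N2", "N3", "N4"))
  all_in <- overlap_metrics(c("N2", "N3"), tr, window = 1)
  expect_true(all(all_in$precision == 1))
  expect_equal(max(all_in$recall), 1)

  g2 <- igraph::make_graph(~ A - B, C - D, E - F)
  tr2 <- make_toy_truth(g2, c("A", "B"), c("A", "B"))
  none <- overlap_metrics(c("C", "D", "E"), tr2, window = 3)
  expect_true(all(none$precision == 0))
  expect_true(all(none$neighbor_precision == 0))
  expect_true(all(none$recall == 0))
})

test_that("recall curves are monotone and bounded on random instances", {
  net <- make_base_network(700, 6, rng_seed = 20)
  for (seed in 1:5) {
    tr <- make_module_pair(net, "shell", overlap_bounds = c(8, 40),
                           size_range = c(40, 80), rng_seed = seed)
    rs <- sample_seeds(tr, 0.5, rng_seed = seed + 100)
    sp <- make_seed_pair(net, rs$raw_a, rs$raw_b)
    sc <- compute_s2b(net, sp, average_path_length(net))
    m <- overlap_metrics(rank_candidates(sc, sp$shared_discarded), tr)
    expect_true(all(diff(m$recall) >= 0))
    expect_true(all(m$recall >= 0 & m$recall <= 1))
    expect_true(all(m$precision >= 0 & m$precision <= 1))
  }
})

test_that("matched precision compares the methods at equal list length", {
  g <- igraph::make_full_graph(8)
  igraph::V(g)$name <- paste0("M", 1:8)
  tr <- make_toy_truth(g, paste0("M", 1:5), paste0("M", 3:7))  # ov: M3,M4,M5

  none <- matched_precision(c("M1", "M2"), character(0), tr)
  expect_equal(none$n_matched, 0L)
  expect_true(is.na(none$precision_s2b))

  both <- matched_precision(c("M3", "M4", "M5"), c("M3", "M4", "M5"), tr)
  expect_equal(both, list(precision_s2b = 1, precision_diamond = 1,
                          n_matched = 3L))

  mix <- matched_precision(c("M3", "M8", "M4", "M5"), c("M3", "M8"), tr)
  expect_equal(mix$precision_s2b, 0.5)     # top-2: M3 in, M8 out
  expect_equal(mix$precision_diamond, 0.5)
  expect_equal(mix$n_matched, 2L)
})

test_that("random rankings hit the overlap at base rate", {
  net <- make_base_network(700, 6, rng_seed = 21)
  tr <- make_module_pair(net, "shell", overlap_bounds = c(10, 40),
                         size_range = c(50, 90), rng_seed = 22)
  nodes <- igraph::V(net)$name
  base_rate <- length(tr$overlap) / length(nodes)
  k <- 25
  trials <- 200
  hits <- withr::with_seed(23, vapply(seq_len(trials), function(i) {
    sum(sample(nodes, k) %in% tr$overlap)
  }, numeric(1)))
  se <- sqrt(base_rate * (1 - base_rate) / (trials * k))
  expect_lt(abs(mean(hits) / k - base_rate), 3 * se + 1e-9)
})

test_that("precision decays with rank on shell modules", {
  net <- make_base_network(1500, 8, rng_seed = 24)
  avgd <- average_path_length(net)
  top <- deep <- c()
  for (seed in 1:6) {
    tr <- make_module_pair(net, "shell", overlap_bounds = c(15, 60),
                           size_range = c(60, 120), rng_seed = seed + 300)
    rs <- sample_seeds(tr, 0.5, rng_seed = seed + 400)
    sp <- make_seed_pair(net, rs$raw_a, rs$raw_b)
    m <- overlap_metrics(
      rank_candidates(compute_s2b(net, sp, avgd), sp$shared_discarded), tr
    )
    top <- c(top, m$in_overlap[1:10])
    deep <- c(deep, m$in_overlap[91:100])
  }
  expect_gt(mean(top), mean(deep))
})

test_that("the benchmark driver is reproducible and summarizes correctly", {
  cfg <- benchmark_config(models = "shell", n_pairs = 2, n_nodes = 700,
                          mean_degree = 6, overlap_bounds = c(8, 40),
                          size_range = c(40, 80), diamond_iters = 25,
                          rng_seed = 77)
  b1 <- suppressWarnings(run_benchmark(cfg))
  expect_equal(nrow(b1$pairs), 2)
  expect_true(all(b1$pairs$overlap >= 8 & b1$pairs$overlap <= 40))
  expect_equal(b1$summary$n_pairs, 2)
  expect_equal(b1$summary$prec_s2b_matched_median,
               stats::median(b1$pairs$prec_s2b_matched, na.rm = TRUE))
  expect_equal(b1$summary$prec_diamond_q3,
               unname(stats::quantile(b1$pairs$prec_diamond, 0.75,
                                      na.rm = TRUE, type = 7)))

  b2 <- suppressWarnings(run_benchmark(cfg))
  expect_identical(b1$pairs, b2$pairs)
})

test_that("robustness knobs (contamination, rewiring, seed fraction) run through", {
  cfg <- benchmark_config(models = "shell", n_pairs = 2, n_nodes = 700,
                          mean_degree = 6, overlap_bounds = c(8, 40),
                          size_range = c(40, 80), diamond_iters = 20,
                          seed_fraction = 0.3, contamination = 0.2,
                          rewire_fraction = 0.1, rng_seed = 88)
  b <- suppressWarnings(run_benchmark(cfg))
  expect_equal(nrow(b$pairs), 2)
  expect_true(all(is.finite(b$pairs$prec_s2b_topk)))
  ok <- !is.na(b$pairs$prec_s2b_matched)
  expect_true(all(b$pairs$prec_s2b_matched[ok] >= 0 &
                  b$pairs$prec_s2b_matched[ok] <= 1))
})
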