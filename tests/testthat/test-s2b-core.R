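test_that("seed pairs discard shared members and police emptiness", {
  g <- igraph::make_graph(~ X - Y - Z)
  sp <- make_seed_pair(g, c("X", "Y"), c("Y", "Z"))
  expect_equal(sp$seeds_a, "X")
  expect_equal(sp$seeds_b, "Z")
  expect_equal(sp$shared_discarded, "Y")

  sp2 <- make_seed_pair(g, "X", "Z")
  expect_length(sp2$shared_discarded, 0)

  expect_error(make_seed_pair(g, "X", "X"), "empty")
  expect_message(make_seed_pair(g, c("X", "nope"), "Z"), "absent")
})

test_that("single-path toy graph follows the path-length filter", {
  g <- igraph::make_graph(~ A - K - B)
  sp <- make_seed_pair(g, "A", "B")
  avgd <- average_path_length(g)          # 4/3 < 2: the only pair is filtered
  expect_equal(unname(compute_s2b(g, sp, avgd)), c(0, 0, 0))
  s <- compute_s2b(g, sp, 2)              # override keeps the pair
  expect_equal(s[["K"]], 1)
  expect_equal(s[["B"]], 0)               # j = k exclusion empties B's sums
  expect_error(compute_s2b(g, sp, 0), "positive")
})

test_that("nodes in foreign components score zero", {
  g <- igraph::make_graph(~ A - K - B, P - Q)
  sp <- make_seed_pair(g, "A", "B")
  s <- compute_s2b(g, sp, 3)
  expect_equal(s[["P"]], 0)
  expect_equal(s[["Q"]], 0)
})

test_that("S2B equals the shortest-path enumeration oracle on random graphs", {
  for (seed in 1:40) {
    g <- rand_graph(40, 0.09, seed)
    nodes <- igraph::V(g)$name
    sp <- withr::with_seed(seed, {
      a <- sample(nodes, 5)
      b <- sample(setdiff(nodes, a), 5)
      make_seed_pair(g, a, b)
    })
    avgd <- average_path_length(g)
    expect_equal(compute_s2b(g, sp, avgd), s2b_path_oracle(g, sp, avgd))
  }
})

test_that("scores are in range, symmetric off-seed, and monotone in avgd", {
  for (seed in 41:55) {
    g <- rand_graph(45, 0.08, seed)
    nodes <- igraph::V(g)$name
    sp <- withr::with_seed(seed, {
      a <- sample(nodes, 6)
      b <- sample(setdiff(nodes, a), 6)
      make_seed_pair(g, a, b)
    })
    avgd <- average_path_length(g)
    s_ab <- compute_s2b(g, sp, avgd)
    expect_true(all(s_ab >= 0 & s_ab <= 1, na.rm = TRUE))

    # swapping the two seed sets leaves every non-seed score unchanged
    sp_rev <- make_seed_pair(g, sp$seeds_b, sp$seeds_a)
    s_ba <- compute_s2b(g, sp_rev, avgd)
    off <- setdiff(nodes, c(sp$seeds_a, sp$seeds_b))
    expect_equal(s_ab[off], s_ba[off])

    # a weaker path filter never retains fewer pairs: denominators grow
    den_of <- function(avgd) {
      d <- igraph::distances(g, v = sp$seeds_a)[, sp$seeds_b, drop = FALSE]
      sum(is.finite(d) & d <= avgd)
    }
    expect_gte(den_of(avgd + 1), den_of(avgd))
    s_wide <- compute_s2b(g, sp, avgd + 1)
    expect_true(all(!is.na(s_wide[off])))
  }
})

test_that("scoring is deterministic", {
  g <- rand_graph(50, 0.07, seed = 99)
  nodes <- igraph::V(g)$name
  sp <- make_seed_pair(g, nodes[1:5], nodes[6:10])
  expect_identical(compute_s2b(g, sp, 3), compute_s2b(g, sp, 3))
})

test_that("the threshold minimizes the L-curve objective over observed scores", {
  expect_equal(s2b_threshold(rep(0.37, 10)), 0.37)

  # two-valued score set, objective evaluated by hand:
  # s = 0.01: (0.01)^2 + (1 - 0.99)^2 = 2.01e-4 ; s = 1: 1 + 0 = 1
  expect_equal(s2b_threshold(c(1, rep(0.01, 99))), 0.01)

  expect_error(s2b_threshold(rep(0, 5)), "positive")

  brute <- function(s) {
    vals <- sort(unique(s))
    obj <- vapply(vals, function(v) {
      (v / max(s))^2 + (1 - mean(s <= v))^2
    }, numeric(1))
    vals[which.min(obj)]
  }
  for (seed in 1:25) {
    s <- withr::with_seed(seed, round(stats::rbeta(50, 0.4, 4), 3))
    if (max(s) == 0) next
    thr <- s2b_threshold(s)
    expect_true(thr %in% s)
    expect_equal(thr, brute(s))
  }
})

test_that("candidate selection applies strict cuts and ordering", {
  res <- structure(list(
    score = c(A = 0.9, B = 0.5, C = 0.1, D = 0.4),
    ss1 = c(A = 1, B = 1, C = 1, D = 1),
    ss2 = c(A = 1, B = 1, C = 1, D = 1),
    threshold = 0.4,
    seed_pair = structure(list(seeds_a = "Z1", seeds_b = "Z2",
                               shared_discarded = character(0)),
                          class = "s2b_seed_pair")
  ), class = "s2b_result")
  expect_equal(select_candidates(res, 0.9), c("A", "B"))  # D at threshold: out
  res$ss1["A"] <- 0.9                                      # strict: 0.9 !> 0.9
  expect_equal(select_candidates(res, 0.9), "B")
  expect_equal(select_candidates(res, 0), c("A", "B"))
})

test_that("the full driver produces a coherent per-node table", {
  net <- make_base_network(300, 6, rng_seed = 8)
  tr <- make_module_pair(net, "shell", overlap_bounds = c(8, 40),
                         size_range = c(30, 60), rng_seed = 9)
  rs <- sample_seeds(tr, 0.5, rng_seed = 10)
  res <- s2b_run(net, rs$raw_a, rs$raw_b, n_random = 5, rng_seed = 11)
  df <- as.data.frame(res)
  expect_named(df, c("node", "s2b", "ss1", "ss2", "rank", "is_candidate",
                     "is_seed_a", "is_seed_b"))
  expect_true(all(df$s2b >= 0 & df$s2b <= 1, na.rm = TRUE))
  expect_true(all(df$ss1 >= 0 & df$ss1 <= 1, na.rm = TRUE))
  expect_true(all(diff(df$s2b[!is.na(df$rank)]) <= 0))
  expect_true(all(df$is_candidate[df$is_candidate] %in% TRUE))
  # identical seed, identical output
  res2 <- s2b_run(net, rs$raw_a, rs$raw_b, n_random = 5, rng_seed = 11)
  expect_identical(as.data.frame(res2), df)
})
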