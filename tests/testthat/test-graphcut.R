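test_that("costs are absolute deviations from the seed average", {
  tpl <- build_template(c(5, 5), radius = 3, rays = 3, nodes = 2)
  s <- structure(list(template = tpl,
                      gray = matrix(c(131, 160, 100, 40, 100, 70), 3, 2),
                      seed_avg = 100),
                 class = "ray_samples")
  p <- compute_costs(s)
  expect_equal(p$costs, matrix(c(31, 60, 0, 60, 0, 30), 3, 2))
  expect_true(all(p$costs >= 0))
})

test_that("terminal weights follow the adjacent-cost-difference rule", {
  # worked bright-side ray: gray (109,110,94,155,160,131) at seed average 100
  bright <- abs(100 - c(109, 110, 94, 155, 160, 131))
  expect_equal(bright, c(9, 10, 6, 55, 60, 31))
  wb <- compute_terminal_weights(bright)
  expect_equal(wb, c(-9, 1, -4, 49, 5, 31))

  # worked dark-side ray: gray (95,101,98,55,40,60)
  dark <- abs(100 - c(95, 101, 98, 55, 40, 60))
  expect_equal(dark, c(5, 1, 2, 45, 60, 40))
  wd <- compute_terminal_weights(dark)
  expect_equal(wd, c(-5, -4, 1, 43, 15, 40))

  # lesion-to-tissue transitions carry the large sink weights 49 and 43
  expect_equal(wb[4], 49)
  expect_equal(wd[4], 43)

  # constant costs: boundary bindings only, zero interior weights
  expect_equal(compute_terminal_weights(c(5, 5, 5)), c(-5, 0, 5))

  expect_error(compute_terminal_weights(9), "length")
  expect_error(compute_terminal_weights(c(-1, 2)), "non-negative")
})

test_that("graph structure matches the construction rules", {
  costs <- matrix(1, 4, 3)
  g <- build_graph(costs, delta_r = 1)
  expect_equal(g$n_nodes, 4 * 3 + 2)
  expect_equal(sum(g$type == "intra"), 4 * (3 - 1))
  expect_equal(sum(g$type == "inter"), 2 * 4 * 3)
  expect_gt(g$INF, sum(g$src_cap) + sum(g$snk_cap))

  # delta_r = 0: every inter-edge targets the same level on the neighbour
  g0 <- build_graph(costs, delta_r = 0)
  lvl <- function(id) (id - 1) %% 3 + 1
  inter <- g0$type == "inter"
  expect_true(all(lvl(g0$from[inter]) == lvl(g0$to[inter])))

  # delta_r >= 1: inter-edges drop at most delta_r levels, floored at 1
  g2 <- build_graph(costs, delta_r = 2)
  inter2 <- g2$type == "inter"
  expect_true(all(lvl(g2$to[inter2]) == pmax(lvl(g2$from[inter2]) - 2, 1)))

  expect_error(build_graph(costs, delta_r = -1), "delta_r")
})

test_that("min cut solves degenerate instances correctly", {
  # strictly increasing costs: cutting right after the innermost node severs
  # nothing (cost 0) and is the unique minimum; keeping zero nodes would
  # sever the innermost source bindings instead
  costs <- matrix(rep(c(2, 4, 7, 11), each = 3), 3, 4)
  cut <- solve_min_cut(build_graph(costs, 1))
  expect_equal(cut$k, rep(1L, 3))
  expect_equal(cut$cut_cost, 0)
  expect_equal(brute_force_min_cut(costs, 1)$k, cut$k)

  # all-zero costs: every cut ties at 0; canonical maximal cut keeps all
  z <- matrix(0, 4, 3)
  cutz <- solve_min_cut(build_graph(z, 1))
  expect_equal(cutz$cut_cost, 0)
  expect_equal(cutz$k, rep(3L, 4))

  # per-ray costs (0, 10): zero-cost cuts keep at most the inner node;
  # canonical maximal min cut is k = (1,1,1) (frozen from the exhaustive
  # oracle; cutting the outer sink bindings would cost 30)
  c01 <- matrix(rep(c(0, 10), each = 3), 3, 2)
  a <- solve_min_cut(build_graph(c01, 1))
  b <- brute_force_min_cut(c01, 1)
  expect_equal(a$cut_cost, 0)
  expect_equal(a$k, rep(1L, 3))
  expect_equal(b$k, a$k)

  # per-ray costs (10, 0): the fully-inside cut is free
  c10 <- matrix(rep(c(10, 0), each = 3), 3, 2)
  a2 <- solve_min_cut(build_graph(c10, 1))
  expect_equal(a2$cut_cost, 0)
  expect_equal(a2$k, rep(2L, 3))
})

test_that("solver agrees with the exhaustive oracle on random small instances", {
  set.seed(7)
  for (trial in 1:100) {
    R <- sample(3:6, 1)
    L <- sample(2:5, 1)
    dr <- sample(0:2, 1)
    costs <- random_costs(R, L)
    cut <- solve_min_cut(build_graph(costs, dr))
    oracle <- brute_force_min_cut(costs, dr)
    expect_equal(cut$cut_cost, oracle$cut_cost)
    expect_equal(cut$k, oracle$k)
    # structural invariants on every solve
    expect_true(all(abs(diff(c(cut$k, cut$k[1]))) <= dr))
    expect_true(all(cut$k >= 0 & cut$k <= L))
  }
})

test_that("cut cost is non-increasing in delta_r and delta_r = 0 forces equal levels", {
  set.seed(21)
  for (trial in 1:20) {
    costs <- random_costs(sample(4:6, 1), sample(3:5, 1))
    prev <- Inf
    for (dr in 0:3) {
      cut <- solve_min_cut(build_graph(costs, dr))
      expect_lte(cut$cut_cost, prev + 1e-9)
      prev <- cut$cut_cost
      if (dr == 0) expect_length(unique(cut$k), 1L)
    }
  }
})

test_that("no infinite edge is ever part of the minimum cut", {
  set.seed(33)
  for (trial in 1:20) {
    costs <- random_costs(5, 4)
    g <- build_graph(costs, 1)
    cut <- solve_min_cut(g)
    # every intra/inter capacity strictly exceeds the optimal cut cost
    expect_true(all(g$cap[g$type %in% c("intra", "inter")] > cut$cut_cost))
  }
})

test_that("the brute-force oracle is a true minimum and guards its size", {
  # L = 1 equivalent: 2 levels per ray, delta_r = 0 collapses the search to
  # concyclic vectors whose costs can be enumerated by hand
  costs <- matrix(c(3, 1, 2, 7, 9, 8), 3, 2)
  lc0 <- sum(costs[, 1])                 # k = 0: sever inner source bindings
  lc1 <- 0                               # k = 1: nothing severed
  lc2 <- sum(costs[, 2])                 # k = 2: sever outer sink bindings
  oracle <- brute_force_min_cut(costs, 0)
  expect_equal(oracle$cut_cost, min(lc0, lc1, lc2))
  expect_equal(oracle$k, rep(1L, 3))

  # the oracle's cost is a lower bound on any explicitly enumerated vector
  set.seed(5)
  costs2 <- random_costs(4, 3)
  oracle2 <- brute_force_min_cut(costs2, 2)
  lc <- starcut:::ray_level_costs(
    matrix(starcut:::terminal_capacities(as_cost_profile(costs2))$src, 4, 3),
    matrix(starcut:::terminal_capacities(as_cost_profile(costs2))$snk, 4, 3))
  for (i in 1:50) {
    k <- sample(0:3, 4, replace = TRUE)
    if (any(abs(diff(c(k, k[1]))) > 2)) next
    expect_lte(oracle2$cut_cost,
               starcut:::cut_vector_cost(k, lc) + 1e-9)
  }

  expect_error(brute_force_min_cut(matrix(1, 12, 9), 1), "too large")
})
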