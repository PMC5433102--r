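test_that("the supergraph has the stated vertex and arc counts", {
  g2 <- cnt_supergraph(2)
  expect_identical(g2$n_vertices, 3L)
  expect_identical(nrow(g2$arcs), 2L)
  expect_identical(g2$arcs$j, c(2L, 3L))
  g3 <- cnt_supergraph(3)
  expect_identical(g3$n_vertices, 5L)
  expect_identical(nrow(g3$arcs), 7L)
  g4 <- cnt_supergraph(4)
  expect_identical(g4$n_vertices, 7L)
  expect_identical(nrow(g4$arcs), 15L)
  expect_true(all(g4$arcs$i < g4$arcs$j))   # acyclic by construction
  expect_error(cnt_supergraph(1), "two leaves")
})

test_that("the model carries the expected variable system", {
  # k = 2, n = 1, e = 2: x over 2 arcs; y and the zero-indicator per vertex;
  # 3 binary-expansion digits per vertex; a, d, abar, dbar, w per arc
  m <- cnphylo:::cnt_build_model(rbind(c(2L), c(2L)), e = 2)
  expect_identical(m$V, 3L)
  expect_identical(nrow(m$arcs), 2L)
  q_digits <- floor(log2(2)) + 2
  expect_identical(length(m$obj),
                   as.integer(2 + 3 + 3 * q_digits + 3 + 5 * 2))
  # root and leaf labels are fixed through the bounds
  expect_identical(m$lb[m$vy(1, 1)], 2)
  expect_identical(m$ub[m$vy(1, 1)], 2)
})

test_that("trivial and near-trivial instances solve to known optima", {
  dip <- rbind(s1 = c(2L, 2L), s2 = c(2L, 2L))
  sol <- cnt_solve(dip, e = 2, time_limit = 60)
  expect_identical(sol$status, "optimal")
  expect_equal(sol$cost, 0)
  expect_identical(validate_tree(sol$tree, dip, 2), character(0))

  two <- rbind(s1 = c(2L, 2L), s2 = c(3L, 3L))
  sol2 <- cnt_solve(two, e = 3, time_limit = 60)
  expect_equal(sol2$cost, 1)  # one amplification spanning both positions

  # root out-degree one: both leaves at (1); the augmented instance lets a
  # single deletion above an internal vertex serve both
  one <- rbind(s1 = 1L, s2 = 1L)
  sol3 <- cnt_solve(one, e = 2, time_limit = 60)
  expect_equal(sol3$cost, 1)
  expect_false(is.na(sol3$tree$aux_leaf))
  sol3b <- cnt_solve(one, e = 2, time_limit = 60, augment = FALSE)
  expect_equal(sol3b$cost, 2)
})

test_that("the ILP matches the exhaustive oracle on random tiny instances", {
  set.seed(61)
  for (rep in 1:8) {
    k <- sample(2:3, 1); n <- sample(1:3, 1); e <- sample(2:3, 1)
    C <- matrix(sample(0:e, k * n, replace = TRUE), k, n)
    rownames(C) <- paste0("s", seq_len(k))
    sol <- cnt_solve(C, e = e, time_limit = 120)
    expect_identical(sol$status, "optimal")
    expect_equal(sol$cost, cnt_brute(C, e))
    expect_identical(validate_tree(sol$tree, C, e), character(0))
  }
})

test_that("decoded trees are consistent and cost what the objective says", {
  set.seed(62)
  sim <- simulate_cnt(3, 5, m = 2, rho = 0.3, seed = 63)
  sol <- cnt_solve(sim$profiles, e = sim$e, time_limit = 120)
  expect_identical(validate_tree(sol$tree, sim$profiles, sim$e), character(0))
  expect_identical(tree_cost(sol$tree), as.integer(sol$cost))
  for (v in seq_len(nrow(sol$tree$profiles))) {
    ev <- sol$tree$edge_events[[v]]
    if (!is.null(ev)) expect_true(events_sorted(ev))
  }
})

test_that("the optimum never exceeds the simulated event cost", {
  for (seed in c(71, 72)) {
    sim <- simulate_cnt(4, 6, m = 2, rho = 0.2, seed = seed)
    sol <- cnt_solve(sim$profiles, e = sim$e, time_limit = 300)
    expect_identical(sol$status, "optimal")
    expect_lte(sol$cost, sim$simulated_cost)
  }
})

test_that("duplicating a leaf never raises the optimum", {
  C <- rbind(s1 = c(2L, 1L), s2 = c(1L, 2L))
  base <- cnt_solve(C, e = 2, time_limit = 60)$cost
  C3 <- rbind(C, s3 = c(1L, 2L))
  dup <- cnt_solve(C3, e = 2, time_limit = 60)$cost
  # splitting the duplicated leaf into two identical children is free, and
  # suppressing the duplicate maps any solution back, so the optima agree
  expect_equal(dup, base)
})
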