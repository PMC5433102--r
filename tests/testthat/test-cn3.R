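test_that("common-zero positions are stripped and restored", {
  red <- strip_common_zeros(c(0, 2), c(0, 1))
  expect_identical(red$u, 2L)
  expect_identical(red$v, 1L)
  expect_identical(red$keep, 2L)
  red2 <- strip_common_zeros(c(2), c(1))
  expect_identical(red2$keep, 1L)
  red3 <- strip_common_zeros(c(0), c(0))
  expect_identical(length(red3$keep), 0L)
  expect_equal(cn_triplet(c(0), c(0))$cost, 0)
  expect_identical(cn_triplet(c(0), c(0))$median, 0L)
})

test_that("triplet cost matches worked examples on both algorithms", {
  cases <- list(
    list(u = c(2), v = c(2), cost = 0),
    list(u = c(2), v = c(0), cost = 2),
    list(u = c(2, 0), v = c(0, 2), cost = 4),
    list(u = c(1), v = c(3), cost = 2)
  )
  for (cs in cases) {
    expect_equal(cn_triplet(cs$u, cs$v, algorithm = "alg1")$cost, cs$cost)
    expect_equal(cn_triplet(cs$u, cs$v, algorithm = "alg2")$cost, cs$cost)
    expect_equal(cn_triplet_brute(cs$u, cs$v), cs$cost)
  }
})

test_that("the two DPs and the brute oracle agree exhaustively (entries <= 2)", {
  for (n in 1:2) {
    profs <- all_profiles(n, 2)
    for (a in seq_len(nrow(profs))) {
      for (b in seq_len(nrow(profs))) {
        u <- as.integer(profs[a, ]); v <- as.integer(profs[b, ])
        c1 <- cn_triplet(u, v, algorithm = "alg1")$cost
        c2 <- cn_triplet(u, v, algorithm = "alg2")$cost
        cb <- cn_triplet_brute(u, v)
        expect_equal(c1, c2)
        expect_equal(c1, cb)
      }
    }
  }
})

test_that("the two DPs agree on larger random instances", {
  set.seed(21)
  for (rep in 1:15) {
    n <- sample(3:25, 1)
    B <- sample(2:5, 1)
    u <- sample(0:B, n, replace = TRUE)
    v <- sample(0:B, n, replace = TRUE)
    expect_equal(cn_triplet(u, v, algorithm = "alg1")$cost,
                 cn_triplet(u, v, algorithm = "alg2")$cost)
  }
})

test_that("triplet cost is symmetric and bounded by the endpoint distances", {
  set.seed(22)
  for (rep in 1:25) {
    n <- sample(1:12, 1)
    u <- sample(0:4, n, replace = TRUE)
    v <- sample(0:4, n, replace = TRUE)
    duv <- cn_triplet(u, v, algorithm = "alg2")$cost
    expect_equal(duv, cn_triplet(v, u, algorithm = "alg2")$cost)
    expect_lte(duv, min(cn_distance(u, v), cn_distance(v, u)))
  }
})

test_that("traceback yields a valid sorted solution at the optimal cost", {
  sol <- cn_triplet(c(2, 2), c(2, 2))
  expect_identical(sol$median, c(2L, 2L))
  expect_identical(nrow(sol$events_u), 0L)
  expect_identical(nrow(sol$events_v), 0L)

  sol2 <- cn_triplet(c(2), c(0))
  expect_equal(sol2$cost, 2)
  expect_identical(apply_events(sol2$median, sol2$events_u), 2L)
  expect_identical(apply_events(sol2$median, sol2$events_v), 0L)

  set.seed(23)
  for (rep in 1:40) {
    n <- sample(1:10, 1)
    u <- sample(0:4, n, replace = TRUE)
    v <- sample(0:4, n, replace = TRUE)
    B <- max(u, v, 1L)
    sol <- cn_triplet(u, v)
    expect_identical(apply_events(sol$median, sol$events_u), u)
    expect_identical(apply_events(sol$median, sol$events_v), v)
    expect_equal(event_cost(sol$events_u) + event_cost(sol$events_v),
                 sol$cost)
    expect_true(events_sorted(sol$events_u))
    expect_true(events_sorted(sol$events_v))
    expect_true(all(sol$median <= B))
  }
})

test_that("an explicit median cap constrains the solution", {
  # without a cap the best median for (3) vs (3) is (3) at cost 0;
  # capping at e = 2 forces a smaller median and one amplification per side
  expect_equal(cn_triplet(c(3), c(3), e = 2)$cost, 2)
  expect_equal(cn_triplet(c(3), c(3))$cost, 0)
  sol <- cn_triplet(c(3), c(3), e = 2)
  expect_lte(max(sol$median), 2L)
})
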