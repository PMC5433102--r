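test_that("budget table matches the stated base cases", {
  G <- cn_distance_table(c(2), c(2))
  expect_equal(G[1, 0 + 1, 0 + 1], 0)
  G2 <- cn_distance_table(c(2), c(0))
  expect_true(all(is.infinite(G2[1, 1:2, ]))) # d < p1 infeasible
  expect_equal(G2[1, 2 + 1, 0 + 1], 2)
  # q1 > 0: only d < p1 with q1 = p1 - d + a feasible
  G3 <- cn_distance_table(c(2, 2), c(3, 1))
  expect_equal(min(G3[2, , ]), 2)
})

test_that("distance reproduces worked examples and the BFS oracle agrees", {
  expect_equal(cn_distance(c(2, 2), c(3, 1)), 2)
  expect_equal(cn_distance_bfs(c(2, 2), c(3, 1)), 2)
  expect_equal(cn_distance(c(2, 1, 2), c(1, 2, 1)), 3)
  expect_equal(cn_distance_bfs(c(2, 1, 2), c(1, 2, 1)), 3)
  expect_equal(cn_distance(c(1, 4, 2), c(2, 2, 2)),
               cn_distance_bfs(c(1, 4, 2), c(2, 2, 2)))
  expect_equal(cn_max_bound(c(2, 2), c(3, 1)), 3)
  expect_equal(cn_max_bound(c(0), c(0)), 0)
  expect_equal(cn_max_bound(c(1, 4, 2), c(2, 2, 2)), 4)
  expect_error(cn_distance(c(1, 2), c(1)), "length")
})

test_that("identity, asymmetry and the finiteness characterization hold", {
  expect_equal(cn_distance(c(0), c(1)), Inf)
  expect_equal(cn_distance(c(2), c(0)), 2)
  expect_equal(cn_distance_bfs(c(2), c(0), cap = 2), 2)
  profs <- all_profiles(2, 3)
  for (a in seq_len(nrow(profs))) {
    pa <- as.integer(profs[a, ])
    expect_equal(cn_distance(pa, pa), 0)
    for (b in seq_len(nrow(profs))) {
      pb <- as.integer(profs[b, ])
      d <- cn_distance(pa, pb)
      expect_identical(is.finite(d), all(pa > 0L | pb == 0L))
    }
  }
})

test_that("distance equals the BFS oracle exhaustively (n <= 2)", {
  for (n in 1:2) {
    profs <- all_profiles(n, 3)
    np <- nrow(profs)
    D <- matrix(Inf, np, np)
    for (a in seq_len(np)) {
      d <- cnphylo:::cn_distance_bfs_all(as.integer(profs[a, ]), cap = 3)
      D[a, ] <- d
    }
    for (a in seq_len(np)) {
      for (b in seq_len(np)) {
        expect_equal(cn_distance(as.integer(profs[a, ]),
                                 as.integer(profs[b, ])), D[a, b])
      }
    }
  }
})

test_that("directed triangle inequality holds exhaustively (n <= 2)", {
  for (n in 1:2) {
    profs <- all_profiles(n, 3)
    np <- nrow(profs)
    D <- matrix(0, np, np)
    for (a in seq_len(np)) for (b in seq_len(np)) {
      D[a, b] <- cn_distance(as.integer(profs[a, ]), as.integer(profs[b, ]))
    }
    for (a in seq_len(np)) for (b in seq_len(np)) for (c in seq_len(np)) {
      expect_lte(D[a, c], D[a, b] + D[b, c])
    }
  }
})

test_that("any event sequence upper-bounds the distance to its image", {
  set.seed(9)
  for (rep in 1:60) {
    n <- sample(1:5, 1)
    p <- sample(0:4, n, replace = TRUE)
    ev <- random_events(n, sample(0:5, 1), bmax = 2L)
    q <- apply_events(p, ev)
    expect_lte(cn_distance(p, q), event_cost(ev))
  }
})
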