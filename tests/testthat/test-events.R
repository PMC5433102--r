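test_that("event application follows the clamped piecewise rule", {
  expect_identical(apply_event(c(2, 2, 2), 1, 2, +1), c(3L, 3L, 2L))
  expect_identical(apply_event(c(2, 0, 1), 1, 3, -2), c(0L, 0L, 0L))
  # a lost position can never be regained
  expect_identical(apply_event(c(0, 2), 1, 2, +1), c(0L, 3L))
  expect_error(apply_event(c(2, 2), 1, 3, 1), "out of range")
  expect_error(apply_event(c(2, 2), 2, 1, 1), "out of range")
})

test_that("sequences fold left and freeze lost positions", {
  expect_identical(apply_events(c(2, 2), events()), c(2L, 2L))
  expect_identical(apply_events(c(2, 2), events(c(2, 1), c(2, 1), c(-1, 1))),
                   c(3L, 1L))
  expect_identical(apply_events(c(2), events(c(1, 1), c(1, 1), c(-2, 5))),
                   0L)
})

test_that("zero absorption holds along random sequences", {
  set.seed(11)
  for (rep in 1:50) {
    n <- sample(1:5, 1)
    p <- sample(0:3, n, replace = TRUE)
    ev <- random_events(n, sample(0:6, 1))
    lost <- rep(FALSE, n)
    for (r in seq_len(nrow(ev))) {
      p <- apply_event(p, ev$s[r], ev$t[r], ev$b[r])
      lost <- lost | p == 0L
      expect_true(all(p[lost] == 0L))
    }
  }
})

test_that("sequence cost is the sum of magnitudes and is additive", {
  expect_identical(event_cost(events()), 0L)
  expect_identical(event_cost(events(c(1, 3), c(2, 3), c(2, -1))), 3L)
  expect_identical(event_cost(events(1, 5, -3)), 3L)
  set.seed(2)
  for (rep in 1:20) {
    e1 <- random_events(4, sample(0:5, 1))
    e2 <- random_events(4, sample(0:5, 1))
    expect_identical(event_cost(rbind(e1, e2)),
                     event_cost(e1) + event_cost(e2))
  }
})

test_that("unit decomposition preserves cost and outcome", {
  expect_identical(unit_events(events(1, 2, -2)),
                   events(c(1, 1), c(2, 2), c(-1, -1)))
  expect_identical(nrow(unit_events(events())), 0L)
  set.seed(3)
  for (rep in 1:60) {
    n <- sample(1:4, 1)
    p <- sample(0:3, n, replace = TRUE)
    ev <- random_events(n, sample(0:5, 1), bmax = 3L)
    ue <- unit_events(ev)
    expect_identical(event_cost(ue), event_cost(ev))
    expect_true(all(abs(ue$b) == 1L))
    expect_identical(apply_events(p, ue), apply_events(p, ev))
  }
})

test_that("unit decomposition equivalence holds exhaustively at tiny scale", {
  for (n in 1:2) {
    profs <- all_profiles(n, 3)
    evs <- all_events(n, bmax = 3L)
    for (r in seq_len(nrow(evs))) {
      ev <- evs[r, , drop = FALSE]
      ue <- unit_events(ev)
      for (pr in seq_len(nrow(profs))) {
        p <- as.integer(profs[pr, ])
        expect_identical(apply_events(p, ue), apply_events(p, ev))
      }
    }
  }
})

test_that("sortedness means no deletion after an amplification", {
  expect_true(events_sorted(events(c(1, 2), c(1, 2), c(-1, 1))))
  expect_false(events_sorted(events(c(2, 1), c(2, 1), c(1, -1))))
  expect_true(events_sorted(events()))
  expect_true(events_sorted(events(c(1, 1), c(1, 2), c(-2, -1))))
})

test_that("skyline reconstruction inverts coverage tracks", {
  ev <- cnphylo:::tracks_to_events(c(0, 1), c(1, 0))
  expect_identical(ev, events(c(2, 1), c(2, 1), c(-1, 1)))
  expect_identical(nrow(cnphylo:::tracks_to_events(c(0, 0), c(0, 0))), 0L)
  # round trip: coverage of a sorted unit sequence -> skyline -> same result
  set.seed(4)
  for (rep in 1:50) {
    n <- sample(1:6, 1)
    parent <- sample(0:4, n, replace = TRUE)
    nd <- sample(0:3, 1); na <- sample(0:3, 1)
    del <- random_events(n, nd, bmax = 1L); del$b <- rep(-1L, nd)
    amp <- random_events(n, na, bmax = 1L); amp$b <- rep(1L, na)
    seq <- rbind(del, amp)
    child <- apply_events(parent, seq)
    dtrack <- atrack <- integer(n)
    for (r in seq_len(nrow(seq))) {
      idx <- seq$s[r]:seq$t[r]
      if (seq$b[r] < 0) dtrack[idx] <- dtrack[idx] + 1L
      else atrack[idx] <- atrack[idx] + 1L
    }
    rec <- cnphylo:::tracks_to_events(dtrack, atrack)
    expect_identical(apply_events(parent, rec), child)
    # skyline cost: one unit event per new start; never above the original
    expect_identical(event_cost(rec),
                     sum(pmax(diff(c(0L, dtrack)), 0L)) +
                       sum(pmax(diff(c(0L, atrack)), 0L)))
    expect_lte(event_cost(rec), event_cost(seq))
    expect_true(events_sorted(rec))
  }
})
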