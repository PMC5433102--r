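test_that("nontrivial clades exclude the root set and singletons", {
  cl <- nontrivial_clades("((a,b),(c,d));")
  expect_setequal(vapply(cl, paste, character(1), collapse = ""),
                  c("ab", "cd"))
  cl2 <- nontrivial_clades("(a,(b,(c,d)));")
  expect_setequal(vapply(cl2, paste, character(1), collapse = ""),
                  c("cd", "bcd"))
  expect_length(nontrivial_clades("(a,b);"), 0)
})

test_that("normalized RF matches hand-computed values", {
  expect_equal(normalized_rf("((a,b),(c,d));", "((a,b),(c,d));"), 0)
  expect_equal(normalized_rf("((a,b),(c,d));", "((a,c),(b,d));"), 1)
  # clades {ab, cd} vs {cd, bcd}: symmetric difference {ab, bcd} -> 2/4
  expect_equal(normalized_rf("((a,b),(c,d));", "(a,(b,(c,d)));"), 0.5)
  # the same pair is identical when compared unrooted (one split ab|cd each)
  expect_equal(normalized_rf("((a,b),(c,d));", "(a,(b,(c,d)));",
                             rooted = FALSE), 0)
  expect_error(normalized_rf("((a,b),(c,d));", "((a,b),(c,x));"),
               "leaf label")
})

test_that("normalized RF is symmetric, bounded and zero on identity", {
  set.seed(41)
  for (rep in 1:15) {
    k <- sample(3:7, 1)
    nwk <- function() {
      topo <- random_topology(k)
      prof <- matrix(2L, length(topo$parent), 1)
      labs <- topo$leaves
      names(labs) <- letters[seq_len(k)]
      tr <- cnt_tree(prof, topo$parent,
                     rep(list(events()), length(topo$parent)), labs, 2L)
      topology_newick(tr)
    }
    t1 <- nwk(); t2 <- nwk()
    r12 <- normalized_rf(t1, t2)
    expect_equal(r12, normalized_rf(t2, t1))
    expect_gte(r12, 0); expect_lte(r12, 1)
    expect_equal(normalized_rf(t1, t1), 0)
  }
})

test_that("unrooted comparison agrees with phangorn's RF distance", {
  skip_if_not_installed("phangorn")
  set.seed(42)
  for (rep in 1:10) {
    k <- sample(4:8, 1)
    nwk <- function() {
      topo <- random_topology(k)
      prof <- matrix(2L, length(topo$parent), 1)
      labs <- topo$leaves
      names(labs) <- letters[seq_len(k)]
      tr <- cnt_tree(prof, topo$parent,
                     rep(list(events()), length(topo$parent)), labs, 2L)
      topology_newick(tr)
    }
    t1 <- nwk(); t2 <- nwk()
    mine <- normalized_rf(t1, t2, rooted = FALSE)
    p1 <- ape::unroot(ape::read.tree(text = t1))
    p2 <- ape::unroot(ape::read.tree(text = t2))
    rf <- phangorn::RF.dist(p1, p2, normalize = FALSE)
    # phangorn counts the symmetric difference of internal splits; our
    # normalization divides by the total split count of both trees
    n1 <- p1$Nnode - 1L; n2 <- p2$Nnode - 1L
    expected <- if (n1 + n2 == 0) 0 else rf / (n1 + n2)
    expect_equal(mine, expected)
  }
})

test_that("auxiliary diploid leaves are ignored in comparisons", {
  # root with aux leaf and a subtree ((a,b),c)
  prof <- matrix(2L, 7, 1)
  parent <- c(NA, 1L, 1L, 3L, 3L, 4L, 4L)
  labs <- c(a = 6L, b = 7L, c = 5L)
  tr <- cnt_tree(prof, parent, rep(list(events()), 7), labs, 2L,
                 aux_leaf = 2L)
  expect_identical(topology_newick(tr), "((a,b),c);")
  expect_equal(normalized_rf(tr, "((a,b),c);"), 0)
})
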