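## Ground-truthed instance generator for the copy-number tree problem.

#' Random full binary tree topology
#'
#' Grows a full binary tree by repeatedly splitting a uniformly chosen
#' current leaf into two children until `k` leaves exist, then assigns the
#' sample labels `1..k` to the leaves by a uniform random permutation.
#' Uses the current R random number generator state.
#'
#' @param k number of leaves (at least 2).
#' @return list with `parent` (integer vector, `NA` at the root),
#'   `children` (list) and `leaves` (vertex indices in label order: the
#'   vertex of sample 1 first).
#' @export
random_topology <- function(k) {
  k <- as.integer(k)
  if (k < 2L) stop("need at least two leaves", call. = FALSE)
  parent <- NA_integer_
  leaves <- 1L
  nv <- 1L
  while (length(leaves) < k) {
    pick <- leaves[sample.int(length(leaves), 1L)]
    c1 <- nv + 1L; c2 <- nv + 2L; nv <- nv + 2L
    parent[c1] <- pick; parent[c2] <- pick
    leaves <- c(setdiff(leaves, pick), c1, c2)
  }
  children <- vector("list", nv)
  for (i in seq_len(nv)) {
    if (!is.na(parent[i])) children[[parent[i]]] <- c(children[[parent[i]]], i)
  }
  perm <- sample.int(k)
  list(parent = parent, children = children, leaves = leaves[order(perm)])
}

#' Simulate a ground-truthed copy-number tree instance
#'
#' Generates a random full binary tree with `k` leaves, labels each edge
#' with `d ~ Uniform{1..m}` unit events -- each event's interval `(s, t)`
#' drawn uniformly among all `n(n+1)/2` pairs `s <= t` and its sign
#' positive (amplification) with probability `rho` -- and propagates
#' profiles down from the diploid root. The instance's maximum copy number
#' `e` is the largest observed *leaf* entry, floored at 2. Events drawn
#' over already-lost positions are no-ops but still count toward the
#' simulated cost, so an inferred tree may legitimately cost less than the
#' simulation did.
#'
#' @param k leaves; `n` positions; `m` maximum events per edge; `rho`
#'   amplification probability in `[0, 1]`.
#' @param n,m,rho see above.
#' @param seed optional integer seed (restores the RNG state on exit).
#' @return list of class `cnt_simulation`: `profiles` (k x n matrix with
#'   rownames `s1..sk`), `e`, `truth` (a [cnt_tree()]), `simulated_cost`,
#'   and `config`.
#' @examples
#' sim <- simulate_cnt(k = 4, n = 10, m = 1, rho = 0.2, seed = 1)
#' sim$simulated_cost # 6 = 2k - 2 unit events
#' @export
simulate_cnt <- function(k, n, m = 1L, rho = 0.2, seed = NULL) {
  stopifnot(k >= 2L, n >= 1L, m >= 1L, rho >= 0, rho <= 1)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  topo <- random_topology(k)
  nv <- length(topo$parent)
  prof <- matrix(0L, nv, n)
  prof[1L, ] <- 2L
  edge_events <- vector("list", nv)
  total <- 0L
  ## root-to-leaf order: vertices were created parent before child
  for (v in seq_len(nv)[-1L]) {
    nev <- sample.int(m, 1L)
    idx <- sample.int(n * (n + 1L) / 2L, nev, replace = TRUE)
    ## map a draw in 1..n(n+1)/2 to the pair (s, t), s <= t
    pairs <- which(upper.tri(matrix(0, n, n), diag = TRUE), arr.ind = TRUE)
    s <- pairs[idx, 1L]; t <- pairs[idx, 2L]
    b <- ifelse(runif(nev) < rho, 1L, -1L)
    ev <- events(s, t, b)
    prof[v, ] <- apply_events(prof[topo$parent[v], ], ev)
    edge_events[[v]] <- ev
    total <- total + nev
  }
  labs <- topo$leaves
  names(labs) <- paste0("s", seq_len(k))
  leafprof <- prof[labs, , drop = FALSE]
  rownames(leafprof) <- names(labs)
  e <- max(2L, max(leafprof))
  truth <- cnt_tree(prof, topo$parent, edge_events, labs, e)
  structure(list(profiles = leafprof, e = e, truth = truth,
                 simulated_cost = total,
                 config = list(k = k, n = n, m = m, rho = rho, seed = seed)),
            class = "cnt_simulation")
}

#' @export
print.cnt_simulation <- function(x, ...) {
  cfg <- x$config
  cat("Simulated copy-number tree instance: k =", cfg$k, "n =", cfg$n,
      "m =", cfg$m, "rho =", cfg$rho, "\n")
  cat("e =", x$e, " simulated cost =", x$simulated_cost, "\n")
  invisible(x)
}
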