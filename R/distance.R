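## Pairwise event distance between two profiles.
##
## The distance from p to q is the minimum total cost of an event sequence
## yielding q from p (infinite when some p_i = 0 but q_i > 0, since lost
## positions cannot be regained). It is computed by dynamic programming over
## per-position deletion/amplification budgets: G[i, d, a] is the minimum
## cost of a sorted sequence turning the length-i prefix of p into that of q
## with exactly d deletion cost and a amplification cost covering position i.

## Sentinel: strictly greater than any feasible cost (<= 2 n B) so that
## min-folds need no special-casing.
INF_COST <- .Machine$integer.max %/% 4L

#' Maximum copy number over two profiles
#'
#' The bound `B` that caps the deletion/amplification budgets of the
#' distance and triplet dynamic programs.
#'
#' @param p,q integer profiles of equal length.
#' @return non-negative integer.
#' @export
cn_max_bound <- function(p, q) {
  p <- as_profile(p); q <- as_profile(q)
  if (length(p) != length(q)) stop("profiles differ in length", call. = FALSE)
  max(p, q)
}

#' Budget table of the pairwise distance dynamic program
#'
#' Computes the full table `G[i, d, a]` for `1 <= i <= n`,
#' `0 <= d, a <= B`: the minimum cost of an event sequence yielding
#' `q[1:i]` from `p[1:i]` whose deletions (resp. amplifications) covering
#' position `i` cost `d` (resp. `a`). Entries are `Inf` where no such
#' sequence exists: when `q[i] > 0` and (`d >= p[i]` or
#' `q[i] != p[i] - d + a`), or when `q[i] == 0` and `d < p[i]`. The base
#' case `i = 1` is `d + a`; otherwise the entry is the minimum over
#' predecessor budgets `(d', a')` of
#' `G[i-1, d', a'] + max(d - d', 0) + max(a - a', 0)`.
#'
#' @param p,q integer profiles of equal length.
#' @param B budget bound; defaults to [cn_max_bound()].
#' @return numeric array of dimension `c(n, B+1, B+1)` (`Inf` marks
#'   infeasible states); dimensions `d` and `a` are 0-based budgets.
#' @export
cn_distance_table <- function(p, q, B = cn_max_bound(p, q)) {
  p <- as_profile(p); q <- as_profile(q)
  if (length(p) != length(q)) stop("profiles differ in length", call. = FALSE)
  n <- length(p)
  stopifnot(B >= max(p, q))
  dgrid <- matrix(0:B, B + 1L, B + 1L)            # d varies over rows
  agrid <- t(dgrid)                                # a varies over columns
  G <- array(Inf, dim = c(n, B + 1L, B + 1L))
  prev <- NULL
  for (i in seq_len(n)) {
    feas <- if (q[i] > 0L) {
      dgrid < p[i] & q[i] == p[i] - dgrid + agrid
    } else {
      dgrid >= p[i]
    }
    cur <- matrix(Inf, B + 1L, B + 1L)
    if (i == 1L) {
      cur[feas] <- (dgrid + agrid)[feas]
    } else if (any(feas) && any(is.finite(prev))) {
      for (d in 0:B) {
        ddelta <- pmax(d - 0:B, 0L)                # over d'
        for (a in 0:B) {
          if (!feas[d + 1L, a + 1L]) next
          adelta <- pmax(a - 0:B, 0L)              # over a'
          cur[d + 1L, a + 1L] <-
            min(prev + outer(ddelta, adelta, `+`))
        }
      }
    }
    G[i, , ] <- cur
    prev <- cur
  }
  G
}

#' Event distance from one profile to another
#'
#' Minimum total cost of an event sequence yielding `q` from `p`; `Inf`
#' when impossible (some position lost in `p` but present in `q`). The
#' distance is not symmetric.
#'
#' @param p,q integer profiles of equal length.
#' @return non-negative integer, or `Inf`.
#' @examples
#' cn_distance(c(2, 2), c(3, 1)) # 2
#' cn_distance(c(0), c(1))       # Inf
#' @export
cn_distance <- function(p, q) {
  p <- as_profile(p); q <- as_profile(q)
  if (length(p) != length(q)) stop("profiles differ in length", call. = FALSE)
  if (any(p == 0L & q > 0L)) return(Inf)
  n <- length(p)
  G <- cn_distance_table(p, q)
  min(G[n, , ])
}

#' Breadth-first-search oracle for the pairwise distance
#'
#' Independent check of [cn_distance()]: shortest path from `p` to `q` in the
#' graph whose nodes are all profiles with entries in `0..cap` and whose arcs
#' are all unit events `(s, t, +1)` and `(s, t, -1)`, each of weight 1.
#' Intended for tiny state spaces only.
#'
#' @param p,q integer profiles of equal length.
#' @param cap cap on intermediate entries; defaults to `max(p, q)`.
#' @param max_states guard on the state-space size `(cap+1)^n`.
#' @return non-negative integer, or `Inf` if `q` is unreachable.
#' @export
cn_distance_bfs <- function(p, q, cap = max(p, q), max_states = 2e6) {
  p <- as_profile(p); q <- as_profile(q)
  n <- length(p)
  if (length(q) != n) stop("profiles differ in length", call. = FALSE)
  if (max(p, q) > cap) stop("cap below profile entries", call. = FALSE)
  nstates <- (cap + 1)^n
  if (nstates > max_states) stop("state space too large for BFS oracle",
                                 call. = FALSE)
  enc <- function(x) sum(x * (cap + 1)^(seq_len(n) - 1L)) + 1L
  start <- enc(p); goal <- enc(q)
  if (start == goal) return(0L)
  iv <- unlist(lapply(seq_len(n), function(s) rep(s, n - s + 1L)))
  tv <- unlist(lapply(seq_len(n), function(s) s:n))
  dist <- rep(NA_integer_, nstates)
  dist[start] <- 0L
  frontier <- list(p)
  depth <- 0L
  while (length(frontier)) {
    depth <- depth + 1L
    nxt <- list()
    for (x in frontier) {
      for (j in seq_along(iv)) {
        for (b in c(-1L, 1L)) {
          y <- x
          idx <- seq.int(iv[j], tv[j])
          live <- idx[y[idx] != 0L]
          y[live] <- pmin(pmax(y[live] + b, 0L), cap)
          # pmin-cap: amplification beyond cap leaves the capped graph; the
          # uncapped value is unreachable within this oracle, so skip it.
          if (b > 0L && any(x[live] + b > cap)) next
          code <- enc(y)
          if (is.na(dist[code])) {
            dist[code] <- depth
            if (code == goal) return(depth)
            nxt[[length(nxt) + 1L]] <- y
          }
        }
      }
    }
    frontier <- nxt
  }
  Inf
}

## All-pairs variant used by exhaustive sweeps: BFS from one source over the
## capped unit-event graph, returning the distance vector to every profile
## (indexed by the same encoding as above).
cn_distance_bfs_all <- function(p, cap, max_states = 2e6) {
  p <- as_profile(p)
  n <- length(p)
  nstates <- (cap + 1)^n
  if (nstates > max_states) stop("state space too large for BFS oracle",
                                 call. = FALSE)
  enc <- function(x) sum(x * (cap + 1)^(seq_len(n) - 1L)) + 1L
  iv <- unlist(lapply(seq_len(n), function(s) rep(s, n - s + 1L)))
  tv <- unlist(lapply(seq_len(n), function(s) s:n))
  dist <- rep(Inf, nstates)
  dist[enc(p)] <- 0L
  frontier <- list(p)
  depth <- 0L
  while (length(frontier)) {
    depth <- depth + 1L
    nxt <- list()
    for (x in frontier) {
      for (j in seq_along(iv)) {
        for (b in c(-1L, 1L)) {
          idx <- seq.int(iv[j], tv[j])
          live <- idx[x[idx] != 0L]
          if (b > 0L && any(x[live] + b > cap)) next
          y <- x
          y[live] <- pmax(y[live] + b, 0L)
          code <- enc(y)
          if (!is.finite(dist[code])) {
            dist[code] <- depth
            nxt[[length(nxt) + 1L]] <- y
          }
        }
      }
    }
    frontier <- nxt
  }
  dist
}
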