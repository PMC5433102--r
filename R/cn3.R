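## The copy-number triplet (median) problem: given profiles u and v, find a
## profile m and sorted event sequences from m to u and from m to v of
## minimum total cost.

#' Remove positions lost in both profiles
#'
#' At positions where both profiles are zero the median can be fixed at zero
#' with no events, so such positions can be dropped without changing the
#' triplet cost.
#'
#' @param u,v integer profiles of equal length.
#' @return list with reduced `u`, `v` and `keep`, the original indices of
#'   the retained positions (possibly empty).
#' @export
strip_common_zeros <- function(u, v) {
  u <- as_profile(u); v <- as_profile(v)
  if (length(u) != length(v)) stop("profiles differ in length", call. = FALSE)
  keep <- which(u > 0L | v > 0L)
  list(u = u[keep], v = v[keep], keep = keep)
}

#' Solve the copy-number triplet (median) problem
#'
#' Computes the minimum total event cost `Delta(u, v)` of a triple
#' `(m, sigma(m, u), sigma(m, v))` where the event sequences yield `u` and
#' `v` from the median profile `m`. Two dynamic programs are available over
#' per-position budget states `(m, du, au, dv, av)` with budgets bounded by
#' the maximum input copy number `B`:
#'
#' * `"alg1"` fills the complete table and supports traceback of an optimal
#'   median and its two sorted unit-event sequences;
#' * `"alg2"` computes the cost only, using a pruned predecessor enumeration
#'   (amplification budgets are determined by the profile values at nonzero
#'   positions) that lowers the time bound.
#'
#' Ties in the traceback are broken toward the lexicographically smallest
#' state, so results are deterministic.
#'
#' @param u,v integer profiles of equal length.
#' @param algorithm `"alg1"` (table + traceback) or `"alg2"` (cost only).
#' @param e optional cap on the median's entries; by default the median is
#'   only bounded by `B` (an optimal median never needs more).
#' @return an object of class `cn_triplet`: list with `cost`, and for
#'   `"alg1"` also `median` (full-length profile), `events_u` and `events_v`
#'   (sorted unit-event sequences in original coordinates).
#' @examples
#' cn_triplet(c(2, 0), c(0, 2))$cost # 4
#' sol <- cn_triplet(c(2, 1, 2), c(1, 2, 1))
#' apply_events(sol$median, sol$events_u) # reproduces the first profile
#' @export
cn_triplet <- function(u, v, algorithm = c("alg1", "alg2"), e = Inf) {
  algorithm <- match.arg(algorithm)
  u <- as_profile(u); v <- as_profile(v)
  if (length(u) != length(v)) stop("profiles differ in length", call. = FALSE)
  n <- length(u)
  red <- strip_common_zeros(u, v)
  emax <- if (is.finite(e)) as.integer(e) else -1L
  if (length(red$keep) == 0L) {
    out <- list(cost = 0L, median = rep(0L, n),
                events_u = events(), events_v = events(),
                algorithm = algorithm)
    return(structure(out, class = "cn_triplet"))
  }
  if (algorithm == "alg2") {
    cost <- cnp_cn3_fast(red$u, red$v, emax)
    return(structure(list(cost = cost, median = NULL,
                          events_u = NULL, events_v = NULL,
                          algorithm = "alg2"),
                     class = "cn_triplet"))
  }
  raw <- cnp_cn3_full(red$u, red$v, emax)
  median <- rep(0L, n)
  median[red$keep] <- raw$median
  ## coverage tracks live on reduced coordinates; maximal runs are mapped
  ## back through `keep` (interior stripped positions have median 0 and are
  ## frozen, so widened events are no-ops there)
  remap <- function(ev) {
    if (nrow(ev) == 0L) return(ev)
    events(red$keep[ev$s], red$keep[ev$t], ev$b)
  }
  events_u <- remap(tracks_to_events(raw$du, raw$au))
  events_v <- remap(tracks_to_events(raw$dv, raw$av))
  structure(list(cost = raw$cost, median = median,
                 events_u = events_u, events_v = events_v,
                 algorithm = "alg1"),
            class = "cn_triplet")
}

#' @export
print.cn_triplet <- function(x, ...) {
  cat("Copy-number triplet solution (", x$algorithm, "): cost ", x$cost,
      "\n", sep = "")
  if (!is.null(x$median)) {
    cat("median:", paste(x$median, collapse = " "), "\n")
    cat("events to u:", nrow(x$events_u), " events to v:",
        nrow(x$events_v), "\n")
  }
  invisible(x)
}

#' Exhaustive oracle for the triplet problem
#'
#' Independent check of [cn_triplet()]: enumerates every candidate median
#' with entries in `1..B` (0 where both inputs are 0) and sums the two
#' breadth-first-search distances [cn_distance_bfs()]. Feasible for tiny
#' instances only.
#'
#' @param u,v integer profiles of equal length.
#' @param max_medians guard on the number of candidate medians.
#' @return minimum total cost (integer).
#' @export
cn_triplet_brute <- function(u, v, max_medians = 1e5) {
  u <- as_profile(u); v <- as_profile(v)
  if (length(u) != length(v)) stop("profiles differ in length", call. = FALSE)
  red <- strip_common_zeros(u, v)
  if (length(red$keep) == 0L) return(0L)
  B <- max(red$u, red$v)
  nr <- length(red$u)
  if (B^nr > max_medians) stop("median space too large", call. = FALSE)
  grid <- as.matrix(expand.grid(rep(list(seq_len(B)), nr)))
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    m <- as.integer(grid[r, ])
    du <- cn_distance_bfs(m, red$u, cap = max(m, red$u))
    if (!is.finite(du) || du >= best) next
    dv <- cn_distance_bfs(m, red$v, cap = max(m, red$v))
    best <- min(best, du + dv)
  }
  as.integer(best)
}
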