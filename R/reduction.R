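## Hardness gadget: encoding binary-character maximum parsimony (MPP) as a
## copy-number tree instance.
##
## A binary vector b of length n maps to a profile phi(b_1) W phi(b_2) W ...
## W phi(b_n) of length n + (n-1)nk, where phi(1) = 1, phi(0) = 2 and the
## wall W is the length-nk vector 2,1,2,1,... Walls block any event from
## spanning two true positions when e = 2, so tree costs on encoded profiles
## differ from MPP parsimony costs by exactly the fixed wall-initialization
## cost W = (n-1)nk/2.

#' Wall-initialization cost of the parsimony encoding
#'
#' @param n length of the binary vectors; `k` their number.
#' @param k see above.
#' @return `(n - 1) * n * k / 2` (an integer: `(n-1)n` is even).
#' @export
wall_cost <- function(n, k) {
  as.integer((n - 1L) * n * k / 2L)
}

#' Encode one binary vector as a copy-number profile
#'
#' Interleaves the mapped values (`1 -> 1`, `0 -> 2`) with alternating-2,1
#' walls of length `n * k`.
#'
#' @param b binary vector (0/1 entries).
#' @param k number of vectors in the parsimony instance (sets wall length).
#' @return integer profile of length `n + (n - 1) * n * k`.
#' @examples
#' mpp_encode(c(0, 1), k = 2) # 2 2 1 2 1 1
#' @export
mpp_encode <- function(b, k) {
  b <- as.integer(b)
  if (any(!b %in% c(0L, 1L))) stop("entries must be 0 or 1", call. = FALSE)
  n <- length(b)
  phi <- ifelse(b == 1L, 1L, 2L)
  if (n == 1L) return(phi)
  wall <- rep_len(c(2L, 1L), n * k)
  out <- phi[1]
  for (i in 2:n) out <- c(out, wall, phi[i])
  out
}

#' Transform a parsimony instance into a copy-number tree instance
#'
#' Encodes each of the `k` binary vectors with [mpp_encode()] and appends
#' the all-diploid profile `c[k+1]`; the resulting instance has `e = 2`.
#' Minimum tree costs of the two problems then differ by exactly
#' [wall_cost()].
#'
#' @param B binary matrix, one vector per row.
#' @return list with `profiles` ((k+1)-row integer matrix, rownames
#'   `b1..bk, wall_init`) and `e = 2`.
#' @export
mpp_to_cnt <- function(B) {
  B <- as.matrix(B)
  storage.mode(B) <- "integer"
  k <- nrow(B); n <- ncol(B)
  if (k < 2L) stop("need at least two binary vectors", call. = FALSE)
  prof <- t(apply(B, 1, mpp_encode, k = k))
  if (ncol(B) + (ncol(B) - 1L) * ncol(B) * k == 1L) prof <- matrix(prof, k, 1L)
  prof <- rbind(prof, rep(2L, ncol(prof)))
  rownames(prof) <- c(paste0("b", seq_len(k)), "wall_init")
  list(profiles = prof, e = 2L)
}

#' Exhaustive maximum-parsimony solver for binary vectors
#'
#' Minimum summed Hamming distance over all rooted full binary leaf-labeled
#' topologies and internal binary labelings, with the root fixed all-zero.
#' Positions are independent under Hamming distance, so each topology is
#' scored by dynamic programming per position; the enumeration over
#' topologies is exhaustive.
#'
#' @param B binary matrix, one leaf vector per row.
#' @param max_leaves guard on the topology enumeration.
#' @return minimum parsimony cost (integer).
#' @examples
#' mpp_brute(rbind(c(1, 0), c(1, 0))) # 2
#' @export
mpp_brute <- function(B, max_leaves = 6L) {
  B <- as.matrix(B)
  storage.mode(B) <- "integer"
  k <- nrow(B); n <- ncol(B)
  if (k < 2L) stop("need at least two binary vectors", call. = FALSE)
  if (k > max_leaves) stop("too many leaves for brute force", call. = FALSE)
  best <- Inf
  for (topo in enum_topologies(as.list(seq_len(k)))) {
    total <- 0L
    for (s in seq_len(n)) {
      ## cost_below[state + 1]: minimum subtree cost with vertex in state
      below <- function(node) {
        if (!is.list(node)) {
          v <- c(Inf, Inf); v[B[node, s] + 1L] <- 0; return(v)
        }
        l <- below(node[[1]]); r <- below(node[[2]])
        vapply(0:1, function(st) {
          min(l + abs(0:1 - st)) + min(r + abs(0:1 - st))
        }, numeric(1))
      }
      l <- below(topo[[1]]); r <- below(topo[[2]])
      total <- total + min(l + c(0, 1)) + min(r + c(0, 1)) # root state 0
    }
    best <- min(best, total)
  }
  as.integer(best)
}
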