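## The copy-number tree problem as an integer linear program.
##
## A full binary tree with k labeled leaves is a spanning tree of the
## supergraph G on 2k-1 vertices (vertex 1 the root, vertices k..2k-1 the
## leaves) with arcs (i, j) for 1 <= i < k, i < j <= 2k-1. Binary variables
## x select the arcs of the tree; integer variables y in {0..e} label every
## vertex position; per-arc, per-position integer variables a and d carry
## the amplification and deletion cost covering that position, abar and dbar
## count the events *starting* at the position, and w linearizes
## x * (abar + dbar), whose sum is minimized.

#' Supergraph of all full binary trees with k leaves
#'
#' @param k number of leaves, at least 2.
#' @return a list with `n_vertices = 2k - 1`, the leaf indices
#'   (`k..2k-1`; vertex 1 is the root) and an arc table `arcs` with columns
#'   `i`, `j`.
#' @export
cnt_supergraph <- function(k) {
  k <- as.integer(k)
  if (k < 2L) stop("the supergraph needs at least two leaves", call. = FALSE)
  V <- 2L * k - 1L
  i <- rep(seq_len(k - 1L), times = V - seq_len(k - 1L))
  j <- unlist(lapply(seq_len(k - 1L), function(ii) seq.int(ii + 1L, V)))
  list(n_vertices = V, leaves = seq.int(k, V),
       arcs = data.frame(i = i, j = j))
}

## Build the ILP for one instance (no augmentation here). Returns the model
## triplets plus the index maps needed to decode a solution.
cnt_build_model <- function(profiles, e) {
  C <- as.matrix(profiles)
  storage.mode(C) <- "integer"
  k <- nrow(C); n <- ncol(C)
  if (k < 2L) stop("need at least two profiles", call. = FALSE)
  if (any(C > e)) stop("profile entries exceed e", call. = FALSE)
  if (e < 2L) stop("e must be at least 2 (diploid root)", call. = FALSE)
  G <- cnt_supergraph(k)
  V <- G$n_vertices
  arcs <- G$arcs
  A <- nrow(arcs)
  Q <- floor(log2(e)) + 2L   # binary expansion digits q = 0..floor(log2 e)+1

  ## variable layout (1-based column offsets)
  nx <- A; ny <- V * n; nz <- V * n * Q; nyb <- V * n
  sz <- c(x = nx, y = ny, z = nz, yb = nyb,
          a = A * n, d = A * n, ab = A * n, db = A * n, w = A * n)
  off <- cumsum(c(0, sz))[seq_along(sz)]
  names(off) <- names(sz)
  nvar <- sum(sz)
  vx  <- function(arc) off[["x"]] + arc
  vy  <- function(i, s) off[["y"]] + (i - 1L) * n + s
  vz  <- function(i, s, q) off[["z"]] + ((i - 1L) * n + (s - 1L)) * Q + q + 1L
  vyb <- function(i, s) off[["yb"]] + (i - 1L) * n + s
  va  <- function(arc, s) off[["a"]] + (arc - 1L) * n + s
  vd  <- function(arc, s) off[["d"]] + (arc - 1L) * n + s
  vab <- function(arc, s) off[["ab"]] + (arc - 1L) * n + s
  vdb <- function(arc, s) off[["db"]] + (arc - 1L) * n + s
  vw  <- function(arc, s) off[["w"]] + (arc - 1L) * n + s

  lb <- rep(0, nvar); ub <- rep(0, nvar)
  ub[vx(seq_len(A))] <- 1
  ub[off[["y"]] + seq_len(ny)] <- e
  ub[off[["z"]] + seq_len(nz)] <- 1
  ub[off[["yb"]] + seq_len(nyb)] <- 1
  for (nm in c("a", "d", "ab", "db")) ub[off[[nm]] + seq_len(A * n)] <- e
  ub[off[["w"]] + seq_len(A * n)] <- 2 * e
  integrality <- rep(TRUE, nvar)
  integrality[off[["w"]] + seq_len(A * n)] <- FALSE

  ## fixed labels: root diploid, leaves = input profiles
  lb[vy(1L, seq_len(n))] <- 2; ub[vy(1L, seq_len(n))] <- 2
  for (li in seq_len(k)) {
    i <- k - 1L + li
    lb[vy(i, seq_len(n))] <- C[li, ]
    ub[vy(i, seq_len(n))] <- C[li, ]
  }

  ai <- vector("list", 64L); aj <- ai; av <- ai; rl <- ai; ru <- ai
  nb <- 0L; row <- 0L
  add <- function(cols, coefs, lo, hi) {
    nb <<- nb + 1L; row <<- row + 1L
    if (nb > length(ai)) {
      length(ai) <<- 2L * nb; length(aj) <<- 2L * nb; length(av) <<- 2L * nb
      length(rl) <<- 2L * nb; length(ru) <<- 2L * nb
    }
    ai[[nb]] <<- rep.int(row, length(cols)); aj[[nb]] <<- cols
    av[[nb]] <<- coefs; rl[[nb]] <<- lo; ru[[nb]] <<- hi
  }

  inward <- split(seq_len(A), arcs$j)
  outward <- split(seq_len(A), arcs$i)
  for (j in 2:V) add(vx(inward[[as.character(j)]]),          # one parent
                     rep(1, length(inward[[as.character(j)]])), 1, 1)
  for (i in seq_len(k - 1L)) add(vx(outward[[as.character(i)]]), # two children
                                 rep(1, length(outward[[as.character(i)]])), 2, 2)

  qs <- seq.int(0L, Q - 1L)
  for (i in seq_len(V)) {
    for (s in seq_len(n)) {
      add(c(vy(i, s), vz(i, s, qs)), c(1, -(2^qs)), 0, 0)       # y = sum 2^q z
      add(c(vyb(i, s), vz(i, s, qs)), c(1, rep(-1, Q)), -Inf, 0) # yb <= sum z
      for (q in qs) add(c(vyb(i, s), vz(i, s, q)), c(1, -1), 0, Inf) # yb >= z
    }
  }

  for (arc in seq_len(A)) {
    i <- arcs$i[arc]; j <- arcs$j[arc]
    for (s in seq_len(n)) {
      ## nonzero parent & child: y_j + d = y_i + a, d <= y_i - 1
      add(c(vy(j, s), vy(i, s), vd(arc, s), va(arc, s), vyb(i, s), vyb(j, s)),
          c(1, -1, 1, -1, 2 * e, 2 * e), -Inf, 4 * e)
      add(c(vy(j, s), vy(i, s), vd(arc, s), va(arc, s), vyb(i, s), vyb(j, s)),
          c(1, -1, 1, -1, -2 * e, -2 * e), -4 * e, Inf)
      add(c(vd(arc, s), vy(i, s), vyb(i, s), vyb(j, s)),
          c(1, -1, e + 1, e + 1), -Inf, 2 * (e + 1) - 1)
      ## child lost: deletions must reach the parent value
      add(c(vy(i, s), vd(arc, s), vyb(i, s), vyb(j, s)),
          c(1, -1, e, -e), -Inf, e)
      ## a lost position stays lost along selected arcs
      add(c(vx(arc), vyb(i, s), vyb(j, s)), c(-1, 1, -1), -1, Inf)
      ## event starts: abar >= a_s - a_{s-1} (a_0 = 0), same for deletions
      if (s == 1L) {
        add(c(vab(arc, s), va(arc, s)), c(1, -1), 0, Inf)
        add(c(vdb(arc, s), vd(arc, s)), c(1, -1), 0, Inf)
      } else {
        add(c(vab(arc, s), va(arc, s), va(arc, s - 1L)), c(1, -1, 1), 0, Inf)
        add(c(vdb(arc, s), vd(arc, s), vd(arc, s - 1L)), c(1, -1, 1), 0, Inf)
      }
      ## w >= abar + dbar - 2e(1 - x)
      add(c(vw(arc, s), vab(arc, s), vdb(arc, s), vx(arc)),
          c(1, -1, -1, -2 * e), -2 * e, Inf)
    }
  }

  obj <- rep(0, nvar)
  obj[off[["w"]] + seq_len(A * n)] <- 1

  list(obj = obj, lb = lb, ub = ub, integrality = integrality,
       ai = unlist(ai[seq_len(nb)]), aj = unlist(aj[seq_len(nb)]),
       av = unlist(av[seq_len(nb)]),
       rl = unlist(rl[seq_len(nb)]), ru = unlist(ru[seq_len(nb)]),
       k = k, n = n, e = e, V = V, arcs = arcs,
       vy = vy, va = va, vd = vd, vx = vx)
}

## Decode a raw MILP assignment into a cnt_tree; errors if the tracks on a
## selected arc do not reproduce the child profile.
cnt_decode <- function(model, x, ids, aux = FALSE) {
  k <- model$k; n <- model$n; V <- model$V
  arcs <- model$arcs
  sel <- which(round(x[model$vx(seq_len(nrow(arcs)))]) == 1)
  parent <- rep(NA_integer_, V)
  parent[arcs$j[sel]] <- arcs$i[sel]
  prof <- matrix(0L, V, n)
  for (i in seq_len(V)) prof[i, ] <- as.integer(round(x[model$vy(i, seq_len(n))]))
  edge_events <- vector("list", V)
  for (arc in sel) {
    j <- arcs$j[arc]
    dtr <- as.integer(round(x[model$vd(arc, seq_len(n))]))
    atr <- as.integer(round(x[model$va(arc, seq_len(n))]))
    ev <- tracks_to_events(dtr, atr)
    got <- apply_events(prof[arcs$i[arc], ], ev)
    if (!identical(got, prof[j, ])) {
      bad <- which(got != prof[j, ])[1]
      stop("decoding error on arc (", arcs$i[arc], ",", j, ") at position ",
           bad, ": tracks do not reproduce the child profile", call. = FALSE)
    }
    edge_events[[j]] <- ev
  }
  leaf_ids <- ids
  labs <- seq.int(k, V)
  names(labs) <- leaf_ids
  aux_leaf <- if (aux) labs[[length(labs)]] else NA_integer_
  if (aux) labs <- labs[-length(labs)]
  cnt_tree(prof, parent, edge_events, labs, model$e, aux_leaf = aux_leaf)
}

#' Solve the copy-number tree problem
#'
#' Finds a minimum-cost copy-number tree for `k` observed profiles: a rooted
#' full binary tree with the profiles at its leaves, an all-2's (diploid)
#' root, every vertex entry at most `e`, and minimum total event cost over
#' the edges. The search is an integer linear program over the supergraph of
#' all full binary topologies, solved by the HiGHS backend ([milp_python()]).
#'
#' Because a full binary tree cannot have a root of out-degree one, a second
#' instance augmented with an all-diploid profile `c[k+1]` is solved as well
#' (unless `augment = FALSE`) and the cheaper of the two solutions is
#' returned; the auxiliary leaf, when present, is retained in the tree but
#' flagged so that topology comparisons can drop it.
#'
#' @param profiles integer matrix of observed profiles, one row per sample
#'   (row names are used as leaf labels), or the result of [read_profiles()].
#' @param e maximum copy number allowed at any vertex; defaults to the
#'   largest input entry (at least 2).
#' @param time_limit per-solve time limit in seconds.
#' @param augment also solve the instance augmented with a diploid leaf.
#' @param verbose print backend output.
#' @return a list of class `cnt_solution`: `tree` (a [cnt_tree()]), `cost`,
#'   `status` (`"optimal"` when both solves proved optimality), `bound`
#'   (best lower bound) and `objective` per solved variant.
#' @examples
#' \donttest{
#' prof <- rbind(s1 = c(2L, 2L), s2 = c(3L, 3L))
#' sol <- cnt_solve(prof, e = 3)
#' sol$cost # 1: a single amplification covering both positions
#' }
#' @export
cnt_solve <- function(profiles, e = NULL, time_limit = 600, augment = TRUE,
                      verbose = FALSE) {
  C <- as.matrix(profiles)
  storage.mode(C) <- "integer"
  if (is.null(rownames(C))) rownames(C) <- paste0("s", seq_len(nrow(C)))
  if (is.null(e)) e <- max(2L, max(C))
  e <- as.integer(e)

  solve_one <- function(mat, aux) {
    model <- cnt_build_model(mat, e)
    res <- milp_solve(model$obj, model$lb, model$ub, model$integrality,
                      model$ai, model$aj, model$av, model$rl, model$ru,
                      time_limit = time_limit, verbose = verbose)
    if (is.null(res$x) || res$status %in% c("infeasible", "unbounded",
                                            "unknown")) {
      stop("CNT solve failed with status ", res$status, call. = FALSE)
    }
    tree <- cnt_decode(model, res$x, rownames(mat), aux = aux)
    list(tree = tree, cost = tree_cost(tree), status = res$status,
         bound = res$bound)
  }

  plain <- solve_one(C, aux = FALSE)
  picked <- plain
  aug <- NULL
  if (augment) {
    Ca <- rbind(C, matrix(2L, 1L, ncol(C)))
    rownames(Ca) <- c(rownames(C), ".diploid")
    aug <- solve_one(Ca, aux = TRUE)
    if (aug$cost < plain$cost) picked <- aug
  }
  status <- if (plain$status == "optimal" &&
                (is.null(aug) || aug$status == "optimal")) "optimal"
            else "feasible"
  viol <- validate_tree(picked$tree, C, e)
  if (length(viol)) {
    stop("decoded tree failed validation: ", paste(viol, collapse = "; "),
         call. = FALSE)
  }
  structure(list(tree = picked$tree, cost = picked$cost, status = status,
                 bound = if (is.null(aug)) plain$bound
                         else min(plain$bound, aug$bound),
                 objective = c(plain = plain$cost,
                               augmented = if (is.null(aug)) NA_real_
                                           else aug$cost),
                 e = e),
            class = "cnt_solution")
}

#' @export
print.cnt_solution <- function(x, ...) {
  cat("Copy-number tree solution: cost", x$cost, "(", x$status, ")\n")
  print(x$tree)
  invisible(x)
}

## -------------------------------------------------------------------------
## Exhaustive oracle

## All rooted full binary leaf-labeled topologies on the given labels, as
## nested lists. Each unordered tree is produced exactly once (the first
## label always stays in the first child's side).
enum_topologies <- function(labels) {
  if (length(labels) == 1L) return(list(labels[[1]]))
  first <- labels[[1]]; rest <- labels[-1]
  out <- list()
  for (size in 0:(length(rest) - 1L)) {
    combs <- if (size == 0L) list(integer(0))
             else utils::combn(seq_along(rest), size, simplify = FALSE)
    for (cb in combs) {
      left <- c(list(first), rest[cb])
      right <- rest[setdiff(seq_along(rest), cb)]
      for (lt in enum_topologies(left)) {
        for (rt in enum_topologies(right)) {
          out[[length(out) + 1L]] <- list(lt, rt)
        }
      }
    }
  }
  out
}

#' Exhaustive small-scale solver for the copy-number tree problem
#'
#' Independent oracle for [cnt_solve()]: enumerates every rooted full binary
#' leaf-labeled topology and, by dynamic programming over each topology,
#' every assignment of internal profiles with entries in `0..e` (root fixed
#' diploid), scoring edges with the pairwise distance [cn_distance()]. Both
#' the plain instance and the diploid-augmented instance are scored and the
#' minimum returned. Feasible only for tiny instances.
#'
#' @param profiles integer matrix of leaf profiles (rows).
#' @param e maximum copy number; defaults to the largest entry (at least 2).
#' @param augment also score the diploid-augmented instance.
#' @param max_leaves,max_profiles guards on the enumeration size.
#' @return the minimum tree cost (integer).
#' @export
cnt_brute <- function(profiles, e = NULL, augment = TRUE,
                      max_leaves = 5L, max_profiles = 512L) {
  C <- as.matrix(profiles)
  storage.mode(C) <- "integer"
  if (is.null(e)) e <- max(2L, max(C))
  n <- ncol(C)
  P <- (e + 1L)^n
  if (P > max_profiles) stop("profile space too large for brute force",
                             call. = FALSE)
  ## all profiles with entries 0..e; row r of allp has code(allp[r, ]) == r
  allp <- as.matrix(expand.grid(rep(list(0:e), n)))
  code <- function(p) sum(p * (e + 1L)^(seq_len(n) - 1L)) + 1L
  ## pairwise distance lookup (parent row -> child column)
  D <- matrix(Inf, P, P)
  for (a in seq_len(P)) {
    pa <- as.integer(allp[a, ])
    for (b in seq_len(P)) {
      D[a, b] <- cn_distance(pa, as.integer(allp[b, ]))
    }
  }
  root_code <- code(rep(2L, n))

  score <- function(mat) {
    k <- nrow(mat)
    if (k > max_leaves) stop("too many leaves for brute force", call. = FALSE)
    leafcode <- apply(mat, 1, code)
    best <- Inf
    for (topo in enum_topologies(as.list(seq_len(k)))) {
      ## cost_below[[vertex]]: vector over profile codes
      below <- function(node) {
        if (!is.list(node)) {
          v <- rep(Inf, P); v[leafcode[node]] <- 0; return(v)
        }
        l <- below(node[[1]]); r <- below(node[[2]])
        ## min over child codes of D[p, c] + below[c], per parent code p
        lmin <- apply(D + rep(l, each = P), 1, min)
        rmin <- apply(D + rep(r, each = P), 1, min)
        lmin + rmin
      }
      if (!is.list(topo)) next
      l <- below(topo[[1]]); r <- below(topo[[2]])
      cost <- min(D[root_code, ] + l) + min(D[root_code, ] + r)
      ## root is its own vertex: children chosen freely, root fixed diploid
      best <- min(best, cost)
    }
    best
  }

  best <- score(C)
  if (augment) best <- min(best, score(rbind(C, rep(2L, n))))
  as.integer(best)
}
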