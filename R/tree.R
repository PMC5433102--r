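## Copy-number trees: rooted full binary trees with profile-labeled vertices
## and event-sequence-labeled edges.

#' Construct a copy-number tree
#'
#' A copy-number tree is a rooted full binary tree (every vertex has 0 or 2
#' children) whose vertices carry copy-number profiles, whose root is diploid
#' (all 2's), and whose edges carry ordered event sequences transforming the
#' parent profile into the child profile.
#'
#' @param profiles integer matrix, one row per vertex (row 1 is the root),
#'   one column per position.
#' @param parent integer vector: `parent[i]` is the parent vertex of vertex
#'   `i`, `NA` for the root.
#' @param edge_events list indexed by child vertex: `edge_events[[i]]` is the
#'   event sequence on the edge into vertex `i` (`NULL` for the root).
#' @param leaf_labels named integer vector mapping sample identifiers to leaf
#'   vertex indices, in input-profile order.
#' @param e maximum copy number allowed at any vertex.
#' @param aux_leaf index of an auxiliary all-diploid leaf added when solving
#'   the root-degree-one variant, or `NA` if none.
#' @return an object of class `cnt_tree`.
#' @seealso [tree_cost()], [validate_tree()], [topology_newick()]
#' @export
cnt_tree <- function(profiles, parent, edge_events, leaf_labels, e,
                     aux_leaf = NA_integer_) {
  profiles <- as.matrix(profiles)
  storage.mode(profiles) <- "integer"
  nv <- nrow(profiles)
  stopifnot(length(parent) == nv, length(edge_events) == nv)
  children <- vector("list", nv)
  for (i in seq_len(nv)) {
    if (!is.na(parent[i])) {
      children[[parent[i]]] <- c(children[[parent[i]]], i)
    }
  }
  structure(list(
    profiles = profiles,
    parent = as.integer(parent),
    children = children,
    edge_events = edge_events,
    root = which(is.na(parent))[1],
    leaf_labels = leaf_labels,
    e = as.integer(e),
    aux_leaf = as.integer(aux_leaf)
  ), class = "cnt_tree")
}

#' @export
print.cnt_tree <- function(x, ...) {
  k <- length(x$leaf_labels)
  cat("Copy-number tree:", nrow(x$profiles), "vertices,", k, "leaves,",
      ncol(x$profiles), "positions, cost", tree_cost(x), "\n")
  if (!is.na(x$aux_leaf)) cat("  (includes one auxiliary diploid leaf)\n")
  invisible(x)
}

#' Total event cost of a copy-number tree
#'
#' The sum over edges of the edge's event-sequence cost.
#'
#' @param tree a [cnt_tree()].
#' @return non-negative integer.
#' @export
tree_cost <- function(tree) {
  sum(vapply(tree$edge_events, event_cost, integer(1)))
}

#' Check a copy-number tree against its problem instance
#'
#' Verifies, and reports as character messages rather than raising, every
#' condition a valid solution must satisfy: full binary shape, diploid root,
#' leaves labeled by the input profiles in order, all entries at most `e`,
#' and each edge's event sequence transforming the parent profile into the
#' child profile.
#'
#' @param tree a [cnt_tree()].
#' @param profiles the instance's leaf profile matrix (one row per sample).
#' @param e the instance's maximum copy number.
#' @return character vector of violations; `character(0)` if valid.
#' @export
validate_tree <- function(tree, profiles = NULL, e = tree$e) {
  bad <- character(0)
  nv <- nrow(tree$profiles)
  deg <- vapply(tree$children, length, integer(1))
  if (!all(deg %in% c(0L, 2L))) {
    bad <- c(bad, paste0("not a full binary tree: vertices with out-degree ",
                         paste(sort(unique(deg[!deg %in% c(0L, 2L)])),
                               collapse = ",")))
  }
  if (sum(is.na(tree$parent)) != 1L) {
    bad <- c(bad, "tree must have exactly one root")
  }
  if (!all(tree$profiles[tree$root, ] == 2L)) {
    bad <- c(bad, "root not diploid")
  }
  if (!is.null(e) && is.finite(e) && any(tree$profiles > e)) {
    bad <- c(bad, paste0("profile entries exceed e = ", e))
  }
  if (!is.null(profiles)) {
    profiles <- as.matrix(profiles)
    labs <- tree$leaf_labels
    if (length(labs) != nrow(profiles)) {
      bad <- c(bad, "leaf count differs from instance profile count")
    } else {
      for (i in seq_along(labs)) {
        if (!identical(as.integer(tree$profiles[labs[i], ]),
                       as.integer(profiles[i, ]))) {
          bad <- c(bad, paste0("leaf ", names(labs)[i],
                               " profile differs from input row ", i))
        }
      }
    }
  }
  for (v in seq_len(nv)) {
    if (is.na(tree$parent[v])) next
    got <- apply_events(tree$profiles[tree$parent[v], ], tree$edge_events[[v]])
    if (!identical(got, as.integer(tree$profiles[v, ]))) {
      bad <- c(bad, paste0("edge into vertex ", v,
                           " inconsistent: events do not yield child profile"))
    }
  }
  bad
}

## Leaf label set below each vertex (list indexed by vertex).
descendant_leaves <- function(tree, drop_aux = TRUE) {
  nv <- nrow(tree$profiles)
  labs <- character(nv)
  leaf_of <- rep(NA_character_, nv)
  leaf_of[tree$leaf_labels] <- names(tree$leaf_labels)
  if (drop_aux && !is.na(tree$aux_leaf)) leaf_of[tree$aux_leaf] <- NA_character_
  below <- vector("list", nv)
  order <- postorder(tree)
  for (v in order) {
    kids <- tree$children[[v]]
    if (length(kids) == 0L) {
      below[[v]] <- if (is.na(leaf_of[v])) character(0) else leaf_of[v]
    } else {
      below[[v]] <- sort(unique(unlist(below[kids])))
    }
  }
  below
}

postorder <- function(tree) {
  nv <- nrow(tree$profiles)
  out <- integer(0)
  stack <- tree$root
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    out <- c(v, out)
    stack <- c(stack, tree$children[[v]])
  }
  out
}

#' Leaf topology of a copy-number tree in Newick format
#'
#' Emits the rooted leaf-labeled topology (no branch lengths, internal nodes
#' unlabeled), suppressing degree-one vertices left after dropping the
#' auxiliary diploid leaf if one is present.
#'
#' @param tree a [cnt_tree()].
#' @param drop_aux drop the auxiliary all-diploid leaf before writing.
#' @return a Newick string terminated by `;`.
#' @export
topology_newick <- function(tree, drop_aux = TRUE) {
  leaf_of <- rep(NA_character_, nrow(tree$profiles))
  leaf_of[tree$leaf_labels] <- names(tree$leaf_labels)
  skip <- if (drop_aux && !is.na(tree$aux_leaf)) tree$aux_leaf else -1L
  rec <- function(v) {
    kids <- setdiff(tree$children[[v]], skip)
    if (length(kids) == 0L) {
      if (v == skip || is.na(leaf_of[v])) return(NULL)
      return(leaf_of[v])
    }
    parts <- Filter(Negate(is.null), lapply(kids, rec))
    if (length(parts) == 0L) return(NULL)
    if (length(parts) == 1L) return(parts[[1]]) # suppress degree-1 vertex
    paste0("(", paste(unlist(parts), collapse = ","), ")")
  }
  paste0(rec(tree$root), ";")
}
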