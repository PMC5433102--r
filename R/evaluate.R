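## Robinson-Foulds comparison of leaf-labeled tree topologies.

## Coerce a tree argument to a set of leaf labels per internal vertex.
## Accepts a cnt_tree, an ape "phylo" object, or a Newick string.
topology_clades <- function(x) {
  if (inherits(x, "cnt_tree")) {
    below <- descendant_leaves(x, drop_aux = TRUE)
    internal <- which(vapply(x$children, length, integer(1)) > 0L)
    sets <- below[internal]
  } else {
    if (is.character(x)) x <- ape::read.tree(text = x)
    if (!inherits(x, "phylo")) {
      stop("expected a cnt_tree, phylo or Newick string", call. = FALSE)
    }
    pp <- ape::prop.part(x)
    sets <- lapply(pp, function(ix) sort(attr(pp, "labels")[ix]))
  }
  all_leaves <- sort(unique(unlist(sets)))
  keep <- vapply(sets, function(s) length(s) >= 2L &&
                   length(s) < length(all_leaves), logical(1))
  list(clades = unique(vapply(sets[keep], paste, character(1),
                              collapse = "\r")),
       leaves = all_leaves)
}

#' Nontrivial rooted clades of a leaf-labeled topology
#'
#' The leaf-label sets of the internal vertices, excluding the root's full
#' set and singletons.
#'
#' @param x a [cnt_tree()], an `ape::phylo`, or a Newick string.
#' @return list of character vectors (sorted leaf labels).
#' @examples
#' nontrivial_clades("((a,b),(c,d));") # {a,b} and {c,d}
#' @export
nontrivial_clades <- function(x) {
  cl <- topology_clades(x)
  lapply(cl$clades, function(s) strsplit(s, "\r", fixed = TRUE)[[1]])
}

#' Normalized Robinson-Foulds distance between two topologies
#'
#' Compares leaf-labeled tree topologies by the symmetric difference of
#' their nontrivial clade sets, normalized by the total number of
#' nontrivial clades of both trees, giving a value in `[0, 1]`: 0 means
#' identical rooted topologies, 1 means no shared clade. Trees are compared
#' as rooted by default (copy-number trees are rooted at the diploid
#' ancestor); `rooted = FALSE` compares unrooted bipartitions instead
#' (sides of size `>= 2` on both ends). Auxiliary diploid leaves of a
#' [cnt_tree()] are dropped before comparison.
#'
#' @param t1,t2 topologies: [cnt_tree()], `ape::phylo`, or Newick strings;
#'   they must carry identical leaf label sets.
#' @param rooted compare rooted clades (default) or unrooted splits.
#' @return numeric in `[0, 1]` (0 when both clade sets are empty).
#' @examples
#' normalized_rf("((a,b),(c,d));", "((a,c),(b,d));") # 1
#' normalized_rf("((a,b),(c,d));", "(a,(b,(c,d)));") # 0.5
#' @export
normalized_rf <- function(t1, t2, rooted = TRUE) {
  c1 <- topology_clades(t1); c2 <- topology_clades(t2)
  if (!identical(c1$leaves, c2$leaves)) {
    stop("trees carry different leaf label sets", call. = FALSE)
  }
  s1 <- c1$clades; s2 <- c2$clades
  if (!rooted) {
    canon <- function(clades, leaves) {
      k <- length(leaves)
      out <- character(0)
      for (s in clades) {
        side <- strsplit(s, "\r", fixed = TRUE)[[1]]
        if (length(side) < 2L || length(side) > k - 2L) next
        if (leaves[1] %in% side) side <- setdiff(leaves, side)
        out <- c(out, paste(sort(side), collapse = "\r"))
      }
      unique(out)
    }
    s1 <- canon(s1, c1$leaves); s2 <- canon(s2, c2$leaves)
  }
  denom <- length(s1) + length(s2)
  if (denom == 0L) return(0)
  (length(setdiff(s1, s2)) + length(setdiff(s2, s1))) / denom
}
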