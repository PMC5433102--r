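## Tab-separated profile tables and tree bundles.

#' Read a profile table
#'
#' Plain tab-separated text: one profile per row, first column a unique
#' sample identifier, remaining columns non-negative integer copy numbers.
#' Lines starting with `#` and blank lines are ignored.
#'
#' @param path file path.
#' @return integer matrix with sample identifiers as rownames.
#' @export
read_profiles <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (length(keep) == 0L) stop("no profile rows in ", path, call. = FALSE)
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  widths <- lengths(parts)
  if (length(unique(widths)) != 1L) {
    bad <- keep[which(widths != widths[1])[1]]
    stop("ragged row at line ", bad, " of ", path, call. = FALSE)
  }
  if (widths[1] < 2L) stop("rows need an identifier and at least one value",
                           call. = FALSE)
  ids <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    bad <- keep[which(duplicated(ids))[1]]
    stop("duplicate identifier at line ", bad, " of ", path, call. = FALSE)
  }
  vals <- lapply(seq_along(parts), function(r) {
    v <- suppressWarnings(as.numeric(parts[[r]][-1]))
    if (any(is.na(v)) || any(v < 0) || any(v != floor(v))) {
      stop("non-integer or negative value at line ", keep[r], " of ", path,
           call. = FALSE)
    }
    as.integer(v)
  })
  out <- do.call(rbind, vals)
  rownames(out) <- ids
  out
}

#' Write a profile table
#'
#' Inverse of [read_profiles()].
#'
#' @param profiles integer matrix with rownames.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  profiles <- as.matrix(profiles)
  if (is.null(rownames(profiles))) {
    rownames(profiles) <- paste0("s", seq_len(nrow(profiles)))
  }
  lines <- vapply(seq_len(nrow(profiles)), function(r) {
    paste(c(rownames(profiles)[r], profiles[r, ]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

## Vertex display names: sample ids for leaves, v<i> otherwise.
vertex_names <- function(tree) {
  nm <- paste0("v", seq_len(nrow(tree$profiles)))
  nm[tree$leaf_labels] <- names(tree$leaf_labels)
  if (!is.na(tree$aux_leaf)) nm[tree$aux_leaf] <- ".diploid"
  nm
}

#' Write a copy-number tree as a bundle of plain-text files
#'
#' Writes `<prefix>.edges.tsv` (parent, child, cost), `<prefix>.profiles.tsv`
#' (vertex, values), `<prefix>.events.tsv` (parent, child, order, s, t, b)
#' and `<prefix>.nwk` (leaf topology in Newick).
#'
#' @param tree a [cnt_tree()].
#' @param prefix output path prefix.
#' @return character vector of the written paths, invisibly.
#' @export
write_tree_bundle <- function(tree, prefix) {
  nm <- vertex_names(tree)
  nv <- nrow(tree$profiles)
  epath <- paste0(prefix, ".edges.tsv")
  ppath <- paste0(prefix, ".profiles.tsv")
  vpath <- paste0(prefix, ".events.tsv")
  npath <- paste0(prefix, ".nwk")
  erows <- c("#parent\tchild\tcost")
  vrows <- c("#parent\tchild\torder\ts\tt\tb")
  for (v in seq_len(nv)) {
    p <- tree$parent[v]
    if (is.na(p)) next
    ev <- tree$edge_events[[v]]
    erows <- c(erows, paste(nm[p], nm[v], event_cost(ev), sep = "\t"))
    if (!is.null(ev) && nrow(ev)) {
      vrows <- c(vrows, paste(nm[p], nm[v], seq_len(nrow(ev)),
                              ev$s, ev$t, ev$b, sep = "\t"))
    }
  }
  writeLines(erows, epath)
  writeLines(vrows, vpath)
  prof <- tree$profiles
  rownames(prof) <- nm
  write_profiles(prof, ppath)
  writeLines(topology_newick(tree), npath)
  invisible(c(epath, ppath, vpath, npath))
}
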