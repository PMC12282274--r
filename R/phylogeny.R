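#' Distance matrix from pairwise identities
#'
#' Distance is `100 - identity_pct`, a p-distance-like quantity on the same
#' scale as the grouping thresholds; no evolutionary-model correction is
#' applied because raw identity is the quantity the classification
#' thresholds act on.
#'
#' @param m An `identity_matrix`.
#' @return A symmetric numeric matrix with zero diagonal and ids as dimnames.
#' @export
identity_to_distance <- function(m) {
  stopifnot(inherits(m, "identity_matrix"))
  d <- 100 - m$identity
  diag(d) <- 0
  d
}

#' Neighbor-joining tree of head domains
#'
#' Canonical neighbor-joining on a symmetric distance matrix. Negative
#' estimated branch lengths (possible on non-additive inputs) are clamped to
#' zero with a warning. The two-taxon case is the closed form: one edge
#' split equally. On additive distances the true tree is recovered exactly.
#'
#' @param d A symmetric nonnegative matrix with zero diagonal and dimnames,
#'   or the output of [identity_to_distance()].
#' @return An unrooted `phylo` tree (ape).
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 2L) abort("Need at least two taxa to build a tree.")
  if (is.null(rownames(d))) abort("Distance matrix must carry ids as dimnames.")
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8))) {
    abort("Distance matrix must be symmetric.")
  }
  ids <- rownames(d)
  if (nrow(d) == 2L) {
    tr <- ape::read.tree(text = sprintf(
      "(%s:%.10g,%s:%.10g);",
      quote_newick(ids[1]), d[1, 2] / 2, quote_newick(ids[2]), d[1, 2] / 2
    ))
    return(tr)
  }
  tr <- ape::nj(stats::as.dist(d))
  if (any(tr$edge.length < 0)) {
    warn(paste0(
      sum(tr$edge.length < 0),
      " negative branch length(s) clamped to 0."
    ))
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr
}

quote_newick <- function(id) {
  reserved <- stringr::str_detect(id, "[\\s,;:()\\[\\]']")
  ifelse(reserved, paste0("'", gsub("'", "''", id), "'"), id)
}

#' Serialize a tree as Newick text
#'
#' Branch lengths are written in 6-decimal fixed format; labels containing
#' Newick-reserved characters are quoted. Re-parsing yields an isomorphic
#' tree.
#'
#' @param tree A `phylo` object.
#' @param path Optional file path; when given the Newick string is also
#'   written there.
#' @return The Newick string (terminated by `;`), invisibly when `path` is
#'   given.
#' @export
to_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  fmt_node <- function(node, edge_row) {
    len <- if (is.null(edge_row)) NULL else tree$edge.length[edge_row]
    body <- if (node <= ntip) {
      quote_newick(tree$tip.label[node])
    } else {
      rows <- kids[[as.character(node)]]
      paste0(
        "(",
        paste(purrr::map_chr(rows, ~ fmt_node(tree$edge[.x, 2], .x)),
              collapse = ","),
        ")"
      )
    }
    if (is.null(len)) body else sprintf("%s:%.6f", body, len)
  }
  txt <- paste0(fmt_node(root, NULL), ";")
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Leaf-to-leaf path lengths of a tree
#'
#' @param tree A `phylo` object.
#' @return Symmetric matrix of patristic distances between leaves.
#' @export
tree_path_lengths <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ape::cophenetic.phylo(tree)
}
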