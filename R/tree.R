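#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining: repeatedly join the pair minimising the
#' Q-criterion `Q_ij = (m - 2) d_ij - r_i - r_j`, compute the two branch
#' lengths from the rate-corrected formulas, collapse the pair, and stop at
#' three nodes, which join at the final internal vertex. Ties in Q are
#' broken by the lowest index pair in current matrix order (original label
#' order first, created nodes appended). Negative branch lengths are handled
#' by the Kuhner-Felsenstein convention: set to zero with the deficit
#' transferred to the sister branch so the pairwise path length is
#' preserved; the terminal three-way join clamps at zero.
#'
#' For an additive (tree-like) matrix the input tree is recovered exactly.
#'
#' @param m Symmetric distance matrix with labels, at least 3 taxa, finite
#'   entries.
#' @return An unrooted binary tree of class `phylo` (ape).
#' @examples
#' d <- matrix(c(0, 5, 7, 8, 5, 0, 8, 9, 7, 8, 0, 9, 8, 9, 9, 0), 4, 4,
#'             dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
#' nj_tree(d)
#' @export
nj_tree <- function(m) {
  validate_distance_matrix(m, tol = 1e-8)
  n <- nrow(m)
  abort_if(n < 3, "neighbor joining needs at least 3 taxa")
  labels <- rownames(m)

  # registry of nodes: leaves 1..n, internal nodes appended as created
  kids <- vector("list", n)         # child registry ids per internal node
  lens <- vector("list", n)         # branch length to each child
  active <- seq_len(n)              # registry ids of current matrix rows
  D <- unname(m)

  while (length(active) > 3) {
    mm <- length(active)
    r <- rowSums(D)
    Q <- (mm - 2) * D - outer(r, r, `+`)
    qmin <- min(Q[upper.tri(Q)])
    cand <- which(Q <= qmin + 0 & upper.tri(Q), arr.ind = TRUE)
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    i <- cand[1, 1]; j <- cand[1, 2]
    dij <- D[i, j]
    vi <- 0.5 * dij + (r[i] - r[j]) / (2 * (mm - 2))
    vj <- dij - vi
    if (vi < 0) { vj <- vj + vi; vi <- 0 }
    if (vj < 0) { vi <- vi + vj; vj <- 0 }
    z <- length(kids) + 1L
    kids[[z]] <- c(active[i], active[j])
    lens[[z]] <- c(vi, vj)
    dz <- 0.5 * (D[i, ] + D[j, ] - dij)
    D <- rbind(cbind(D, dz), c(dz, 0))
    keep <- setdiff(seq_len(mm + 1), c(i, j))
    D <- D[keep, keep, drop = FALSE]
    active <- c(active[-c(i, j)], z)
  }

  dxy <- D[1, 2]; dxz <- D[1, 3]; dyz <- D[2, 3]
  root <- length(kids) + 1L
  kids[[root]] <- active
  lens[[root]] <- pmax(c((dxy + dxz - dyz) / 2,
                         (dxy + dyz - dxz) / 2,
                         (dxz + dyz - dxy) / 2), 0)
  registry_to_phylo(kids, lens, root, n, labels)
}

#' Serialise a tree to Newick text
#'
#' Writes branch lengths at 6-decimal precision with deterministic child
#' ordering: at every internal node, children are sorted by their smallest
#' descendant tip label. The output ends with `";"` and parses back (e.g.
#' with `ape::read.tree`) to the same topology and lengths.
#'
#' @param tree A `phylo` object (e.g. from [nj_tree()]).
#' @param digits Decimal places for branch lengths (default 6).
#' @return A single Newick string.
#' @export
to_newick <- function(tree, digits = 6) {
  stopifnot(inherits(tree, "phylo"))
  n <- length(tree$tip.label)
  root <- n + 1L
  fmt <- paste0("%s:%.", digits, "f")
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  min_label <- function(node) {
    if (node <= n) return(tree$tip.label[node])
    min(vapply(tree$edge[children[[as.character(node)]], 2], min_label, ""))
  }
  serialise <- function(node) {
    if (node <= n) return(tree$tip.label[node])
    eids <- children[[as.character(node)]]
    ord <- order(vapply(tree$edge[eids, 2], min_label, ""), method = "radix")
    parts <- vapply(eids[ord], function(e) {
      sprintf(fmt, serialise(tree$edge[e, 2]), tree$edge.length[e])
    }, "")
    paste0("(", paste(parts, collapse = ","), ")")
  }
  paste0(serialise(root), ";")
}

#' Write a tree as a Newick file
#'
#' @inheritParams to_newick
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path, digits = 6) {
  writeLines(to_newick(tree, digits = digits), path)
  invisible(path)
}

# convert the join registry into an ape phylo object; tips keep the original
# label order, internal nodes are numbered in preorder from the root
registry_to_phylo <- function(kids, lens, root, n, labels) {
  n_internal <- length(kids) - n
  new_id <- integer(length(kids))
  new_id[seq_len(n)] <- seq_len(n)
  counter <- n
  edges <- matrix(0L, 0, 2)
  elens <- numeric(0)
  assign_ids <- function(node) {
    counter <<- counter + 1L
    new_id[node] <<- counter
    for (idx in seq_along(kids[[node]])) {
      child <- kids[[node]][idx]
      if (child > n) assign_ids(child)
    }
  }
  assign_ids(root)
  emit <- function(node) {
    for (idx in seq_along(kids[[node]])) {
      child <- kids[[node]][idx]
      edges <<- rbind(edges, c(new_id[node], new_id[child]))
      elens <<- c(elens, lens[[node]][idx])
      if (child > n) emit(child)
    }
  }
  emit(root)
  tree <- list(edge = edges, edge.length = elens, Nnode = n_internal,
               tip.label = labels)
  class(tree) <- "phylo"
  attr(tree, "order") <- "cladewise"  # edges were emitted in preorder
  tree
}
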