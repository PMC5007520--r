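#' Neighbor-joining tree
#'
#' The standard Saitou-Nei agglomeration: at each step the pair minimizing
#' `Q(i,j) = (n-2) d(i,j) - r(i) - r(j)` is joined (ties broken by the
#' lexicographically smallest pair, so runs are reproducible), branch
#' lengths follow the usual rate-corrected split, and a negative branch
#' length is clamped to zero with the deficit moved to its sister edge.
#' The final three clusters are joined at an unrooted trifurcation.
#'
#' @param distances symmetric distance matrix with row/col names; >= 3
#'   taxa for a resolved tree (2 taxa return a degenerate tree with a
#'   warning).
#' @return An [ape::as.phylo] `"phylo"` object (unrooted).
#' @export
nj_tree <- function(distances) {
  D <- as.matrix(distances)
  if (is.null(rownames(D))) rownames(D) <- colnames(D) <-
      paste0("t", seq_len(nrow(D)))
  labels <- rownames(D)
  n <- nrow(D)
  if (n < 2L) stop("need >= 2 taxa")
  if (any(abs(D - t(D)) > 1e-8)) stop("distance matrix not symmetric")
  if (n == 2L) {
    warning("only 2 taxa: degenerate tree")
    tr <- list(edge = matrix(c(3L, 1L, 3L, 2L), 2, 2, byrow = TRUE),
               edge.length = c(D[1, 2] / 2, D[1, 2] / 2),
               tip.label = labels, Nnode = 1L)
    class(tr) <- "phylo"
    return(tr)
  }

  # active clusters: node id, with leaves 1..n; internal nodes appended
  active <- seq_len(n)
  node_id <- seq_len(n)
  next_node <- n + 1L
  edges <- NULL; elens <- NULL
  Dm <- D
  while (length(active) > 3L) {
    m <- length(active)
    r <- rowSums(Dm)
    Q <- (m - 2) * Dm - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin < 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    pick <- cand[order(cand[, 1], cand[, 2])[1L], ]
    i <- pick[1L]; j <- pick[2L]
    dij <- Dm[i, j]
    li <- dij / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- dij - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    li <- max(li, 0); lj <- max(lj, 0)
    u <- next_node; next_node <- next_node + 1L
    edges <- rbind(edges, c(u, node_id[i]), c(u, node_id[j]))
    elens <- c(elens, li, lj)
    dnew <- (Dm[i, ] + Dm[j, ] - dij) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    Dm <- rbind(cbind(Dm[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    node_id <- c(node_id[keep], u)
    active <- c(active[keep], u)
  }
  if (length(active) == 3L) {
    d12 <- Dm[1, 2]; d13 <- Dm[1, 3]; d23 <- Dm[2, 3]
    l1 <- (d12 + d13 - d23) / 2
    l2 <- (d12 + d23 - d13) / 2
    l3 <- (d13 + d23 - d12) / 2
    u <- next_node; next_node <- next_node + 1L
    edges <- rbind(edges, c(u, node_id[1]), c(u, node_id[2]),
                   c(u, node_id[3]))
    elens <- c(elens, pmax(c(l1, l2, l3), 0))
  } else {  # exactly 2 active clusters (n == 3 never reaches here)
    u <- next_node; next_node <- next_node + 1L
    edges <- rbind(edges, c(u, node_id[1]), c(u, node_id[2]))
    elens <- c(elens, Dm[1, 2] / 2, Dm[1, 2] / 2)
  }
  build_phylo(edges, elens, labels)
}

# internal: assemble a valid "phylo" from an edge list; internal nodes
# renumbered in preorder from the root (the node that is never a child)
build_phylo <- function(edges, elens, labels) {
  n <- length(labels)
  all_parents <- unique(edges[, 1])
  root_old <- setdiff(all_parents, edges[, 2])
  stopifnot(length(root_old) == 1L)
  # preorder renumbering of internal nodes
  newid <- integer(max(edges))
  newid[seq_len(n)] <- seq_len(n)
  counter <- n
  assign_ids <- function(node) {
    counter <<- counter + 1L
    newid[node] <<- counter
    kids <- edges[edges[, 1] == node, 2]
    for (k in kids) if (k > n) assign_ids(k)
  }
  assign_ids(root_old)
  edge <- cbind(newid[edges[, 1]], newid[edges[, 2]])
  tr <- list(edge = edge, edge.length = as.numeric(elens),
             tip.label = labels, Nnode = counter - n)
  class(tr) <- "phylo"
  ape::reorder.phylo(tr, "cladewise")
}

# leaf label sets below each internal edge; canonical split keys
tree_splits <- function(tree, include_trivial = FALSE) {
  n <- length(tree$tip.label)
  root <- n + 1L
  desc <- function(node) {
    if (node <= n) return(tree$tip.label[node])
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, desc))
  }
  child_nodes <- tree$edge[, 2]
  keep <- if (include_trivial) rep(TRUE, length(child_nodes))
          else child_nodes > n
  out <- list()
  for (k in which(keep)) {
    node <- child_nodes[k]
    side <- desc(node)
    out[[length(out) + 1L]] <- list(
      node = node, edge = k, side = side,
      key = split_key(side, tree$tip.label))
  }
  out
}

# canonical key: the side not containing the alphabetically first leaf
split_key <- function(side, all_leaves) {
  ref <- sort(all_leaves)[1L]
  s <- if (ref %in% side) setdiff(all_leaves, side) else side
  paste(sort(s), collapse = "|")
}

#' Bootstrap support for a neighbor-joining protein tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree for
#' each replicate (Poisson-corrected p-distances), and annotates each
#' internal edge of the full-alignment tree with the percentage of
#' replicates containing the same unrooted bipartition.  Edges with
#' support below `collapse` (default 50%) are collapsed into
#' multifurcations.
#'
#' @param msa a [build_msa()] result.
#' @param replicates number of bootstrap replicates (default 1000).
#' @param seed RNG seed for resampling.
#' @param collapse support threshold (percent) below which internal edges
#'   are collapsed; `NULL` to keep all edges.
#' @return The NJ tree (`"phylo"`) with `node.label` holding internal-edge
#'   support percentages.
#' @export
bootstrap_support <- function(msa, replicates = 1000L, seed = 1L,
                              collapse = 50) {
  if (replicates < 1L) stop("replicates must be >= 1")
  mat <- as_alignment_matrix(msa)
  ids <- msa$ids
  n <- nrow(mat); L <- ncol(mat)
  # precompute per-pair per-column validity and mismatch
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  isgap <- mat == "-" | mat == "."
  V <- !isgap[pairs[, 1], , drop = FALSE] & !isgap[pairs[, 2], , drop = FALSE]
  Mm <- (mat[pairs[, 1], , drop = FALSE] != mat[pairs[, 2], , drop = FALSE]) & V

  dist_from_cols <- function(cols) {
    mm <- rowSums(Mm[, cols, drop = FALSE])
    vv <- rowSums(V[, cols, drop = FALSE])
    if (any(vv == 0))
      stop("bootstrap replicate with zero comparable sites for a pair")
    p <- mm / vv
    d <- ifelse(p >= 0.95, 3.0, -log(1 - p))
    D <- matrix(0, n, n, dimnames = list(ids, ids))
    D[pairs] <- d
    D + t(D)
  }

  base_tree <- nj_tree(dist_from_cols(seq_len(L)))
  base_splits <- tree_splits(base_tree)
  counts <- setNames(rep(0L, length(base_splits)),
                     vapply(base_splits, `[[`, "", "key"))
  set.seed(seed)
  for (b in seq_len(replicates)) {
    cols <- sample.int(L, L, replace = TRUE)
    rt <- nj_tree(dist_from_cols(cols))
    rk <- vapply(tree_splits(rt), `[[`, "", "key")
    hit <- names(counts) %in% rk
    counts[hit] <- counts[hit] + 1L
  }
  support <- 100 * counts / replicates
  # node.label: internal nodes in order n+1 .. n+Nnode; root unlabeled
  node_lab <- rep(NA_real_, base_tree$Nnode)
  for (k in seq_along(base_splits)) {
    node_lab[base_splits[[k]]$node - n] <- support[k]
  }
  base_tree$node.label <- ifelse(is.na(node_lab), "",
                                 format(round(node_lab), trim = TRUE))
  attr(base_tree, "support") <- node_lab
  if (!is.null(collapse))
    base_tree <- collapse_low_support(base_tree, collapse)
  base_tree
}

#' Collapse poorly supported internal edges
#'
#' Contracts every internal edge whose child-node support is below the
#' threshold, producing multifurcations (the collapsed edge's length is
#' discarded, as when drawing consensus-style trees).
#'
#' @param tree a `"phylo"` with numeric support in `attr(tree,
#'   "support")` (as produced by [bootstrap_support()]) or in
#'   `node.label`.
#' @param threshold support percentage below which edges are removed.
#' @return The collapsed `"phylo"`, support annotations updated.
#' @export
collapse_low_support <- function(tree, threshold = 50) {
  n <- length(tree$tip.label)
  support <- attr(tree, "support")
  if (is.null(support))
    support <- suppressWarnings(as.numeric(tree$node.label))
  repeat {
    child <- tree$edge[, 2]
    internal <- which(child > n)
    bad <- internal[which(support[child[internal] - n] < threshold)]
    if (!length(bad)) break
    e <- bad[1L]
    parent_node <- tree$edge[e, 1]
    child_node <- tree$edge[e, 2]
    # reattach child's children to parent, drop the edge and the node
    tree$edge[tree$edge[, 1] == child_node, 1] <- parent_node
    keep <- seq_len(nrow(tree$edge)) != e
    edges <- tree$edge[keep, , drop = FALSE]
    elens <- tree$edge.length[keep]
    support <- support[-(child_node - n)]
    # renumber nodes above the removed one
    edges[edges > child_node] <- edges[edges > child_node] - 1L
    tree$edge <- edges
    tree$edge.length <- elens
    tree$Nnode <- tree$Nnode - 1L
  }
  attr(tree, "support") <- support
  tree$node.label <- ifelse(is.na(support), "",
                            format(round(support), trim = TRUE))
  tree
}

#' Assign subfamily labels from labeled reference leaves
#'
#' Each query leaf takes the label of the smallest supported clade (either
#' side of an internal edge with support >= `support_threshold`; leaf
#' edges count as fully supported) that contains the query together with
#' reference leaves of exactly one label.  Queries contained in no such
#' clade are `"orphan"`.
#'
#' @param tree `"phylo"` with support as produced by
#'   [bootstrap_support()] (trees without support annotations treat all
#'   edges as supported).
#' @param reference_labels named character vector: reference leaf ->
#'   subfamily label.
#' @param support_threshold minimum support for a clade to count.
#' @return Named character vector: query leaf -> subfamily label (or
#'   `"orphan"`).
#' @export
assign_subfamilies <- function(tree, reference_labels,
                               support_threshold = 50) {
  leaves <- tree$tip.label
  refs <- intersect(names(reference_labels), leaves)
  if (!length(refs)) stop("tree contains no reference leaves")
  queries <- setdiff(leaves, names(reference_labels))
  n <- length(leaves)
  support <- attr(tree, "support")
  if (is.null(support) && !is.null(tree$node.label))
    support <- suppressWarnings(as.numeric(tree$node.label))

  splits <- tree_splits(tree, include_trivial = TRUE)
  clades <- list()
  for (sp in splits) {
    supp <- if (sp$node > n) {
      s <- if (is.null(support)) 100 else support[sp$node - n]
      if (is.na(s)) 100 else s
    } else 100
    if (supp < support_threshold) next
    clades[[length(clades) + 1L]] <- sp$side
    clades[[length(clades) + 1L]] <- setdiff(leaves, sp$side)
  }
  out <- setNames(rep("orphan", length(queries)), queries)
  for (q in queries) {
    best_size <- Inf; best_label <- "orphan"
    for (cl in clades) {
      if (!(q %in% cl)) next
      rl <- unique(reference_labels[intersect(cl, refs)])
      if (length(rl) != 1L) next
      if (length(cl) < best_size) {
        best_size <- length(cl); best_label <- rl
      }
    }
    out[q] <- best_label
  }
  out
}
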