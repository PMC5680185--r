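# Internal unrooted tree representation ("utree").
#
# Leaves are nodes 1..n_tip (labels in $labels); internal nodes follow.
# $nbr[[v]] is the integer vector of neighbours of v and $len[[v]] the
# parallel edge lengths, kept symmetric.  The likelihood engine, the
# simulator and the NNI search all operate on this structure; ape "phylo"
# objects are the user-facing carrier and are converted at the boundary.

new_utree <- function(n_tip, labels, nbr, len, support = NULL) {
  structure(list(n_tip = n_tip, labels = labels, nbr = nbr, len = len,
                 support = support),
            class = "utree")
}

as_utree <- function(tree) {
  if (inherits(tree, "utree")) return(tree)
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  nbr <- vector("list", nnode)
  len <- vector("list", nnode)
  el <- if (is.null(tree$edge.length)) rep(NA_real_, nrow(tree$edge)) else
    tree$edge.length
  for (i in seq_len(nrow(tree$edge))) {
    u <- tree$edge[i, 1]; v <- tree$edge[i, 2]
    nbr[[u]] <- c(nbr[[u]], v); len[[u]] <- c(len[[u]], el[i])
    nbr[[v]] <- c(nbr[[v]], u); len[[v]] <- c(len[[v]], el[i])
  }
  support <- rep(NA_real_, nnode)
  if (!is.null(tree$node.label)) {
    sup <- suppressWarnings(as.numeric(tree$node.label))
    support[(ntip + 1L):nnode] <- sup
  }
  new_utree(ntip, tree$tip.label, nbr, len, support)
}

# Convert to ape phylo rooted at `root` (default: first internal node).
# When keep_ids = TRUE node numbering is preserved, which requires the
# root to be the first internal node (ape convention root = n_tip + 1).
as_phylo <- function(ut, root = ut$n_tip + 1L, keep_ids = TRUE) {
  if (inherits(ut, "phylo")) return(ut)
  stopifnot(inherits(ut, "utree"))
  n_nodes <- length(ut$nbr)
  if (!keep_ids || root != ut$n_tip + 1L) {
    return(as_phylo_renumber(ut, root))
  }
  parent <- integer(0); child <- integer(0); elen <- numeric(0)
  stack <- c(root); from <- c(0L)
  while (length(stack)) {
    u <- stack[length(stack)]; p <- from[length(stack)]
    stack <- stack[-length(stack)]; from <- from[-length(from)]
    nb <- ut$nbr[[u]]
    for (j in seq_along(nb)) {
      v <- nb[j]
      if (v == p) next
      parent <- c(parent, u); child <- c(child, v)
      elen <- c(elen, ut$len[[u]][j])
      stack <- c(stack, v); from <- c(from, u)
    }
  }
  tr <- list(edge = cbind(parent, child), Nnode = n_nodes - ut$n_tip,
             tip.label = ut$labels, edge.length = elen)
  if (!is.null(ut$support) && any(!is.na(ut$support))) {
    tr$node.label <- ifelse(is.na(ut$support[(ut$n_tip + 1L):n_nodes]), "",
                            format(ut$support[(ut$n_tip + 1L):n_nodes]))
  }
  class(tr) <- "phylo"
  attr(tr, "order") <- NULL
  if (all(is.na(elen))) tr$edge.length <- NULL
  tr
}

as_phylo_renumber <- function(ut, root) {
  n_nodes <- length(ut$nbr)
  newid <- integer(n_nodes)
  newid[seq_len(ut$n_tip)] <- seq_len(ut$n_tip)
  nxt <- ut$n_tip
  # assign internal ids in preorder from root
  order_nodes <- integer(0)
  stack <- c(root); from <- c(0L)
  edges <- list()
  while (length(stack)) {
    u <- stack[length(stack)]; p <- from[length(stack)]
    stack <- stack[-length(stack)]; from <- from[-length(from)]
    if (u > ut$n_tip) { nxt <- nxt + 1L; newid[u] <- nxt }
    nb <- ut$nbr[[u]]
    for (j in seq_along(nb)) {
      v <- nb[j]
      if (v == p) next
      edges[[length(edges) + 1L]] <- c(u, v, ut$len[[u]][j])
      stack <- c(stack, v); from <- c(from, u)
    }
  }
  em <- do.call(rbind, edges)
  tr <- list(edge = cbind(newid[em[, 1]], newid[em[, 2]]),
             Nnode = n_nodes - ut$n_tip, tip.label = ut$labels,
             edge.length = em[, 3])
  class(tr) <- "phylo"
  if (all(is.na(tr$edge.length))) tr$edge.length <- NULL
  tr
}

ut_n_nodes <- function(ut) length(ut$nbr)

ut_internal_nodes <- function(ut) {
  setdiff(seq_len(ut_n_nodes(ut)), seq_len(ut$n_tip))
}

ut_degree <- function(ut) lengths(ut$nbr)

ut_is_binary_unrooted <- function(ut) {
  deg <- ut_degree(ut)
  all(deg[seq_len(ut$n_tip)] == 1L) &&
    all(deg[ut_internal_nodes(ut)] == 3L)
}

# undirected edge list: matrix with columns u, v (u < v), len
ut_edges <- function(ut) {
  res <- list()
  for (u in seq_along(ut$nbr)) {
    nb <- ut$nbr[[u]]
    keep <- nb > u
    if (any(keep)) {
      res[[length(res) + 1L]] <- cbind(u, nb[keep], ut$len[[u]][keep])
    }
  }
  m <- do.call(rbind, res)
  colnames(m) <- c("u", "v", "len")
  m
}

ut_get_len <- function(ut, u, v) ut$len[[u]][match(v, ut$nbr[[u]])]

ut_set_len <- function(ut, u, v, value) {
  ut$len[[u]][match(v, ut$nbr[[u]])] <- value
  ut$len[[v]][match(u, ut$nbr[[v]])] <- value
  ut
}

# leaves on the `v` side of edge (u, v)
ut_side_leaves <- function(ut, u, v) {
  acc <- integer(0)
  stack <- c(v); from <- c(u)
  while (length(stack)) {
    x <- stack[length(stack)]; p <- from[length(stack)]
    stack <- stack[-length(stack)]; from <- from[-length(from)]
    if (x <= ut$n_tip) acc <- c(acc, x)
    for (w in ut$nbr[[x]]) {
      if (w != p) { stack <- c(stack, w); from <- c(from, x) }
    }
  }
  acc
}

bipartition_hash <- function(ut, u, v) {
  side <- sort(ut$labels[ut_side_leaves(ut, u, v)], method = "radix")
  anchor <- sort(ut$labels, method = "radix")[1]
  if (anchor %in% side) {
    side <- sort(setdiff(ut$labels, side), method = "radix")
  }
  paste(side, collapse = "\r")
}

# non-trivial bipartitions (internal edges) as a character set
tree_bipartitions <- function(tree) {
  ut <- as_utree(tree)
  em <- ut_edges(ut)
  internal <- em[, "u"] > ut$n_tip & em[, "v"] > ut$n_tip
  if (!any(internal)) return(character(0))
  apply(em[internal, , drop = FALSE], 1,
        function(e) bipartition_hash(ut, e[1], e[2]))
}

same_topology <- function(t1, t2) {
  setequal(tree_bipartitions(t1), tree_bipartitions(t2))
}

# Signature of an internal node: the multiset of leaf sets of the subtrees
# hanging off it.  Used to match internal nodes between two renderings of
# the same (or a congruent) topology.
node_signature <- function(ut, node) {
  hashes <- vapply(ut$nbr[[node]], function(v) {
    paste(sort(ut$labels[ut_side_leaves(ut, node, v)], method = "radix"),
          collapse = "\r")
  }, character(1))
  paste(sort(hashes, method = "radix"), collapse = "\n")
}

#' Match internal nodes between two trees on the same taxa
#'
#' Internal node numbering is representation-dependent; two renderings of
#' the same unrooted topology (for example a simulated tree and the same
#' tree after a Newick round trip) may number their ancestors differently.
#' Nodes are matched by the multiset of leaf sets of their incident
#' subtrees, which identifies a node uniquely in a binary tree.
#'
#' @param t1,t2 trees (`ape::phylo`) on identical leaf label sets.
#' @return integer vector: for each internal node id of `t1`, the matching
#'   internal node id of `t2` (`NA` when no counterpart exists), named by
#'   the `t1` node ids.
#' @export
match_internal_nodes <- function(t1, t2) {
  u1 <- as_utree(t1); u2 <- as_utree(t2)
  if (!setequal(u1$labels, u2$labels)) {
    stop("trees have different leaf label sets")
  }
  n1 <- ut_internal_nodes(u1); n2 <- ut_internal_nodes(u2)
  s1 <- vapply(n1, function(v) node_signature(u1, v), character(1))
  s2 <- vapply(n2, function(v) node_signature(u2, v), character(1))
  out <- n2[match(s1, s2)]
  names(out) <- n1
  out
}
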