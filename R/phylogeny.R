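#' Jaccard distance matrix between matrix rows
#'
#' Distance between two taxa is one minus the Jaccard similarity of their
#' presence vectors, the input for the neighbour-joining starting tree.
#'
#' @param m a character matrix from [encode()].
#' @return a symmetric distance matrix.
#' @export
jaccard_distance <- function(m) {
  stopifnot(inherits(m, "bcm"))
  X <- m$mat
  n <- nrow(X)
  D <- matrix(0, n, n, dimnames = list(m$taxa, m$taxa))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      inter <- sum(X[i, ] & X[j, ])
      uni <- sum(X[i, ] | X[j, ])
      D[i, j] <- D[j, i] <- if (uni == 0) 0 else 1 - inter / uni
    }
  }
  D
}

# one NNI move across internal edge (u, v); pair selects which neighbour
# of v is exchanged with the second neighbour of u
ut_nni <- function(ut, u, v, pair) {
  others_u <- setdiff(ut$nbr[[u]], v)
  others_v <- setdiff(ut$nbr[[v]], u)
  b <- others_u[2]
  cc <- others_v[pair]
  lb <- ut_get_len(ut, u, b)
  lc <- ut_get_len(ut, v, cc)
  iu <- match(b, ut$nbr[[u]]); iv <- match(cc, ut$nbr[[v]])
  ut$nbr[[u]][iu] <- cc; ut$len[[u]][iu] <- lc
  ut$nbr[[v]][iv] <- b;  ut$len[[v]][iv] <- lb
  ib <- match(u, ut$nbr[[b]]); ut$nbr[[b]][ib] <- v
  ic <- match(v, ut$nbr[[cc]]); ut$nbr[[cc]][ic] <- u
  ut
}

#' Infer a maximum-likelihood tree from a binary character matrix
#'
#' Search strategy: a neighbour-joining starting tree on the Jaccard
#' distances between rows, followed by branch-length optimization and
#' nearest-neighbour-interchange (NNI) hill climbing.  NNI moves are
#' evaluated in a fixed deterministic edge order with first-improvement
#' acceptance; the search stops when no move improves the log-likelihood
#' by more than `1e-6`.  The result is an unrooted binary tree.
#'
#' @param m a character matrix from [encode()] with at least three taxa.
#' @param p a [model_params()] object.
#' @param seed integer seed (the search is deterministic; the seed is
#'   recorded for provenance).
#' @return an `ape::phylo` tree with optimized branch lengths and the
#'   log-likelihood in `attr(, "loglik")`.
#' @export
infer_tree <- function(m, p = model_params(), seed = 1L) {
  stopifnot(inherits(m, "bcm"))
  n <- length(m$taxa)
  if (n < 3) stop("need at least 3 taxa to infer a tree")
  set.seed(seed)
  if (n == 3) {
    ut <- new_utree(3L, m$taxa,
                    nbr = list(4L, 4L, 4L, c(1L, 2L, 3L)),
                    len = list(0.1, 0.1, 0.1, c(0.1, 0.1, 0.1)))
    start <- as_phylo(ut)
  } else {
    D <- jaccard_distance(m)
    njt <- ape::unroot(ape::nj(stats::as.dist(D)))
    njt$edge.length[is.na(njt$edge.length) | njt$edge.length < 0] <- 1e-6
    start <- njt
  }
  cur <- optimize_branch_lengths(start, m, p)
  cur_ll <- attr(cur, "loglik")
  repeat {
    ut <- as_utree(cur)
    em <- ut_edges(ut)
    internal <- which(em[, "u"] > ut$n_tip & em[, "v"] > ut$n_tip)
    improved <- FALSE
    for (i in internal) {
      for (pair in 1:2) {
        cand <- ut_nni(ut, em[i, "u"], em[i, "v"], pair)
        cand_opt <- optimize_branch_lengths(cand, m, p, max_rounds = 2)
        if (attr(cand_opt, "loglik") > cur_ll + 1e-6) {
          cur <- cand_opt
          cur_ll <- attr(cand_opt, "loglik")
          improved <- TRUE
          break
        }
      }
      if (improved) break
    }
    if (!improved) break
  }
  cur <- optimize_branch_lengths(cur, m, p)
  cur
}

#' Nonparametric bootstrap support for the ML tree
#'
#' Characters (matrix columns) are resampled with replacement to the
#' original width `B` times; a tree is inferred from each replicate, and
#' the support of an internal edge of the ML tree is the percentage of
#' replicate trees containing the same bipartition.
#'
#' @param m a character matrix from [encode()].
#' @param p a [model_params()] object.
#' @param B number of bootstrap replicates (>= 1).
#' @param seed integer seed for the resampling.
#' @return the ML tree with supports as internal `node.label` and a
#'   `support` data frame (`bipartition`, `support`, `level`) in
#'   `attr(, "support")`.
#' @export
bootstrap_support <- function(m, p = model_params(), B = 100, seed = 1L) {
  stopifnot(B >= 1)
  main <- infer_tree(m, p, seed = seed)
  main_bp <- tree_bipartitions(main)
  counts <- stats::setNames(numeric(length(main_bp)), main_bp)
  set.seed(seed)
  K <- ncol(m$mat)
  for (b in seq_len(B)) {
    idx <- sample.int(K, K, replace = TRUE)
    mb <- m
    mb$mat <- m$mat[, idx, drop = FALSE]
    mb$col_class <- m$col_class[idx]
    tb <- infer_tree(mb, p, seed = seed)
    hit <- main_bp %in% tree_bipartitions(tb)
    counts[hit] <- counts[hit] + 1
  }
  support <- 100 * counts / B
  ut <- as_utree(main)
  ut$support <- rep(NA_real_, ut_n_nodes(ut))
  # attach each bipartition's support to the edge endpoint away from the
  # conversion root (ape convention: node labels annotate the subtree)
  em <- ut_edges(ut)
  depth <- rep(NA_integer_, ut_n_nodes(ut))
  root <- ut$n_tip + 1L
  depth[root] <- 0L
  queue <- root
  while (length(queue)) {
    x <- queue[1]; queue <- queue[-1]
    for (w in ut$nbr[[x]]) {
      if (is.na(depth[w])) { depth[w] <- depth[x] + 1L; queue <- c(queue, w) }
    }
  }
  for (i in seq_len(nrow(em))) {
    u <- em[i, "u"]; v <- em[i, "v"]
    if (u <= ut$n_tip || v <= ut$n_tip) next
    h <- bipartition_hash(ut, u, v)
    child <- if (depth[u] > depth[v]) u else v
    ut$support[child] <- support[h]
  }
  out <- as_phylo(ut)
  attr(out, "loglik") <- attr(main, "loglik")
  attr(out, "support") <- data.frame(
    bipartition = gsub("\r", ",", names(support)),
    support = as.numeric(support),
    level = support_level(as.numeric(support)),
    stringsAsFactors = FALSE)
  out
}

#' Classify bootstrap support values
#'
#' Three levels: strong (support > 90), medium (60 <= support <= 90) and
#' weak (support < 60).
#'
#' @param x numeric bootstrap values in `[0, 100]`.
#' @return a factor with levels `strong`, `medium`, `weak`.
#' @export
support_level <- function(x) {
  lev <- ifelse(x > 90, "strong", ifelse(x >= 60, "medium", "weak"))
  factor(lev, levels = c("strong", "medium", "weak"))
}
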