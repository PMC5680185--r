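#' Partial likelihoods of a character set at an ancestral node
#'
#' The pruning recursion: the partial likelihood of state `s` at node `a`
#' is the product, over the subtrees incident to `a`, of the transition-
#' weighted sums of the child partials.  Leaves carry indicator partials.
#' At an internal node of an unrooted binary tree the product runs over
#' all three incident subtrees, which is exactly the re-rooting of the
#' tree at `a`.
#'
#' @param tree an `ape::phylo` tree with branch lengths.
#' @param m a character matrix from [encode()].
#' @param p a [model_params()] object.
#' @param node internal node id (ape numbering: tips first).
#' @return a list with `partials` (2 x K matrix, rows = states 0/1,
#'   columns rescaled to a maximum of 1) and `log_scale` (per-column log
#'   of the factor removed; the true partial is
#'   `partials * exp(log_scale)`).
#' @export
partial_likelihood <- function(tree, m, p, node) {
  eng <- make_engine(tree, m, p)
  ut <- eng$ut()
  if (node <= ut$n_tip || node > ut_n_nodes(ut)) {
    stop("'node' must be an internal node id")
  }
  P <- eng$node_partial(node)
  rownames(P$mat) <- c("0", "1")
  colnames(P$mat) <- colnames(m$mat)
  list(partials = P$mat, log_scale = P$ls)
}

#' Posterior probability of characters at an ancestral node
#'
#' Bayes' rule per character: `P(state 1 | data) = f p1 / (f p1 +
#' (1 - f) p0)` where `p_s` are the pruning partial likelihoods at the
#' node and the prior `f` is the empirical frequency of state 1 among the
#' leaves for that character.  When the prior is degenerate (`f` of 0 or
#' 1) and the likelihood contradicts it, the prior is returned.
#'
#' @inheritParams partial_likelihood
#' @param prior optional numeric vector of per-character priors
#'   (defaults to leaf frequencies).
#' @return named numeric vector: posterior probability of presence for
#'   every character column.
#' @export
posterior <- function(tree, m, p, node, prior = NULL) {
  eng <- make_engine(tree, m, p)
  ut <- eng$ut()
  if (node <= ut$n_tip || node > ut_n_nodes(ut)) {
    stop("'node' must be an internal node id")
  }
  f <- if (is.null(prior)) eng$freq1 else prior
  stopifnot(length(f) == ncol(m$mat), all(f >= 0 & f <= 1))
  P <- eng$node_partial(node)
  num <- f * P$mat[2, ]
  den <- num + (1 - f) * P$mat[1, ]
  out <- ifelse(den > 0, num / den, f)
  names(out) <- colnames(m$mat)
  out
}

#' Reconstruct posterior probabilities for every ancestor
#'
#' For each internal node of the unrooted binary guide tree the tree is
#' conceptually re-rooted at that node and the posterior probability of
#' every character (gene content and gene adjacency) is computed from all
#' genomes in the data set, not only the node's descendants.  A tree with
#' `n` leaves yields `n - 2` ancestors.
#'
#' The per-character prior of Bayes' rule can be either the empirical
#' frequency of the character among the leaves (`"leaf"`, the default)
#' or the stationary distribution of the gain/loss chain
#' (`"stationary"`).  Under heavy rearrangement the stationary prior is
#' the consistent choice: it encodes how unlikely a specific adjacency
#' is to arise at all, so characters gained once inside a single clade
#' are not promoted to ancestral presence.
#'
#' @param tree an `ape::phylo` guide tree with branch lengths whose leaf
#'   labels match the matrix taxa.
#' @param m a character matrix from [encode()].
#' @param p a [model_params()] object.
#' @param prior `"leaf"` (empirical leaf frequency) or `"stationary"`.
#' @return an object of class `ancestor_posteriors`: list with `nodes`
#'   (internal node ids), `prob` (nodes x characters matrix of posterior
#'   presence probabilities), `tree`, and `params`.
#' @export
reconstruct_all <- function(tree, m, p = model_params(),
                            prior = c("leaf", "stationary")) {
  prior <- match.arg(prior)
  eng <- make_engine(tree, m, p)
  ut <- eng$ut()
  if (!ut_is_binary_unrooted(ut)) {
    stop("guide tree must be an unrooted binary tree")
  }
  nodes <- ut_internal_nodes(ut)
  prob <- eng$posteriors(nodes,
                         f = if (prior == "leaf") eng$freq1 else eng$pi1)
  structure(list(nodes = nodes, prob = prob, tree = as_phylo(ut),
                 params = p, col_class = m$col_class,
                 adj_keys = m$adj_keys, families = m$families,
                 labels = colnames(m$mat)),
            class = "ancestor_posteriors")
}

#' @export
print.ancestor_posteriors <- function(x, ...) {
  cat("<ancestor_posteriors>", length(x$nodes), "ancestors x",
      ncol(x$prob), "characters\n")
  invisible(x)
}

#' Select ancestral gene content by posterior threshold
#'
#' Families whose posterior presence probability strictly exceeds the
#' threshold are included in the ancestral gene set (a posterior exactly
#' equal to the threshold is excluded).
#'
#' @param ap an [reconstruct_all()] result.
#' @param node internal node id.
#' @param threshold inclusion threshold in (0, 1).
#' @return integer vector of selected family IDs.
#' @export
select_content <- function(ap, node, threshold = 0.5) {
  stopifnot(inherits(ap, "ancestor_posteriors"),
            threshold > 0, threshold < 1)
  i <- match(node, ap$nodes)
  if (is.na(i)) stop("node ", node, " has no reconstruction")
  pc <- ap$prob[i, ap$col_class == "C"]
  sort(ap$families[pc > threshold])
}

# adjacency posteriors of one ancestor as a data frame (keys + prob)
node_adjacency_posteriors <- function(ap, node) {
  i <- match(node, ap$nodes)
  if (is.na(i)) stop("node ", node, " has no reconstruction")
  keys <- ap$adj_keys
  data.frame(key = keys,
             e1 = adj_ext1(keys), e2 = adj_ext2(keys),
             prob = unname(ap$prob[i, ap$col_class == "A"]))
}

#' Export ancestor posteriors as a TSV table
#'
#' @param ap an [reconstruct_all()] result.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_posteriors_tsv <- function(ap, path) {
  stopifnot(inherits(ap, "ancestor_posteriors"))
  long <- data.frame(
    node = rep(ap$nodes, each = ncol(ap$prob)),
    character = rep(colnames(ap$prob), times = length(ap$nodes)),
    probability = as.vector(t(ap$prob)),
    stringsAsFactors = FALSE)
  utils::write.table(long, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Double a genome after whole-genome duplication
#'
#' Produces the post-WGD version of an ancestor by copying every
#' chromosome, mirroring a whole-genome duplication event.  This is an
#' explicit operation, never inferred.
#'
#' @param g a [genome()].
#' @param name optional name for the doubled genome.
#' @return a [genome()] with every chromosome duplicated.
#' @export
double_genome <- function(g, name = paste0(g$name, "_x2")) {
  stopifnot(inherits(g, "genome"))
  genome(name, c(g$chromosomes, g$chromosomes))
}
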