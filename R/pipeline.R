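`%||%` <- function(a, b) if (is.null(a)) b else a

# representative genome of the parent side of internal node `a`:
# the nearest leaf reached through the parent edge (breadth-first)
parent_side_leaf <- function(ut, a, parent) {
  queue <- parent; from <- a
  seen <- c(a)
  while (length(queue)) {
    x <- queue[1]; queue <- queue[-1]
    seen <- c(seen, x)
    if (x <= ut$n_tip) return(x)
    for (w in ut$nbr[[x]]) if (!w %in% seen) queue <- c(queue, w)
  }
  stop("no leaf found on parent side")  # unreachable on valid trees
}

#' Reconstruct and assemble every ancestor of a genome set
#'
#' The complete reconstruction stage: encode the genomes, optimize
#' branch lengths on the guide tree, compute posterior probabilities for
#' every character at every internal node, select ancestral gene content
#' by threshold, and assemble each ancestor's chromosomes.  Ancestors
#' are assembled in postorder from the tree's reference root, so the two
#' child genomes handed to the telomere rules are already-assembled
#' ancestors (or observed leaves) while the parent side is represented
#' by its nearest observed leaf.
#'
#' @param tree guide tree (`ape::phylo`, unrooted binary); if it carries
#'   no usable branch lengths they are optimized from the data.
#' @param gs a [genome_set()] of observed genomes.
#' @param params [model_params()]; default derived from the genomes via
#'   [model_params_from_genomes()].
#' @param threshold posterior threshold for ancestral gene content.
#' @param seed integer seed (tour search).
#' @param tour_method passed to [solve_tour()].
#' @param prior prior for [reconstruct_all()]; the pipeline defaults to
#'   the stationary prior of the gain/loss chain, which stays calibrated
#'   under heavy rearrangement.
#' @return a list with `matrix`, `params`, `tree` (optimized),
#'   `posteriors` ([reconstruct_all()] result) and `ancestors` (named
#'   list of assembled [genome()]s, one per internal node).
#' @export
reconstruct_genomes <- function(tree, gs, params = NULL, threshold = 0.5,
                                seed = 1L, tour_method = "heuristic",
                                prior = "stationary") {
  stopifnot(inherits(gs, "genome_set"))
  m <- encode(gs)
  p <- params %||% model_params_from_genomes(gs)
  tree_opt <- optimize_branch_lengths(tree, m, p)
  ap <- reconstruct_all(tree_opt, m, p, prior = prior)
  ut <- as_utree(tree_opt)
  root <- ut$n_tip + 1L
  # rooted orientation + postorder over internal nodes
  parent <- integer(ut_n_nodes(ut))
  order_post <- integer(0)
  stack <- c(root); from <- c(0L)
  preorder <- integer(0)
  while (length(stack)) {
    u <- stack[length(stack)]; pua <- from[length(stack)]
    stack <- stack[-length(stack)]; from <- from[-length(from)]
    parent[u] <- pua
    preorder <- c(preorder, u)
    for (v in ut$nbr[[u]]) {
      if (v != pua) { stack <- c(stack, v); from <- c(from, u) }
    }
  }
  order_post <- rev(preorder)
  leaf_of <- function(v) gs$genomes[[ut$labels[v]]]
  ancestors <- list()
  rep_of <- function(v) {
    if (v <= ut$n_tip) leaf_of(v) else ancestors[[as.character(v)]]
  }
  for (a in order_post) {
    if (a <= ut$n_tip) next
    kids <- setdiff(ut$nbr[[a]], parent[a])
    if (a == root) {
      # no parent: the third subtree stands in for the parent side
      par_rep <- rep_of(kids[3])
      kids <- kids[1:2]
    } else {
      par_rep <- leaf_of(parent_side_leaf(ut, a, parent[a]))
    }
    ancestors[[as.character(a)]] <- assemble_ancestor(
      ap, a, child1 = rep_of(kids[1]), child2 = rep_of(kids[2]),
      parent = par_rep, threshold = threshold, seed = seed,
      method = tour_method)
  }
  list(matrix = m, params = p, tree = tree_opt, posteriors = ap,
       ancestors = ancestors)
}

#' Simulate a data set and reconstruct its ancestors
#'
#' Runs the simulator, reconstructs every ancestor with the true tree as
#' guide, and scores each reconstruction against the recorded true
#' ancestral genome (Jaccard content and adjacency accuracy).
#'
#' @param cfg a [sim_config()].
#' @param threshold posterior threshold for gene content.
#' @param tour_method passed to [solve_tour()].
#' @return a list with `sim` ([evolve()] result), `rec`
#'   ([reconstruct_genomes()] result), `accuracy` (one row per ancestor)
#'   and the means `mean_content` / `mean_adjacency`.
#' @export
reconstruction_experiment <- function(cfg, threshold = 0.5,
                                      tour_method = "heuristic") {
  sim <- evolve(cfg)
  rec <- reconstruct_genomes(sim$tree, sim$leaves, threshold = threshold,
                             seed = cfg$seed, tour_method = tour_method)
  nodes <- names(rec$ancestors)
  rows <- lapply(nodes, function(nd) {
    acc <- accuracy(rec$ancestors[[nd]], sim$ancestors[[nd]])
    data.frame(node = as.integer(nd),
               content = acc$content_accuracy,
               adjacency = acc$adjacency_accuracy,
               fp_content = acc$fp[["content"]],
               fn_content = acc$fn[["content"]],
               fp_adjacency = acc$fp[["adjacency"]],
               fn_adjacency = acc$fn[["adjacency"]])
  })
  acc <- do.call(rbind, rows)
  list(sim = sim, rec = rec, accuracy = acc,
       mean_content = mean(acc$content),
       mean_adjacency = mean(acc$adjacency))
}

#' Run the full pipeline on files
#'
#' Orchestrates encode, tree inference (or a user guide tree), bootstrap,
#' ancestral reconstruction, assembly, and report writing.  All outputs
#' land in `out_dir`; given the same inputs and seed the outputs are
#' identical.
#'
#' @param genomes path to a GRIMM gene-order file or a [genome_set()].
#' @param out_dir output directory (created if missing).
#' @param tree optional Newick guide tree path or `phylo`; inferred by
#'   [infer_tree()] when absent.
#' @param bootstrap bootstrap replicate count (0 = skip).
#' @param threshold posterior threshold for ancestral content.
#' @param seed integer seed used by every stochastic stage.
#' @param params optional [model_params()].
#' @return invisibly, a list with the stage objects and output paths.
#' @export
run_pipeline <- function(genomes, out_dir, tree = NULL, bootstrap = 0,
                         threshold = 0.5, seed = 1L, params = NULL) {
  gs <- if (inherits(genomes, "genome_set")) genomes else
    read_gene_orders(genomes)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  m <- encode(gs)
  p <- params %||% model_params_from_genomes(gs)
  write_bcm_tsv(m, file.path(out_dir, "matrix.tsv"))
  write_phylip(m, file.path(out_dir, "matrix.phy"))
  if (is.null(tree)) {
    message("inferring tree (", length(gs$genomes), " taxa)")
    tr <- if (bootstrap > 0) bootstrap_support(m, p, B = bootstrap,
                                               seed = seed) else
      infer_tree(m, p, seed = seed)
  } else {
    tr <- if (inherits(tree, "phylo")) tree else read_newick(tree,
                                                             binary = TRUE)
  }
  message("reconstructing ancestors")
  rec <- reconstruct_genomes(tr, gs, params = p, threshold = threshold,
                             seed = seed)
  write_newick(rec$tree, file.path(out_dir, "tree.nwk"))
  write_posteriors_tsv(rec$posteriors, file.path(out_dir,
                                                 "posteriors.tsv"))
  anc_set <- genome_set(unname(rec$ancestors))
  write_gene_orders(anc_set, file.path(out_dir, "ancestors.grimm"))
  summary <- data.frame(
    node = names(rec$ancestors),
    genes = vapply(rec$ancestors, function(g) sum(lengths(g$chromosomes)),
                   numeric(1)),
    chromosomes = vapply(rec$ancestors,
                         function(g) length(g$chromosomes), numeric(1)))
  utils::write.table(summary, file.path(out_dir, "ancestors_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(genome_set = gs, matrix = m, params = p, tree = rec$tree,
                 posteriors = rec$posteriors, ancestors = rec$ancestors,
                 out_dir = out_dir))
}
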