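# small fixture: a bcm built directly from presence vectors
make_bcm <- function(X, taxa = rownames(X)) {
  gs_cols <- ncol(X)
  m <- list(taxa = taxa,
            mat = matrix(as.integer(X), nrow(X), gs_cols,
                         dimnames = list(taxa, paste0("C:", seq_len(gs_cols)))),
            col_class = rep("C", gs_cols),
            adj_keys = numeric(0), families = seq_len(gs_cols),
            duplicate_table = data.frame(), include_telomeres = FALSE)
  class(m) <- "bcm"
  m
}

three_leaf_tree <- function(lens = c(0.3, 0.2, 0.4), labels = c("a", "b", "c")) {
  tr <- list(edge = cbind(4L, 1:3), Nnode = 1L, tip.label = labels,
             edge.length = lens)
  class(tr) <- "phylo"
  tr
}

test_that("pruning log-likelihood equals brute-force state enumeration", {
  set.seed(4)
  p <- model_params(loss_rate = 0.8, gain_rate = 0.3)
  # 3-leaf and 4/5-leaf random trees, random binary data
  for (ntax in 3:5) {
    tr <- random_tree(ntax)
    tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 1.5)
    X <- matrix(rbinom(ntax * 6, 1, 0.5), ntax,
                dimnames = list(tr$tip.label, NULL))
    m <- make_bcm(X)
    expected <- sum(log(enum_char_liks(tr, X, 0.8, 0.3)))
    expect_equal(log_likelihood(tr, m, p), expected, tolerance = 1e-10)
  }
})

test_that("likelihood is invariant to the rooting of the tree", {
  set.seed(9)
  tr <- random_tree(6)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 1)
  X <- matrix(rbinom(6 * 40, 1, 0.4), 6, dimnames = list(tr$tip.label, NULL))
  m <- make_bcm(X)
  p <- model_params(loss_rate = 1, gain_rate = 0.25)
  base <- log_likelihood(tr, m, p)
  for (node in 8:10) {
    rr <- ape::root(tr, node = node, resolve.root = FALSE)
    expect_equal(log_likelihood(rr, m, p), base, tolerance = 1e-8)
  }
})

test_that("degenerate branches reduce the likelihood to the prior", {
  X <- matrix(c(1, 1, 1, 0, 0, 0), 3, 2,
              dimnames = list(c("a", "b", "c"), NULL))
  m <- make_bcm(X)
  p <- model_params(loss_rate = 1, gain_rate = 0.5)
  tr <- three_leaf_tree(rep(1e-9, 3))
  pi1 <- 0.5 / 1.5
  expect_equal(log_likelihood(tr, m, p), log(pi1) + log(1 - pi1),
               tolerance = 1e-6)
})

test_that("branch-length optimization never decreases the likelihood", {
  set.seed(12)
  tr <- random_tree(5)
  tr$edge.length <- rep(0.5, nrow(tr$edge))
  X <- matrix(rbinom(5 * 60, 1, 0.5), 5, dimnames = list(tr$tip.label, NULL))
  m <- make_bcm(X)
  p <- model_params(loss_rate = 1, gain_rate = 0.3)
  before <- log_likelihood(tr, m, p)
  opt <- optimize_branch_lengths(tr, m, p)
  expect_gte(attr(opt, "loglik"), before - 1e-9)
  expect_equal(log_likelihood(opt, m, p), attr(opt, "loglik"),
               tolerance = 1e-9)
})

test_that("tree search recovers clean signal and handles 3 taxa", {
  p <- model_params(loss_rate = 1, gain_rate = 0.2)
  # 3 taxa: the unique unrooted topology
  X3 <- matrix(rbinom(3 * 30, 1, 0.5), 3,
               dimnames = list(c("a", "b", "c"), NULL))
  t3 <- infer_tree(make_bcm(X3), p)
  expect_equal(length(t3$tip.label), 3)
  expect_error(infer_tree(make_bcm(X3[1:2, , drop = FALSE]), p),
               "at least 3 taxa")
  # 4 taxa, 200 characters perfectly supporting AB|CD
  X4 <- rbind(A = rep(c(1, 0), each = 100), B = rep(c(1, 0), each = 100),
              C = rep(c(0, 1), each = 100), D = rep(c(0, 1), each = 100))
  t4 <- infer_tree(make_bcm(X4), p)
  bp <- orderphy:::tree_bipartitions(t4)
  expect_equal(length(bp), 1)
  # the returned split is AB|CD: verify via an explicit comparison tree
  ref <- ape::read.tree(text = "((A,B),(C,D));")
  expect_true(orderphy:::same_topology(t4, ref))
})

test_that("an identical duplicate taxon attaches as sibling", {
  set.seed(20)
  X <- matrix(rbinom(5 * 120, 1, 0.5), 5,
              dimnames = list(paste0("t", 1:5), NULL))
  X <- rbind(X, "t1bis" = X["t1", ])
  tr <- infer_tree(make_bcm(X), model_params(1, 0.2))
  ut <- orderphy:::as_utree(tr)
  i <- match("t1", ut$labels); j <- match("t1bis", ut$labels)
  expect_equal(ut$nbr[[i]], ut$nbr[[j]])
})

test_that("tree search is invariant to column permutations", {
  set.seed(31)
  X <- matrix(rbinom(5 * 80, 1, 0.5), 5,
              dimnames = list(paste0("t", 1:5), NULL))
  m1 <- make_bcm(X)
  perm <- sample(ncol(X))
  m2 <- make_bcm(X[, perm])
  p <- model_params(1, 0.3)
  t1 <- infer_tree(m1, p); t2 <- infer_tree(m2, p)
  expect_true(orderphy:::same_topology(t1, t2))
  expect_equal(attr(t1, "loglik"), attr(t2, "loglik"), tolerance = 1e-6)
})

test_that("bootstrap gives full support to a clean 4-taxon split", {
  X4 <- rbind(A = rep(c(1, 0), each = 100), B = rep(c(1, 0), each = 100),
              C = rep(c(0, 1), each = 100), D = rep(c(0, 1), each = 100))
  bs <- bootstrap_support(make_bcm(X4), model_params(1, 0.2), B = 20,
                          seed = 3)
  sup <- attr(bs, "support")
  expect_equal(nrow(sup), 1)
  expect_equal(sup$support, 100)
  expect_equal(as.character(sup$level), "strong")
  # B = 1: supports are all-or-nothing
  bs1 <- bootstrap_support(make_bcm(X4), model_params(1, 0.2), B = 1,
                           seed = 5)
  expect_true(all(attr(bs1, "support")$support %in% c(0, 100)))
})

test_that("support levels use the published thresholds", {
  lv <- support_level(c(91, 84, 59, 90, 60, 100, 0))
  expect_equal(as.character(lv),
               c("strong", "medium", "weak", "medium", "medium",
                 "strong", "weak"))
})

test_that("simulated low-rate data recovers the generating topology", {
  hits <- 0
  for (s in 1:10) {
    cfg <- sim_config(n_taxa = 6, n_genes = 120, n_chromosomes = 2,
                      budget = c(8, 20), seed = 400 + s)
    sim <- evolve(cfg)
    m <- encode(sim$leaves)
    tr <- infer_tree(m, model_params_from_genomes(sim$leaves))
    if (orderphy:::same_topology(tr, sim$tree)) hits <- hits + 1
  }
  expect_gte(hits, 9)
})
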