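make_bcm2 <- function(X, taxa = rownames(X)) {
  K <- ncol(X)
  m <- list(taxa = taxa,
            mat = matrix(as.integer(X), nrow(X), K,
                         dimnames = list(taxa, paste0("C:", seq_len(K)))),
            col_class = rep("C", K),
            adj_keys = numeric(0), families = seq_len(K),
            duplicate_table = data.frame(), include_telomeres = FALSE)
  class(m) <- "bcm"
  m
}

test_that("partials at a node match brute-force enumeration", {
  set.seed(14)
  p <- model_params(loss_rate = 0.9, gain_rate = 0.4)
  for (rep in 1:3) {
    tr <- random_tree(4)
    tr$edge.length <- stats::runif(nrow(tr$edge), 0.1, 1.2)
    X <- matrix(rbinom(4 * 5, 1, 0.5), 4, dimnames = list(tr$tip.label, NULL))
    m <- make_bcm2(X)
    for (node in orderphy:::ut_internal_nodes(orderphy:::as_utree(tr))) {
      got <- partial_likelihood(tr, m, p, node)
      expected <- enum_partials(tr, X, 0.9, 0.4, node)
      back <- got$partials * rep(exp(got$log_scale), each = 2)
      expect_equal(unname(back), expected, tolerance = 1e-10)
    }
  }
})

test_that("zero-length branches make child states decisive", {
  tr <- ape::read.tree(text = "((a:0,b:0):1,(c:1,d:1):1);")
  X <- matrix(c(1, 1, 0, 0), 4, 1, dimnames = list(letters[1:4], NULL))
  m <- make_bcm2(X)
  got <- partial_likelihood(tr, m, model_params(1, 0.5), node = 6)
  vals <- got$partials * rep(exp(got$log_scale), each = 2)
  # node 6 carries two zero-branch leaves in state 1: under T(0) = I the
  # absent-state partial is exactly zero whatever the third subtree says
  expect_equal(vals[1, 1], 0)
  expect_gt(vals[2, 1], 0)
  post <- posterior(tr, m, model_params(1, 0.5), node = 6)
  expect_gt(post[[1]], 0.5)
})

test_that("deep caterpillar partials stay finite under scaling", {
  n <- 12
  tr <- ape::stree(n, type = "left")
  tr$edge.length <- rep(0.1, nrow(tr$edge))
  X <- matrix(rbinom(n * 4, 1, 0.5), n,
              dimnames = list(tr$tip.label, NULL))
  m <- make_bcm2(X)
  got <- partial_likelihood(tr, m, model_params(1, 1e-3),
                            node = n + 2L)
  expect_true(all(is.finite(got$partials)))
  expect_true(all(is.finite(got$log_scale)))
  expect_true(all(got$partials >= 0))
  expect_true(any(got$partials > 0))
})

test_that("posteriors follow Bayes' rule against the enumeration oracle", {
  set.seed(21)
  tr <- random_tree(4)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.2, 1)
  X <- matrix(rbinom(4 * 6, 1, 0.5), 4, dimnames = list(tr$tip.label, NULL))
  m <- make_bcm2(X)
  p <- model_params(0.7, 0.2)
  f <- colMeans(X)
  for (node in 5:6) {
    got <- posterior(tr, m, p, node)
    part <- enum_partials(tr, X, 0.7, 0.2, node)
    expected <- f * part[2, ] / (f * part[2, ] + (1 - f) * part[1, ])
    expected[f == 0] <- 0; expected[f == 1] <- 1
    expect_equal(unname(got), unname(expected), tolerance = 1e-10)
  }
})

test_that("degenerate priors win over contradicting likelihoods", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  X <- matrix(c(1, 1, 1, 1, 0, 0, 0, 0), 4, 2,
              dimnames = list(letters[1:4], NULL))
  m <- make_bcm2(X)
  post <- posterior(tr, m, model_params(1, 0.5), node = 5)
  expect_equal(unname(post), c(1, 0))
})

test_that("reconstruct_all yields one record per internal node", {
  set.seed(2)
  cfg <- sim_config(n_taxa = 20, n_genes = 60, n_chromosomes = 2,
                    budget = c(2, 6), seed = 77)
  sim <- evolve(cfg)
  m <- encode(sim$leaves)
  tr <- optimize_branch_lengths(sim$tree, m, model_params(1, 1e-3),
                                max_rounds = 1)
  ap <- reconstruct_all(tr, m, model_params(1, 1e-3))
  expect_equal(length(ap$nodes), 18)
  expect_true(all(ap$prob >= 0 & ap$prob <= 1))
  # 4-leaf tree: n - 2 = 2 ancestors
  t4 <- random_tree(4)
  t4$edge.length <- rep(0.3, nrow(t4$edge))
  X <- matrix(rbinom(4 * 10, 1, 0.5), 4,
              dimnames = list(t4$tip.label, NULL))
  expect_equal(length(reconstruct_all(t4, make_bcm2(X),
                                      model_params(1, 0.3))$nodes), 2)
})

test_that("memoized reconstruction equals naive per-node re-rooting", {
  set.seed(27)
  tr <- random_tree(5)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.1, 1)
  X <- matrix(rbinom(5 * 8, 1, 0.5), 5, dimnames = list(tr$tip.label, NULL))
  m <- make_bcm2(X)
  p <- model_params(0.8, 0.25)
  ap <- reconstruct_all(tr, m, p)
  f <- colMeans(X)
  for (i in seq_along(ap$nodes)) {
    part <- enum_partials(tr, X, 0.8, 0.25, ap$nodes[i])
    expected <- f * part[2, ] / (f * part[2, ] + (1 - f) * part[1, ])
    expected[f %in% c(0, 1)] <- f[f %in% c(0, 1)]
    expect_equal(unname(ap$prob[i, ]), unname(expected), tolerance = 1e-9)
  }
})

test_that("posterior is monotone in the prior", {
  set.seed(35)
  tr <- random_tree(5)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.2, 0.8)
  X <- matrix(rbinom(5 * 10, 1, 0.5), 5, dimnames = list(tr$tip.label, NULL))
  m <- make_bcm2(X)
  p <- model_params(1, 0.3)
  f1 <- rep(0.2, ncol(X)); f2 <- rep(0.6, ncol(X))
  post1 <- posterior(tr, m, p, node = 6, prior = f1)
  post2 <- posterior(tr, m, p, node = 6, prior = f2)
  expect_true(all(post2 >= post1 - 1e-12))
})

test_that("uniform leaf states give the same posterior at every node", {
  tr <- random_tree(6, seed = 8)
  tr$edge.length <- rep(0.5, nrow(tr$edge))
  X <- matrix(rep(c(1, 0), each = 6), 6, 2,
              dimnames = list(tr$tip.label, NULL))
  m <- make_bcm2(X)
  ap <- reconstruct_all(tr, m, model_params(1, 0.4))
  expect_equal(unname(ap$prob[, 1]), rep(1, 4))
  expect_equal(unname(ap$prob[, 2]), rep(0, 4))
})

test_that("content selection applies a strict threshold", {
  ap <- structure(list(nodes = 7L,
                       prob = matrix(c(0.9, 0.1, 0.5), 1, 3,
                                     dimnames = list("7", NULL)),
                       col_class = rep("C", 3), families = c(1L, 2L, 3L),
                       adj_keys = numeric(0)),
                  class = "ancestor_posteriors")
  expect_equal(select_content(ap, 7, 0.5), 1L)  # 0.5 itself excluded
  expect_error(select_content(ap, 7, 0), "threshold")
  expect_error(select_content(ap, 99), "no reconstruction")
})

test_that("thresholded posteriors recover simulated ancestral content", {
  accs <- numeric(0)
  for (s in 1:10) {
    cfg <- sim_config(n_taxa = 6, n_genes = 200, n_chromosomes = 2,
                      budget = c(10, 30), seed = 500 + s)
    sim <- evolve(cfg)
    m <- encode(sim$leaves)
    p <- model_params_from_genomes(sim$leaves)
    tr <- optimize_branch_lengths(sim$tree, m, p)
    ap <- reconstruct_all(tr, m, p, prior = "stationary")
    for (nd in ap$nodes) {
      sel <- select_content(ap, nd, 0.5)
      tru <- orderphy:::genome_families(sim$ancestors[[as.character(nd)]])
      accs <- c(accs, length(intersect(sel, tru)) /
                  length(union(sel, tru)))
    }
  }
  expect_gt(mean(accs), 0.95)
})

test_that("whole-genome duplication doubles every chromosome", {
  g <- genome("anc", list(c(1, 2), c(3, -4)))
  d <- double_genome(g)
  expect_equal(length(d$chromosomes), 4)
  expect_identical(d$chromosomes[1:2], d$chromosomes[3:4])
  expect_equal(sum(lengths(d$chromosomes)), 8)
})
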