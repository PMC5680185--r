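genome_keys_telomeric <- function(g) {
  orderphy:::genome_adj_keys(g, telomeres = TRUE)
}

# genome-level oracle for the adjacency-change count of an event
symdiff_count <- function(before, after) {
  kb <- genome_keys_telomeric(before)
  ka <- genome_keys_telomeric(after)
  length(setdiff(kb, ka)) + length(setdiff(ka, kb))
}

test_that("random trees are unrooted binary with the requested leaves", {
  expect_error(random_tree(2), "at least 3")
  t3 <- random_tree(3, seed = 1)
  expect_equal(length(t3$tip.label), 3)
  t20 <- random_tree(20, seed = 1)
  expect_equal(length(t20$tip.label), 20)
  ut <- orderphy:::as_utree(t20)
  expect_equal(length(orderphy:::ut_internal_nodes(ut)), 18)
  expect_true(orderphy:::ut_is_binary_unrooted(ut))
  # distinct seeds give distinct topologies essentially always
  diffs <- sum(vapply(1:100, function(s) {
    !orderphy:::same_topology(random_tree(20, seed = s),
                              random_tree(20, seed = 10000 + s))
  }, logical(1)))
  expect_gte(diffs, 99)
})

test_that("event change counts equal the direct set-comparison oracle", {
  set.seed(61)
  g <- random_genome(40, C = 3, name = "g")
  for (kind in c("inversion", "translocation", "fusion", "fission",
                 "deletion", "insertion", "duplication")) {
    for (r in 1:10) {
      res <- apply_event(g, kind, sim_config(n_taxa = 3, n_genes = 40,
                                             n_chromosomes = 3,
                                             budget = c(0, 0)))
      if (is.null(res)) next
      expect_equal(res$changes, symdiff_count(g, res$genome),
                   info = paste(kind, r))
    }
  }
})

test_that("event mechanics match their definitions", {
  cfg <- sim_config(n_taxa = 3, n_genes = 30, n_chromosomes = 3,
                    budget = c(0, 0))
  g <- genome("g", list(1:10, 11:20, 21:30))
  # a mid-chromosome length-1 inversion replaces two adjacencies with
  # two new ones: symmetric difference 4
  ev <- list(kind = "inversion", chrom = 1L, start = 5L, len = 1L)
  after <- genome("g", orderphy:::exec_event(g$chromosomes, ev))
  expect_identical(after$chromosomes[[1]],
                   c(1:4, -5L, 6:10))
  expect_equal(symdiff_count(g, after), 4)
  # fusion concatenates and gains one internal adjacency
  evf <- list(kind = "fusion", chrom = 1L, chrom2 = 2L, flip = FALSE)
  fused <- genome("g", orderphy:::exec_event(g$chromosomes, evf))
  expect_equal(length(fused$chromosomes), 2)
  n_adj <- function(x) nrow(genome_to_adjacencies(x))
  expect_equal(n_adj(fused), n_adj(g) + 1)
  # WGD doubles gene count and populates the duplicate table
  res <- apply_event(g, "wgd", cfg)
  expect_equal(sum(lengths(res$genome$chromosomes)), 60)
  doubled <- genome("g2", res$genome$chromosomes)
  m <- encode(genome_set(list(doubled, g)))
  expect_equal(sort(unique(m$duplicate_table$family)), 1:30)
  expect_true(all(m$duplicate_table$copies == 2))
})

test_that("a zero budget leaves every genome at the root state", {
  cfg <- sim_config(n_taxa = 5, n_genes = 40, n_chromosomes = 2,
                    budget = c(0, 0), seed = 9)
  sim <- evolve(cfg)
  for (g in sim$leaves$genomes) {
    expect_identical(g$chromosomes,
                     sim$ancestors[[as.character(sim$root)]]$chromosomes)
  }
})

test_that("realized changes meet the budget without large overshoot", {
  cfg <- sim_config(n_taxa = 6, n_genes = 200, n_chromosomes = 4,
                    budget = c(40, 80), seed = 13)
  sim <- evolve(cfg)
  for (rec in sim$events) {
    expect_gte(rec$realized, rec$budget)
    # overshoot is at most one event's worth of changes
    maxev <- max(vapply(rec$events, function(e) e$changes, numeric(1)))
    expect_lte(rec$realized, rec$budget + maxev)
  }
})

test_that("replaying the event log reproduces every leaf exactly", {
  cfg <- sim_config(n_taxa = 5, n_genes = 80, n_chromosomes = 3,
                    budget = c(20, 50), seed = 21)
  sim <- evolve(cfg)
  ut <- orderphy:::as_utree(sim$tree)
  # reconstruct each node genome by replaying along the path from root
  genomes <- list()
  genomes[[as.character(sim$root)]] <-
    sim$ancestors[[as.character(sim$root)]]
  for (rec in sim$events) {
    parent_g <- genomes[[as.character(rec$parent)]]
    genomes[[as.character(rec$child)]] <- replay_events(parent_g,
                                                        rec$events)
  }
  for (i in seq_len(ut$n_tip)) {
    expect_identical(genomes[[as.character(i)]]$chromosomes,
                     sim$leaves$genomes[[ut$labels[i]]]$chromosomes)
  }
  # true ancestors are the recorded intermediates
  for (nd in names(sim$ancestors)) {
    expect_identical(genomes[[nd]]$chromosomes,
                     sim$ancestors[[nd]]$chromosomes)
  }
})

test_that("pure inversions conserve gene content", {
  cfg <- sim_config(n_taxa = 5, n_genes = 60, n_chromosomes = 2,
                    budget = c(20, 40), seed = 31,
                    event_mix = c(inversion = 1, translocation = 0,
                                  fusion = 0, fission = 0, deletion = 0,
                                  insertion = 0, duplication = 0))
  sim <- evolve(cfg)
  for (g in sim$leaves$genomes) {
    expect_equal(orderphy:::genome_families(g), 1:60)
  }
})

test_that("simulation is deterministic given the seed", {
  cfg <- sim_config(n_taxa = 5, n_genes = 50, n_chromosomes = 2,
                    budget = c(10, 30), seed = 77)
  s1 <- evolve(cfg); s2 <- evolve(cfg)
  expect_identical(lapply(s1$leaves$genomes, `[[`, "chromosomes"),
                   lapply(s2$leaves$genomes, `[[`, "chromosomes"))
  expect_identical(s1$tree$edge, s2$tree$edge)
})

test_that("wgd edges double the genome on that lineage", {
  cfg <- sim_config(n_taxa = 4, n_genes = 20, n_chromosomes = 2,
                    budget = c(0, 0), seed = 3, wgd_edges = 1L)
  sim <- evolve(cfg)
  ut <- orderphy:::as_utree(sim$tree)
  g1 <- sim$leaves$genomes[[ut$labels[1]]]
  expect_equal(sum(lengths(g1$chromosomes)), 40)
})

test_that("logged change counts equal the genome-level oracle on replay", {
  cfg <- sim_config(n_taxa = 4, n_genes = 50, n_chromosomes = 3,
                    budget = c(15, 40), seed = 91)
  sim <- evolve(cfg)
  genomes <- list()
  genomes[[as.character(sim$root)]] <-
    sim$ancestors[[as.character(sim$root)]]
  for (rec in sim$events) {
    cur <- genomes[[as.character(rec$parent)]]
    for (ev in rec$events) {
      nxt <- replay_events(cur, list(ev))
      expect_equal(ev$changes, symdiff_count(cur, nxt), info = ev$kind)
      cur <- nxt
    }
    genomes[[as.character(rec$child)]] <- cur
  }
})
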