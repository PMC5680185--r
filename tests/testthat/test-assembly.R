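# random assembly instance: n genes, sharp or noisy posteriors
random_tsp <- function(n, seed, sharp = FALSE) {
  set.seed(seed)
  fams <- seq_len(n)
  # a hidden true order with high-probability adjacencies plus noise
  perm <- sample(fams) * sample(c(-1L, 1L), n, replace = TRUE)
  re <- ifelse(perm[-n] > 0, 2 * perm[-n] + 1, -2 * perm[-n])
  le <- ifelse(perm[-1] > 0, 2 * perm[-1], -2 * perm[-1] + 1)
  truth <- data.frame(e1 = re, e2 = le,
                      prob = if (sharp) 0.99 else stats::runif(n - 1, 0.5, 1))
  noise_n <- 2 * n
  ne1 <- 2 * sample(fams, noise_n, replace = TRUE) +
    sample(0:1, noise_n, replace = TRUE)
  ne2 <- 2 * sample(fams, noise_n, replace = TRUE) +
    sample(0:1, noise_n, replace = TRUE)
  ok <- (ne1 %/% 2) != (ne2 %/% 2)
  noise <- data.frame(e1 = ne1[ok], e2 = ne2[ok],
                      prob = stats::runif(sum(ok), 0,
                                          if (sharp) 0.2 else 0.8))
  list(g = build_tsp(fams, rbind(truth, noise)), truth_order = perm)
}

same_arrangement <- function(tour, perm) {
  identical(tour, perm) || identical(tour, -rev(perm))
}

test_that("dominant adjacency posteriors drive the tour", {
  g <- build_tsp(1:2, data.frame(e1 = 3, e2 = 4, prob = 0.9))  # {1t, 2h}
  sol <- solve_tour(g, method = "exact")
  expect_true(same_arrangement(sol$tour, c(1L, 2L)))
  # single family: trivial chromosome
  g1 <- build_tsp(5L, data.frame(e1 = numeric(0), e2 = numeric(0),
                                 prob = numeric(0)))
  expect_equal(solve_tour(g1)$tour, 5L)
})

test_that("flat posteriors give a deterministic tour", {
  probs <- data.frame(e1 = c(2, 2, 4), e2 = c(4, 6, 6),
                      prob = rep(0.5, 3))
  g <- build_tsp(1:3, probs)
  s1 <- solve_tour(g, seed = 7, method = "heuristic")
  s2 <- solve_tour(g, seed = 7, method = "heuristic")
  expect_identical(s1$tour, s2$tour)
  expect_equal(s1$cost, s2$cost)
})

test_that("heuristic tours match the exact optimum on small instances", {
  worse <- 0
  for (r in 1:100) {
    n <- 4L + (r %% 5L)
    inst <- random_tsp(n, seed = 900 + r)
    he <- solve_tour(inst$g, seed = r, method = "heuristic")
    ex <- solve_tour(inst$g, method = "exact")
    expect_gte(he$cost, ex$cost - 1e-8)  # never below the optimum
    if (he$cost > ex$cost + 1e-8) worse <- worse + 1
  }
  expect_lte(worse, 5)
})

test_that("polish never increases the tour cost", {
  for (r in 1:10) {
    inst <- random_tsp(30, seed = 70 + r)
    g <- inst$g
    env <- orderphy:::tsp_cost_env(g)
    set.seed(r)
    raw <- sample(inst$truth_order)  # scrambled starting cycle
    polished <- orderphy:::tour_polish(raw, g, env)
    expect_lte(orderphy:::tour_cost_cycle(polished, g, env),
               orderphy:::tour_cost_cycle(raw, g, env) + 1e-9)
    expect_setequal(abs(polished), abs(raw))
  }
})

test_that("sharp posteriors reconstruct a 50-gene order exactly", {
  hits <- 0
  for (s in 1:10) {
    inst <- random_tsp(50, seed = 1200 + s, sharp = TRUE)
    sol <- solve_tour(inst$g, seed = s, method = "heuristic")
    if (same_arrangement(sol$tour, inst$truth_order) ||
        same_arrangement(sol$tour, inst$truth_order * 1L)) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("every selected family appears exactly once in the output", {
  inst <- random_tsp(40, seed = 55)
  sol <- solve_tour(inst$g, seed = 1, method = "heuristic")
  c1 <- genome("c1", list(1:20, 21:40))
  c2 <- genome("c2", list(1:40))
  out <- split_into_chromosomes(sol$tour, inst$g, c1, c2)
  expect_setequal(abs(unlist(out$chromosomes)), 1:40)
  expect_equal(sum(lengths(out$chromosomes)), 40)
})

test_that("telomere priority rules order the cuts", {
  # toy: 9 genes in a known tour; target 3 chromosomes
  tour <- 1:9
  g <- build_tsp(1:9, data.frame(
    e1 = 2 * (1:8) + 1, e2 = 2 * (2:9), prob = 0.9))
  # children both end chromosomes at gene 3 (tail) / gene 4 (head);
  # parent alone suggests a boundary after gene 6
  c1 <- genome("c1", list(1:3, 4:9))
  c2 <- genome("c2", list(1:3, 4:9))
  par <- genome("p", list(1:6, 7:9))
  out <- split_into_chromosomes(tour, g, c1, c2, parent = par, target = 2)
  # the class-2 candidate (both children) must win over class-4 (parent)
  expect_identical(out$chromosomes, list(c(1L, 2L, 3L), c(4L, 5L, 6L,
                                                          7L, 8L, 9L)))
  out3 <- split_into_chromosomes(tour, g, c1, c2, parent = par, target = 3)
  expect_identical(out3$chromosomes,
                   list(c(1L, 2L, 3L), c(4L, 5L, 6L), c(7L, 8L, 9L)))
  # target 1: no cuts beyond opening the cycle
  out1 <- split_into_chromosomes(tour, g, c1, c2, parent = par, target = 1)
  expect_equal(length(out1$chromosomes), 1)
})

test_that("parent & children consensus bounds a single chromosome", {
  # all three genomes agree chromosomes run 1..9: one chromosome, with
  # extremities 1h and 9t telomeric
  tour <- 1:9
  g <- build_tsp(1:9, data.frame(
    e1 = 2 * (1:8) + 1, e2 = 2 * (2:9), prob = 0.9))
  gen <- genome("x", list(1:9))
  out <- split_into_chromosomes(tour, g, gen, gen, parent = gen,
                                target = 1)
  expect_identical(out$chromosomes, list(1:9))
})

test_that("default chromosome-count target is the median of the trio", {
  tour <- 1:12
  g <- build_tsp(1:12, data.frame(
    e1 = 2 * (1:11) + 1, e2 = 2 * (2:12), prob = 0.9))
  par <- genome("p", list(1:4, 5:8, 9:12))          # 3 chromosomes
  c1 <- genome("c1", list(1:6, 7:12))               # 2
  c2 <- genome("c2", list(1:3, 4:6, 7:9, 10:12))    # 4
  out <- split_into_chromosomes(tour, g, c1, c2, parent = par)
  expect_equal(length(out$chromosomes), 3)
})

test_that("tour cost decomposes into the retained adjacency costs", {
  inst <- random_tsp(20, seed = 5)
  g <- inst$g
  sol <- solve_tour(g, seed = 2, method = "heuristic")
  env <- orderphy:::tsp_cost_env(g)
  n <- length(sol$tour)
  inner_keys <- orderphy:::adj_key(
    orderphy:::right_ext(sol$tour[-n]),
    orderphy:::left_ext(sol$tour[-1]))
  inner_cost <- sum(vapply(as.character(inner_keys), function(k) {
    v <- env[[k]]
    if (is.null(v)) g$base_cost else v
  }, numeric(1)))
  caps <- orderphy:::tsp_cap_cost(g, orderphy:::left_ext(sol$tour[1])) +
    orderphy:::tsp_cap_cost(g, orderphy:::right_ext(sol$tour[n]))
  expect_equal(sol$cost, inner_cost + caps, tolerance = 1e-9)
})
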