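#' Expected genome-level event counts
#'
#' Container for the estimated numbers of rearrangement (`R`),
#' duplication (`D`), insertion (`I`) and deletion (`d`) events for a
#' lineage, together with its gene count `n` and chromosome count `C`.
#' These feed the adjacency gain/loss probabilities of the two-state
#' model.
#'
#' @param R,D,I,d expected event counts (non-negative).
#' @param n gene count (>= 1).
#' @param C chromosome count (>= 1).
#' @return an object of class `event_rates`.
#' @export
event_rates <- function(R = 0, D = 0, I = 0, d = 0, n, C) {
  vals <- c(R = R, D = D, I = I, d = d)
  if (any(vals < 0)) stop("event counts must be non-negative")
  if (n < 1 || C < 1) stop("need n >= 1 and C >= 1")
  structure(list(R = R, D = D, I = I, d = d, n = n, C = C),
            class = "event_rates")
}

#' Probability of losing an existing gene adjacency
#'
#' A genome with `n` genes and `C` chromosomes carries `n + C` adjacencies
#' (counting one telomeric join per chromosome); every rearrangement,
#' duplication, insertion or deletion event removes two adjacencies, so
#' the per-adjacency loss probability is `2(R + D + I + d) / (n + C)`,
#' clamped to `[0, 1]`.
#'
#' @param er an [event_rates()] object.
#' @return a probability.
#' @export
adjacency_loss_prob <- function(er) {
  stopifnot(inherits(er, "event_rates"))
  min(1, 2 * (er$R + er$D + er$I + er$d) / (er$n + er$C))
}

#' Probability of gaining a specific new gene adjacency
#'
#' Each event also creates two new adjacencies, drawn from the
#' `choose(2n + 2, 2)` possible pairings of the `2n` gene extremities
#' plus telomeres, giving `2(R + D + I + d) / choose(2n + 2, 2)`,
#' clamped to `[0, 1]`.  The gain probability is orders of magnitude
#' smaller than the loss probability for any realistic `n`, which is the
#' asymmetry the two-state model encodes.
#'
#' @param er an [event_rates()] object.
#' @return a probability.
#' @export
adjacency_gain_prob <- function(er) {
  stopifnot(inherits(er, "event_rates"))
  ends <- (2 * er$n + 2) * (2 * er$n + 1) / 2
  min(1, 2 * (er$R + er$D + er$I + er$d) / ends)
}

#' Transition matrix of the two-state presence/absence chain
#'
#' Continuous-time Markov chain on states `0` (absent) and `1` (present)
#' with gain rate `mu` (0 -> 1) and loss rate `lambda` (1 -> 0).  Over a
#' branch of length `t`:
#' \deqn{P(1 \to 0; t) = \frac{\lambda}{\lambda+\mu}(1 - e^{-(\lambda+\mu)t})}
#' \deqn{P(0 \to 1; t) = \frac{\mu}{\lambda+\mu}(1 - e^{-(\lambda+\mu)t})}
#' `T(0)` is the identity and rows tend to the stationary distribution
#' `(lambda, mu) / (lambda + mu)` as `t` grows.
#'
#' @param loss_rate,gain_rate positive rates (`lambda`, `mu`).
#' @param t branch length (>= 0).
#' @return a 2x2 row-stochastic matrix with dimnames `c("0","1")`.
#' @export
transition_matrix <- function(loss_rate, gain_rate, t) {
  if (loss_rate <= 0 || gain_rate <= 0) stop("rates must be positive")
  if (t < 0) stop("branch length must be non-negative")
  s <- loss_rate + gain_rate
  w <- 1 - exp(-s * t)
  p01 <- gain_rate / s * w
  p10 <- loss_rate / s * w
  matrix(c(1 - p01, p10, p01, 1 - p10), 2, 2,
         dimnames = list(c("0", "1"), c("0", "1")))
}

#' Reduce a genome to one exemplar copy per family
#'
#' Keeps the first occurrence of each family (scanning chromosomes in
#' order) and drops later copies, the simplest reproducible rule for
#' computing rearrangement distances in the presence of duplicates.
#'
#' @param g a [genome()].
#' @return a duplicate-free [genome()] (empty chromosomes are dropped).
#' @export
reduce_to_exemplars <- function(g) {
  stopifnot(inherits(g, "genome"))
  seen <- integer(0)
  chroms <- list()
  for (ch in g$chromosomes) {
    keep <- !(abs(ch) %in% seen)
    # within-chromosome duplicates: keep first occurrence only
    first <- !duplicated(abs(ch))
    keep <- keep & first
    seen <- c(seen, abs(ch[keep]))
    if (any(keep)) chroms[[length(chroms) + 1L]] <- ch[keep]
  }
  if (length(chroms) == 0) stop("exemplar reduction left an empty genome")
  genome(g$name, chroms)
}

restrict_to_families <- function(g, fams) {
  chroms <- list()
  for (ch in g$chromosomes) {
    keep <- abs(ch) %in% fams
    if (any(keep)) chroms[[length(chroms) + 1L]] <- ch[keep]
  }
  if (length(chroms) == 0) {
    stop("no shared gene content between genomes")
  }
  genome(g$name, chroms)
}

#' Double-cut-and-join (DCJ) distance between two genomes
#'
#' Genomes are first reduced to exemplars ([reduce_to_exemplars()]) and
#' restricted to their shared families, then the classical
#' adjacency-graph formula is applied: `d = N - (cycles + odd_paths / 2)`,
#' where `N` is the shared gene count and components are counted in the
#' graph whose vertices are the adjacencies and telomeres of the two
#' genomes, connected once per shared gene extremity.
#'
#' @param a,b [genome()] objects.
#' @return a non-negative integer; 0 iff the shared-content gene orders
#'   are identical.
#' @export
dcj_distance <- function(a, b) {
  a <- reduce_to_exemplars(a)
  b <- reduce_to_exemplars(b)
  shared <- intersect(genome_families(a), genome_families(b))
  if (length(shared) == 0) stop("no shared gene content between genomes")
  a <- restrict_to_families(a, shared)
  b <- restrict_to_families(b, shared)
  exts <- sort(c(2 * shared, 2 * shared + 1))
  pairing <- function(g) {
    # group id per extremity: adjacent extremities share a group,
    # telomeric extremities get singleton groups
    grp <- seq_along(exts)
    names(grp) <- exts
    gid <- 0L
    for (ch in g$chromosomes) {
      n <- length(ch)
      if (n >= 2) {
        r <- right_ext(ch[-n]); l <- left_ext(ch[-1])
        for (k in seq_len(n - 1)) {
          gid <- gid + 1L
          grp[as.character(c(r[k], l[k]))] <- -gid
        }
      }
    }
    grp
  }
  ga <- pairing(a); gb <- pairing(b)
  # union-find over vertices: A-groups and B-groups
  va <- match(ga, unique(ga))
  vb <- match(gb, unique(gb)) + max(va)
  parent <- seq_len(max(vb))
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (i in seq_along(exts)) {
    ra <- find(va[i]); rb <- find(vb[i])
    if (ra != rb) parent[rb] <- ra
  }
  comp_of_ext <- vapply(va, find, integer(1))
  edges_per_comp <- table(comp_of_ext)
  # telomere vertices = singleton groups; find their components
  tel_vertices <- c(unique(va[ga > 0]), unique(vb[gb > 0]))
  tel_comp <- vapply(tel_vertices, find, integer(1))
  tel_per_comp <- table(tel_comp)
  comps <- names(edges_per_comp)
  tel_counts <- as.integer(tel_per_comp[comps])
  tel_counts[is.na(tel_counts)] <- 0L
  cycles <- sum(tel_counts == 0L)
  odd_paths <- sum(tel_counts > 0L & as.integer(edges_per_comp) %% 2 == 1L)
  as.integer(length(shared) - (cycles + odd_paths / 2))
}

#' Decompose the difference between two genomes into event classes
#'
#' Rearrangements are counted as the DCJ distance on the shared gene
#' content (after exemplar reduction); gene losses are families of `a`
#' absent from `b` and gene gains the reverse.
#'
#' @param a,b [genome()] objects.
#' @return an object of class `event_breakdown` with fields
#'   `rearrangements`, `gene_losses`, `gene_gains`, `total`.
#' @export
event_breakdown <- function(a, b) {
  fa <- genome_families(a); fb <- genome_families(b)
  losses <- length(setdiff(fa, fb))
  gains <- length(setdiff(fb, fa))
  rearr <- dcj_distance(a, b)
  structure(list(rearrangements = rearr, gene_losses = losses,
                 gene_gains = gains, total = rearr + losses + gains),
            class = "event_breakdown")
}

#' @export
print.event_breakdown <- function(x, ...) {
  cat("<event_breakdown> rearrangements:", x$rearrangements,
      "losses:", x$gene_losses, "gains:", x$gene_gains,
      "total:", x$total, "\n")
  invisible(x)
}
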