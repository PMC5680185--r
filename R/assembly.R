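# Ancestral chromosome assembly.
#
# Selected ancestral genes are assembled into chromosomes by maximising
# the product of adjacency posteriors, equivalently minimising the sum of
# -log(eps + P) edge costs over a Hamiltonian cycle through one "cap"
# node (the travelling-salesman formulation).  Genes are contracted
# nodes with two ports (head/tail), so the forced head-tail pairing never
# appears explicitly in the solver.

#' Build the adjacency-assembly TSP instance for an ancestor
#'
#' Nodes are the two extremities of every selected family plus one cap
#' node standing for chromosome ends; the cost of joining two extremities
#' is `-log(eps + P)` where `P` is the posterior probability of that
#' adjacency (zero for pairs never observed or estimated).  Telomeric
#' posteriors, when present among `adj_probs`, set the cap edge costs;
#' otherwise cap edges carry the uniform zero-probability cost.
#'
#' @param families integer vector of selected family IDs (non-empty).
#' @param adj_probs data frame with extremity key columns `e1`, `e2` and
#'   `prob` (e.g. from an [reconstruct_all()] result); rows touching
#'   unselected families are dropped.
#' @param eps floor added to posteriors before taking logs.
#' @return an object of class `adjacency_tsp`.
#' @export
build_tsp <- function(families, adj_probs, eps = 1e-9) {
  families <- sort(unique(as.integer(families)))
  if (length(families) == 0) stop("no families selected")
  if (is.null(adj_probs) || nrow(adj_probs) == 0) {
    adj_probs <- data.frame(e1 = numeric(0), e2 = numeric(0),
                            prob = numeric(0))
  }
  stopifnot(all(c("e1", "e2", "prob") %in% names(adj_probs)))
  in_set <- function(e) e == 0 | (e %/% 2) %in% families
  keep <- in_set(adj_probs$e1) & in_set(adj_probs$e2)
  ap <- adj_probs[keep, , drop = FALSE]
  tel <- ap$e1 == 0 | ap$e2 == 0
  cand <- ap[!tel & ap$prob > 0, , drop = FALSE]
  cand$cost <- -log(eps + cand$prob)
  cand <- cand[order(cand$cost, cand$e1, cand$e2), , drop = FALSE]
  cap <- ap[tel, , drop = FALSE]
  cap_ext <- ifelse(cap$e1 == 0, cap$e2, cap$e1)
  structure(list(families = families,
                 cand = cand,
                 cap_prob = stats::setNames(cap$prob, cap_ext),
                 eps = eps, base_cost = -log(eps)),
            class = "adjacency_tsp")
}

#' @export
print.adjacency_tsp <- function(x, ...) {
  cat("<adjacency_tsp>", length(x$families), "genes,",
      nrow(x$cand), "candidate adjacencies\n")
  invisible(x)
}

# cost environment: candidate adjacency key -> cost; default base_cost.
# Cap (telomere) edges are stored under adj_key(0, e) = e, which cannot
# collide with gene-gene keys (those are at least 2^27).
tsp_cost_env <- function(g) {
  env <- new.env(parent = emptyenv(), size = max(29L, nrow(g$cand)))
  if (nrow(g$cand)) {
    keys <- as.character(adj_key(g$cand$e1, g$cand$e2))
    for (i in seq_along(keys)) {
      cur <- env[[keys[i]]]
      if (is.null(cur) || g$cand$cost[i] < cur) {
        env[[keys[i]]] <- g$cand$cost[i]
      }
    }
  }
  for (e in names(g$cap_prob)) {
    cost <- -log(g$eps + unname(g$cap_prob[[e]]))
    cur <- env[[e]]
    if (is.null(cur) || cost < cur) env[[e]] <- cost
  }
  env
}

tsp_cost_of <- function(env, base, e1, e2) {
  v <- env[[as.character(adj_key(e1, e2))]]
  if (is.null(v)) base else v
}

tsp_cap_cost <- function(g, e) {
  p <- g$cap_prob[as.character(e)]
  -log(g$eps + if (is.na(p)) 0 else unname(p))
}

# signed tour (cycle) cost including cap edges given a cut position
tour_cycle_keys <- function(s) {
  n <- length(s)
  adj_key(right_ext(s), left_ext(s[c(2:n, 1)]))
}

#' Heuristic or exact tour through the assembly graph
#'
#' The heuristic builds a tour by greedy edge matching (candidate
#' adjacencies accepted in increasing cost under port and subtour
#' constraints), joins the leftover path ends, and improves the cycle by
#' candidate-guided 2-opt reversals and single-gene or-opt relocations;
#' small instances can be restarted from double-bridge perturbations.
#' The exact mode is a Held-Karp dynamic program over gene subsets and
#' entry ports, feasible up to a dozen genes and used as the reference
#' in tests.
#'
#' @param g an [build_tsp()] instance.
#' @param seed integer seed (restart perturbations).
#' @param method `"heuristic"`, `"exact"`, or `"auto"` (exact for up to
#'   10 genes).
#' @param restarts number of perturbation restarts (heuristic, small
#'   instances).
#' @return a list with `tour` (signed family vector; the cycle opened at
#'   the cap, i.e. one linear arrangement), `cost` (cycle cost including
#'   both cap edges), and `method`.
#' @export
solve_tour <- function(g, seed = 1L, method = c("auto", "heuristic",
                                                "exact"), restarts = 2L) {
  stopifnot(inherits(g, "adjacency_tsp"))
  method <- match.arg(method)
  n <- length(g$families)
  if (method == "auto") method <- if (n <= 10) "exact" else "heuristic"
  if (n == 1) {
    return(list(tour = g$families, cost = 2 * tsp_cap_cost(g, 2 * g$families),
                method = method))
  }
  set.seed(seed)
  if (method == "exact") solve_tour_exact(g) else solve_tour_heuristic(
    g, restarts)
}

solve_tour_heuristic <- function(g, restarts = 2L) {
  fams <- g$families
  n <- length(fams)
  env <- tsp_cost_env(g)
  fam_idx <- function(f) match(f, fams)
  # --- greedy edge matching -------------------------------------------
  occupied <- new.env(parent = emptyenv())
  partner <- new.env(parent = emptyenv())
  uf <- seq_len(n)
  find <- function(x) {
    while (uf[x] != x) { uf[x] <<- uf[uf[x]]; x <- uf[x] }
    x
  }
  if (nrow(g$cand)) {
    f1v <- match(g$cand$e1 %/% 2, fams)
    f2v <- match(g$cand$e2 %/% 2, fams)
    for (i in seq_len(nrow(g$cand))) {
      e1 <- g$cand$e1[i]; e2 <- g$cand$e2[i]
      k1 <- as.character(e1); k2 <- as.character(e2)
      if (!is.null(occupied[[k1]]) || !is.null(occupied[[k2]])) next
      f1 <- f1v[i]; f2 <- f2v[i]
      r1 <- find(f1); r2 <- find(f2)
      if (r1 == r2) next
      uf[r2] <- r1
      occupied[[k1]] <- TRUE; occupied[[k2]] <- TRUE
      partner[[k1]] <- e2; partner[[k2]] <- e1
    }
  }
  # --- join path ends into one cycle ----------------------------------
  roots <- vapply(seq_len(n), find, integer(1))
  free_exts <- lapply(seq_len(n), function(i) {
    exts <- c(2 * fams[i], 2 * fams[i] + 1)
    exts[vapply(exts, function(e) is.null(occupied[[as.character(e)]]),
                logical(1))]
  })
  path_ends <- split(unlist(free_exts), roots[rep(seq_len(n),
                                                  lengths(free_exts))])
  path_order <- names(path_ends)[order(vapply(path_ends, min, numeric(1)))]
  cand_by_ext <- NULL
  if (nrow(g$cand)) {
    cb <- rbind(data.frame(e = g$cand$e1, p = g$cand$e2, cost = g$cand$cost),
                data.frame(e = g$cand$e2, p = g$cand$e1, cost = g$cand$cost))
    cand_by_ext <- split(cb[, c("p", "cost")], cb$e)
  }
  link <- function(a, b) {
    partner[[as.character(a)]] <- b
    partner[[as.character(b)]] <- a
  }
  cur_path <- path_order[1]
  ends <- sort(path_ends[[cur_path]])
  start_ext <- ends[1]
  cur_end <- ends[length(ends)]
  remaining <- setdiff(path_order, cur_path)
  end_owner <- new.env(parent = emptyenv())
  for (r in remaining) {
    for (e in path_ends[[r]]) end_owner[[as.character(e)]] <- r
  }
  while (length(remaining)) {
    chosen <- NULL
    cands <- cand_by_ext[[as.character(cur_end)]]
    if (!is.null(cands)) {
      ok <- vapply(cands$p, function(x)
        !is.null(end_owner[[as.character(x)]]), logical(1))
      if (any(ok)) {
        cands <- cands[ok, , drop = FALSE]
        chosen <- cands$p[order(cands$cost, cands$p)][1]
      }
    }
    if (is.null(chosen)) {
      r <- remaining[1]
      chosen <- min(path_ends[[r]])
    }
    r <- end_owner[[as.character(chosen)]]
    link(cur_end, chosen)
    es <- path_ends[[r]]
    cur_end <- if (length(es) > 1) es[es != chosen][1] else chosen
    for (e in es) rm(list = as.character(e), envir = end_owner)
    remaining <- setdiff(remaining, r)
  }
  link(cur_end, start_ext)
  # --- walk the cycle into a signed gene sequence ---------------------
  s <- integer(n)
  f0 <- fams[1]
  cur_fam <- f0; cur_sign <- 1L
  exit_ext <- 2 * f0 + 1   # tail of +f0
  for (i in seq_len(n)) {
    s[i] <- as.integer(cur_sign * cur_fam)
    nxt <- partner[[as.character(exit_ext)]]
    cur_fam <- nxt %/% 2
    cur_sign <- if (nxt %% 2 == 0) 1L else -1L  # enter via head => forward
    exit_ext <- if (nxt %% 2 == 0) nxt + 1 else nxt - 1
  }
  # insert the cap node (0) where it absorbs the most cost, then let
  # the polish moves relocate it like any other node
  keys <- as.character(tour_cycle_keys(s))
  costs <- vapply(keys, function(k) {
    v <- env[[k]]
    if (is.null(v)) g$base_cost else v
  }, numeric(1))
  caps_r <- vapply(right_ext(s), function(e) tsp_cap_cost(g, e), numeric(1))
  caps_l <- vapply(left_ext(s[c(2:n, 1)]), function(e) tsp_cap_cost(g, e),
                   numeric(1))
  s <- append(s, 0L, after = which.min(caps_r + caps_l - costs))
  s <- tour_polish(s, g, env)
  best <- s; best_cost <- tour_cost_cycle(best, g, env)
  m <- length(s)
  n_restarts <- if (n <= 12) max(restarts, 8L) else restarts
  if (n_restarts > 0 && n >= 4 && n <= 500) {
    for (r in seq_len(n_restarts)) {
      pert <- if (n >= 8) double_bridge(best) else
        as.integer(sample(abs(best)) * sample(c(-1L, 1L), m,
                                              replace = TRUE))
      pert <- tour_polish(pert, g, env)
      pc <- tour_cost_cycle(pert, g, env)
      if (pc < best_cost - 1e-12) { best <- pert; best_cost <- pc }
    }
  }
  i0 <- which(best == 0L)
  tour <- if (i0 == m) best[-m] else
    c(best[(i0 + 1):m], best[seq_len(i0 - 1L)])
  list(tour = as.integer(tour), cost = unname(best_cost),
       method = "heuristic")
}

# cycle cost without cap (sum of -log(eps + P) over realized adjacencies)
tour_cost_cycle <- function(s, g, env) {
  keys <- as.character(tour_cycle_keys(s))
  sum(vapply(keys, function(k) {
    v <- env[[k]]
    if (is.null(v)) g$base_cost else v
  }, numeric(1)))
}

double_bridge <- function(s) {
  n <- length(s)
  if (n < 8) return(s)
  cuts <- sort(sample(2:(n - 1), 3))
  c(s[1:(cuts[1] - 1)], s[cuts[2]:(cuts[3] - 1)],
    s[cuts[1]:(cuts[2] - 1)], s[cuts[3]:n])
}

# candidate-guided 2-opt / or-opt improvement on the cycle
tour_polish <- function(s, g, env, max_passes = 3L) {
  n <- length(s)
  if (n < 3 || nrow(g$cand) == 0) return(s)
  pos_of <- function() {
    p <- integer(max(abs(s)))
    idx <- abs(s)
    keep <- idx > 0L
    p[idx[keep]] <- seq_len(n)[keep]
    p
  }
  pos <- pos_of()
  cost_of <- function(e1, e2) tsp_cost_of(env, g$base_cost, e1, e2)
  # guide moves by candidates with non-negligible posterior; weaker ones
  # still enter through the greedy construction and the cost lookups
  active <- which(g$cand$prob >= 0.01)
  ord <- active[order(g$cand$cost[active])]
  for (pass in seq_len(max_passes)) {
    changed <- FALSE
    for (ci in ord) {
      e1 <- g$cand$e1[ci]; e2 <- g$cand$e2[ci]
      i <- pos[e1 %/% 2]; j <- pos[e2 %/% 2]
      if (i == j) next  # same gene (within-family pseudo adjacency)
      r1 <- right_ext(s[i]) == e1
      r2 <- right_ext(s[j]) == e2
      nxt <- function(k) if (k == n) 1L else k + 1L
      prv <- function(k) if (k == 1L) n else k - 1L
      # already realized?
      if ((r1 && !r2 && nxt(i) == j) || (r2 && !r1 && nxt(j) == i)) next
      new_cost <- g$cand$cost[ci]
      if (r1 && r2) {
        a <- min(i, j); b <- max(i, j)
        if (b - a < 1) next
        rem <- cost_of(right_ext(s[a]), left_ext(s[nxt(a)])) +
          cost_of(right_ext(s[b]), left_ext(s[nxt(b)]))
        add <- new_cost +
          cost_of(left_ext(s[a + 1]), left_ext(s[nxt(b)]))
        if (add < rem - 1e-12) {
          idx <- (a + 1):b
          s[idx] <- -rev(s[idx])
          pos <- pos_of()
          changed <- TRUE
        }
      } else if (!r1 && !r2) {
        a <- min(i, j); b <- max(i, j)
        if (b - a < 1) next
        rem <- cost_of(right_ext(s[prv(a)]), left_ext(s[a])) +
          cost_of(right_ext(s[b - 1]), left_ext(s[b]))
        add <- new_cost +
          cost_of(right_ext(s[prv(a)]), right_ext(s[b - 1]))
        if (add < rem - 1e-12) {
          idx <- a:(b - 1)
          s[idx] <- -rev(s[idx])
          pos <- pos_of()
          changed <- TRUE
        }
      } else {
        # mixed facing: relocate the left-facing gene after the
        # right-facing one (or-opt, single gene)
        if (r1) { ir <- i; jl <- j } else { ir <- j; jl <- i }
        if (nxt(ir) == jl) next
        if (jl == ir || prv(ir) == jl) next
        gene <- s[jl]
        rem <- cost_of(right_ext(s[ir]), left_ext(s[nxt(ir)])) +
          cost_of(right_ext(s[prv(jl)]), left_ext(s[jl])) +
          cost_of(right_ext(s[jl]), left_ext(s[nxt(jl)]))
        add <- new_cost +
          cost_of(right_ext(gene), left_ext(s[nxt(ir)])) +
          cost_of(right_ext(s[prv(jl)]), left_ext(s[nxt(jl)]))
        if (add < rem - 1e-12) {
          s2 <- s[-jl]
          ir2 <- if (jl < ir) ir - 1L else ir
          s <- append(s2, gene, after = ir2)
          pos <- pos_of()
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  if (n <= 100) s <- tour_polish_exhaustive(s, g, env)
  s
}

# plain first-improvement 2-opt (signed reversals, including single-gene
# sign flips) and single-gene or-opt over all positions; affordable for
# small tours and used to finish what the candidate-guided pass started
tour_polish_exhaustive <- function(s, g, env, max_sweeps = 50L) {
  n <- length(s)
  if (n < 3) return(s)
  cost_of <- function(e1, e2) tsp_cost_of(env, g$base_cost, e1, e2)
  nxt <- function(k) if (k == n) 1L else k + 1L
  prv <- function(k) if (k == 1L) n else k - 1L
  for (sweep in seq_len(max_sweeps)) {
    changed <- FALSE
    for (a in seq_len(n)) {
      for (b in a:n) {
        if (a == 1L && b == n) next
        rem <- cost_of(right_ext(s[prv(a)]), left_ext(s[a])) +
          cost_of(right_ext(s[b]), left_ext(s[nxt(b)]))
        add <- cost_of(right_ext(s[prv(a)]), right_ext(s[b])) +
          cost_of(left_ext(s[a]), left_ext(s[nxt(b)]))
        if (add < rem - 1e-12) {
          s[a:b] <- -rev(s[a:b])
          changed <- TRUE
        }
      }
    }
    for (j in seq_len(n)) {
      moved <- FALSE
      for (i in seq_len(n)) {
        if (i == j || i == prv(j)) next
        base_rem <- cost_of(right_ext(s[prv(j)]), left_ext(s[j])) +
          cost_of(right_ext(s[j]), left_ext(s[nxt(j)])) +
          cost_of(right_ext(s[i]), left_ext(s[nxt(i)]))
        bridge <- cost_of(right_ext(s[prv(j)]), left_ext(s[nxt(j)]))
        for (o in c(1L, -1L)) {
          gene <- o * s[j]
          add <- bridge +
            cost_of(right_ext(s[i]), left_ext(gene)) +
            cost_of(right_ext(gene), left_ext(s[nxt(i)]))
          if (add < base_rem - 1e-12) {
            s2 <- s[-j]
            i2 <- if (j < i) i - 1L else i
            s <- append(s2, gene, after = i2)
            changed <- TRUE
            moved <- TRUE
            break
          }
        }
        if (moved) break
      }
    }
    if (!changed) break
  }
  s
}

# Held-Karp DP over gene subsets with entry/exit ports; cycle through cap
solve_tour_exact <- function(g) {
  fams <- g$families
  n <- length(fams)
  if (n > 14) stop("exact mode is limited to 14 genes")
  env <- tsp_cost_env(g)
  exts <- as.vector(rbind(2 * fams, 2 * fams + 1))  # head, tail per gene
  ne <- length(exts)
  cost_m <- matrix(g$base_cost, ne, ne)
  if (nrow(g$cand)) {
    i1 <- match(g$cand$e1, exts); i2 <- match(g$cand$e2, exts)
    for (k in seq_along(i1)) {
      cost_m[i1[k], i2[k]] <- min(cost_m[i1[k], i2[k]], g$cand$cost[k])
      cost_m[i2[k], i1[k]] <- cost_m[i1[k], i2[k]]
    }
  }
  caps <- vapply(exts, function(e) tsp_cap_cost(g, e), numeric(1))
  gene_of_ext <- rep(seq_len(n), each = 2)
  other_ext <- as.vector(rbind(seq(2, ne, 2), seq(1, ne - 1, 2)))
  nS <- bitwShiftL(1L, n)
  dp <- matrix(Inf, nS, ne)
  par_ext <- matrix(NA_integer_, nS, ne)
  for (e in seq_len(ne)) {
    S <- bitwShiftL(1L, gene_of_ext[e] - 1L)
    # enter via the other extremity, exit at e
    dp[S + 1L, e] <- caps[other_ext[e]]
  }
  for (S in seq_len(nS - 1L)) {
    row <- dp[S + 1L, ]
    act <- which(is.finite(row))
    if (!length(act)) next
    out <- which(bitwAnd(S, bitwShiftL(1L, seq_len(n) - 1L)) == 0L)
    if (!length(out)) next
    for (e in act) {
      base <- row[e]
      for (h in out) {
        S2 <- S + bitwShiftL(1L, h - 1L)
        for (ent in c(2L * h - 1L, 2L * h)) {
          ex <- other_ext[ent]
          val <- base + cost_m[e, ent]
          if (val < dp[S2 + 1L, ex]) {
            dp[S2 + 1L, ex] <- val
            par_ext[S2 + 1L, ex] <- e
          }
        }
      }
    }
  }
  full <- nS - 1L
  tot <- dp[full + 1L, ] + caps
  ex <- which.min(tot)
  best <- tot[ex]
  # backtrack
  seq_exts <- integer(n)
  S <- full; e <- ex
  for (k in n:1) {
    seq_exts[k] <- e
    pe <- par_ext[S + 1L, e]
    S <- S - bitwShiftL(1L, gene_of_ext[e] - 1L)
    e <- pe
  }
  tour <- vapply(seq_exts, function(ee) {
    f <- fams[gene_of_ext[ee]]
    if (ee %% 2 == 0) f else -f  # exit at tail (even index) => forward
  }, numeric(1))
  # exit extremity index even within pair <-> tail: exts order head,tail
  tour <- as.integer(tour)
  list(tour = tour, cost = best, method = "exact")
}

# telomere priority class of an extremity given the telomeric extremity
# sets of the parent and the two children genomes (lower = higher
# priority): 1 all three; 2 both children; 3 any two of the three;
# 4 parent only; 5 one child; 6 none.
telomere_class <- function(e, tel_parent, tel_c1, tel_c2) {
  p <- e %in% tel_parent
  a <- e %in% tel_c1
  b <- e %in% tel_c2
  ifelse(p & a & b, 1L,
  ifelse(a & b, 2L,
  ifelse((p & a) | (p & b), 3L,
  ifelse(p, 4L,
  ifelse(a | b, 5L, 6L)))))
}

#' Cut an assembly tour into linear chromosomes
#'
#' The tour (the TSP cycle opened at the cap node) is one linear gene
#' arrangement; additional chromosome ends are introduced at extremity
#' positions in strict priority order based on where telomeres sit in the
#' parent and the two children genomes: (1) telomeric in all three,
#' (2) in both children, (3) in any two of the three, (4) in the parent,
#' (5) in one child.  Within a class, weaker adjacencies (lower
#' posterior) are cut first.  Cutting stops when the chromosome count
#' reaches the target (default: the median of the parent's and children's
#' chromosome counts).  If the telomere candidates are exhausted the
#' remaining cuts fall back to the lowest-posterior adjacencies, with a
#' message.
#'
#' @param tour signed family vector from [solve_tour()].
#' @param g the [build_tsp()] instance (adjacency posteriors for
#'   tie-breaking and provenance).
#' @param child1,child2 [genome()] objects flanking the ancestor.
#' @param parent optional parent-side [genome()] (`NULL` at the root).
#' @param target target chromosome count (override).
#' @param name name for the assembled genome.
#' @return a [genome()]; per-adjacency posteriors of the retained
#'   adjacencies are attached as the `provenance` attribute.
#' @export
split_into_chromosomes <- function(tour, g, child1, child2, parent = NULL,
                                   target = NULL, name = "ancestor") {
  stopifnot(inherits(g, "adjacency_tsp"))
  n <- length(tour)
  counts <- c(if (!is.null(parent)) length(parent$chromosomes),
              length(child1$chromosomes), length(child2$chromosomes))
  if (is.null(target)) target <- max(1L, round(stats::median(counts)))
  tel_p <- if (is.null(parent)) numeric(0) else genome_telomere_exts(parent)
  tel_1 <- genome_telomere_exts(child1)
  tel_2 <- genome_telomere_exts(child2)
  env <- tsp_cost_env(g)
  cuts <- integer(0)
  if (target > 1 && n > 1) {
    k <- seq_len(n - 1)
    re <- right_ext(tour[k]); le <- left_ext(tour[k + 1])
    cl_r <- telomere_class(re, tel_p, tel_1, tel_2)
    cl_l <- telomere_class(le, tel_p, tel_1, tel_2)
    prim <- pmin(cl_r, cl_l)
    seco <- pmax(cl_r, cl_l)
    cost <- vapply(seq_along(k), function(i) {
      tsp_cost_of(env, g$base_cost, re[i], le[i])
    }, numeric(1))
    eligible <- which(prim <= 5L)
    ord <- eligible[order(prim[eligible], seco[eligible],
                          -cost[eligible], k[eligible])]
    need <- target - 1L
    cuts <- ord[seq_len(min(need, length(ord)))]
    if (length(cuts) < need) {
      rest <- setdiff(k[order(-cost, k)], cuts)
      extra <- rest[seq_len(min(need - length(cuts), length(rest)))]
      message("telomere candidates exhausted: ", length(extra),
              " cut(s) fall back to lowest-posterior adjacencies")
      cuts <- c(cuts, extra)
    }
  }
  bounds <- c(0L, sort(cuts), n)
  chroms <- lapply(seq_len(length(bounds) - 1L), function(i) {
    ch <- tour[(bounds[i] + 1L):bounds[i + 1L]]
    if (length(ch) == 1L) return(abs(ch))
    if (abs(ch[1]) > abs(ch[length(ch)])) ch <- -rev(ch)
    ch
  })
  chroms <- chroms[order(vapply(chroms, function(ch) min(abs(ch)),
                                numeric(1)))]
  out <- genome(name, chroms)
  keys <- unlist(lapply(chroms, chrom_adj_keys, telomeres = FALSE),
                 use.names = FALSE)
  attr(out, "provenance") <- data.frame(
    label = adj_label(keys),
    posterior = vapply(keys, function(kk) {
      v <- env[[as.character(kk)]]
      if (is.null(v)) 0 else exp(-v) - g$eps
    }, numeric(1)))
  out
}

#' Assemble one ancestral genome from posterior reconstructions
#'
#' Convenience wrapper over [select_content()], [build_tsp()],
#' [solve_tour()] and [split_into_chromosomes()].
#'
#' @param ap an [reconstruct_all()] result.
#' @param node internal node id to assemble.
#' @param child1,child2 genomes of the two child subtrees (assembled
#'   ancestors or observed leaves).
#' @param parent optional parent-side genome.
#' @param threshold posterior threshold for gene content inclusion.
#' @param seed integer seed passed to [solve_tour()].
#' @param target optional chromosome-count override.
#' @param method tour method passed to [solve_tour()].
#' @return a [genome()] named `A<node>` with assembly provenance.
#' @export
assemble_ancestor <- function(ap, node, child1, child2, parent = NULL,
                              threshold = 0.5, seed = 1L, target = NULL,
                              method = "auto") {
  fams <- select_content(ap, node, threshold)
  if (length(fams) == 0) stop("no families selected for node ", node)
  adj <- node_adjacency_posteriors(ap, node)
  g <- build_tsp(fams, adj)
  sol <- solve_tour(g, seed = seed, method = method)
  split_into_chromosomes(sol$tour, g, child1 = child1, child2 = child2,
                         parent = parent, target = target,
                         name = paste0("A", node))
}
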