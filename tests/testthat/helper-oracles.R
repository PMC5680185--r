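# Independent oracles used across the suite.  Each is a deliberately
# naive implementation (enumeration, breadth-first search, brute force)
# that shares no code with the package internals it checks.

# --- two-state transition probabilities (closed form, re-derived) ------
oracle_tm <- function(loss, gain, t) {
  s <- loss + gain
  w <- 1 - exp(-s * t)
  matrix(c(1 - gain / s * w, loss / s * w,
           gain / s * w, 1 - loss / s * w), 2, 2)
}

# orient the edges of a phylo away from `root` (node id); returns a
# matrix (from, to, len)
orient_edges <- function(phy, root) {
  ntip <- length(phy$tip.label)
  nn <- ntip + phy$Nnode
  adj <- vector("list", nn)
  for (i in seq_len(nrow(phy$edge))) {
    u <- phy$edge[i, 1]; v <- phy$edge[i, 2]
    l <- phy$edge.length[i]
    adj[[u]] <- rbind(adj[[u]], c(v, l))
    adj[[v]] <- rbind(adj[[v]], c(u, l))
  }
  out <- NULL
  queue <- root; seen <- root
  while (length(queue)) {
    u <- queue[1]; queue <- queue[-1]
    for (r in seq_len(NROW(adj[[u]]))) {
      v <- adj[[u]][r, 1]
      if (v %in% seen) next
      out <- rbind(out, c(u, v, adj[[u]][r, 2]))
      seen <- c(seen, v); queue <- c(queue, v)
    }
  }
  out
}

# brute-force likelihood of binary characters by summing over all
# internal-state assignments; X is taxa x K with rownames = tip labels
enum_char_liks <- function(phy, X, loss, gain, root_node = NULL,
                           use_pi = TRUE) {
  ntip <- length(phy$tip.label)
  nn <- ntip + phy$Nnode
  root <- if (is.null(root_node)) ntip + 1L else root_node
  em <- orient_edges(phy, root)
  internals <- sort(unique(c(root, em[em[, 2] > ntip, 2])))
  K <- ncol(X)
  X <- X[phy$tip.label, , drop = FALSE]
  pi1 <- gain / (gain + loss)
  total <- numeric(K)
  n_int <- length(internals)
  for (code in 0:(2^n_int - 1)) {
    states <- integer(nn)
    bits <- as.integer(intToBits(code))[seq_len(n_int)]
    states[internals] <- bits
    contrib <- rep(1, K)
    for (r in seq_len(nrow(em))) {
      u <- em[r, 1]; v <- em[r, 2]
      Tm <- oracle_tm(loss, gain, em[r, 3])
      if (v <= ntip) {
        contrib <- contrib * Tm[states[u] + 1, X[v, ] + 1]
      } else {
        contrib <- contrib * Tm[states[u] + 1, states[v] + 1]
      }
    }
    w <- if (use_pi) {
      if (states[root] == 1) pi1 else 1 - pi1
    } else 1
    total <- total + w * contrib
  }
  total
}

# per-state partials at `node` by enumeration (no root prior)
enum_partials <- function(phy, X, loss, gain, node) {
  ntip <- length(phy$tip.label)
  em <- orient_edges(phy, node)
  internals_other <- setdiff(sort(unique(em[em[, 2] > ntip, 2])), node)
  K <- ncol(X)
  X <- X[phy$tip.label, , drop = FALSE]
  out <- matrix(0, 2, K)
  for (s_node in 0:1) {
    tot <- numeric(K)
    n_int <- length(internals_other)
    for (code in 0:(2^max(0, n_int) - 1)) {
      states <- integer(ntip + phy$Nnode)
      if (n_int > 0) {
        states[internals_other] <- as.integer(intToBits(code))[seq_len(n_int)]
      }
      states[node] <- s_node
      contrib <- rep(1, K)
      for (r in seq_len(nrow(em))) {
        u <- em[r, 1]; v <- em[r, 2]
        Tm <- oracle_tm(loss, gain, em[r, 3])
        if (v <= ntip) {
          contrib <- contrib * Tm[states[u] + 1, X[v, ] + 1]
        } else {
          contrib <- contrib * Tm[states[u] + 1, states[v] + 1]
        }
      }
      tot <- tot + contrib
    }
    out[s_node + 1, ] <- tot
  }
  out
}

# --- BFS oracle for the DCJ distance ----------------------------------
# A genome state is the set of adjacencies (packed unordered extremity
# pairs); telomeres are implicit.  DCJ moves: recombine two adjacencies
# (two ways), split an adjacency, join an adjacency with a free
# extremity, or join two free extremities.
pack2 <- function(a, b) min(a, b) * 2^26 + max(a, b)

genome_state <- function(g) {
  keys <- c()
  for (ch in g$chromosomes) {
    n <- length(ch)
    if (n >= 2) {
      re <- ifelse(ch[-n] > 0, 2 * ch[-n] + 1, -2 * ch[-n])
      le <- ifelse(ch[-1] > 0, 2 * ch[-1], -2 * ch[-1] + 1)
      keys <- c(keys, mapply(pack2, re, le))
    }
  }
  sort(unique(keys))
}

state_exts <- function(g) {
  fams <- sort(unique(abs(unlist(g$chromosomes))))
  sort(c(2 * fams, 2 * fams + 1))
}

dcj_neighbors <- function(state, exts) {
  unpack <- function(k) c(k %/% 2^26, k %% 2^26)
  used <- unlist(lapply(state, unpack))
  free <- setdiff(exts, used)
  res <- list()
  addst <- function(s) res[[length(res) + 1L]] <<- sort(s)
  n <- length(state)
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        pq <- unpack(state[i]); rs <- unpack(state[j])
        rest <- state[-c(i, j)]
        addst(c(rest, pack2(pq[1], rs[1]), pack2(pq[2], rs[2])))
        addst(c(rest, pack2(pq[1], rs[2]), pack2(pq[2], rs[1])))
      }
    }
  }
  for (i in seq_len(length(state))) {
    pq <- unpack(state[i])
    rest <- state[-i]
    addst(rest)                                   # split into 2 telomeres
    for (f in free) {
      addst(c(rest, pack2(pq[1], f)))
      addst(c(rest, pack2(pq[2], f)))
    }
  }
  if (length(free) >= 2) {
    for (i in seq_along(free)[-length(free)]) {
      for (j in (i + 1):length(free)) {
        addst(c(state, pack2(free[i], free[j])))
      }
    }
  }
  unique(lapply(res, identity))
}

bfs_dcj <- function(a, b) {
  sa <- genome_state(a); sb <- genome_state(b)
  exts <- state_exts(a)
  stopifnot(identical(exts, state_exts(b)))
  key <- function(s) paste0("s:", paste(s, collapse = ","))
  if (key(sa) == key(sb)) return(0L)
  frontier <- list(sa)
  seen <- new.env(parent = emptyenv())
  assign(key(sa), TRUE, envir = seen)
  d <- 0L
  repeat {
    d <- d + 1L
    nxt <- list()
    for (s in frontier) {
      for (nb in dcj_neighbors(s, exts)) {
        k <- key(nb)
        if (k == key(sb)) return(d)
        if (is.null(seen[[k]])) {
          seen[[k]] <- TRUE
          nxt[[length(nxt) + 1L]] <- nb
        }
      }
    }
    frontier <- nxt
    if (d > 12 || length(frontier) == 0) stop("BFS oracle exhausted")
  }
}

# --- brute-force synteny blocks ---------------------------------------
# all maximal matching runs by direct interval comparison
brute_synteny <- function(a, b) {
  sc <- function(g) {
    f <- abs(unlist(g$chromosomes)); as.integer(names(table(f))[table(f) == 1])
  }
  fams <- intersect(sc(a), sc(b))
  locate <- function(g) {
    out <- list()
    for (ci in seq_along(g$chromosomes)) {
      ch <- g$chromosomes[[ci]]
      for (k in seq_along(ch)) {
        if (abs(ch[k]) %in% fams) {
          out[[as.character(abs(ch[k]))]] <- c(ci, k, sign(ch[k]))
        }
      }
    }
    out
  }
  lb <- locate(b)
  runs <- list()
  for (ci in seq_along(a$chromosomes)) {
    ch <- a$chromosomes[[ci]]
    n <- length(ch)
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (j <= i) next
        seg <- ch[i:j]
        if (!all(abs(seg) %in% fams)) next
        pb <- t(vapply(as.character(abs(seg)), function(f) lb[[f]],
                       numeric(3)))
        same_chrom <- length(unique(pb[, 1])) == 1
        fwd <- all(diff(pb[, 2]) == 1) && all(pb[, 3] == sign(seg))
        rev_ <- all(diff(pb[, 2]) == -1) && all(pb[, 3] == -sign(seg))
        if (same_chrom && (fwd || rev_)) {
          runs[[length(runs) + 1L]] <- list(chrom = ci, i = i, j = j,
                                            orient = if (fwd) 1 else -1)
        }
      }
    }
  }
  # keep maximal runs only
  keep <- vapply(seq_along(runs), function(k) {
    r <- runs[[k]]
    !any(vapply(runs, function(s) {
      s$chrom == r$chrom && s$i <= r$i && s$j >= r$j &&
        (s$j - s$i) > (r$j - r$i)
    }, logical(1)))
  }, logical(1))
  runs[keep]
}

# --- misc generators ---------------------------------------------------
random_genome <- function(n, C = 1, name = "g", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  perm <- sample(n) * sample(c(-1L, 1L), n, replace = TRUE)
  cuts <- if (C > 1) sort(sample(seq_len(n - 1), C - 1)) else integer(0)
  bounds <- c(0L, cuts, n)
  chroms <- lapply(seq_len(C), function(i) {
    perm[(bounds[i] + 1):bounds[i + 1]]
  })
  orderphy::genome(name, chroms)
}
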