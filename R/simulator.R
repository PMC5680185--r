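#' Configuration for the genome rearrangement simulator
#'
#' The defaults are the study conditions of the simulation protocol: 20
#' genomes, a start genome of 5,000 genes on eight chromosomes, and a
#' per-edge budget of gene-adjacency changes drawn uniformly from
#' \[2750, 8250\].  The event mix weights the rearrangement and content
#' event types; segment lengths (inversions, deletions, insertions,
#' duplications) are geometric with mean `seg_mean` genes.
#'
#' @param n_taxa number of leaf genomes.
#' @param n_genes genes in the start (root) genome.
#' @param n_chromosomes chromosomes in the start genome.
#' @param budget integer interval `c(lo, hi)`: per-edge adjacency-change
#'   budget is drawn uniformly from it.
#' @param event_mix named non-negative weights over event kinds
#'   `inversion`, `translocation`, `fusion`, `fission`, `deletion`,
#'   `insertion`, `duplication`; normalized to sum to 1.
#' @param seg_mean mean segment length in genes.
#' @param wgd_edges optional integer vector of child node ids; a
#'   whole-genome duplication is applied at the start of each such edge.
#' @param seed integer seed; [evolve()] is deterministic given the config.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_taxa = 20, n_genes = 5000, n_chromosomes = 8,
                       budget = c(2750, 8250),
                       event_mix = c(inversion = 0.70, translocation = 0.10,
                                     fusion = 0.02, fission = 0.02,
                                     deletion = 0.08, insertion = 0.04,
                                     duplication = 0.04),
                       seg_mean = 5, wgd_edges = NULL, seed = 1L) {
  stopifnot(n_taxa >= 3, n_genes >= n_chromosomes, n_chromosomes >= 1,
            length(budget) == 2, budget[1] <= budget[2], budget[1] >= 0,
            seg_mean >= 1)
  kinds <- c("inversion", "translocation", "fusion", "fission",
             "deletion", "insertion", "duplication")
  if (!setequal(names(event_mix), kinds) || any(event_mix < 0) ||
      sum(event_mix) <= 0) {
    stop("event_mix must be non-negative weights over: ",
         paste(kinds, collapse = ", "))
  }
  event_mix <- event_mix[kinds] / sum(event_mix)
  structure(list(n_taxa = as.integer(n_taxa), n_genes = as.integer(n_genes),
                 n_chromosomes = as.integer(n_chromosomes),
                 budget = as.integer(budget), event_mix = event_mix,
                 seg_mean = seg_mean, wgd_edges = wgd_edges,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Random unrooted binary tree
#'
#' Sequential random attachment: starting from the three-leaf tree, each
#' new leaf is attached to a uniformly chosen existing edge.
#'
#' @param n_taxa number of leaves (>= 3).
#' @param seed optional seed; when `NULL` the ambient RNG state is used.
#' @return an `ape::phylo` unrooted binary tree without branch lengths;
#'   leaves are labelled `T01`, `T02`, ...
#' @export
random_tree <- function(n_taxa, seed = NULL) {
  if (n_taxa < 3) stop("need at least 3 taxa")
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n_taxa)
  edges <- matrix(c(1L, n + 1L, 2L, n + 1L, 3L, n + 1L),
                  ncol = 2, byrow = TRUE)
  for (k in seq_len(n)[-(1:3)]) {
    i <- sample.int(nrow(edges), 1)
    new_int <- n + k - 2L
    a <- edges[i, 1]; b <- edges[i, 2]
    edges[i, ] <- c(a, new_int)
    edges <- rbind(edges, c(new_int, b), c(k, new_int))
  }
  n_nodes <- 2L * n - 2L
  nbr <- vector("list", n_nodes)
  len <- vector("list", n_nodes)
  for (i in seq_len(nrow(edges))) {
    u <- edges[i, 1]; v <- edges[i, 2]
    nbr[[u]] <- c(nbr[[u]], v); len[[u]] <- c(len[[u]], NA_real_)
    nbr[[v]] <- c(nbr[[v]], u); len[[v]] <- c(len[[v]], NA_real_)
  }
  ut <- new_utree(n, sprintf("T%02d", seq_len(n)), nbr, len)
  as_phylo(ut)
}

# symmetric difference of telomere-inclusive adjacency sets
# (the package's adjacency-change unit)
count_changes <- function(before, after) {
  kb <- unique(unlist(lapply(before, chrom_adj_keys, telomeres = TRUE),
                      use.names = FALSE))
  ka <- unique(unlist(lapply(after, chrom_adj_keys, telomeres = TRUE),
                      use.names = FALSE))
  length(setdiff(kb, ka)) + length(setdiff(ka, kb))
}

seg_len <- function(seg_mean, max_len) {
  if (max_len < 1) return(0L)
  L <- 1L + stats::rgeom(1, 1 / seg_mean)
  min(L, max_len)
}

# draw a random parameterization of an event; NULL when inapplicable
draw_event <- function(chroms, kind, cfg, next_id) {
  nlen <- lengths(chroms)
  nc <- length(chroms)
  pick_chrom <- function() sample.int(nc, 1, prob = nlen)
  switch(kind,
    inversion = {
      i <- pick_chrom()
      start <- sample.int(nlen[i], 1)
      L <- seg_len(cfg$seg_mean, nlen[i] - start + 1L)
      list(kind = "inversion", chrom = i, start = start, len = L)
    },
    translocation = {
      if (nc < 2) return(NULL)
      ij <- sample.int(nc, 2)
      list(kind = "translocation", chrom = ij[1], chrom2 = ij[2],
           cut1 = sample(0:nlen[ij[1]], 1), cut2 = sample(0:nlen[ij[2]], 1))
    },
    fusion = {
      if (nc < 2) return(NULL)
      ij <- sample.int(nc, 2)
      list(kind = "fusion", chrom = ij[1], chrom2 = ij[2],
           flip = stats::runif(1) < 0.5)
    },
    fission = {
      ok <- which(nlen >= 2)
      if (!length(ok)) return(NULL)
      i <- if (length(ok) == 1) ok else
        sample(ok, 1, prob = nlen[ok])
      list(kind = "fission", chrom = i, cut = sample.int(nlen[i] - 1L, 1))
    },
    deletion = {
      i <- pick_chrom()
      start <- sample.int(nlen[i], 1)
      L <- seg_len(cfg$seg_mean, nlen[i] - start + 1L)
      if (sum(nlen) - L < 1) return(NULL)
      list(kind = "deletion", chrom = i, start = start, len = L)
    },
    insertion = {
      i <- pick_chrom()
      L <- seg_len(cfg$seg_mean, .Machine$integer.max)
      ids <- (next_id):(next_id + L - 1L)
      signs <- sample(c(-1L, 1L), L, replace = TRUE)
      list(kind = "insertion", chrom = i, pos = sample(0:nlen[i], 1),
           ids = ids * signs)
    },
    duplication = {
      i <- pick_chrom()
      start <- sample.int(nlen[i], 1)
      L <- seg_len(cfg$seg_mean, nlen[i] - start + 1L)
      j <- pick_chrom()
      list(kind = "duplication", chrom = i, start = start, len = L,
           chrom2 = j, pos = sample(0:nlen[j], 1),
           flip = stats::runif(1) < 0.5)
    },
    wgd = list(kind = "wgd"),
    stop("unknown event kind: ", kind))
}

# Apply a drawn event to a chromosome list (deterministic given params).
# Returns the new list; the indices of the touched chromosomes in the
# old and the new list; and old_of, mapping each untouched new index to
# the old index it was carried over from (NA for touched chromosomes).
exec_event_touched <- function(chroms, ev) {
  n0 <- length(chroms)
  carry <- function(nc, touched, dropped = integer(0)) {
    old <- setdiff(seq_len(n0), dropped)
    out <- rep(NA_integer_, nc)
    kept <- setdiff(seq_len(min(nc, length(old))), touched)
    out[kept] <- old[kept]
    out
  }
  res <- switch(ev$kind,
    inversion = {
      ch <- chroms[[ev$chrom]]
      idx <- ev$start:(ev$start + ev$len - 1L)
      ch[idx] <- -rev(ch[idx])
      chroms[[ev$chrom]] <- ch
      list(chroms = chroms, touched = ev$chrom,
           old_of = carry(n0, ev$chrom))
    },
    translocation = {
      a <- chroms[[ev$chrom]]; b <- chroms[[ev$chrom2]]
      chroms[[ev$chrom]] <- c(a[seq_len(ev$cut1)],
                              b[seq_len(length(b) - ev$cut2) + ev$cut2])
      chroms[[ev$chrom2]] <- c(b[seq_len(ev$cut2)],
                               a[seq_len(length(a) - ev$cut1) + ev$cut1])
      keep <- which(lengths(chroms) > 0)
      touched <- match(intersect(c(ev$chrom, ev$chrom2), keep), keep)
      old_of <- keep
      old_of[touched] <- NA_integer_
      list(chroms = chroms[keep], touched = touched, old_of = old_of)
    },
    fusion = {
      b <- chroms[[ev$chrom2]]
      if (ev$flip) b <- -rev(b)
      chroms[[ev$chrom]] <- c(chroms[[ev$chrom]], b)
      old_of <- setdiff(seq_len(n0), ev$chrom2)
      touched <- ev$chrom - (ev$chrom2 < ev$chrom)
      old_of[touched] <- NA_integer_
      list(chroms = chroms[-ev$chrom2], touched = touched,
           old_of = old_of)
    },
    fission = {
      ch <- chroms[[ev$chrom]]
      chroms[[ev$chrom]] <- ch[seq_len(ev$cut)]
      chroms <- c(chroms, list(ch[(ev$cut + 1L):length(ch)]))
      old_of <- c(seq_len(n0), NA_integer_)
      old_of[ev$chrom] <- NA_integer_
      list(chroms = chroms, touched = c(ev$chrom, length(chroms)),
           old_of = old_of)
    },
    deletion = {
      ch <- chroms[[ev$chrom]]
      ch <- ch[-(ev$start:(ev$start + ev$len - 1L))]
      if (length(ch) == 0) {
        list(chroms = chroms[-ev$chrom], touched = integer(0),
             old_of = setdiff(seq_len(n0), ev$chrom))
      } else {
        chroms[[ev$chrom]] <- ch
        list(chroms = chroms, touched = ev$chrom,
             old_of = carry(n0, ev$chrom))
      }
    },
    insertion = {
      chroms[[ev$chrom]] <- append(chroms[[ev$chrom]], ev$ids,
                                   after = ev$pos)
      list(chroms = chroms, touched = ev$chrom,
           old_of = carry(n0, ev$chrom))
    },
    duplication = {
      seg <- chroms[[ev$chrom]][ev$start:(ev$start + ev$len - 1L)]
      if (ev$flip) seg <- -rev(seg)
      chroms[[ev$chrom2]] <- append(chroms[[ev$chrom2]], seg,
                                    after = ev$pos)
      list(chroms = chroms, touched = ev$chrom2,
           old_of = carry(n0, ev$chrom2))
    },
    wgd = list(chroms = c(chroms, chroms),
               touched = seq_len(2L * n0),
               old_of = rep(NA_integer_, 2L * n0)),
    stop("unknown event kind: ", ev$kind))
  res$touched_old <- switch(ev$kind,
    wgd = seq_len(n0),
    duplication = ev$chrom2,
    unique(c(ev$chrom, ev$chrom2)))
  res
}

exec_event <- function(chroms, ev) exec_event_touched(chroms, ev)$chroms

#' Apply one random evolutionary event to a genome
#'
#' Draws the event's parameters from the ambient RNG, applies it, and
#' reports the number of gene-adjacency changes: the size of the
#' symmetric difference of the genome's telomere-inclusive adjacency
#' sets before and after the event.  Inapplicable events (e.g. a translocation on a
#' single-chromosome genome) return `NULL`.
#'
#' @param g a [genome()].
#' @param kind one of `inversion`, `translocation`, `fusion`, `fission`,
#'   `deletion`, `insertion`, `duplication`, `wgd`.
#' @param cfg a [sim_config()] (segment-length parameters).
#' @param next_id first unused family ID for insertions.
#' @return `NULL` if inapplicable, else a list with `genome` (the mutated
#'   genome), `changes` (adjacency-change count), and `event` (the drawn
#'   parameters).
#' @export
apply_event <- function(g, kind, cfg = sim_config(), next_id = NULL) {
  stopifnot(inherits(g, "genome"))
  if (is.null(next_id)) {
    next_id <- max(abs(unlist(g$chromosomes, use.names = FALSE))) + 1L
  }
  ev <- draw_event(g$chromosomes, kind, cfg, next_id)
  if (is.null(ev)) return(NULL)
  chroms <- exec_event(g$chromosomes, ev)
  list(genome = genome(g$name, chroms),
       changes = count_changes(g$chromosomes, chroms),
       event = ev)
}

#' Replay a logged event sequence
#'
#' @param g the starting [genome()].
#' @param events list of event parameter lists, as logged by [evolve()].
#' @return the resulting [genome()].
#' @export
replay_events <- function(g, events) {
  chroms <- g$chromosomes
  for (ev in events) chroms <- exec_event(chroms, ev)
  genome(g$name, chroms)
}

#' Simulate genome evolution along a random phylogeny
#'
#' The start genome (families `1..n_genes` split evenly over
#' `n_chromosomes` linear chromosomes) is placed at an internal root node
#' of a [random_tree()] and evolved along each edge: events are drawn
#' from the event mix until the cumulative adjacency-change count reaches
#' a per-edge budget drawn uniformly from `cfg$budget`.  Every internal
#' node's genome is recorded as a true ancestor; realized adjacency
#' changes become the edge lengths of the returned tree.
#'
#' @param cfg a [sim_config()].
#' @return an object of class `sim_result`: list with `tree` (phylo with
#'   realized-change edge lengths; node ids match `ancestors` names),
#'   `leaves` (a [genome_set()]), `ancestors` (named list of true
#'   ancestral genomes, one per internal node including the root),
#'   `root` (root node id), `events` (per-edge event log) and `config`.
#' @export
evolve <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  tree <- random_tree(cfg$n_taxa)
  ut <- as_utree(tree)
  root <- ut$n_tip + 1L
  sizes <- diff(round(seq(0, cfg$n_genes, length.out =
                            cfg$n_chromosomes + 1)))
  chroms <- split(seq_len(cfg$n_genes), rep(seq_len(cfg$n_chromosomes),
                                            times = sizes))
  genomes <- vector("list", ut_n_nodes(ut))
  genomes[[root]] <- genome("root", unname(chroms))
  next_id <- cfg$n_genes + 1L
  kinds <- names(cfg$event_mix)
  log_edge <- list()
  # preorder edge traversal from the root
  stack <- c(root); from <- c(0L)
  order_edges <- list()
  while (length(stack)) {
    u <- stack[length(stack)]; p <- from[length(stack)]
    stack <- stack[-length(stack)]; from <- from[-length(from)]
    for (v in ut$nbr[[u]]) {
      if (v == p) next
      order_edges[[length(order_edges) + 1L]] <- c(u, v)
      stack <- c(stack, v); from <- c(from, u)
    }
  }
  for (e in order_edges) {
    u <- e[1]; v <- e[2]
    g <- genomes[[u]]
    chroms <- g$chromosomes
    events <- list()
    cum <- 0L
    if (!is.null(cfg$wgd_edges) && v %in% cfg$wgd_edges) {
      chroms <- exec_event(chroms, list(kind = "wgd"))
      events[[length(events) + 1L]] <- list(kind = "wgd")
    }
    budget <- if (cfg$budget[1] == cfg$budget[2]) cfg$budget[1] else
      sample(cfg$budget[1]:cfg$budget[2], 1)
    guard <- 0L
    # per-chromosome telomere-inclusive key sets, maintained
    # incrementally so the genome-level change count stays O(touched)
    keysets <- lapply(chroms, function(ch)
      unique(chrom_adj_keys(ch, telomeres = TRUE)))
    while (cum < budget) {
      guard <- guard + 1L
      if (guard > 10L * budget + 1000L) {
        stop("event budget not reachable on edge ", u, "-", v)
      }
      kind <- sample(kinds, 1, prob = cfg$event_mix)
      ev <- draw_event(chroms, kind, cfg, next_id)
      if (is.null(ev)) next
      res <- exec_event_touched(chroms, ev)
      new_keysets <- vector("list", length(res$chroms))
      kept <- which(!is.na(res$old_of))
      new_keysets[kept] <- keysets[res$old_of[kept]]
      for (i in res$touched) {
        new_keysets[[i]] <- unique(chrom_adj_keys(res$chroms[[i]],
                                                  telomeres = TRUE))
      }
      tb <- unique(unlist(keysets[res$touched_old], use.names = FALSE))
      ta <- unique(unlist(new_keysets[res$touched], use.names = FALSE))
      cand <- c(tb[is.na(match(tb, ta))], ta[is.na(match(ta, tb))])
      delta <- length(cand)
      if (delta > 0 && length(kept)) {
        # a key removed from (or added to) the touched chromosomes is
        # only a genome-level change if no untouched chromosome has it
        elsewhere <- unlist(new_keysets[kept], use.names = FALSE)
        hit <- match(elsewhere, cand)
        delta <- delta - length(unique(hit[!is.na(hit)]))
      }
      chroms <- res$chroms
      keysets <- new_keysets
      cum <- cum + delta
      ev$changes <- delta
      if (ev$kind == "insertion") next_id <- next_id + length(ev$ids)
      events[[length(events) + 1L]] <- ev
    }
    nm <- if (v <= ut$n_tip) ut$labels[v] else paste0("A", v)
    genomes[[v]] <- genome(nm, chroms)
    ut <- ut_set_len(ut, u, v, cum)
    log_edge[[length(log_edge) + 1L]] <-
      list(parent = u, child = v, budget = budget, realized = cum,
           events = events)
  }
  internal <- ut_internal_nodes(ut)
  ancestors <- genomes[internal]
  names(ancestors) <- as.character(internal)
  ancestors[[as.character(root)]] <- genome(paste0("A", root),
                                            genomes[[root]]$chromosomes)
  structure(list(tree = as_phylo(ut),
                 leaves = genome_set(genomes[seq_len(ut$n_tip)]),
                 ancestors = ancestors, root = root,
                 events = log_edge, config = cfg),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat("<sim_result>", length(x$leaves$genomes), "leaves,",
      length(x$ancestors), "true ancestors, root node", x$root, "\n")
  invisible(x)
}
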