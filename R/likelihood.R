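# Felsenstein pruning engine for the two-state gain/loss model.
#
# Messages are computed per directed edge: msg(u -> v) is the 2 x K matrix
# of probabilities of the data in the subtree behind u (away from v),
# given the state at u; the transition over edge (u, v) is applied by the
# consumer, so a message does not depend on the length of the edge it is
# sent across.  Columns are rescaled to a maximum of 1 with the log scale
# accumulated separately (underflow guard for deep trees).

tm2 <- function(loss, gain, t) {
  s <- loss + gain
  w <- 1 - exp(-s * t)
  p01 <- gain / s * w
  p10 <- loss / s * w
  c(p00 = 1 - p01, p01 = p01, p10 = p10, p11 = 1 - p10)
}

#' Model parameters of the two-state gain/loss chain
#'
#' Loss (`1 -> 0`) and gain (`0 -> 1`) rates, optionally distinct for the
#' adjacency (`A`) and content (`C`) character classes.  Only the
#' loss/gain ratio is identifiable once branch lengths are optimized; the
#' defaults fix the loss rate at 1 so branch lengths are expressed in
#' expected losses per present character.
#'
#' @param loss_rate,gain_rate positive rates applied to both classes.
#' @param adjacency,content optional per-class overrides, each a numeric
#'   vector `c(loss, gain)`.
#' @return an object of class `model_params`.
#' @export
model_params <- function(loss_rate = 1, gain_rate = 1e-4,
                         adjacency = NULL, content = NULL) {
  as_pair <- function(x, default) {
    if (is.null(x)) return(default)
    stopifnot(is.numeric(x), length(x) == 2)
    c(loss = unname(x[1]), gain = unname(x[2]))
  }
  default <- c(loss = loss_rate, gain = gain_rate)
  if (any(default <= 0)) stop("rates must be positive")
  p <- structure(list(adjacency = as_pair(adjacency, default),
                      content = as_pair(content, default)),
                 class = "model_params")
  if (any(unlist(p) <= 0)) stop("rates must be positive")
  p
}

#' Derive model parameters from a genome set
#'
#' Sets the loss/gain ratio from the genome geometry: a genome with `n`
#' genes and `C` chromosomes has `n + C` adjacencies that can be lost but
#' `choose(2n + 2, 2)` candidate adjacencies that can be gained, so the
#' gain rate is smaller by that ratio (see [adjacency_loss_prob()] and
#' [adjacency_gain_prob()]; the shared event-count factor cancels).  The
#' loss rate is normalized to 1.
#'
#' @param gs a [genome_set()].
#' @return a [model_params()] object.
#' @export
model_params_from_genomes <- function(gs) {
  stopifnot(inherits(gs, "genome_set"))
  n <- mean(vapply(gs$genomes,
                   function(g) sum(lengths(g$chromosomes)), numeric(1)))
  C <- mean(vapply(gs$genomes,
                   function(g) length(g$chromosomes), numeric(1)))
  ends <- (2 * n + 2) * (2 * n + 1) / 2
  model_params(loss_rate = 1, gain_rate = (n + C) / ends)
}

# engine: closures over a utree + character matrix + params
make_engine <- function(tree, m, params) {
  ut <- as_utree(tree)
  stopifnot(inherits(m, "bcm"), inherits(params, "model_params"))
  if (!setequal(ut$labels, m$taxa)) {
    stop("tree leaf labels do not match matrix taxa")
  }
  K <- ncol(m$mat)
  row_of <- match(ut$labels, m$taxa)
  idxA <- which(m$col_class == "A")
  idxC <- which(m$col_class == "C")
  rA <- params$adjacency
  rC <- params$content
  pi1 <- numeric(K)
  pi1[idxA] <- rA["gain"] / sum(rA)
  pi1[idxC] <- rC["gain"] / sum(rC)
  pi0 <- 1 - pi1
  freq1 <- colMeans(m$mat)

  apply_trans <- function(M, t) {
    out <- matrix(0, 2, K)
    if (length(idxA)) {
      p <- tm2(rA["loss"], rA["gain"], t)
      out[1, idxA] <- p[1] * M[1, idxA] + p[2] * M[2, idxA]
      out[2, idxA] <- p[3] * M[1, idxA] + p[4] * M[2, idxA]
    }
    if (length(idxC)) {
      p <- tm2(rC["loss"], rC["gain"], t)
      out[1, idxC] <- p[1] * M[1, idxC] + p[2] * M[2, idxC]
      out[2, idxC] <- p[3] * M[1, idxC] + p[4] * M[2, idxC]
    }
    out
  }

  leaf_msgs <- lapply(seq_len(ut$n_tip), function(i) {
    x <- m$mat[row_of[i], ]
    rbind(1 - x, x)
  })

  msgs <- new.env(parent = emptyenv())

  get_msg <- function(u, v) {
    key <- paste0(u, "|", v)
    got <- msgs[[key]]
    if (!is.null(got)) return(got)
    res <- if (u <= ut$n_tip) {
      list(mat = leaf_msgs[[u]], ls = numeric(K))
    } else {
      mat <- matrix(1, 2, K)
      ls <- numeric(K)
      nb <- ut$nbr[[u]]
      for (j in seq_along(nb)) {
        w <- nb[j]
        if (w == v) next
        mw <- get_msg(w, u)
        mat <- mat * apply_trans(mw$mat, ut$len[[u]][j])
        ls <- ls + mw$ls
      }
      sc <- pmax(mat[1, ], mat[2, ])
      sc[sc <= 0] <- 1
      list(mat = mat / rep(sc, each = 2), ls = ls + log(sc))
    }
    msgs[[key]] <- res
    res
  }

  node_partial <- function(a, exclude = 0L) {
    if (a <= ut$n_tip) {
      return(list(mat = leaf_msgs[[a]], ls = numeric(K)))
    }
    mat <- matrix(1, 2, K)
    ls <- numeric(K)
    nb <- ut$nbr[[a]]
    for (j in seq_along(nb)) {
      w <- nb[j]
      if (w == exclude) next
      mw <- get_msg(w, a)
      mat <- mat * apply_trans(mw$mat, ut$len[[a]][j])
      ls <- ls + mw$ls
    }
    list(mat = mat, ls = ls)
  }

  invalidate <- function() {
    rm(list = ls(envir = msgs), envir = msgs)
  }

  set_len <- function(u, v, value) {
    ut <<- ut_set_len(ut, u, v, value)
    invalidate()
  }

  # incremental variants for the branch-length sweep: messages exclude
  # the transition over their own sending edge, so a length update only
  # invalidates message *combinations*, which are always formed fresh;
  # the sweep keeps the store consistent by hand
  set_len_quiet <- function(u, v, value) {
    ut <<- ut_set_len(ut, u, v, value)
  }

  put_msg <- function(u, v, value) {
    msgs[[paste0(u, "|", v)]] <- value
  }

  # recompute msg(u -> v) assuming the messages from u's other
  # neighbours are current
  refresh_msg <- function(u, v) {
    if (u <= ut$n_tip) return(invisible())
    mat <- matrix(1, 2, K)
    ls <- numeric(K)
    nb <- ut$nbr[[u]]
    for (j in seq_along(nb)) {
      w <- nb[j]
      if (w == v) next
      mw <- get_msg(w, u)
      mat <- mat * apply_trans(mw$mat, ut$len[[u]][j])
      ls <- ls + mw$ls
    }
    sc <- pmax(mat[1, ], mat[2, ])
    sc[sc <= 0] <- 1
    msgs[[paste0(u, "|", v)]] <- list(mat = mat / rep(sc, each = 2),
                                      ls = ls + log(sc))
    invisible()
  }

  loglik <- function() {
    a <- if (ut$n_tip >= 2) ut$n_tip + 1L else 1L
    P <- node_partial(a)
    sum(log(pi0 * P$mat[1, ] + pi1 * P$mat[2, ])) + sum(P$ls)
  }

  # log-likelihood as a function of the length of edge (u, v), with all
  # other lengths fixed; O(K) per evaluation
  edge_loglik_fun <- function(u, v) {
    A <- node_partial(u, exclude = v)
    B <- get_msg(v, u)
    lsc <- sum(A$ls) + sum(B$ls)
    pA <- if (length(idxA)) rA else NULL
    function(t) {
      TB <- matrix(0, 2, K)
      if (length(idxA)) {
        p <- tm2(rA["loss"], rA["gain"], t)
        TB[1, idxA] <- p[1] * B$mat[1, idxA] + p[2] * B$mat[2, idxA]
        TB[2, idxA] <- p[3] * B$mat[1, idxA] + p[4] * B$mat[2, idxA]
      }
      if (length(idxC)) {
        p <- tm2(rC["loss"], rC["gain"], t)
        TB[1, idxC] <- p[1] * B$mat[1, idxC] + p[2] * B$mat[2, idxC]
        TB[2, idxC] <- p[3] * B$mat[1, idxC] + p[4] * B$mat[2, idxC]
      }
      lk <- pi0 * A$mat[1, ] * TB[1, ] + pi1 * A$mat[2, ] * TB[2, ]
      sum(log(lk)) + lsc
    }
  }

  posteriors <- function(nodes, f = freq1) {
    out <- matrix(NA_real_, length(nodes), K,
                  dimnames = list(as.character(nodes), colnames(m$mat)))
    for (i in seq_along(nodes)) {
      P <- node_partial(nodes[i])
      num <- f * P$mat[2, ]
      den <- num + (1 - f) * P$mat[1, ]
      post <- ifelse(den > 0, num / den, f)
      out[i, ] <- post
    }
    out
  }

  list(ut = function() ut, loglik = loglik, node_partial = node_partial,
       edge_loglik_fun = edge_loglik_fun, set_len = set_len,
       set_len_quiet = set_len_quiet, put_msg = put_msg,
       refresh_msg = refresh_msg,
       posteriors = posteriors, invalidate = invalidate,
       freq1 = freq1, pi0 = pi0, pi1 = pi1, K = K)
}

#' Log-likelihood of a character matrix on a tree
#'
#' Felsenstein pruning under the asymmetric two-state model: the
#' likelihood of each character is summed over root states weighted by the
#' stationary distribution of the gain/loss chain, and the per-character
#' log-likelihoods are added.  The chain is reversible, so the value does
#' not depend on where the (un)rooted tree is rooted.
#'
#' @param tree an `ape::phylo` tree with branch lengths; leaf labels must
#'   match the matrix taxa.
#' @param m a character matrix from [encode()].
#' @param p a [model_params()] object.
#' @return the log-likelihood (scalar).
#' @export
log_likelihood <- function(tree, m, p) {
  make_engine(tree, m, p)$loglik()
}

#' Optimize branch lengths by maximum likelihood
#'
#' Coordinate ascent: each branch in turn is optimized by univariate
#' maximization ([stats::optimize()]) with all other branches fixed,
#' sweeping the tree until the log-likelihood improves by less than
#' `tol` or `max_rounds` is reached.
#'
#' @param tree an `ape::phylo` tree (topology is kept).
#' @param m a character matrix from [encode()].
#' @param p a [model_params()] object.
#' @param max_t upper bound for a single branch length.
#' @param tol convergence tolerance on the log-likelihood.
#' @param max_rounds maximum number of sweeps over all branches.
#' @return the tree with optimized `edge.length` and the final
#'   log-likelihood in `attr(, "loglik")`.
#' @export
optimize_branch_lengths <- function(tree, m, p, max_t = 50,
                                    tol = 1e-3, max_rounds = 10) {
  ut0 <- as_utree(tree)
  scale_msg <- function(P) {
    sc <- pmax(P$mat[1, ], P$mat[2, ])
    sc[sc <= 0] <- 1
    list(mat = P$mat / rep(sc, each = 2), ls = P$ls + log(sc))
  }
  ascend <- function(ut, rounds) {
    eng <- make_engine(ut, m, p)
    ll <- eng$loglik()
    root <- ut$n_tip + 1L
    # preorder sweep: optimize each edge with exact current messages,
    # pushing down-messages ahead and refreshing up-messages on return
    walk <- function(u, parent) {
      for (v in eng$ut()$nbr[[u]]) {
        if (v == parent) next
        f <- eng$edge_loglik_fun(u, v)
        opt <- stats::optimize(f, interval = c(0, max_t), maximum = TRUE,
                               tol = 1e-6)
        if (opt$objective > f(ut_get_len(eng$ut(), u, v))) {
          eng$set_len_quiet(u, v, opt$maximum)
        }
        if (v > ut$n_tip) {
          eng$put_msg(u, v, scale_msg(eng$node_partial(u, exclude = v)))
          walk(v, u)
          eng$refresh_msg(v, u)
        }
      }
    }
    for (round in seq_len(rounds)) {
      eng$invalidate()
      walk(root, 0L)
      ll_new <- eng$loglik()
      improved <- ll_new - ll
      ll <- ll_new
      if (improved < tol) break
    }
    list(ut = eng$ut(), ll = ll)
  }
  # Guide trees may carry lengths in arbitrary units (or none).  The
  # stationary region of the transition function is flat, so coordinate
  # ascent started there cannot move; one sweep from both the supplied
  # lengths and a neutral start decides which basin to pursue, making
  # the result unit-agnostic.
  with_len <- ut0
  for (u in seq_along(with_len$nbr)) {
    bad <- is.na(with_len$len[[u]]) | with_len$len[[u]] <= 0
    with_len$len[[u]][bad] <- 0.5
    with_len$len[[u]] <- pmin(with_len$len[[u]], max_t)
  }
  neutral <- ut0
  for (u in seq_along(neutral$nbr)) {
    neutral$len[[u]][] <- 0.5
  }
  res1 <- ascend(with_len, 1L)
  res2 <- ascend(neutral, 1L)
  best <- if (res1$ll >= res2$ll) res1 else res2
  if (max_rounds > 1L) best <- ascend(best$ut, max_rounds - 1L)
  out <- as_phylo(best$ut)
  attr(out, "loglik") <- best$ll
  out
}
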