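#' Reconstruction accuracy of an ancestral genome
#'
#' Jaccard agreement between the reconstructed genome `G` and the true
#' genome `G'`: `|G intersect G'| / |G union G'|`, computed separately on
#' the gene-content sets (family IDs) and on the adjacency sets
#' (telomeric adjacencies excluded).  False positives are elements of the
#' reconstruction missing from the truth; false negatives the reverse.
#'
#' @param reconstructed,truth [genome()] objects.
#' @return an object of class `accuracy_report`: list with
#'   `content_accuracy`, `adjacency_accuracy`, and per-category `fp` and
#'   `fn` counts.
#' @export
accuracy <- function(reconstructed, truth) {
  stopifnot(inherits(reconstructed, "genome"), inherits(truth, "genome"))
  jacc <- function(a, b) {
    u <- length(union(a, b))
    if (u == 0) return(list(acc = 1, fp = 0L, fn = 0L))
    list(acc = length(intersect(a, b)) / u,
         fp = length(setdiff(a, b)), fn = length(setdiff(b, a)))
  }
  cont <- jacc(genome_families(reconstructed), genome_families(truth))
  adj <- jacc(genome_adj_keys(reconstructed, telomeres = FALSE),
              genome_adj_keys(truth, telomeres = FALSE))
  structure(list(content_accuracy = cont$acc,
                 adjacency_accuracy = adj$acc,
                 fp = c(content = cont$fp, adjacency = adj$fp),
                 fn = c(content = cont$fn, adjacency = adj$fn)),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf(
    "<accuracy_report> content %.4f (FP %d / FN %d), adjacency %.4f (FP %d / FN %d)\n",
    x$content_accuracy, x$fp["content"], x$fn["content"],
    x$adjacency_accuracy, x$fp["adjacency"], x$fn["adjacency"]))
  invisible(x)
}

#' Adjacencies conserved across every genome of a set
#'
#' "Non-split" adjacencies are gene pairs that were never separated
#' during the evolution relating the genomes: the intersection of all
#' genomes' adjacency sets (telomeric adjacencies excluded).
#'
#' @param gs a [genome_set()] with at least two genomes.
#' @return a data frame as returned by [genome_to_adjacencies()].
#' @export
non_split_adjacencies <- function(gs) {
  stopifnot(inherits(gs, "genome_set"))
  if (length(gs$genomes) < 2) stop("need at least 2 genomes")
  keys <- Reduce(intersect,
                 lapply(gs$genomes, genome_adj_keys, telomeres = FALSE))
  keys <- sort(keys)
  data.frame(label = if (length(keys)) adj_label(keys) else character(0),
             telomeric = rep(FALSE, length(keys)),
             key = keys, stringsAsFactors = FALSE)
}

# per-genome position table of single-copy shared families
anchor_table <- function(g, fams) {
  pos <- integer(0); chrom <- integer(0); sign_ <- integer(0)
  fam <- integer(0); within <- integer(0)
  off <- 0L
  for (ci in seq_along(g$chromosomes)) {
    ch <- g$chromosomes[[ci]]
    fam <- c(fam, abs(ch)); sign_ <- c(sign_, sign(ch))
    chrom <- c(chrom, rep(ci, length(ch)))
    within <- c(within, seq_along(ch))
    pos <- c(pos, off + seq_along(ch))
    off <- off + length(ch)
  }
  keep <- fam %in% fams
  data.frame(family = fam[keep], sign = sign_[keep], chrom = chrom[keep],
             pos = pos[keep], within = within[keep])
}

single_copy_shared <- function(a, b) {
  fa <- abs(unlist(a$chromosomes, use.names = FALSE))
  fb <- abs(unlist(b$chromosomes, use.names = FALSE))
  ta <- table(fa); tb <- table(fb)
  intersect(as.integer(names(ta)[ta == 1]), as.integer(names(tb)[tb == 1]))
}

#' Synteny blocks between two genomes
#'
#' A synteny block is a maximal run of two or more genes with identical
#' gene order and relative orientation in both genomes; a run that
#' appears reversed and sign-flipped in the second genome counts as one
#' reversed block.  Duplicated families are excluded (single-copy
#' anchors).  The summary reports the total number of syntenic genes, the
#' block count and the mean block length (genes / blocks).
#'
#' @param a,b [genome()] objects.
#' @return a list with `blocks` (data frame: chromosome, 1-based start /
#'   end gene indices per genome, `length`, `orientation`) and the
#'   summary fields `genes`, `n_blocks`, `avg_length`.
#' @export
synteny_blocks <- function(a, b) {
  stopifnot(inherits(a, "genome"), inherits(b, "genome"))
  fams <- single_copy_shared(a, b)
  empty <- list(blocks = data.frame(), genes = 0L, n_blocks = 0L,
                avg_length = NA_real_)
  if (length(fams) == 0) return(empty)
  tb <- anchor_table(b, fams)
  bpos <- tb$pos[match(fams, tb$family)]
  bchrom <- tb$chrom[match(fams, tb$family)]
  bsign <- tb$sign[match(fams, tb$family)]
  bwithin <- tb$within[match(fams, tb$family)]
  blocks <- list()
  for (ci in seq_along(a$chromosomes)) {
    ch <- a$chromosomes[[ci]]
    keep <- which(abs(ch) %in% fams)
    if (length(keep) < 2) next
    run <- list(start = NULL)
    flush <- function(run_idx, orient) {
      if (length(run_idx) < 2) return()
      i <- match(abs(ch[run_idx]), fams)
      blocks[[length(blocks) + 1L]] <<- data.frame(
        chrom_a = ci, start_a = run_idx[1], end_a = run_idx[length(run_idx)],
        chrom_b = bchrom[i[1]],
        start_b = min(bwithin[i]), end_b = max(bwithin[i]),
        length = length(run_idx),
        orientation = if (orient > 0) "forward" else "reversed",
        stringsAsFactors = FALSE)
    }
    cur <- keep[1]; orient <- 0L
    for (j in seq_along(keep)[-1]) {
      p <- keep[j - 1]; q <- keep[j]
      # consecutive anchors in a must be consecutive in the same
      # chromosome of b, same relative order and orientation, and
      # contiguous in a (strict rule: no gaps)
      ip <- match(abs(ch[p]), fams); iq <- match(abs(ch[q]), fams)
      contiguous_a <- q == p + 1L
      same_chrom <- bchrom[ip] == bchrom[iq]
      dirn <- bpos[iq] - bpos[ip]
      fwd_ok <- dirn == 1L && sign(ch[p]) == bsign[ip] &&
        sign(ch[q]) == bsign[iq]
      rev_ok <- dirn == -1L && sign(ch[p]) == -bsign[ip] &&
        sign(ch[q]) == -bsign[iq]
      step_orient <- if (fwd_ok) 1L else if (rev_ok) -1L else 0L
      extend <- contiguous_a && same_chrom && step_orient != 0L &&
        (orient == 0L || orient == step_orient)
      if (extend) {
        cur <- c(cur, q)
        orient <- step_orient
      } else {
        flush(cur, orient)
        cur <- q
        orient <- 0L
      }
    }
    flush(cur, orient)
  }
  if (length(blocks) == 0) return(empty)
  bl <- do.call(rbind, blocks)
  rownames(bl) <- NULL
  list(blocks = bl, genes = sum(bl$length), n_blocks = nrow(bl),
       avg_length = sum(bl$length) / nrow(bl))
}

#' Dot-plot coordinates between two genomes
#'
#' One point per shared single-copy family: cumulative 1-based gene
#' indices in each genome, the chromosomes the gene sits on, and whether
#' the signs agree.
#'
#' @param a,b [genome()] objects.
#' @return a data frame with columns `family`, `pos_a`, `pos_b`,
#'   `chrom_a`, `chrom_b`, `same_sign`.
#' @export
dotplot_coords <- function(a, b) {
  fams <- single_copy_shared(a, b)
  if (length(fams) == 0) {
    return(data.frame(family = integer(0), pos_a = integer(0),
                      pos_b = integer(0), chrom_a = integer(0),
                      chrom_b = integer(0), same_sign = logical(0)))
  }
  ta <- anchor_table(a, fams)
  tbl <- anchor_table(b, fams)
  ia <- match(fams, ta$family); ib <- match(fams, tbl$family)
  out <- data.frame(family = fams,
                    pos_a = ta$pos[ia], pos_b = tbl$pos[ib],
                    chrom_a = ta$chrom[ia], chrom_b = tbl$chrom[ib],
                    same_sign = ta$sign[ia] == tbl$sign[ib])
  out[order(out$pos_a), , drop = FALSE]
}
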