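#' Construct a genome from signed gene orders
#'
#' A genome is a named set of linear chromosomes; each chromosome is an
#' ordered vector of signed integer family identifiers.  The sign encodes
#' the strand (reading direction) of the gene.  Family identifiers may
#' repeat within a genome (duplicated genes); zero is not a valid
#' identifier.
#'
#' @param name taxon label (single non-empty string).
#' @param chromosomes list of integer vectors, one per linear chromosome.
#' @return an object of class `genome`.
#' @examples
#' g <- genome("G1", list(c(1L, -2L, 3L, 4L)))
#' @export
genome <- function(name, chromosomes) {
  if (!is.character(name) || length(name) != 1 || !nzchar(name)) {
    stop("genome name must be a single non-empty string")
  }
  if (!is.list(chromosomes) || length(chromosomes) == 0) {
    stop("empty genome: '", name, "' has no chromosomes")
  }
  chromosomes <- lapply(chromosomes, function(ch) {
    ch <- as.integer(ch)
    if (length(ch) == 0) stop("genome '", name, "': empty chromosome")
    if (anyNA(ch) || any(ch == 0L)) {
      stop("genome '", name, "': family IDs must be non-zero integers")
    }
    ch
  })
  structure(list(name = name, chromosomes = chromosomes), class = "genome")
}

#' @export
print.genome <- function(x, ...) {
  cat("<genome>", x$name, "-", length(x$chromosomes), "chromosome(s),",
      sum(lengths(x$chromosomes)), "genes\n")
  invisible(x)
}

#' Bundle genomes into a genome set
#'
#' @param genomes list of [genome()] objects with unique taxon names.
#' @return an object of class `genome_set` with elements `genomes` (named
#'   list) and `family_universe` (sorted vector of all family IDs observed).
#' @export
genome_set <- function(genomes) {
  if (!is.list(genomes) || length(genomes) == 0) stop("no genomes supplied")
  genomes <- lapply(genomes, function(g) {
    if (!inherits(g, "genome")) stop("all elements must be genome objects")
    g
  })
  nm <- vapply(genomes, function(g) g$name, character(1))
  if (anyDuplicated(nm)) {
    stop("duplicate taxon name: ", nm[duplicated(nm)][1])
  }
  names(genomes) <- nm
  fam <- sort(unique(unlist(lapply(genomes, genome_families),
                            use.names = FALSE)))
  structure(list(genomes = genomes, family_universe = fam),
            class = "genome_set")
}

#' @export
print.genome_set <- function(x, ...) {
  cat("<genome_set>", length(x$genomes), "genomes,",
      length(x$family_universe), "gene families\n")
  invisible(x)
}

#' Read genomes from a GRIMM-style gene-order file
#'
#' The dialect is the de-facto standard of genome rearrangement tools:
#' a `>name` header line starts each genome, chromosomes are
#' whitespace-separated signed integers, and `$` terminates a linear
#' chromosome (chromosomes may span lines).  Circular chromosomes
#' (`@` terminator) are rejected: the package models linear (nuclear)
#' chromosomes only.  Lines starting with `#` are comments.
#'
#' @param path path to the gene-order file.
#' @return a [genome_set()].
#' @export
read_gene_orders <- function(path) {
  lines <- readLines(path)
  genomes <- list()
  cur_name <- NULL
  cur_chroms <- list()
  buf <- integer(0)
  flush_genome <- function() {
    if (is.null(cur_name)) return()
    if (length(buf) > 0) {
      stop("genome '", cur_name, "': chromosome not terminated by '$'")
    }
    if (length(cur_chroms) == 0) stop("empty genome: '", cur_name, "'")
    if (cur_name %in% vapply(genomes, function(g) g$name, character(1))) {
      stop("duplicate taxon name: '", cur_name, "'")
    }
    genomes[[length(genomes) + 1L]] <<- genome(cur_name, cur_chroms)
  }
  for (i in seq_along(lines)) {
    line <- trimws(lines[i])
    if (!nzchar(line) || startsWith(line, "#")) next
    if (startsWith(line, ">")) {
      flush_genome()
      cur_name <- trimws(substring(line, 2))
      if (!nzchar(cur_name)) stop("line ", i, ": empty genome name")
      cur_chroms <- list()
      buf <- integer(0)
      next
    }
    if (is.null(cur_name)) stop("line ", i, ": gene data before '>' header")
    for (tok in strsplit(line, "\\s+")[[1]]) {
      if (tok == "$") {
        if (length(buf) == 0) stop("line ", i, ": empty chromosome")
        cur_chroms[[length(cur_chroms) + 1L]] <- buf
        buf <- integer(0)
      } else if (tok == "@") {
        stop("line ", i, ": circular chromosomes ('@') are not supported")
      } else {
        v <- suppressWarnings(as.integer(tok))
        if (is.na(v) || v == 0L) {
          stop("line ", i, ": malformed token '", tok, "'")
        }
        buf <- c(buf, v)
      }
    }
  }
  flush_genome()
  genome_set(genomes)
}

#' Write genomes in canonical GRIMM form
#'
#' The canonical writer sorts genomes by taxon name and writes one
#' chromosome per line, terminated by `$`, so `write_gene_orders()` after
#' [read_gene_orders()] is the identity on canonical files.
#'
#' @param gs a [genome_set()] or single [genome()].
#' @param path output file path.
#' @export
write_gene_orders <- function(gs, path) {
  if (inherits(gs, "genome")) gs <- genome_set(list(gs))
  stopifnot(inherits(gs, "genome_set"))
  nm <- sort(names(gs$genomes), method = "radix")
  out <- unlist(lapply(nm, function(n) {
    g <- gs$genomes[[n]]
    c(paste0(">", n),
      vapply(g$chromosomes,
             function(ch) paste(c(ch, "$"), collapse = " "), character(1)))
  }), use.names = FALSE)
  writeLines(out, path)
  invisible(path)
}

#' Read a phylogenetic tree in Newick format
#'
#' @param path path to a Newick file.
#' @param binary require a fully resolved (binary) tree; an unrooted tree
#'   is binary when every internal node has degree three, a rooted one when
#'   the root has degree two and all other internal nodes degree three.
#' @return an `ape::phylo` tree.
#' @export
read_newick <- function(path, binary = FALSE) {
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) stop("Newick parse error: ",
                                          conditionMessage(e)))
  if (is.null(tr)) stop("Newick parse error in '", path, "'")
  if (!is.null(tr$edge.length) && anyNA(tr$edge.length)) {
    stop("non-numeric branch length in '", path, "'")
  }
  if (binary) assert_binary_tree(tr)
  tr
}

#' Write a tree in Newick format
#'
#' Branch lengths are written with 15 significant digits so that writing
#' and re-reading preserves them to within 1e-12; internal node labels
#' (e.g. bootstrap supports) are preserved.
#'
#' @param tree an `ape::phylo` tree.
#' @param path output file path.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  edge_idx <- seq_len(nrow(tree$edge))
  blen_of <- rep(NA_real_, ntip + tree$Nnode)
  if (!is.null(tree$edge.length)) blen_of[tree$edge[, 2]] <- tree$edge.length
  fmt <- function(node) {
    lab <- if (node <= ntip) {
      tree$tip.label[node]
    } else {
      inner <- paste(vapply(kids[[as.character(node)]], fmt, character(1)),
                     collapse = ",")
      nl <- if (!is.null(tree$node.label)) tree$node.label[node - ntip] else ""
      if (is.na(nl)) nl <- ""
      paste0("(", inner, ")", nl)
    }
    bl <- blen_of[node]
    if (!is.na(bl)) paste0(lab, ":", sprintf("%.15g", bl)) else lab
  }
  writeLines(paste0(fmt(root), ";"), path)
  invisible(path)
}

#' Check that a tree is binary
#'
#' @param tree an `ape::phylo` tree.
#' @return invisibly `TRUE`; errors if the tree is not binary.
#' @export
assert_binary_tree <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  deg <- tabulate(c(tree$edge[, 1], tree$edge[, 2]), ntip + tree$Nnode)
  internal <- deg[(ntip + 1L):(ntip + tree$Nnode)]
  root_deg <- deg[ntip + 1L]
  ok <- all(deg[seq_len(ntip)] == 1L) &&
    (all(internal == 3L) ||
       (root_deg == 2L && all(internal[-1L] == 3L)))
  if (!ok) stop("tree is not binary (fully resolved)")
  invisible(TRUE)
}
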