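#' Extract the gene adjacencies of a genome
#'
#' Each gene has a head (5' end) and a tail (3' end).  For two consecutive
#' signed genes `a, b` on a chromosome, the right end of `a` (tail if
#' `a > 0`, head if `a < 0`) forms an adjacency with the left end of `b`
#' (head if `b > 0`, tail if `b < 0`).  A gene order `{1, -2, 3, 4}` thus
#' yields the adjacency set `{1t,2t}, {2h,3h}, {3t,4h}`.  With
#' `include_telomeres = TRUE` every chromosome additionally contributes
#' two extremity-telomere adjacencies.
#'
#' @param g a [genome()].
#' @param include_telomeres also report extremity-telomere adjacencies.
#' @return a data frame with one row per distinct adjacency: `label`
#'   (canonical, e.g. `"1t|2t"` or `"4h|T"`), `telomeric`, and the packed
#'   numeric `key` used internally.
#' @export
genome_to_adjacencies <- function(g, include_telomeres = FALSE) {
  stopifnot(inherits(g, "genome"))
  keys <- genome_adj_keys(g, telomeres = include_telomeres)
  keys <- sort(keys)
  data.frame(label = adj_label(keys),
             telomeric = adj_is_telomeric(keys),
             key = keys,
             stringsAsFactors = FALSE)
}

#' Encode a genome set as a binary character matrix
#'
#' Rows are taxa; columns are presence/absence characters of two classes:
#' one column per gene adjacency observed in any genome (class `A`) and
#' one per gene family (class `C`, genome content).  Duplicated genes stay
#' binary in the matrix: a family's content character is 1 for any copy
#' number, and copy numbers of two or more are recorded in the side table
#' `duplicate_table`.  Column order is deterministic: adjacency columns
#' sorted by canonical extremity pair, then content columns by family ID.
#'
#' Telomeric adjacencies are excluded from the character matrix by default
#' (they are still available to the assembly stage via
#' [genome_to_adjacencies()]); set `include_telomeres = TRUE` to encode
#' them as characters too.
#'
#' @param gs a [genome_set()] with at least two genomes.
#' @param include_telomeres encode telomeric adjacencies as characters.
#' @return an object of class `bcm`: list with `taxa`, `mat` (0/1 integer
#'   matrix, column names are character labels `"A:..."`/`"C:..."`),
#'   `col_class` (`"A"`/`"C"` per column), `adj_keys`, `families`, and
#'   `duplicate_table` (taxon, family, copies >= 2).
#' @export
encode <- function(gs, include_telomeres = FALSE) {
  stopifnot(inherits(gs, "genome_set"))
  if (length(gs$genomes) < 2) stop("need at least 2 genomes to encode")
  adj_sets <- lapply(gs$genomes, genome_adj_keys,
                     telomeres = include_telomeres)
  adj_univ <- sort(unique(unlist(adj_sets, use.names = FALSE)))
  fams <- gs$family_universe
  taxa <- names(gs$genomes)
  K <- length(adj_univ) + length(fams)
  mat <- matrix(0L, nrow = length(taxa), ncol = K,
                dimnames = list(taxa, c(paste0("A:", adj_label(adj_univ)),
                                        paste0("C:", fams))))
  dup <- list()
  for (i in seq_along(taxa)) {
    g <- gs$genomes[[i]]
    mat[i, seq_along(adj_univ)] <-
      as.integer(adj_univ %in% adj_sets[[i]])
    cnt <- table(abs(unlist(g$chromosomes, use.names = FALSE)))
    present <- as.integer(names(cnt))
    mat[i, length(adj_univ) + match(present, fams)] <- 1L
    multi <- cnt[cnt >= 2]
    if (length(multi)) {
      dup[[length(dup) + 1L]] <- data.frame(
        taxon = taxa[i], family = as.integer(names(multi)),
        copies = as.integer(multi), stringsAsFactors = FALSE)
    }
  }
  dup_tab <- if (length(dup)) do.call(rbind, dup) else
    data.frame(taxon = character(0), family = integer(0),
               copies = integer(0), stringsAsFactors = FALSE)
  rownames(dup_tab) <- NULL
  structure(list(taxa = taxa, mat = mat,
                 col_class = rep(c("A", "C"),
                                 c(length(adj_univ), length(fams))),
                 adj_keys = adj_univ, families = fams,
                 duplicate_table = dup_tab,
                 include_telomeres = include_telomeres),
            class = "bcm")
}

#' @export
print.bcm <- function(x, ...) {
  cat("<bcm>", length(x$taxa), "taxa x", ncol(x$mat), "characters (",
      length(x$adj_keys), "adjacency,", length(x$families), "content ),",
      nrow(x$duplicate_table), "duplicate records\n")
  invisible(x)
}

#' Decode a character-matrix column label
#'
#' Inverse of the labelling used by [encode()].
#'
#' @param label a column label such as `"A:1t|2t"` or `"C:5"`.
#' @return for adjacency columns, a list with `type = "adjacency"`,
#'   extremity fields and the packed key; for content columns a list with
#'   `type = "content"` and the `family` ID.
#' @export
decode_column <- function(label) {
  stopifnot(is.character(label), length(label) == 1)
  if (startsWith(label, "A:")) {
    key <- parse_adj_label(substring(label, 3))
    e1 <- adj_ext1(key); e2 <- adj_ext2(key)
    list(type = "adjacency",
         ext1 = if (e1 == 0) "T" else
           list(family = as.integer(ext_family(e1)), end = ext_end(e1)),
         ext2 = list(family = as.integer(ext_family(e2)), end = ext_end(e2)),
         telomeric = e1 == 0, key = key)
  } else if (startsWith(label, "C:")) {
    fam <- suppressWarnings(as.integer(substring(label, 3)))
    if (is.na(fam) || fam <= 0) stop("unknown column label: ", label)
    list(type = "content", family = fam)
  } else {
    stop("unknown column label: ", label)
  }
}

#' Export a binary character matrix as relaxed PHYLIP
#'
#' Binary states are written as `0`/`1`; the header holds taxon and
#' character counts.  The format is accepted by external maximum
#' likelihood programs that support binary data.
#'
#' @param m a [encode()] matrix.
#' @param path output file path.
#' @export
write_phylip <- function(m, path) {
  stopifnot(inherits(m, "bcm"))
  rows <- apply(m$mat, 1, paste, collapse = "")
  writeLines(c(paste(nrow(m$mat), ncol(m$mat)),
               paste(m$taxa, rows)), path)
  invisible(path)
}

#' Export a binary character matrix as TSV with header labels
#'
#' @param m a [encode()] matrix.
#' @param path output file path.
#' @export
write_bcm_tsv <- function(m, path) {
  stopifnot(inherits(m, "bcm"))
  df <- data.frame(taxon = m$taxa, m$mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
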