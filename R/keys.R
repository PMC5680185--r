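# Integer keys for gene extremities and adjacencies.
#
# Every gene family f has two extremities: the head (5' end) and the tail
# (3' end).  They are packed into integers so that adjacency sets can be
# manipulated as numeric vectors: head(f) = 2f, tail(f) = 2f + 1, and the
# chromosome end (telomere) is 0.  An unordered extremity pair is packed
# into a single double, smaller extremity first; EXT_MULT bounds the
# extremity key at 2^26 so the packed key stays below 2^53 (exact doubles).

EXT_MULT <- 2^26

ext_key <- function(family, end) {
  2 * family + as.integer(end == "t")
}

ext_family <- function(key) key %/% 2

ext_end <- function(key) c("h", "t")[key %% 2 + 1]

ext_label <- function(key) {
  ifelse(key == 0, "T", paste0(key %/% 2, c("h", "t")[key %% 2 + 1]))
}

parse_ext_label <- function(lab) {
  if (identical(lab, "T")) return(0)
  end <- substr(lab, nchar(lab), nchar(lab))
  fam <- suppressWarnings(as.integer(substr(lab, 1L, nchar(lab) - 1L)))
  if (is.na(fam) || !end %in% c("h", "t")) {
    stop("malformed extremity label: ", lab)
  }
  ext_key(fam, end)
}

adj_key <- function(e1, e2) pmin(e1, e2) * EXT_MULT + pmax(e1, e2)

adj_ext1 <- function(key) key %/% EXT_MULT

adj_ext2 <- function(key) key %% EXT_MULT

adj_is_telomeric <- function(key) adj_ext1(key) == 0

# canonical printed form: gene extremities ordered by key, telomere last
adj_label <- function(key) {
  e1 <- adj_ext1(key)
  e2 <- adj_ext2(key)
  ifelse(e1 == 0,
         paste0(ext_label(e2), "|T"),
         paste0(ext_label(e1), "|", ext_label(e2)))
}

parse_adj_label <- function(lab) {
  parts <- strsplit(lab, "|", fixed = TRUE)[[1]]
  if (length(parts) != 2) stop("malformed adjacency label: ", lab)
  adj_key(parse_ext_label(parts[1]), parse_ext_label(parts[2]))
}

# extremity on the left/right flank of a signed gene as read along the
# chromosome: +f is traversed head->tail, -f tail->head
left_ext <- function(x) 2 * abs(x) + (x < 0)

right_ext <- function(x) 2 * abs(x) + (x > 0)

# adjacency keys of one chromosome (ordered signed vector)
chrom_adj_keys <- function(ch, telomeres = FALSE) {
  n <- length(ch)
  keys <- if (n >= 2) {
    adj_key(right_ext(ch[-n]), left_ext(ch[-1]))
  } else {
    numeric(0)
  }
  if (telomeres && n >= 1) {
    keys <- c(keys, adj_key(0, left_ext(ch[1])), adj_key(0, right_ext(ch[n])))
  }
  keys
}

# set of adjacency keys of a genome (duplicates collapse: set semantics)
genome_adj_keys <- function(g, telomeres = FALSE) {
  unique(unlist(lapply(g$chromosomes, chrom_adj_keys, telomeres = telomeres),
                use.names = FALSE))
}

# extremity keys at chromosome ends (telomeric extremities) of a genome
genome_telomere_exts <- function(g) {
  unique(unlist(lapply(g$chromosomes, function(ch) {
    c(left_ext(ch[1]), right_ext(ch[length(ch)]))
  }), use.names = FALSE))
}

genome_families <- function(g) {
  sort(unique(abs(unlist(g$chromosomes, use.names = FALSE))))
}
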