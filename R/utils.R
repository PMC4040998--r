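# Internal helpers shared across modules.

.pkg_env <- new.env(parent = emptyenv())

BASES <- c("A", "C", "G", "T")

#' Codon -> amino acid lookup under the bacterial genetic code
#'
#' Named character vector mapping all 64 codons to one-letter amino acids
#' ("*" for stop), translation table 11.  Cached after first use.
#' @return named character vector of length 64
#' @keywords internal
codon_table <- function() {
  if (is.null(.pkg_env$codon_table)) {
    codons <- as.vector(outer(outer(BASES, BASES, paste0), BASES, paste0))
    aa <- vapply(codons, function(cd) {
      seqinr::translate(strsplit(cd, "")[[1]], numcode = 11)
    }, character(1))
    .pkg_env$codon_table <- stats::setNames(aa, codons)
  }
  .pkg_env$codon_table
}

#' Codons whose third position is 4-fold degenerate
#' @return character vector of codons
#' @keywords internal
fourfold_codons <- function() {
  if (is.null(.pkg_env$fourfold)) {
    tab <- codon_table()
    codons <- names(tab)
    ff <- vapply(codons, function(cd) {
      pre <- substr(cd, 1, 2)
      aas <- tab[paste0(pre, BASES)]
      length(unique(aas)) == 1L && !any(aas == "*")
    }, logical(1))
    .pkg_env$fourfold <- codons[ff]
  }
  .pkg_env$fourfold
}

# split a DNA string into codons (uppercase)
split_codons <- function(seq) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n %% 3L != 0L) stop("sequence length not a multiple of 3")
  substring(seq, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}

# character matrix (sequences x positions) from a named character vector
seq_matrix <- function(seqs) {
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) stop("sequences differ in length")
  m <- do.call(rbind, strsplit(toupper(seqs), ""))
  rownames(m) <- names(seqs)
  m
}

# union-find for single-linkage clustering; returns integer component labels
single_linkage_components <- function(ids, pairs_i, pairs_j) {
  parent <- seq_along(ids)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (k in seq_along(pairs_i)) {
    ri <- find(pairs_i[k]); rj <- find(pairs_j[k])
    if (ri != rj) parent[ri] <- rj
  }
  roots <- vapply(seq_along(ids), find, integer(1))
  match(roots, unique(roots))
}

# count of pairwise differences between rows of a character matrix
hamming_matrix <- function(m) {
  n <- nrow(m)
  d <- matrix(0L, n, n, dimnames = list(rownames(m), rownames(m)))
  if (n < 2L) return(d)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      dij <- sum(m[i, ] != m[j, ])
      d[i, j] <- d[j, i] <- dij
    }
  }
  d
}

`%||%` <- function(a, b) if (is.null(a)) b else a
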