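# Independent oracles and construction helpers used across tests.

# small config for fast simulations
tiny_cfg <- function(..., seed = 1) {
  defaults <- list(n_strains = c(focal = 12, sister = 6, outA = 2, outB = 1),
                   n_genes = c(chr = 100), replicon_lengths = c(chr = 1e5),
                   n_core_clusters = 200, n_ht_events = 40,
                   aln_n_genes = 5, seed = seed)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

# brute-force Snn: independent double-loop implementation
snn_oracle <- function(seqs, pops) {
  m <- do.call(rbind, strsplit(seqs, ""))
  n <- nrow(m)
  xs <- numeric(n)
  for (j in 1:n) {
    ds <- sapply(setdiff(1:n, j), function(k) sum(m[j, ] != m[k, ]))
    others <- setdiff(1:n, j)
    nn <- others[ds == min(ds)]
    xs[j] <- sum(pops[nn] == pops[j]) / length(nn)
  }
  mean(xs)
}

# brute-force mean pairwise difference per site over haplotypes
pi_oracle <- function(hap, L) {
  n <- nrow(hap)
  tot <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) tot <- tot + sum(hap[i, ] != hap[j, ])
  tot / choose(n, 2) / L
}

# independent Tajima's D from a spectrum, straight from the 1989 formulas
tajima_oracle <- function(counts, n, L) {
  S <- sum(counts)
  i <- seq_along(counts)
  a1 <- sum(1 / (1:(n - 1)))
  a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  pi_hat <- sum(2 * i * (n - i) / (n * (n - 1)) * counts)
  (pi_hat - S / a1) / sqrt((c1 / a1) * S + (c2 / (a1^2 + a2)) * S * (S - 1))
}

# build a codon_alignment from explicit sequence vectors
make_aln <- function(ingroup_seqs, outgroup_seqs, gene = "g1") {
  names(ingroup_seqs) <- paste0("in", seq_along(ingroup_seqs))
  names(outgroup_seqs) <- paste0("out", seq_along(outgroup_seqs))
  aln <- list(gene = gene, seqs = c(ingroup_seqs, outgroup_seqs),
              ingroup = names(ingroup_seqs),
              outgroup = names(outgroup_seqs))
  class(aln) <- "codon_alignment"
  aln
}

# minimal gene_presence_matrix from a 0/1 matrix and species labels
make_matrix <- function(presence, species) {
  meta <- data.frame(cluster_id = rownames(presence),
                     replicon = "chr", cog = "S",
                     gc = 0.6, stringsAsFactors = FALSE)
  out <- list(presence = presence > 0, species = species, meta = meta,
              order = NULL)
  class(out) <- "gene_presence_matrix"
  out
}

# minimal duplication_callset from a carrier-count vector
make_callset <- function(carrier_counts, gene_calls = NULL, strains = NULL) {
  out <- list(gene_calls = gene_calls %||% data.frame(
                gene_id = character(0), strain = character(0),
                duplicated = logical(0)),
              carrier_counts = carrier_counts,
              events = NULL, strains = strains %||% character(0))
  class(out) <- "duplication_callset"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
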