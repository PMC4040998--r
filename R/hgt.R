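#' Identify horizontally transferred genes from phyletic patterns
#'
#' A cluster is called HT for the focal species iff it is present in at
#' least one focal strain and absent from every strain of every other
#' species in the matrix.  With the focal pair being the two most closely
#' related species in the sample, genes private to one of them are inferred
#' to have been acquired after the pair diverged (de novo gene origination,
#' which is rare, is ignored).
#'
#' @param matrix a `gene_presence_matrix` (see [simulate_pangenome()] or
#'   [read_presence_matrix()])
#' @param focal focal species name
#' @return an `ht_gene_set`: data.frame with cluster_id, carrier_count,
#'   sample_size, frequency, fixed, replicon, cog, gc; plus attributes
#'   `focal` and `n`
#' @export
identify_ht_genes <- function(matrix, focal) {
  if (!focal %in% matrix$species) stop("focal species absent from matrix")
  focal_cols <- names(matrix$species)[matrix$species == focal]
  other_cols <- names(matrix$species)[matrix$species != focal]
  pres <- matrix$presence
  in_focal <- rowSums(pres[, focal_cols, drop = FALSE])
  in_other <- rowSums(pres[, other_cols, drop = FALSE])
  ht <- in_focal >= 1L & in_other == 0L
  n <- length(focal_cols)
  out <- data.frame(cluster_id = rownames(pres)[ht],
                    carrier_count = as.integer(in_focal[ht]),
                    sample_size = n,
                    frequency = as.numeric(in_focal[ht]) / n,
                    fixed = in_focal[ht] == n,
                    stringsAsFactors = FALSE, row.names = NULL)
  mi <- match(out$cluster_id, matrix$meta$cluster_id)
  out$replicon <- matrix$meta$replicon[mi]
  out$cog <- matrix$meta$cog[mi]
  out$gc <- matrix$meta$gc[mi]
  attr(out, "focal") <- focal
  attr(out, "n") <- n
  class(out) <- c("ht_gene_set", "data.frame")
  out
}

#' Spatial clustering of HT genes along each carrier genome
#'
#' Within each carrier strain's gene order, HT genes separated by at most
#' `max_gap` intervening non-HT genes are joined into one spatial cluster
#' (transitive closure).  Per HT gene the median of its cluster sizes across
#' its carrier strains is reported.
#'
#' @param htset an `ht_gene_set`
#' @param gene_order named list: per strain, the vector of cluster ids in
#'   genomic order (as in `gene_presence_matrix$order`)
#' @param max_gap maximum number of intervening non-HT genes
#' @return list: `per_gene` (data.frame cluster_id, median_cluster_size),
#'   `per_strain` (list of per-strain cluster assignments)
#' @export
ht_spatial_clusters <- function(htset, gene_order, max_gap = 3L) {
  ht_ids <- htset$cluster_id
  sizes <- stats::setNames(vector("list", length(ht_ids)), ht_ids)
  per_strain <- list()
  for (st in names(gene_order)) {
    ord <- gene_order[[st]]
    pos <- which(ord %in% ht_ids)
    if (length(pos) == 0) next
    gaps <- diff(pos) - 1L          # intervening non-HT genes
    cl <- cumsum(c(1L, gaps > max_gap))
    asg <- data.frame(strain = st, cluster_id = ord[pos],
                      spatial_cluster = cl, stringsAsFactors = FALSE)
    per_strain[[st]] <- asg
    cs <- table(cl)
    for (k in seq_along(pos)) {
      id <- ord[pos[k]]
      sizes[[id]] <- c(sizes[[id]], as.integer(cs[[as.character(cl[k])]]))
    }
  }
  med <- vapply(sizes, function(s) {
    if (is.null(s)) NA_real_ else stats::median(s)
  }, numeric(1))
  list(per_gene = data.frame(cluster_id = ht_ids,
                             median_cluster_size = unname(med[ht_ids]),
                             stringsAsFactors = FALSE),
       per_strain = per_strain)
}

#' Correlation between HT gene frequency and spatial cluster size
#'
#' Pearson correlation between per-gene population frequency and median
#' spatial cluster size, with df = number of genes - 2.
#'
#' @param htset an `ht_gene_set`
#' @param cluster_sizes `per_gene` data.frame from [ht_spatial_clusters()]
#' @return list: r, df, p, undefined (flag set when either variable has
#'   zero variance)
#' @export
frequency_clustersize_correlation <- function(htset, cluster_sizes) {
  m <- merge(htset[, c("cluster_id", "frequency")], cluster_sizes,
             by = "cluster_id")
  m <- m[stats::complete.cases(m), ]
  if (nrow(m) < 3) stop("need at least 3 HT genes")
  if (stats::sd(m$frequency) == 0 || stats::sd(m$median_cluster_size) == 0)
    return(list(r = NA_real_, df = nrow(m) - 2L, p = NA_real_,
                undefined = TRUE))
  ct <- stats::cor.test(m$frequency, m$median_cluster_size)
  list(r = unname(ct$estimate), df = unname(ct$parameter),
       p = ct$p.value, undefined = FALSE)
}

#' Fixation of HT genes across COG categories
#'
#' Chi-square contingency test of fixed versus segregating status across COG
#' categories holding at least `min_genes` HT genes, plus the per-category
#' fixed proportion.  For any 2x2 sub-table (category versus rest) with an
#' expected cell below 5, Fisher's exact test is used for that category's
#' individual comparison; the omnibus test remains chi-square.
#'
#' @param htset an `ht_gene_set`
#' @param min_genes minimum HT genes for a category to enter the test
#' @return list: statistic, df, p, per_category (data.frame cog, n, n_fixed,
#'   prop_fixed, p_vs_rest, test)
#' @export
cog_fixation_contingency <- function(htset, min_genes = 50L) {
  tab <- table(htset$cog, htset$fixed)
  n_cat <- rowSums(tab)
  keep <- names(n_cat)[n_cat >= min_genes]
  if (length(keep) < 2) stop("fewer than 2 COG categories with enough HT genes")
  sub <- htset[htset$cog %in% keep, ]
  ct <- table(factor(sub$cog, levels = keep),
              factor(sub$fixed, levels = c(FALSE, TRUE)))
  chi <- suppressWarnings(stats::chisq.test(ct, correct = FALSE))
  per <- do.call(rbind, lapply(keep, function(cg) {
    a <- sum(sub$cog == cg & sub$fixed)
    b <- sum(sub$cog == cg & !sub$fixed)
    c2 <- sum(sub$cog != cg & sub$fixed)
    d <- sum(sub$cog != cg & !sub$fixed)
    m2 <- matrix(c(a, b, c2, d), 2)
    expct <- outer(rowSums(m2), colSums(m2)) / sum(m2)
    if (any(expct < 5)) {
      p <- stats::fisher.test(m2)$p.value
      test <- "fisher"
    } else {
      p <- suppressWarnings(stats::chisq.test(m2, correct = FALSE)$p.value)
      test <- "chisq"
    }
    data.frame(cog = cg, n = a + b, n_fixed = a, prop_fixed = a / (a + b),
               p_vs_rest = p, test = test, stringsAsFactors = FALSE)
  }))
  list(statistic = unname(chi$statistic), df = unname(chi$parameter),
       p = chi$p.value, per_category = per)
}

#' GC-content distributions of HT versus core genes
#'
#' Histograms of per-gene GC fraction for the two classes plus the
#' two-sample Kolmogorov-Smirnov comparison.
#'
#' @param ht_gc,core_gc numeric vectors of GC fractions
#' @param binwidth histogram bin width over \[0, 1\]
#' @return list: breaks, ht_density, core_density, ks_statistic, ks_p
#' @export
gc_distributions <- function(ht_gc, core_gc, binwidth = 0.02) {
  if (length(ht_gc) == 0 || length(core_gc) == 0) stop("empty GC class")
  breaks <- seq(0, 1, by = binwidth)
  h1 <- graphics::hist(ht_gc, breaks = breaks, plot = FALSE)
  h2 <- graphics::hist(core_gc, breaks = breaks, plot = FALSE)
  ks <- suppressWarnings(stats::ks.test(ht_gc, core_gc))
  list(breaks = breaks, ht_density = h1$density, core_density = h2$density,
       ks_statistic = unname(ks$statistic), ks_p = ks$p.value)
}

#' Infer a 1:1 ortholog map between two gene sets
#'
#' Pairs passing identity >= `min_identity`, alignment coverage >
#' `min_coverage` and synteny are candidate orthologs; any gene involved in
#' more than one passing pair is dropped so the map is strictly 1:1.
#'
#' @param identity_table data.frame with columns `gene_a`, `gene_b`,
#'   `identity` (amino-acid fraction), `coverage` (aligned fraction of gene
#'   length) and logical `syntenic`
#' @param min_identity,min_coverage thresholds
#' @return data.frame `gene_focal`, `gene_outgroup`
#' @export
infer_ortholog_map <- function(identity_table, min_identity = 0.90,
                               min_coverage = 0.95) {
  it <- identity_table
  pass <- it$identity >= min_identity & it$coverage > min_coverage &
    it$syntenic
  it <- it[pass, , drop = FALSE]
  multi_a <- names(which(table(it$gene_a) > 1))
  multi_b <- names(which(table(it$gene_b) > 1))
  it <- it[!(it$gene_a %in% multi_a) & !(it$gene_b %in% multi_b), ,
           drop = FALSE]
  data.frame(gene_focal = it$gene_a, gene_outgroup = it$gene_b,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Infer within-genome gene families
#'
#' Single-linkage clustering of genes under the relation
#' identity > `min_identity` and coverage > `min_coverage`: if a-b and b-c
#' pass, a, b and c form one family even if a-c fails.
#'
#' @param gene_ids character vector of all genes in the genome
#' @param identity_table data.frame `gene_a`, `gene_b`, `identity`,
#'   `coverage` (within-genome pairs; missing pairs are non-passing)
#' @param min_identity,min_coverage thresholds (strict >)
#' @return named character vector gene id -> family id
#' @export
infer_gene_families <- function(gene_ids, identity_table,
                                min_identity = 0.95, min_coverage = 0.95) {
  it <- identity_table
  pass <- it$identity > min_identity & it$coverage > min_coverage
  it <- it[pass, , drop = FALSE]
  i <- match(it$gene_a, gene_ids)
  j <- match(it$gene_b, gene_ids)
  ok <- !is.na(i) & !is.na(j)
  comp <- single_linkage_components(gene_ids, i[ok], j[ok])
  stats::setNames(sprintf("fam%04d", comp), gene_ids)
}

#' Pairwise amino-acid identity of aligned sequences
#'
#' Computes percent identity and coverage for pairs of pre-aligned coding
#' sequences (equal length, gaps as "-").  Identity is the fraction of
#' identical amino acids among columns where neither sequence is gapped;
#' coverage is the fraction of such columns relative to the shorter
#' ungapped sequence length.
#'
#' @param seqs_a,seqs_b named character vectors of aligned DNA sequences
#'   (same alignment length); if `seqs_b` is `NULL`, all within-set pairs of
#'   `seqs_a` are compared
#' @return data.frame `gene_a`, `gene_b`, `identity`, `coverage`
#' @export
identity_table <- function(seqs_a, seqs_b = NULL) {
  aa <- function(s) {
    cds <- split_codons(s)
    vapply(cds, function(cd) {
      if (grepl("-", cd)) "-" else codon_table()[[cd]]
    }, character(1))
  }
  pep_a <- lapply(seqs_a, aa)
  within <- is.null(seqs_b)
  pep_b <- if (within) pep_a else lapply(seqs_b, aa)
  pairs <- if (within) {
    utils::combn(seq_along(pep_a), 2, simplify = FALSE)
  } else {
    unlist(lapply(seq_along(pep_a), function(i)
      lapply(seq_along(pep_b), function(j) c(i, j))), recursive = FALSE)
  }
  out <- do.call(rbind, lapply(pairs, function(pr) {
    x <- pep_a[[pr[1]]]; y <- pep_b[[pr[2]]]
    both <- x != "-" & y != "-"
    ident <- if (any(both)) mean(x[both] == y[both]) else 0
    cov <- sum(both) / min(sum(x != "-"), sum(y != "-"))
    data.frame(gene_a = names(pep_a)[pr[1]],
               gene_b = if (within) names(pep_a)[pr[2]] else
                 names(pep_b)[pr[2]],
               identity = ident, coverage = cov, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
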