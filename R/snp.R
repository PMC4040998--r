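#' Core, outgroup-present, single-copy gene filter
#'
#' Retains clusters present in every ingroup strain, in at least one
#' outgroup strain, and single-copy in every strain where present.
#'
#' @param matrix a `gene_presence_matrix`
#' @param ingroup,outgroup species names
#' @param copy_numbers optional integer matrix (clusters x strains) of
#'   per-assembly copy numbers; defaults to 1 wherever present
#' @return character vector of retained cluster ids
#' @export
filter_core_single_copy <- function(matrix, ingroup, outgroup,
                                    copy_numbers = NULL) {
  in_cols <- names(matrix$species)[matrix$species %in% ingroup]
  out_cols <- names(matrix$species)[matrix$species %in% outgroup]
  stopifnot(length(in_cols) > 0, length(out_cols) > 0)
  pres <- matrix$presence
  core <- rowSums(pres[, in_cols, drop = FALSE]) == length(in_cols)
  has_out <- rowSums(pres[, out_cols, drop = FALSE]) >= 1L
  single <- rep(TRUE, nrow(pres))
  if (!is.null(copy_numbers)) {
    cn <- copy_numbers[rownames(pres), colnames(pres), drop = FALSE]
    single <- apply(cn, 1, function(x) all(x <= 1L, na.rm = TRUE))
  }
  rownames(pres)[core & has_out & single]
}

#' Ratio of fixed differences to shared polymorphisms
#'
#' Counts alignment columns fixed-different between two species panels
#' (monomorphic for different alleles) and columns where both panels are
#' polymorphic for the same pair of alleles.  Ratios above the threshold
#' flag the gene; a gene with fixed differences but zero shared
#' polymorphisms has ratio `Inf` and is flagged, reading the threshold rule
#' literally (direction configurable via `flag_above`).
#'
#' @param aln_a,aln_b character vectors of aligned sequences (equal length)
#'   for the two species
#' @param threshold flag threshold on the ratio
#' @param flag_above if `TRUE` (default) flag ratios strictly above the
#'   threshold; set `FALSE` to flag low ratios instead
#' @return list: n_fixed, n_shared, ratio, flagged
#' @export
fixed_shared_ratio <- function(aln_a, aln_b, threshold = 0.2,
                               flag_above = TRUE) {
  if (length(aln_a) == 0 || length(aln_b) == 0) stop("empty alignment")
  ma <- seq_matrix(aln_a)
  mb <- seq_matrix(aln_b)
  if (ncol(ma) != ncol(mb)) stop("alignments differ in length")
  n_fixed <- 0L
  n_shared <- 0L
  for (j in seq_len(ncol(ma))) {
    ua <- unique(ma[, j]); ub <- unique(mb[, j])
    if (any(c(ua, ub) == "-")) next
    if (length(ua) == 1L && length(ub) == 1L) {
      if (ua != ub) n_fixed <- n_fixed + 1L
    } else if (length(ua) >= 2L && length(ub) >= 2L &&
               length(intersect(ua, ub)) >= 2L) {
      n_shared <- n_shared + 1L
    }
  }
  ratio <- if (n_shared == 0L) {
    if (n_fixed > 0L) Inf else 0
  } else n_fixed / n_shared
  flagged <- if (flag_above) ratio > threshold else ratio <= threshold
  list(n_fixed = n_fixed, n_shared = n_shared, ratio = ratio,
       flagged = flagged)
}

#' Hudson's nearest-neighbor statistic (Snn)
#'
#' For each sequence, the fraction of its nearest neighbors (minimum
#' pairwise difference count; ties split fractionally) that belong to the
#' same population; Snn is the mean over sequences.  Snn = 1 means every
#' nearest neighbor is within-population (complete differentiation); values
#' below 1 indicate sequences whose closest relative sits in the other
#' population.  If all sequences are identical the statistic is undefined
#' and `NA` is returned with `flagged = TRUE` (manual review).
#'
#' @param seqs character vector of aligned sequences
#' @param pops population label per sequence (>= 2 sequences per population)
#' @return list: snn, flagged (TRUE when Snn < 1 or undefined)
#' @export
snn_statistic <- function(seqs, pops) {
  stopifnot(length(seqs) == length(pops), length(unique(pops)) >= 2)
  if (any(table(pops) < 2)) stop("need >= 2 sequences per population")
  m <- seq_matrix(seqs)
  d <- hamming_matrix(m)
  if (all(d == 0))
    return(list(snn = NA_real_, flagged = TRUE))
  n <- nrow(d)
  x <- numeric(n)
  for (j in seq_len(n)) {
    dj <- d[j, -j]
    pj <- pops[-j]
    nn <- which(dj == min(dj))
    x[j] <- mean(pj[nn] == pops[j])
  }
  snn <- mean(x)
  list(snn = snn, flagged = snn < 1)
}

#' Flag genes in the top percentile of synonymous divergence
#'
#' Genes with Ks at or above the empirical `percentile` quantile are
#' flagged.  With ties at the threshold, all tied genes are flagged.  With
#' fewer than 100 genes the quantile is still computed, with a warning.
#'
#' @param ks named numeric vector of per-gene Ks values
#' @param percentile quantile defining the flagging threshold
#' @return character vector of flagged gene names
#' @export
ks_percentile_filter <- function(ks, percentile = 0.99) {
  ks <- ks[!is.na(ks)]
  if (length(ks) < 100)
    warning("fewer than 100 genes; top-percentile cut is unstable")
  thr <- stats::quantile(ks, percentile, names = FALSE)
  names(ks)[ks >= thr]
}

#' Split clusters by identity and drop gappy alignments
#'
#' Single-linkage split of each cluster's sequences under the relation
#' (amino-acid identity >= `min_identity` along >= `min_coverage` of the
#' gene), then removal of sub-alignments in which more than `max_gap_frac`
#' of positions are gaps (strictly more: exactly 10% is retained).
#'
#' @param aln named character vector of aligned DNA sequences for a cluster
#' @param min_identity,min_coverage 70/70 split thresholds
#' @param max_gap_frac maximum tolerated gap fraction
#' @return list of retained sub-alignments (named character vectors);
#'   attribute `n_removed_gappy` counts discarded sub-alignments
#' @export
split_and_gap_filter <- function(aln, min_identity = 0.70,
                                 min_coverage = 0.70, max_gap_frac = 0.10) {
  it <- identity_table(aln)
  pass <- it$identity >= min_identity & it$coverage >= min_coverage
  ids <- names(aln)
  comp <- single_linkage_components(ids, match(it$gene_a[pass], ids),
                                    match(it$gene_b[pass], ids))
  groups <- split(ids, comp)
  removed <- 0L
  out <- list()
  for (g in groups) {
    sub <- aln[g]
    gap_frac <- mean(strsplit(paste0(sub, collapse = ""), "")[[1]] == "-")
    if (gap_frac > max_gap_frac) {
      removed <- removed + 1L
      next
    }
    out[[length(out) + 1L]] <- sub
  }
  attr(out, "n_removed_gappy") <- removed
  out
}

#' Call classified, polarized, biallelic variants from a codon alignment
#'
#' Scans ingroup columns for segregating sites and keeps those that are
#' biallelic within the ingroup, monomorphic in the outgroup, and whose
#' outgroup allele matches one ingroup allele (the ancestral state).  A site
#' is classed `syn4` when it is the third position of a 4-fold degenerate
#' codon whose first two positions are monomorphic across all sequences, and
#' `nonsyn` when (with monomorphic codon context) the two ingroup codons
#' encode different amino acids.  Synonymous sites that are not 4-fold
#' (e.g. 2-fold) are left unclassified and dropped.  Columns inside codons
#' containing alignment gaps are skipped.
#'
#' @param aln a `codon_alignment` (fields `seqs`, `ingroup`, `outgroup`)
#' @return data.frame: gene, column, codon, pos, class, derived_count, n,
#'   minor_count; attribute `n_unpolarizable` counts sites dropped because
#'   the outgroup matched neither ingroup allele
#' @export
call_classified_variants <- function(aln) {
  m <- seq_matrix(aln$seqs)
  ing <- m[aln$ingroup, , drop = FALSE]
  outg <- m[aln$outgroup, , drop = FALSE]
  n <- nrow(ing)
  L <- ncol(ing)
  if (L %% 3L != 0L) stop("alignment length not a multiple of 3")
  tab <- codon_table()
  ff <- fourfold_codons()
  res <- list()
  unpol <- 0L
  for (cd in seq_len(L / 3L)) {
    cols <- (3L * (cd - 1L) + 1L):(3L * cd)
    block <- m[, cols, drop = FALSE]
    if (any(block == "-")) next
    for (p in 1:3) {
      j <- cols[p]
      a_in <- ing[, j]
      alleles <- unique(a_in)
      if (length(alleles) != 2L) next
      a_out <- unique(outg[, j])
      if (length(a_out) != 1L) next                 # outgroup polymorphic
      # require the rest of the codon monomorphic across all sequences
      ctx <- cols[-p]
      if (any(apply(m[, ctx, drop = FALSE], 2,
                    function(x) length(unique(x)) > 1L))) next
      if (!a_out %in% alleles) { unpol <- unpol + 1L; next }
      derived_allele <- setdiff(alleles, a_out)
      dcount <- sum(a_in == derived_allele)
      counts <- table(a_in)
      # classify via the two ingroup codons (context is monomorphic)
      base_codon <- paste0(ing[1, cols], collapse = "")
      cdn1 <- base_codon
      substr(cdn1, p, p) <- alleles[1]
      cdn2 <- base_codon
      substr(cdn2, p, p) <- alleles[2]
      if (tab[[cdn1]] == "*" || tab[[cdn2]] == "*") next
      cls <- if (tab[[cdn1]] != tab[[cdn2]]) {
        "nonsyn"
      } else if (p == 3L && cdn1 %in% ff) {
        "syn4"
      } else {
        NA_character_                               # synonymous but not 4-fold
      }
      if (is.na(cls)) next
      res[[length(res) + 1L]] <- data.frame(
        gene = aln$gene %||% NA_character_, column = j, codon = cd, pos = p,
        class = cls, derived_count = dcount, n = n,
        minor_count = min(counts), stringsAsFactors = FALSE)
    }
  }
  out <- if (length(res) > 0) do.call(rbind, res) else
    data.frame(gene = character(0), column = integer(0), codon = integer(0),
               pos = integer(0), class = character(0),
               derived_count = integer(0), n = integer(0),
               minor_count = integer(0), stringsAsFactors = FALSE)
  attr(out, "n_unpolarizable") <- unpol
  out
}

#' Apply the full recombination/quality gene-filter battery
#'
#' Runs, per gene: the fixed:shared ratio test, the Snn test (flag when
#' below its maximum of 1), the top-Ks-percentile filter across genes, and
#' the gap-fraction rule.  Returns a per-gene report; a gene contributes
#' variants iff all filters pass.
#'
#' @param alignments named list of `codon_alignment`s (each with ingroup and
#'   outgroup panels of the two species)
#' @param ks_percentile percentile for the synonymous-divergence filter
#' @param fs_flag_above direction of the fixed:shared flag, passed to
#'   [fixed_shared_ratio()]; the default follows the printed rule (flag
#'   ratios above the threshold), `FALSE` flags low ratios — the direction
#'   under which well-separated species panels pass and introgressed genes
#'   fail
#' @return data.frame: gene, fixed_shared_ratio, snn, ks, gap_frac, and
#'   logical pass columns (pass_fixed_shared, pass_snn, pass_ks, pass_gaps,
#'   pass_all)
#' @export
gene_filter_report <- function(alignments, ks_percentile = 0.99,
                               fs_flag_above = TRUE) {
  per <- lapply(alignments, function(aln) {
    fa <- aln$seqs[aln$ingroup]
    fb <- aln$seqs[aln$outgroup]
    fs <- fixed_shared_ratio(fa, fb, flag_above = fs_flag_above)
    pops <- c(rep("A", length(fa)), rep("B", length(fb)))
    snn <- snn_statistic(c(fa, fb), pops)
    # between-species Ks from species consensus-vs-consensus pair
    kv <- ng86_divergence(fa[[1]], fb[[1]])
    gap_frac <- mean(strsplit(paste0(aln$seqs, collapse = ""), "")[[1]] == "-")
    data.frame(gene = aln$gene, fixed_shared_ratio = fs$ratio,
               fs_flagged = fs$flagged, snn = snn$snn,
               snn_flagged = snn$flagged, ks = kv$Ks, gap_frac = gap_frac,
               stringsAsFactors = FALSE)
  })
  rep <- do.call(rbind, per)
  rownames(rep) <- NULL
  ks <- stats::setNames(rep$ks, rep$gene)
  ks_flag <- ks_percentile_filter(ks, ks_percentile)
  rep$pass_fixed_shared <- !rep$fs_flagged
  rep$pass_snn <- !rep$snn_flagged
  rep$pass_ks <- !(rep$gene %in% ks_flag)
  rep$pass_gaps <- rep$gap_frac <= 0.10
  rep$pass_all <- rep$pass_fixed_shared & rep$pass_snn & rep$pass_ks &
    rep$pass_gaps
  rep
}
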