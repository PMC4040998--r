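#' Simulate per-gene codon alignments with planted variants
#'
#' For each of `aln_n_genes` core genes, generates a codon alignment holding
#' a panel of focal-species sequences (the ingroup) and a panel of
#' sister-species sequences (used both as the comparison species and as the
#' polarizing outgroup).  Planted signal, all recorded in the truth set:
#' \itemize{
#'   \item fixed synonymous differences between the species at 4-fold
#'     degenerate third positions (per-site probability `divergence_4fold`)
#'     and occasional nonsynonymous substitutions on the outgroup lineage;
#'   \item segregating derived alleles in the focal panel — synonymous ones
#'     at 4-fold sites, nonsynonymous ones as amino-acid-changing single-base
#'     changes — with derived counts drawn from the configured expected SFS
#'     (neutral 1/i or a selected spectrum);
#'   \item independent synonymous polymorphism in the sister panel (such
#'     sites are outgroup-polymorphic and must be dropped by variant calling);
#'   \item "recombinant" genes with shared polymorphism between the species
#'     and almost no fixed differences (fixed:shared ratio below 0.2 by
#'     construction);
#'   \item "distant recombinant" genes with 3x elevated synonymous
#'     divergence, emulating transfer from a distant lineage.
#' }
#' Planted features occupy disjoint codons, so called derived counts can be
#' compared with the truth exactly.
#'
#' @param config a [sim_config()]
#' @return list with elements
#'   \describe{
#'     \item{alignments}{named list of `codon_alignment` objects (fields:
#'       `gene`, `seqs` named character vector, `ingroup`, `outgroup` name
#'       vectors)}
#'     \item{truth}{list: `sites` (gene, codon, pos, column, class,
#'       derived_count), `recombinant_genes`, `distant_recombinant_genes`}
#'   }
#' @export
simulate_codon_alignments <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  species <- names(config$n_strains)
  n <- config$n_strains[[1]]
  n_sis <- config$n_strains[[2]]
  focal_strains <- sprintf("%s_%02d", species[1], seq_len(n))
  sister_strains <- sprintf("%s_%02d", species[2], seq_len(n_sis))
  L <- config$aln_n_codons
  tab <- codon_table()
  sense <- names(tab)[tab != "*"]
  ff <- fourfold_codons()

  ng <- config$aln_n_genes
  n_rec <- config$n_recombinant_genes
  n_dist <- config$n_distant_recombinant_genes
  if (n_rec + n_dist > ng)
    stop("more recombinant genes requested than genes")
  gene_ids <- sprintf("gene%04d", seq_len(ng))
  rec_ids <- if (n_rec > 0) gene_ids[seq_len(n_rec)] else character(0)
  dist_ids <- if (n_dist > 0) gene_ids[n_rec + seq_len(n_dist)] else character(0)
  site_probs <- sfs_site_probs(config$sfs_model, n)

  # single-base changes from codon cd at position p that alter the amino acid
  # without creating a stop
  nonsyn_changes <- function(cd) {
    out <- list()
    for (p in 1:3) {
      for (b in setdiff(BASES, substr(cd, p, p))) {
        m <- cd
        substr(m, p, p) <- b
        if (tab[[m]] != "*" && tab[[m]] != tab[[cd]])
          out[[length(out) + 1L]] <- c(pos = p, base = b)
      }
    }
    out
  }

  alignments <- vector("list", ng)
  names(alignments) <- gene_ids
  sites <- list()

  for (g in seq_len(ng)) {
    gid <- gene_ids[g]
    anc <- sample(sense, L, replace = TRUE)
    used <- rep(FALSE, L)
    is_rec <- gid %in% rec_ids
    div4 <- if (gid %in% dist_ids) min(0.95, 3 * config$divergence_4fold)
            else config$divergence_4fold

    # outgroup/sister ancestral sequence: fixed differences vs focal ancestor
    sis_anc <- anc
    ff_idx <- which(anc %in% ff & !used)
    if (is_rec) {
      n_fix <- min(1L, length(ff_idx))
      fix_idx <- if (n_fix > 0) sample(ff_idx, n_fix) else integer(0)
    } else {
      fix_idx <- ff_idx[stats::runif(length(ff_idx)) < div4]
    }
    for (ci in fix_idx) {
      third <- substr(anc[ci], 3, 3)
      substr(sis_anc[ci], 3, 3) <- sample(setdiff(BASES, third), 1L)
    }
    used[fix_idx] <- TRUE
    # nonsynonymous divergence on the outgroup lineage (suppressed for
    # recombinant genes, whose species panels must stay nearly identical)
    ns_div <- if (is_rec) integer(0) else
      which(stats::runif(L) < config$divergence_nonsyn & !used)
    for (ci in ns_div) {
      ch <- nonsyn_changes(anc[ci])
      if (length(ch) == 0) next
      pick <- ch[[sample.int(length(ch), 1L)]]
      substr(sis_anc[ci], as.integer(pick["pos"]),
             as.integer(pick["pos"])) <- pick["base"]
      used[ci] <- TRUE
    }

    focal <- matrix(rep(anc, n), nrow = n, byrow = TRUE,
                    dimnames = list(focal_strains, NULL))
    sister <- matrix(rep(sis_anc, n_sis), nrow = n_sis, byrow = TRUE,
                     dimnames = list(sister_strains, NULL))

    plant <- function(panel, ci, pos, base, count) {
      carriers <- sample.int(nrow(panel), count)
      for (s in carriers) {
        cd <- panel[s, ci]
        substr(cd, pos, pos) <- base
        panel[s, ci] <- cd
      }
      panel
    }

    # focal synonymous variants at 4-fold third positions
    m_s <- stats::rpois(1L, config$syn_per_gene)
    avail <- which(anc %in% ff & !used)
    if (m_s > length(avail))
      stop(sprintf("gene %s: %d synonymous variants requested, %d 4-fold sites available",
                   gid, m_s, length(avail)))
    syn_idx <- if (m_s > 0) sample(avail, m_s) else integer(0)
    used[syn_idx] <- TRUE
    for (ci in syn_idx) {
      i <- sample.int(n - 1L, 1L, prob = site_probs)
      b <- sample(setdiff(BASES, substr(anc[ci], 3, 3)), 1L)
      focal <- plant(focal, ci, 3L, b, i)
      sites[[length(sites) + 1L]] <- data.frame(
        gene = gid, codon = ci, pos = 3L, column = 3L * (ci - 1L) + 3L,
        class = "syn4", derived_count = i, stringsAsFactors = FALSE)
    }

    # focal nonsynonymous variants
    m_n <- stats::rpois(1L, config$nonsyn_per_gene)
    avail <- which(!used)
    if (m_n > length(avail))
      stop(sprintf("gene %s: %d nonsynonymous variants requested, %d codons available",
                   gid, m_n, length(avail)))
    nsy_idx <- if (m_n > 0) sample(avail, m_n) else integer(0)
    for (ci in nsy_idx) {
      ch <- nonsyn_changes(anc[ci])
      if (length(ch) == 0) next
      used[ci] <- TRUE
      pick <- ch[[sample.int(length(ch), 1L)]]
      i <- sample.int(n - 1L, 1L, prob = site_probs)
      focal <- plant(focal, ci, as.integer(pick["pos"]), pick["base"], i)
      sites[[length(sites) + 1L]] <- data.frame(
        gene = gid, codon = ci, pos = as.integer(pick["pos"]),
        column = 3L * (ci - 1L) + as.integer(pick["pos"]),
        class = "nonsyn", derived_count = i, stringsAsFactors = FALSE)
    }

    # sister-panel synonymous polymorphism (outgroup-polymorphic sites)
    m_o <- stats::rpois(1L, config$syn_per_gene / 2)
    avail <- which(sis_anc %in% ff & !used)
    out_idx <- if (m_o > 0 && length(avail) > 0)
      sample(avail, min(m_o, length(avail))) else integer(0)
    used[out_idx] <- TRUE
    for (ci in out_idx) {
      b <- sample(setdiff(BASES, substr(sis_anc[ci], 3, 3)), 1L)
      sister <- plant(sister, ci, 3L, b,
                      sample.int(max(1L, n_sis - 1L), 1L))
    }

    # shared polymorphism for recombinant genes: same two alleles segregate
    # in both panels at the same column
    if (is_rec) {
      n_shared <- 8L
      avail <- which(anc %in% ff & !used)
      sh_idx <- sample(avail, min(n_shared, length(avail)))
      used[sh_idx] <- TRUE
      for (ci in sh_idx) {
        b <- sample(setdiff(BASES, substr(anc[ci], 3, 3)), 1L)
        focal <- plant(focal, ci, 3L, b, max(2L, sample.int(n - 1L, 1L)))
        sister <- plant(sister, ci, 3L, b,
                        max(2L, sample.int(max(2L, n_sis - 1L), 1L)))
      }
    }

    seqs <- c(apply(focal, 1, paste0, collapse = ""),
              apply(sister, 1, paste0, collapse = ""))
    aln <- list(gene = gid, seqs = seqs, ingroup = focal_strains,
                outgroup = sister_strains)
    class(aln) <- "codon_alignment"
    alignments[[g]] <- aln
  }

  sites <- if (length(sites) > 0) do.call(rbind, sites) else
    data.frame(gene = character(0), codon = integer(0), pos = integer(0),
               column = integer(0), class = character(0),
               derived_count = integer(0), stringsAsFactors = FALSE)
  list(alignments = alignments,
       truth = list(sites = sites, recombinant_genes = rec_ids,
                    distant_recombinant_genes = dist_ids))
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("Codon alignment", x$gene, "-", length(x$seqs), "sequences x",
      nchar(x$seqs[[1]]), "bp (", length(x$ingroup), "ingroup,",
      length(x$outgroup), "outgroup )\n")
  invisible(x)
}
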