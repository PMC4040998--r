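#' Configuration for the synthetic-data generator
#'
#' Builds a validated configuration shared by [simulate_coverage()],
#' [simulate_pangenome()] and [simulate_codon_alignments()].  Defaults mirror
#' the study system the package emulates: a focal species sampled at 12
#' strains and a sister species at 20, with three additional outgroup species
#' (2 + 1 + 1 strains), a three-replicon genome (chromosome and two
#' megaplasmids) and 140x mean read depth in 100-bp windows.
#'
#' @param n_strains named integer vector of strains per species.  The first
#'   two entries are the ingroup (focal species first), the rest outgroups.
#' @param n_genes named integer vector, genes per replicon.
#' @param replicon_lengths named numeric vector, replicon lengths in bp.
#' @param window_size coverage window width in bp.
#' @param mean_depth expected read starts per window at copy number 1.
#' @param gc_bias either `NULL` (no bias) or a data.frame with columns `gc`
#'   and `mult` defining a piecewise-linear multiplier over GC fraction
#'   (linearly interpolated, constant beyond the range).
#' @param dup_rate expected number of duplication events per strain.
#' @param dup_fold integer copy number of planted duplications.
#' @param dup_span_windows number of consecutive windows per planted event.
#' @param dup_freq_spectrum probability vector over carrier counts
#'   1..(n_focal + 1) for planted duplication loci; the "+1" genome is the
#'   reference.  Default is the neutral 1/i shape.
#' @param reference_in_population logical; if `TRUE` the reference genome is
#'   treated as one extra exchangeable population member that may itself
#'   carry planted duplications (this is what creates the ascertainment bias
#'   the 1-P correction undoes).
#' @param n_core_clusters number of core gene clusters in the pangenome.
#' @param n_ht_events number of horizontal-transfer events planted per
#'   ingroup species; each event inserts a block of genes with one carrier
#'   set.
#' @param ht_event_size_mean mean genes per transfer event (geometric).
#' @param ht_gain_spectrum probability vector over carrier counts 1..n for HT
#'   events (per focal species sample size n); default neutral 1/i including
#'   the fixed class i = n.
#' @param gc_core,gc_ht shape parameters `c(mean, sd)` of the per-gene GC
#'   fraction distributions for core and HT genes.
#' @param aln_n_genes number of core genes for which codon alignments are
#'   generated.
#' @param aln_n_codons codons per gene.
#' @param syn_per_gene,nonsyn_per_gene expected segregating 4-fold synonymous
#'   / nonsynonymous sites planted per gene (Poisson means).
#' @param sfs_model either `list(type = "neutral")` or
#'   `list(type = "selected", gamma = <Ne s>)`; the expected site frequency
#'   spectrum from which planted derived counts are drawn.
#' @param divergence_4fold per-site substitution probability at 4-fold sites
#'   between ingroup and outgroup (raw proportion, not corrected).
#' @param divergence_nonsyn per-codon probability of a nonsynonymous
#'   substitution on the outgroup lineage.
#' @param n_recombinant_genes genes planted with elevated shared polymorphism
#'   between the two ingroup species (low fixed:shared ratio).
#' @param n_distant_recombinant_genes genes planted with ~3x elevated
#'   synonymous divergence, emulating transfer from a distant lineage.
#' @param seed integer RNG seed; a single global stream is used per run.
#'
#' @return an object of class `sim_config` (a validated list)
#' @examples
#' cfg <- sim_config(n_strains = c(focal = 6, sister = 6, out = 1),
#'                   replicon_lengths = c(chromosome = 5e4),
#'                   n_genes = c(chromosome = 40), seed = 1)
#' @export
sim_config <- function(n_strains = c(medicae = 12L, meliloti = 20L,
                                     fredii = 2L, saheli = 1L, terangae = 1L),
                       n_genes = c(chromosome = 3520L, pSymA = 1597L,
                                   pSymB = 1694L),
                       replicon_lengths = c(chromosome = 3.65e6,
                                            pSymA = 1.35e6, pSymB = 1.68e6),
                       window_size = 100L,
                       mean_depth = 140,
                       gc_bias = NULL,
                       dup_rate = 20,
                       dup_fold = 2L,
                       dup_span_windows = 20L,
                       dup_freq_spectrum = NULL,
                       reference_in_population = TRUE,
                       n_core_clusters = 2000L,
                       n_ht_events = 150L,
                       ht_event_size_mean = 3,
                       ht_gain_spectrum = NULL,
                       gc_core = c(0.62, 0.03),
                       gc_ht = c(0.54, 0.05),
                       aln_n_genes = 50L,
                       aln_n_codons = 300L,
                       syn_per_gene = 10,
                       nonsyn_per_gene = 6,
                       sfs_model = list(type = "neutral"),
                       divergence_4fold = 0.26,
                       divergence_nonsyn = 0.02,
                       n_recombinant_genes = 0L,
                       n_distant_recombinant_genes = 0L,
                       seed = 1L) {
  stopifnot(length(n_strains) >= 1, all(n_strains >= 1),
            !is.null(names(n_strains)),
            all(n_genes >= 1), all(replicon_lengths > 0),
            length(window_size) == 1, window_size >= 1,
            mean_depth > 0, dup_rate >= 0, dup_fold >= 2,
            dup_span_windows >= 1, n_core_clusters >= 0, n_ht_events >= 0,
            ht_event_size_mean >= 1, aln_n_genes >= 0, aln_n_codons >= 10,
            syn_per_gene >= 0, nonsyn_per_gene >= 0,
            divergence_4fold >= 0, divergence_4fold < 1,
            n_recombinant_genes >= 0, n_distant_recombinant_genes >= 0)
  if (!identical(names(n_genes), names(replicon_lengths)))
    stop("n_genes and replicon_lengths must name the same replicons")
  if (!is.null(gc_bias)) {
    stopifnot(is.data.frame(gc_bias), all(c("gc", "mult") %in% names(gc_bias)),
              all(gc_bias$mult > 0))
  }
  n_focal <- n_strains[[1]]
  if (is.null(dup_freq_spectrum)) {
    nn <- n_focal + as.integer(reference_in_population)
    dup_freq_spectrum <- (1 / seq_len(nn)) / sum(1 / seq_len(nn))
  }
  stopifnot(abs(sum(dup_freq_spectrum) - 1) < 1e-8, all(dup_freq_spectrum >= 0))
  if (is.null(ht_gain_spectrum)) {
    ht_gain_spectrum <- (1 / seq_len(n_focal)) / sum(1 / seq_len(n_focal))
  }
  stopifnot(abs(sum(ht_gain_spectrum) - 1) < 1e-8, all(ht_gain_spectrum >= 0))
  if (!sfs_model$type %in% c("neutral", "selected"))
    stop("sfs_model$type must be 'neutral' or 'selected'")
  cfg <- list(
    n_strains = n_strains, n_genes = n_genes,
    replicon_lengths = replicon_lengths, window_size = as.integer(window_size),
    mean_depth = mean_depth, gc_bias = gc_bias, dup_rate = dup_rate,
    dup_fold = as.integer(dup_fold),
    dup_span_windows = as.integer(dup_span_windows),
    dup_freq_spectrum = dup_freq_spectrum,
    reference_in_population = isTRUE(reference_in_population),
    n_core_clusters = as.integer(n_core_clusters),
    n_ht_events = as.integer(n_ht_events),
    ht_event_size_mean = ht_event_size_mean,
    ht_gain_spectrum = ht_gain_spectrum,
    gc_core = gc_core, gc_ht = gc_ht,
    aln_n_genes = as.integer(aln_n_genes),
    aln_n_codons = as.integer(aln_n_codons),
    syn_per_gene = syn_per_gene, nonsyn_per_gene = nonsyn_per_gene,
    sfs_model = sfs_model,
    divergence_4fold = divergence_4fold,
    divergence_nonsyn = divergence_nonsyn,
    n_recombinant_genes = as.integer(n_recombinant_genes),
    n_distant_recombinant_genes = as.integer(n_distant_recombinant_genes),
    seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

# evaluate the GC-bias multiplier at given GC fractions
gc_multiplier <- function(cfg, gc) {
  if (is.null(cfg$gc_bias)) return(rep(1, length(gc)))
  stats::approx(cfg$gc_bias$gc, cfg$gc_bias$mult, xout = gc, rule = 2)$y
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic data configuration\n")
  cat("  species:", paste0(names(x$n_strains), " (", x$n_strains, ")",
                           collapse = ", "), "\n")
  cat("  replicons:", paste0(names(x$replicon_lengths), " ",
                             format(x$replicon_lengths, big.mark = ","), " bp",
                             collapse = ", "), "\n")
  cat("  mean depth:", x$mean_depth, "reads per", x$window_size, "bp window\n")
  cat("  duplications: rate", x$dup_rate, "per strain, fold", x$dup_fold,
      ", span", x$dup_span_windows, "windows\n")
  cat("  HT events:", x$n_ht_events, "per ingroup species, mean size",
      x$ht_event_size_mean, "\n")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}
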