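#' Simulate a multi-species gene presence/absence matrix
#'
#' Generates a pangenome for all configured species: a common set of core
#' clusters present in every strain, plus horizontally transferred (HT)
#' clusters planted per ingroup species.  HT genes arrive in transfer events:
#' each event inserts a block of adjacent genes (geometric size) at one
#' genomic anchor with a single carrier set whose size is drawn from
#' `ht_gain_spectrum`.  Cluster metadata carries a replicon label (HT genes
#' may be "unmatched" or "ambiguous"), a COG category and a GC fraction; HT
#' genes are drawn from a lower-GC distribution than core genes.
#'
#' @param config a [sim_config()]; at least two ingroup species and one
#'   outgroup species must be configured.
#' @return list with elements
#'   \describe{
#'     \item{matrix}{a `gene_presence_matrix`: `presence` (logical clusters x
#'       strains), `species` (named strain -> species vector), `meta`
#'       (cluster_id, replicon, cog, gc), `order` (per-strain gene order as a
#'       list of cluster-id vectors)}
#'     \item{truth}{data.frame of planted HT clusters: cluster_id, species,
#'       event_id, carrier_count, fixed}
#'   }
#' @export
simulate_pangenome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (length(config$n_strains) < 3)
    stop("need >= 2 ingroup species and >= 1 outgroup species")
  set.seed(config$seed + 1L)
  species <- names(config$n_strains)
  ingroup <- species[1:2]
  strains <- unlist(lapply(species, function(sp)
    sprintf("%s_%02d", sp, seq_len(config$n_strains[[sp]]))))
  strain_species <- rep(species, times = config$n_strains)
  names(strain_species) <- strains

  cogs <- c("J", "K", "L", "D", "V", "T", "M", "N", "U", "O",
            "C", "G", "E", "F", "H", "I", "P", "Q", "R", "S")
  reps <- names(config$replicon_lengths)
  rep_prob <- config$n_genes / sum(config$n_genes)

  n_core <- config$n_core_clusters
  core_ids <- sprintf("core%05d", seq_len(n_core))
  meta <- data.frame(
    cluster_id = core_ids,
    replicon = sample(reps, n_core, replace = TRUE, prob = rep_prob),
    cog = sample(cogs, n_core, replace = TRUE),
    gc = pmin(0.85, pmax(0.15, stats::rnorm(n_core, config$gc_core[1],
                                            config$gc_core[2]))),
    stringsAsFactors = FALSE)

  ht_rows <- list()
  truth <- list()
  events <- list()  # per ingroup species: list of (ids, carriers, anchor)
  for (sp in ingroup) {
    n_sp <- config$n_strains[[sp]]
    sp_strains <- strains[strain_species == sp]
    # the configured gain spectrum applies to species of matching sample
    # size; other species default to the neutral 1/i shape over 1..n
    gain <- if (length(config$ht_gain_spectrum) == n_sp) {
      config$ht_gain_spectrum
    } else {
      (1 / seq_len(n_sp)) / sum(1 / seq_len(n_sp))
    }
    if (config$n_ht_events == 0) next
    for (e in seq_len(config$n_ht_events)) {
      k <- 1L + stats::rgeom(1L, 1 / config$ht_event_size_mean)
      i <- sample.int(n_sp, 1L, prob = gain)
      carriers <- sample(sp_strains, i)
      ids <- sprintf("ht_%s_%03d_%02d", sp, e, seq_len(k))
      anchor <- sample.int(n_core, 1L)
      events[[length(events) + 1L]] <-
        list(species = sp, ids = ids, carriers = carriers, anchor = anchor)
      ht_rows[[length(ht_rows) + 1L]] <- data.frame(
        cluster_id = ids,
        replicon = sample(c(reps, "unmatched", "ambiguous"), k, replace = TRUE,
                          prob = c(rep_prob * 0.6, 0.3, 0.1)),
        cog = sample(cogs, k, replace = TRUE),
        gc = pmin(0.85, pmax(0.15, stats::rnorm(k, config$gc_ht[1],
                                                config$gc_ht[2]))),
        stringsAsFactors = FALSE)
      truth[[length(truth) + 1L]] <- data.frame(
        cluster_id = ids, species = sp,
        event_id = sprintf("ev_%s_%03d", sp, e),
        carrier_count = i, fixed = (i == n_sp), stringsAsFactors = FALSE)
    }
  }
  if (length(ht_rows) > 0) meta <- rbind(meta, do.call(rbind, ht_rows))
  truth <- if (length(truth) > 0) do.call(rbind, truth) else
    data.frame(cluster_id = character(0), species = character(0),
               event_id = character(0), carrier_count = integer(0),
               fixed = logical(0), stringsAsFactors = FALSE)

  presence <- matrix(FALSE, nrow(meta), length(strains),
                     dimnames = list(meta$cluster_id, strains))
  presence[core_ids, ] <- TRUE
  for (ev in events) presence[ev$ids, ev$carriers] <- TRUE

  # per-strain gene order: shared core backbone, HT events inserted as
  # blocks immediately after their anchor core gene
  order <- lapply(strains, function(st) {
    ins <- Filter(function(ev) st %in% ev$carriers, events)
    if (length(ins) == 0) return(core_ids)
    by_anchor <- split(ins, vapply(ins, `[[`, numeric(1), "anchor"))
    out <- vector("list", n_core)
    for (a in seq_len(n_core)) out[[a]] <- core_ids[a]
    for (anch in names(by_anchor)) {
      a <- as.integer(anch)
      out[[a]] <- c(out[[a]],
                    unlist(lapply(by_anchor[[anch]], `[[`, "ids")))
    }
    unlist(out)
  })
  names(order) <- strains

  mat <- list(presence = presence, species = strain_species, meta = meta,
              order = order)
  class(mat) <- "gene_presence_matrix"
  list(matrix = mat, truth = truth)
}

#' @export
print.gene_presence_matrix <- function(x, ...) {
  cat("Gene presence/absence matrix:",
      nrow(x$presence), "clusters x", ncol(x$presence), "strains\n")
  cat("  species:", paste(unique(x$species), collapse = ", "), "\n")
  invisible(x)
}
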