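#' Synthetic reference annotation
#'
#' Tiles each replicon with non-overlapping genes of roughly typical
#' bacterial length, assigns COG categories at random and marks a small
#' fraction of genes as transposon-related.  Coordinates are 0-based,
#' half-open.
#'
#' @param config a [sim_config()]
#' @return a `ref_annotation` list with elements `replicons`
#'   (data.frame: replicon, length) and `genes` (data.frame: gene_id,
#'   replicon, start, end, strand, cog, transposon)
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cogs <- c("J", "K", "L", "D", "V", "T", "M", "N", "U", "O",
            "C", "G", "E", "F", "H", "I", "P", "Q", "R", "S")
  genes <- do.call(rbind, lapply(names(config$n_genes), function(rep_id) {
    ng <- config$n_genes[[rep_id]]
    len <- config$replicon_lengths[[rep_id]]
    pitch <- floor(len / ng)
    glen <- min(900L, max(100L, pitch - 50L))
    start <- (seq_len(ng) - 1L) * pitch
    data.frame(
      gene_id = sprintf("%s_g%04d", rep_id, seq_len(ng)),
      replicon = rep_id, start = start, end = start + glen,
      strand = sample(c("+", "-"), ng, replace = TRUE),
      cog = sample(cogs, ng, replace = TRUE),
      transposon = stats::runif(ng) < 0.05,
      stringsAsFactors = FALSE)
  }))
  rownames(genes) <- NULL
  out <- list(replicons = data.frame(replicon = names(config$replicon_lengths),
                                     length = unname(config$replicon_lengths),
                                     stringsAsFactors = FALSE),
              genes = genes)
  class(out) <- "ref_annotation"
  out
}

#' Simulate per-strain window coverage tracks with planted duplications
#'
#' Draws Poisson read-start counts for fixed-width windows across each
#' replicon of every focal-species strain.  The Poisson mean is
#' `mean_depth * gc_bias(GC) * relative copy number`, where the relative copy
#' number compares the strain with the reference genome: planted duplication
#' loci carry `dup_fold` copies in a random carrier set of genomes which, when
#' `reference_in_population` is set, may include the reference itself — in
#' that case carrier strains show no coverage elevation (the read-depth
#' signal is relative), which is exactly the ascertainment bias the
#' 1-P spectrum correction compensates for.
#'
#' A trailing window shorter than `window_size` is dropped with a message.
#'
#' @param config a [sim_config()]
#' @param annotation optionally a pre-built [simulate_annotation()] result
#' @return list with elements
#'   \describe{
#'     \item{tracks}{data.frame (strain, replicon, window_start, raw_count,
#'       gc_fraction, corrected_count = NA) — one row per strain x window}
#'     \item{annotation}{the `ref_annotation` used}
#'     \item{truth}{list: `duplications` (locus table with carrier sets and
#'       reference-carrier flag), `gene_calls` (per gene x strain true
#'       duplication status and detectability given the reference)}
#'   }
#' @export
simulate_coverage <- function(config, annotation = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  if (is.null(annotation)) annotation <- simulate_annotation(config)
  focal <- names(config$n_strains)[1]
  n <- config$n_strains[[1]]
  strains <- sprintf("%s_%02d", focal, seq_len(n))
  w <- config$window_size

  # windows per replicon, trailing partial window dropped
  win <- lapply(names(config$replicon_lengths), function(rep_id) {
    len <- config$replicon_lengths[[rep_id]]
    k <- floor(len / w)
    if (len %% w != 0)
      message(sprintf("replicon %s: dropping %d bp trailing partial window",
                      rep_id, len %% w))
    data.frame(replicon = rep_id, window_start = (seq_len(k) - 1L) * w,
               stringsAsFactors = FALSE)
  })
  win <- do.call(rbind, win)
  win$gc_fraction <- pmin(0.85, pmax(0.15,
    stats::rnorm(nrow(win), config$gc_core[1], config$gc_core[2])))

  # plant duplication loci
  N <- n + as.integer(config$reference_in_population)  # exchangeable genomes
  genomes <- c(strains, if (config$reference_in_population) "REF")
  span <- config$dup_span_windows
  dups <- NULL
  if (config$dup_rate > 0) {
    e_strain_carriers <-
      sum(config$dup_freq_spectrum * seq_along(config$dup_freq_spectrum)) * n / N
    n_loci <- max(1L, round(config$dup_rate * n / e_strain_carriers))
    # choose non-overlapping window runs, replicon weighted by window count
    rep_tab <- table(win$replicon)
    taken <- lapply(names(rep_tab), function(r) integer(0))
    names(taken) <- names(rep_tab)
    loci <- vector("list", n_loci)
    placed <- 0L
    attempts <- 0L
    while (placed < n_loci && attempts < 50L * n_loci) {
      attempts <- attempts + 1L
      rep_id <- sample(names(rep_tab), 1L, prob = as.numeric(rep_tab))
      kmax <- rep_tab[[rep_id]] - span
      if (kmax < 1L) next
      s <- sample.int(kmax, 1L)
      idx <- s:(s + span - 1L)
      if (length(intersect(idx, taken[[rep_id]])) > 0L) next
      taken[[rep_id]] <- c(taken[[rep_id]], idx)
      placed <- placed + 1L
      i <- sample.int(length(config$dup_freq_spectrum), 1L,
                      prob = config$dup_freq_spectrum)
      carriers <- sample(genomes, i)
      loci[[placed]] <- data.frame(
        locus_id = sprintf("dup%04d", placed), replicon = rep_id,
        start = (s - 1L) * w, end = (s + span - 1L) * w,
        copy_number = config$dup_fold,
        carriers = paste(carriers, collapse = ","),
        ref_carrier = "REF" %in% carriers,
        carrier_count = sum(carriers != "REF"),
        stringsAsFactors = FALSE)
    }
    dups <- do.call(rbind, loci[seq_len(placed)])
  }
  if (is.null(dups)) {
    dups <- data.frame(locus_id = character(0), replicon = character(0),
                       start = integer(0), end = integer(0),
                       copy_number = integer(0), carriers = character(0),
                       ref_carrier = logical(0), carrier_count = integer(0),
                       stringsAsFactors = FALSE)
  }

  # relative copy number per window x strain
  mult <- gc_multiplier(config, win$gc_fraction)
  base_lambda <- config$mean_depth * mult
  tracks <- vector("list", n)
  for (si in seq_len(n)) {
    rel <- rep(1, nrow(win))
    if (nrow(dups) > 0) {
      for (k in seq_len(nrow(dups))) {
        carr <- strsplit(dups$carriers[k], ",")[[1]]
        strain_cn <- if (strains[si] %in% carr) dups$copy_number[k] else 1
        ref_cn <- if (dups$ref_carrier[k]) dups$copy_number[k] else 1
        if (strain_cn == ref_cn) next
        sel <- win$replicon == dups$replicon[k] &
          win$window_start >= dups$start[k] & win$window_start < dups$end[k]
        rel[sel] <- strain_cn / ref_cn
      }
    }
    tracks[[si]] <- data.frame(
      strain = strains[si], replicon = win$replicon,
      window_start = win$window_start,
      raw_count = stats::rpois(nrow(win), base_lambda * rel),
      gc_fraction = win$gc_fraction, corrected_count = NA_real_,
      stringsAsFactors = FALSE)
  }
  tracks <- do.call(rbind, tracks)

  # gene-level truth: gene duplicated in a strain iff >50% of its length lies
  # inside a planted locus carried by that strain; detectable iff the
  # reference is not also a carrier
  genes <- annotation$genes
  gene_truth <- expand.grid(gene_id = genes$gene_id, strain = strains,
                            KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  gene_truth$duplicated_true <- FALSE
  gene_truth$detectable <- TRUE
  if (nrow(dups) > 0) {
    for (k in seq_len(nrow(dups))) {
      g <- genes[genes$replicon == dups$replicon[k], ]
      ov <- pmax(0, pmin(g$end, dups$end[k]) - pmax(g$start, dups$start[k]))
      hit <- g$gene_id[ov > 0.5 * (g$end - g$start)]
      if (length(hit) == 0) next
      carr <- intersect(strsplit(dups$carriers[k], ",")[[1]], strains)
      sel <- gene_truth$gene_id %in% hit & gene_truth$strain %in% carr
      gene_truth$duplicated_true[sel] <- TRUE
      if (dups$ref_carrier[k])
        gene_truth$detectable[gene_truth$gene_id %in% hit] <- FALSE
    }
  }

  list(tracks = tracks, annotation = annotation,
       truth = list(duplications = dups, gene_calls = gene_truth))
}
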