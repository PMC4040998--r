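#' Window read-start coverage from read placements
#'
#' Bins read start positions into fixed-width windows, counting each read
#' fractionally: a read with k equally best alignment locations contributes
#' 1/k at each location, so repeated reference sequence present at reference
#' copy number shows no excess coverage.
#'
#' @param reads data.frame with columns `strain`, `replicon`, `start`
#'   (0-based read start) and `n_best` (number of equally best locations; a
#'   read aligned to two locations appears as two rows with `n_best = 2`)
#' @param annotation a `ref_annotation` (supplies replicon lengths)
#' @param window_size window width in bp
#' @return coverage track data.frame (strain, replicon, window_start,
#'   raw_count, gc_fraction = NA, corrected_count = NA)
#' @export
compute_window_coverage <- function(reads, annotation, window_size = 100L) {
  stopifnot(all(c("strain", "replicon", "start", "n_best") %in% names(reads)),
            all(reads$n_best >= 1))
  rl <- stats::setNames(annotation$replicons$length,
                        annotation$replicons$replicon)
  if (any(!reads$replicon %in% names(rl)))
    stop("read on unknown replicon")
  if (any(reads$start < 0 | reads$start >= rl[reads$replicon]))
    stop("read start outside replicon bounds")
  grid <- do.call(rbind, lapply(names(rl), function(r) {
    k <- floor(rl[[r]] / window_size)
    data.frame(replicon = r, window_start = (seq_len(k) - 1L) * window_size,
               stringsAsFactors = FALSE)
  }))
  strains <- unique(reads$strain)
  if (length(strains) == 0) {
    out <- grid[0, ]
    out$strain <- character(0)
    out$raw_count <- numeric(0)
    out$gc_fraction <- numeric(0)
    out$corrected_count <- numeric(0)
    return(out[, c("strain", "replicon", "window_start", "raw_count",
                   "gc_fraction", "corrected_count")])
  }
  out <- lapply(strains, function(st) {
    sub <- reads[reads$strain == st, ]
    tr <- grid
    tr$strain <- st
    tr$raw_count <- 0
    key <- paste(tr$replicon, tr$window_start)
    wk <- paste(sub$replicon, (sub$start %/% window_size) * window_size)
    add <- tapply(1 / sub$n_best, wk, sum)
    hit <- match(names(add), key)
    keep <- !is.na(hit)  # reads in a dropped trailing partial window
    tr$raw_count[hit[keep]] <- as.numeric(add[keep])
    tr
  })
  out <- do.call(rbind, out)
  out$gc_fraction <- NA_real_
  out$corrected_count <- NA_real_
  out[, c("strain", "replicon", "window_start", "raw_count", "gc_fraction",
          "corrected_count")]
}

#' GC-bias correction of a coverage track
#'
#' Median normalization per GC bin, computed per strain: windows are binned
#' by GC fraction into `n_gc_bins` equal-width bins over the observed range,
#' and each window's count is multiplied by
#' (global median count) / (median count of its GC bin).  Bins holding fewer
#' than 20 windows fall back to multiplier 1.
#'
#' @param track coverage track data.frame with `gc_fraction` populated
#' @param n_gc_bins number of GC bins
#' @return the track with `corrected_count` filled in
#' @export
gc_correct_coverage <- function(track, n_gc_bins = 20L) {
  stopifnot(all(c("strain", "raw_count", "gc_fraction") %in% names(track)))
  if (anyNA(track$gc_fraction)) stop("gc_fraction missing")
  out <- lapply(split(track, track$strain), function(tr) {
    if (all(tr$raw_count == 0)) stop("all-zero coverage track")
    global_med <- stats::median(tr$raw_count)
    if (min(tr$gc_fraction) == max(tr$gc_fraction)) {
      tr$corrected_count <- tr$raw_count   # single GC value, nothing to do
      return(tr)
    }
    br <- seq(min(tr$gc_fraction), max(tr$gc_fraction),
              length.out = n_gc_bins + 1L)
    bin <- cut(tr$gc_fraction, breaks = br, include.lowest = TRUE)
    bin_med <- tapply(tr$raw_count, bin, stats::median)
    bin_n <- tapply(tr$raw_count, bin, length)
    mult <- global_med / bin_med
    mult[is.na(mult) | bin_n < 20L | bin_med == 0] <- 1
    tr$corrected_count <- tr$raw_count * as.numeric(mult[bin])
    tr
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Flag windows with elevated copy number
#'
#' Tests each window's corrected count against Poisson(replicon mean
#' corrected count), upper tail, with Benjamini-Hochberg correction across
#' the windows of each strain x replicon.  Fractional counts are rounded up
#' to the next integer for the tail probability (P(X >= ceiling(x))).
#'
#' @param track GC-corrected coverage track
#' @param alpha FDR level
#' @return the track with logical column `elevated` added
#' @export
call_elevated_windows <- function(track, alpha = 0.05) {
  if (anyNA(track$corrected_count))
    stop("corrected_count missing; run gc_correct_coverage first")
  grp <- interaction(track$strain, track$replicon, drop = TRUE)
  flags <- logical(nrow(track))
  for (g in levels(grp)) {
    idx <- which(grp == g)
    x <- track$corrected_count[idx]
    lambda <- mean(x)
    if (lambda <= 0) stop("replicon mean coverage is zero")
    p <- stats::ppois(ceiling(x) - 1L, lambda, lower.tail = FALSE)
    flags[idx] <- stats::p.adjust(p, method = "BH") < alpha
  }
  track$elevated <- flags
  track
}

#' Merge flagged windows into duplication events and filter by fold coverage
#'
#' Maximal runs of contiguous flagged windows become candidate events; an
#' event is retained only if its mean corrected coverage is at least
#' `fold_threshold` times the mean corrected coverage of its replicon.
#'
#' @param track output of [call_elevated_windows()]
#' @param fold_threshold retention threshold; conventional values are 1.5,
#'   1.8 and 2.0 (any positive value is accepted)
#' @param window_size window width in bp (for event coordinates)
#' @return data.frame of events: strain, replicon, start, end (bp, 0-based
#'   half-open), n_windows, mean_fold
#' @export
merge_events_and_filter <- function(track, fold_threshold = 1.5,
                                    window_size = 100L) {
  stopifnot(is.numeric(fold_threshold), length(fold_threshold) == 1)
  if (fold_threshold <= 0) stop("fold_threshold must be positive")
  if (is.null(track$elevated)) stop("run call_elevated_windows first")
  res <- list()
  grp <- interaction(track$strain, track$replicon, drop = TRUE)
  for (g in levels(grp)) {
    tr <- track[grp == g, ]
    tr <- tr[order(tr$window_start), ]
    rep_mean <- mean(tr$corrected_count)
    r <- rle(tr$elevated)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      idx <- starts[k]:ends[k]
      fold <- mean(tr$corrected_count[idx]) / rep_mean
      if (fold < fold_threshold) next
      res[[length(res) + 1L]] <- data.frame(
        strain = tr$strain[1], replicon = tr$replicon[1],
        start = tr$window_start[starts[k]],
        end = tr$window_start[ends[k]] + window_size,
        n_windows = length(idx), mean_fold = fold, stringsAsFactors = FALSE)
    }
  }
  if (length(res) == 0)
    return(data.frame(strain = character(0), replicon = character(0),
                      start = integer(0), end = integer(0),
                      n_windows = integer(0), mean_fold = numeric(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Per-gene duplication status from events
#'
#' A gene is called duplicated in a strain iff strictly more than half of its
#' length overlaps that strain's retained events (ties at exactly 50% are
#' not called).
#'
#' @param events event data.frame from [merge_events_and_filter()]
#' @param annotation a `ref_annotation`
#' @return a `duplication_callset`: list with `gene_calls` (gene_id, strain,
#'   duplicated), `carrier_counts` (named vector over genes, number of
#'   strains carrying a call), `events`, and `strains`
#' @export
assign_gene_status <- function(events, annotation) {
  genes <- annotation$genes
  strains <- unique(events$strain)
  calls <- list()
  for (st in strains) {
    ev <- events[events$strain == st, ]
    dup <- logical(nrow(genes))
    for (r in unique(ev$replicon)) {
      evr <- ev[ev$replicon == r, ]
      gi <- which(genes$replicon == r)
      if (length(gi) == 0) next
      ov <- numeric(length(gi))
      for (k in seq_len(nrow(evr))) {
        ov <- ov + pmax(0, pmin(genes$end[gi], evr$end[k]) -
                          pmax(genes$start[gi], evr$start[k]))
      }
      dup[gi] <- ov > 0.5 * (genes$end[gi] - genes$start[gi])
    }
    calls[[st]] <- data.frame(gene_id = genes$gene_id, strain = st,
                              duplicated = dup, stringsAsFactors = FALSE)
  }
  gene_calls <- if (length(calls) > 0) do.call(rbind, calls) else
    data.frame(gene_id = character(0), strain = character(0),
               duplicated = logical(0), stringsAsFactors = FALSE)
  rownames(gene_calls) <- NULL
  carrier <- tapply(gene_calls$duplicated, gene_calls$gene_id, sum)
  carrier_counts <- stats::setNames(rep(0L, nrow(genes)), genes$gene_id)
  carrier_counts[names(carrier)] <- as.integer(carrier)
  out <- list(gene_calls = gene_calls, carrier_counts = carrier_counts,
              events = events, strains = strains)
  class(out) <- "duplication_callset"
  out
}

#' End-to-end duplication calling on a coverage track
#'
#' Convenience wrapper: GC correction, window testing, event merging and
#' per-gene assignment.
#'
#' @inheritParams gc_correct_coverage
#' @inheritParams call_elevated_windows
#' @inheritParams merge_events_and_filter
#' @param annotation a `ref_annotation`
#' @param exclude_replicons replicons to drop before testing (e.g. a small
#'   accessory plasmid with unreliable population-wide coverage)
#' @return a `duplication_callset`
#' @export
call_duplications <- function(track, annotation, fold_threshold = 1.5,
                              alpha = 0.05, n_gc_bins = 20L,
                              window_size = 100L,
                              exclude_replicons = character(0)) {
  track <- track[!track$replicon %in% exclude_replicons, ]
  track <- gc_correct_coverage(track, n_gc_bins = n_gc_bins)
  track <- call_elevated_windows(track, alpha = alpha)
  events <- merge_events_and_filter(track, fold_threshold = fold_threshold,
                                    window_size = window_size)
  cs <- assign_gene_status(events, annotation)
  # keep zero-call strains visible in downstream carrier counts
  cs$strains <- unique(track$strain)
  cs
}

#' @export
print.duplication_callset <- function(x, ...) {
  cat("Duplication callset:", nrow(x$events), "events,",
      sum(x$carrier_counts > 0), "duplicated genes across",
      length(x$strains), "strains\n")
  invisible(x)
}

#' Polarize duplicated genes against an outgroup species
#'
#' A duplicated gene is retained as a derived duplication iff it has exactly
#' one ortholog in the outgroup species and that ortholog shows no
#' duplication call in any outgroup strain.  Genes without an ortholog entry
#' are excluded and counted.
#'
#' @param callset_focal `duplication_callset` for the focal species
#' @param callset_outgroup `duplication_callset` for the outgroup species
#' @param ortholog_map data.frame with columns `gene_focal`, `gene_outgroup`
#'   (a 1:1 map, e.g. from [infer_ortholog_map()])
#' @return list: `derived` (data.frame gene_id, carrier_count),
#'   `excluded_no_ortholog`, `excluded_outgroup_duplicated` (counts)
#' @export
polarize_duplications <- function(callset_focal, callset_outgroup,
                                  ortholog_map) {
  dup_genes <- names(callset_focal$carrier_counts)[
    callset_focal$carrier_counts > 0]
  has_orth <- dup_genes %in% ortholog_map$gene_focal
  orth <- ortholog_map$gene_outgroup[
    match(dup_genes[has_orth], ortholog_map$gene_focal)]
  out_cc <- callset_outgroup$carrier_counts
  out_dup <- ifelse(orth %in% names(out_cc), out_cc[orth] > 0, FALSE)
  derived_genes <- dup_genes[has_orth][!out_dup]
  list(derived = data.frame(
         gene_id = derived_genes,
         carrier_count = as.integer(
           callset_focal$carrier_counts[derived_genes]),
         stringsAsFactors = FALSE),
       excluded_no_ortholog = sum(!has_orth),
       excluded_outgroup_duplicated = sum(out_dup))
}

#' Fixed copy-number differences between species
#'
#' Gene families with unequal reference copy number between two species and
#' no within-species copy-number variation calls in either species.
#'
#' @param families_a,families_b named character vectors mapping gene id to
#'   family id (family ids shared across species, e.g. linked via orthologs)
#' @param callset_a,callset_b `duplication_callset`s for the two species
#' @return data.frame: family, copies_a, copies_b
#' @export
fixed_family_differences <- function(families_a, families_b,
                                     callset_a, callset_b) {
  ca <- table(families_a)
  cb <- table(families_b)
  fams <- union(names(ca), names(cb))
  copies_a <- ifelse(fams %in% names(ca), as.integer(ca[fams]), 0L)
  copies_b <- ifelse(fams %in% names(cb), as.integer(cb[fams]), 0L)
  seg_a <- vapply(fams, function(f) {
    g <- names(families_a)[families_a == f]
    any(callset_a$carrier_counts[intersect(g,
      names(callset_a$carrier_counts))] > 0)
  }, logical(1))
  seg_b <- vapply(fams, function(f) {
    g <- names(families_b)[families_b == f]
    any(callset_b$carrier_counts[intersect(g,
      names(callset_b$carrier_counts))] > 0)
  }, logical(1))
  keep <- copies_a != copies_b & !seg_a & !seg_b
  data.frame(family = fams[keep], copies_a = copies_a[keep],
             copies_b = copies_b[keep], stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Flag strains with outlying duplication counts
#'
#' Tukey's fence on per-strain duplicated-gene counts: a strain is flagged
#' when its count exceeds Q3 + 1.5 IQR.  Strains are flagged, never removed
#' automatically.
#'
#' @param callset a `duplication_callset`
#' @return data.frame: strain, n_duplicated, outlier
#' @export
flag_outlier_strains <- function(callset) {
  strains <- callset$strains
  if (length(strains) < 4) stop("need at least 4 strains")
  counts <- vapply(strains, function(st) {
    sum(callset$gene_calls$duplicated[callset$gene_calls$strain == st])
  }, numeric(1))
  counts[setdiff(strains, unique(callset$gene_calls$strain))] <- 0
  q <- stats::quantile(counts, c(0.25, 0.75), names = FALSE)
  fence <- q[2] + 1.5 * (q[2] - q[1])
  data.frame(strain = strains, n_duplicated = as.integer(counts),
             outlier = counts > fence, stringsAsFactors = FALSE,
             row.names = NULL)
}
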