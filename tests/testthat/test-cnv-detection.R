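# Read-depth duplication calling: window counts, GC correction, event
# merging, gene assignment, polarization, QC.

ann1 <- function(len = 1000, genes = data.frame(
                   gene_id = "g1", replicon = "chr", start = 0, end = 600,
                   strand = "+", cog = "S", transposon = FALSE)) {
  out <- list(replicons = data.frame(replicon = "chr", length = len),
              genes = genes)
  class(out) <- "ref_annotation"
  out
}

test_that("window coverage tallies read starts fractionally", {
  ann <- ann1()
  none <- data.frame(strain = character(0), replicon = character(0),
                     start = numeric(0), n_best = numeric(0))
  tr0 <- compute_window_coverage(none, ann)
  expect_equal(nrow(tr0), 0)

  # a read aligned equally to two locations adds 0.5 at each
  reads <- data.frame(strain = "s1", replicon = "chr",
                      start = c(10, 210), n_best = c(2, 2))
  tr <- compute_window_coverage(reads, ann)
  expect_equal(tr$raw_count[tr$window_start == 0], 0.5)
  expect_equal(tr$raw_count[tr$window_start == 200], 0.5)

  # deterministic reads match a direct tally
  set.seed(42)
  starts <- sample(0:999, 10)
  reads <- data.frame(strain = "s1", replicon = "chr", start = starts,
                      n_best = 1)
  tr <- compute_window_coverage(reads, ann)
  tally <- table(factor(starts %/% 100, levels = 0:9))
  expect_equal(tr$raw_count[order(tr$window_start)], as.numeric(tally))

  bad <- data.frame(strain = "s1", replicon = "chr", start = 1000, n_best = 1)
  expect_error(compute_window_coverage(bad, ann), "outside")
})

test_that("GC correction equalizes bin medians without touching flat tracks", {
  # gc-uniform track: corrected equals raw
  tr <- data.frame(strain = "s1", replicon = "chr",
                   window_start = (0:199) * 100,
                   raw_count = rep(c(100, 120), 100),
                   gc_fraction = 0.6, corrected_count = NA_real_)
  out <- gc_correct_coverage(tr, n_gc_bins = 5)
  expect_equal(out$corrected_count, out$raw_count)

  # one GC bin biased 2x: its corrected median equals the global median
  tr2 <- data.frame(strain = "s1", replicon = "chr",
                    window_start = (0:199) * 100,
                    raw_count = c(rep(100, 150), rep(200, 50)),
                    gc_fraction = c(rep(0.5, 150), rep(0.8, 50)),
                    corrected_count = NA_real_)
  out2 <- gc_correct_coverage(tr2, n_gc_bins = 3)
  high <- out2$gc_fraction > 0.7
  expect_equal(median(out2$corrected_count[high]),
               median(out2$raw_count))
  expect_error(gc_correct_coverage(transform(tr2, raw_count = 0)),
               "all-zero")
})

test_that("GC correction recovers simulated bias within 5% per bin", {
  bias <- data.frame(gc = c(0.3, 0.6, 0.9), mult = c(0.7, 1.0, 1.4))
  cfg <- sim_config(n_strains = c(f = 1, s = 1, o = 1),
                    n_genes = c(chr = 100), replicon_lengths = c(chr = 1e6),
                    dup_rate = 0, gc_bias = bias, seed = 8)
  sim <- simulate_coverage(cfg)
  out <- gc_correct_coverage(sim$tracks, n_gc_bins = 20)
  bin <- cut(out$gc_fraction, 20)
  med <- tapply(out$corrected_count, bin, median)
  cnt <- tapply(out$corrected_count, bin, length)
  med <- med[!is.na(med) & cnt >= 50]
  expect_true(all(abs(med / median(out$corrected_count) - 1) <= 0.05))
})

test_that("elevated-window calling flags what Poisson theory says it should", {
  base <- data.frame(strain = "s1", replicon = "chr",
                     window_start = (0:499) * 100,
                     raw_count = 140, gc_fraction = 0.6,
                     corrected_count = 140)
  expect_true(!any(call_elevated_windows(base)$elevated))

  spike <- base
  spike$corrected_count[100] <- 1400
  expect_true(call_elevated_windows(spike)$elevated[100])

  # synthetic 2x duplication at depth 140: >= 95% of its windows flagged
  cfg <- sim_config(n_strains = c(f = 1, s = 1, o = 1),
                    n_genes = c(chr = 100), replicon_lengths = c(chr = 1e6),
                    dup_rate = 3, dup_fold = 2,
                    reference_in_population = FALSE, seed = 10)
  sim <- simulate_coverage(cfg)
  tr <- gc_correct_coverage(sim$tracks)
  tr <- call_elevated_windows(tr)
  dups <- sim$truth$duplications
  focal <- sprintf("f_%02d", 1)
  for (k in seq_len(nrow(dups))) {
    if (!grepl(focal, dups$carriers[k])) next
    sel <- tr$window_start >= dups$start[k] & tr$window_start < dups$end[k]
    expect_gte(mean(tr$elevated[sel]), 0.95)
  }
})

test_that("event merging respects contiguity and the fold threshold", {
  mk <- function(flags, counts, mean_count = 100) {
    n <- length(flags)
    data.frame(strain = "s1", replicon = "chr",
               window_start = (seq_len(n) - 1) * 100,
               raw_count = counts, gc_fraction = 0.6,
               corrected_count = counts, elevated = as.logical(flags))
  }
  # flags 1,1,0,1 -> two events of 2 and 1 windows
  tr <- mk(c(1, 1, 0, 1, rep(0, 96)), c(300, 300, 100, 300, rep(100, 96)))
  ev <- merge_events_and_filter(tr, fold_threshold = 1.5)
  expect_equal(nrow(ev), 2)
  expect_equal(sort(ev$n_windows), c(1, 2))

  # mean fold 1.4 removed at threshold 1.5; fold 2.0 retained
  base <- rep(100, 100)
  f14 <- base; f14[11:20] <- 147  # event mean/replicon mean ~ 1.4
  tr14 <- mk(c(rep(0, 10), rep(1, 10), rep(0, 80)), f14)
  rep_mean <- mean(f14)
  expect_true(mean(f14[11:20]) / rep_mean < 1.5)
  expect_equal(nrow(merge_events_and_filter(tr14, 1.5)), 0)

  f20 <- base; f20[11:20] <- 2 * mean(base)
  tr20 <- mk(c(rep(0, 10), rep(1, 10), rep(0, 80)), f20)
  expect_equal(nrow(merge_events_and_filter(tr20, 1.5)), 1)

  expect_error(merge_events_and_filter(tr20, -1), "positive")

  # monotonicity: higher threshold never retains more events
  set.seed(3)
  counts <- rpois(200, 120)
  counts[31:40] <- rpois(10, 200)
  counts[101:105] <- rpois(5, 260)
  trm <- mk(c(rep(0, 30), rep(1, 10), rep(0, 60), rep(1, 5), rep(0, 95)),
            counts)
  ns <- vapply(c(1.5, 1.8, 2.0), function(th)
    nrow(merge_events_and_filter(trm, th)), numeric(1))
  expect_true(all(diff(ns) <= 0))

  # event set is invariant to window processing order
  shuf <- trm[sample(nrow(trm)), ]
  ev_a <- merge_events_and_filter(trm, 1.5)
  ev_b <- merge_events_and_filter(shuf, 1.5)
  expect_equal(ev_a[order(ev_a$start), ], ev_b[order(ev_b$start), ],
               ignore_attr = TRUE)
})

test_that("gene status needs a strict majority of length in events", {
  ann <- ann1()
  ev <- function(s, e) data.frame(strain = "s1", replicon = "chr",
                                  start = s, end = e, n_windows = 1,
                                  mean_fold = 2)
  # 400 of 600 bp inside -> duplicated
  cs <- assign_gene_status(ev(0, 400), ann)
  expect_true(cs$gene_calls$duplicated)
  # exactly 50% -> not duplicated
  cs <- assign_gene_status(ev(0, 300), ann)
  expect_false(cs$gene_calls$duplicated)
  # zero overlap -> not duplicated
  cs <- assign_gene_status(ev(700, 900), ann)
  expect_false(cs$gene_calls$duplicated)
})

test_that("polarization keeps only derived single-ortholog duplications", {
  cs_f <- make_callset(c(gA = 3L, gB = 2L, gC = 1L))
  cs_o <- make_callset(c(hA = 0L, hB = 4L))
  omap <- data.frame(gene_focal = c("gA", "gB"),
                     gene_outgroup = c("hA", "hB"))
  out <- polarize_duplications(cs_f, cs_o, omap)
  # gA: ortholog unduplicated in outgroup -> derived
  expect_equal(out$derived$gene_id, "gA")
  expect_equal(out$derived$carrier_count, 3L)
  # gB duplicated in both species -> excluded
  expect_equal(out$excluded_outgroup_duplicated, 1L)
  # gC has no ortholog -> excluded and counted
  expect_equal(out$excluded_no_ortholog, 1L)
})

test_that("fixed family differences require unequal copies and no CNV", {
  fam_a <- c(a1 = "famX", a2 = "famX", a3 = "famY", a4 = "famZ")
  fam_b <- c(b1 = "famX", b2 = "famY", b3 = "famZ")
  cs_a <- make_callset(c(a1 = 0L, a2 = 0L, a3 = 0L, a4 = 0L))
  cs_b <- make_callset(c(b1 = 0L, b2 = 0L, b3 = 0L))
  out <- fixed_family_differences(fam_a, fam_b, cs_a, cs_b)
  expect_equal(out$family, "famX")      # 2 vs 1 copies, no CNV
  expect_equal(out$copies_a, 2L)
  # segregating CNV in species A removes the family
  cs_a2 <- make_callset(c(a1 = 2L, a2 = 0L, a3 = 0L, a4 = 0L))
  expect_equal(nrow(fixed_family_differences(fam_a, fam_b, cs_a2, cs_b)), 0)
})

test_that("outlier strains are flagged by the Tukey fence", {
  mk_calls <- function(counts) {
    strains <- paste0("s", seq_along(counts))
    gc <- do.call(rbind, lapply(seq_along(counts), function(i)
      data.frame(gene_id = paste0("g", seq_len(max(counts))),
                 strain = strains[i],
                 duplicated = seq_len(max(counts)) <= counts[i])))
    make_callset(NULL, gene_calls = gc, strains = strains)
  }
  eq <- flag_outlier_strains(mk_calls(c(5, 5, 5, 5)))
  expect_false(any(eq$outlier))
  out <- flag_outlier_strains(mk_calls(c(10, 11, 12, 13, 100)))
  expect_equal(out$strain[out$outlier], "s5")
  expect_error(flag_outlier_strains(mk_calls(c(3, 4))), "4 strains")
})

test_that("reference-carried duplications are invisible to the caller", {
  cfg <- sim_config(n_strains = c(f = 6, s = 1, o = 1),
                    n_genes = c(chr = 200), replicon_lengths = c(chr = 5e5),
                    dup_rate = 6, reference_in_population = TRUE, seed = 21)
  sim <- simulate_coverage(cfg)
  dups <- sim$truth$duplications
  expect_gt(sum(dups$ref_carrier), 0)  # this construction plants some
  cs <- call_duplications(sim$tracks, sim$annotation)
  hidden <- sim$truth$gene_calls[!sim$truth$gene_calls$detectable &
                                   sim$truth$gene_calls$duplicated_true, ]
  called <- merge(hidden, cs$gene_calls, by = c("gene_id", "strain"))
  expect_false(any(called$duplicated))
})
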