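# Gene filters, Snn, NG86 divergence and classified variant calling.

test_that("core/outgroup/single-copy filter applies all three rules", {
  strains <- c("f1", "f2", "s1", "o1")
  species <- setNames(c("fo", "fo", "si", "ou"), strains)
  pres <- rbind(g1 = c(1, 1, 1, 1),   # core, outgroup present -> keep
                g2 = c(1, 0, 1, 1),   # missing from one ingroup strain
                g3 = c(1, 1, 0, 0),   # absent from outgroup
                g4 = c(1, 1, 1, 1))   # 2 copies in f1 (below)
  colnames(pres) <- strains
  m <- make_matrix(pres, species)
  cn <- matrix(1L, 4, 4, dimnames = dimnames(pres))
  cn["g4", "f1"] <- 2L
  keep <- filter_core_single_copy(m, ingroup = "fo", outgroup = c("si", "ou"),
                                  copy_numbers = cn)
  expect_equal(keep, "g1")
})

test_that("fixed:shared ratio counts and flags as specified", {
  # build alignments column-wise: 13 columns
  # 3 fixed differences, 10 shared polymorphic columns
  colA <- c(rep("A", 3), rep("C", 10))
  colB <- c(rep("G", 3), rep("C", 10))
  a <- c(paste0(colA, collapse = ""), paste0(colA, collapse = ""),
         paste0(sub("C", "T", colA), collapse = ""))
  # make the 10 shared columns polymorphic in both with the same alleles
  mkseq <- function(fixed_base, poly) paste0(c(rep(fixed_base, 3), poly),
                                             collapse = "")
  A <- c(mkseq("A", rep("C", 10)), mkseq("A", rep("T", 10)))
  B <- c(mkseq("G", rep("C", 10)), mkseq("G", rep("T", 10)))
  out <- fixed_shared_ratio(A, B)
  expect_equal(out$n_fixed, 3L)
  expect_equal(out$n_shared, 10L)
  expect_equal(out$ratio, 0.3)
  expect_true(out$flagged)

  # 1 fixed : 10 shared -> 0.1, not flagged
  A1 <- c(mkseq("A", rep("C", 10)), mkseq("A", rep("T", 10)))
  B1 <- c(paste0(c("G", "A", "A", rep("C", 10)), collapse = ""),
          paste0(c("G", "A", "A", rep("T", 10)), collapse = ""))
  out1 <- fixed_shared_ratio(A1, B1)
  expect_equal(out1$n_fixed, 1L)
  expect_equal(out1$ratio, 0.1)
  expect_false(out1$flagged)

  # 0 fixed, shared > 0 -> ratio 0, not flagged
  A0 <- c(mkseq("A", rep("C", 5)), mkseq("A", rep("T", 5)))
  out0 <- fixed_shared_ratio(A0, A0)
  expect_equal(out0$ratio, 0)
  expect_false(out0$flagged)

  # no shared but fixed present -> Inf, flagged (literal rule); the
  # configurable direction flips both decisions
  AF <- c("AAAA", "AAAA")
  BF <- c("GAAA", "GAAA")
  outF <- fixed_shared_ratio(AF, BF)
  expect_equal(outF$ratio, Inf)
  expect_true(outF$flagged)
  expect_false(fixed_shared_ratio(AF, BF, flag_above = FALSE)$flagged)

  expect_error(fixed_shared_ratio(character(0), "A"), "empty")
})

test_that("Snn matches brute force, with fractional ties", {
  # two fully distinct populations: Snn = 1
  s1 <- c("AAAA", "AAAT", "TTTT", "TTTA")
  p1 <- c("x", "x", "y", "y")
  expect_equal(snn_statistic(s1, p1)$snn, 1)
  # hand-computed 4-sequence case with ties: (1 + 1/2 + 1/2 + 1)/4
  s2 <- c("AAA", "AAT", "ATT", "TTT")
  expect_equal(snn_statistic(s2, c("x", "x", "y", "y"))$snn, 0.75)
  # identical sequences: undefined, flagged
  out <- snn_statistic(rep("AAA", 4), c("x", "x", "y", "y"))
  expect_true(is.na(out$snn))
  expect_true(out$flagged)
  # random instances against an independent brute-force oracle
  set.seed(7)
  for (r in 1:20) {
    n <- sample(6:10, 1)
    seqs <- vapply(seq_len(n), function(i)
      paste0(sample(c("A", "T"), 12, replace = TRUE), collapse = ""),
      character(1))
    pops <- sample(rep(c("x", "y"), length.out = n))
    expect_equal(snn_statistic(seqs, pops)$snn, snn_oracle(seqs, pops))
  }
  # a panmictic sample under label permutation: mean Snn near 0.5 when the
  # label split is even (exchangeability)
  set.seed(8)
  seqs <- vapply(1:8, function(i)
    paste0(sample(c("A", "C", "G", "T"), 30, replace = TRUE), collapse = ""),
    character(1))
  perm <- replicate(200, snn_statistic(seqs, sample(rep(c("x", "y"), 4)))$snn)
  expect_lt(abs(mean(perm) - 0.5), 0.1)
})

test_that("NG86 divergence matches independent oracle values", {
  pad <- "ATGAAACCCGGGTTTGCAGACGAAGTTCTGATTAAGCGTAGCACCGGC"
  d0 <- ng86_divergence(paste0(pad, "GGG"), paste0(pad, "GGG"))
  expect_equal(d0$Ka, 0)
  expect_equal(d0$Ks, 0)
  # one synonymous difference: Ka = 0, Ks > 0
  d1 <- ng86_divergence(paste0(pad, "GGG"), paste0(pad, "GGA"))
  expect_equal(d1$Ka, 0)
  expect_gt(d1$Ks, 0)
  # frozen values from an independent NG86 implementation (pathway
  # enumeration with Jukes-Cantor correction) on the same toy pairs
  expect_equal(d1$Ks, 0.0883372767, tolerance = 1e-8)
  d2 <- ng86_divergence(paste0(pad, "AAA"), paste0(pad, "GAA"))
  expect_equal(d2$Ka, 0.0256435236, tolerance = 1e-8)
  expect_equal(d2$Ks, 0)
  d3 <- ng86_divergence(paste0(pad, "TTT"), paste0(pad, "CTA"))
  expect_equal(d3$Ka, 0.0259766225, tolerance = 1e-8)
  expect_equal(d3$Ks, 0.0896588630, tolerance = 1e-8)
  d4 <- ng86_divergence(paste0(pad, "ATGGGC"), paste0(pad, "GCAGGG"))
  expect_equal(d4$Ka, 0.0584440210, tolerance = 1e-8)
  expect_equal(d4$Ks, 0.1468084328, tolerance = 1e-8)
  # symmetry
  expect_equal(ng86_divergence(paste0(pad, "TTT"), paste0(pad, "CTA")),
               ng86_divergence(paste0(pad, "CTA"), paste0(pad, "TTT")))
  # saturation flag
  sat <- ng86_divergence("GGG", "GGA")
  expect_true(is.na(sat$Ks))
  expect_true(sat$saturated[["syn"]])
})

test_that("Ks percentile filter flags the top of the distribution", {
  ks <- setNames(c(rep(0.3, 99), 3), paste0("g", 1:100))
  expect_equal(ks_percentile_filter(ks), "g100")
  # ties at the threshold flag everything
  ks_eq <- setNames(rep(0.3, 100), paste0("g", 1:100))
  expect_length(ks_percentile_filter(ks_eq), 100)
  expect_warning(ks_percentile_filter(setNames(1:10, paste0("g", 1:10))),
                 "fewer than 100")
})

test_that("70/70 split and the 10% gap rule behave at their boundaries", {
  # two divergent haplotype groups split apart
  base <- strrep("ATGAAACCCGGGTTTGCAGACGAAGTTCTG", 3)  # 30 codons
  far <- strrep("ATGTGGCACTATCAGTCACGCATTCGAGAA", 3)
  aln <- c(a1 = base, a2 = base, b1 = far, b2 = far)
  out <- split_and_gap_filter(aln)
  expect_length(out, 2)
  expect_setequal(names(out[[1]]), c("a1", "a2"))

  # gap fraction: > 10% removed, exactly 10% retained
  g30 <- function(n_gap) {
    s <- strsplit(strrep("ATGAAACCC", 10), "")[[1]]  # 90 positions
    s[seq_len(n_gap)] <- "-"
    paste0(s, collapse = "")
  }
  aln_gap <- c(x = g30(10), y = g30(8))   # pooled gap fraction 10%
  out10 <- split_and_gap_filter(aln_gap)
  expect_length(out10, 1)
  aln_gap2 <- c(x = g30(12), y = g30(8))  # pooled 11.1%
  out11 <- split_and_gap_filter(aln_gap2)
  expect_length(out11, 0)
  expect_equal(attr(out11, "n_removed_gappy"), 1L)
})

test_that("variant calling classifies, polarizes and drops as specified", {
  # 12 ingroup sequences; one 4-fold third position with A x10 / G x2,
  # outgroup A -> syn4, derived count 2
  mk <- function(third) paste0("ATGGG", third)  # ATG + GGx (Gly, 4-fold)
  ing <- c(rep(mk("A"), 10), rep(mk("G"), 2))
  aln <- make_aln(ing, c(mk("A"), mk("A")))
  v <- call_classified_variants(aln)
  expect_equal(nrow(v), 1)
  expect_equal(v$class, "syn4")
  expect_equal(v$derived_count, 2L)
  expect_equal(v$n, 12L)

  # nonsynonymous column: AAA (K) vs GAA (E) at position 1
  ing2 <- c(rep("ATGAAA", 9), rep("ATGGAA", 3))
  v2 <- call_classified_variants(make_aln(ing2, rep("ATGAAA", 2)))
  expect_equal(v2$class, "nonsyn")
  expect_equal(v2$derived_count, 3L)

  # three alleles: dropped
  ing3 <- c(rep(mk("A"), 8), rep(mk("G"), 2), rep(mk("T"), 2))
  v3 <- call_classified_variants(make_aln(ing3, rep(mk("A"), 2)))
  expect_equal(nrow(v3), 0)

  # outgroup polymorphic: dropped
  v4 <- call_classified_variants(make_aln(ing, c(mk("A"), mk("G"))))
  expect_equal(nrow(v4), 0)

  # outgroup matches neither allele: dropped and counted unpolarizable
  v5 <- call_classified_variants(make_aln(ing, rep(mk("C"), 2)))
  expect_equal(nrow(v5), 0)
  expect_equal(attr(v5, "n_unpolarizable"), 1L)

  # 2-fold synonymous sites are left unclassified
  ing6 <- c(rep("ATGAAA", 9), rep("ATGAAG", 3))  # AAA/AAG both Lys, 2-fold
  v6 <- call_classified_variants(make_aln(ing6, rep("ATGAAA", 2)))
  expect_equal(nrow(v6), 0)
})

test_that("called variants equal planted truth on synthetic alignments", {
  al <- simulate_codon_alignments(tiny_cfg(aln_n_genes = 10, seed = 41))
  for (a in al$alignments) {
    v <- call_classified_variants(a)
    tv <- al$truth$sites[al$truth$sites$gene == a$gene, ]
    m <- merge(v[, c("column", "class", "derived_count")],
               tv[, c("column", "class", "derived_count")], by = "column")
    # every planted polarizable site is called with the planted count
    expect_equal(nrow(m), nrow(tv))
    expect_equal(nrow(v), nrow(tv))
    expect_equal(m$class.x, m$class.y)
    expect_equal(m$derived_count.x, m$derived_count.y)
  }
})

test_that("recombinant genes are caught by at least one filter", {
  hits <- vapply(1:10, function(s) {
    al <- simulate_codon_alignments(
      tiny_cfg(aln_n_genes = 8, n_recombinant_genes = 2, seed = 100 + s))
    rep <- suppressWarnings(   # few genes: percentile-cut warning expected
      gene_filter_report(al$alignments, fs_flag_above = FALSE))
    rec <- rep[rep$gene %in% al$truth$recombinant_genes, ]
    all(!rec$pass_fixed_shared | !rec$pass_snn | !rec$pass_ks)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("distant-lineage genes land in the top Ks percentile", {
  al <- simulate_codon_alignments(
    tiny_cfg(aln_n_genes = 30, n_distant_recombinant_genes = 2, seed = 55))
  ks <- vapply(al$alignments, function(a)
    ng86_divergence(a$seqs[a$ingroup][[1]], a$seqs[a$outgroup][[1]])$Ks,
    numeric(1))
  names(ks) <- names(al$alignments)
  flagged <- suppressWarnings(ks_percentile_filter(ks, 0.93))
  expect_true(all(al$truth$distant_recombinant_genes %in% flagged))
})
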