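#' Derived allele frequency spectrum
#'
#' Histogram of derived counts over bins 1..n-1 (segregating); for
#' horizontally transferred genes the fixed-in-sample bin i = n is also
#' allowed.  Proportions are computed over the segregating bins.
#'
#' @param counts integer vector of per-variant derived (carrier) counts
#' @param n sample size
#' @param class one of "S", "NS", "DUP", "HT"
#' @return a `freq_spectrum`: list with `class`, `n`, `counts` (named vector
#'   over bins), `weights` (per-bin correction weights, all 1 before
#'   correction), `proportions` (over segregating bins), `empty` flag
#' @export
build_derived_spectrum <- function(counts, n, class = c("S", "NS", "DUP",
                                                        "HT")) {
  class <- match.arg(class)
  max_bin <- if (class == "HT") n else n - 1L
  if (length(counts) > 0 &&
      (any(counts < 1L) || any(counts > max_bin)))
    stop("derived counts outside 1..", max_bin)
  bins <- seq_len(max_bin)
  cnt <- stats::setNames(tabulate(counts, nbins = max_bin), bins)
  seg <- cnt[seq_len(n - 1L)]
  props <- if (sum(seg) > 0) seg / sum(seg) else seg * 0
  out <- list(class = class, n = n, counts = cnt,
              weights = stats::setNames(rep(1, max_bin), bins),
              proportions = props, empty = sum(cnt) == 0)
  class(out) <- "freq_spectrum"
  out
}

#' @export
print.freq_spectrum <- function(x, ...) {
  cat("Derived frequency spectrum (", x$class, "), n = ", x$n, ", ",
      sum(x$counts), " variants\n", sep = "")
  print(x$counts)
  invisible(x)
}

#' Reference-genome ascertainment correction of a duplication spectrum
#'
#' Duplications carried by the reference genome cannot be detected by
#' elevated-coverage calling, so the observed spectrum under-represents
#' common duplications.  Treating the reference as one extra exchangeable
#' sampled genome, a duplication observed in i of n strains sits in the
#' reference with probability p_i = i/(n+1); each bin count is therefore
#' divided by 1 - p_i and the proportions renormalized.  The bin i = n
#' carries weight n+1 and is flagged as high-variance.
#'
#' @param spectrum a `freq_spectrum` of class "DUP"
#' @return the corrected `freq_spectrum` (weights record 1/(1-p_i))
#' @export
ascertainment_correct <- function(spectrum) {
  stopifnot(inherits(spectrum, "freq_spectrum"))
  if (spectrum$class != "DUP")
    stop("ascertainment correction applies to reference-ascertained ",
         "duplication spectra only")
  n <- spectrum$n
  i <- as.integer(names(spectrum$counts))
  w <- 1 / (1 - i / (n + 1))
  spectrum$weights <- stats::setNames(w, names(spectrum$counts))
  spectrum$counts <- spectrum$counts * w
  seg <- spectrum$counts[seq_len(n - 1L)]
  spectrum$proportions <- if (sum(seg) > 0) seg / sum(seg) else seg * 0
  spectrum$corrected <- TRUE
  spectrum
}

#' Watterson's theta
#'
#' theta_w = S / (a1 * L) with a1 = sum_{k=1}^{n-1} 1/k.  For gene-level
#' duplication diversity, S is the number of segregating duplicated genes
#' and L the number of genes in the reference genome.
#'
#' @param S segregating sites (or segregating duplicated genes)
#' @param n sample size
#' @param L sites (or genes) surveyed
#' @return theta_w per site (or per gene)
#' @export
watterson_theta <- function(S, n, L) {
  if (n < 2) stop("n must be >= 2")
  stopifnot(L > 0, S >= 0)
  a1 <- sum(1 / seq_len(n - 1L))
  S / (a1 * L)
}

#' Pairwise diversity from a frequency spectrum
#'
#' theta_pi = sum_i 2 i (n - i) / (n (n - 1)) * count_i / L, the mean
#' pairwise difference per site (or per gene for duplication spectra).
#'
#' @param spectrum a `freq_spectrum`, or a bare named numeric vector of
#'   counts over derived bins
#' @param n sample size
#' @param L sites (or genes) surveyed
#' @return theta_pi per site (or per gene)
#' @export
pairwise_theta <- function(spectrum, n, L) {
  if (n < 2) stop("n must be >= 2")
  stopifnot(L > 0)
  cnt <- if (inherits(spectrum, "freq_spectrum")) spectrum$counts else spectrum
  i <- as.integer(names(cnt) %||% seq_along(cnt))
  seg <- i >= 1L & i <= n - 1L
  sum(2 * i[seg] * (n - i[seg]) / (n * (n - 1)) * cnt[seg]) / L
}

#' Tajima's D
#'
#' Standard normalization (Tajima 1989):
#' D = (theta_pi*L - theta_w*L) / sqrt(e1*S + e2*S*(S-1)) with the usual
#' a1, a2, b1, b2, c1, c2, e1, e2 constants from n.  Also serves the
#' duplication-based analog, where S is the count of segregating duplicated
#' genes and the thetas are per gene.
#'
#' @param S segregating count (>= 1)
#' @param theta_w,theta_pi per-site (or per-gene) estimates from the same S,
#'   n and L
#' @param n sample size
#' @return D (NA with a warning if S = 0)
#' @export
tajimas_d <- function(S, theta_w, theta_pi, n) {
  if (S == 0) {
    warning("Tajima's D undefined when S = 0")
    return(NA_real_)
  }
  stopifnot(n >= 2, theta_w > 0)
  k <- seq_len(n - 1L)
  a1 <- sum(1 / k)
  a2 <- sum(1 / k^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  L <- S / (a1 * theta_w)   # recovers the surveyed length
  (theta_pi * L - theta_w * L) / sqrt(e1 * S + e2 * S * (S - 1))
}

#' Diversity summary for a variant class
#'
#' Convenience wrapper assembling S, theta_w, theta_pi and Tajima's D from a
#' spectrum.
#'
#' @param spectrum a `freq_spectrum`
#' @param L sites (or genes) surveyed
#' @return data.frame: class, n, L, S, theta_w, theta_pi, tajimas_d
#' @export
diversity_summary <- function(spectrum, L) {
  n <- spectrum$n
  seg <- spectrum$counts[seq_len(n - 1L)]
  S <- sum(seg)
  tw <- watterson_theta(S, n, L)
  tp <- pairwise_theta(spectrum, n, L)
  D <- if (S > 0) tajimas_d(S, tw, tp, n) else NA_real_
  data.frame(class = spectrum$class, n = n, L = L, S = S, theta_w = tw,
             theta_pi = tp, tajimas_d = D, stringsAsFactors = FALSE)
}

#' Per-bin permutation test between two variant classes
#'
#' Pools the derived counts of both classes; each permutation draws two
#' samples without replacement of the original sizes and recomputes the
#' per-bin difference in proportions.  Two-sided p per bin is the fraction
#' of permutations with |difference| at least the observed one, with
#' (r + 1)/(m + 1) smoothing.
#'
#' @param counts_a,counts_b per-variant derived counts of the two classes
#' @param n shared sample size (bins 1..n-1)
#' @param n_perm permutations
#' @param seed RNG seed
#' @return data.frame: bin, prop_a, prop_b, observed_diff, p
#' @export
spectrum_permutation_test <- function(counts_a, counts_b, n,
                                      n_perm = 1000L, seed = 1L) {
  stopifnot(length(counts_a) > 0, length(counts_b) > 0)
  if (any(c(counts_a, counts_b) < 1L) || any(c(counts_a, counts_b) > n - 1L))
    stop("counts must be segregating (1..n-1)")
  set.seed(seed)
  nb <- n - 1L
  na <- length(counts_a)
  nbt <- length(counts_b)
  prop <- function(x) tabulate(x, nbins = nb) / length(x)
  obs <- prop(counts_a) - prop(counts_b)
  pool <- c(counts_a, counts_b)
  exceed <- integer(nb)
  for (r in seq_len(n_perm)) {
    idx <- sample.int(na + nbt, na)
    d <- prop(pool[idx]) - prop(pool[-idx])
    exceed <- exceed + (abs(d) >= abs(obs) - 1e-12)
  }
  data.frame(bin = seq_len(nb), prop_a = prop(counts_a),
             prop_b = prop(counts_b), observed_diff = obs,
             p = (exceed + 1) / (n_perm + 1))
}

#' Randomization test on mean segregating frequency
#'
#' Tests whether class B segregates at lower mean frequency than class A:
#' variant labels are reshuffled `n_rand` times and the one-sided p is the
#' proportion of randomizations in which mean(A) - mean(B) exceeds the
#' observed difference.  Mean segregating frequency is the mean of i/n over
#' variants with 1 <= i <= n-1 (fixed-in-sample variants are excluded
#' before calling).
#'
#' @param counts_a,counts_b per-variant derived counts (segregating)
#' @param n sample size
#' @param n_rand randomizations
#' @param seed RNG seed
#' @return list: mean_a, mean_b, observed_diff, p
#' @export
mean_frequency_randomization <- function(counts_a, counts_b, n,
                                         n_rand = 1000L, seed = 1L) {
  stopifnot(length(counts_a) > 0, length(counts_b) > 0)
  set.seed(seed)
  fa <- counts_a / n
  fb <- counts_b / n
  obs <- mean(fa) - mean(fb)
  pool <- c(fa, fb)
  na <- length(fa)
  excess <- 0L
  for (r in seq_len(n_rand)) {
    idx <- sample.int(length(pool), na)
    if (mean(pool[idx]) - mean(pool[-idx]) > obs) excess <- excess + 1L
  }
  list(mean_a = mean(fa), mean_b = mean(fb), observed_diff = obs,
       p = excess / n_rand)
}

#' Subsample one species to the other's sample size and compare
#'
#' Draws `n_reps` random subsamples of `k` strains from species A; within
#' each subsample, carrier counts are recomputed (variants absent from the
#' subsample drop out, variants fixed in the subsample are excluded from
#' the segregating mean) and the statistic — the difference between the two
#' classes' mean segregating frequencies — is compared with species B's
#' observed value.
#'
#' @param carriers_class1,carriers_class2 logical matrices (variants x
#'   strains of species A): which strains carry each variant, for the two
#'   variant classes being contrasted (e.g. nucleotide variants and
#'   duplications)
#' @param k subsample size
#' @param value_b the statistic's value in species B
#' @param n_reps subsamples
#' @param seed RNG seed
#' @return list: exceedance (proportion of subsamples with statistic >
#'   value_b), statistics (vector)
#' @export
strain_subsample_comparison <- function(carriers_class1, carriers_class2,
                                        k, value_b, n_reps = 100L,
                                        seed = 1L) {
  n_strains <- ncol(carriers_class1)
  stopifnot(ncol(carriers_class2) == n_strains)
  if (k > n_strains) stop("k exceeds the number of strains")
  set.seed(seed)
  stat_one <- function(cols) {
    m1 <- rowSums(carriers_class1[, cols, drop = FALSE])
    m2 <- rowSums(carriers_class2[, cols, drop = FALSE])
    s1 <- m1[m1 >= 1 & m1 <= k - 1] / k
    s2 <- m2[m2 >= 1 & m2 <= k - 1] / k
    mean(s1) - mean(s2)
  }
  stats_v <- vapply(seq_len(n_reps), function(r) {
    stat_one(sample.int(n_strains, k))
  }, numeric(1))
  list(exceedance = mean(stats_v > value_b, na.rm = TRUE),
       statistics = stats_v)
}
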