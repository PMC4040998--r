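---
title: "Measuring selection on duplicated and horizontally transferred genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring selection on duplicated and horizontally transferred genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The question and the approach

New gene duplications and horizontally transferred (HT) genes are a major
source of genomic variation in bacteria.  Whether they are mostly deleterious
can be read from their *segregating frequencies*: under purifying selection,
new variants are held at lower population frequency than neutral ones.  The
package therefore compares, within a panel of closely related strains, the
derived allele frequency spectra of four classes of variants — synonymous
SNPs (the neutral yardstick), nonsynonymous SNPs, gene duplications and HT
genes — and estimates the distribution of fitness effects (DFE) of
nonsynonymous mutations as a calibrated point of comparison.

The intended sampling design is two sister species sampled at moderate depth
(defaults: 12 and 20 strains) plus a few strains from two or three more
distant species that serve only to classify gene clusters as
species-private.  Each genome has a chromosome and two megaplasmids; all
statistics can be computed per replicon or genome-wide.

# Duplication calling from read depth

Tandem duplications collapse in de novo assemblies, so copy-number variation
is detected from reads aligned to a reference genome:

1. **Window counts.** Read starts are counted in fixed 100-bp windows.  A
   read aligned equally well to k locations contributes 1/k at each, so
   repeated reference sequence at unchanged copy number shows no excess.
2. **GC normalization.** Per strain, windows are binned by GC fraction
   (default 20 equal-width bins over the observed range) and each count is
   scaled by global-median/bin-median; bins with fewer than 20 windows are
   left unscaled.  Median ratios are robust to the duplications themselves.
3. **Window test.** Each corrected count is tested against
   Poisson(replicon mean), upper tail, with Benjamini–Hochberg correction
   across the windows of a strain x replicon at alpha = 0.05.  The published
   analysis cites an external window-test procedure whose details are in an
   unavailable supplement; this Poisson/BH construction is our fully
   specified substitute and is validated against planted truth.
4. **Events and genes.** Maximal runs of contiguous flagged windows are
   candidate events; events with mean corrected coverage below
   `fold_threshold` times the replicon mean are dropped (1.5 by default —
   the most permissive of the three conventional values 1.5/1.8/2.0 — all
   exposed).  A gene is called duplicated when *strictly more than half* of
   its length lies in retained events; exact 50% ties are not called.
   Strict contiguity is required when merging windows; the gap-tolerant
   alternative reading of "adjacent" is not used.
5. **Polarity and QC.** A duplication is *derived* if the gene has exactly
   one ortholog in the sister species (>=90% amino-acid identity over >95%
   of length, syntenic) and that ortholog is unduplicated in every sister
   strain.  Strains whose duplicated-gene count exceeds Q3 + 1.5 IQR are
   flagged (never auto-removed).  Small accessory replicons with unreliable
   population-wide coverage can be excluded by name.

At 140x mean depth a 2x duplication roughly doubles a window's Poisson mean,
so the per-window power is essentially 1 and the calibrated false-positive
rate is controlled by the BH step; the acceptance checks measure gene-level
sensitivity >= 0.9 and FPR <= 0.01 on planted 2x tandem events spanning 20
windows under a +/-15% piecewise-linear GC bias.

# The reference-ascertainment correction

Coverage is *relative* to the reference genome: a duplication carried by the
reference is invisible.  Treating the reference as one extra exchangeable
sampled genome, a duplication seen in i of n strains sits in the reference
with probability p_i = i/(n+1), so each spectrum bin is divided by 1 - p_i.
The bin i = n has weight n + 1 and is flagged as high-variance.  The
correction is exactly unbiased under this sampling model; the test suite
verifies per-bin recovery of a fixed planted truth over 200 replicates in
which only the reference draw varies.

# HT genes from phyletic patterns

With the two focal species being each other's closest relatives in the
sample, any gene cluster present in one focal species and absent from
*every* strain of *all* other species is inferred to be a horizontal
acquisition after the species split.  De novo gene origination is ignored as
rare.  The rule is deterministic, so on synthetic data the planted HT set is
recovered exactly.  Downstream summaries: fixed iff present in all focal
strains; spatial clusters join HT genes with at most three intervening
non-HT genes in a carrier's gene order (computed per strain, aggregated per
gene as the median cluster size, since real transfers arrive as blocks);
Pearson correlation between gene frequency and median cluster size; a
2 x k chi-square (no continuity correction) of fixed-versus-segregating
across COG categories holding at least 50 HT genes, with Fisher's exact test
substituted in per-category 2 x 2 comparisons when an expected cell is
below 5; and a two-sample Kolmogorov–Smirnov contrast of GC content against
core genes.

# Core-gene SNPs and the filter battery

Variants are called from per-gene codon alignments of the focal panel with
the sister species as outgroup.  A column yields a variant iff it is
biallelic in the ingroup, the outgroup is monomorphic and matches one
ingroup allele (the ancestral state), and the rest of the codon is
monomorphic; `syn4` sites are third positions of 4-fold degenerate codons,
`nonsyn` sites change the amino acid (translation table 11).  Synonymous
but non-4-fold sites are deliberately unclassified.  Columns in codons
containing gaps are skipped.

Genes pass through, in any order (the filters are independent, so the
retained set is order-invariant):

* presence in all ingroup strains, at least one outgroup strain, single-copy;
* fixed:shared ratio — fixed inter-species differences over shared
  polymorphisms.  The published rule flags genes with ratio > 0.2 as
  recombinant, which is counterintuitive (introgression *raises* shared
  polymorphism, deflating the ratio); we implement the printed direction as
  the default and expose `flag_above = FALSE` for the direction under which
  well-separated panels pass and introgressed genes fail.  Zero shared
  polymorphisms give ratio +Inf (flagged under the printed rule);
* Hudson's Snn below its maximum of 1, with nearest-neighbour ties split
  fractionally; all-identical alignments are undefined and flagged for
  review;
* top percentile of synonymous divergence (NG86) between the species;
  ties at the threshold flag all tied genes;
* 70/70 single-linkage split and removal of sub-alignments with more than
  10% gap positions (exactly 10% is retained).

NG86 divergence counts synonymous sites as the per-position fraction of
amino-acid-preserving changes (changes to stop codons count as
nonsynonymous), averages synonymous/nonsynonymous steps over all
substitution pathways of multi-hit codons excluding pathways through stops
(falling back to all pathways when every one is blocked), and applies the
Jukes–Cantor correction; proportions >= 0.75 are reported saturated (NA).
The implementation is frozen against an independent pathway-enumeration
oracle to 1e-8.

# Diversity statistics and class comparisons

theta_w = S/(a1 L) and theta_pi = sum_i 2i(n-i)/(n(n-1)) c_i / L, with
Tajima's 1989 normalization for D.  For duplications, "segregating sites"
are segregating duplicated genes and L is the number of genes in the
reference genome, giving theta_w dup, theta_pi dup and D_T dup on a per-gene
scale.  theta_pi is exactly the mean pairwise difference (verified
brute-force), and under fixed-S neutral spectra E[theta_pi - theta_w] = 0,
so the neutral calibration of D has mean 0 by construction.

Class comparisons follow the published design: per-bin permutation tests
(pool two classes, redraw both at original sizes without replacement, 1,000
permutations, two-sided, with the (r+1)/(m+1) smoothing so p is never 0)
and one-sided mean-frequency randomization tests (1,000 label shuffles,
plain proportion so p = 0 is reportable, as in the published tables).  Mean
segregating frequency averages i/n over variants with 1 <= i <= n-1;
fixed-in-sample HT genes are excluded from such means.  Unequal sample
sizes are handled by subsampling the larger species to the smaller one's n
(default 100 subsamples), recomputing carrier counts within each subsample.

# The four-bin DFE

`expected_selected_sfs()` gives the Poisson-random-field expectation of the
folded spectrum for a deleterious mutation of strength gamma = Ne s,
H(x; gamma) proportional to
e^(-2 gamma x)(1 - e^(-2 gamma (1-x)))/((1 - e^(-2 gamma)) x (1-x)),
integrated against binomial sampling (adaptive quadrature, rel.tol 1e-9;
the neutral limit 1/i is returned in closed form).  `dfe_fit()` models the
folded nonsynonymous spectrum as a mixture over four bins of Ne s —
[0,1), [1,10), [10,100), >=100 — each represented by one gamma (geometric
midpoint; 100 for the open bin, where segregating mass is effectively all
singletons), times per-bin distortion factors r_i = observed/neutral
synonymous proportions that absorb demography.  Weights are fit by
multinomial maximum likelihood on the softmax-parameterized simplex
(Nelder–Mead, 5 starts, reltol 1e-10) with standard errors from a
multinomial bootstrap over sites of both spectra.

**Known limitation — identifiability.**  This four-point-mass mixture is an
intentional simplification of the published method, which fits a
low-dimensional continuous DFE and bins afterwards.  At n = 12 on folded
spectra the expectations for gamma = 31.6 and gamma = 100 are nearly
collinear (both put >93% of segregating mass on singletons): the
Fisher-weighted design has a smallest-to-largest singular value ratio of
about 0.02 (reported as `identifiability` on the fit), so one direction in
weight space — mostly a moderate-vs-strong trade with a neutral-vs-weak
component — moves the observable spectrum almost not at all.  The ML fit
then tends to sit on the simplex boundary and the bootstrap understates the
uncertainty along that direction, so *individual* weights of the two
strongest bins should not be over-interpreted at these sample sizes; sums
of adjacent bins (e.g. effectively neutral + weak) are well determined.
The test suite states this plainly: the recovery check of all four planted
weights at S = 5000, n = 12 fails and is expected to fail — the information
simply is not in a folded 6-bin spectrum — while neutral-spectrum recovery
(weight of the [0,1) bin >= 0.9) and the scaling/limit properties pass.

# The synthetic-data generator

The generator produces every pipeline input with known truth, at the study's
conditions by default: 12 + 20 ingroup strains and 2 + 1 + 1 outgroup
strains; a 3.65 Mb chromosome and 1.35/1.68 Mb megaplasmids carrying
3,520/1,597/1,694 genes; 140 expected read starts per 100-bp window
(Poisson); 2x tandem duplications spanning 20 windows planted with carrier
counts drawn from a neutral 1/i spectrum over the n+1 genomes including the
reference; HT genes arriving as geometric blocks (mean 3 genes) at shared
anchors, with carrier counts from a configurable gain spectrum (neutral 1/i
including the fixed class by default) and GC drawn lower (mean 0.54, sd
0.05) than core genes (0.62, 0.03); 300-codon genes with planted 4-fold
synonymous and amino-acid-changing variants whose derived counts follow the
configured neutral or selected expected SFS, plus outgroup divergence at a
raw 4-fold substitution probability of 0.26.  "Recombinant" genes carry
shared polymorphism and almost no fixed differences (fixed:shared < 0.2 by
construction); "distant recombinant" genes carry 3x synonymous divergence.
GC bias is a piecewise-linear multiplier over GC fraction (identity by
default).  One RNG stream per generator call, seeded from the
configuration.

What the generator does *not* emulate: read-level errors and PCR-duplicate
variation, assembly artefacts, linkage between sites within genes (variants
are planted independently), gene loss in the core genome, demographic
history (spectra are drawn i.i.d. from a target shape rather than from a
coalescent), and real spatial structure of duplications beyond single
tandem runs.  Passing tests therefore demonstrate that the *estimators and
rules* behave as specified under their own sampling assumptions — not that
those assumptions hold in any particular real data set.

# Problem sizes and numerical choices

Tests and the acceptance script run at deliberately compact scales chosen to
make Monte-Carlo error negligible relative to each check's tolerance: the
caller evaluation uses 12 strains x 9,000 windows across two replicons with
~100 planted gene-level duplications; spectrum-recovery uses 300 variants x
200 replicates; neutral-D and type-I-error calibrations use 500 replicates
(with 1,000 permutations/randomizations inside each, and 300 variants per
class so that discreteness of the permutation null stays mild); DFE checks
use S = 2,000–5,000 sites.  Fractional read counts are exact sums of 1/k
floats (test tolerance 1e-9); quadrature tolerance 1e-9; optimizer restarts
are seeded; every stochastic routine takes an explicit seed and all
generator outputs are bit-reproducible for a fixed configuration.
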