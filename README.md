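# strucsel

Population-genetic analysis of **structural variation in bacterial
populations**: gene duplications detected from read depth and horizontally
transferred (HT) genes detected from phyletic patterns, compared against
synonymous and nonsynonymous nucleotide variants to ask whether new
structural variants are under purifying selection.

The package is aimed at microbial population genomicists working with
resequencing panels of closely related strains (the motivating system is a
pair of sister *Sinorhizobium* species — 20 and 12 strains — plus three
outgroup species, three replicons per genome, ~140x coverage).  It
implements, as composable functions with a synthetic-data generator for
end-to-end testing:

* **Read-depth duplication calling** — fractional counting of multi-mapped
  read starts in 100-bp windows, GC-bin median normalization, Poisson
  upper-tail window tests with per-replicon Benjamini–Hochberg correction,
  merging of contiguous flagged windows into events, fold-coverage filtering
  (1.5/1.8/2.0), and the majority-of-gene-length rule for per-gene calls;
  polarization against an outgroup species via a 1:1 ortholog map, fixed
  copy-number differences between species, and Tukey-fence strain QC.
* **HT gene identification** — a cluster present in ≥1 strain of exactly one
  species is a derived horizontal acquisition; spatial clustering along each
  carrier genome (≤3 intervening genes), frequency–cluster-size correlation,
  fixation-by-COG-category contingency tests, and GC-content contrasts with
  the core genome.
* **Core-gene SNP classification** — biallelic 4-fold synonymous and
  nonsynonymous sites polarized against a monomorphic outgroup, behind the
  full gene-filter battery: core/outgroup presence, single-copy,
  fixed:shared ratio, Hudson's Snn, top-percentile synonymous divergence
  (NG86 with pathway averaging and Jukes–Cantor correction), 70/70 identity
  split and the 10% gap rule.
* **Frequency spectra and diversity** — derived allele frequency spectra per
  variant class; the 1−P reference-ascertainment correction for duplications
  (bin i is up-weighted by 1/(1−i/(n+1))); Watterson's θ_w, pairwise θ_π and
  Tajima's D, including their gene-level duplication analogs θ_w dup,
  θ_π dup and D_T dup, where "sites" are genes in the reference genome;
  per-bin permutation tests and mean-frequency randomization tests between
  variant classes, and strain subsampling for unequal sample sizes.
* **Distribution of fitness effects** — `dfe_fit()` estimates the
  proportions of nonsynonymous mutations in four N_e·s bins
  ([0,1), [1,10), [10,100), ≥100) by multinomial maximum likelihood on the
  folded minor-allele spectrum, using the synonymous spectrum to absorb
  demographic distortion; returns a classed object with `print`, `summary`,
  `coef`, `logLik`, `plot` and `simulate` methods and bootstrap standard
  errors.  (See the vignette for an honest account of how weakly the two
  strongest-selection bins are identified at n = 12.)

The core quantities, in standard notation: θ_w = S/(a₁L) with
a₁ = Σ_{k<n} 1/k; θ_π = Σᵢ 2i(n−i)/(n(n−1)) · cᵢ/L; Tajima's
D = (θ̂_π − θ̂_w)L / √(e₁S + e₂S(S−1)); the expected segregating-site density
under genic selection H(x;γ) ∝ e^{−2γx}(1−e^{−2γ(1−x)})/((1−e^{−2γ})x(1−x)).

## Worked example

Simulate a 12-strain panel at 140x with planted tandem duplications, call
duplications, and summarize gene-level duplication diversity:

```r
library(strucsel)

cfg <- sim_config(n_strains = c(medicae = 12, meliloti = 6, fredii = 2),
                  n_genes = c(chromosome = 400, pSymA = 200),
                  replicon_lengths = c(chromosome = 4e5, pSymA = 2e5),
                  dup_rate = 6, mean_depth = 140, seed = 42)
sim   <- simulate_coverage(cfg)
calls <- call_duplications(sim$tracks, sim$annotation, fold_threshold = 1.5)
calls
#> Duplication callset: 43 events, 26 duplicated genes across 12 strains

n        <- 12
carriers <- calls$carrier_counts
seg      <- carriers[carriers >= 1 & carriers <= n - 1]
spec <- ascertainment_correct(build_derived_spectrum(as.integer(seg), n, "DUP"))
diversity_summary(spec, L = length(carriers))
#>   class  n   L        S    theta_w   theta_pi tajimas_d
#> 1   DUP 12 600 37.24978 0.02055811 0.02453921 0.8795962
```

26 of the 600 annotated genes carry a duplication in at least one strain.
The spectrum is built from per-gene carrier counts and corrected for the
reference-genome ascertainment bias (duplications the reference itself
carries are invisible to relative read depth, so common variants are
up-weighted — which is why S is fractional).  θ_w dup ≈ 0.021 and
θ_π dup ≈ 0.025 are segregating duplicated genes *per gene*, the gene-level
analog of per-site nucleotide diversity, and Tajima's D is their normalized
difference.

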