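---
title: "Selection scans, fitness enrichment and antagonistic pleiotropy: models and design"
author: "selpleio"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selection scans, fitness enrichment and antagonistic pleiotropy: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The question the pipeline answers

Alleles that raise the risk of a late-onset disease should be slowly
removed by purifying selection — unless they also do something useful
earlier in life. `selpleio` implements, end to end, the analysis needed
to interrogate that hypothesis for a panel of disease loci (the packaged
example is a 76-gene coronary-artery-disease panel across 12
populations):

1. scan phased haplotypes for signatures of recent positive selection
   (EHH / iHS, module `ihs_scan()` and friends);
2. ask, gene by gene and population by population, whether per-SNP GWAS
   log odds covary with the selection signal
   (`fit_selection_risk_model()`);
3. ask whether the selected variants are regulatory
   (`fit_eqtl()`, `compare_selected_vs_random()`);
4. ask whether the same loci are associated with lifetime reproductive
   success (LRS), a direct fitness proxy (`lmm_assoc()`,
   `set_enrichment_test()`, `gene_based_test()`);
5. classify index SNPs as antagonistically pleiotropic when the allele
   that raises fitness also raises disease risk
   (`classify_antagonism()`).

Real inputs of this design (reference haplotype panels, consortium GWAS
summary files, cohort phenotypes) are access-restricted or bulky, so the
package carries a first-class synthetic-data module whose planted truths
every stage must recover. This vignette records the models, the tunable
parameters, and the design decisions that were genuinely open.

# The haplotype simulator

`simulate_neutral_panel()` runs a forward Wright–Fisher process on
binary haplotypes. The 2N founder haplotypes receive derived alleles at
uniformly placed sites; initial derived counts follow the neutral site
frequency spectrum (P(count = i) ∝ 1/i), which gives the scan's
derived-allele-frequency (DAF) bins realistic occupancy. Each
generation, every offspring draws two parents uniformly (selection
re-weights by genotype fitness 1, 1+s, 1+2s at the focal site); each
gamete is a recombinant of the parent's two haplotypes with a
Poisson(map length in Morgans) crossover count and crossover points
uniform on the genetic map. No new mutation enters after founding, and
the map is linear in physical position.

**Default study condition.** N = 400 diploids, 200 generations, 100
sampled diploids, a 10 Mb chromosome carrying a 30 cM map
(`sim_spec()`). The map is deliberately compressed (3 cM/Mb versus the
~1 cM/Mb human average): at desk-scale population sizes, pairs of
haplotypes coalesce recently, and extended haplotype homozygosity only
decays within the chromosome if the map is long in Morgans relative to
1/N. The compression trades physical realism for the *statistical*
regime of a large-Nₑ genome — EHH curves that reach the 0.05 cutoff well
inside the chromosome — which is the regime the scan statistics assume.
SNPs whose EHH is still above the cutoff at a chromosome end are
flagged and excluded, exactly as in a real scan.

**Sweeps.** `inject_sweep()` treats the panel itself as the breeding
population and applies genotype selection at the segregating site
nearest the requested position (a soft start: iHS targets incomplete
sweeps of standing or young variation). The process stops the first
time the derived frequency reaches `stop_frequency`; the crossing
generation is conditioned (by redraw) to land on the boundary count, so
replicate sweeps complete at the same frequency — within one haplotype
copy — and remain segregating. If the allele is lost, the sweep
restarts from the input panel, up to `max_restarts` times.

**What the generator does not emulate** — demography, migration,
background selection, mutation after founding, gene conversion,
variable recombination, genotyping error. Passing tests therefore show
the *methods* are correct and calibrated under a clean neutral-plus-
sweep model; they do not show robustness to demographic confounding,
which in real analyses is handled upstream and by the empirical
standardization.

# EHH, iHS and candidate signals

For a core SNP and core allele, EHH at marker m is the probability that
two random carrier haplotypes are identical between the core and m
(`ehh_curve()`; computed by prefix-partition refinement, with
`ehh_curve_brute()`, a quadratic pair-enumeration oracle, kept for
testing). iHH integrates EHH over genetic distance by the trapezoid
rule, truncated at the last marker with EHH ≥ cutoff — no interpolation,
a simpler and exactly testable convention — and summed over both
directions. A SNP is undefined when either direction reaches the
chromosome end above the cutoff, when adjacent markers are more than
`max_gap_bp` apart (default 200 kb), or when its minor allele frequency
is below 5%.

`ihs_raw = ln(iHH_A / iHH_D)` is standardized to mean 0, SD 1 within
DAF bins of width 0.025 (the "similar derived allele frequency" classes;
the width is a package convention, configurable). `standardize_ihs()`
can standardize against a *reference* scan — the normal situation, where
a locus is judged against the genome-wide distribution in which selected
regions are a negligible fraction; self-standardization is the fallback
when the scanned set is itself genome-wide.

Permuted p values compare each |iHS| against `n_perm` draws (default
10,000) from its DAF class with the add-one pseudocount
(1 + exceedances)/(n_perm + 1), so p > 0 always. Because the draws are
i.i.d. from the class pool, the exceedance count is sampled directly as
Binomial(n_perm, pool exceedance fraction) — distributionally identical
to looping, and linear-time. Classes under 10 SNPs widen to neighbours.

A candidate signal (`call_candidate_signals()`) needs |iHS| > 2,
permuted p < 0.05, and at least `cluster_k = 2` other |iHS| > 2 SNPs
within 50 kb. The cluster rule is verbal in the source design; (k = 2,
50 kb) is this package's declared quantification, and both knobs are
exposed. Apex magnitude classes are 2–3, 3–4, > 4.

# Gene loci, LD summaries and null genes

`extract_locus_snps()` reproduces the locus rule: all genic SNPs, plus
flank SNPs within ±5,000 bp of the gene ends when r² > 0.7 with a genic
SNP, plus — for an intergenic index SNP — the index and its ±5,000 bp
r² > 0.7 neighbourhood. With interval-only annotations the gene ends
stand in for UTR coordinates; this is the closest reproducible anchor.
r² is the squared haplotype correlation (phased data are available by
construction, so no genotype-phase approximation is needed). LD blocks
are greedy contiguous segments (extend while the next SNP has
r² ≥ 0.7 with any block member). The first eigenvector of the gene's r²
matrix is unit-norm with its largest-magnitude loading made positive —
an arbitrary but reproducible sign — and exact eigenvalue ties resolve
towards the eigenvector with the lowest-index leading component.
`match_random_genes()` draws length-matched null genes at ±20% relative
length (doubling once before failing), never from the disease panel.

# The selection-risk mixed model

Per gene and population the model is

y = β₀ + β₁ x + u v + e,  u ~ N(0, σᵤ²),  e ~ N(0, σₑ² I),

with y the per-SNP |ln(OR)|, x the per-SNP |iHS|, both standardized to
unit variance (so β₁ is a scaled coefficient), and v the gene's first
LD eigenvector. "The first eigenvector as a random effect" is
formalized as a random coefficient on the eigenvector loading — the
rank-1 covariance σᵤ² v vᵀ + σₑ² I — the one construction in which a
single continuous vector acts as a random effect, and whose two limits
are analytically testable: σᵤ² = 0 recovers OLS, σᵤ² → ∞ recovers OLS
with v as a fixed covariate. σᵤ² is estimated by REML; with ‖v‖ = 1,
V⁻¹ = (I − γ/(1+γ) v vᵀ)/σₑ² (γ = σᵤ²/σₑ²) makes every REML evaluation
O(1) after one pass over the data, so the 10,000 iHS-shuffling
permutations refit the full model each time. Permutations compare
|β₁|; the alternative of comparing p values is equivalent under the
model and |β₁| is the quantity the figure-level summaries report.
Absolute values are the model-wide default (magnitudes of risk against
magnitudes of selection); a signed mode remains for sensitivity
analysis. The gene-matched null compares the observed nominal p against
the same model on 100 length-matched random genes,
(1 + #{null p ≤ observed})/101. Genes are ranked by the count of
populations significant at α = 0.05, ties alphabetical, headline flag at
≥ 4 of 12.

# eQTL comparison

Expression is assumed log2-scale and pre-normalized (an input contract;
normalization pipelines are out of scope). `fit_eqtl()` is OLS of
expression on dosage and sex; `permute_eqtl()` shuffles expression
across samples and uses the closed-form identity that the dosage t
statistic is the partial correlation of residualized dosage and
expression — algebraically the same as refitting, vectorized over
permutations. `compare_selected_vs_random()` takes the apex SNP of each
gene-population candidate signal (stratum A) against an equal number of
SNPs drawn one at a time from LD blocks containing no significant-iHS
SNP ("different LD blocks" is read as block-disjointness from every
signal block; stratum B is not frequency-matched, matching the source
design, and a flag could be added trivially). The two-sample
Kolmogorov–Smirnov test is exact when both strata are ≤ 25, asymptotic
otherwise; the one-sided mode tests A stochastically smaller, which in
R's CDF-based naming is `alternative = "greater"`.

# Fitness: adjusted LRS under a relatedness kernel

`adjust_lrs()` splits women into six equal-count birth-year groups
(quantile cuts on the rank; the original grouping is unspecified) and
divides raw LRS by the group mean, cancelling secular fertility change;
every group's adjusted mean is 1 by construction. The analysis default
is female-only, matching the completed-reproduction cohort the design
targets.

`compute_grm()` builds the realized relationship matrix
K = (1/m) Σᵢ (xᵢ − 2pᵢ)(xᵢ − 2pᵢ)ᵀ / (2pᵢ(1−pᵢ)) from an LD-pruned
(r² ≤ 0.2, greedy 500 kb window) SNP subset, excluding SNPs inside the
disease loci ± a window (default 1 Mb) or with r² ≥ 0.8 to them —
avoiding proximal contamination, where kernel SNPs in LD with test SNPs
absorb the association being tested.

`lmm_assoc()` fits y = Wα + xβ + g + e with g ~ N(0, σ_g² K). K is
eigendecomposed once; the restricted likelihood is profiled over
δ = σₑ²/σ_g² on a 21-point log₁₀ grid over [10⁻⁵, 10⁵] refined by
golden section, per SNP; α, β follow by GLS and the SNP p value is a
two-sided Wald test. REML (rather than ML) is used throughout — the
original tool's flavour is unstated, and REML's variance components are
unbiased under the fixed effects. h² = σ_g²/(σ_g² + σₑ²) = 1/(1 + δ).

Per-SNP permutation p values resample 10,000 nominal p values from the
SNP's MAF bin (width 0.05, a package convention; bins under 100 SNPs
widen). The set-level test draws, 100 times, a MAF-histogram-matched
non-focal SNP set of the focal size without replacement and counts
draws with at least as many p < 0.05; pooled draw p values are compared
to the focal p values by two-sided and one-sided KS (one-sided: focal p
values stochastically *larger* — the direction expected if focal SNPs
are enriched for true effects is stochastically smaller p, so the
published orientation is preserved as stated). `multiple_testing()`
wraps `stats::p.adjust` for Bonferroni and Benjamini–Hochberg.

**Gene-based test.** T = Σ zᵢ² over a gene's SNPs has null distribution
Σ λᵢ χ²₁ with λ the eigenvalues of the SNP correlation matrix.
The tail is evaluated by Imhof's characteristic-function inversion
(`imhof_tail()`), exact to integration tolerance; the two-moment
Satterthwaite approximation (T ≈ c χ²_d, c = Σλ²/Σλ, d = (Σλ)²/Σλ²) is
also reported. The package initially planned to report Satterthwaite
directly, but its two-moment bias (~2×10⁻³ absolute near p = 0.02) is
an order of magnitude larger than the Monte-Carlo oracle the test suite
holds it to, so the exact inversion became the primary method — with
equal eigenvalues short-circuited to the closed-form scaled chi-square,
and p < 10⁻³ refined by 10⁶-draw Monte-Carlo of the weighted sum.
Gene-level and gene-set permutations against size-matched genes use the
same add-one rank statistics as everywhere else (1/101 and 1/301
floors).

# Antagonism calls

`harmonize_alleles()` re-signs the LRS effect onto the GWAS effect
allele, resolving allele swaps by negation and strand flips by
complementation; palindromic A/T and C/G SNPs are excluded rather than
frequency-resolved — at these sample sizes frequency-based resolution
is error-prone, and a flag overrides. The significance gate is
deliberately asymmetric, as in the source design: the SNP must be a
genome-wide-significant disease index SNP (membership in the supplied
list) and LRS-significant at nominal p < 0.05. The call is
*antagonistic* when, for the shared allele, the LRS effect and the
disease log odds have the same sign. `expand_proxies()` widens an index
SNP to r² ≥ 0.8 neighbours within ±1 Mb for sensitivity analyses.

# Numerical conventions and degenerate inputs

* Permutation p values always carry the add-one pseudocount; they can
  never be 0.
* Zero-variance inputs (monomorphic dosages, constant |ln OR|) flag the
  result undefined rather than erroring, except where a hard error is
  the contract (monomorphic r², kernels with < 50 SNPs, all-SNPs-failed
  QC).
* Eigenvector signs and ties are fixed as above; REML optima on the
  boundary (γ = 0, δ at the grid edge) are accepted as fits.
* Every generator and every permutation consumes an explicit seed;
  the pipeline derives stage seeds as base × 100 + stage index so any
  stage can be reproduced alone.
* Hardy–Weinberg is the 1-df goodness-of-fit chi-square on founder
  genotypes; monomorphic sites return p = 1 and are left to the MAF
  filter.

# Validation problem sizes

The shipped test battery runs, per check: EHH oracle equivalence on 200
random panels (≤ 20 haplotypes × 50 SNPs); DAF-bin standardization on a
20,000-site neutral simulation (N = 300, 150 generations); sweep
detection (s = 0.05 to frequency 0.6, N = 200) over 50 replicates
against the matched neutral scan's 95th percentile; permutation-null
calibration with 400–500 draws per family at 1,000 permutations each;
parameter recovery at n = 1,000 individuals (SNP effect β = 0.2,
heritability 0.3) over 25–50 seeds; and set-enrichment power with
effects confined to a 1.5 Mb locus stripe over 20 simulations. These
sizes are the package's chosen desk-scale study conditions: large
enough for the stated tolerances, small enough to re-run routinely.

# Known limitations

* The Wright–Fisher panel has no post-founding mutation; very rare
  variants thin over long simulations, so long runs need larger initial
  site counts.
* EHH truncation (no interpolation at the cutoff crossing) makes iHH
  slightly conservative relative to interpolating implementations;
  consistent within the package, and irrelevant after empirical
  standardization.
* The rank-1 LD random effect captures one LD direction; genes whose LD
  has two strong blocks lean on the permutation null rather than the
  nominal Wald p.
* Kernel LMM variance components are profiled per SNP, which is exact
  but slower than the shared-δ approximation of large-scale tools; at
  desk scale the difference is immaterial.
* The antagonism gate inherits the asymmetry of its source design
  (index-SNP membership for the disease side, nominal p for the fitness
  side); both thresholds are arguments.
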