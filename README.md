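# selpleio

Have the loci underlying a late-onset disease been shaped by recent
positive selection — and do the risk alleles persist because they also
raise early-life fitness? `selpleio` implements the full analysis
pipeline for that question at a panel of disease loci (the packaged
example is a 76-gene coronary-artery-disease panel studied across 12
populations), for population geneticists and genetic epidemiologists
who want every stage reproducible and testable on synthetic data with
planted truths.

The pipeline's core statistics:

* **iHS selection scan.** For each SNP, extended haplotype homozygosity
  EHH(m) = Σ_h C(n_h,2) / C(n_c,2) is integrated (trapezoid, cutoff
  0.05) to iHH for ancestral- and derived-allele carriers, and
  iHS = ln(iHH_A / iHH_D) is standardized to mean 0, SD 1 within
  derived-allele-frequency bins, with permutation p values drawn from
  the same frequency class. Candidate signals need |iHS| > 2, permuted
  p < 0.05, and a cluster of elevated neighbours.
* **Selection–risk mixed model.** Per gene × population,
  y = β₀ + β₁x + u·v + e with y = standardized |ln OR| from GWAS
  summary statistics, x = standardized |iHS|, and u ~ N(0, σ²ᵤ) a
  random coefficient on the gene's first LD eigenvector v
  (cov = σ²ᵤ vvᵀ + σ²ₑ I, REML). Permutation nulls shuffle iHS within
  the gene (10,000×) or refit on 100 length-matched random genes.
* **cis-eQTL comparison.** Expression ~ dosage + sex, with
  expression-shuffling permutations; apex SNPs of selection signals are
  compared with SNPs from signal-free LD blocks by Kolmogorov–Smirnov.
* **Fitness enrichment.** Lifetime reproductive success, adjusted for
  secular change in six birth-year groups, is tested per SNP under a
  kernel LMM y = Wα + xβ + g + e, g ~ N(0, σ²_g K) with K a realized
  relationship matrix from LD-pruned SNPs kept out of LD with the
  disease loci. MAF-binned permutations, a MAF-matched set-enrichment
  test, and a sum-of-chi-squares gene test (T = Σz², null Σλχ²₁ with λ
  the LD eigenvalues) complete the battery.
* **Antagonistic pleiotropy.** After allele harmonization, an index SNP
  whose allele significantly raises both LRS and disease log odds is
  classified antagonistic.

A forward Wright–Fisher simulator (with selective sweeps stopped at a
target frequency) generates the phased panels, GWAS summaries,
expression and fitness phenotypes that exercise all of this end to end.

## Worked example

Simulate a neutral panel, sweep a rare allele to 60% frequency, scan,
and call candidate signals against the matched neutral scan:

```r
library(selpleio)

spec <- sim_spec(n_samples = 200, n_snps = 1500, chrom_length_bp = 1e7,
                 recomb_rate_cM_per_Mb = 9, wf_population_size = 200,
                 wf_generations = 100, seed = 23)
panel <- simulate_neutral_panel(spec)
panel
#> haplotype_panel: 200 samples x 620 SNPs, chrom chr1 (SIM)
#>   span: 3055 - 9953124 bp; 89.551 cM

f <- derived_freq(panel)
cand <- which(abs(panel$positions_bp - 5e6) < 2e6 & f > 0.03 & f < 0.08)
focal <- cand[which.min(abs(panel$positions_bp[cand] - 5e6))]
neutral_raw <- ihs_scan(panel)
neutral <- standardize_ihs(neutral_raw)

swept <- inject_sweep(panel, panel$positions_bp[focal], s = 0.05,
                      stop_frequency = 0.6, seed = 123)
attr(swept, "sweep")[c("focal_snp", "position_bp", "generations")]
#> $focal_snp    [1] "snp00735"
#> $position_bp  [1] 5045461
#> $generations  [1] 101

scores <- standardize_ihs(ihs_scan(swept), reference = neutral_raw)
scores <- permute_ihs_p(scores, n_perm = 1000, seed = 1,
                        reference = neutral)
gene <- list(gene = "GENE1", chrom = "chr1",
             start = attr(swept, "sweep")$position_bp - 4e5,
             end   = attr(swept, "sweep")$position_bp + 4e5)
locus <- extract_locus_snps(swept, gene)
call_candidate_signals(scores, list(locus), population = "SIM")
#>    gene population signal n_members apex_snp apex_ihs  permuted_p magnitude_class
#> 1 GENE1        SIM      1         1 snp00680 3.888944 0.000999001             3-4
#> 2 GENE1        SIM      2         3 snp00736 4.013340 0.000999001              >4
#> 3 GENE1        SIM      3         4 snp00764 3.396008 0.000999001             3-4
```

The apex of the strongest signal (snp00736, |iHS| = 4.0, class ">4")
sits one SNP from the true sweep target (snp00735): the scan localizes
the planted selection event, with permutation p values at the 1/1001
floor.

The selection–risk mixed model, on a gene with a planted coupling of
0.1 between |iHS| and |ln OR|:

```r
set.seed(7)
ihs_mag  <- abs(rnorm(40))                                   # |iHS|
lnor_mag <- abs(0.05 + 0.1 * ihs_mag + rnorm(40, 0, 0.02))   # |ln OR|
v <- rnorm(40); v <- v / sqrt(sum(v^2))       # first LD eigenvector
fit <- fit_selection_risk_model(lnor_mag, ihs_mag, v)
round(unlist(fit[c("beta_scaled", "se", "nominal_p", "n_snps")]), 4)
#> beta_scaled          se   nominal_p      n_snps
#>      0.9661      0.0419      0.0000     40.0000
permute_association(lnor_mag, ihs_mag, v, n_perm = 1000,
                    seed = 1)$perm_p_shuffle
#> [1] 0.001
```

`beta_scaled` is the scaled regression coefficient (here ≈ 0.97: with
noise SD 0.02 the planted coupling makes risk track selection almost
perfectly on standardized scales) and the shuffling permutation p sits
at its 1/1001 floor.

`run_pipeline(default_config(), out_dir)` chains everything — simulate,
scan, associate, eQTL, fitness, antagonism, report — writing per-stage
TSVs, an `enrichment.json`, and a manifest with per-stage seeds and MD5
hashes; re-running a config reproduces byte-identical tables.

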