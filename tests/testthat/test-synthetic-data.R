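test_that("generators are pure functions of (spec, seed)", {
  sp <- sim_spec(n_samples = 20, n_snps = 60, chrom_length_bp = 1e6,
                 wf_population_size = 40, wf_generations = 10, seed = 3)
  a <- simulate_neutral_panel(sp)
  b <- simulate_neutral_panel(sp)
  expect_identical(a$hap_matrix, b$hap_matrix)
  expect_identical(a$positions_bp, b$positions_bp)
  sp2 <- sp; sp2$seed <- 4L
  c <- simulate_neutral_panel(sp2)
  expect_false(identical(a$hap_matrix, c$hap_matrix))
})

test_that("neutral drift conserves expected allele frequency", {
  # one tracked SNP started at 0.5 in N = 100, 10 generations, 200 reps
  finals <- vapply(1:200, function(s) {
    sp <- sim_spec(n_samples = 10, n_snps = 2, chrom_length_bp = 1e5,
                   wf_population_size = 100, wf_generations = 10,
                   init_daf = 0.5, seed = s)
    p <- simulate_neutral_panel(sp, drop_monomorphic = FALSE)
    attr(p, "population_freq")[1]
  }, numeric(1))
  se <- sd(finals) / sqrt(length(finals))
  expect_lt(abs(mean(finals) - 0.5), 3 * se)
})

test_that("without recombination every haplotype is a founder copy", {
  sp <- sim_spec(n_samples = 15, n_snps = 40, chrom_length_bp = 1e6,
                 recomb_rate_cM_per_Mb = 0, wf_population_size = 30,
                 wf_generations = 15, seed = 11)
  p <- simulate_neutral_panel(sp, drop_monomorphic = FALSE,
                              keep_founders = TRUE)
  founders <- attr(p, "founder_haps")
  fkey <- apply(founders, 1, paste, collapse = "")
  okey <- apply(p$hap_matrix, 1, paste, collapse = "")
  expect_true(all(okey %in% fkey))
})

test_that("sweep stops at the target frequency and stays segregating", {
  sp <- sim_spec(n_samples = 50, n_snps = 200, chrom_length_bp = 1e6,
                 wf_population_size = 100, wf_generations = 30, seed = 21)
  p <- simulate_neutral_panel(sp)
  sw <- inject_sweep(p, 5e5, s = 0.05, stop_frequency = 0.6, seed = 8)
  a <- attr(sw, "sweep")
  f <- derived_freq(sw)[a$focal_index]
  expect_true(a$reached)
  expect_gte(f, 0.6)
  expect_lte(f, 0.6 + 1 / nrow(sw$hap_matrix))
})

test_that("sweeps elevate local derived-haplotype homozygosity", {
  pair_hom <- function(panel, idx, win_bp) {
    h <- panel$hap_matrix
    span <- which(abs(panel$positions_bp - panel$positions_bp[idx]) <= win_bp)
    carriers <- which(h[, idx] == 1L)
    if (length(carriers) < 2) return(NA_real_)
    key <- apply(h[carriers, span, drop = FALSE], 1, paste, collapse = "")
    tab <- table(key)
    sum(choose(tab, 2)) / choose(length(carriers), 2)
  }
  # sweep a rare allele (initial frequency 2-8%) hard (s = 0.2) to 70%;
  # compare the swept site's homozygosity over +/- 25 kb against
  # frequency-matched SNPs away from the sweep
  hits <- vapply(1:50, function(s) {
    sp <- sim_spec(n_samples = 80, n_snps = 300, chrom_length_bp = 2e6,
                   recomb_rate_cM_per_Mb = 10, wf_population_size = 150,
                   wf_generations = 20, seed = 1000 + s)
    p <- simulate_neutral_panel(sp)
    f <- derived_freq(p)
    cand <- which(f > 0.02 & f < 0.08 &
                    abs(p$positions_bp - 1e6) < 5e5)
    if (!length(cand)) return(NA)
    sw <- inject_sweep(p, p$positions_bp[cand[1]], 0.2, 0.7,
                       seed = 2000 + s)
    a <- attr(sw, "sweep")
    focal_hom <- pair_hom(sw, a$focal_index, 2.5e4)
    f2 <- derived_freq(sw)
    ff <- f2[a$focal_index]
    others <- setdiff(which(abs(f2 - ff) < 0.15), which(
      abs(sw$positions_bp - a$position_bp) < 2e5))
    base <- mean(vapply(others, function(i) pair_hom(sw, i, 2.5e4),
                        numeric(1)), na.rm = TRUE)
    focal_hom > base
  }, logical(1))
  expect_gte(mean(hits, na.rm = TRUE), 0.9)
})

test_that("a zero-coefficient sweep is indistinguishable from neutral drift", {
  # independent oracle: 1-locus binomial Wright-Fisher chain with the same
  # restart-on-absorption rule
  N2 <- 80L
  gens <- 25L
  oracle <- function(seed) {
    set.seed(seed)
    repeat {
      f <- 0.5
      lost <- FALSE
      for (g in seq_len(gens)) {
        f <- rbinom(1, N2, f) / N2
        if (f == 0 || f == 1) { lost <- TRUE; break }
      }
      if (!lost) return(f)
    }
  }
  oracle_draws <- vapply(1:2000, oracle, numeric(1))
  sim_draws <- vapply(1:200, function(s) {
    sp <- sim_spec(n_samples = 40, n_snps = 10, chrom_length_bp = 1e6,
                   wf_population_size = 40, wf_generations = 0,
                   init_daf = 0.5, seed = 300 + s)
    p <- simulate_neutral_panel(sp, drop_monomorphic = FALSE)
    sw <- inject_sweep(p, 5e5, s = 0, stop_frequency = 0.999,
                       seed = 400 + s, max_gen = gens)
    derived_freq(sw)[attr(sw, "sweep")$focal_index]
  }, numeric(1))
  ks <- suppressWarnings(ks.test(sim_draws, oracle_draws))
  expect_gt(ks$p.value, 0.01)
})

test_that("GWAS simulation plants exact effects and Wald machinery", {
  p <- random_panel(40, 20, seed = 31)
  es <- effect_spec(gwas_causal = data.frame(snp_id = "s5", beta = 0.1),
                    gwas_noise_sd = 0)
  g <- simulate_gwas_summary(p, es, seed = 2)
  expect_equal(g$ln_or[5], 0.1)
  expect_equal(g$ln_or[-5], rep(0, 19))
  expect_equal(g$p, pmax(2 * pnorm(-abs(g$ln_or / g$se)),
                         .Machine$double.xmin))
  # two-sided normal tail at z = 2
  expect_equal(2 * pnorm(-2), 0.0455, tolerance = 1e-3)
  expect_error(simulate_gwas_summary(
    p, effect_spec(gwas_causal = data.frame(snp_id = "nope", beta = 1))),
    "absent")
})

test_that("uncoupled GWAS effects are uncorrelated with sweep distance", {
  p <- random_panel(60, 40, seed = 32)
  es <- effect_spec(coupling = 0, gwas_noise_sd = 0.05)
  rs <- vapply(1:100, function(s) {
    g <- simulate_gwas_summary(p, es, sweep_positions = 2e4, seed = s)
    d <- abs(p$positions_bp - 2e4)
    cor(abs(g$ln_or), d)
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.05)
})

test_that("expression simulation is exact without noise and errors without gene links", {
  p <- random_panel(40, 10, seed = 33)
  es <- effect_spec(eqtl = data.frame(snp_id = "s3", probe_id = "pr1",
                                      gene = "G1", beta = 1, sex_beta = 0.5,
                                      noise_sd = 0))
  sex <- rep(c(0, 1), each = 10)
  em <- simulate_expression(p, es, seed = 4, sex = sex)
  dos <- dosage_matrix(p)[, "s3"]
  expect_equal(unname(em$values["pr1", ]), unname(dos + 0.5 * sex))
  es_bad <- effect_spec(eqtl = data.frame(snp_id = "s3", probe_id = "pr1",
                                          gene = NA, beta = 1, sex_beta = 0,
                                          noise_sd = 0))
  expect_error(simulate_expression(p, es_bad, seed = 4), "gene link")
})

test_that("planted eQTLs are recovered with high power and nulls stay null", {
  p <- cached("eqtl_power_panel", function() random_panel(200, 30, seed = 35))
  dos <- dosage_matrix(p)
  hits <- vapply(1:100, function(s) {
    es <- effect_spec(eqtl = data.frame(snp_id = "s7", probe_id = "pr1",
                                        gene = "G1", beta = 1,
                                        sex_beta = 0.2, noise_sd = 0.5))
    em <- simulate_expression(p, es, seed = s)
    fit_eqtl(dos[, "s7"], attr(em, "sex"), em$values["pr1", ])$nominal_p < 1e-3
  }, logical(1))
  expect_gte(mean(hits), 0.95)

  null_p <- vapply(1:400, function(s) {
    es <- effect_spec(null_probes = data.frame(probe_id = "pr1", gene = "G1",
                                               noise_sd = 1))
    em <- simulate_expression(p, es, seed = 10000 + s)
    fit_eqtl(dos[, "s9"], attr(em, "sex"), em$values["pr1", ])$nominal_p
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(null_p, "punif"))$p.value, 0.01)
})

test_that("fitness simulation honours its null and its adjustment contract", {
  p <- random_panel(120, 30, seed = 36)
  es <- effect_spec(lrs = list(h2 = 0, residual_sd = 1, secular_trend = 0,
                               covariate_betas = c(education = 0, smoking = 0,
                                                   born_in_country = 0,
                                                   estrogen_use = 0)))
  ph <- simulate_fitness(p, es, seed = 5)
  adj <- adjust_lrs(ph)
  gm <- tapply(adj$lrs_adjusted, adj$by_group, mean)
  expect_equal(as.numeric(gm), rep(1, 6), tolerance = 1e-12)
  expect_error(effect_spec(lrs = list(h2 = 1.2)), "h2")
})

test_that("the fixture bundle round-trips through the on-disk formats", {
  dir <- tempfile("bundle")
  sp <- sim_spec(n_samples = 30, n_snps = 150, chrom_length_bp = 1e6,
                 wf_population_size = 60, wf_generations = 20, seed = 12)
  es <- effect_spec(null_probes = data.frame(probe_id = "pr1", gene = "G1",
                                             noise_sd = 1))
  out <- write_fixture_bundle(dir, sp, es, seed = 9)
  expect_true(all(file.exists(file.path(
    dir, c("panel.vcf", "genes.bed", "gwas.tsv", "expr.tsv", "pheno.tsv",
           "truth.json")))))
  p2 <- read_phased_vcf(file.path(dir, "panel.vcf"))
  expect_equal(p2$hap_matrix, out$panel$hap_matrix, ignore_attr = TRUE)
  g2 <- read_gwas_summary(file.path(dir, "gwas.tsv"))
  expect_equal(g2$ln_or, out$gwas$ln_or, tolerance = 1e-12)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(truth$seed, 9)
})
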