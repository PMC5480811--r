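test_that("LRS adjustment divides by the birth-year group mean", {
  ph <- data.frame(birth_year = rep(1901:1906, each = 10),
                   lrs_raw = rep(c(2, 2, 2, 4, 4, 4), each = 10))
  ph$lrs_raw[1] <- 3  # group 1 mean becomes 2.1
  adj <- adjust_lrs(ph, n_groups = 6)
  expect_equal(adj$lrs_adjusted[1], 3 / 2.1)
  gm <- tapply(adj$lrs_adjusted, adj$by_group, mean)
  expect_equal(as.numeric(gm), rep(1, 6), tolerance = 1e-12)
  # constant LRS -> all adjusted values 1
  ph2 <- data.frame(birth_year = 1:60, lrs_raw = rep(2, 60))
  expect_true(all(adjust_lrs(ph2)$lrs_adjusted == 1))
  ph3 <- data.frame(birth_year = 1:12, lrs_raw = c(rep(0, 2), rep(2, 10)))
  expect_error(adjust_lrs(ph3), "zero mean")
})

test_that("the relationship kernel is centred, PSD and detects duplicates", {
  p <- wf_panel()
  g <- compute_grm(p, prune_r2 = 0.3, min_snps = 30)
  K <- g$kernel
  expect_true(isSymmetric(K, tol = 1e-10))
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8 * max(ev))
  # unrelated-sample centring: small mean off-diagonal
  off <- K[upper.tri(K)]
  expect_lt(abs(mean(off)), 3 / sqrt(g$m))
  # duplicated individual: kernel entry equals the diagonal
  pd <- subset_samples_panel(p, c(1:20, 1))
  gd <- compute_grm(pd, prune_r2 = 0.3, min_snps = 30)
  n <- length(gd$sample_ids)
  expect_equal(gd$kernel[n, 1], gd$kernel[n, n], tolerance = 1e-10)
  expect_error(compute_grm(p, prune_r2 = 0.3, min_snps = 1e5),
               "relationship kernel")
})

test_that("kernel SNP exclusion avoids proximal contamination", {
  p <- wf_panel()
  excl <- data.frame(chrom = p$chrom, start = 4e6, end = 6e6)
  g <- compute_grm(p, prune_r2 = 0.3, exclude_intervals = excl,
                   exclude_window_bp = 5e5, r2_excl = 0.8, min_snps = 20)
  pos <- p$positions_bp[match(g$snps, p$snp_ids)]
  expect_false(any(pos >= 3.5e6 & pos <= 6.5e6))
  inside <- which(p$positions_bp >= 4e6 & p$positions_bp <= 6e6 &
                    minor_freq(p) > 0)
  r2 <- cor(p$hap_matrix[, match(g$snps, p$snp_ids)],
            p$hap_matrix[, inside])^2
  expect_lt(max(r2), 0.8)
})

test_that("the kernel LMM matches OLS when heritability is absent", {
  set.seed(30)
  p <- wf_panel()
  keep <- 1:80
  ps <- subset_samples_panel(p, keep)
  g <- compute_grm(ps, prune_r2 = 0.3, min_snps = 30)
  dos <- dosage_matrix(ps)[, minor_freq(ps) > 0.1][, 1:5]
  W <- matrix(rnorm(80), ncol = 1, dimnames = list(NULL, "cov"))
  y <- 0.2 * dos[, 3] + 0.3 * W[, 1] + rnorm(80)   # no polygenic term
  fit <- lmm_assoc(y, W, g, dos)
  ols <- coef(lm(y ~ W + dos[, 3]))
  expect_equal(fit$beta[3], unname(ols[3]), tolerance = 1e-4)
  expect_gt(fit$delta[3], 100)   # variance pushed to the residual
})

test_that("the kernel LMM equals a dense-covariance GLS oracle", {
  set.seed(31)
  p <- subset_samples_panel(wf_panel(), 1:60)
  g <- compute_grm(p, prune_r2 = 0.3, min_snps = 30)
  K <- g$kernel
  L <- t(chol(0.6 * K + 0.4 * diag(60) + 1e-8 * diag(60)))
  y <- as.numeric(L %*% rnorm(60))
  W <- matrix(rbinom(60, 1, 0.5), ncol = 1, dimnames = list(NULL, "w"))
  dos <- dosage_matrix(p)[, minor_freq(p) > 0.1][, 1:3]
  fit <- lmm_assoc(y, W, g, dos)
  for (j in 1:3) {
    V <- K + fit$delta[j] * diag(60)
    Vi <- solve(V)
    X <- cbind(1, W, dos[, j])
    bh <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
    expect_equal(fit$beta[j], bh[3], tolerance = 1e-6, ignore_attr = TRUE)
  }
  expect_error(lmm_assoc(y, cbind(W, w2 = W[, 1]), g, dos), "singular")
})

test_that("planted SNP effects and heritability are recovered", {
  hits <- vapply(1:12, function(s) {
    sp <- sim_spec(n_samples = 300, n_snps = 500, chrom_length_bp = 1e7,
                   recomb_rate_cM_per_Mb = 3, wf_population_size = 300,
                   wf_generations = 60, seed = 6000 + s)
    p <- simulate_neutral_panel(sp)
    common <- which(minor_freq(p) > 0.2)
    snp <- p$snp_ids[common[10]]
    es <- effect_spec(lrs = list(snp_effects = data.frame(snp_id = snp,
                                                          beta = 0.25),
                                 h2 = 0.2, residual_sd = 1))
    g <- compute_grm(p, prune_r2 = 0.3, min_snps = 30)
    ph <- simulate_fitness(p, es, seed = 7000 + s, grm = g)
    ph <- adjust_lrs(ph)
    W <- ph[, c("education", "smoking", "born_in_country", "estrogen_use")]
    scale_y <- mean(tapply(ph$lrs_raw, ph$by_group, mean))
    fit <- lmm_assoc(ph$lrs_adjusted * scale_y, W, g,
                     dosage_matrix(p)[, snp, drop = FALSE])
    abs(fit$beta[1] - 0.25) <= 2 * fit$se[1]
  }, logical(1))
  expect_gte(mean(hits), 0.75)
})

test_that("MAF-binned SNP permutations floor, centre and calibrate", {
  set.seed(33)
  pool_p <- runif(5000)
  pool_maf <- runif(5000, 0, 0.5)
  expect_equal(permute_snp_p(1e-9, 0.25, pool_p, pool_maf, n_perm = 1000,
                             seed = 1), 1 / 1001)
  med <- permute_snp_p(0.5, 0.25, pool_p, pool_maf, n_perm = 2000, seed = 2)
  expect_lt(abs(med - 0.5), 0.05)
  targets <- runif(300)
  pp <- permute_snp_p(targets, runif(300, 0, 0.5), pool_p, pool_maf,
                      n_perm = 500, seed = 3)
  expect_gt(suppressWarnings(ks.test(pp, "punif"))$p.value, 0.01)
})

test_that("the MAF-matched set test matches histograms and calibrates", {
  set.seed(34)
  cad_maf <- runif(150, 0.05, 0.45)
  cad_p <- runif(150)
  pool_maf <- runif(6000, 0, 0.5)
  pool_p <- runif(6000)
  out <- set_enrichment_test(cad_p, cad_maf, pool_p, pool_maf, n_draws = 20,
                             seed = 5, return_draws = TRUE)
  bins <- function(m) table(factor(floor(m / 0.05), levels = 0:9))
  for (d in out$draw_maf)
    expect_equal(as.integer(bins(d)), as.integer(bins(cad_maf)))
  # calibration: focal set drawn from the null pool itself
  reps <- vapply(1:40, function(s) {
    idx <- sample.int(6000, 150)
    set_enrichment_test(pool_p[idx], pool_maf[idx], pool_p[-idx],
                        pool_maf[-idx], n_draws = 30, seed = s)$perm_p_set
  }, numeric(1))
  expect_gt(mean(reps > 0.1), 0.7)   # not stacked at the floor
  expect_gt(min(reps), 1 / 31 - 1e-12)
})

test_that("the sum-of-chi-squares gene test matches its closed forms", {
  # single SNP, z^2 = 4: chi-square(1) tail at 4
  g1 <- gene_based_test(z = 2, R = matrix(1, 1, 1))
  expect_equal(g1$p_gene, pchisq(4, 1, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_equal(g1$p_gene, 0.0455, tolerance = 1e-3)
  # two perfectly correlated SNPs, each z^2 = 4: T = 8 ~ 2 chi2_1
  g2 <- gene_based_test(z = c(2, 2), R = matrix(1, 2, 2))
  expect_equal(sort(g2$lambda), c(0, 2), tolerance = 1e-12)
  expect_equal(g2$p_satterthwaite, pchisq(4, 1, lower.tail = FALSE),
               tolerance = 1e-10)
  # independent SNPs: exact chi-square(m) tail
  for (m in 2:5) {
    z <- seq(0.5, 1.5, length.out = m)
    gm <- gene_based_test(z, diag(m))
    expect_equal(gm$p_gene, pchisq(sum(z^2), m, lower.tail = FALSE),
                 tolerance = 1e-6)
  }
  expect_equal(sum(gene_based_test(rnorm(4), diag(4))$lambda), 4,
               tolerance = 1e-12)
})

test_that("gene and gene-set permutation p values follow rank rules", {
  expect_equal(gene_perm_p(1e-8, runif(100)), 1 / 101)
  set.seed(35)
  nullmat <- matrix(runif(300 * 76), 300, 76)
  cad <- runif(76)
  gs <- gene_set_enrichment(cad, nullmat)
  expect_gte(gs$perm_p, 1 / 301)
  expect_lte(gs$perm_p, 1)
  # planted signal: every focal gene significant
  gs2 <- gene_set_enrichment(rep(1e-4, 76), nullmat)
  expect_equal(gs2$perm_p, 1 / 301)
})

test_that("multiple-testing adjustments match their definitions", {
  out <- multiple_testing(0.05 / 76, m = 76)
  expect_equal(out$bonferroni, 0.05)
  bh <- multiple_testing(c(0.01, 0.02, 0.03))
  expect_equal(bh$fdr_bh, c(0.03, 0.03, 0.03))
  expect_true(all(multiple_testing(rep(1, 5))$bonferroni == 1))
  expect_true(all(multiple_testing(rep(1, 5))$fdr_bh == 1))
})
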