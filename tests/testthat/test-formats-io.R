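test_that("phased VCF is read as ALT dosage when the ancestral allele is REF", {
  path <- write_vcf_text(c(
    "chr1\t100\trs1\tA\tG\t.\tPASS\tAA=A\tGT\t0|1\t1|1",
    "chr1\t200\trs2\tC\tT\t.\tPASS\tAA=C\tGT\t0|0\t0|1",
    "chr1\t300\trs3\tG\tA\t.\tPASS\tAA=G\tGT\t1|0\t0|0"))
  p <- read_phased_vcf(path, "TEST")
  expect_equal(dim(p$hap_matrix), c(4L, 3L))
  expect_equal(p$hap_matrix[, 1], c(0L, 1L, 1L, 1L))
  expect_equal(p$hap_matrix[, 2], c(0L, 0L, 0L, 1L))
  expect_equal(p$hap_matrix[, 3], c(1L, 0L, 0L, 0L))
  expect_equal(p$population, "TEST")
})

test_that("a site with AA = ALT is complemented, and recoding is an involution", {
  lines <- c(
    "chr1\t100\trs1\tA\tG\t.\tPASS\tAA=A\tGT\t0|1\t1|1",
    "chr1\t200\trs2\tC\tT\t.\tPASS\tAA=T\tGT\t0|0\t0|1",
    "chr1\t300\trs3\tG\tA\t.\tPASS\tAA=G\tGT\t1|0\t0|0")
  p <- read_phased_vcf(write_vcf_text(lines), "TEST")
  expect_equal(p$hap_matrix[, 2], 1L - c(0L, 0L, 0L, 1L))
  # swapping the AA annotation back restores the original column
  lines2 <- sub("AA=T", "AA=C", lines)
  p2 <- read_phased_vcf(write_vcf_text(lines2), "TEST")
  expect_equal(p2$hap_matrix[, 2], c(0L, 0L, 0L, 1L))
  expect_equal(p$hap_matrix[, 2], 1L - p2$hap_matrix[, 2])
})

test_that("unphased genotypes are a hard error naming the record", {
  path <- write_vcf_text(c(
    "chr1\t100\trs1\tA\tG\t.\tPASS\tAA=A\tGT\t0|1\t1|1",
    "chr1\t200\trs2\tC\tT\t.\tPASS\tAA=C\tGT\t0/1\t0|1"))
  expect_error(read_phased_vcf(path), "chr1:200")
})

test_that("sites with missing or mismatching ancestral state are dropped and counted", {
  path <- write_vcf_text(c(
    "chr1\t100\trs1\tA\tG\t.\tPASS\tAA=A\tGT\t0|1\t1|1",
    "chr1\t200\trs2\tC\tT\t.\tPASS\t.\tGT\t0|0\t0|1",
    "chr1\t300\trs3\tG\tA\t.\tPASS\tAA=C\tGT\t1|0\t0|0",
    "chr1\t400\trs4\tG\tAT\t.\tPASS\tAA=G\tGT\t1|0\t0|0"))
  expect_warning(p <- read_phased_vcf(path), "ancestral")
  expect_equal(n_snps(p), 1L)
  rep <- attr(p, "drop_report")
  expect_equal(unname(rep["missing_aa"]), 1L)
  expect_equal(unname(rep["aa_mismatch"]), 1L)
  expect_equal(unname(rep["non_snp"]), 1L)
})

test_that("a sidecar ancestral table substitutes for INFO/AA", {
  path <- write_vcf_text(c(
    "chr1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0|1\t1|1"))
  p <- read_phased_vcf(path, ancestral = data.frame(snp_id = "rs1", aa = "G"))
  expect_equal(p$hap_matrix[, 1], 1L - c(0L, 1L, 1L, 1L))
})

test_that("panel -> VCF -> panel round-trips exactly", {
  p <- random_panel(8, 12, seed = 5)
  path <- tempfile(fileext = ".vcf")
  write_phased_vcf(p, path)
  q <- read_phased_vcf(path, population_label = p$population)
  expect_equal(q$hap_matrix, p$hap_matrix, ignore_attr = TRUE)
  expect_equal(q$positions_bp, p$positions_bp)
  expect_equal(q$snp_ids, p$snp_ids)
})

test_that("BED4 coordinates convert to 1-based inclusive and round-trip", {
  path <- tempfile(fileext = ".bed")
  writeLines("chr6\t12716893\t13290103\tPHACTR1", path)
  g <- read_gene_bed(path)
  expect_equal(g$start, 12716894L)
  expect_equal(g$end, 13290103L)
  out <- tempfile(fileext = ".bed")
  write_gene_bed(g, out)
  expect_equal(read_gene_bed(out), g)
})

test_that("summary-statistic reader validates its schema", {
  df <- data.frame(snp_id = paste0("rs", 1:5), chrom = "chr1",
                   pos_bp = 1:5 * 100L, effect_allele = "A",
                   other_allele = "G", ln_or = rnorm(5), se = runif(5) + 0.1,
                   p = runif(5))
  path <- tempfile(fileext = ".tsv")
  data.table::fwrite(df, path, sep = "\t")
  expect_equal(read_gwas_summary(path), df, ignore_attr = TRUE)

  bad <- df; bad$p[2] <- 0
  data.table::fwrite(bad, path, sep = "\t")
  expect_error(read_gwas_summary(path), "p must lie")

  bad <- df; bad$snp_id[2] <- "rs1"
  data.table::fwrite(bad, path, sep = "\t")
  expect_error(read_gwas_summary(path), "duplicated")

  data.table::fwrite(df[, -6], path, sep = "\t")
  expect_error(read_gwas_summary(path), "ln_or")
})

test_that("expression and phenotype tables round-trip through their writers", {
  em <- structure(list(probe_ids = c("p1", "p2"),
                       gene_links = c(p1 = "G1", p2 = "G2"),
                       values = matrix(rnorm(6), 2, 3,
                                       dimnames = list(c("p1", "p2"),
                                                       c("A", "B", "C"))),
                       sample_ids = c("A", "B", "C")),
                  class = "expression_matrix")
  path <- tempfile(fileext = ".tsv")
  write_expression(em, path)
  em2 <- read_expression(path)
  expect_equal(em2$values, em$values, tolerance = 1e-12)
  expect_equal(em2$gene_links, em$gene_links)

  ph <- data.frame(sample_id = c("A", "B"), sex = c(1L, 0L),
                   birth_year = c(1930L, 1940L), lrs_raw = c(2L, 3L),
                   education = c(1L, 2L), smoking = c(0L, 1L),
                   born_in_country = c(1L, 1L), estrogen_use = c(0L, 1L))
  pp <- tempfile(fileext = ".tsv")
  data.table::fwrite(ph, pp, sep = "\t")
  expect_equal(read_phenotypes(pp), ph, ignore_attr = TRUE)
})

test_that("QC removes low-MAF, monomorphic and HWE-failing SNPs and is idempotent", {
  set.seed(9)
  n <- 100
  hap <- cbind(
    rbinom(2 * n, 1, 0.5),                       # common, fine
    c(rep(1L, 1), rep(0L, 2 * n - 1)),           # MAF 0.005 -> out
    rep(0L, 2 * n),                              # monomorphic -> out
    rep(c(1L, 0L), n),                           # het excess -> HWE fail
    rbinom(2 * n, 1, 0.3))                       # fine
  p <- hand_panel(hap)
  q <- apply_qc_filters(p, maf_min = 0.01)
  expect_equal(n_snps(q), 2L)
  rep <- attr(q, "qc_report")
  expect_equal(unname(rep["maf"]), 2L)
  expect_equal(unname(rep["hwe"]), 1L)
  q2 <- apply_qc_filters(q, maf_min = 0.01)
  expect_equal(q2$hap_matrix, q$hap_matrix)
  expect_error(apply_qc_filters(hand_panel(matrix(0L, 10, 2))),
               "all SNPs removed")
})

test_that("Hardy-Weinberg chi-square matches the hand computation", {
  # (25, 50, 25) of 100 is exactly at equilibrium: chi-square 0, p 1
  expect_equal(hwe_chisq_p(25, 50, 25), 1)
  # (30, 40, 30): p = 0.5, expected (25, 50, 25); chi2 = 1+2+1 = 4
  expect_equal(hwe_chisq_p(30, 40, 30),
               pchisq(4, df = 1, lower.tail = FALSE))
  expect_equal(hwe_chisq_p(100, 0, 0), 1)  # monomorphic
})

test_that("run configuration validates permutation counts and round-trips YAML", {
  cfg <- default_config()
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, path)
  cfg2 <- read_run_config(path)
  expect_equal(cfg2$scan$n_perm, cfg$scan$n_perm)
  cfg$assoc$n_perm <- 0L
  yaml::write_yaml(cfg, path)
  expect_error(read_run_config(path), "permutation count")
})
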