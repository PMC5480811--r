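# Shared fixture builders. Everything is generated in code; heavier
# simulated panels are cached per test run in `fix_env`.

fix_env <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = fix_env)) assign(name, builder(), envir = fix_env)
  get(name, envir = fix_env)
}

# A hand-built panel: explicit haplotypes, unit spacing.
hand_panel <- function(hap, pos = NULL, cm = NULL, chrom = "chr1") {
  hap <- as.matrix(hap)
  S <- ncol(hap)
  if (is.null(pos)) pos <- seq_len(S) * 1000L
  if (is.null(cm)) cm <- pos / 1e6
  haplotype_panel(
    snp_ids = paste0("s", seq_len(S)), chrom = chrom, positions_bp = pos,
    genetic_pos_cM = cm,
    alleles = data.frame(ancestral = rep("A", S), derived = rep("G", S),
                         stringsAsFactors = FALSE),
    hap_matrix = hap, sample_ids = paste0("I", seq_len(nrow(hap) / 2))
  )
}

# Small random panel for oracle comparisons (no WF structure needed).
random_panel <- function(n_hap, n_snp, seed) {
  set.seed(seed)
  repeat {
    hap <- matrix(rbinom(n_hap * n_snp, 1, runif(1, 0.2, 0.8)),
                  nrow = n_hap)
    f <- colMeans(hap)
    if (all(f > 0 & f < 1)) break
  }
  hand_panel(hap)
}

# Mid-sized Wright-Fisher panel reused across scan tests.
wf_panel <- function() cached("wf_panel", function() {
  spec <- sim_spec(n_samples = 100, n_snps = 1500, chrom_length_bp = 1e7,
                   recomb_rate_cM_per_Mb = 9, wf_population_size = 200,
                   wf_generations = 120, seed = 424)
  simulate_neutral_panel(spec)
})

wf_scores <- function() cached("wf_scores", function() {
  s <- ihs_scan(wf_panel())
  s <- suppressWarnings(standardize_ihs(s))
  suppressWarnings(permute_ihs_p(s, n_perm = 1000, seed = 77))
})

# Dense-covariance GLS oracle for the rank-1 mixed model at fixed gamma.
rank1_gls_oracle <- function(y, x, v, gamma) {
  n <- length(y)
  V <- diag(n) + gamma * tcrossprod(v)
  Vi <- solve(V)
  X <- cbind(1, x)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  as.numeric(beta)[2]
}

# Rank-1 REML criterion evaluated densely (independent of the C++ path).
rank1_reml_oracle <- function(y, x, v, gamma) {
  n <- length(y)
  X <- cbind(1, x)
  V <- diag(n) + gamma * tcrossprod(v)
  Vi <- solve(V)
  XtVX <- t(X) %*% Vi %*% X
  beta <- solve(XtVX, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  rss <- as.numeric(t(r) %*% Vi %*% r)
  s2 <- rss / (n - 2)
  -0.5 * ((n - 2) * log(s2) + determinant(V)$modulus +
          determinant(XtVX)$modulus + (n - 2))
}

# Write a small VCF text file and return its path.
write_vcf_text <- function(body_lines, samples = c("S1", "S2")) {
  path <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    body_lines), path)
  path
}
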