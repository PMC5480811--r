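#' Single SNP-probe eQTL regression
#'
#' Ordinary least squares of expression on derived-allele dosage and sex,
#' with a two-sided t-test for the dosage term.
#'
#' @param dosage 0/1/2 genotype dosage per sample.
#' @param sex 0/1 covariate per sample.
#' @param expression probe expression per sample (log2 scale).
#' @return list: `beta`, `se`, `t`, `nominal_p`, `n`, `defined` (FALSE
#'   for constant dosage or fewer than 10 complete samples).
#' @export
fit_eqtl <- function(dosage, sex, expression) {
  ok <- complete.cases(dosage, sex, expression)
  und <- list(beta = NA_real_, se = NA_real_, t = NA_real_,
              nominal_p = NA_real_, n = sum(ok), defined = FALSE)
  if (sum(ok) < 10) return(und)
  d <- dosage[ok]; s <- sex[ok]; e <- expression[ok]
  if (sd(d) == 0) return(und)
  fit <- lm(e ~ d + s)
  co <- summary(fit)$coefficients
  list(beta = co["d", 1], se = co["d", 2], t = co["d", 3],
       nominal_p = co["d", 4], n = sum(ok), defined = TRUE)
}

#' Expression-shuffling permutation p value for an eQTL
#'
#' Shuffles the probe expression across samples, refits, and counts
#' permutations with |t| at least the observed |t|:
#' `permuted_p = (1 + #exceedances) / (n_perm + 1)`. The refits are
#' computed in closed form (the t statistic of the dosage term equals the
#' partial correlation of dosage and expression given sex), vectorized
#' over permutations; this is algebraically identical to refitting the
#' OLS model per shuffle.
#'
#' @inheritParams fit_eqtl
#' @param n_perm number of shuffles (default 10000).
#' @param seed integer seed.
#' @return list: `permuted_p`, `observed` (the observed fit), `n_perm`.
#' @export
permute_eqtl <- function(dosage, sex, expression, n_perm = 10000, seed = 1) {
  obs <- fit_eqtl(dosage, sex, expression)
  if (!obs$defined)
    return(list(permuted_p = NA_real_, observed = obs, n_perm = n_perm))
  ok <- complete.cases(dosage, sex, expression)
  d <- dosage[ok]; s <- sex[ok]; e <- expression[ok]
  n <- length(d)
  Z <- cbind(1, s)
  Qz <- qr(Z)
  rd <- qr.resid(Qz, d)
  set.seed(seed)
  perm_idx <- replicate(n_perm, sample.int(n))
  E <- matrix(e[perm_idx], nrow = n)
  RE <- E - Z %*% qr.coef(qr(Z), E)
  df <- n - 3
  num <- as.numeric(crossprod(rd, RE))
  den <- sqrt(sum(rd^2)) * sqrt(colSums(RE^2))
  r <- ifelse(den > 0, num / den, 0)
  r <- pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)
  tstat <- r * sqrt(df) / sqrt(1 - r^2)
  p <- (1 + sum(abs(tstat) >= abs(obs$t))) / (n_perm + 1)
  list(permuted_p = p, observed = obs, n_perm = n_perm)
}

#' Compare eQTL p values of selected apex SNPs versus random SNPs
#'
#' Stratum A holds the permuted eQTL p value of the apex SNP of each
#' gene-population candidate signal. Stratum B holds an equal count of
#' SNPs drawn one per draw from LD blocks containing no significant-iHS
#' SNP (a block uniformly among eligible blocks, then a SNP uniformly
#' within it). The strata are compared by a two-sample Kolmogorov-Smirnov
#' test (exact for strata of at most 25, asymptotic otherwise); the
#' one-sided mode tests whether stratum A is stochastically smaller
#' (mapped to `stats::ks.test(..., alternative = "greater")`, whose
#' naming refers to the CDF of the first sample).
#'
#' @param apex_p permuted eQTL p values of the apex SNPs (stratum A).
#' @param snp_p permuted eQTL p values of the candidate pool for
#'   stratum B.
#' @param snp_block LD block label per pool SNP.
#' @param signal_blocks block labels containing any significant-iHS SNP
#'   (never drawn from).
#' @param seed integer seed.
#' @param alternative `"two.sided"` (default) or `"one.sided"` (A
#'   stochastically smaller).
#' @return list: `D`, `ks_p`, `n_selected`, `n_random`, `random_p`.
#' @export
compare_selected_vs_random <- function(apex_p, snp_p, snp_block,
                                       signal_blocks, seed = 1,
                                       alternative = c("two.sided",
                                                       "one.sided")) {
  alternative <- match.arg(alternative)
  ks_alt <- if (alternative == "one.sided") "greater" else "two.sided"
  apex_p <- apex_p[!is.na(apex_p)]
  if (length(apex_p) < 5)
    stop("need at least 5 gene-population combinations with a signal")
  ok <- !is.na(snp_p) & !(snp_block %in% signal_blocks)
  if (!any(ok)) stop("no eligible LD block without a significant-iHS SNP")
  blocks <- unique(snp_block[ok])
  set.seed(seed)
  draw <- vapply(seq_along(apex_p), function(i) {
    b <- blocks[sample.int(length(blocks), 1)]
    cand <- which(ok & snp_block == b)
    snp_p[cand[sample.int(length(cand), 1)]]
  }, numeric(1))
  exact <- length(apex_p) <= 25 && length(draw) <= 25
  ks <- suppressWarnings(
    ks.test(apex_p, draw, alternative = ks_alt, exact = exact))
  list(D = unname(ks$statistic), ks_p = ks$p.value,
       n_selected = length(apex_p), n_random = length(draw),
       random_p = draw)
}
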