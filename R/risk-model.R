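#' Fit the per-gene selection-vs-risk mixed model
#'
#' Regresses per-SNP GWAS log odds on selection scores within one gene,
#' with the gene's first LD eigenvector v as a random effect:
#' y = b0 + b1 x + u v + e, u ~ N(0, sigma_u^2), e ~ N(0, sigma_e^2 I),
#' so cov(y) = sigma_u^2 v v' + sigma_e^2 I (a rank-1 random-coefficient
#' formalization of "the first eigenvector as a random effect").
#' sigma_u^2 is estimated by REML through the rank-1 spectral identity,
#' b1 by generalized least squares. Both y and x are taken as absolute
#' values by default (magnitude-on-magnitude, matching how selection and
#' risk peaks are compared) and standardized to unit variance, so
#' `beta_scaled` is the scaled regression coefficient. SNP pairs with an
#' undefined score are dropped pairwise.
#'
#' @param ln_or per-SNP GWAS ln(OR) for the gene's SNPs.
#' @param ihs per-SNP standardized iHS (NA allowed; dropped pairwise).
#' @param v first LD eigenvector, same length (subset with the same
#'   pairwise drops and renormalized).
#' @param absolute use |ln_or| and |ihs| (default TRUE); FALSE is the
#'   signed sensitivity mode.
#' @param gamma fix the variance ratio sigma_u^2/sigma_e^2 instead of
#'   estimating it (NULL, the default, estimates by REML; 0 collapses to
#'   ordinary least squares; `Inf` gives the projection limit in which v
#'   acts as a fixed covariate).
#' @return list: `beta_scaled`, `se`, `nominal_p` (two-sided Wald),
#'   `sigma_u2`, `sigma_e2`, `gamma` (sigma_u^2/sigma_e^2), `n_snps`,
#'   `defined` (FALSE when x or y has zero variance or n < 3).
#' @export
fit_selection_risk_model <- function(ln_or, ihs, v, absolute = TRUE,
                                     gamma = NULL) {
  stopifnot(length(ln_or) == length(ihs), length(ihs) == length(v))
  ok <- !is.na(ln_or) & !is.na(ihs) & !is.na(v)
  y <- ln_or[ok]; x <- ihs[ok]; vv <- v[ok]
  und <- list(beta_scaled = NA_real_, se = NA_real_, nominal_p = NA_real_,
              sigma_u2 = NA_real_, sigma_e2 = NA_real_, gamma = NA_real_,
              n_snps = sum(ok), defined = FALSE)
  if (sum(ok) < 3) return(und)
  if (absolute) { y <- abs(y); x <- abs(x) }
  if (sd(y) == 0 || sd(x) == 0) return(und)
  y <- as.numeric(scale(y))
  x <- as.numeric(scale(x))
  nv <- sqrt(sum(vv^2))
  if (nv == 0) return(und)
  vv <- vv / nv
  f <- cpp_rank1_fit(y, x, vv, if (is.null(gamma)) -1 else gamma)
  z <- f$beta1 / f$se1
  list(beta_scaled = f$beta1, se = f$se1, nominal_p = 2 * pnorm(-abs(z)),
       sigma_u2 = f$sigma_u2, sigma_e2 = f$sigma_e2, gamma = f$gamma,
       n_snps = sum(ok), defined = TRUE)
}

#' iHS-shuffling permutation p value for the selection-risk model
#'
#' Shuffles the iHS vector across the gene's SNPs (ln(OR) and v fixed),
#' refits the mixed model each time, and compares |beta_scaled|:
#' `perm_p = (1 + #permutations with |beta| >= observed) / (n_perm + 1)`.
#'
#' @inheritParams fit_selection_risk_model
#' @param n_perm number of shuffles (default 10000).
#' @param seed integer seed.
#' @return list: `perm_p_shuffle`, `observed` (the observed fit),
#'   `n_perm`.
#' @export
permute_association <- function(ln_or, ihs, v, n_perm = 10000, seed = 1,
                                absolute = TRUE) {
  obs <- fit_selection_risk_model(ln_or, ihs, v, absolute = absolute)
  if (!obs$defined)
    return(list(perm_p_shuffle = NA_real_, observed = obs, n_perm = n_perm))
  ok <- !is.na(ln_or) & !is.na(ihs) & !is.na(v)
  y <- ln_or[ok]; x <- ihs[ok]; vv <- v[ok]
  if (absolute) { y <- abs(y); x <- abs(x) }
  y <- as.numeric(scale(y))
  x <- as.numeric(scale(x))
  vv <- vv / sqrt(sum(vv^2))
  set.seed(seed)
  perm <- cpp_rank1_perm(y, x, vv, as.integer(n_perm))
  p <- (1 + sum(perm >= abs(obs$beta_scaled))) / (n_perm + 1)
  list(perm_p_shuffle = p, observed = obs, n_perm = n_perm)
}

#' Gene-matched null permutation p value
#'
#' Compares a gene's observed nominal p value against the nominal p
#' values of the same model fitted on length-matched random genes:
#' `perm_p_genes = (1 + #null p <= observed p) / (n_null + 1)`.
#'
#' @param observed_p nominal p value of the target gene's fit.
#' @param null_p nominal p values from the null genes (NA dropped).
#' @return permuted p value in (0, 1].
#' @export
gene_matched_null <- function(observed_p, null_p) {
  null_p <- null_p[!is.na(null_p)]
  (1 + sum(null_p <= observed_p)) / (length(null_p) + 1)
}

#' Rank genes by count of significant selection-risk associations
#'
#' Counts, per gene, the populations with `perm_p_shuffle` below `alpha`,
#' sorts by descending count (ties alphabetically by gene name) and flags
#' the headline panel of genes with at least `min_count` significant
#' populations.
#'
#' @param results data.frame with columns `gene`, `population`,
#'   `perm_p_shuffle`.
#' @param alpha significance threshold (default 0.05).
#' @param min_count count required for the headline flag (default 4).
#' @return data.frame: `gene`, `n_significant`, `headline`.
#' @export
rank_genes <- function(results, alpha = 0.05, min_count = 4) {
  sig <- !is.na(results$perm_p_shuffle) & results$perm_p_shuffle < alpha
  tab <- tapply(sig, results$gene, sum)
  out <- data.frame(gene = names(tab), n_significant = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_significant, out$gene), ]
  out$headline <- out$n_significant >= min_count
  rownames(out) <- NULL
  out
}
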