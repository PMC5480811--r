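#' MAF-binned permutation p value for a SNP's association
#'
#' Draws `n_perm` SNPs uniformly with replacement from the genome-wide
#' pool restricted to the target's MAF bin and counts how often a drawn
#' nominal p value is at or below the target's:
#' `permuted_p = (1 + #draws with p <= target) / (n_perm + 1)`. Bins with
#' fewer than `min_bin` SNPs are widened to their neighbours.
#'
#' @param target_p nominal p value(s) of the target SNP(s).
#' @param target_maf MAF of the target SNP(s).
#' @param pool_p genome-wide nominal p values.
#' @param pool_maf genome-wide MAFs, aligned with `pool_p`.
#' @param n_perm draws per target (default 10000).
#' @param maf_bin bin width (default 0.05).
#' @param seed integer seed.
#' @param min_bin minimum bin occupancy before widening (default 100).
#' @return numeric vector of permuted p values.
#' @export
permute_snp_p <- function(target_p, target_maf, pool_p, pool_maf,
                          n_perm = 10000, maf_bin = 0.05, seed = 1,
                          min_bin = 100) {
  ok <- !is.na(pool_p) & !is.na(pool_maf)
  pool_p <- pool_p[ok]
  pool_maf <- pool_maf[ok]
  pb <- floor(pool_maf / maf_bin)
  set.seed(seed)
  widened <- 0L
  out <- vapply(seq_along(target_p), function(i) {
    if (is.na(target_p[i])) return(NA_real_)
    b <- floor(target_maf[i] / maf_bin)
    w <- 0L
    repeat {
      sel <- abs(pb - b) <= w
      if (sum(sel) >= min_bin || w > 1 / maf_bin) break
      w <- w + 1L
    }
    if (w > 0) widened <<- widened + 1L
    draws <- sample(pool_p[sel], n_perm, replace = TRUE)
    (1 + sum(draws <= target_p[i])) / (n_perm + 1)
  }, numeric(1))
  if (widened)
    message(widened, " target(s) used a widened MAF bin (occupancy < ",
            min_bin, ")")
  out
}

#' MAF-matched SNP-set enrichment test
#'
#' Each of `n_draws` draws samples, without replacement, a non-focal SNP
#' set matched bin-for-bin to the focal set's MAF histogram; the permuted
#' p value counts draws whose number of p values below `alpha` reaches
#' the focal count. All pooled draw p values are also compared to the
#' focal p values by two-sided and one-sided Kolmogorov-Smirnov tests
#' (the one-sided test asks whether the focal p values are stochastically
#' larger, i.e. `ks.test(focal, pooled, alternative = "less")` in R's
#' CDF-based naming).
#'
#' @param cad_p nominal p values of the focal (disease-locus) SNP set.
#' @param cad_maf their MAFs.
#' @param pool_p,pool_maf the non-focal genome-wide pool.
#' @param n_draws number of matched draws (default 100).
#' @param alpha per-SNP significance threshold (default 0.05).
#' @param maf_bin bin width for matching (default 0.05).
#' @param seed integer seed.
#' @param return_draws also return the drawn MAF vectors (for auditing
#'   the histogram matching; default FALSE).
#' @return list: `perm_p_set`, `ks_two_sided`, `ks_one_sided`,
#'   `cad_sig`, `draw_sig` (per-draw significant counts), `n_draws`
#'   (plus `draw_maf` when `return_draws`).
#' @export
set_enrichment_test <- function(cad_p, cad_maf, pool_p, pool_maf,
                                n_draws = 100, alpha = 0.05, maf_bin = 0.05,
                                seed = 1, return_draws = FALSE) {
  ok <- !is.na(cad_p)
  cad_p <- cad_p[ok]
  cad_maf <- cad_maf[ok]
  okp <- !is.na(pool_p)
  pool_p <- pool_p[okp]
  pool_maf <- pool_maf[okp]
  M <- length(cad_p)
  if (length(pool_p) < 2 * M)
    stop("pool too small for MAF-matched draws without replacement")
  cb <- floor(cad_maf / maf_bin)
  pb <- floor(pool_maf / maf_bin)
  need <- table(cb)
  set.seed(seed)
  cad_sig <- sum(cad_p < alpha)
  draw_sig <- integer(n_draws)
  pooled <- vector("list", n_draws)
  draw_maf <- if (return_draws) vector("list", n_draws) else NULL
  borrowed <- 0L
  for (d in seq_len(n_draws)) {
    take <- integer(0)
    for (b in names(need)) {
      bi <- as.integer(b)
      avail <- which(pb == bi)
      k <- need[[b]]
      if (length(avail) < k) {
        borrowed <- borrowed + 1L
        w <- 1L
        while (length(avail) < k && w <= 1 / maf_bin) {
          avail <- which(abs(pb - bi) <= w)
          w <- w + 1L
        }
      }
      take <- c(take, sample(avail, min(k, length(avail))))
    }
    ps <- pool_p[take]
    draw_sig[d] <- sum(ps < alpha)
    pooled[[d]] <- ps
    if (return_draws) draw_maf[[d]] <- pool_maf[take]
  }
  if (borrowed)
    message(borrowed, " draw-bin(s) borrowed from neighbouring MAF bins")
  pooled <- unlist(pooled)
  ks2 <- suppressWarnings(ks.test(cad_p, pooled))
  ks1 <- suppressWarnings(ks.test(cad_p, pooled, alternative = "less"))
  out <- list(perm_p_set = (1 + sum(draw_sig >= cad_sig)) / (n_draws + 1),
              ks_two_sided = ks2$p.value, ks_one_sided = ks1$p.value,
              D = unname(ks2$statistic), cad_sig = cad_sig,
              draw_sig = draw_sig, n_draws = n_draws)
  if (return_draws) out$draw_maf <- draw_maf
  out
}

#' Gene-based sum-of-chi-squares association test
#'
#' Combines per-SNP z statistics into T = sum z_i^2, whose null
#' distribution under the gene's LD is the weighted sum
#' sum lambda_i chi^2_1 with lambda the eigenvalues of the SNP
#' correlation matrix. The tail probability is evaluated by numerical
#' inversion of the characteristic function (Imhof's method), which is
#' exact to integration tolerance; equal-weight cases use the closed-form
#' scaled chi-square tail. The two-moment (Satterthwaite) approximation
#' -- T ~ c chi^2_d with c = sum(lambda^2)/sum(lambda) and
#' d = sum(lambda)^2/sum(lambda^2) -- is also reported, and p values
#' below `mc_threshold` are refined by Monte-Carlo sampling of the
#' weighted sum (`mc_n` draws).
#'
#' @param z per-SNP z statistics of one gene.
#' @param R the gene's SNP correlation (LD) matrix, index-aligned with
#'   `z`. Mild negative eigenvalues are floored at zero.
#' @param mc_threshold p value below which Monte-Carlo refinement runs
#'   (default 1e-3).
#' @param mc_n Monte-Carlo sample size (default 1e6).
#' @param seed integer seed for the refinement.
#' @return list: `T`, `lambda`, `p_gene`, `p_satterthwaite`, `method`,
#'   `n_snps`.
#' @export
gene_based_test <- function(z, R, mc_threshold = 1e-3, mc_n = 1e6,
                            seed = 1) {
  ok <- !is.na(z)
  z <- z[ok]
  R <- as.matrix(R)[ok, ok, drop = FALSE]
  stopifnot(length(z) == nrow(R))
  Tstat <- sum(z^2)
  lam <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (any(lam < -1e-6 * max(abs(lam))))
    message("correlation matrix not PSD; eigenvalues floored at zero")
  lam <- pmax(lam, 0)
  s1 <- sum(lam)
  s2 <- sum(lam^2)
  cc <- s2 / s1
  dd <- s1^2 / s2
  p_satt <- pchisq(Tstat / cc, df = dd, lower.tail = FALSE)
  lam_pos <- lam[lam > 1e-12]
  if (max(lam_pos) - min(lam_pos) < 1e-9 * max(lam_pos)) {
    # equal weights: exact scaled chi-square tail
    p <- pchisq(Tstat / max(lam_pos), df = length(lam_pos),
                lower.tail = FALSE)
    method <- "exact_chisq"
  } else {
    p <- tryCatch(imhof_tail(Tstat, lam_pos), error = function(e) NA_real_)
    method <- "imhof"
    if (!is.finite(p) || p < 0 || p > 1) {
      p <- p_satt
      method <- "satterthwaite"
    }
  }
  if (p < mc_threshold && method != "exact_chisq") {
    set.seed(seed)
    exceed <- 0L
    chunk <- 1e5
    done <- 0
    while (done < mc_n) {
      nb <- min(chunk, mc_n - done)
      draws <- colSums(matrix(rchisq(length(lam_pos) * nb, df = 1),
                              nrow = length(lam_pos)) * lam_pos)
      exceed <- exceed + sum(draws >= Tstat)
      done <- done + nb
    }
    p <- (1 + exceed) / (mc_n + 1)
    method <- "monte_carlo"
  }
  list(T = Tstat, lambda = lam, p_gene = p, p_satterthwaite = p_satt,
       method = method, n_snps = length(z))
}

#' Upper-tail probability of a weighted sum of chi-square(1) variables
#'
#' Imhof's numerical inversion of the characteristic function of
#' sum lambda_i chi^2_1: P(T > t) = 1/2 + (1/pi) integral of
#' sin(theta(u)) / (u rho(u)) du, with theta(u) =
#' (1/2) sum atan(lambda_i u) - t u / 2 and rho(u) =
#' prod (1 + lambda_i^2 u^2)^(1/4). Exact to integration tolerance.
#'
#' @param t the observed statistic.
#' @param lambda positive weights.
#' @return upper-tail probability, clamped to [0, 1].
#' @export
imhof_tail <- function(t, lambda) {
  lambda <- lambda[lambda > 1e-12]
  f <- function(u) {
    th <- 0.5 * colSums(atan(outer(lambda, u))) - 0.5 * t * u
    rho <- exp(0.25 * colSums(log1p(outer(lambda^2, u^2))))
    sin(th) / (u * rho)
  }
  val <- integrate(f, 0, Inf, rel.tol = 1e-10, abs.tol = 1e-12,
                   subdivisions = 5000L)$value
  min(max(0.5 + val / pi, 0), 1)
}

#' Permutation p value of one gene against size-matched genes
#'
#' `perm_p_gene = (1 + #matched-gene p <= gene p) / (n + 1)`.
#'
#' @param p_obs the gene's test p value.
#' @param p_null p values of the size-matched random genes.
#' @return permuted p value.
#' @export
gene_perm_p <- function(p_obs, p_null) {
  p_null <- p_null[!is.na(p_null)]
  (1 + sum(p_null <= p_obs)) / (length(p_null) + 1)
}

#' Gene-set enrichment by size-matched resampling
#'
#' Counts, per draw of size-matched non-focal genes, how many gene p
#' values fall below `alpha`, and compares with the focal gene set:
#' `perm_p = (1 + #draws with >= as many significant genes) /
#' (n_draws + 1)`.
#'
#' @param cad_gene_p p values of the focal gene set.
#' @param null_gene_p matrix (draws x genes) of p values for the matched
#'   draws.
#' @param alpha per-gene significance threshold (default 0.05).
#' @return list: `perm_p`, `cad_sig`, `draw_sig`.
#' @export
gene_set_enrichment <- function(cad_gene_p, null_gene_p, alpha = 0.05) {
  cad_sig <- sum(cad_gene_p < alpha, na.rm = TRUE)
  draw_sig <- apply(null_gene_p < alpha, 1, sum, na.rm = TRUE)
  list(perm_p = (1 + sum(draw_sig >= cad_sig)) / (nrow(null_gene_p) + 1),
       cad_sig = cad_sig, draw_sig = draw_sig)
}

#' Bonferroni and Benjamini-Hochberg adjustment
#'
#' @param p vector of p values.
#' @param m number of tests (defaults to `length(p)`; the study design
#'   may fix it externally, e.g. at the full SNP count).
#' @return data.frame with columns `p`, `bonferroni`, `fdr_bh`.
#' @export
multiple_testing <- function(p, m = length(p)) {
  data.frame(p = p,
             bonferroni = p.adjust(p, method = "bonferroni", n = m),
             fdr_bh = p.adjust(p, method = "BH", n = m))
}
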