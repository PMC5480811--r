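#' @noRd
# Profile restricted likelihood of the rotated kernel LMM at one delta.
# yt, Xt are U'y, U'X with K = U diag(D) U'; V = sigma_g2 (K + delta I).
lmm_profile <- function(yt, Xt, D, delta) {
  w <- D + delta
  Xw <- Xt / w
  XtX <- crossprod(Xt, Xw)
  Xty <- crossprod(Xw, yt)
  R <- tryCatch(chol(XtX), error = function(e) NULL)
  if (is.null(R)) return(list(ll = -Inf))
  beta <- backsolve(R, forwardsolve(t(R), Xty))
  rss <- sum(yt^2 / w) - sum(beta * Xty)
  np <- length(yt) - ncol(Xt)
  sg2 <- max(rss / np, 1e-300)
  ll <- -0.5 * (np * log(sg2) + sum(log(w)) + 2 * sum(log(diag(R))) + np)
  list(ll = ll, beta = as.numeric(beta), sigma_g2 = sg2, R = R)
}

#' @noRd
# Grid (21 points on log10 delta in [-5, 5]) + golden-section refinement.
lmm_optimize_delta <- function(yt, Xt, D, grid = 10^seq(-5, 5, length.out = 21)) {
  ll <- vapply(grid, function(d) lmm_profile(yt, Xt, D, d)$ll, numeric(1))
  k <- which.max(ll)
  lo <- log10(grid[max(1, k - 1)])
  hi <- log10(grid[min(length(grid), k + 1)])
  opt <- optimize(function(ld) lmm_profile(yt, Xt, D, 10^ld)$ll,
                  lower = lo, upper = hi, maximum = TRUE, tol = 1e-8)
  if (opt$objective >= ll[k]) 10^opt$maximum else grid[k]
}

#' REML variance components of the kernel mixed model
#'
#' Fits y = W alpha + g + e with g ~ N(0, sigma_g^2 K), e ~ N(0,
#' sigma_e^2 I). K is eigendecomposed once and the restricted likelihood
#' is profiled over delta = sigma_e^2 / sigma_g^2 on a log grid refined by
#' golden section.
#'
#' @param y numeric response (e.g. adjusted LRS).
#' @param W fixed-effect design matrix or data.frame (an intercept is
#'   added).
#' @param grm a [compute_grm()] result aligned with `y`.
#' @return list: `delta`, `sigma_g2`, `sigma_e2`, `h2`
#'   (sigma_g^2 / (sigma_g^2 + sigma_e^2)), `alpha`, `reml`.
#' @export
lmm_reml_fit <- function(y, W, grm) {
  prep <- lmm_prepare(y, W, grm)
  delta <- lmm_optimize_delta(prep$yt, prep$Wt, prep$D)
  f <- lmm_profile(prep$yt, prep$Wt, prep$D, delta)
  sg2 <- f$sigma_g2
  list(delta = delta, sigma_g2 = sg2, sigma_e2 = delta * sg2,
       h2 = 1 / (1 + delta), alpha = f$beta, reml = f$ll)
}

#' @noRd
lmm_prepare <- function(y, W, grm) {
  n <- length(y)
  if (n != length(grm$sample_ids))
    stop("phenotype and kernel sample counts differ")
  W <- if (is.null(W)) matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
       else cbind("(Intercept)" = 1, as.matrix(W))
  qrW <- qr(W)
  if (qrW$rank < ncol(W)) {
    bad <- colnames(W)[qrW$pivot[(qrW$rank + 1):ncol(W)]]
    stop("singular covariates: ", paste(bad, collapse = ", "))
  }
  eg <- eigen(grm$kernel, symmetric = TRUE)
  tol <- 1e-6 * max(abs(eg$values))
  if (any(eg$values < -tol))
    stop("relationship kernel is not positive semi-definite")
  D <- pmax(eg$values, 0)
  U <- eg$vectors
  list(yt = as.numeric(crossprod(U, y)), Wt = crossprod(U, W),
       D = D, U = U, W = W)
}

#' Per-SNP association with a relatedness-corrected mixed model
#'
#' For each test SNP fits y = W alpha + x beta + g + e with g ~ N(0,
#' sigma_g^2 K): the kernel is eigendecomposed once, delta is profiled
#' per SNP (grid + golden section, REML), alpha and beta come from
#' generalized least squares at the optimum, and the SNP p value is a
#' two-sided Wald test on beta.
#'
#' @param y numeric response (adjusted LRS), one per sample.
#' @param covariates data.frame/matrix of fixed covariates (may be NULL).
#' @param grm a [compute_grm()] result aligned with `y`.
#' @param dosages samples x SNPs dosage matrix of the SNPs to test.
#' @param maf optional per-SNP MAF (computed from dosages if missing).
#' @return data.frame: `snp_id`, `beta`, `se`, `nominal_p`, `sigma_g2`,
#'   `sigma_e2`, `delta`, `h2`, `maf`. Constant-dosage SNPs come back NA.
#' @export
lmm_assoc <- function(y, covariates, grm, dosages, maf = NULL) {
  prep <- lmm_prepare(y, covariates, grm)
  dosages <- as.matrix(dosages)
  if (nrow(dosages) != length(y))
    stop("dosage rows must align with phenotype samples")
  Xt_all <- crossprod(prep$U, dosages)
  S <- ncol(dosages)
  if (is.null(maf)) {
    p <- colMeans(dosages) / 2
    maf <- pmin(p, 1 - p)
  }
  out <- data.frame(snp_id = colnames(dosages) %||% paste0("snp", seq_len(S)),
                    beta = NA_real_, se = NA_real_, nominal_p = NA_real_,
                    sigma_g2 = NA_real_, sigma_e2 = NA_real_,
                    delta = NA_real_, h2 = NA_real_, maf = maf,
                    stringsAsFactors = FALSE)
  pcol <- ncol(prep$Wt) + 1L
  for (j in seq_len(S)) {
    if (sd(dosages[, j]) == 0) next
    Xt <- cbind(prep$Wt, Xt_all[, j])
    delta <- lmm_optimize_delta(prep$yt, Xt, prep$D)
    f <- lmm_profile(prep$yt, Xt, prep$D, delta)
    cov_b <- chol2inv(f$R) * f$sigma_g2
    b <- f$beta[pcol]
    se <- sqrt(cov_b[pcol, pcol])
    out$beta[j] <- b
    out$se[j] <- se
    out$nominal_p[j] <- 2 * pnorm(-abs(b / se))
    out$sigma_g2[j] <- f$sigma_g2
    out$sigma_e2[j] <- delta * f$sigma_g2
    out$delta[j] <- delta
    out$h2[j] <- 1 / (1 + delta)
  }
  out
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
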