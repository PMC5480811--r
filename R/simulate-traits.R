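#' Planted-effect specification for simulated traits
#'
#' Houses the simulation truth that downstream analyses are expected to
#' recover: per-SNP GWAS effects and their optional coupling to sweep
#' positions, cis-eQTL effects with a sex covariate, and the lifetime
#' reproductive success (LRS) model with covariate effects, per-SNP
#' effects, a relatedness-structured polygenic background and a secular
#' birth-year trend.
#'
#' @param gwas_causal data.frame with columns `snp_id`, `beta` (true
#'   ln(OR)); may be empty.
#' @param gwas_noise_sd SD of the noise added to the true ln(OR).
#' @param coupling coefficient linking |true ln(OR)| to sweep proximity
#'   through an exponential-decay kernel (0 = no coupling).
#' @param coupling_decay_bp length scale of the decay kernel.
#' @param n_cases,n_controls nominal case/control sizes used to set the
#'   summary-statistic standard errors.
#' @param eqtl data.frame with columns `snp_id`, `probe_id`, `gene`,
#'   `beta`, `sex_beta`, `noise_sd`; may be empty.
#' @param null_probes data.frame with columns `probe_id`, `gene`,
#'   `noise_sd` for probes with no genetic effect; may be empty.
#' @param lrs list with elements `mean` (baseline LRS), `covariate_betas`
#'   (named: education, smoking, born_in_country, estrogen_use),
#'   `snp_effects` (data.frame `snp_id`, `beta`), `h2` in [0, 1),
#'   `residual_sd` (> 0), `birth_year_range`, `secular_trend` (latent
#'   change per birth year) and `link` ("gaussian" or "poisson").
#' @return an `effect_spec` list.
#' @export
effect_spec <- function(gwas_causal = NULL, gwas_noise_sd = 0.02,
                        coupling = 0, coupling_decay_bp = 1e5,
                        n_cases = 60000, n_controls = 120000,
                        eqtl = NULL, null_probes = NULL,
                        lrs = list()) {
  lrs <- modifyList(list(
    mean = 2.5,
    covariate_betas = c(education = -0.15, smoking = -0.1,
                        born_in_country = 0.05, estrogen_use = -0.1),
    snp_effects = NULL, h2 = 0, residual_sd = 1,
    birth_year_range = c(1900, 1960), secular_trend = -0.015,
    link = "gaussian"), lrs)
  if (lrs$h2 < 0 || lrs$h2 >= 1) stop("lrs h2 must lie in [0, 1)")
  if (lrs$residual_sd <= 0) stop("lrs residual_sd must be positive")
  structure(list(gwas_causal = gwas_causal, gwas_noise_sd = gwas_noise_sd,
                 coupling = coupling, coupling_decay_bp = coupling_decay_bp,
                 n_cases = n_cases, n_controls = n_controls, eqtl = eqtl,
                 null_probes = null_probes, lrs = lrs),
            class = "effect_spec")
}

check_spec_snps <- function(spec_snps, panel) {
  miss <- setdiff(spec_snps, panel$snp_ids)
  if (length(miss))
    stop("effect_spec references SNP(s) absent from the panel: ",
         paste(head(miss, 3), collapse = ", "))
}

#' Simulate GWAS summary statistics for a panel
#'
#' Observed ln(OR) = true ln(OR) + Normal(0, `gwas_noise_sd`). The true
#' value is the planted causal effect (0 elsewhere), plus -- when
#' `coupling` > 0 -- `coupling * exp(-distance / coupling_decay_bp)` for
#' the distance to the nearest sweep position, which makes |ln(OR)|
#' increase near sweeps. Standard errors follow the usual additive-model
#' case-control approximation and p values are two-sided Wald.
#'
#' @param panel a [haplotype_panel()].
#' @param spec an [effect_spec()].
#' @param sweep_positions bp positions of sweeps (defaults to the panel's
#'   `sweep` attribute, if any).
#' @param seed integer seed.
#' @return a GWAS summary data.frame (see [read_gwas_summary()]); the true
#'   effects are attached as attribute `truth`.
#' @export
simulate_gwas_summary <- function(panel, spec, sweep_positions = NULL,
                                  seed = 1) {
  stopifnot(inherits(spec, "effect_spec"))
  set.seed(seed)
  if (is.null(sweep_positions)) {
    sw <- attr(panel, "sweep")
    sweep_positions <- if (is.null(sw)) numeric(0) else sw$position_bp
  }
  S <- n_snps(panel)
  true_lnor <- numeric(S)
  if (!is.null(spec$gwas_causal) && nrow(spec$gwas_causal)) {
    check_spec_snps(spec$gwas_causal$snp_id, panel)
    idx <- match(spec$gwas_causal$snp_id, panel$snp_ids)
    true_lnor[idx] <- spec$gwas_causal$beta
  }
  if (spec$coupling > 0 && length(sweep_positions)) {
    d <- vapply(panel$positions_bp,
                function(x) min(abs(x - sweep_positions)), numeric(1))
    true_lnor <- true_lnor + spec$coupling * exp(-d / spec$coupling_decay_bp)
  }
  p <- derived_freq(panel)
  pq <- pmax(p * (1 - p), 1e-4)
  se <- sqrt((1 / spec$n_cases + 1 / spec$n_controls) / (2 * pq))
  ln_or <- true_lnor + rnorm(S, 0, spec$gwas_noise_sd)
  z <- ln_or / se
  pval <- pmax(2 * pnorm(-abs(z)), .Machine$double.xmin)
  out <- data.frame(snp_id = panel$snp_ids, chrom = panel$chrom,
                    pos_bp = panel$positions_bp,
                    effect_allele = panel$alleles$derived,
                    other_allele = panel$alleles$ancestral,
                    ln_or = ln_or, se = se, p = pval,
                    stringsAsFactors = FALSE)
  attr(out, "truth") <- data.frame(snp_id = panel$snp_ids,
                                   true_ln_or = true_lnor)
  out
}

#' Simulate a cis-eQTL expression matrix
#'
#' Probe value = sum of planted genotype-dosage effects + sex effect +
#' Gaussian noise, on the log2 scale the analysis assumes.
#'
#' @param panel a [haplotype_panel()].
#' @param spec an [effect_spec()] with `eqtl` (and optionally
#'   `null_probes`) filled in; every probe must carry a gene link.
#' @param seed integer seed.
#' @param sex optional 0/1 vector per sample; generated under `seed` if
#'   missing.
#' @return an `expression_matrix` (see [read_expression()]) with
#'   attributes `sex` and `truth`.
#' @export
simulate_expression <- function(panel, spec, seed = 1, sex = NULL) {
  stopifnot(inherits(spec, "effect_spec"))
  set.seed(seed)
  n <- n_samples(panel)
  if (is.null(sex)) sex <- rbinom(n, 1, 0.5)
  eq <- spec$eqtl
  np <- spec$null_probes
  probes <- rbind(
    if (!is.null(eq) && nrow(eq))
      data.frame(probe_id = eq$probe_id, gene = eq$gene,
                 noise_sd = eq$noise_sd, stringsAsFactors = FALSE),
    if (!is.null(np) && nrow(np))
      data.frame(probe_id = np$probe_id, gene = np$gene,
                 noise_sd = np$noise_sd, stringsAsFactors = FALSE))
  if (is.null(probes) || !nrow(probes)) stop("effect_spec plants no probes")
  if (any(is.na(probes$gene) | probes$gene == ""))
    stop("probe without gene link: ",
         probes$probe_id[is.na(probes$gene) | probes$gene == ""][1])
  probes <- probes[!duplicated(probes$probe_id), ]
  dos <- dosage_matrix(panel)
  vals <- matrix(0, nrow = nrow(probes), ncol = n,
                 dimnames = list(probes$probe_id, panel$sample_ids))
  if (!is.null(eq) && nrow(eq)) {
    check_spec_snps(eq$snp_id, panel)
    for (k in seq_len(nrow(eq))) {
      vals[eq$probe_id[k], ] <- vals[eq$probe_id[k], ] +
        eq$beta[k] * dos[, eq$snp_id[k]] + eq$sex_beta[k] * sex
    }
  }
  vals <- vals + matrix(rnorm(nrow(probes) * n, 0, rep(probes$noise_sd, n)),
                        nrow = nrow(probes))
  out <- structure(list(probe_ids = probes$probe_id,
                        gene_links = setNames(probes$gene, probes$probe_id),
                        values = vals, sample_ids = panel$sample_ids),
                   class = "expression_matrix")
  attr(out, "sex") <- sex
  attr(out, "truth") <- eq
  out
}

#' Simulate a lifetime-reproductive-success phenotype table
#'
#' The latent trait is baseline + covariate effects + planted SNP effects
#' + a polygenic term g ~ N(0, sigma_g^2 K) with K from [compute_grm()]
#' (the same kernel the analysis uses) + Gaussian residual, with a linear
#' secular trend in birth year so that [adjust_lrs()] is non-trivial.
#' `lrs_raw` is the latent value rounded and floored at zero (default
#' "gaussian" link, matching the linear analysis model) or a Poisson draw
#' on the exp scale ("poisson").
#'
#' The polygenic variance is set from `h2` and `residual_sd` via
#' sigma_g^2 = h2 / (1 - h2) * residual_sd^2, so h2 is the narrow-sense
#' heritability of the latent trait net of fixed effects.
#'
#' @param panel a [haplotype_panel()].
#' @param spec an [effect_spec()]; see its `lrs` element.
#' @param seed integer seed.
#' @param sex optional 0/1 vector per sample (1 = female); generated under
#'   `seed` if missing.
#' @param grm optional [compute_grm()] result to reuse; computed from the
#'   panel (no exclusions) if missing.
#' @return a phenotype data.frame (see [read_phenotypes()]) with attribute
#'   `truth` holding the planted parameters.
#' @export
simulate_fitness <- function(panel, spec, seed = 1, sex = NULL, grm = NULL) {
  stopifnot(inherits(spec, "effect_spec"))
  lp <- spec$lrs
  set.seed(seed)
  n <- n_samples(panel)
  if (is.null(sex)) sex <- rbinom(n, 1, 0.5)
  covs <- data.frame(
    education = sample(0:2, n, replace = TRUE),
    smoking = rbinom(n, 1, 0.3),
    born_in_country = rbinom(n, 1, 0.85),
    estrogen_use = rbinom(n, 1, 0.4))
  birth_year <- sample(seq(lp$birth_year_range[1], lp$birth_year_range[2]),
                       n, replace = TRUE)
  latent <- lp$mean +
    as.matrix(covs) %*% lp$covariate_betas[colnames(covs)] +
    lp$secular_trend * (birth_year - mean(lp$birth_year_range))
  latent <- as.numeric(latent)
  if (!is.null(lp$snp_effects) && nrow(lp$snp_effects)) {
    check_spec_snps(lp$snp_effects$snp_id, panel)
    dos <- dosage_matrix(panel)[, lp$snp_effects$snp_id, drop = FALSE]
    latent <- latent + as.numeric(dos %*% lp$snp_effects$beta)
  }
  g <- numeric(n)
  if (lp$h2 > 0) {
    if (is.null(grm)) grm <- compute_grm(panel, prune_r2 = 0.5, min_snps = 10)
    sigma_g2 <- lp$h2 / (1 - lp$h2) * lp$residual_sd^2
    eg <- eigen(grm$kernel, symmetric = TRUE)
    lam <- pmax(eg$values, 0)
    g <- as.numeric(eg$vectors %*% (sqrt(sigma_g2 * lam) * rnorm(n)))
  }
  latent <- latent + g + rnorm(n, 0, lp$residual_sd)
  lrs_raw <- switch(lp$link,
    gaussian = pmax(0, round(latent)),
    poisson = rpois(n, exp(pmax(pmin(latent / lp$mean, 30), -30))),
    stop("unknown lrs link: ", lp$link))
  out <- data.frame(sample_id = panel$sample_ids, sex = sex,
                    birth_year = birth_year, lrs_raw = as.integer(lrs_raw),
                    covs, stringsAsFactors = FALSE)
  attr(out, "truth") <- list(latent = latent, g = g, lrs = lp)
  out
}

#' Write a complete fixture bundle to a directory
#'
#' Generates a panel (with any sweeps in the spec), GWAS summary
#' statistics, gene annotations, an expression matrix and a phenotype
#' table, writes them in their on-disk formats, and records every planted
#' parameter in `truth.json`.
#'
#' @param out_dir output directory (created if absent).
#' @param spec a [sim_spec()].
#' @param effects an [effect_spec()].
#' @param genes data.frame of gene intervals (gene, chrom, start, end);
#'   a default 4-gene tiling of the chromosome is used if missing.
#' @param seed integer seed.
#' @return invisibly, a list of the objects generated.
#' @export
write_fixture_bundle <- function(out_dir, spec = sim_spec(),
                                 effects = effect_spec(), genes = NULL,
                                 seed = 1) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  panel <- simulate_neutral_panel(spec)
  for (sw in spec$sweep)
    panel <- inject_sweep(panel, sw$position, sw$s, sw$stop_frequency,
                          seed = seed + 17)
  if (is.null(genes)) {
    br <- round(seq(min(panel$positions_bp), max(panel$positions_bp),
                    length.out = 9))
    genes <- data.frame(gene = paste0("GENE", 1:4), chrom = panel$chrom,
                        start = br[c(1, 3, 5, 7)] + 1L,
                        end = br[c(2, 4, 6, 8)], stringsAsFactors = FALSE)
  }
  set.seed(seed)
  sex <- rbinom(n_samples(panel), 1, 0.5)
  gwas <- simulate_gwas_summary(panel, effects, seed = seed + 1)
  expr <- if (!is.null(effects$eqtl) || !is.null(effects$null_probes))
    simulate_expression(panel, effects, seed = seed + 2, sex = sex)
  pheno <- simulate_fitness(panel, effects, seed = seed + 3, sex = sex)

  write_phased_vcf(panel, file.path(out_dir, "panel.vcf"))
  write_gene_bed(genes, file.path(out_dir, "genes.bed"))
  data.table::fwrite(gwas, file.path(out_dir, "gwas.tsv"), sep = "\t")
  if (!is.null(expr)) write_expression(expr, file.path(out_dir, "expr.tsv"))
  data.table::fwrite(pheno, file.path(out_dir, "pheno.tsv"), sep = "\t")
  jsonlite::write_json(
    list(seed = seed, sim = unclass(spec),
         effects = lapply(unclass(effects), function(x)
           if (is.data.frame(x)) x else x)),
    file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
  invisible(list(panel = panel, genes = genes, gwas = gwas, expr = expr,
                 pheno = pheno, sex = sex))
}
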