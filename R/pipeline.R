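#' Run the full analysis pipeline on synthetic data
#'
#' Orchestrates the stages end-to-end at desk scale: simulate (panel with
#' a sweep, GWAS summary coupled to it, expression with a planted
#' cis-eQTL, LRS phenotypes with planted risk-concordant SNP effects) ->
#' iHS scan -> per-gene selection-risk association -> eQTL comparison ->
#' fitness enrichment -> antagonism calls -> report. Every stage writes
#' its tables under `out_dir` and is recorded in a JSON manifest with
#' input/output MD5 hashes and its derived seed (base seed * 100 + stage
#' index, so stages are independently reproducible). Re-running with the
#' same config reproduces byte-identical result tables.
#'
#' @param config a config list (see [default_config()] /
#'   [read_run_config()]).
#' @param out_dir output directory.
#' @return the manifest list, invisibly (also written as
#'   `manifest.json`).
#' @export
run_pipeline <- function(config = default_config(), out_dir) {
  config <- validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  seed_of <- function(stage_i) config$seed * 100L + stage_i
  manifest <- list(config = config,
                   version = as.character(utils::packageVersion("selpleio")),
                   started = format(Sys.time()), stages = list())
  note <- function(stage, files, seed) {
    manifest$stages[[stage]] <<- list(
      seed = seed, files = as.list(tools::md5sum(files)))
    run_log(log_path, "stage ", stage, " done (seed ", seed, ")")
  }

  ## stage 1: simulate --------------------------------------------------
  seed1 <- seed_of(1L)
  sim <- config$sim
  spec0 <- sim_spec(n_samples = sim$n_samples, n_snps = sim$n_snps,
                    chrom_length_bp = sim$chrom_length_bp,
                    recomb_rate_cM_per_Mb = sim$recomb_rate_cM_per_Mb,
                    wf_population_size = sim$wf_population_size,
                    wf_generations = sim$wf_generations, seed = seed1)
  L <- sim$chrom_length_bp
  width <- round(L / (4 * config$n_genes))
  starts <- round(L * (seq_len(config$n_genes) - 0.5) / config$n_genes)
  genes <- data.frame(gene = paste0("GENE", seq_len(config$n_genes)),
                      chrom = "chr1", start = starts, end = starts + width,
                      stringsAsFactors = FALSE)
  target_gene <- ceiling(config$n_genes / 2)
  sweep_target <- round((genes$start[target_gene] +
                           genes$end[target_gene]) / 2)
  set.seed(seed1)
  shared_pos <- sort(sample.int(sim$chrom_length_bp, sim$n_snps))
  panels <- list()
  for (i in seq_along(config$populations)) {
    pop <- config$populations[i]
    sp <- spec0
    sp$positions_bp <- shared_pos
    sp$seed <- seed1 + i
    panel <- simulate_neutral_panel(sp, population = pop)
    panel <- inject_sweep(panel, sweep_target, sim$sweep_s,
                          sim$sweep_stop, seed = seed1 + 50L + i)
    panels[[pop]] <- panel
  }
  ref <- panels[[1]]
  sweep_pos <- attr(ref, "sweep")$position_bp
  near <- order(abs(ref$positions_bp - sweep_pos))[1:3]
  set.seed(seed1)
  sex <- rbinom(n_samples(ref), 1, 0.5)
  eff <- effect_spec(
    coupling = 0.05, gwas_noise_sd = 0.02,
    eqtl = data.frame(snp_id = ref$snp_ids[near[1]], probe_id = "probe_sweep",
                      gene = genes$gene[target_gene],
                      beta = 1, sex_beta = 0.3, noise_sd = 0.5,
                      stringsAsFactors = FALSE),
    null_probes = data.frame(probe_id = paste0("probe_null", 1:4),
                             gene = genes$gene, noise_sd = 0.5,
                             stringsAsFactors = FALSE),
    lrs = list(snp_effects = data.frame(snp_id = ref$snp_ids[near],
                                        beta = c(0.25, 0.2, 0.15)),
               h2 = 0.2))
  gwas <- simulate_gwas_summary(ref, eff, seed = seed1 + 70L)
  expr <- simulate_expression(ref, eff, seed = seed1 + 71L, sex = sex)
  pheno <- simulate_fitness(ref, eff, seed = seed1 + 72L, sex = sex)
  for (pop in names(panels))
    write_phased_vcf(panels[[pop]],
                     file.path(out_dir, paste0("panel_", pop, ".vcf")))
  write_gene_bed(genes, file.path(out_dir, "genes.bed"))
  write_results(list(gwas = gwas, pheno = pheno), out_dir)
  write_expression(expr, file.path(out_dir, "expr.tsv"))
  note("simulate", file.path(out_dir, c("genes.bed", "gwas.tsv", "pheno.tsv",
                                        "expr.tsv")), seed1)

  ## stage 2: scan -------------------------------------------------------
  seed2 <- seed_of(2L)
  sc <- config$scan
  scores <- list()
  loci <- list()
  signals <- list()
  for (pop in names(panels)) {
    p <- apply_qc_filters(panels[[pop]], config$qc$call_rate_min,
                          config$qc$hwe_p_min, config$qc$maf_min)
    panels[[pop]] <- p
    s <- ihs_scan(p, cutoff = sc$cutoff, max_gap_bp = sc$max_gap_bp,
                  maf_min = sc$maf_min)
    s <- suppressWarnings(standardize_ihs(s, bin_width = sc$daf_bin_width))
    s <- suppressWarnings(permute_ihs_p(s, n_perm = sc$n_perm,
                                        seed = seed2))
    scores[[pop]] <- s
    loci[[pop]] <- lapply(seq_len(nrow(genes)), function(k)
      extract_locus_snps(p, genes[k, ], flank_bp = config$locus$flank_bp,
                         r2_link = config$locus$r2_link))
    signals[[pop]] <- call_candidate_signals(
      s, loci[[pop]], ihs_min = sc$ihs_min, p_max = sc$p_max,
      cluster_k = sc$cluster_k, cluster_window_bp = sc$cluster_window_bp,
      population = pop)
    data.table::fwrite(s, file.path(out_dir, paste0("scores_", pop, ".tsv")),
                       sep = "\t")
  }
  sig_all <- do.call(rbind, signals)
  data.table::fwrite(sig_all, file.path(out_dir, "signals.tsv"), sep = "\t")
  note("scan", file.path(out_dir, c(paste0("scores_", names(panels), ".tsv"),
                                    "signals.tsv")), seed2)

  ## stage 3: associate --------------------------------------------------
  seed3 <- seed_of(3L)
  null_ann <- random_gene_annotation(ref, n = 4 * config$locus$n_null_genes,
                                     lengths = genes$end - genes$start + 1,
                                     seed = seed3)
  assoc <- list()
  for (pop in names(panels)) {
    p <- panels[[pop]]
    s <- scores[[pop]]
    for (k in seq_len(nrow(genes))) {
      locus <- loci[[pop]][[k]]
      idx <- locus$poly_idx
      ids <- p$snp_ids[idx]
      lnor <- gwas$ln_or[match(ids, gwas$snp_id)]
      ihs <- s$ihs_std[match(ids, s$snp_id)]
      pa <- permute_association(lnor, ihs, locus$first_eigvec,
                                n_perm = config$assoc$n_perm,
                                seed = seed3 + k)
      nulls <- match_random_genes(locus, null_ann,
                                  n = config$locus$n_null_genes,
                                  length_tol = config$locus$length_tol,
                                  seed = seed3 + 31L * k,
                                  exclude_genes = genes$gene)
      null_p <- vapply(seq_len(nrow(nulls)), function(q) {
        nl <- tryCatch(extract_locus_snps(p, nulls[q, ],
                                          flank_bp = config$locus$flank_bp,
                                          r2_link = config$locus$r2_link),
                       error = function(e) NULL)
        if (is.null(nl) || length(nl$poly_idx) < 3) return(NA_real_)
        nid <- p$snp_ids[nl$poly_idx]
        fit <- fit_selection_risk_model(
          gwas$ln_or[match(nid, gwas$snp_id)],
          s$ihs_std[match(nid, s$snp_id)], nl$first_eigvec)
        fit$nominal_p
      }, numeric(1))
      assoc[[length(assoc) + 1L]] <- data.frame(
        gene = genes$gene[k], population = pop, n_snps = pa$observed$n_snps,
        beta_scaled = pa$observed$beta_scaled,
        nominal_p = pa$observed$nominal_p,
        perm_p_shuffle = pa$perm_p_shuffle,
        perm_p_genes = gene_matched_null(pa$observed$nominal_p, null_p),
        stringsAsFactors = FALSE)
    }
  }
  assoc <- do.call(rbind, assoc)
  assoc$significant <- !is.na(assoc$perm_p_shuffle) &
    assoc$perm_p_shuffle < config$assoc$alpha
  ranking <- rank_genes(assoc, alpha = config$assoc$alpha,
                        min_count = config$assoc$min_count)
  write_results(list(assoc = assoc, gene_ranking = ranking), out_dir)
  note("associate", file.path(out_dir, c("assoc.tsv", "gene_ranking.tsv")),
       seed3)

  ## stage 4: eqtl -------------------------------------------------------
  seed4 <- seed_of(4L)
  pop1 <- names(panels)[1]
  p1 <- panels[[pop1]]
  dos <- dosage_matrix(p1)
  s1 <- scores[[pop1]]
  eq_rows <- list()
  for (pr in expr$probe_ids) {
    gene_of <- unname(expr$gene_links[pr])
    k <- match(gene_of, genes$gene)
    if (is.na(k)) next
    for (sid in intersect(p1$snp_ids[loci[[pop1]][[k]]$poly_idx],
                          colnames(dos))) {
      pe <- permute_eqtl(dos[, sid], sex, expr$values[pr, ],
                         n_perm = config$eqtl$n_perm, seed = seed4)
      eq_rows[[length(eq_rows) + 1L]] <- data.frame(
        snp_id = sid, probe_id = pr, beta = pe$observed$beta,
        nominal_p = pe$observed$nominal_p, permuted_p = pe$permuted_p,
        stringsAsFactors = FALSE)
    }
  }
  eqtl_tab <- do.call(rbind, eq_rows)
  write_results(list(eqtl = eqtl_tab), out_dir)
  note("eqtl", file.path(out_dir, "eqtl.tsv"), seed4)

  ## stage 5: fitness ----------------------------------------------------
  seed5 <- seed_of(5L)
  fem <- pheno$sex == 1
  ph <- adjust_lrs(pheno[fem, ], n_groups = config$fitness$n_groups)
  fp <- subset_samples_panel(p1, fem)
  grm <- compute_grm(fp, prune_r2 = config$fitness$prune_r2,
                     exclude_intervals = genes,
                     exclude_window_bp = min(config$fitness$exclude_window_bp,
                                             sim$chrom_length_bp / 20),
                     r2_excl = config$fitness$r2_excl, min_snps = 20)
  dosf <- dosage_matrix(fp)
  poly <- apply(dosf, 2, sd) > 0
  W <- ph[, c("education", "smoking", "born_in_country", "estrogen_use")]
  fits <- lmm_assoc(ph$lrs_adjusted, W, grm, dosf[, poly, drop = FALSE])
  cad_ids <- unique(unlist(lapply(loci[[pop1]], function(l) l$snp_ids)))
  in_cad <- fits$snp_id %in% cad_ids
  fits$permuted_p <- NA_real_
  fits$permuted_p[in_cad] <- permute_snp_p(
    fits$nominal_p[in_cad], fits$maf[in_cad], fits$nominal_p, fits$maf,
    n_perm = config$fitness$n_perm, maf_bin = config$fitness$maf_bin,
    seed = seed5, min_bin = 50)
  adj <- multiple_testing(fits$nominal_p[in_cad])
  fits$bonferroni <- fits$fdr_bh <- NA_real_
  fits$bonferroni[in_cad] <- adj$bonferroni
  fits$fdr_bh[in_cad] <- adj$fdr_bh
  enr <- suppressMessages(set_enrichment_test(
    fits$nominal_p[in_cad], fits$maf[in_cad], fits$nominal_p[!in_cad],
    fits$maf[!in_cad], n_draws = config$fitness$n_set_draws,
    alpha = config$fitness$alpha, maf_bin = config$fitness$maf_bin,
    seed = seed5))
  gene_tests <- lapply(seq_len(nrow(genes)), function(k) {
    l <- loci[[pop1]][[k]]
    ids <- intersect(fp$snp_ids[l$poly_idx], fits$snp_id)
    if (length(ids) < 1) return(NULL)
    z <- with(fits[match(ids, fits$snp_id), ], beta / se)
    gt <- gene_based_test(z, ld_matrix(fp, ids, stat = "r"),
                          seed = seed5 + k)
    data.frame(gene = genes$gene[k], T = gt$T, p_gene = gt$p_gene,
               n_snps = gt$n_snps, stringsAsFactors = FALSE)
  })
  gene_tests <- do.call(rbind, gene_tests)
  write_results(list(snp_assoc = fits, gene_tests = gene_tests), out_dir)
  jsonlite::write_json(
    list(perm_p_set = enr$perm_p_set, ks_two_sided = enr$ks_two_sided,
         ks_one_sided = enr$ks_one_sided, cad_sig = enr$cad_sig,
         seed = seed5),
    file.path(out_dir, "enrichment.json"), auto_unbox = TRUE, digits = NA)
  note("fitness", file.path(out_dir, c("snp_assoc.tsv", "gene_tests.tsv",
                                       "enrichment.json")), seed5)

  ## stage 6: antagonism -------------------------------------------------
  seed6 <- seed_of(6L)
  index_snps <- vapply(loci[[pop1]], function(l) {
    gp <- gwas[match(l$snp_ids, gwas$snp_id), ]
    gp$snp_id[which.min(gp$p)]
  }, character(1))
  fit_al <- data.frame(
    snp_id = fits$snp_id,
    effect_allele = fp$alleles$derived[match(fits$snp_id, fp$snp_ids)],
    other_allele = fp$alleles$ancestral[match(fits$snp_id, fp$snp_ids)],
    beta = fits$beta, nominal_p = fits$nominal_p, stringsAsFactors = FALSE)
  calls <- antagonism_calls(gwas, fit_al, index_snps,
                            alpha = config$antagonism$alpha)
  write_results(list(antagonism = calls), out_dir)
  note("antagonism", file.path(out_dir, "antagonism.tsv"), seed6)

  ## stage 7: report -----------------------------------------------------
  seed7 <- seed_of(7L)
  apex <- do.call(rbind, lapply(names(panels), function(pop) {
    s <- scores[[pop]]
    do.call(rbind, lapply(seq_len(nrow(genes)), function(k) {
      ids <- loci[[pop]][[k]]$snp_ids
      sk <- s[match(ids, s$snp_id), ]
      sk <- sk[!is.na(sk$ihs_std), ]
      if (!nrow(sk)) return(data.frame(
        gene = genes$gene[k], population = pop, apex_ihs = NA_real_,
        apex_perm_p = NA_real_))
      a <- which.max(abs(sk$ihs_std))
      data.frame(gene = genes$gene[k], population = pop,
                 apex_ihs = sk$ihs_std[a], apex_perm_p = sk$permuted_p[a])
    }))
  }))
  panelA <- reshape_matrix(apex, "apex_ihs")
  panelB <- reshape_matrix(assoc, "beta_scaled")
  panelC <- reshape_matrix(assoc, "perm_p_genes")
  write_results(list(report_apex = apex, report_panelA = panelA,
                     report_panelB = panelB, report_panelC = panelC),
                out_dir)
  note("report", file.path(out_dir, paste0(
    c("report_apex", "report_panelA", "report_panelB", "report_panelC"),
    ".tsv")), seed7)

  manifest$finished <- format(Sys.time())
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(manifest)
}

#' @noRd
reshape_matrix <- function(df, value_col) {
  pops <- unique(df$population)
  genes <- unique(df$gene)
  m <- matrix(NA_real_, length(genes), length(pops),
              dimnames = list(genes, pops))
  for (r in seq_len(nrow(df)))
    m[df$gene[r], df$population[r]] <- df[[value_col]][r]
  data.frame(gene = rownames(m), m, check.names = FALSE)
}

#' Random gene annotation over a panel's chromosome
#'
#' Draws interval start points uniformly over the panel span with lengths
#' resampled (with noise) from the target lengths; used to build the
#' length-matched null gene universe on synthetic chromosomes.
#'
#' @param panel a [haplotype_panel()].
#' @param n number of random genes.
#' @param lengths target lengths resampled from.
#' @param seed integer seed.
#' @return data.frame: `gene`, `chrom`, `start`, `end`.
#' @export
random_gene_annotation <- function(panel, n, lengths, seed = 1) {
  set.seed(seed)
  span <- range(panel$positions_bp)
  len <- round(sample(lengths, n, replace = TRUE) *
                 runif(n, 0.85, 1.15))
  start <- floor(runif(n, span[1], pmax(span[1] + 1, span[2] - len)))
  data.frame(gene = sprintf("NULL%04d", seq_len(n)), chrom = panel$chrom,
             start = as.integer(start), end = as.integer(start + len - 1),
             stringsAsFactors = FALSE)
}

#' Restrict a panel to a subset of samples
#' @param panel a [haplotype_panel()].
#' @param keep logical or integer index over samples.
#' @return the restricted panel (monomorphic sites retained).
#' @export
subset_samples_panel <- function(panel, keep) {
  if (is.logical(keep)) keep <- which(keep)
  keep <- as.integer(keep)
  rows <- as.vector(rbind(2L * keep - 1L, 2L * keep))
  haplotype_panel(
    snp_ids = panel$snp_ids, chrom = panel$chrom,
    positions_bp = panel$positions_bp,
    genetic_pos_cM = panel$genetic_pos_cM, alleles = panel$alleles,
    hap_matrix = panel$hap_matrix[rows, , drop = FALSE],
    sample_ids = panel$sample_ids[keep], population = panel$population,
    founder_flags = panel$founder_flags[keep]
  )
}
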