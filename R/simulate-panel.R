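#' Simulation specification for a haplotype panel
#'
#' Bundles the parameters of the forward Wright-Fisher simulation. The
#' defaults describe the desk-scale study condition used throughout the
#' package's validation: a 10 Mb chromosome carrying a 30 cM map (the
#' genetic map is compressed relative to the human genome-wide average so
#' that, at simulable population sizes, haplotype homozygosity decays
#' within the chromosome as it does within real chromosomes at large
#' effective population size), N = 400 diploids evolved for 200
#' generations, 100 sampled diploids.
#'
#' @param n_samples diploid samples drawn from the final population.
#' @param n_snps number of segregating sites initialised in the founders.
#' @param chrom_length_bp chromosome length in base pairs.
#' @param recomb_rate_cM_per_Mb uniform recombination rate; the genetic map
#'   is linear in physical position.
#' @param wf_population_size diploid population size N.
#' @param wf_generations generations of neutral random mating.
#' @param sweep optional list of lists with elements `position`, `s`,
#'   `stop_frequency` passed to [inject_sweep()] by the pipeline.
#' @param init_daf optional initial derived-allele frequencies (recycled);
#'   by default initial derived counts follow the neutral site-frequency
#'   spectrum, P(count = i) proportional to 1/i.
#' @param positions_bp optional fixed site map (strictly increasing bp
#'   positions); lets several populations share one SNP namespace. When
#'   given it overrides `n_snps`.
#' @param seed integer seed; every generator is a pure function of
#'   (spec, seed).
#' @return a `sim_spec` list.
#' @export
sim_spec <- function(n_samples = 100, n_snps = 2000, chrom_length_bp = 1e7,
                     recomb_rate_cM_per_Mb = 3, wf_population_size = 400,
                     wf_generations = 200, sweep = list(), init_daf = NULL,
                     positions_bp = NULL, seed = 1) {
  if (!is.null(positions_bp)) n_snps <- length(positions_bp)
  spec <- list(n_samples = as.integer(n_samples), n_snps = as.integer(n_snps),
               positions_bp = positions_bp,
               chrom_length_bp = chrom_length_bp,
               recomb_rate_cM_per_Mb = recomb_rate_cM_per_Mb,
               wf_population_size = as.integer(wf_population_size),
               wf_generations = as.integer(wf_generations), sweep = sweep,
               init_daf = init_daf, seed = as.integer(seed))
  stopifnot(spec$n_samples >= 2, spec$n_snps >= 2,
            spec$n_samples <= spec$wf_population_size,
            spec$wf_generations >= 0, spec$recomb_rate_cM_per_Mb >= 0)
  for (sw in spec$sweep)
    stopifnot(sw$s >= 0, sw$stop_frequency > 0, sw$stop_frequency < 1)
  structure(spec, class = "sim_spec")
}

#' Simulate a neutral phased haplotype panel
#'
#' Forward Wright-Fisher simulation on binary haplotypes: 2N founder
#' haplotypes receive derived alleles at random positions (initial counts
#' from the neutral frequency spectrum unless `init_daf` is given), then
#' each generation every offspring haplotype is a recombinant copy of a
#' uniformly chosen parent's two haplotypes, with crossover count
#' Poisson(genetic length in Morgans) and crossover points uniform on the
#' genetic map. After `wf_generations`, `n_samples` diploids are sampled
#' and (by default) sites fixed or lost in the sample are dropped.
#'
#' @param spec a [sim_spec()].
#' @param drop_monomorphic drop fixed/lost sites from the returned panel
#'   (default TRUE; allele-frequency conservation checks want FALSE).
#' @param population population label for the panel.
#' @param keep_founders attach the founder haplotype matrix as attribute
#'   `founder_haps` (default FALSE; used by lineage checks).
#' @return a [haplotype_panel()].
#' @export
simulate_neutral_panel <- function(spec, drop_monomorphic = TRUE,
                                   population = "SIM",
                                   keep_founders = FALSE) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  H <- 2L * spec$wf_population_size
  S <- spec$n_snps
  pos <- if (!is.null(spec$positions_bp)) as.integer(spec$positions_bp)
         else sort(sample.int(spec$chrom_length_bp, S))
  cm <- pos * spec$recomb_rate_cM_per_Mb / 1e6

  if (is.null(spec$init_daf)) {
    # neutral SFS: P(initial derived count = i) ~ 1/i, i in 1..H-1
    w <- 1 / seq_len(H - 1L)
    cnt <- sample.int(H - 1L, S, replace = TRUE, prob = w)
  } else {
    cnt <- pmax(1L, pmin(H - 1L, round(rep_len(spec$init_daf, S) * H)))
  }
  haps <- matrix(0L, nrow = H, ncol = S)
  for (j in seq_len(S)) haps[sample.int(H, cnt[j]), j] <- 1L
  founders <- if (keep_founders) haps else NULL

  if (spec$wf_generations > 0)
    haps <- cpp_wf_generations(haps, cm, spec$wf_generations)

  take <- sort(sample.int(spec$wf_population_size, spec$n_samples))
  rows <- as.vector(rbind(2L * take - 1L, 2L * take))
  sub <- haps[rows, , drop = FALSE]

  keep <- rep(TRUE, S)
  if (drop_monomorphic) {
    f <- colMeans(sub)
    keep <- f > 0 & f < 1
    if (!any(keep))
      stop("all sites fixed or lost; increase n_snps or reduce ",
           "wf_generations")
  }
  panel <- haplotype_panel(
    snp_ids = sprintf("snp%05d", which(keep)), chrom = "chr1",
    positions_bp = pos[keep], genetic_pos_cM = cm[keep],
    alleles = data.frame(ancestral = rep("A", sum(keep)),
                         derived = rep("G", sum(keep)),
                         stringsAsFactors = FALSE),
    hap_matrix = sub[, keep, drop = FALSE],
    sample_ids = sprintf("S%04d", seq_len(spec$n_samples)),
    population = population
  )
  attr(panel, "population_freq") <- colMeans(haps)
  attr(panel, "sim_spec") <- spec
  if (keep_founders)
    attr(panel, "founder_haps") <- founders[, keep, drop = FALSE]
  panel
}

#' Inject a selective sweep at a segregating site
#'
#' Continues the Wright-Fisher process on the panel's haplotypes (the
#' panel is treated as the breeding population) with genotype fitnesses
#' 1, 1+s, 1+2s by derived-allele count at the focal site, until the focal
#' derived frequency first reaches `stop_frequency`. The crossing
#' generation is conditioned to land at the boundary (to within one
#' haplotype copy), so replicate sweeps complete at the same frequency and
#' the focal site is still segregating. If the allele is lost the process
#' restarts from the input panel, up to `max_restarts` times.
#'
#' @param panel a [haplotype_panel()].
#' @param position target position in bp; the nearest segregating site is
#'   used as the focal site.
#' @param s selection coefficient (>= 0).
#' @param stop_frequency derived-allele frequency at which the sweep stops,
#'   in (0, 1).
#' @param seed integer seed.
#' @param max_gen generation cap per attempt (attribute `reached` records
#'   whether the stop frequency was hit).
#' @param max_restarts restarts allowed after allele loss before erroring.
#' @return the re-sampled panel; attribute `sweep` records the focal site,
#'   restarts, generations and whether `stop_frequency` was reached.
#' @export
inject_sweep <- function(panel, position, s, stop_frequency, seed = 1,
                         max_gen = 5000, max_restarts = 20) {
  validate_panel(panel)
  stopifnot(s >= 0, stop_frequency > 0, stop_frequency < 1)
  set.seed(seed)
  f <- derived_freq(panel)
  seg <- which(f > 0 & f < 1)
  if (!length(seg)) stop("panel has no segregating site")
  focal <- seg[which.min(abs(panel$positions_bp[seg] - position))]

  restarts <- 0L
  repeat {
    res <- cpp_wf_select(panel$hap_matrix, panel$genetic_pos_cM,
                         focal - 1L, s, stop_frequency, max_gen)
    if (res$status != 1L) break
    restarts <- restarts + 1L
    if (restarts > max_restarts)
      stop("focal allele lost before reaching stop_frequency after ",
           restarts - 1L, " restarts")
  }
  out <- panel
  out$hap_matrix <- res$haps
  validate_panel(out)
  attr(out, "sweep") <- list(focal_snp = panel$snp_ids[focal],
                             focal_index = focal,
                             position_bp = panel$positions_bp[focal],
                             s = s, stop_frequency = stop_frequency,
                             reached = res$status == 0L,
                             generations = res$generations,
                             restarts = restarts)
  out
}
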