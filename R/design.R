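#' The twelve study populations
#'
#' Population codes (grouped by ancestry) over which the per-gene
#' selection-risk associations are counted: four African, three
#' East-Asian, three European, plus GIH and MEX.
#'
#' @return data.frame with columns `population` and `ancestry`.
#' @export
study_populations <- function() {
  data.frame(
    population = c("ASW", "MKK", "YRI", "LWK", "CHB", "CHD", "JPT",
                   "CEU", "TSI", "FIN", "GIH", "MEX"),
    ancestry = c(rep("African", 4), rep("East-Asian", 3),
                 rep("European", 3), "South-Asian", "Admixed-American"),
    stringsAsFactors = FALSE)
}

#' The packaged coronary-artery-disease gene roster
#'
#' A 76-gene locus list standing in for the published CAD candidate-gene
#' panel. Only a handful of the published gene names are reproduced in
#' text sources (flagged `published_text` in the `source` column, with
#' their genomic intervals); the remainder of the roster is synthetic
#' (`synthetic`), carrying realistic but invented intervals, and exists
#' so that panel-level design constants and length-matching procedures
#' operate at the true roster size. Coordinates are 1-based inclusive.
#'
#' @return data.frame: `gene`, `chrom`, `start`, `end`, `source`.
#' @export
cad_gene_panel <- function() {
  path <- system.file("extdata", "cad_gene_panel_synthetic.tsv",
                      package = "selpleio")
  as.data.frame(data.table::fread(path, sep = "\t"))
}

#' Analysis design constants
#'
#' Recomputes, from the packaged gene and population lists, the two
#' analytic constants the study design fixes: the size of the gene x
#' population regression grid, and the Bonferroni-corrected significance
#' threshold alpha / n_genes used for the per-gene permuted p values.
#'
#' @param alpha family-wise level (default 0.05).
#' @return list: `n_genes`, `n_populations`, `grid_size`,
#'   `bonferroni_alpha`.
#' @export
design_constants <- function(alpha = 0.05) {
  ng <- nrow(cad_gene_panel())
  np <- nrow(study_populations())
  list(n_genes = ng, n_populations = np, grid_size = ng * np,
       bonferroni_alpha = alpha / ng)
}
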