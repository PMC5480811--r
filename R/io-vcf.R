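#' Read a phased VCF into a haplotype panel
#'
#' Parses a phased VCF (via \pkg{vcfR}) and recodes genotypes to
#' ancestral/derived states. The ancestral allele is taken from the INFO
#' `AA` key, or from a sidecar table (`ancestral`) mapping SNP id to the
#' ancestral base. Multiallelic and non-SNP records are dropped; sites
#' whose ancestral state is missing are dropped and counted; sites whose
#' ancestral allele matches neither REF nor ALT are dropped with a warning.
#' Any unphased genotype is a hard error naming the offending record.
#'
#' @param path path to a VCF (plain text or gzipped).
#' @param population_label population label attached to the panel.
#' @param ancestral optional data.frame with columns `snp_id` and `aa`,
#'   used when the VCF lacks INFO/AA.
#' @param recomb_rate_cM_per_Mb linear genetic map applied when the VCF
#'   carries no map (default 1 cM/Mb).
#' @param founders optional character vector of founder sample ids; all
#'   samples are founders by default.
#' @return a [haplotype_panel()]; attribute `drop_report` counts records
#'   removed per reason.
#' @export
read_phased_vcf <- function(path, population_label = "POP", ancestral = NULL,
                            recomb_rate_cM_per_Mb = 1, founders = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(rbind(vcfR::getFIX(vcf)), stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1, dimnames = list(
    NULL, names(gt)))
  drop <- c(non_snp = 0L, missing_aa = 0L, aa_mismatch = 0L)

  snp_ok <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    !grepl(",", fix$ALT, fixed = TRUE) &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  drop["non_snp"] <- sum(!snp_ok)

  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <-
    paste0(fix$CHROM, ":", fix$POS)[is.na(ids) | ids == "."]
  if (!is.null(ancestral)) {
    aa <- ancestral$aa[match(ids, ancestral$snp_id)]
  } else {
    aa <- vcfR::extract.info(vcf, element = "AA")
  }
  aa <- toupper(aa)
  aa_missing <- is.na(aa) | aa == "." | aa == ""
  drop["missing_aa"] <- sum(aa_missing & snp_ok)
  aa_bad <- !aa_missing & !(aa == fix$REF | aa == fix$ALT)
  if (any(aa_bad & snp_ok))
    warning(sum(aa_bad & snp_ok),
            " site(s) dropped: ancestral allele not among REF/ALT")
  drop["aa_mismatch"] <- sum(aa_bad & snp_ok)

  keep <- snp_ok & !aa_missing & !aa_bad
  if (!any(keep)) stop("no biallelic SNPs with ancestral state in ", path)

  gtk <- gt[keep, , drop = FALSE]
  unphased <- grepl("/", gtk, fixed = TRUE)
  if (any(unphased)) {
    bad <- (which(unphased)[1] - 1L) %% nrow(gtk) + 1L
    rec <- which(keep)[bad]
    stop("unphased genotype at ", fix$CHROM[rec], ":", fix$POS[rec])
  }
  n_site <- nrow(gtk)
  n_samp <- ncol(gtk)
  a1 <- substr(gtk, 1L, 1L)
  a2 <- substr(gtk, 3L, 3L)
  to_int <- function(a) {
    out <- suppressWarnings(as.integer(a))
    out  # "." -> NA
  }
  # haplotype rows interleaved: sample1 hapA, sample1 hapB, sample2 hapA, ...
  hap <- matrix(NA_integer_, nrow = 2L * n_samp, ncol = n_site)
  hap[seq(1L, 2L * n_samp, by = 2L), ] <- t(matrix(to_int(a1), nrow = n_site))
  hap[seq(2L, 2L * n_samp, by = 2L), ] <- t(matrix(to_int(a2), nrow = n_site))

  # recode ALT dosage -> derived dosage: flip where ancestral == ALT
  flip <- (aa[keep] == fix$ALT[keep])
  if (any(flip)) hap[, flip] <- 1L - hap[, flip]

  anc_allele <- ifelse(flip, fix$ALT[keep], fix$REF[keep])
  der_allele <- ifelse(flip, fix$REF[keep], fix$ALT[keep])
  pos <- as.integer(fix$POS[keep])
  o <- order(pos)

  samp <- colnames(gtk)
  panel <- haplotype_panel(
    snp_ids = ids[keep][o], chrom = fix$CHROM[keep][1],
    positions_bp = pos[o],
    genetic_pos_cM = pos[o] * recomb_rate_cM_per_Mb / 1e6,
    alleles = data.frame(ancestral = anc_allele[o], derived = der_allele[o],
                         stringsAsFactors = FALSE),
    hap_matrix = hap[, o, drop = FALSE],
    sample_ids = samp, population = population_label,
    founder_flags = if (is.null(founders)) NULL else samp %in% founders
  )
  attr(panel, "drop_report") <- drop
  panel
}

#' Write a haplotype panel as a phased VCF
#'
#' Emits a minimal VCF 4.2 text file with REF = ancestral allele,
#' ALT = derived allele, `AA` in INFO and phased `GT` fields, so that
#' [read_phased_vcf()] round-trips the panel exactly.
#'
#' @param panel a [haplotype_panel()].
#' @param path output path (plain text).
#' @return `path`, invisibly.
#' @export
write_phased_vcf <- function(panel, path) {
  validate_panel(panel)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", panel$sample_ids), collapse = "\t")
  ), con)
  h <- panel$hap_matrix
  ns <- length(panel$sample_ids)
  a1 <- h[seq(1L, 2L * ns, by = 2L), , drop = FALSE]
  a2 <- h[seq(2L, 2L * ns, by = 2L), , drop = FALSE]
  gt_chr <- function(m) {
    x <- as.character(m)
    x[is.na(x)] <- "."
    matrix(x, nrow = nrow(m))
  }
  gt <- matrix(paste0(gt_chr(a1), "|", gt_chr(a2)), nrow = ns)
  lines <- vapply(seq_along(panel$snp_ids), function(j) {
    paste(c(panel$chrom, panel$positions_bp[j], panel$snp_ids[j],
            panel$alleles$ancestral[j], panel$alleles$derived[j], ".",
            "PASS", paste0("AA=", panel$alleles$ancestral[j]), "GT",
            gt[, j]), collapse = "\t")
  }, character(1))
  writeLines(lines, con)
  invisible(path)
}
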