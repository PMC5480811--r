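#' Adjust lifetime reproductive success for secular change
#'
#' Samples are split into `n_groups` equal-count groups by birth year
#' (quantile cuts on the rank) and each individual's raw LRS is divided by
#' the mean raw LRS of their group, so every group's adjusted mean is 1 by
#' construction and cohort-wide fertility trends cancel.
#'
#' @param phenotypes data.frame with `birth_year` and `lrs_raw` (see
#'   [read_phenotypes()]).
#' @param n_groups number of birth-year groups (default 6).
#' @return `phenotypes` with added columns `by_group` and `lrs_adjusted`.
#' @export
adjust_lrs <- function(phenotypes, n_groups = 6) {
  require_cols(phenotypes, c("birth_year", "lrs_raw"), "adjust_lrs")
  n <- nrow(phenotypes)
  rk <- rank(phenotypes$birth_year, ties.method = "first")
  grp <- floor((rk - 1) * n_groups / n) + 1L
  gm <- tapply(phenotypes$lrs_raw, grp, mean)
  if (any(gm == 0)) stop("birth-year group with zero mean LRS")
  phenotypes$by_group <- as.integer(grp)
  phenotypes$lrs_adjusted <- phenotypes$lrs_raw / gm[as.character(grp)]
  phenotypes
}
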