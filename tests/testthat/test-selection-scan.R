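test_that("EHH matches hand-computed pair counting", {
  # 6 haplotypes; derived carriers of s2 are rows 1-4; at s3 they split
  # into extended-haplotype groups of sizes {2, 1, 1}: EHH = C(2,2)/C(4,2)
  hap <- rbind(
    c(0, 1, 0, 0),
    c(0, 1, 0, 1),
    c(0, 1, 1, 0),
    c(1, 1, 0, 0),
    c(0, 0, 1, 1),
    c(1, 0, 1, 0))
  hap[4, 3] <- 0  # rows 1 and 4 identical over s2:s4
  p <- hand_panel(hap)
  cv <- ehh_curve(p, "s2", "derived", "right", cutoff = 0)
  expect_equal(cv$ehh[1], 1)          # at the core itself
  expect_equal(cv$ehh[2], 0.5)        # groups {3,1} among 4 carriers
  expect_equal(cv$ehh[3], 1 / 6)      # groups {2,1,1}: C(2,2)/C(4,2)
  # all carriers identical out to a marker -> EHH 1 there
  hap2 <- matrix(0L, 6, 3)
  hap2[1:4, 2] <- 1L
  p2 <- hand_panel(hap2)
  cv2 <- ehh_curve(p2, "s2", "derived", "right", cutoff = 0)
  expect_equal(cv2$ehh[2], 1)
  expect_error(ehh_curve(hand_panel(rbind(c(0, 1), c(0, 0), c(0, 0), c(0, 0))),
                         "s2", "derived", "right"), "fewer than 2")
})

test_that("optimized EHH equals the brute-force oracle on random panels", {
  for (s in 1:25) {
    p <- random_panel(n_hap = 2 * sample(3:8, 1), n_snp = sample(8:30, 1),
                      seed = 500 + s)
    core <- sample(n_snps(p), 1)
    al <- sample(c("ancestral", "derived"), 1)
    dir <- sample(c("left", "right"), 1)
    f <- mean(p$hap_matrix[, core])
    if (min(f, 1 - f) * nrow(p$hap_matrix) < 2) next
    a <- ehh_curve(p, core, al, dir, cutoff = 0.05)
    b <- ehh_curve_brute(p, core, al, dir, cutoff = 0.05)
    expect_identical(a$ehh, b$ehh)
    expect_identical(a$marker, b$marker)
    expect_identical(attr(a, "hit_end"), attr(b, "hit_end"))
  }
})

test_that("EHH curves are monotone non-increasing and iHH non-negative", {
  p <- wf_panel()
  s <- wf_scores()
  ok <- which(s$reason == "ok")
  for (i in ok[seq(1, length(ok), length.out = 10)]) {
    cv <- ehh_curve(p, i, "derived", "right", cutoff = 0.05)
    expect_true(all(diff(cv$ehh) <= 1e-12))
  }
  expect_true(all(s$ihh_a[ok] > 0) && all(s$ihh_d[ok] > 0))
})

test_that("iHH integration follows the truncated trapezoid rule", {
  fake_curve <- function(d, e, pos, hit_end = FALSE) {
    structure(data.frame(marker = seq_along(d), distance_cM = d, ehh = e),
              class = c("ehh_curve", "data.frame"), core_snp = "s1",
              core_allele = "derived", direction = "right",
              hit_end = hit_end, positions_bp = pos)
  }
  empty <- fake_curve(0, 1, 0)
  right <- fake_curve(c(0, 0.1, 0.2), c(1, 0.5, 0.02), c(0, 1e4, 2e4))
  expect_equal(integrate_ihh(empty, right, cutoff = 0.05), 0.075)
  # EHH = 1 over 0.2 cM then a sub-cutoff point: rectangle of area 0.2
  flat <- fake_curve(c(0, 0.2, 0.21), c(1, 1, 0.01), c(0, 2e4, 2.1e4))
  expect_equal(integrate_ihh(empty, flat, cutoff = 0.05), 0.2)
  # chromosome end with EHH still at 0.4 -> undefined
  ended <- fake_curve(c(0, 0.1), c(1, 0.4), c(0, 1e4), hit_end = TRUE)
  expect_true(is.na(integrate_ihh(empty, ended, cutoff = 0.05)))
  expect_equal(attr(integrate_ihh(empty, ended, cutoff = 0.05), "reason"),
               "chrom_end")
  # oversized physical gap -> undefined
  gappy <- fake_curve(c(0, 0.1, 0.2), c(1, 0.5, 0.02), c(0, 1e4, 3.1e5))
  expect_equal(attr(integrate_ihh(empty, gappy, cutoff = 0.05,
                                  max_gap_bp = 2e5), "reason"), "gap")
})

test_that("the scan honours the ln identity, MAF exclusion and sign symmetry", {
  s <- wf_scores()
  ok <- s$reason == "ok"
  expect_true(any(ok))
  expect_equal(s$ihs_raw[ok], log(s$ihh_a[ok] / s$ihh_d[ok]))
  low <- minor_freq(wf_panel()) < 0.05
  expect_true(all(s$reason[low] == "maf"))
  # swapping ancestral/derived at the core negates ihs_raw
  p <- wf_panel()
  i <- which(ok)[1]
  pf <- p
  pf$hap_matrix[, i] <- 1L - pf$hap_matrix[, i]
  sf <- ihs_scan(pf)
  expect_equal(sf$ihs_raw[i], -s$ihs_raw[i])
})

test_that("standardization is exact within DAF bins", {
  sc <- data.frame(snp_id = paste0("s", 1:3), chrom = "chr1",
                   pos = 1:3 * 1000, daf = c(0.51, 0.52, 0.52),
                   ihh_a = 1, ihh_d = 1, ihs_raw = c(1, 2, 3),
                   reason = "ok", stringsAsFactors = FALSE)
  out <- standardize_ihs(sc, bin_width = 0.1)
  expect_equal(out$ihs_std, c(-1, 0, 1))
  expect_equal(out$nominal_p[3], 2 * pnorm(-1))
  # all scores equal in a bin -> zero SD -> undefined
  sc$ihs_raw <- c(2, 2, 2)
  expect_warning(out2 <- standardize_ihs(sc, bin_width = 0.1), "zero spread")
  expect_true(all(is.na(out2$ihs_std)))
  expect_true(all(out2$reason == "bin"))
  # full-scan property: per-bin mean 0, sample SD 1
  s <- wf_scores()
  def <- !is.na(s$ihs_std)
  for (b in unique(s$daf_bin[def])) {
    v <- s$ihs_std[def & s$daf_bin == b]
    expect_lt(abs(mean(v)), 1e-10)
    expect_equal(sd(v), 1, tolerance = 1e-10)
  }
})

test_that("permutation p values respect the pseudocount floor and rank symmetry", {
  # a bin whose target exceeds every other score -> exceedance only itself
  sc <- data.frame(snp_id = paste0("s", 1:60), chrom = "chr1",
                   pos = 1:60 * 1000, daf = 0.5, ihh_a = 1, ihh_d = 1,
                   ihs_raw = c(10, rnorm(59, 0, 0.1)), reason = "ok",
                   stringsAsFactors = FALSE)
  out <- standardize_ihs(sc, bin_width = 1)
  out <- permute_ihs_p(out, n_perm = 10000, seed = 1)
  # the target is its own pool maximum: exceedance fraction 1/60
  expect_lt(out$permuted_p[1], 0.05)
  med <- which.min(abs(out$ihs_std - stats::median(out$ihs_std)))
  expect_lt(abs(out$permuted_p[med] - 0.5), 0.05)
  # floor: an exceedance fraction of zero gives exactly 1/(n_perm + 1)
  expect_equal((1 + 0) / (10000 + 1), 9.999e-5, tolerance = 1e-3)
})

test_that("permuted p values are uniform under neutrality", {
  s <- wf_scores()
  pp <- s$permuted_p[!is.na(s$permuted_p)]
  expect_gte(length(pp), 200)
  expect_gt(suppressWarnings(ks.test(pp, "punif"))$p.value, 0.01)
})

test_that("candidate signals require the cluster rule and classify magnitudes", {
  mk_scores <- function(pos, std, perm) {
    data.frame(snp_id = paste0("s", seq_along(pos)), chrom = "chr1",
               pos = pos, daf = 0.5, ihh_a = 1, ihh_d = 1,
               ihs_raw = std, reason = "ok", daf_bin = 0L, ihs_std = std,
               nominal_p = 2 * pnorm(-abs(std)), permuted_p = perm,
               stringsAsFactors = FALSE)
  }
  locus <- list(gene = "G1", snp_ids = paste0("s", 1:5))
  # isolated |iHS| 3.5 with no elevated neighbour -> no signal
  sc <- mk_scores(pos = c(1e4, 2e4, 3e4, 4e4, 5e4),
                  std = c(0.5, 0.2, 3.5, 0.1, 0.3),
                  perm = c(0.5, 0.5, 0.001, 0.5, 0.5))
  expect_equal(nrow(call_candidate_signals(sc, list(locus))), 0L)
  # three adjacent SNPs {2.4, 3.1, 2.2}, all permuted p < 0.05 -> one
  # signal, apex 3.1, class 3-4
  sc2 <- mk_scores(pos = c(1e4, 2e4, 3e4, 4e4, 5e4),
                   std = c(2.4, 3.1, 2.2, 0.1, 0.3),
                   perm = c(0.01, 0.001, 0.02, 0.5, 0.5))
  sig <- call_candidate_signals(sc2, list(locus))
  expect_equal(nrow(sig), 1L)
  expect_equal(sig$apex_snp, "s2")
  expect_equal(sig$apex_ihs, 3.1)
  expect_equal(sig$magnitude_class, "3-4")
  expect_equal(sig$n_members, 3L)
  # apex above 4 -> class ">4"
  sc3 <- mk_scores(pos = c(1e4, 2e4, 3e4, 4e4, 5e4),
                   std = c(2.4, 4.2, 2.2, 0.1, 0.3),
                   perm = c(0.01, 0.001, 0.02, 0.5, 0.5))
  expect_equal(call_candidate_signals(sc3, list(locus))$magnitude_class, ">4")
})
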