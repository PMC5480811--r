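#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Wright-Fisher forward simulation on phased 0/1 haplotypes.
// Rows 2i, 2i+1 of the haplotype matrix are the two haplotypes of diploid i.
// All randomness goes through R's RNG so set.seed() governs everything.
// ---------------------------------------------------------------------------

static void make_gamete(const IntegerMatrix &src, int parent, IntegerMatrix &dst,
                        int row, const NumericVector &cm, double morgans) {
  const int S = src.ncol();
  int h = (unif_rand() < 0.5) ? 0 : 1;
  int k = (morgans > 0.0) ? (int) R::rpois(morgans) : 0;
  if (k == 0) {
    for (int s = 0; s < S; ++s) dst(row, s) = src(2 * parent + h, s);
    return;
  }
  std::vector<double> xp(k);
  const double c0 = cm[0], span = cm[S - 1] - cm[0];
  for (int i = 0; i < k; ++i) xp[i] = c0 + unif_rand() * span;
  std::sort(xp.begin(), xp.end());
  int xi = 0;
  for (int s = 0; s < S; ++s) {
    while (xi < k && xp[xi] <= cm[s]) { h ^= 1; ++xi; }
    dst(row, s) = src(2 * parent + h, s);
  }
}

static int sample_weighted(const std::vector<double> &cw) {
  // cw: cumulative weights, last element is the total
  double u = unif_rand() * cw.back();
  return (int)(std::lower_bound(cw.begin(), cw.end(), u) - cw.begin());
}

// One generation of random mating; selection at `focal` (0-based column,
// or -1 for neutral) with fitnesses 1, 1+s, 1+2s by derived-allele count.
static void wf_generation(const IntegerMatrix &src, IntegerMatrix &dst,
                          const NumericVector &cm, double morgans,
                          int focal, double s) {
  const int N = src.nrow() / 2;
  std::vector<double> cw;
  const bool sel = (focal >= 0 && s > 0.0);
  if (sel) {
    cw.resize(N);
    double acc = 0.0;
    for (int i = 0; i < N; ++i) {
      int g = src(2 * i, focal) + src(2 * i + 1, focal);
      acc += 1.0 + s * g;
      cw[i] = acc;
    }
  }
  for (int i = 0; i < N; ++i) {
    int p1 = sel ? sample_weighted(cw) : (int)(unif_rand() * N);
    int p2 = sel ? sample_weighted(cw) : (int)(unif_rand() * N);
    if (p1 >= N) p1 = N - 1;
    if (p2 >= N) p2 = N - 1;
    make_gamete(src, p1, dst, 2 * i, cm, morgans);
    make_gamete(src, p2, dst, 2 * i + 1, cm, morgans);
  }
}

// [[Rcpp::export]]
IntegerMatrix cpp_wf_generations(IntegerMatrix haps, NumericVector cm,
                                 int generations) {
  const int S = haps.ncol();
  double morgans = (S > 1) ? (cm[S - 1] - cm[0]) / 100.0 : 0.0;
  IntegerMatrix a = clone(haps), b(haps.nrow(), S);
  for (int g = 0; g < generations; ++g) {
    wf_generation(a, b, cm, morgans, -1, 0.0);
    std::swap(a, b);
  }
  return a;
}

// Continue evolution with selection at `focal` until its derived frequency
// first reaches stop_freq. The crossing generation is conditioned on first
// passage landing exactly at the boundary count (redrawn while it would
// overshoot or fix), so the focal site stays segregating and the stopping
// frequency is met to within one haplotype copy.
// Status codes: 0 = reached, 1 = allele lost/fixed, 2 = max_gen exceeded.
// [[Rcpp::export]]
List cpp_wf_select(IntegerMatrix haps, NumericVector cm, int focal, double s,
                   double stop_freq, int max_gen) {
  const int S = haps.ncol(), H = haps.nrow();
  const int max_redraw = 500;
  double morgans = (S > 1) ? (cm[S - 1] - cm[0]) / 100.0 : 0.0;
  int cstar = (int) std::ceil(stop_freq * H);
  if (cstar >= H) cstar = H - 1;
  if (cstar < 1) cstar = 1;
  IntegerMatrix a = clone(haps), b(H, S);
  int status = 2, gens = 0;

  int cnt = 0;
  for (int r = 0; r < H; ++r) cnt += a(r, focal);
  if (cnt >= cstar && cnt < H)
    return List::create(_["haps"] = a, _["status"] = 0, _["generations"] = 0);

  for (int g = 0; g < max_gen; ++g) {
    int cnt_b = 0, attempts = 0;
    for (;;) {
      wf_generation(a, b, cm, morgans, focal, s);
      cnt_b = 0;
      for (int r = 0; r < H; ++r) cnt_b += b(r, focal);
      ++attempts;
      if (cnt_b <= cstar && cnt_b < H) break;             // no overshoot
      if (attempts >= max_redraw && cnt_b < H) break;     // accept overshoot
      if (attempts >= 4 * max_redraw) break;              // give up (fixed)
    }
    std::swap(a, b);
    gens = g + 1;
    if (cnt_b == 0 || cnt_b == H) { status = 1; break; }
    if (cnt_b >= cstar) { status = 0; break; }
  }
  return List::create(_["haps"] = a, _["status"] = status,
                      _["generations"] = gens);
}

// ---------------------------------------------------------------------------
// EHH by incremental prefix-partition refinement.
// Haplotypes carrying the core allele are partitioned by their extended
// haplotype; at each further marker the partition is refined by that
// marker's allele.  EHH(m) = sum_h C(n_h,2) / C(n_c,2).
// ---------------------------------------------------------------------------

struct EhhCurve {
  std::vector<double> dist;  // |cM - cM_core|, starting at 0
  std::vector<double> ehh;   // starting at 1
  std::vector<int> marker;   // 0-based marker index, core first
  bool hit_end;              // ran out of markers while EHH >= cutoff
};

static EhhCurve ehh_walk(const IntegerMatrix &haps,
                         const std::vector<int> &carriers, int core, int dir,
                         const NumericVector &cm, double cutoff) {
  const int S = haps.ncol();
  const int nc = (int) carriers.size();
  const double denom = 0.5 * nc * (nc - 1);
  EhhCurve out;
  out.hit_end = false;
  out.dist.push_back(0.0);
  out.ehh.push_back(1.0);
  out.marker.push_back(core);
  std::vector<int> grp(nc, 0);
  int ngrp = 1;
  double e = 1.0;
  int m = core + dir;
  std::vector<int> remap;
  while (e >= cutoff) {
    if (m < 0 || m >= S) { out.hit_end = true; break; }
    // refine: new key = 2*grp + allele, then relabel compactly
    remap.assign(2 * ngrp, -1);
    int nnew = 0;
    for (int i = 0; i < nc; ++i) {
      int key = 2 * grp[i] + haps(carriers[i], m);
      if (remap[key] < 0) remap[key] = nnew++;
      grp[i] = remap[key];
    }
    ngrp = nnew;
    std::vector<int> cnt(ngrp, 0);
    for (int i = 0; i < nc; ++i) cnt[grp[i]]++;
    double num = 0.0;
    for (int g = 0; g < ngrp; ++g) num += 0.5 * (double) cnt[g] * (cnt[g] - 1);
    e = num / denom;
    out.dist.push_back(std::fabs(cm[m] - cm[core]));
    out.ehh.push_back(e);
    out.marker.push_back(m);
    m += dir;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_ehh_curve(IntegerMatrix haps, IntegerVector carriers, int core,
                   int dir, NumericVector cm, double cutoff) {
  std::vector<int> cs(carriers.begin(), carriers.end());
  EhhCurve c = ehh_walk(haps, cs, core, dir, cm, cutoff);
  return List::create(_["distance_cM"] = wrap(c.dist), _["ehh"] = wrap(c.ehh),
                      _["marker"] = wrap(c.marker), _["hit_end"] = c.hit_end);
}

// Trapezoid integral truncated at the last marker with EHH >= cutoff.
// Returns -1 for "undefined" (chromosome end or oversized bp gap), else >= 0.
static double ihh_one_side(const IntegerMatrix &haps,
                           const std::vector<int> &carriers, int core, int dir,
                           const NumericVector &cm, const NumericVector &bp,
                           double cutoff, double max_gap_bp, int *reason) {
  EhhCurve c = ehh_walk(haps, carriers, core, dir, cm, cutoff);
  if (c.hit_end) { *reason = 2; return -1.0; }
  double acc = 0.0;
  for (size_t i = 1; i < c.ehh.size(); ++i) {
    double gap = std::fabs(bp[c.marker[i]] - bp[c.marker[i - 1]]);
    if (gap > max_gap_bp) { *reason = 3; return -1.0; }
    if (c.ehh[i] < cutoff) break;
    acc += 0.5 * (c.ehh[i] + c.ehh[i - 1]) * (c.dist[i] - c.dist[i - 1]);
  }
  return acc;
}

// Full iHS scan.  reason codes: 0 ok, 1 maf, 2 chrom_end, 3 gap, 4 zero_ihh.
// [[Rcpp::export]]
List cpp_ihs_scan(IntegerMatrix haps, NumericVector cm, NumericVector bp,
                  double cutoff, double max_gap_bp, double maf_min) {
  const int S = haps.ncol(), H = haps.nrow();
  NumericVector daf(S), ihh_a(S, NA_REAL), ihh_d(S, NA_REAL),
      ihs_raw(S, NA_REAL);
  IntegerVector reason(S, 0);
  std::vector<int> anc, der;
  for (int s = 0; s < S; ++s) {
    anc.clear();
    der.clear();
    for (int r = 0; r < H; ++r) {
      if (haps(r, s) == 1) der.push_back(r); else anc.push_back(r);
    }
    double p = (double) der.size() / H;
    daf[s] = p;
    double maf = std::min(p, 1.0 - p);
    if (maf < maf_min) { reason[s] = 1; continue; }
    int rs = 0;
    double ia_l = ihh_one_side(haps, anc, s, -1, cm, bp, cutoff, max_gap_bp, &rs);
    if (rs) { reason[s] = rs; continue; }
    double ia_r = ihh_one_side(haps, anc, s, +1, cm, bp, cutoff, max_gap_bp, &rs);
    if (rs) { reason[s] = rs; continue; }
    double id_l = ihh_one_side(haps, der, s, -1, cm, bp, cutoff, max_gap_bp, &rs);
    if (rs) { reason[s] = rs; continue; }
    double id_r = ihh_one_side(haps, der, s, +1, cm, bp, cutoff, max_gap_bp, &rs);
    if (rs) { reason[s] = rs; continue; }
    double ia = ia_l + ia_r, id = id_l + id_r;
    if (ia <= 0.0 || id <= 0.0) { reason[s] = 4; continue; }
    ihh_a[s] = ia;
    ihh_d[s] = id;
    ihs_raw[s] = std::log(ia / id);
  }
  return List::create(_["daf"] = daf, _["ihh_a"] = ihh_a, _["ihh_d"] = ihh_d,
                      _["ihs_raw"] = ihs_raw, _["reason"] = reason);
}

// ---------------------------------------------------------------------------
// Rank-1 mixed model:  y = b0 + b1 x + u v + e,  u ~ N(0, su2), e ~ N(0, se2),
// cov(y) = su2 v v' + se2 I with ||v|| = 1.  REML profiled over g = su2/se2
// using V^{-1} = (I - c v v') / se2, c = g/(1+g).
// All sufficient statistics are O(1) per candidate g.
// ---------------------------------------------------------------------------

struct R1Stats {
  double n;
  double sx, sxx;          // sums over x
  double sv, svv;          // sums over v (svv = ||v||^2 = 1 by contract)
  double sxv;
  double sy, sxy, svy, syy;
};

static void r1_accum(const NumericVector &y, const NumericVector &x,
                     const NumericVector &v, R1Stats *st) {
  const int n = y.size();
  st->n = n;
  st->sx = st->sxx = st->sv = st->svv = st->sxv = 0.0;
  st->sy = st->sxy = st->svy = st->syy = 0.0;
  for (int i = 0; i < n; ++i) {
    st->sx += x[i]; st->sxx += x[i] * x[i];
    st->sv += v[i]; st->svv += v[i] * v[i];
    st->sxv += x[i] * v[i];
    st->sy += y[i]; st->sxy += x[i] * y[i];
    st->svy += v[i] * y[i]; st->syy += y[i] * y[i];
  }
}

struct R1Fit {
  double beta0, beta1, se1, se2hat, su2hat, gamma, reml;
};

// REML criterion (up to an additive constant) and GLS fit at a given gamma.
static double r1_eval(const R1Stats &st, double gamma, R1Fit *fit) {
  const double c = gamma / (1.0 + gamma);
  // A = X' V~^{-1} X, b = X' V~^{-1} y, q = y' V~^{-1} y (V~ = I + g vv')
  double a11 = st.n - c * st.sv * st.sv;
  double a12 = st.sx - c * st.sv * st.sxv;
  double a22 = st.sxx - c * st.sxv * st.sxv;
  double b1 = st.sy - c * st.sv * st.svy;
  double b2 = st.sxy - c * st.sxv * st.svy;
  double q = st.syy - c * st.svy * st.svy;
  double det = a11 * a22 - a12 * a12;
  double beta0 = (a22 * b1 - a12 * b2) / det;
  double beta1 = (a11 * b2 - a12 * b1) / det;
  double rss = q - beta0 * b1 - beta1 * b2;
  if (rss < 1e-300) rss = 1e-300;
  double np = st.n - 2.0;
  double se2 = rss / np;
  // restricted log-likelihood: -0.5[ (n-p) log se2 + log|I+g vv'| + log|A| + rss/se2 ]
  double ll = -0.5 * (np * std::log(se2) + std::log1p(gamma * st.svv) +
                      std::log(det) + np);
  if (fit) {
    fit->beta0 = beta0;
    fit->beta1 = beta1;
    fit->se1 = std::sqrt(se2 * a11 / det);
    fit->se2hat = se2;
    fit->su2hat = gamma * se2;
    fit->gamma = gamma;
    fit->reml = ll;
  }
  return ll;
}

static R1Fit r1_fit(const R1Stats &st) {
  // golden-section search over log(gamma) in [-18.5, 18.5], plus gamma = 0
  const double lo = -18.5, hi = 18.5, gr = 0.6180339887498949;
  double a = lo, b = hi;
  double c1 = b - gr * (b - a), c2 = a + gr * (b - a);
  double f1 = r1_eval(st, std::exp(c1), NULL), f2 = r1_eval(st, std::exp(c2), NULL);
  for (int it = 0; it < 80; ++it) {
    if (f1 < f2) {
      a = c1; c1 = c2; f1 = f2;
      c2 = a + gr * (b - a); f2 = r1_eval(st, std::exp(c2), NULL);
    } else {
      b = c2; c2 = c1; f2 = f1;
      c1 = b - gr * (b - a); f1 = r1_eval(st, std::exp(c1), NULL);
    }
  }
  double gbest = std::exp(0.5 * (a + b));
  R1Fit fit, fit0;
  r1_eval(st, gbest, &fit);
  r1_eval(st, 0.0, &fit0);
  return (fit0.reml >= fit.reml) ? fit0 : fit;
}

// fixed_gamma < 0 means "optimize"; R_PosInf gives the c = 1 projection
// limit (v absorbed as if a fixed covariate).
// [[Rcpp::export]]
List cpp_rank1_fit(NumericVector y, NumericVector x, NumericVector v,
                   double fixed_gamma = -1.0) {
  R1Stats st;
  r1_accum(y, x, v, &st);
  R1Fit f;
  if (fixed_gamma >= 0.0) {
    double g = traits::is_infinite<REALSXP>(fixed_gamma) ? 1e12 : fixed_gamma;
    r1_eval(st, g, &f);
  } else {
    f = r1_fit(st);
  }
  return List::create(_["beta0"] = f.beta0, _["beta1"] = f.beta1,
                      _["se1"] = f.se1, _["sigma_e2"] = f.se2hat,
                      _["sigma_u2"] = f.su2hat, _["gamma"] = f.gamma,
                      _["reml"] = f.reml);
}

// |beta1| from n_perm refits with x shuffled (Fisher-Yates on R's RNG).
// [[Rcpp::export]]
NumericVector cpp_rank1_perm(NumericVector y, NumericVector x, NumericVector v,
                             int n_perm) {
  const int n = x.size();
  NumericVector out(n_perm);
  std::vector<double> xs(x.begin(), x.end());
  R1Stats st;
  for (int p = 0; p < n_perm; ++p) {
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(xs[i], xs[j]);
    }
    NumericVector xv(xs.begin(), xs.end());
    r1_accum(y, xv, v, &st);
    R1Fit f = r1_fit(st);
    out[p] = std::fabs(f.beta1);
  }
  return out;
}
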