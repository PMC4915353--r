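// Forward Wright-Fisher engine for a constant-size haploid population over a
// finite-sites locus. Only currently-polymorphic sites are materialised: the
// population is a monomorphic "background" sequence plus a set of columns,
// one per segregating site, each carrying per-individual alleles, the
// ancestral (pre-mutation) allele and per-allele selection coefficients.
// Columns are created by mutation and retired when a site fixes (the fixed
// allele is folded into the background) or reverts to monomorphic ancestral.
//
// All randomness goes through R's global RNG (RNGScope), so set.seed() on the
// R side makes whole runs reproducible.

#include <Rcpp.h>
#include <map>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

struct Engine {
  int N, L;
  double u;          // per-site per-generation mutation probability
  double p_del, p_adv;
  double s_del, s_adv;
  double conv_ratio; // gene-conversion initiation rate / mutation rate
  double tract_mean;

  std::vector<unsigned char> background;     // L, alleles 0..3
  std::vector<unsigned char> G, G2;          // column-major, cap * N
  std::vector<int> site;                     // per column
  std::vector<unsigned char> anc;            // per column, ancestral allele
  std::vector<double> s;                     // per column, 4 coefficients
  std::vector<unsigned char> s_set;          // per column, 4 flags
  std::vector<double> logfit, logfit2;       // per individual
  std::map<int, int> site2col;
  int P = 0;
  size_t cap = 0;
  bool any_selection = false;

  std::vector<int> parent;                   // scratch
  std::vector<double> cumw;

  void reserve(size_t newcap) {
    G.resize(newcap * N);
    G2.resize(newcap * N);
    s.resize(newcap * 4);
    s_set.resize(newcap * 4);
    site.resize(newcap);
    anc.resize(newcap);
    cap = newcap;
  }

  int new_column(int j, unsigned char bg) {
    if ((size_t)P == cap) reserve(cap ? cap * 2 : 256);
    int c = P++;
    std::fill(G.begin() + (size_t)c * N, G.begin() + (size_t)(c + 1) * N, bg);
    site[c] = j;
    anc[c] = bg;
    for (int a = 0; a < 4; ++a) { s[(size_t)c * 4 + a] = 0.0; s_set[(size_t)c * 4 + a] = 0; }
    s_set[(size_t)c * 4 + bg] = 1; // ancestral allele is neutral by definition
    site2col[j] = c;
    return c;
  }

  double draw_s() {
    double r = unif_rand();
    if (r < p_del) return s_del;
    if (r < p_del + p_adv) return s_adv;
    return 0.0;
  }

  void mutate() {
    double lambda = (double)N * L * u;
    int nm = (int)R::rpois(lambda);
    for (int e = 0; e < nm; ++e) {
      int i = (int)(unif_rand() * N); if (i == N) i = N - 1;
      int j = (int)((double)unif_rand() * L); if (j == L) j = L - 1;
      int c;
      unsigned char cur;
      std::map<int, int>::iterator it = site2col.find(j);
      if (it == site2col.end()) {
        cur = background[j];
        c = new_column(j, cur);
      } else {
        c = it->second;
        cur = G[(size_t)c * N + i];
      }
      int k = (int)(unif_rand() * 3); if (k == 3) k = 2;
      unsigned char a = (unsigned char)((cur + 1 + k) % 4);
      size_t sc = (size_t)c * 4;
      if (!s_set[sc + a]) { // first appearance of this derived allele
        s[sc + a] = draw_s();
        s_set[sc + a] = 1;
        if (s[sc + a] != 0.0) any_selection = true;
      }
      logfit[i] += std::log1p(s[sc + a]) - std::log1p(s[sc + cur]);
      G[(size_t)c * N + i] = a;
    }
  }

  void convert() {
    if (conv_ratio <= 0.0 || P == 0) return;
    double lambda = (double)N * L * conv_ratio * u;
    int nc = (int)R::rpois(lambda);
    double p_geom = 1.0 / tract_mean;
    for (int e = 0; e < nc; ++e) {
      int i = (int)(unif_rand() * N); if (i == N) i = N - 1;
      int j = (int)((double)unif_rand() * L); if (j == L) j = L - 1;
      int d = (int)(unif_rand() * (N - 1)); if (d == N - 1) d = N - 2;
      if (d >= i) ++d;
      int len = 1 + (int)R::rgeom(p_geom);
      int jend = j + len - 1;
      if (jend >= L) jend = L - 1;
      std::map<int, int>::iterator it = site2col.lower_bound(j);
      for (; it != site2col.end() && it->first <= jend; ++it) {
        int c = it->second;
        unsigned char da = G[(size_t)c * N + d];
        unsigned char ra = G[(size_t)c * N + i];
        if (da != ra) {
          size_t sc = (size_t)c * 4;
          logfit[i] += std::log1p(s[sc + da]) - std::log1p(s[sc + ra]);
          G[(size_t)c * N + i] = da;
        }
      }
    }
  }

  void reproduce() {
    parent.resize(N);
    if (!any_selection) {
      for (int i = 0; i < N; ++i) {
        int p = (int)(unif_rand() * N); if (p == N) p = N - 1;
        parent[i] = p;
      }
    } else {
      cumw.resize(N);
      double mx = logfit[0];
      for (int i = 1; i < N; ++i) if (logfit[i] > mx) mx = logfit[i];
      double acc = 0.0;
      for (int i = 0; i < N; ++i) { acc += std::exp(logfit[i] - mx); cumw[i] = acc; }
      for (int i = 0; i < N; ++i) {
        double r = unif_rand() * acc;
        int lo = 0, hi = N - 1;
        while (lo < hi) { int mid = (lo + hi) / 2; if (cumw[mid] < r) lo = mid + 1; else hi = mid; }
        parent[i] = lo;
      }
    }
    logfit2.resize(N);
    for (int i = 0; i < N; ++i) logfit2[i] = logfit[parent[i]];
    logfit.swap(logfit2);

    // gather columns into G2, flagging columns that became monomorphic
    std::vector<int> fixed_cols;
    for (int c = 0; c < P; ++c) {
      const unsigned char* src = &G[(size_t)c * N];
      unsigned char* dst = &G2[(size_t)c * N];
      unsigned char first = src[parent[0]];
      bool allequal = true;
      for (int i = 0; i < N; ++i) {
        unsigned char v = src[parent[i]];
        dst[i] = v;
        if (v != first) allequal = false;
      }
      if (allequal) fixed_cols.push_back(c);
    }
    G.swap(G2);

    // retire monomorphic columns, highest index first so swap-with-last is safe
    for (int t = (int)fixed_cols.size() - 1; t >= 0; --t) {
      int c = fixed_cols[t];
      unsigned char a = G[(size_t)c * N];
      background[site[c]] = a;
      double sa = s[(size_t)c * 4 + a];
      if (sa != 0.0) // carried by everyone: a constant factor, rebase to 0
        for (int i = 0; i < N; ++i) logfit[i] -= std::log1p(sa);
      site2col.erase(site[c]);
      int last = P - 1;
      if (c != last) {
        std::copy(G.begin() + (size_t)last * N, G.begin() + (size_t)(last + 1) * N,
                  G.begin() + (size_t)c * N);
        site[c] = site[last];
        anc[c] = anc[last];
        for (int a2 = 0; a2 < 4; ++a2) {
          s[(size_t)c * 4 + a2] = s[(size_t)last * 4 + a2];
          s_set[(size_t)c * 4 + a2] = s_set[(size_t)last * 4 + a2];
        }
        site2col[site[c]] = c;
      }
      --P;
    }
  }
};

} // namespace

// [[Rcpp::export]]
List wf_engine_run(int N, int L, double u, int generations,
                   double p_del, double p_adv, double s_del, double s_adv,
                   double conv_ratio, double tract_mean) {
  if (N < 2) stop("N must be >= 2");
  if (L < 1) stop("L must be >= 1");
  if (u < 0 || u >= 1) stop("u must be in [0, 1)");
  Engine e;
  e.N = N; e.L = L; e.u = u;
  e.p_del = p_del; e.p_adv = p_adv; e.s_del = s_del; e.s_adv = s_adv;
  e.conv_ratio = conv_ratio; e.tract_mean = tract_mean;
  e.background.assign(L, 0);
  e.logfit.assign(N, 0.0);
  e.reserve(256);

  RNGScope scope;
  // initial background drawn uniformly over {A,C,G,T} per site
  for (int j = 0; j < L; ++j) {
    int a = (int)(unif_rand() * 4); if (a == 4) a = 3;
    e.background[j] = (unsigned char)a;
  }

  for (int g = 0; g < generations; ++g) {
    e.mutate();
    e.convert();
    e.reproduce();
    if (g % 512 == 0) Rcpp::checkUserInterrupt();
  }

  // order columns by site for a tidy R-side object
  std::vector<int> ord;
  for (std::map<int, int>::iterator it = e.site2col.begin(); it != e.site2col.end(); ++it)
    ord.push_back(it->second);

  int P = e.P;
  IntegerMatrix geno(N, P);
  IntegerVector sites(P), ancv(P);
  NumericMatrix smat(4, P);
  for (int k = 0; k < P; ++k) {
    int c = ord[k];
    sites[k] = e.site[c] + 1;
    ancv[k] = e.anc[c] + 1;
    for (int a = 0; a < 4; ++a) smat(a, k) = e.s[(size_t)c * 4 + a];
    for (int i = 0; i < N; ++i) geno(i, k) = e.G[(size_t)c * N + i] + 1;
  }
  IntegerVector bg(L);
  for (int j = 0; j < L; ++j) bg[j] = e.background[j] + 1;
  NumericVector lf(e.logfit.begin(), e.logfit.end());

  return List::create(_["background"] = bg, _["positions"] = sites,
                      _["geno"] = geno, _["anc"] = ancv, _["s"] = smat,
                      _["logfit"] = lf, _["generations"] = generations);
}

// Pairwise Hamming distances (counts of differing columns) between rows of an
// integer allele matrix; individuals sharing the monomorphic background differ
// only at polymorphic columns, so this is the full-sequence Hamming count.
// [[Rcpp::export]]
NumericMatrix hamming_counts(const IntegerMatrix& geno) {
  int n = geno.nrow(), P = geno.ncol();
  std::vector<unsigned char> M((size_t)n * P);
  for (int c = 0; c < P; ++c)
    for (int i = 0; i < n; ++i)
      M[(size_t)i * P + c] = (unsigned char)geno(i, c);
  NumericMatrix D(n, n);
  for (int i = 0; i < n; ++i) {
    const unsigned char* ri = &M[(size_t)i * P];
    for (int j = i + 1; j < n; ++j) {
      const unsigned char* rj = &M[(size_t)j * P];
      int d = 0;
      for (int c = 0; c < P; ++c) d += (ri[c] != rj[c]);
      D(i, j) = d;
      D(j, i) = d;
    }
  }
  return D;
}

// PAM (partitioning around medoids): BUILD then best-improvement SWAP until no
// single (medoid, candidate) exchange lowers the total within-cluster distance
// to medoids. Deterministic: ties broken by lowest index.
// [[Rcpp::export]]
List pam_core(const NumericMatrix& D, int k) {
  int n = D.nrow();
  if (k < 1 || k > n) stop("k out of range");
  std::vector<int> med;
  std::vector<bool> is_med(n, false);

  // BUILD: first medoid minimises total distance; then greedily add the point
  // with the largest reduction in cost.
  {
    int best = 0; double bestsum = R_PosInf;
    for (int i = 0; i < n; ++i) {
      double sum = 0.0;
      for (int j = 0; j < n; ++j) sum += D(j, i);
      if (sum < bestsum) { bestsum = sum; best = i; }
    }
    med.push_back(best); is_med[best] = true;
  }
  std::vector<double> dn(n); // distance to nearest medoid
  for (int i = 0; i < n; ++i) dn[i] = D(i, med[0]);
  while ((int)med.size() < k) {
    int best = -1; double bestgain = -1.0;
    for (int c = 0; c < n; ++c) {
      if (is_med[c]) continue;
      double gain = 0.0;
      for (int i = 0; i < n; ++i) {
        double d = D(i, c);
        if (d < dn[i]) gain += dn[i] - d;
      }
      if (gain > bestgain) { bestgain = gain; best = c; }
    }
    med.push_back(best); is_med[best] = true;
    for (int i = 0; i < n; ++i) if (D(i, best) < dn[i]) dn[i] = D(i, best);
  }

  // nearest and second-nearest medoid bookkeeping
  std::vector<int> nearest(n);
  std::vector<double> ds(n);
  int K = k;
  std::vector<double> trace;
  auto recompute = [&]() {
    // medoids kept sorted so that equidistant points attach to the
    // lowest-index medoid
    std::sort(med.begin(), med.end());
    for (int i = 0; i < n; ++i) {
      double d1 = R_PosInf, d2 = R_PosInf; int m1 = -1;
      for (int t = 0; t < K; ++t) {
        double d = D(i, med[t]);
        if (d < d1) { d2 = d1; d1 = d; m1 = t; }
        else if (d < d2) { d2 = d; }
      }
      dn[i] = d1; ds[i] = d2; nearest[i] = m1;
    }
  };
  recompute();
  double cost = 0.0;
  for (int i = 0; i < n; ++i) cost += dn[i];
  trace.push_back(cost);

  for (;;) {
    double bestdelta = -1e-12; int bestm = -1, bestc = -1;
    for (int t = 0; t < K; ++t) {
      for (int c = 0; c < n; ++c) {
        if (is_med[c]) continue;
        double delta = 0.0;
        for (int i = 0; i < n; ++i) {
          double dic = D(i, c);
          if (nearest[i] == t) delta += std::min(ds[i], dic) - dn[i];
          else if (dic < dn[i]) delta += dic - dn[i];
        }
        if (delta < bestdelta) { bestdelta = delta; bestm = t; bestc = c; }
      }
    }
    if (bestm < 0) break;
    is_med[med[bestm]] = false;
    med[bestm] = bestc;
    is_med[bestc] = true;
    recompute();
    cost = 0.0;
    for (int i = 0; i < n; ++i) cost += dn[i];
    trace.push_back(cost);
  }

  IntegerVector medv(K), assign(n);
  for (int t = 0; t < K; ++t) medv[t] = med[t] + 1;
  for (int i = 0; i < n; ++i) assign[i] = nearest[i] + 1;
  return List::create(_["medoids"] = medv, _["assignment"] = assign,
                      _["cost"] = cost, _["cost_trace"] = NumericVector(trace.begin(), trace.end()));
}
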