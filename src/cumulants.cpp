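// Spatio-temporal cross-cumulant engine (SOFI orders 2..6).
//
// For a virtual pixel at sub-position (a/n, b/n) inside a raw pixel, n
// distinct raw pixels are chosen whose coordinate sum equals (a, b) modulo
// the raw pixel (so their centroid is the virtual position), minimising the
// total pairwise squared separation. The order-n joint cumulant of the n
// mean-subtracted pixel traces (zero time lag) is computed as the cumulant
// of the empirical distribution (plug-in estimator) via the partition
// formula; only partitions with all blocks of size >= 2 contribute because
// sample-centred traces have exactly zero mean. The result is divided by
// the Gaussian distance factor exp(-sum_{k<l}|r_k-r_l|^2 / (2 n sigma^2)).
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <map>
#include <functional>
using namespace Rcpp;

struct Combo {
  std::vector<int> dy, dx;  // n offsets
  double pair_d2;           // sum of pairwise squared separations (px^2)
};

// best pixel combinations per (a, b) for one order, cached per order
static std::map<int, std::vector<Combo> > combo_cache;

static void search_combos(int n, std::vector<Combo> &out) {
  // candidate offsets in a 5x5 neighbourhood
  std::vector<int> cy, cx;
  for (int dy = -2; dy <= 2; ++dy)
    for (int dx = -2; dx <= 2; ++dx) {
      cy.push_back(dy);
      cx.push_back(dx);
    }
  const int m = (int)cy.size();
  out.assign(n * n, Combo());
  std::vector<double> best(n * n, R_PosInf);
  std::vector<int> pick(n);
  // enumerate combinations of n distinct candidates (lexicographic)
  std::function<void(int, int)> rec = [&](int start, int depth) {
    if (depth == n) {
      int sy = 0, sx = 0;
      double s2 = 0;
      for (int k = 0; k < n; ++k) {
        sy += cy[pick[k]];
        sx += cx[pick[k]];
        s2 += cy[pick[k]] * cy[pick[k]] + cx[pick[k]] * cx[pick[k]];
      }
      if (sy < 0 || sy >= n || sx < 0 || sx >= n) return;
      // sum of pairwise squared distances = n*sum|r|^2 - |sum r|^2
      double d2 = n * s2 - (double)(sy * sy + sx * sx);
      int cell = sy * n + sx;
      if (d2 < best[cell] - 1e-12) {
        best[cell] = d2;
        Combo c;
        c.pair_d2 = d2;
        for (int k = 0; k < n; ++k) {
          c.dy.push_back(cy[pick[k]]);
          c.dx.push_back(cx[pick[k]]);
        }
        out[cell] = c;
      }
      return;
    }
    for (int i = start; i < m; ++i) {
      pick[depth] = i;
      rec(i + 1, depth + 1);
    }
  };
  rec(0, 0);
}

static const std::vector<Combo> &get_combos(int n) {
  auto it = combo_cache.find(n);
  if (it == combo_cache.end()) {
    std::vector<Combo> v;
    search_combos(n, v);
    it = combo_cache.insert(std::make_pair(n, v)).first;
  }
  return it->second;
}

// set partitions of {0..n-1} with all blocks of size >= 2, as bit masks
static void gen_partitions(int remaining, std::vector<int> &blocks,
                           std::vector<std::vector<int> > &out) {
  if (remaining == 0) {
    out.push_back(blocks);
    return;
  }
  int lo = remaining & (-remaining);  // lowest element must lead its block
  int rest = remaining ^ lo;
  // enumerate subsets s of rest; block = lo | s with popcount >= 2
  for (int s = rest;; s = (s - 1) & rest) {
    int block = lo | s;
    if (__builtin_popcount(block) >= 2) {
      blocks.push_back(block);
      gen_partitions(remaining ^ block, blocks, out);
      blocks.pop_back();
    }
    if (s == 0) break;
  }
}

static std::map<int, std::vector<std::vector<int> > > part_cache;
static const std::vector<std::vector<int> > &get_partitions(int n) {
  auto it = part_cache.find(n);
  if (it == part_cache.end()) {
    std::vector<std::vector<int> > v;
    std::vector<int> blocks;
    gen_partitions((1 << n) - 1, blocks, v);
    it = part_cache.insert(std::make_pair(n, v)).first;
  }
  return it->second;
}

template <int N>
static void accumulate_moments(const double *const *tr, int T, double *m,
                               std::vector<double> &work) {
  const int NS = 1 << N;
  // subset-product traces, built up by lowest set bit; elementwise
  // multiplies over contiguous time vectors so the compiler can vectorise
  work.resize((size_t)NS * T);
  double *v = work.data();
  for (int s = 1; s < NS; ++s) {
    const int l = s & (-s);
    const int idx = __builtin_ctz(l);
    const int hi = s ^ l;
    const double *src = tr[idx];
    double sum = 0.0;
    if (s & 1) {
      // subsets containing element 0 are never parents: sum only
      if (hi == 0) {
        for (int t = 0; t < T; ++t) sum += src[t];
      } else {
        const double *par = v + (size_t)hi * T;
        for (int t = 0; t < T; ++t) sum += par[t] * src[t];
      }
    } else {
      double *dst = v + (size_t)s * T;
      if (hi == 0) {
        for (int t = 0; t < T; ++t) {
          dst[t] = src[t];
          sum += dst[t];
        }
      } else {
        const double *par = v + (size_t)hi * T;
        for (int t = 0; t < T; ++t) {
          dst[t] = par[t] * src[t];
          sum += dst[t];
        }
      }
    }
    m[s] = sum / T;
  }
}

static double fact(int k) {
  double f = 1;
  for (int i = 2; i <= k; ++i) f *= i;
  return f;
}

// [[Rcpp::export]]
NumericMatrix cpp_cumulant_image(NumericVector frames, int ny, int nx, int T,
                                 int order, double sigma_px) {
  if (order < 2 || order > 6) stop("cumulant order must be in 2..6");
  if (T < 2) stop("need at least 2 frames");
  const int n = order;
  const std::vector<Combo> &combos = get_combos(n);
  const std::vector<std::vector<int> > &parts = get_partitions(n);
  // centred traces, contiguous in time: tr[p*T + t]
  const R_xlen_t np = (R_xlen_t)ny * nx;
  std::vector<double> tr(np * T);
  for (R_xlen_t p = 0; p < np; ++p) {
    double mean = 0;
    for (int t = 0; t < T; ++t) mean += frames[p + np * t];
    mean /= T;
    double *dst = &tr[p * T];
    for (int t = 0; t < T; ++t) dst[t] = frames[p + np * t] - mean;
  }
  const int margin = 2;
  NumericMatrix out(n * ny, n * nx);
  const double *trp[6];
  double m[1 << 6];
  std::vector<double> work;
  // per-cell distance-factor gains
  std::vector<double> gain(n * n);
  for (int c = 0; c < n * n; ++c)
    gain[c] = std::exp(combos[c].pair_d2 / (2.0 * n * sigma_px * sigma_px));
  // partition signs/factorials
  std::vector<double> pw(parts.size());
  for (size_t q = 0; q < parts.size(); ++q) {
    int len = (int)parts[q].size();
    pw[q] = ((len - 1) % 2 == 0 ? 1.0 : -1.0) * fact(len - 1);
  }
  for (int a = 0; a < n; ++a) {
    for (int b = 0; b < n; ++b) {
      const Combo &cb = combos[a * n + b];
      const double g = gain[a * n + b];
      for (int j = margin; j < nx - margin; ++j) {
        for (int i = margin; i < ny - margin; ++i) {
          for (int k = 0; k < n; ++k)
            trp[k] = &tr[((R_xlen_t)(i + cb.dy[k]) +
                          (R_xlen_t)ny * (j + cb.dx[k])) * T];
          switch (n) {
            case 2: accumulate_moments<2>(trp, T, m, work); break;
            case 3: accumulate_moments<3>(trp, T, m, work); break;
            case 4: accumulate_moments<4>(trp, T, m, work); break;
            case 5: accumulate_moments<5>(trp, T, m, work); break;
            default: accumulate_moments<6>(trp, T, m, work); break;
          }
          double kappa = 0;
          for (size_t q = 0; q < parts.size(); ++q) {
            double prod = pw[q];
            for (int blk : parts[q]) prod *= m[blk];
            kappa += prod;
          }
          out(i * n + a, j * n + b) = kappa * g;
        }
      }
    }
  }
  return out;
}

// pixel combinations used for a given order (for documentation/tests)
// [[Rcpp::export]]
List cpp_cumulant_combinations(int order) {
  const std::vector<Combo> &combos = get_combos(order);
  List out(order * order);
  for (int a = 0; a < order; ++a)
    for (int b = 0; b < order; ++b) {
      const Combo &c = combos[a * order + b];
      out[a * order + b] = List::create(
          _["a"] = a, _["b"] = b,
          _["dy"] = IntegerVector(c.dy.begin(), c.dy.end()),
          _["dx"] = IntegerVector(c.dx.begin(), c.dx.end()),
          _["pair_d2"] = c.pair_d2);
    }
  return out;
}

// Algebraic leave-one-frame-out jackknife of the order-2 cross-cumulant
// image: returns the full cumulant image and the jackknife variance image
// on the 2x virtual grid.
// [[Rcpp::export]]
List cpp_sofi2_jackknife(NumericVector frames, int ny, int nx, int T,
                         double sigma_px) {
  if (T < 3) stop("need at least 3 frames");
  const int n = 2;
  const std::vector<Combo> &combos = get_combos(n);
  const R_xlen_t np = (R_xlen_t)ny * nx;
  std::vector<double> tr(np * T);
  for (R_xlen_t p = 0; p < np; ++p) {
    double mean = 0;
    for (int t = 0; t < T; ++t) mean += frames[p + np * t];
    mean /= T;
    double *dst = &tr[p * T];
    for (int t = 0; t < T; ++t) dst[t] = frames[p + np * t] - mean;
  }
  const int margin = 2;
  NumericMatrix full(n * ny, n * nx), varim(n * ny, n * nx);
  for (int a = 0; a < n; ++a) {
    for (int b = 0; b < n; ++b) {
      const Combo &cb = combos[a * n + b];
      double g = std::exp(cb.pair_d2 / (2.0 * n * sigma_px * sigma_px));
      for (int j = margin; j < nx - margin; ++j) {
        for (int i = margin; i < ny - margin; ++i) {
          const double *u = &tr[((R_xlen_t)(i + cb.dy[0]) +
                                 (R_xlen_t)ny * (j + cb.dx[0])) * T];
          const double *v = &tr[((R_xlen_t)(i + cb.dy[1]) +
                                 (R_xlen_t)ny * (j + cb.dx[1])) * T];
          double suv = 0;  // sums of centred traces: su = sv = 0 by constr.
          for (int t = 0; t < T; ++t) suv += u[t] * v[t];
          double kfull = suv / T;
          // leave-one-out: traces re-centred without frame t
          double s1 = 0, s2 = 0;
          for (int t = 0; t < T; ++t) {
            double ki = (suv - u[t] * v[t]) / (T - 1) -
                        (-u[t]) * (-v[t]) / ((double)(T - 1) * (T - 1));
            s1 += ki;
            s2 += ki * ki;
          }
          double meank = s1 / T;
          double var = (double)(T - 1) / T * (s2 - T * meank * meank);
          full(i * n + a, j * n + b) = kfull * g;
          varim(i * n + a, j * n + b) = var * g * g;
        }
      }
    }
  }
  return List::create(_["image"] = full, _["var"] = varim);
}
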