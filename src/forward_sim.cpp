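// Forward-in-time Wright-Fisher simulation of one chromosome with an
// arbitrary piecewise-constant recombination map, neutral and deleterious
// mutations (no beneficial ones), multiplicative fitness across sites and
// discrete non-overlapping generations. Haplotypes are sparse sorted lists
// of mutation ids; all randomness comes from R's RNG so runs are fully
// reproducible under set.seed().

#include <Rcpp.h>
#include <unordered_set>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Hap {
  std::vector<int> neu;  // neutral mutation ids, sorted by position
  std::vector<int> del;  // deleterious mutation ids, sorted by position
};

struct MutTable {
  std::vector<int> pos;      // integer bp, unique while segregating
  std::vector<double> sel;   // selection coefficient (0 for neutral)
  std::vector<int> origin;   // generation of origin
};

// insert id into a position-sorted id list
inline void insert_sorted(std::vector<int> &v, int id,
                          const std::vector<int> &pos) {
  auto it = std::lower_bound(v.begin(), v.end(), id,
      [&pos](int a, int b) { return pos[a] < pos[b]; });
  v.insert(it, id);
}

// copy elements of src with position inside [lo, hi) into dst (appending)
inline void copy_range(const std::vector<int> &src, std::vector<int> &dst,
                       double lo, double hi, const std::vector<int> &pos) {
  for (int id : src) {
    double p = pos[id];
    if (p >= hi) break;
    if (p >= lo) dst.push_back(id);
  }
}

}  // namespace

// Build one gamete from the two haplotypes of parent `pi` into `child`.
static void make_gamete(const std::vector<Hap> &popn, int pi,
                        const NumericVector &map_start,
                        const NumericVector &map_end,
                        const NumericVector &map_rate,
                        Hap &child, const MutTable &mt) {
  child.neu.clear();
  child.del.clear();
  // crossover breakpoints: Poisson count per map interval, uniform within
  std::vector<double> bks;
  for (int k = 0; k < map_start.size(); ++k) {
    double lam = map_rate[k] * (map_end[k] - map_start[k]);
    if (lam <= 0) continue;
    int cnt = (int)R::rpois(lam);
    for (int c = 0; c < cnt; ++c)
      bks.push_back(map_start[k] + R::unif_rand() * (map_end[k] - map_start[k]));
  }
  const Hap &A = popn[2 * pi];
  const Hap &B = popn[2 * pi + 1];
  bool from_a = R::unif_rand() < 0.5;
  if (bks.empty()) {
    const Hap &src = from_a ? A : B;
    child.neu = src.neu;
    child.del = src.del;
    return;
  }
  std::sort(bks.begin(), bks.end());
  bks.push_back(R_PosInf);
  double lo = R_NegInf;
  for (double hi : bks) {
    const Hap &src = from_a ? A : B;
    copy_range(src.neu, child.neu, lo, hi, mt.pos);
    copy_range(src.del, child.del, lo, hi, mt.pos);
    from_a = !from_a;
    lo = hi;
  }
}

// multiplicative fitness of individual (h1, h2) over its deleterious sites
static double diploid_fitness(const Hap &h1, const Hap &h2, double h,
                              const MutTable &mt) {
  double w = 1.0;
  size_t i = 0, j = 0;
  const std::vector<int> &a = h1.del;
  const std::vector<int> &b = h2.del;
  while (i < a.size() || j < b.size()) {
    if (j == b.size() || (i < a.size() && mt.pos[a[i]] < mt.pos[b[j]])) {
      w *= 1.0 + h * mt.sel[a[i]];
      ++i;
    } else if (i == a.size() || mt.pos[b[j]] < mt.pos[a[i]]) {
      w *= 1.0 + h * mt.sel[b[j]];
      ++j;
    } else {  // same id: homozygous
      w *= 1.0 + mt.sel[a[i]];
      ++i; ++j;
    }
    if (w <= 0) return 0.0;
  }
  return w;
}

// prune fixed mutations (recording substitutions) and rebuild the used-
// position set from surviving + substituted positions
static void prune(std::vector<Hap> &popn, MutTable &mt,
                  std::unordered_set<int> &used, int gen,
                  std::vector<int> &sub_pos, std::vector<double> &sub_sel,
                  std::vector<int> &sub_origin, std::vector<int> &sub_gen) {
  int M = (int)mt.pos.size();
  std::vector<int> cnt(M, 0);
  for (const Hap &hp : popn) {
    for (int id : hp.neu) ++cnt[id];
    for (int id : hp.del) ++cnt[id];
  }
  int two_n = (int)popn.size();
  std::vector<char> fixed(M, 0);
  bool any_fixed = false;
  for (int id = 0; id < M; ++id) {
    if (cnt[id] == two_n) {
      fixed[id] = 1;
      any_fixed = true;
      sub_pos.push_back(mt.pos[id]);
      sub_sel.push_back(mt.sel[id]);
      sub_origin.push_back(mt.origin[id]);
      sub_gen.push_back(gen);
    }
  }
  if (any_fixed) {
    for (Hap &hp : popn) {
      hp.neu.erase(std::remove_if(hp.neu.begin(), hp.neu.end(),
                   [&fixed](int id) { return fixed[id]; }), hp.neu.end());
      hp.del.erase(std::remove_if(hp.del.begin(), hp.del.end(),
                   [&fixed](int id) { return fixed[id]; }), hp.del.end());
    }
  }
  used.clear();
  for (int id = 0; id < M; ++id)
    if (cnt[id] > 0 && !fixed[id]) used.insert(mt.pos[id]);
  for (int p : sub_pos) used.insert(p);
}

// [[Rcpp::export(name = ".cpp_run_simulation")]]
List cpp_run_simulation(int N, double L, double mu,
                        NumericVector map_start, NumericVector map_end,
                        NumericVector map_rate,
                        double p_del, double s_mean, double s_shape,
                        double h, int generations, int sample_n,
                        IntegerVector init_pos, IntegerVector init_count,
                        NumericVector init_sel, int prune_every = 50) {
  if (N < 2) stop("N must be >= 2");
  if (sample_n > 2 * N) stop("sample_n must be <= 2N");
  int two_n = 2 * N;
  std::vector<Hap> popn(two_n), nextg(two_n);
  MutTable mt;
  std::unordered_set<int> used;
  std::vector<int> sub_pos, sub_origin, sub_gen;
  std::vector<double> sub_sel;

  // optional initial standing variants (validation harness)
  for (int k = 0; k < init_pos.size(); ++k) {
    int id = (int)mt.pos.size();
    mt.pos.push_back(init_pos[k]);
    mt.sel.push_back(init_sel[k]);
    mt.origin.push_back(0);
    used.insert(init_pos[k]);
    // place in init_count[k] distinct haplotypes (partial Fisher-Yates)
    std::vector<int> idx(two_n);
    for (int i = 0; i < two_n; ++i) idx[i] = i;
    int c = std::min<int>(init_count[k], two_n);
    for (int i = 0; i < c; ++i) {
      int j = i + (int)(R::unif_rand() * (two_n - i));
      std::swap(idx[i], idx[j]);
      Hap &hp = popn[idx[i]];
      if (init_sel[k] == 0) insert_sorted(hp.neu, id, mt.pos);
      else insert_sorted(hp.del, id, mt.pos);
    }
  }

  std::vector<double> cumw(N);
  double mu_L = mu * L;
  for (int gen = 1; gen <= generations; ++gen) {
    // fitness and cumulative weights
    double tot = 0;
    for (int i = 0; i < N; ++i) {
      tot += diploid_fitness(popn[2 * i], popn[2 * i + 1], h, mt);
      cumw[i] = tot;
    }
    if (tot <= 0 || !R_finite(tot))
      stop("mean fitness underflow at generation %d (excess deleterious load)",
           gen);
    // next generation: N offspring, two fitness-weighted parents each
    for (int off = 0; off < N; ++off) {
      for (int g = 0; g < 2; ++g) {
        double u = R::unif_rand() * tot;
        int pi = (int)(std::lower_bound(cumw.begin(), cumw.end(), u) -
                       cumw.begin());
        if (pi >= N) pi = N - 1;
        Hap &child = nextg[2 * off + g];
        make_gamete(popn, pi, map_start, map_end, map_rate, child, mt);
        // new mutations: Poisson(mu*L), uniform integer bp, redraw on
        // collision (infinite-sites approximation)
        int nmut = mu_L > 0 ? (int)R::rpois(mu_L) : 0;
        for (int m = 0; m < nmut; ++m) {
          int p;
          int guard = 0;
          do {
            p = (int)(R::unif_rand() * L);
            if (++guard > 1000000) stop("cannot place mutation: chromosome saturated");
          } while (used.count(p));
          used.insert(p);
          int id = (int)mt.pos.size();
          double s = 0.0;
          if (p_del > 0 && R::unif_rand() < p_del) {
            s = (s_shape > 0)
                ? -R::rgamma(s_shape, -s_mean / s_shape)
                : s_mean;
            if (s <= -1.0) s = -0.999999;  // hard floor: lethal at most
          }
          mt.pos.push_back(p);
          mt.sel.push_back(s);
          mt.origin.push_back(gen);
          if (s == 0) insert_sorted(child.neu, id, mt.pos);
          else insert_sorted(child.del, id, mt.pos);
        }
      }
    }
    std::swap(popn, nextg);
    if (gen % prune_every == 0)
      prune(popn, mt, used, gen, sub_pos, sub_sel, sub_origin, sub_gen);
    if (gen % 200 == 0) Rcpp::checkUserInterrupt();
  }
  prune(popn, mt, used, generations, sub_pos, sub_sel, sub_origin, sub_gen);

  // sample haplotypes without replacement
  std::vector<int> idx(two_n);
  for (int i = 0; i < two_n; ++i) idx[i] = i;
  for (int i = 0; i < sample_n; ++i) {
    int j = i + (int)(R::unif_rand() * (two_n - i));
    std::swap(idx[i], idx[j]);
  }
  // mutations present in the sample, ordered by position
  std::vector<int> present;
  {
    std::vector<char> seen(mt.pos.size(), 0);
    for (int i = 0; i < sample_n; ++i) {
      const Hap &hp = popn[idx[i]];
      for (int id : hp.neu) seen[id] = 1;
      for (int id : hp.del) seen[id] = 1;
    }
    for (int id = 0; id < (int)mt.pos.size(); ++id)
      if (seen[id]) present.push_back(id);
    std::sort(present.begin(), present.end(),
              [&](int a, int b) { return mt.pos[a] < mt.pos[b]; });
  }
  int S = (int)present.size();
  std::vector<int> col(mt.pos.size(), -1);
  for (int c = 0; c < S; ++c) col[present[c]] = c;
  IntegerMatrix alleles(sample_n, S);
  for (int i = 0; i < sample_n; ++i) {
    const Hap &hp = popn[idx[i]];
    for (int id : hp.neu) alleles(i, col[id]) = 1;
    for (int id : hp.del) alleles(i, col[id]) = 1;
  }
  IntegerVector mpos(S), morig(S);
  NumericVector msel(S);
  for (int c = 0; c < S; ++c) {
    mpos[c] = mt.pos[present[c]];
    msel[c] = mt.sel[present[c]];
    morig[c] = mt.origin[present[c]];
  }
  return List::create(
      _["positions"] = mpos, _["sel"] = msel, _["origin"] = morig,
      _["alleles"] = alleles,
      _["sub_positions"] = wrap(sub_pos), _["sub_sel"] = wrap(sub_sel),
      _["sub_origin"] = wrap(sub_origin), _["sub_gen"] = wrap(sub_gen));
}
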