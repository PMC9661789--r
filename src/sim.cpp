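// Forward Wright-Fisher simulator with partial selfing, bottlenecked splits,
// infinite-sites mutation and planted logistic selective sweeps.
//
// Three demes on a fixed tree: wild -> progenitor -> ecotype. Haplotypes are
// stored hap-major in flat uint8 buffers with a shared site registry, so a new
// mutation appends one column to every living deme. All randomness comes from
// one std::mt19937_64 stream with hand-rolled uniform/Poisson draws, so runs
// are bit-reproducible across platforms (std::poisson_distribution is
// implementation-defined and deliberately avoided).

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
#include <unordered_map>
#include <random>
#include <algorithm>

using namespace Rcpp;

namespace {

struct Rng {
  std::mt19937_64 eng;
  explicit Rng(uint64_t seed) : eng(seed) {}
  double unif() { return (eng() >> 11) * (1.0 / 9007199254740992.0); }
  // uniform integer in [0, n)
  int uint(int n) { return (int)(unif() * n) % n; }
  int poisson(double lambda) {
    // Knuth's method, chunked to dodge exp() underflow for large lambda
    int total = 0;
    while (lambda > 500.0) {
      total += poisson(500.0);
      lambda -= 500.0;
    }
    double L = std::exp(-lambda), p = 1.0;
    int k = 0;
    do {
      ++k;
      p *= unif();
    } while (p > L);
    return total + k - 1;
  }
};

struct Deme {
  bool alive = false;
  int nhap = 0;                 // 2 * current diploid count
  std::vector<uint8_t> H;       // nhap x cap, hap-major
  std::vector<uint8_t> buf;     // scratch for the next generation
};

struct Sweep {
  int chrom;          // 0-based
  int lo, hi;         // window [lo, hi] in bp, 1-based inclusive
  int target;         // deme index
  int status;         // 0 pending, 1 planted, -1 skipped
  std::vector<long long> keys;     // donor profile site keys
  std::vector<uint8_t> alleles;    // donor alleles at those sites
};

class Sim {
public:
  int n_chrom;
  long long L;
  double mu, recomb, selfing;
  Rng rng;
  int S = 0, cap = 256;
  std::vector<int> s_chrom, s_pos, s_opop, s_ogen;
  std::unordered_map<long long, int> site_idx;
  std::vector<Deme> deme{3};
  int gen = 0;

  Sim(int nc, long long len, double mu_, double rec_, double self_, uint64_t seed)
    : n_chrom(nc), L(len), mu(mu_), recomb(rec_), selfing(self_), rng(seed) {}

  long long key(int c, int p) const { return (long long)c * (L + 2) + p; }

  void ensure_cap() {
    if (S < cap) return;
    int nc = cap * 2;
    for (auto &d : deme) {
      if (!d.alive) continue;
      std::vector<uint8_t> nh((size_t)d.nhap * nc, 0);
      for (int h = 0; h < d.nhap; ++h)
        std::copy(d.H.begin() + (size_t)h * cap, d.H.begin() + (size_t)h * cap + S,
                  nh.begin() + (size_t)h * nc);
      d.H.swap(nh);
      d.buf.assign((size_t)d.nhap * nc, 0);
    }
    cap = nc;
  }

  // append a site carried by hap `hap` of deme `p`
  void add_site(int c, int pos, int p, int hap) {
    ensure_cap();
    for (auto &d : deme) {
      if (!d.alive) continue;
      for (int h = 0; h < d.nhap; ++h) d.H[(size_t)h * cap + S] = 0;
    }
    deme[p].H[(size_t)hap * cap + S] = 1;
    s_chrom.push_back(c);
    s_pos.push_back(pos);
    s_opop.push_back(p);
    s_ogen.push_back(gen);
    site_idx[key(c, pos)] = S;
    ++S;
  }

  void found(int child, int parent, int n_founders) {
    Deme &P = deme[parent], &C = deme[child];
    int NP = P.nhap / 2;
    if (n_founders > NP) n_founders = NP;
    std::vector<int> ids(NP);
    for (int i = 0; i < NP; ++i) ids[i] = i;
    for (int i = 0; i < n_founders; ++i) std::swap(ids[i], ids[i + rng.uint(NP - i)]);
    C.alive = true;
    C.nhap = 2 * n_founders;
    C.H.assign((size_t)C.nhap * cap, 0);
    C.buf.assign((size_t)C.nhap * cap, 0);
    for (int i = 0; i < n_founders; ++i)
      for (int w = 0; w < 2; ++w)
        std::copy(P.H.begin() + (size_t)(2 * ids[i] + w) * cap,
                  P.H.begin() + (size_t)(2 * ids[i] + w) * cap + S,
                  C.H.begin() + (size_t)(2 * i + w) * cap);
  }

  void gamete(const Deme &d, int parent, uint8_t *dest) {
    // per-chromosome random start haplotype + Poisson crossovers
    static thread_local std::vector<int> start;
    static thread_local std::vector<std::vector<int>> bp;
    start.assign(n_chrom, 0);
    if ((int)bp.size() < n_chrom) bp.resize(n_chrom);
    bool any_bp = false;
    for (int c = 0; c < n_chrom; ++c) {
      start[c] = rng.uint(2);
      bp[c].clear();
      int k = recomb > 0 ? rng.poisson(recomb * (double)L) : 0;
      for (int j = 0; j < k; ++j) bp[c].push_back(1 + rng.uint((int)L));
      if (k) { std::sort(bp[c].begin(), bp[c].end()); any_bp = true; }
    }
    const uint8_t *a = d.H.data() + (size_t)(2 * parent) * cap;
    const uint8_t *b = a + cap;
    if (!any_bp) {
      for (int s = 0; s < S; ++s) dest[s] = start[s_chrom[s]] ? b[s] : a[s];
      return;
    }
    for (int s = 0; s < S; ++s) {
      int c = s_chrom[s];
      int cnt = (int)(std::upper_bound(bp[c].begin(), bp[c].end(), s_pos[s]) -
                      bp[c].begin());
      dest[s] = ((start[c] + cnt) & 1) ? b[s] : a[s];
    }
  }

  void reproduce(int p, int n_children) {
    Deme &d = deme[p];
    int NP = d.nhap / 2;
    size_t need = (size_t)(2 * n_children) * cap;
    if (d.buf.size() < need) d.buf.resize(need);
    for (int i = 0; i < n_children; ++i) {
      int p1 = rng.uint(NP);
      int p2 = (rng.unif() < selfing) ? p1 : rng.uint(NP);
      gamete(d, p1, d.buf.data() + (size_t)(2 * i) * cap);
      gamete(d, p2, d.buf.data() + (size_t)(2 * i + 1) * cap);
    }
    d.H.swap(d.buf);
    d.nhap = 2 * n_children;
  }

  double mu_post = -1.0;  // mutation rate after burn-in; < 0 means same as mu
  int burnin_gen = 0;

  void mutate(int p) {
    Deme &d = deme[p];
    double m = (mu_post >= 0.0 && gen > burnin_gen) ? mu_post : mu;
    double lambda = (double)d.nhap * m * (double)L * (double)n_chrom;
    if (lambda <= 0.0) return;
    int n = rng.poisson(lambda);
    for (int j = 0; j < n; ++j) {
      int c = rng.uint(n_chrom);
      int pos = 1 + rng.uint((int)L);
      if (site_idx.count(key(c, pos))) { --j; continue; }  // infinite sites
      add_site(c, pos, p, rng.uint(d.nhap));
    }
  }

  void purge() {
    if (S == 0) return;
    std::vector<long long> cnt(S, 0);
    long long tot_hap = 0;
    for (auto &d : deme) {
      if (!d.alive) continue;
      tot_hap += d.nhap;
      for (int h = 0; h < d.nhap; ++h) {
        const uint8_t *row = d.H.data() + (size_t)h * cap;
        for (int s = 0; s < S; ++s) cnt[s] += row[s];
      }
    }
    std::vector<int> keep;
    keep.reserve(S);
    for (int s = 0; s < S; ++s)
      if (cnt[s] > 0 && cnt[s] < tot_hap) keep.push_back(s);
    if ((int)keep.size() == S) return;
    for (auto &d : deme) {
      if (!d.alive) continue;
      for (int h = 0; h < d.nhap; ++h) {
        uint8_t *row = d.H.data() + (size_t)h * cap;
        for (size_t j = 0; j < keep.size(); ++j) row[j] = row[keep[j]];
      }
    }
    auto compact_i = [&](std::vector<int> &v) {
      for (size_t j = 0; j < keep.size(); ++j) v[j] = v[keep[j]];
      v.resize(keep.size());
    };
    compact_i(s_chrom); compact_i(s_pos); compact_i(s_opop); compact_i(s_ogen);
    S = (int)keep.size();
    site_idx.clear();
    for (int s = 0; s < S; ++s) site_idx[key(s_chrom[s], s_pos[s])] = s;
  }

  void enforce_sweep(Sweep &sw, double f) {
    Deme &d = deme[sw.target];
    if (!d.alive) return;
    if (sw.status == 0) {
      // pick donor: require >= 1 site segregating in the window in the target
      std::vector<int> win;
      for (int s = 0; s < S; ++s)
        if (s_chrom[s] == sw.chrom && s_pos[s] >= sw.lo && s_pos[s] <= sw.hi)
          win.push_back(s);
      bool seg = false;
      for (int s : win) {
        int c0 = 0;
        for (int h = 0; h < d.nhap; ++h) c0 += d.H[(size_t)h * cap + s];
        if (c0 > 0 && c0 < d.nhap) { seg = true; break; }
      }
      if (!seg) { sw.status = -1; return; }
      int donor = rng.uint(d.nhap);
      for (int s : win) {
        sw.keys.push_back(key(s_chrom[s], s_pos[s]));
        sw.alleles.push_back(d.H[(size_t)donor * cap + s]);
      }
      sw.status = 1;
    }
    if (sw.status != 1) return;
    // resolve profile keys to current indices (purging shifts them)
    std::vector<int> idx;
    std::vector<uint8_t> al;
    for (size_t j = 0; j < sw.keys.size(); ++j) {
      auto it = site_idx.find(sw.keys[j]);
      if (it != site_idx.end()) { idx.push_back(it->second); al.push_back(sw.alleles[j]); }
    }
    if (idx.empty()) return;
    int m = (int)std::lround(f * d.nhap);
    if (m > d.nhap) m = d.nhap;
    std::vector<int> noncar;
    int first_carrier = -1, carriers = 0;
    for (int h = 0; h < d.nhap; ++h) {
      bool carry = true;
      const uint8_t *row = d.H.data() + (size_t)h * cap;
      for (size_t j = 0; j < idx.size(); ++j)
        if (row[idx[j]] != al[j]) { carry = false; break; }
      if (carry) { ++carriers; if (first_carrier < 0) first_carrier = h; }
      else noncar.push_back(h);
    }
    // hitchhiking: conversion copies the whole current window segment of an
    // actual carrier (incl. post-planting mutations on the swept background),
    // not just the plant-time profile sites
    std::vector<int> win_idx;
    std::vector<uint8_t> win_al;
    for (int s = 0; s < S; ++s)
      if (s_chrom[s] == sw.chrom && s_pos[s] >= sw.lo && s_pos[s] <= sw.hi)
        win_idx.push_back(s);
    if (first_carrier >= 0) {
      const uint8_t *tmpl = d.H.data() + (size_t)first_carrier * cap;
      for (int s : win_idx) win_al.push_back(tmpl[s]);
    } else {           // no carrier left: rebuild from the stored profile
      win_idx = idx;
      win_al = al;
    }
    int need = m - carriers;
    for (int j = 0; j < need && !noncar.empty(); ++j) {
      int pick = rng.uint((int)noncar.size());
      uint8_t *row = d.H.data() + (size_t)noncar[pick] * cap;
      for (size_t t = 0; t < win_idx.size(); ++t) row[win_idx[t]] = win_al[t];
      noncar[pick] = noncar.back();
      noncar.pop_back();
    }
  }
};

double sweep_traj(double u, double f0, double fend) {
  auto g = [](double x) { return 1.0 / (1.0 + std::exp(-12.0 * (x - 0.5))); };
  double lo = g(0.0), hi = g(1.0);
  return f0 + (fend - f0) * (g(u) - lo) / (hi - lo);
}

} // namespace

// [[Rcpp::export(name = ".wf_sim_cpp")]]
List wf_sim_cpp(int n_chrom, double chrom_len,
                int n_wild, int n_prog, int n_eco,
                int burnin, int t_prog, int t_eco,
                int bottleneck_size, int bottleneck_duration,
                double mu, double recomb, double selfing,
                IntegerVector sweep_chrom, NumericVector sweep_center,
                NumericVector sweep_width, IntegerVector sweep_target,
                double sweep_strength, int sweep_generations,
                int out_wild, int out_prog, int out_eco,
                double seed, double mu_post) {
  Sim sim(n_chrom, (long long)chrom_len, mu, recomb, selfing, (uint64_t)seed);
  sim.mu_post = mu_post;
  sim.burnin_gen = burnin;
  sim.deme[0].alive = true;
  sim.deme[0].nhap = 2 * n_wild;
  sim.deme[0].H.assign((size_t)2 * n_wild * sim.cap, 0);
  sim.deme[0].buf.assign((size_t)2 * n_wild * sim.cap, 0);

  bool have_prog = (t_prog + t_eco) > 0 && n_prog > 0;
  bool have_eco = t_eco > 0 && n_eco > 0;
  int G1 = burnin, G2 = burnin + t_prog;
  int total = burnin + t_prog + t_eco;

  std::vector<Sweep> sweeps;
  for (int i = 0; i < sweep_chrom.size(); ++i) {
    Sweep sw;
    sw.chrom = sweep_chrom[i] - 1;
    sw.lo = (int)(sweep_center[i] - sweep_width[i] / 2.0);
    sw.hi = (int)(sweep_center[i] + sweep_width[i] / 2.0);
    if (sw.lo < 1) sw.lo = 1;
    if (sw.hi > chrom_len) sw.hi = (int)chrom_len;
    sw.target = sweep_target[i];
    sw.status = 0;
    sweeps.push_back(sw);
  }
  double fend = sweep_strength >= 1.0 ? std::sqrt(1.0 - 1.0 / sweep_strength) : 0.0;
  if (fend > 0.98) fend = 0.98;
  int t_plant = total - sweep_generations;
  if (t_plant < 1) t_plant = 1;

  for (sim.gen = 1; sim.gen <= total; ++sim.gen) {
    int g = sim.gen;
    // size schedule
    sim.reproduce(0, n_wild);
    if (sim.deme[1].alive) {
      int age = g - G1;
      sim.reproduce(1, age <= bottleneck_duration ? std::min(bottleneck_size, n_prog) : n_prog);
    }
    if (sim.deme[2].alive) {
      int age = g - G2;
      sim.reproduce(2, age <= bottleneck_duration ? std::min(bottleneck_size, n_eco) : n_eco);
    }
    for (int p = 0; p < 3; ++p)
      if (sim.deme[p].alive) sim.mutate(p);
    // founding happens after the parent generation has reproduced+mutated
    if (have_prog && g == G1) sim.found(1, 0, std::min(bottleneck_size, n_prog));
    if (have_eco && g == G2) sim.found(2, 1, std::min(bottleneck_size, n_eco));
    if (g > t_plant && sweep_generations > 0) {
      double u = (double)(g - t_plant) / (double)(total - t_plant);
      for (auto &sw : sweeps) {
        double f0 = sim.deme[sw.target].alive ? 1.0 / sim.deme[sw.target].nhap : 0.0;
        sim.enforce_sweep(sw, sweep_traj(u, f0, fend));
      }
    }
    if (g % 4 == 0 && g != G1 && g != G2) sim.purge();
  }
  sim.purge();

  int S = sim.S;
  auto emit = [&](int p, int n_out) -> IntegerMatrix {
    Deme &d = sim.deme[p];
    if (!d.alive || n_out <= 0) return IntegerMatrix(0, S);
    int N = d.nhap / 2;
    if (n_out > N) n_out = N;
    std::vector<int> ids(N);
    for (int i = 0; i < N; ++i) ids[i] = i;
    for (int i = 0; i < n_out; ++i) std::swap(ids[i], ids[i + sim.rng.uint(N - i)]);
    IntegerMatrix M(n_out, S);
    for (int i = 0; i < n_out; ++i) {
      const uint8_t *a = d.H.data() + (size_t)(2 * ids[i]) * sim.cap;
      const uint8_t *b = a + sim.cap;
      for (int s = 0; s < S; ++s) M(i, s) = a[s] + b[s];
    }
    return M;
  };

  IntegerMatrix Gw = emit(0, out_wild), Gp = emit(1, out_prog), Ge = emit(2, out_eco);
  IntegerVector status(sweeps.size());
  for (size_t i = 0; i < sweeps.size(); ++i)
    status[i] = sweeps[i].status == 0 ? -1 : sweeps[i].status;

  return List::create(
    _["chrom"] = wrap(sim.s_chrom), _["pos"] = wrap(sim.s_pos),
    _["origin_pop"] = wrap(sim.s_opop), _["origin_gen"] = wrap(sim.s_ogen),
    _["wild"] = Gw, _["prog"] = Gp, _["eco"] = Ge,
    _["sweep_status"] = status,
    _["split_prog_gen"] = G1, _["split_eco_gen"] = G2,
    _["total_generations"] = total);
}
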