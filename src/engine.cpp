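// Compiled kernel for the metabolic replicator cellular automaton.
//
// One generation = L^2 elementary site updates (random site with replacement;
// occupied -> death trial, empty -> metabolism-weighted replication lottery)
// randomly interleaved with round(D * L^2) site-swap diffusion events, then a
// conformation-switch sweep at the generation boundary.
//
// The kernel owns its RNG (xoshiro256+ seeded via splitmix64) so a run is
// bit-reproducible given (params, seed) and independent of R's RNG state.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9E3779B97F4A7C15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }
  inline uint64_t next() {
    uint64_t result = s[0] + s[3];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t;
    s[3] = (s[3] << 45) | (s[3] >> 19);
    return result;
  }
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }
  inline int below(int n) { return (int)(unif() * n); }
};

struct Model {
  int L, L2;
  double p_d, p_m, D, b, g, E_max, k_min, k_max, W_e;
  bool diff_occ_only;
  int rep_deg, diff_deg;            // 4 or 8
  std::vector<int> rep_nb, diff_nb; // L2 * deg neighbour indices
  std::vector<int> moore9;          // L2 * 9, focal site included

  std::vector<uint8_t> occ;
  std::vector<double> e1, e2, k;
  std::vector<uint8_t> conf;        // 0 none, 1 expresses E1, 2 expresses E2

  Xoshiro rng;

  Model(uint64_t seed) : rng(seed) {}

  // column-major linear index, 0-based, torus wrap
  inline int idx(int r, int c) const {
    r = (r % L + L) % L; c = (c % L + L) % L;
    return c * L + r;
  }

  void build_neighbours(bool rep_moore, bool diff_moore) {
    static const int vn_dr[4] = {-1, 1, 0, 0}, vn_dc[4] = {0, 0, -1, 1};
    static const int mo_dr[8] = {-1, -1, -1, 0, 0, 1, 1, 1},
                     mo_dc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
    rep_deg = rep_moore ? 8 : 4;
    diff_deg = diff_moore ? 8 : 4;
    rep_nb.resize((size_t)L2 * rep_deg);
    diff_nb.resize((size_t)L2 * diff_deg);
    moore9.resize((size_t)L2 * 9);
    for (int c = 0; c < L; ++c) {
      for (int r = 0; r < L; ++r) {
        int i = c * L + r;
        for (int d = 0; d < rep_deg; ++d)
          rep_nb[(size_t)i * rep_deg + d] = rep_moore
            ? idx(r + mo_dr[d], c + mo_dc[d])
            : idx(r + vn_dr[d], c + vn_dc[d]);
        for (int d = 0; d < diff_deg; ++d)
          diff_nb[(size_t)i * diff_deg + d] = diff_moore
            ? idx(r + mo_dr[d], c + mo_dc[d])
            : idx(r + vn_dr[d], c + vn_dc[d]);
        moore9[(size_t)i * 9] = i;
        for (int d = 0; d < 8; ++d)
          moore9[(size_t)i * 9 + 1 + d] = idx(r + mo_dr[d], c + mo_dc[d]);
      }
    }
  }

  // metabolic supply of the occupant at site i: geometric mean of the two
  // expressed-activity totals over the metabolic (Moore 3x3) neighbourhood
  inline double metabolism(int i) const {
    double a1 = 0.0, a2 = 0.0;
    const int* nb = &moore9[(size_t)i * 9];
    for (int d = 0; d < 9; ++d) {
      int j = nb[d];
      if (occ[j]) {
        if (conf[j] == 1) a1 += e1[j];
        else if (conf[j] == 2) a2 += e2[j];
      }
    }
    return std::sqrt(a1 * a2);
  }

  // normalised enzyme investment u = ||(e1,e2)||_b / E_max
  inline double load(double a, double b2) const {
    double m = a > b2 ? a : b2;
    if (m <= 0.0) return 0.0;
    double u = m * std::pow(std::pow(a / m, b) + std::pow(b2 / m, b), 1.0 / b);
    return u / E_max;
  }

  inline double cap(double u) const {
    double t = 1.0 - u;
    if (t < 0.0) t = 0.0;
    return k_min + (k_max - k_min) * std::pow(t, 1.0 / g);
  }

  // uniform draw from the feasible trait volume (rejection from the box)
  void sample_mutant(double& me1, double& me2, double& mk, uint8_t& mconf) {
    const bool degenerate = (k_max <= k_min);
    for (;;) {
      double c1 = rng.unif() * E_max;
      double c2 = rng.unif() * E_max;
      double u = load(c1, c2);
      if (u > 1.0) continue;
      double ck;
      if (degenerate) {
        ck = k_min;
      } else {
        ck = k_min + rng.unif() * (k_max - k_min);
        if (ck > cap(u)) continue;
      }
      me1 = c1; me2 = c2; mk = ck;
      if (c1 > 0.0 && c2 > 0.0) mconf = (rng.unif() < 0.5) ? 1 : 2;
      else if (c1 > 0.0) mconf = 1;
      else if (c2 > 0.0) mconf = 2;
      else mconf = 0;
      return;
    }
  }

  void site_update() {
    int i = rng.below(L2);
    if (occ[i]) {
      if (rng.unif() < p_d) occ[i] = 0;
      return;
    }
    // replication lottery at the empty site i
    double w[8];
    int cl[8];
    int ncl = 0;
    double total = 0.0;
    const int* nb = &rep_nb[(size_t)i * rep_deg];
    for (int d = 0; d < rep_deg; ++d) {
      int j = nb[d];
      if (occ[j]) {
        double wj = k[j] * metabolism(j);
        if (wj > 0.0) { w[ncl] = wj; cl[ncl] = j; ++ncl; total += wj; }
      }
    }
    if (total <= 0.0) return;  // stays empty with probability 1
    double u = rng.unif() * (W_e + total);
    if (u < W_e) return;       // stays empty
    u -= W_e;
    int winner = cl[ncl - 1];
    for (int q = 0; q < ncl; ++q) {
      if (u < w[q]) { winner = cl[q]; break; }
      u -= w[q];
    }
    // place offspring
    if (rng.unif() < p_m) {
      double m1, m2, mk; uint8_t mc;
      sample_mutant(m1, m2, mk, mc);
      e1[i] = m1; e2[i] = m2; k[i] = mk; conf[i] = mc;
    } else {
      e1[i] = e1[winner]; e2[i] = e2[winner]; k[i] = k[winner];
      conf[i] = conf[winner];
    }
    occ[i] = 1;
  }

  void diffusion_event() {
    int i = rng.below(L2);
    int j = diff_nb[(size_t)i * diff_deg + rng.below(diff_deg)];
    if (diff_occ_only && !(occ[i] && occ[j])) return;
    std::swap(occ[i], occ[j]);
    std::swap(e1[i], e1[j]);
    std::swap(e2[i], e2[j]);
    std::swap(k[i], k[j]);
    std::swap(conf[i], conf[j]);
  }

  void conformation_sweep() {
    for (int i = 0; i < L2; ++i) {
      if (occ[i] && e1[i] > 0.0 && e2[i] > 0.0) {
        double s = std::fabs(e1[i] - e2[i]) / (e1[i] + e2[i]);
        if (rng.unif() < 1.0 - s) conf[i] = (conf[i] == 1) ? 2 : 1;
      }
    }
  }

  void generation(long n_diff) {
    long rs = L2, rd = n_diff;
    while (rs + rd > 0) {
      bool diff_ev;
      if (rd == 0) diff_ev = false;
      else if (rs == 0) diff_ev = true;
      else diff_ev = rng.unif() * (double)(rs + rd) < (double)rd;
      if (diff_ev) { --rd; diffusion_event(); }
      else { --rs; site_update(); }
    }
    conformation_sweep();
  }
};

} // namespace

// [[Rcpp::export(name = ".run_engine_cpp")]]
List run_engine_cpp(IntegerVector occ, NumericVector e1, NumericVector e2,
                    NumericVector k, IntegerVector conf,
                    int L, List par, int generations, int start_generation,
                    IntegerVector record_at, NumericVector regions,
                    double seed) {
  Model m((uint64_t)seed);
  m.L = L; m.L2 = L * L;
  m.p_d = as<double>(par["p_d"]);
  m.p_m = as<double>(par["p_m"]);
  m.D = as<double>(par["D"]);
  m.b = as<double>(par["b"]);
  m.g = as<double>(par["g"]);
  m.E_max = as<double>(par["E_max"]);
  m.k_min = as<double>(par["k_min"]);
  m.k_max = as<double>(par["k_max"]);
  m.W_e = as<double>(par["W_e"]);
  m.diff_occ_only = as<bool>(par["diffusion_occupied_only"]);
  bool rep_moore = as<std::string>(par["replication_neighbourhood"]) == "Moore";
  bool diff_moore = as<std::string>(par["diffusion_neighbourhood"]) == "Moore";
  m.build_neighbours(rep_moore, diff_moore);

  m.occ.assign(occ.begin(), occ.end());
  m.conf.assign(conf.begin(), conf.end());
  m.e1.assign(e1.begin(), e1.end());
  m.e2.assign(e2.begin(), e2.end());
  m.k.assign(k.begin(), k.end());

  const double par_sum = regions[0], spec_minor = regions[1], gen_s = regions[2];
  long n_diff = (long)std::llround(m.D * (double)m.L2);

  std::vector<int> rec(record_at.begin(), record_at.end());
  int n_rec = (int)rec.size();
  NumericMatrix summary(n_rec, 10);
  int rec_i = 0;

  auto record = [&](int gen_no) {
    int n = 0, n_spec = 0, n_gen = 0, n_par = 0;
    double s1 = 0, s2 = 0, sk = 0;
    for (int i = 0; i < m.L2; ++i) {
      if (!m.occ[i]) continue;
      ++n;
      double a = m.e1[i], b2 = m.e2[i];
      s1 += a; s2 += b2; sk += m.k[i];
      if (a + b2 <= par_sum) ++n_par;
      else if ((a < b2 ? a : b2) <= spec_minor) ++n_spec;
      else if (std::fabs(a - b2) / (a + b2) <= gen_s) ++n_gen;
    }
    summary(rec_i, 0) = gen_no;
    summary(rec_i, 1) = (double)n / m.L2;
    summary(rec_i, 2) = n ? (double)n_spec / n : 0.0;
    summary(rec_i, 3) = n ? (double)n_gen / n : 0.0;
    summary(rec_i, 4) = n ? (double)n_par / n : 0.0;
    summary(rec_i, 5) = n ? (double)(n - n_spec - n_gen - n_par) / n : 0.0;
    summary(rec_i, 6) = n ? s1 / n : NA_REAL;
    summary(rec_i, 7) = n ? s2 / n : NA_REAL;
    summary(rec_i, 8) = n ? sk / n : NA_REAL;
    summary(rec_i, 9) = n == 0 ? 1.0 : 0.0;
    ++rec_i;
  };

  for (int g = 1; g <= generations; ++g) {
    m.generation(n_diff);
    int gen_no = start_generation + g;
    if (rec_i < n_rec && rec[rec_i] == gen_no) record(gen_no);
    if ((g & 1023) == 0) Rcpp::checkUserInterrupt();
  }

  colnames(summary) = CharacterVector::create(
    "generation", "occupancy", "f_specialist", "f_generalist", "f_parasite",
    "f_rest", "mean_e1", "mean_e2", "mean_k", "extinct");

  return List::create(
    _["summary"] = summary,
    _["occ"] = IntegerVector(m.occ.begin(), m.occ.end()),
    _["e1"] = NumericVector(m.e1.begin(), m.e1.end()),
    _["e2"] = NumericVector(m.e2.begin(), m.e2.end()),
    _["k"] = NumericVector(m.k.begin(), m.k.end()),
    _["conf"] = IntegerVector(m.conf.begin(), m.conf.end()),
    _["generation"] = start_generation + generations);
}
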