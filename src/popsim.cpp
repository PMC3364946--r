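#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <cstdint>
using namespace Rcpp;

// Stochastic Eigen-model population dynamics (Gillespie). Genotypes over a
// 4-letter alphabet are packed 2 bits per site into 64-bit codes (L <= 31);
// the genotype ledger grows lazily as mutations create new sequences.
// Single-peak landscapes: the master genotype has its own replication rate
// and per-site error rate; all others share background values. Modes:
//   growth: replication only (exponential growth).
//   constant: replication + degradation, each individual degrading at the
//     population-mean replication rate, so E[N] stays constant.
// Uses R's RNG (set.seed-reproducible).

static inline int hamming2(uint64_t a, uint64_t b, int L) {
  uint64_t x = a ^ b;
  int h = 0;
  for (int i = 0; i < L; ++i) { if (x & 3ULL) ++h; x >>= 2; }
  return h;
}

// [[Rcpp::export(name = ".cpp_popsim")]]
List cpp_popsim(NumericVector genotype_codes, NumericVector counts0,
                double master_code, int L,
                double rep_master, double rep_other,
                double eps_master, double eps_other,
                int constant_N, NumericVector t_grid,
                double max_events) {
  std::vector<uint64_t> codes;
  std::vector<double> cnt;   // counts as doubles (exact integers)
  std::vector<double> rate;  // per-individual replication rate of genotype
  std::vector<int> hd;       // Hamming distance to master
  std::unordered_map<uint64_t, int> index;
  const uint64_t master = (uint64_t)master_code;
  double N = 0.0, total_rep = 0.0;

  auto add_geno = [&](uint64_t g, double n) -> int {
    auto it = index.find(g);
    int i;
    if (it == index.end()) {
      i = (int)codes.size();
      index[g] = i;
      codes.push_back(g);
      cnt.push_back(0.0);
      rate.push_back(g == master ? rep_master : rep_other);
      hd.push_back(hamming2(g, master, L));
    } else i = it->second;
    cnt[i] += n;
    N += n;
    total_rep += n * rate[i];
    return i;
  };
  for (int i = 0; i < genotype_codes.size(); ++i)
    add_geno((uint64_t)genotype_codes[i], counts0[i]);

  auto compact = [&]() { // drop extinct genotypes so per-event scans stay O(N)
    size_t keep = 0;
    index.clear();
    for (size_t k = 0; k < codes.size(); ++k) {
      if (cnt[k] > 0) {
        codes[keep] = codes[k]; cnt[keep] = cnt[k];
        rate[keep] = rate[k]; hd[keep] = hd[k];
        index[codes[keep]] = (int)keep;
        ++keep;
      }
    }
    codes.resize(keep); cnt.resize(keep); rate.resize(keep); hd.resize(keep);
  };

  int ng = t_grid.size();
  NumericVector out_N(ng, NA_REAL), out_xm(ng, NA_REAL), out_hd(ng, NA_REAL);
  int gi = 0;
  double t = 0.0, ev = 0.0, first_dt = NA_REAL;
  std::string status = "max_time";

  auto record_upto = [&](double tnow) {
    while (gi < ng && t_grid[gi] <= tnow) {
      out_N[gi] = N;
      auto it = index.find(master);
      double nm = (it == index.end()) ? 0.0 : cnt[it->second];
      out_xm[gi] = (N > 0) ? nm / N : NA_REAL;
      double s = 0.0;
      for (size_t k = 0; k < codes.size(); ++k) s += cnt[k] * hd[k];
      out_hd[gi] = (N > 0) ? s / (N * L) : NA_REAL;
      ++gi;
    }
  };

  double t_end = t_grid[ng - 1];
  while (t < t_end) {
    if (N <= 0) { status = "extinct"; break; }
    if (ev >= max_events) { status = "max_events"; break; }
    double total = constant_N ? 2.0 * total_rep : total_rep;
    if (total <= 0) { status = "stalled"; break; }
    double dt = R::exp_rand() / total;
    if (ev == 0.0) first_dt = dt;
    if (t + dt > t_end) { t = t_end; break; }
    record_upto(t + dt);
    t += dt;
    double u = unif_rand() * total;
    if (constant_N && u >= total_rep) {
      // degradation: uniform over individuals (rate = mean replication rate)
      double pick = unif_rand() * N;
      double c = 0.0;
      for (size_t k = 0; k < codes.size(); ++k) {
        c += cnt[k];
        if (pick < c && cnt[k] > 0) {
          cnt[k] -= 1.0; N -= 1.0; total_rep -= rate[k];
          break;
        }
      }
    } else {
      // replication: choose parent with probability prop. to count * rate
      double c = 0.0;
      int par = -1;
      for (size_t k = 0; k < codes.size(); ++k) {
        c += cnt[k] * rate[k];
        if (u < c && cnt[k] > 0) { par = (int)k; break; }
      }
      if (par < 0) continue;
      double e = (codes[par] == master) ? eps_master : eps_other;
      uint64_t child = codes[par];
      if (e > 0) {
        for (int s = 0; s < L; ++s) {
          if (unif_rand() < e) {
            uint64_t cur = (child >> (2 * s)) & 3ULL;
            uint64_t nb = (cur + 1 + (uint64_t)(unif_rand() * 3.0)) & 3ULL;
            if (nb == cur) nb = (cur + 1) & 3ULL; // guard unif_rand()==1.0 edge
            child = (child & ~(3ULL << (2 * s))) | (nb << (2 * s));
          }
        }
      }
      add_geno(child, 1.0);
    }
    ++ev;
    if (((long long)ev % 8192LL) == 0) {
      size_t zero = 0;
      for (size_t k = 0; k < codes.size(); ++k) if (cnt[k] <= 0) ++zero;
      if (zero > codes.size() / 2) compact();
    }
  }
  record_upto(t_end + 1.0);

  // final population snapshot (nonzero counts only)
  std::vector<double> fc, fn, fh;
  for (size_t k = 0; k < codes.size(); ++k)
    if (cnt[k] > 0) { fc.push_back((double)codes[k]); fn.push_back(cnt[k]); fh.push_back(hd[k]); }
  return List::create(_["t"] = t_grid, _["N"] = out_N, _["x_master"] = out_xm,
                      _["mean_hd"] = out_hd, _["n_events"] = ev,
                      _["first_event_time"] = first_dt,
                      _["status"] = status,
                      _["final_codes"] = NumericVector(fc.begin(), fc.end()),
                      _["final_counts"] = NumericVector(fn.begin(), fn.end()),
                      _["final_hd"] = NumericVector(fh.begin(), fh.end()));
}
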