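#include <Rcpp.h>
using namespace Rcpp;

// Kinetic Monte Carlo (Gillespie) simulation of reversible templated
// elongation. State = number of added bases l and their identities. Enabled
// reactions: insertion of each of the 4 bases against the next template base
// (forward rates kf), and excision of the last added base with the backward
// rate of the pair actually present at the terminus (required for detailed
// balance at equilibrium). Uses R's RNG so runs are reproducible under
// set.seed(). A chain emptied by excision terminates with its own status.
//
// [[Rcpp::export(name = ".cpp_elongate")]]
List cpp_elongate(IntegerVector tmpl, NumericMatrix kf, NumericMatrix kb,
                  int max_events, int max_length, double max_time,
                  int n_blocks, int stop_at_zero) {
  const int T = tmpl.size();
  if (max_length <= 0 || max_length > T) max_length = T;
  std::vector<int> grown; grown.reserve(max_length);
  double t = 0.0;
  long long ev = 0;
  std::string status = "max_events";
  std::vector<double> blk_t, blk_len; // checkpoints for block standard errors
  long long block_every = max_events / (n_blocks > 0 ? n_blocks : 1);
  if (block_every < 1) block_every = 1;
  while (true) {
    if (ev >= max_events) { status = "max_events"; break; }
    int l = (int)grown.size();
    if (l >= max_length) { status = "max_length"; break; }
    double r[5];
    int nb = tmpl[l]; // next template base (0-based alphabet index)
    double total = 0.0;
    for (int b = 0; b < 4; ++b) { r[b] = kf(b, nb); total += r[b]; }
    r[4] = (l > 0) ? kb(grown[l - 1], tmpl[l - 1]) : 0.0;
    total += r[4];
    t += R::exp_rand() / total;
    if (max_time > 0 && t > max_time) { t = max_time; status = "max_time"; break; }
    double u = unif_rand() * total;
    int pick = 0; double c = r[0];
    while (u > c && pick < 4) { c += r[++pick]; }
    if (pick < 4) grown.push_back(pick); else grown.pop_back();
    ++ev;
    if (ev % block_every == 0) {
      blk_t.push_back(t);
      blk_len.push_back((double)grown.size());
    }
    if (grown.empty() && pick == 4 && stop_at_zero) { status = "shrunk_to_zero"; break; }
  }
  return List::create(_["grown"] = IntegerVector(grown.begin(), grown.end()),
                      _["elapsed"] = t, _["n_events"] = (double)ev,
                      _["status"] = status,
                      _["block_t"] = NumericVector(blk_t.begin(), blk_t.end()),
                      _["block_len"] = NumericVector(blk_len.begin(), blk_len.end()));
}
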