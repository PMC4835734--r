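#include <Rcpp.h>
using namespace Rcpp;

// Discrete-time synchronous SIR final-size ensemble on a CSR adjacency.
//
// Each realization: one uniformly random seed node infected, all others
// susceptible. Per step (synchronous): every infected node attempts to
// infect each susceptible neighbour independently with probability beta,
// then recovers with probability gamma; newly infected nodes become
// infectious the following step. With recover_first = true the recovery
// draw is made first and a node recovering this step does not transmit.
// Absorbs when no infected remain; returns R_final / N per realization.
//
// Uses R's RNG, so results are reproducible from set.seed() on the R side.
// [[Rcpp::export]]
NumericVector sir_final_sizes_cpp(IntegerVector adj, IntegerVector ptr,
                                  double beta, double gamma, int n_real,
                                  bool recover_first) {
  const int N = ptr.size() - 1;
  if (N < 1) stop("empty graph");
  NumericVector out(n_real);
  std::vector<int> status(N);         // 0 = S, 1 = I, 2 = R
  std::vector<int> infected, newly, still;
  std::vector<char> recovers;
  infected.reserve(N); newly.reserve(N); still.reserve(N);

  for (int rep = 0; rep < n_real; ++rep) {
    std::fill(status.begin(), status.end(), 0);
    infected.clear();
    int seed = (int)(unif_rand() * N);
    if (seed >= N) seed = N - 1;
    status[seed] = 1;
    infected.push_back(seed);
    int n_rec = 0;

    while (!infected.empty()) {
      newly.clear();
      const size_t ni = infected.size();
      if (recover_first) {
        recovers.assign(ni, 0);
        for (size_t m = 0; m < ni; ++m) recovers[m] = (unif_rand() < gamma);
      }
      for (size_t m = 0; m < ni; ++m) {
        if (recover_first && recovers[m]) continue;
        const int i = infected[m];
        for (int p = ptr[i]; p < ptr[i + 1]; ++p) {
          const int j = adj[p];
          if (status[j] == 0 && unif_rand() < beta) {
            status[j] = 1;
            newly.push_back(j);
          }
        }
      }
      still.clear();
      for (size_t m = 0; m < ni; ++m) {
        const int i = infected[m];
        const bool rec = recover_first ? (bool)recovers[m]
                                       : (unif_rand() < gamma);
        if (rec) { status[i] = 2; ++n_rec; }
        else still.push_back(i);
      }
      still.insert(still.end(), newly.begin(), newly.end());
      infected.swap(still);
    }
    out[rep] = (double)n_rec / N;
  }
  return out;
}
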