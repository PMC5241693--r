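// Lattice agent-based simulator core.
//
// Encoding: state 1 = altruist carrier (microbe alpha, or allele A in
// genetic mode), 0 = neutral carrier (microbe beta / allele E).
//
// RNG: R's uniform stream, consumed in a fixed order per generation:
//   for each of the K sweeps — a Fisher-Yates permutation of all sites,
//   then per focal site one neighbour draw, then (discordant microbe pairs
//   only, and only when T_alpha or T_beta is positive) the alpha-host's
//   transmission draw followed by the beta-host's; reproduction tie-break
//   draws in row-major site order (drawn only when >1 co-maximal parent);
//   vertical-transmission draws in row-major order (only when VT < 1, one
//   uniform per site plus one more when inheritance fails). Skipping no-op
//   draws keeps the genetic mode and the T=0, VT=1 microbe mode on
//   identical streams, making their trajectories exactly equal under a
//   shared seed.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

namespace {

struct Neighbours {
  // flat Moore neighbourhoods, truncated at the (non-toroidal) edges
  std::vector<int> idx;    // concatenated neighbour indices
  std::vector<int> start;  // start offset per site (size n+1)
  int deg(int s) const { return start[s + 1] - start[s]; }
  const int* at(int s) const { return idx.data() + start[s]; }
};

Neighbours build_neighbours(int rows, int cols) {
  Neighbours nb;
  int n = rows * cols;
  nb.start.resize(n + 1);
  nb.idx.reserve(8 * n);
  int pos = 0;
  for (int r = 0; r < rows; ++r) {
    for (int c = 0; c < cols; ++c) {
      nb.start[r * cols + c] = pos;
      for (int dr = -1; dr <= 1; ++dr) {
        for (int dc = -1; dc <= 1; ++dc) {
          if (dr == 0 && dc == 0) continue;
          int rr = r + dr, cc = c + dc;
          if (rr < 0 || rr >= rows || cc < 0 || cc >= cols) continue;
          nb.idx.push_back(rr * cols + cc);
          ++pos;
        }
      }
    }
  }
  nb.start[n] = pos;
  return nb;
}

inline int rand_below(int k) {
  // uniform integer in [0, k); unif_rand() is in (0, 1)
  int j = (int)(unif_rand() * k);
  return j >= k ? k - 1 : j;
}

// One generation; `state` is overwritten with the offspring grid.
// Exposes the bookkeeping vectors so that single-generation wrappers can
// return them for testing.
void generation(std::vector<int>& state, int rows, int cols,
                const Neighbours& nb,
                double b, double c, double bg, double cg,
                double Ta, double Tb, double VT, int K, bool microbe,
                std::vector<double>& payoff, std::vector<int>& count,
                std::vector<double>& fitness, std::vector<int>& perm,
                std::vector<int>& post_state, std::vector<int>& ties) {
  int n = rows * cols;
  std::fill(payoff.begin(), payoff.end(), 0.0);
  std::fill(count.begin(), count.end(), 0);
  bool do_trans = microbe && (Ta > 0.0 || Tb > 0.0);

  for (int sweep = 0; sweep < K; ++sweep) {
    for (int i = 0; i < n; ++i) perm[i] = i;
    for (int i = n - 1; i > 0; --i) std::swap(perm[i], perm[rand_below(i + 1)]);
    for (int t = 0; t < n; ++t) {
      int i = perm[t];
      int j = nb.at(i)[rand_below(nb.deg(i))];
      int si = state[i], sj = state[j];
      payoff[i] += (bg + b * sj) - (cg + c * si);
      payoff[j] += (bg + b * si) - (cg + c * sj);
      ++count[i];
      ++count[j];
      if (do_trans && si != sj) {
        // the alpha host's microbe may establish in the beta host, and
        // vice versa; both events independent, simultaneous success swaps
        bool alpha_est = unif_rand() < Ta;
        bool beta_est = unif_rand() < Tb;
        int ia = si == 1 ? i : j;  // alpha host
        int ib = si == 1 ? j : i;  // beta host
        if (alpha_est) state[ib] = 1;
        if (beta_est) state[ia] = 0;
      }
    }
  }

  for (int i = 0; i < n; ++i) fitness[i] = payoff[i] / count[i];
  std::copy(state.begin(), state.end(), post_state.begin());

  // Nowak-May reproduction: each site is recolonised by a copy of the
  // fittest host among the site and its neighbours; ties broken uniformly
  for (int i = 0; i < n; ++i) {
    double best = fitness[i];
    int ntie = 1;
    ties[0] = i;
    const int* nbr = nb.at(i);
    int d = nb.deg(i);
    for (int k = 0; k < d; ++k) {
      int j = nbr[k];
      if (fitness[j] > best) {
        best = fitness[j];
        ntie = 1;
        ties[0] = j;
      } else if (fitness[j] == best) {
        ties[ntie++] = j;
      }
    }
    int parent = ntie == 1 ? ties[0] : ties[rand_below(ntie)];
    state[i] = post_state[parent];
  }

  if (microbe && VT < 1.0) {
    for (int i = 0; i < n; ++i) {
      if (unif_rand() >= VT) {
        const int* nbr = nb.at(i);
        int d = nb.deg(i);
        int pick = rand_below(d + 1);  // {site} U neighbours in the old grid
        int src = pick == d ? i : nbr[pick];
        state[i] = post_state[src];
      }
    }
  }
}

}  // namespace

// [[Rcpp::export]]
List lattice_generation_cpp(IntegerVector state, int rows, int cols,
                            double b, double c, double bg, double cg,
                            double Ta, double Tb, double VT, int K,
                            bool microbe) {
  int n = rows * cols;
  if (state.size() != n) stop("state length must equal rows*cols");
  Neighbours nb = build_neighbours(rows, cols);
  std::vector<int> s(state.begin(), state.end());
  std::vector<double> payoff(n), fitness(n);
  std::vector<int> count(n), perm(n), post(n), ties(9);
  generation(s, rows, cols, nb, b, c, bg, cg, Ta, Tb, VT, K, microbe,
             payoff, count, fitness, perm, post, ties);
  double p = 0;
  for (int i = 0; i < n; ++i) p += s[i];
  p /= n;
  return List::create(
    _["state"] = IntegerVector(s.begin(), s.end()),
    _["p"] = p,
    _["fitness"] = NumericVector(fitness.begin(), fitness.end()),
    _["payoff_sum"] = NumericVector(payoff.begin(), payoff.end()),
    _["interaction_count"] = IntegerVector(count.begin(), count.end()),
    _["post_interaction_state"] = IntegerVector(post.begin(), post.end()));
}

// outcome codes: 0 extinct, 1 fixed, 2 reached_target, 3 stabilized,
// 4 max_generations
// [[Rcpp::export]]
List lattice_run_cpp(IntegerVector state, int rows, int cols,
                     double b, double c, double bg, double cg,
                     double Ta, double Tb, double VT, int K, bool microbe,
                     int max_gen, int min_gen, int window, double tol,
                     double upper_target, bool record_trajectory) {
  int n = rows * cols;
  if (state.size() != n) stop("state length must equal rows*cols");
  Neighbours nb = build_neighbours(rows, cols);
  std::vector<int> s(state.begin(), state.end());
  std::vector<double> payoff(n), fitness(n);
  std::vector<int> count(n), perm(n), post(n), ties(9);

  std::vector<double> traj;     // p per generation, generation 1..g
  std::vector<double> csum(1, 0.0);
  traj.reserve(std::min(max_gen, 20000));
  int outcome = 4;
  int g = 0;
  double p = 0;
  for (int i = 0; i < n; ++i) p += s[i];
  p /= n;
  double p0 = p;

  bool fix_is_target = upper_target >= 1.0;
  while (g < max_gen) {
    if (g % 256 == 0) Rcpp::checkUserInterrupt();
    ++g;
    generation(s, rows, cols, nb, b, c, bg, cg, Ta, Tb, VT, K, microbe,
               payoff, count, fitness, perm, post, ties);
    int tot = 0;
    for (int i = 0; i < n; ++i) tot += s[i];
    p = (double)tot / n;
    traj.push_back(p);
    csum.push_back(csum.back() + p);
    if (tot == 0) { outcome = 0; break; }
    if (fix_is_target) {
      if (tot == n) { outcome = 1; break; }
    } else if (p >= upper_target - 1e-12) {
      outcome = 2;
      break;
    }
    if (g > min_gen && g >= 2 * window) {
      double m1 = (csum[g] - csum[g - window]) / window;
      double m2 = (csum[g - window] - csum[g - 2 * window]) / window;
      if (std::abs(m1 - m2) <= tol) { outcome = 3; break; }
    }
  }

  List out = List::create(
    _["outcome"] = outcome,
    _["final_p"] = p,
    _["p0"] = p0,
    _["generations"] = g,
    _["final_state"] = IntegerVector(s.begin(), s.end()));
  if (record_trajectory) {
    out["p_trajectory"] = NumericVector(traj.begin(), traj.end());
  }
  return out;
}
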