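#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Metropolis-Hastings sampler over change-point segmentations of a token
// sequence generated by an order-n Markov chain.  The target is the joint
// integrated likelihood
//   P(x, l | n) = 2^{-D(M+1)} M!(E-M)!/(E+1)!
//                 prod_l prod_mem (D_l-1)!/(k^l_mem + D_l - 1)! prod a^l!
// Transitions are pre-encoded in R as dense integer ids: trans_mem[t-1] is
// the memory id of the transition at step t (t > n, -1 otherwise) and
// trans_pair[t-1] the (memory, token) pair id.  Per-segment likelihood terms
// are cached, so each proposal only re-evaluates the affected segments.
// All randomness comes from R's RNG (unif_rand), so results are fully
// reproducible under set.seed().

namespace {

struct Workspace {
  std::vector<int> cnt_tok, cnt_mem, cnt_pair;
  std::vector<int> tok_touch, mem_touch, pair_touch;
  const int *tok, *mem, *pair;
  int E, n, D;

  Workspace(const IntegerVector &tokens, const IntegerVector &tmem,
            const IntegerVector &tpair, int order, int D_, int U, int P)
      : cnt_tok(D_, 0), cnt_mem(std::max(U, 1), 0),
        cnt_pair(std::max(P, 1), 0), tok(tokens.begin()), mem(tmem.begin()),
        pair(tpair.begin()), E(tokens.size()), n(order), D(D_) {}

  // log-likelihood term of the segment covering steps lo..hi (1-based)
  double segL(int lo, int hi) {
    int dl = 0;
    for (int t = lo; t <= hi; ++t) {
      int x = tok[t - 1];
      if (cnt_tok[x]++ == 0) { tok_touch.push_back(x); ++dl; }
    }
    int t0 = lo > n + 1 ? lo : n + 1;
    for (int t = t0; t <= hi; ++t) {
      int m = mem[t - 1], p = pair[t - 1];
      if (cnt_mem[m]++ == 0) mem_touch.push_back(m);
      if (cnt_pair[p]++ == 0) pair_touch.push_back(p);
    }
    double res = 0.0, lgD = std::lgamma((double)dl);
    for (int m : mem_touch) {
      res += lgD - std::lgamma((double)cnt_mem[m] + dl);
      cnt_mem[m] = 0;
    }
    for (int p : pair_touch) {
      res += std::lgamma((double)cnt_pair[p] + 1.0);
      cnt_pair[p] = 0;
    }
    for (int x : tok_touch) cnt_tok[x] = 0;
    tok_touch.clear(); mem_touch.clear(); pair_touch.clear();
    return res;
  }
};

inline int runif_int(int k) {  // uniform on 0..k-1
  int j = (int)(unif_rand() * k);
  return j >= k ? k - 1 : j;
}

inline double const_term(int M, int E, int D) {
  return -D * (M + 1) * M_LN2 + std::lgamma((double)M + 1.0) +
         std::lgamma((double)(E - M) + 1.0) - std::lgamma((double)E + 2.0);
}

}  // namespace

// [[Rcpp::export]]
List cpm_mcmc_run(IntegerVector tokens, IntegerVector trans_mem,
                  IntegerVector trans_pair, int order, int D, int U, int P,
                  double patience, double min_proposals, double max_proposals,
                  bool record, double record_proposals) {
  const int E = tokens.size();
  Workspace w(tokens, trans_mem, trans_pair, order, D, U, P);

  std::vector<int> bnd;          // boundaries, 1-based, sorted
  std::vector<double> sL;        // cached per-segment terms
  sL.push_back(w.segL(1, E));
  double logpost = const_term(0, E, D) + sL[0];

  std::vector<int> best_bnd = bnd;
  double best_lp = logpost;

  std::vector<double> hist;
  if (record) {
    if (E > 21) stop("histogram recording requires E <= 21");
    hist.assign((size_t)1 << (E - 1), 0.0);
  }

  double total = 0.0, since_improve = 0.0;
  long accepted = 0;

  for (;;) {
    int M = (int)bnd.size();
    int mv = runif_int(3);
    bool changed = false;
    double dlp = 0.0, lacc = 0.0;
    bool applicable = true;

    if (mv == 0) {  // split
      int j = runif_int(M + 1);
      int lo = (j == 0) ? 1 : bnd[j - 1] + 1;
      int hi = (j == M) ? E : bnd[j];
      int len = hi - lo + 1;
      if (len < 2) {
        applicable = false;
      } else {
        int cut = lo + runif_int(len - 1);  // in lo..hi-1
        double L1 = w.segL(lo, cut), L2 = w.segL(cut + 1, hi);
        dlp = L1 + L2 - sL[j] + const_term(M + 1, E, D) - const_term(M, E, D);
        lacc = dlp + std::log((double)(len - 1));
        if (lacc >= 0 || unif_rand() < std::exp(lacc)) {
          bnd.insert(bnd.begin() + j, cut);
          sL[j] = L1;
          sL.insert(sL.begin() + j + 1, L2);
          logpost += dlp;
          changed = true;
        }
      }
    } else if (mv == 1) {  // merge
      if (M == 0) {
        applicable = false;
      } else {
        int j = runif_int(M);  // remove boundary j (0-based)
        int lo = (j == 0) ? 1 : bnd[j - 1] + 1;
        int hi = (j == M - 1) ? E : bnd[j + 1];
        double L = w.segL(lo, hi);
        dlp = L - sL[j] - sL[j + 1] +
              const_term(M - 1, E, D) - const_term(M, E, D);
        lacc = dlp - std::log((double)(hi - lo));
        if (lacc >= 0 || unif_rand() < std::exp(lacc)) {
          bnd.erase(bnd.begin() + j);
          sL[j] = L;
          sL.erase(sL.begin() + j + 1);
          logpost += dlp;
          changed = true;
        }
      }
    } else {  // shift
      if (M == 0) {
        applicable = false;
      } else {
        int j = runif_int(M);
        int lo = (j == 0) ? 0 : bnd[j - 1];
        int hi = (j == M - 1) ? E : bnd[j + 1];
        int pos = lo + 1 + runif_int(hi - lo - 1);  // in lo+1..hi-1
        if (pos != bnd[j]) {
          double L1 = w.segL(lo + 1, pos), L2 = w.segL(pos + 1, hi);
          dlp = L1 + L2 - sL[j] - sL[j + 1];
          lacc = dlp;  // symmetric proposal
          if (lacc >= 0 || unif_rand() < std::exp(lacc)) {
            bnd[j] = pos;
            sL[j] = L1;
            sL[j + 1] = L2;
            logpost += dlp;
            changed = true;
          }
        } else {
          changed = true;  // self-move, trivially accepted
        }
      }
    }

    (void)applicable;
    if (changed) ++accepted;
    total += 1.0;
    if (record) {
      size_t mask = 0;
      for (int b : bnd) mask |= (size_t)1 << (b - 1);
      hist[mask] += 1.0;
    }
    if (logpost > best_lp + 1e-10) {
      best_lp = logpost;
      best_bnd = bnd;
      since_improve = 0.0;
    } else {
      since_improve += 1.0;
    }

    if (record) {
      if (total >= record_proposals) break;
    } else {
      if (total >= max_proposals) break;
      if (total >= min_proposals &&
          since_improve >= patience * ((double)bnd.size() + 1.0))
        break;
    }
  }

  // recompute the best log joint from scratch (guards against fp drift)
  double best_exact = const_term((int)best_bnd.size(), E, D);
  {
    int lo = 1;
    for (size_t i = 0; i <= best_bnd.size(); ++i) {
      int hi = (i == best_bnd.size()) ? E : best_bnd[i];
      best_exact += w.segL(lo, hi);
      lo = hi + 1;
    }
  }

  List out = List::create(
      _["boundaries"] = IntegerVector(best_bnd.begin(), best_bnd.end()),
      _["log_joint"] = best_exact, _["proposals"] = total,
      _["accepted"] = (double)accepted);
  if (record) out["hist"] = NumericVector(hist.begin(), hist.end());
  return out;
}
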