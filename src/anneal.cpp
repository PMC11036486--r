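#include <Rcpp.h>
using namespace Rcpp;

// Metropolis simulated-annealing packer over single-position substitutions.
//
// contacts: m x 2 integer matrix, 1-based residue indices
// pot:      20 x 20 symmetric contact potential
// refs:     20 reference energies
// allowed:  L x 20 logical design task
// scores:   L x 20 profile restraint scores (ignored when w == 0)
// w:        restraint weight; restraint energy is -w * sum(scores[i, x_i])
// start:    1-based amino-acid indices of the start sequence (task-obeying)
//
// Per sweep, L attempted moves: uniform random position, uniform random
// allowed amino acid different from the current one; acceptance
// min(1, exp(-dE / T)); geometric cooling from tStart to tEnd across sweeps.
// Uses the R RNG so set.seed() controls the trajectory. Returns the
// best-energy sequence ever visited. The profile is held fixed throughout.
// [[Rcpp::export(name = ".annealPack")]]
List annealPack(IntegerMatrix contacts, NumericMatrix pot, NumericVector refs,
                LogicalMatrix allowed, NumericMatrix scores, double w,
                double tStart, double tEnd, int nSweeps, IntegerVector start,
                bool trace) {
  const int L = allowed.nrow();
  const int m = contacts.nrow();

  // adjacency lists
  std::vector<std::vector<int>> adj(L);
  for (int k = 0; k < m; ++k) {
    int i = contacts(k, 0) - 1, j = contacts(k, 1) - 1;
    adj[i].push_back(j);
    adj[j].push_back(i);
  }
  // allowed amino-acid index lists (0-based)
  std::vector<std::vector<int>> opts(L);
  for (int i = 0; i < L; ++i)
    for (int a = 0; a < 20; ++a)
      if (allowed(i, a)) opts[i].push_back(a);

  std::vector<int> seq(L);
  for (int i = 0; i < L; ++i) seq[i] = start[i] - 1;

  // full energy of the start state
  double base = 0.0;
  for (int i = 0; i < L; ++i) base += refs[seq[i]];
  for (int k = 0; k < m; ++k)
    base += pot(seq[contacts(k, 0) - 1], seq[contacts(k, 1) - 1]);
  double restr = 0.0;
  if (w != 0.0) {
    for (int i = 0; i < L; ++i) restr -= w * scores(i, seq[i]);
  }
  double energy = base + restr;

  std::vector<int> best = seq;
  double bestE = energy, bestBase = base, bestRestr = restr;
  long accepted = 0;
  const long nMoves = (long)nSweeps * L;

  std::vector<int> trPos, trFrom, trTo, trAcc;
  std::vector<double> trDE;
  if (trace) {
    trPos.reserve(nMoves); trFrom.reserve(nMoves); trTo.reserve(nMoves);
    trAcc.reserve(nMoves); trDE.reserve(nMoves);
  }

  RNGScope rngScope;
  for (int s = 0; s < nSweeps; ++s) {
    double T = (nSweeps == 1) ? tStart
      : tStart * std::pow(tEnd / tStart, (double)s / (double)(nSweeps - 1));
    for (int t = 0; t < L; ++t) {
      int i = (int)(unif_rand() * L);
      if (i >= L) i = L - 1;
      const std::vector<int>& oi = opts[i];
      int nOpt = (int)oi.size();
      int cur = seq[i];
      if (nOpt < 2) {
        if (trace) {
          trPos.push_back(i + 1); trFrom.push_back(cur + 1);
          trTo.push_back(cur + 1); trDE.push_back(0.0); trAcc.push_back(0);
        }
        continue;  // nothing to substitute
      }
      int k = (int)(unif_rand() * (nOpt - 1));
      if (k >= nOpt - 1) k = nOpt - 2;
      // k-th allowed amino acid skipping the current one
      int cand = -1, seen = 0;
      for (int a = 0; a < nOpt; ++a) {
        if (oi[a] == cur) continue;
        if (seen++ == k) { cand = oi[a]; break; }
      }
      double dBase = refs[cand] - refs[cur];
      for (size_t nb = 0; nb < adj[i].size(); ++nb) {
        int xj = seq[adj[i][nb]];
        dBase += pot(cand, xj) - pot(cur, xj);
      }
      double dRestr = (w != 0.0)
        ? -w * (scores(i, cand) - scores(i, cur)) : 0.0;
      double dE = dBase + dRestr;
      bool acc = (dE <= 0.0) || (unif_rand() < std::exp(-dE / T));
      if (acc) {
        seq[i] = cand;
        base += dBase;
        restr += dRestr;
        energy += dE;
        ++accepted;
        if (energy < bestE) {
          bestE = energy; bestBase = base; bestRestr = restr; best = seq;
        }
      }
      if (trace) {
        trPos.push_back(i + 1); trFrom.push_back(cur + 1);
        trTo.push_back(cand + 1); trDE.push_back(dE);
        trAcc.push_back(acc ? 1 : 0);
      }
    }
  }

  IntegerVector bestSeq(L);
  for (int i = 0; i < L; ++i) bestSeq[i] = best[i] + 1;
  List out = List::create(_["bestSeq"] = bestSeq,
                          _["bestTotal"] = bestE,
                          _["bestBase"] = bestBase,
                          _["bestRestraint"] = bestRestr,
                          _["accepted"] = (double)accepted);
  if (trace) {
    out["trace"] = DataFrame::create(
      _["pos"] = wrap(trPos), _["from"] = wrap(trFrom),
      _["to"] = wrap(trTo), _["dE"] = wrap(trDE),
      _["accepted"] = wrap(trAcc));
  }
  return out;
}
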