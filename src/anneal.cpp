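#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// A candidate duplex: a maximal perfectly complementary run between an
// "oligo" molecule o and a "template" molecule t in one antiparallel
// alignment. Positions are 0-based; the run pairs oligo positions
// [o_start, o_start+len) with template positions [t_start, t_start+len)
// such that oligo[o_start] pairs template[t_start+len-1] (antiparallel).
struct Cand {
  int o, t, o_start, t_start, len;
  double energy; // kcal/mol, sum of per-pair dG (negative)
};

// Enumerate maximal complementary runs >= min_duplex for all ordered pairs.
// dG(i, j) is the per-pair free energy between base codes i and j; a value
// of exactly 0 means "not a Watson-Crick pair".
static void enumerate_cands(const std::vector<IntegerVector>& sv,
                            const NumericMatrix& dG, int min_duplex,
                            std::vector<Cand>& cand) {
  const int M = sv.size();
  for (int i = 0; i < M; ++i) {
    const int la = sv[i].size();
    for (int j = 0; j < M; ++j) {
      if (i == j) continue;
      const int lb = sv[j].size();
      // diagonal d: oligo position p pairs template position d - p
      for (int d = 0; d < la + lb - 1; ++d) {
        const int plo = std::max(0, d - lb + 1);
        const int phi = std::min(la - 1, d);
        int run = 0;
        double e = 0.0;
        for (int p = plo; p <= phi + 1; ++p) {
          double g = 0.0;
          if (p <= phi) g = dG(sv[i][p], sv[j][d - p]);
          if (g != 0.0) {
            ++run;
            e += g;
          } else {
            if (run >= min_duplex) {
              Cand c;
              c.o = i;
              c.t = j;
              c.o_start = p - run;
              c.t_start = d - (p - 1);
              c.len = run;
              c.energy = e;
              cand.push_back(c);
            }
            run = 0;
            e = 0.0;
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
DataFrame complementary_runs_cpp(IntegerVector a, IntegerVector b,
                                 NumericMatrix dG, int min_duplex) {
  std::vector<IntegerVector> sv;
  sv.push_back(a);
  sv.push_back(b);
  std::vector<Cand> cand;
  enumerate_cands(sv, dG, min_duplex, cand);
  std::vector<int> os, ts, ln;
  std::vector<double> en;
  for (size_t k = 0; k < cand.size(); ++k) {
    if (cand[k].o != 0) continue; // report a-vs-b direction only
    os.push_back(cand[k].o_start);
    ts.push_back(cand[k].t_start);
    ln.push_back(cand[k].len);
    en.push_back(cand[k].energy);
  }
  return DataFrame::create(_["o_start"] = os, _["t_start"] = ts,
                           _["len"] = ln, _["energy"] = en);
}

// Kinetic annealing as a weighted race. Every candidate duplex run gets a
// Gumbel-perturbed log-weight (-E - dG_assoc)/RT; every molecule also gets a
// "stay unbound" pseudo-candidate with log-weight 0. Processing items in
// decreasing perturbed order is equivalent to repeatedly sampling among the
// remaining feasible items with probability proportional to exp(log-weight):
// strong duplexes tend to lock in first, weak contacts lose the race to the
// unbound state. The result is one kinetically trapped configuration, not a
// free-energy minimum.
//
// Role model (v1): a molecule bound as an oligo occupies one template; a
// molecule carrying bound oligos is a template; roles are exclusive, so no
// branched three-molecule networks form. Template positions claimed by an
// accepted binding are excluded for later candidates (exclusivity).
// [[Rcpp::export]]
List anneal_cpp(List seqs, NumericMatrix dG, int min_duplex, double RT,
                double dg_assoc) {
  const int M = seqs.size();
  std::vector<IntegerVector> sv(M);
  for (int i = 0; i < M; ++i) sv[i] = seqs[i];

  std::vector<Cand> cand;
  enumerate_cands(sv, dG, min_duplex, cand);
  const int C = (int)cand.size();

  // keys: candidates 0..C-1, pseudo-unbound C..C+M-1
  std::vector<double> key(C + M);
  for (int k = 0; k < C; ++k) {
    double lw = (-cand[k].energy - dg_assoc) / RT;
    double u = unif_rand();
    key[k] = lw - std::log(-std::log(u));
  }
  for (int m = 0; m < M; ++m) {
    double u = unif_rand();
    key[C + m] = 0.0 - std::log(-std::log(u));
  }
  std::vector<int> ord(C + M);
  for (int k = 0; k < C + M; ++k) ord[k] = k;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return key[a] > key[b]; });

  std::vector<char> bound_oligo(M, 0), declined(M, 0), is_template(M, 0);
  std::vector<std::vector<char> > cover(M);
  std::vector<int> acc; // accepted candidate indices

  for (int k = 0; k < C + M; ++k) {
    const int id = ord[k];
    if (id >= C) { // pseudo: molecule settles unbound (may still template)
      const int m = id - C;
      if (!bound_oligo[m] && !declined[m] && !is_template[m]) declined[m] = 1;
      continue;
    }
    const Cand& c = cand[id];
    if (bound_oligo[c.o] || declined[c.o] || is_template[c.o]) continue;
    if (bound_oligo[c.t]) continue;
    if (!cover[c.t].empty()) {
      bool clash = false;
      for (int q = c.t_start; q < c.t_start + c.len; ++q)
        if (cover[c.t][q]) { clash = true; break; }
      if (clash) continue;
    }
    // accept
    bound_oligo[c.o] = 1;
    is_template[c.t] = 1;
    if (cover[c.t].empty()) cover[c.t].assign(sv[c.t].size(), 0);
    for (int q = c.t_start; q < c.t_start + c.len; ++q) cover[c.t][q] = 1;
    acc.push_back(id);
  }

  const int B = (int)acc.size();
  IntegerVector templ(B), oligo(B), t_start(B), o_start(B), len(B);
  NumericVector energy(B);
  for (int b = 0; b < B; ++b) {
    const Cand& c = cand[acc[b]];
    templ[b] = c.t + 1; // 1-based molecule ids for R
    oligo[b] = c.o + 1;
    t_start[b] = c.t_start;
    o_start[b] = c.o_start;
    len[b] = c.len;
    energy[b] = c.energy;
  }
  LogicalVector unbound(M);
  for (int m = 0; m < M; ++m)
    unbound[m] = !bound_oligo[m] && !is_template[m];
  return List::create(
      _["bindings"] = DataFrame::create(
          _["templ"] = templ, _["oligo"] = oligo, _["t_start"] = t_start,
          _["o_start"] = o_start, _["len"] = len, _["energy"] = energy),
      _["unbound"] = unbound, _["n_candidates"] = C);
}
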