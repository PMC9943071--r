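// Forward Wright-Fisher trajectories with viability selection, the
// trajectory-conditioned structured coalescent of a derived and an ancestral
// allelic class communicating via recombination, and a plain Kingman sampler
// with infinite-sites mutation.  R's RNG is used throughout.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Forward simulation from a single copy, rejected unless the allele is still
// segregating age_gens generations after it arose (and, optionally, its
// present-day frequency lies in [freq_lo, freq_hi]).  Genotype fitnesses are
// (w_aa, w_Aa, w_AA) = (1, 1+s*h, 1+s).
// [[Rcpp::export]]
List cpp_wf_trajectory(int N, double s, double h, int age_gens,
                       int max_tries, double freq_lo, double freq_hi) {
  const double wAA = 1.0 + s, wAa = 1.0 + s * h, waa = 1.0;
  const double twoN = 2.0 * N;
  NumericVector traj(age_gens + 1);
  long tries = 0;
  while (tries < max_tries) {
    ++tries;
    double x = 1.0 / twoN;
    traj[0] = x;
    bool alive = true;
    for (int g = 1; g <= age_gens; ++g) {
      double num = x * x * wAA + x * (1.0 - x) * wAa;
      double wbar = x * x * wAA + 2.0 * x * (1.0 - x) * wAa +
                    (1.0 - x) * (1.0 - x) * waa;
      double xp = num / wbar;
      double j = R::rbinom(twoN, xp);
      if (j <= 0.0 || j >= twoN) { alive = false; break; }
      x = j / twoN;
      traj[g] = x;
    }
    if (alive && traj[age_gens] >= freq_lo && traj[age_gens] <= freq_hi) {
      return List::create(_["trajectory"] = traj, _["tries"] = (double)tries,
                          _["accepted"] = true);
    }
  }
  return List::create(_["trajectory"] = R_NilValue, _["tries"] = (double)tries,
                      _["accepted"] = false);
}

namespace {

// Drop infinite-sites mutations on a completed genealogy and return the
// haplotype matrix (n x S).  Branch lengths in generations; per-generation
// per-lineage mutation rate mu.
IntegerMatrix drop_mutations(int n, const std::vector<double>& ntime,
                             const std::vector<int>& parent,
                             const std::vector<int>& child1,
                             const std::vector<int>& child2, double mu) {
  const int root = 2 * n - 2;
  std::vector<int> mut_edges;
  for (int v = 0; v < root; ++v) {
    double len = ntime[parent[v]] - ntime[v];
    int k = (int)R::rpois(len * mu);
    for (int i = 0; i < k; ++i) mut_edges.push_back(v);
  }
  IntegerMatrix mat(n, (int)mut_edges.size());
  std::vector<int> stack;
  for (size_t s = 0; s < mut_edges.size(); ++s) {
    stack.clear();
    stack.push_back(mut_edges[s]);
    while (!stack.empty()) {
      int v = stack.back();
      stack.pop_back();
      if (v < n) {
        mat(v, (int)s) = 1;
      } else {
        stack.push_back(child1[v]);
        stack.push_back(child2[v]);
      }
    }
  }
  return mat;
}

}  // namespace

// Structured coalescent of n_der derived-class and n - n_der ancestral-class
// lineages conditioned on a forward trajectory traj (traj[0] = frequency at
// the allele's origin, traj[age] = present-day frequency).  Backward in time,
// within-class pairs coalesce at rate C(k,2)/(2N x) (resp. 2N(1-x)); a
// neutral-locus lineage switches class at rate rho/(4N) times the other
// class's frequency.  At the origin the derived class collapses and joins
// the ancestral class; the remainder is a neutral single-population
// coalescent with size N.  theta = 4*N*mu for the surveyed locus.
// [[Rcpp::export]]
List cpp_traj_coalescent(NumericVector traj, int N, int n, int n_der,
                         double theta, double rho) {
  const int age = traj.size() - 1;
  const int nnode = 2 * n - 1;
  const double twoN = 2.0 * N;
  const double mu = theta / (4.0 * N);

  std::vector<double> ntime(nnode, 0.0);
  std::vector<int> parent(nnode, -1), child1(nnode, -1), child2(nnode, -1);
  std::vector<int> der, anc;
  for (int i = 0; i < n_der; ++i) der.push_back(i);
  for (int i = n_der; i < n; ++i) anc.push_back(i);
  int nn = n;

  auto coalesce = [&](std::vector<int>& cls, double t) {
    int k = cls.size();
    int i = (int)(unif_rand() * k);
    if (i == k) i = k - 1;
    int j = (int)(unif_rand() * (k - 1));
    if (j >= k - 1) j = k - 2;
    if (j >= i) ++j;
    int a = cls[i], b = cls[j];
    ntime[nn] = t;
    parent[a] = nn;
    parent[b] = nn;
    child1[nn] = a;
    child2[nn] = b;
    cls[i] = nn;
    cls[j] = cls.back();
    cls.pop_back();
    ++nn;
  };

  // phase 1: trajectory-covered epoch, generation by generation
  for (int g = 0; g < age && (der.size() + anc.size()) > 1; ++g) {
    double x = traj[age - g];  // frequency during backward generation g
    if (x <= 0.0 || x >= 1.0)
      stop("trajectory hits an absorbing frequency before the allele's origin");
    double tloc = 0.0;
    for (;;) {
      double kd = (double)der.size(), ka = (double)anc.size();
      double cd = kd * (kd - 1.0) / 2.0 / (twoN * x);
      double ca = ka * (ka - 1.0) / 2.0 / (twoN * (1.0 - x));
      double sd = der.empty() ? 0.0 : kd * rho / (4.0 * N) * (1.0 - x);
      double sa = anc.empty() ? 0.0 : ka * rho / (4.0 * N) * x;
      double R = cd + ca + sd + sa;
      if (R <= 0.0) break;
      double dt = exp_rand() / R;
      if (tloc + dt >= 1.0) break;
      tloc += dt;
      double u = unif_rand() * R;
      double t = g + tloc;
      if (u < cd) {
        coalesce(der, t);
      } else if (u < cd + ca) {
        coalesce(anc, t);
      } else if (u < cd + ca + sd) {
        int i = (int)(unif_rand() * der.size());
        if (i == (int)der.size()) i = der.size() - 1;
        anc.push_back(der[i]);
        der[i] = der.back();
        der.pop_back();
      } else {
        int i = (int)(unif_rand() * anc.size());
        if (i == (int)anc.size()) i = anc.size() - 1;
        der.push_back(anc[i]);
        anc[i] = anc.back();
        anc.pop_back();
      }
      if (der.size() + anc.size() <= 1) break;
    }
  }

  // origin: collapse the derived class, then hand its survivor to the
  // ancestral background
  double t0 = (double)age;
  while (der.size() > 1) coalesce(der, t0);
  if (der.size() == 1) {
    anc.push_back(der[0]);
    der.clear();
  }

  // phase 2: neutral coalescent, size N, continuous time
  double t = t0;
  while (anc.size() > 1) {
    double k = (double)anc.size();
    double rate = k * (k - 1.0) / 2.0 / twoN;
    t += exp_rand() / rate;
    coalesce(anc, t);
  }

  IntegerMatrix mat = drop_mutations(n, ntime, parent, child1, child2, mu);
  return List::create(_["haplotypes"] = mat, _["n_derived"] = n_der,
                      _["tmrca_gens"] = ntime[nnode - 1]);
}

// Plain neutral Kingman coalescent sample with infinite-sites mutation.
// Branch lengths in units of 2N generations; theta = 4*N*mu, so the
// per-branch mutation intensity is theta/2 per unit of scaled time.
// [[Rcpp::export]]
IntegerMatrix cpp_kingman_sample(int n, double theta) {
  const int nnode = 2 * n - 1;
  std::vector<double> ntime(nnode, 0.0);
  std::vector<int> parent(nnode, -1), child1(nnode, -1), child2(nnode, -1);
  std::vector<int> act(n);
  for (int i = 0; i < n; ++i) act[i] = i;
  int nn = n;
  double t = 0.0;
  while (act.size() > 1) {
    double k = (double)act.size();
    t += exp_rand() / (k * (k - 1.0) / 2.0);
    int i = (int)(unif_rand() * k);
    if (i == (int)k) i = k - 1;
    int j = (int)(unif_rand() * (k - 1));
    if (j >= (int)k - 1) j = k - 2;
    if (j >= i) ++j;
    int a = act[i], b = act[j];
    ntime[nn] = t;
    parent[a] = nn;
    parent[b] = nn;
    child1[nn] = a;
    child2[nn] = b;
    act[i] = nn;
    act[j] = act.back();
    act.pop_back();
    ++nn;
  }
  return drop_mutations(n, ntime, parent, child1, child2, theta / 2.0);
}
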