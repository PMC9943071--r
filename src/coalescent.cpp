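// Event-driven structured coalescent over piecewise-constant demographies.
//
// Time runs backward from the present in units of generations.  Populations
// have piecewise-constant diploid sizes; "events" move every lineage of a
// source population into a destination population (a population split viewed
// backward); an optional island-migration phase with symmetric per-generation
// migrant fraction m among a set of demes switches on at a given time.  Tips
// may enter at positive (ancient-sampling) times.  One mutation is placed on
// each genealogy with probability proportional to branch length; the derived
// state is inherited by all descendants of the mutated edge.
//
// All randomness is drawn from R's RNG so set.seed() on the R side governs
// reproducibility.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Schedule {
  std::vector<double> times;  // ascending, first is 0
  std::vector<double> sizes;  // diploid N from times[i] until times[i+1]
};

inline int resolve(std::vector<int>& redirect, int p) {
  while (redirect[p] != p) p = redirect[p];
  return p;
}

}  // namespace

// [[Rcpp::export]]
List cpp_sim_loci(IntegerVector tip_pop, NumericVector tip_time,
                  List pop_sizes, NumericVector ev_time, IntegerVector ev_src,
                  IntegerVector ev_dst, double mig_time,
                  IntegerVector mig_demes, double mig_rate, int n_loci,
                  NumericVector query_times, bool return_matrix,
                  IntegerVector tip_group, int n_groups) {
  const int n = tip_pop.size();
  const int npop = pop_sizes.size();
  const int nev = ev_time.size();
  const int nq = query_times.size();
  const int nnode = 2 * n - 1;

  std::vector<Schedule> sched(npop);
  for (int p = 0; p < npop; ++p) {
    NumericMatrix m = pop_sizes[p];
    for (int i = 0; i < m.nrow(); ++i) {
      sched[p].times.push_back(m(i, 0));
      sched[p].sizes.push_back(m(i, 1));
    }
  }

  // tips ordered by entry time
  std::vector<int> tip_order(n);
  for (int i = 0; i < n; ++i) tip_order[i] = i;
  std::stable_sort(tip_order.begin(), tip_order.end(),
                   [&](int a, int b) { return tip_time[a] < tip_time[b]; });

  std::vector<bool> is_mig(npop, false);
  for (int i = 0; i < mig_demes.size(); ++i) is_mig[mig_demes[i]] = true;
  const int n_demes = mig_demes.size();

  // outputs
  LogicalMatrix derived_mat =
      return_matrix ? LogicalMatrix(n_loci, n) : LogicalMatrix(0, 0);
  IntegerMatrix group_counts(n_loci, n_groups);
  IntegerMatrix q_total(nq > 0 ? n_loci : 0, nq);
  IntegerMatrix q_derived(nq > 0 ? n_loci : 0, nq);

  // per-locus workspace
  std::vector<double> ntime(nnode);
  std::vector<int> parent(nnode), child1(nnode), child2(nnode);
  std::vector<std::vector<int>> active(npop);
  std::vector<int> size_idx(npop), redirect(npop);
  std::vector<double> coal_rate(npop);
  std::vector<bool> flag(nnode);
  std::vector<int> stack;

  for (int locus = 0; locus < n_loci; ++locus) {
    for (int p = 0; p < npop; ++p) {
      active[p].clear();
      size_idx[p] = 0;
      redirect[p] = p;
    }
    std::fill(parent.begin(), parent.end(), -1);
    for (int v = 0; v < n; ++v) ntime[v] = tip_time[v];

    double t = 0.0;
    int next_tip = 0, next_ev = 0, nn = n, active_total = 0;
    bool mig_on = false;

    while (active_total > 1 || next_tip < n) {
      // bring state up to time t
      while (next_tip < n && tip_time[tip_order[next_tip]] <= t) {
        int tip = tip_order[next_tip++];
        active[resolve(redirect, tip_pop[tip])].push_back(tip);
        ++active_total;
      }
      while (next_ev < nev && ev_time[next_ev] <= t) {
        int src = ev_src[next_ev];
        if (ev_dst[next_ev] < 0) {
          // scatter: each lineage of src enters a uniform migration deme
          for (int v : active[src]) {
            int di = (int)(unif_rand() * n_demes);
            if (di >= n_demes) di = n_demes - 1;
            active[mig_demes[di]].push_back(v);
          }
          active[src].clear();
          redirect[src] = mig_demes[0];  // late-entering tips join deme 1
        } else {
          int dst = resolve(redirect, ev_dst[next_ev]);
          for (int v : active[src]) active[dst].push_back(v);
          active[src].clear();
          redirect[src] = dst;
        }
        ++next_ev;
      }
      for (int p = 0; p < npop; ++p) {
        const Schedule& s = sched[p];
        while (size_idx[p] + 1 < (int)s.times.size() &&
               s.times[size_idx[p] + 1] <= t)
          ++size_idx[p];
      }
      if (!mig_on && t >= mig_time) mig_on = true;

      // rates
      double R = 0.0;
      int k_mig = 0;
      for (int p = 0; p < npop; ++p) {
        double k = (double)active[p].size();
        coal_rate[p] = k * (k - 1.0) / 2.0 / (2.0 * sched[p].sizes[size_idx[p]]);
        R += coal_rate[p];
        if (mig_on && is_mig[p]) k_mig += active[p].size();
      }
      double mig_tot = mig_on ? mig_rate * (n_demes - 1) * (double)k_mig : 0.0;
      R += mig_tot;

      // next deterministic boundary
      double tb = R_PosInf;
      if (next_tip < n) tb = std::min(tb, (double)tip_time[tip_order[next_tip]]);
      if (next_ev < nev) tb = std::min(tb, (double)ev_time[next_ev]);
      if (!mig_on && mig_time > t) tb = std::min(tb, mig_time);
      for (int p = 0; p < npop; ++p) {
        const Schedule& s = sched[p];
        if (size_idx[p] + 1 < (int)s.times.size())
          tb = std::min(tb, s.times[size_idx[p] + 1]);
      }

      if (R <= 0.0) {
        if (!R_FINITE(tb)) stop("coalescent stalled: no rates and no boundary");
        t = tb;
        continue;
      }
      double dt = exp_rand() / R;
      if (t + dt >= tb) {
        t = tb;
        continue;
      }
      t += dt;

      double u = unif_rand() * R;
      int done = -1;
      for (int p = 0; p < npop; ++p) {
        if (u < coal_rate[p]) {
          // coalesce a uniform pair in p
          std::vector<int>& A = active[p];
          int k = A.size();
          int i = (int)(unif_rand() * k);
          if (i == k) i = k - 1;
          int j = (int)(unif_rand() * (k - 1));
          if (j >= k - 1) j = k - 2;
          if (j >= i) ++j;
          int a = A[i], b = A[j];
          ntime[nn] = t;
          parent[a] = nn;
          parent[b] = nn;
          child1[nn] = a;
          child2[nn] = b;
          A[i] = nn;
          A[j] = A.back();
          A.pop_back();
          ++nn;
          --active_total;
          done = p;
          break;
        }
        u -= coal_rate[p];
      }
      if (done < 0) {
        // migration: uniform lineage among migration demes
        int r = (int)(u / (mig_rate * (n_demes - 1)));
        if (r >= k_mig) r = k_mig - 1;
        int src = -1, idx = -1;
        for (int di = 0; di < n_demes; ++di) {
          int p = mig_demes[di];
          if (r < (int)active[p].size()) {
            src = p;
            idx = r;
            break;
          }
          r -= active[p].size();
        }
        int dd = (int)(unif_rand() * (n_demes - 1));
        if (dd >= n_demes - 1) dd = n_demes - 2;
        int dst = -1, seen = 0;
        for (int di = 0; di < n_demes; ++di) {
          if (mig_demes[di] == src) continue;
          if (seen++ == dd) { dst = mig_demes[di]; break; }
        }
        active[dst].push_back(active[src][idx]);
        active[src][idx] = active[src].back();
        active[src].pop_back();
      }
    }
    if (nn != nnode) stop("internal error: incomplete genealogy");
    const int root = nnode - 1;

    // place one mutation, branch-length weighted
    double L = 0.0;
    for (int v = 0; v < root; ++v) L += ntime[parent[v]] - ntime[v];
    double target = unif_rand() * L, acc = 0.0, mut_t = 0.0;
    int edge = root - 1;
    for (int v = 0; v < root; ++v) {
      double len = ntime[parent[v]] - ntime[v];
      if (target < acc + len) {
        edge = v;
        mut_t = ntime[v] + (target - acc);
        break;
      }
      acc += len;
    }

    // mark subtree of the mutated edge
    std::fill(flag.begin(), flag.end(), false);
    stack.clear();
    stack.push_back(edge);
    while (!stack.empty()) {
      int v = stack.back();
      stack.pop_back();
      flag[v] = true;
      if (v >= n) {
        stack.push_back(child1[v]);
        stack.push_back(child2[v]);
      }
    }

    for (int v = 0; v < n; ++v) {
      if (flag[v]) ++group_counts(locus, tip_group[v]);
      if (return_matrix) derived_mat(locus, v) = flag[v];
    }

    for (int qi = 0; qi < nq; ++qi) {
      double q = query_times[qi];
      int tot = 0, der = 0;
      for (int v = 0; v < root; ++v) {
        if (ntime[v] <= q && ntime[parent[v]] > q) {
          ++tot;
          if (flag[v] && (v != edge || mut_t > q)) ++der;
        }
      }
      if (ntime[root] <= q) ++tot;  // root lineage persists pastward
      q_total(locus, qi) = tot;
      q_derived(locus, qi) = der;
    }
  }

  List out = List::create(_["group_counts"] = group_counts);
  if (return_matrix) out["derived"] = derived_mat;
  if (nq > 0) {
    out["lineages_total"] = q_total;
    out["lineages_derived"] = q_derived;
  }
  return out;
}
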