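#include <Rcpp.h>
#include <list>
#include <vector>
using namespace Rcpp;

// Coalescent machinery shared by the simulators.
//
// Conventions: diploid effective sizes, per-pair coalescence rate 1/(2*Ne)
// per generation (k lineages: k*(k-1)/2 / (2*Ne)); time in generations
// before present; epoch e of a piecewise-constant demography is active on
// [t_start[e], t_start[e+1]) and the last epoch extends to infinity.
// Mutation follows the infinite-sites model: each branch accumulates
// mutations at rate theta_rep = mu * L / reps per generation; a mutation on
// a branch subtending s sample lineages contributes one site with derived
// count s. R-level wrappers control the RNG via set.seed().

static inline int sample_int(int k) {
  // uniform integer in [0, k)
  int i = (int)(unif_rand() * k);
  return (i >= k) ? (k - 1) : i;
}

// Single-population folded-SFS simulator under piecewise-constant Ne.
// Returns the UNFOLDED expected/realised counts xi_1..xi_{n-1}, summed over
// all replicate loci. poisson=true draws Poisson mutation counts;
// poisson=false accumulates the expectation mu*L*branch_length directly
// (Rao-Blackwellised estimate used for likelihood expectations).
// [[Rcpp::export(name = ".sim_sfs_single_cpp")]]
NumericVector sim_sfs_single_cpp(NumericVector ne, NumericVector t_start,
                                 int n, double theta_rep, int reps,
                                 bool poisson) {
  NumericVector xi(n - 1);
  const int nep = ne.size();
  std::vector<int> sz(n);

  for (int r = 0; r < reps; ++r) {
    int k = n;
    for (int i = 0; i < n; ++i) sz[i] = 1;
    double t = 0.0;
    int ep = 0;
    while (k > 1) {
      while (ep + 1 < nep && t >= t_start[ep + 1]) ++ep;
      double rate = 0.5 * k * (k - 1.0) / (2.0 * ne[ep]);
      double w = exp_rand() / rate;
      double t_next = (ep + 1 < nep) ? t_start[ep + 1] : R_PosInf;
      bool coal = (t + w < t_next);
      double dt = coal ? w : (t_next - t);
      for (int i = 0; i < k; ++i) {
        double m = poisson ? R::rpois(theta_rep * dt) : theta_rep * dt;
        if (m > 0.0) xi[sz[i] - 1] += m;
      }
      t += dt;
      if (coal) {
        int a = sample_int(k);
        int b = sample_int(k - 1);
        if (b >= a) ++b;
        int lo = (a < b) ? a : b, hi = (a < b) ? b : a;
        sz[lo] += sz[hi];
        sz[hi] = sz[k - 1];
        --k;
      }
    }
  }
  return xi;
}

// Single-population haplotype simulator: returns, for `loci` independent
// genealogies of n haploid samples, the carrier sets of every segregating
// site (1-based sample indices). theta_locus = mu * L_per_locus.
// [[Rcpp::export(name = ".sim_haplotypes_cpp")]]
List sim_haplotypes_cpp(NumericVector ne, NumericVector t_start,
                        int n, double theta_locus, int loci) {
  const int nep = ne.size();
  std::vector< std::vector<int> > members(n);
  std::list< std::vector<int> > sites;
  int n_sites = 0;

  for (int r = 0; r < loci; ++r) {
    int k = n;
    for (int i = 0; i < n; ++i) members[i].assign(1, i + 1);
    double t = 0.0;
    int ep = 0;
    while (k > 1) {
      while (ep + 1 < nep && t >= t_start[ep + 1]) ++ep;
      double rate = 0.5 * k * (k - 1.0) / (2.0 * ne[ep]);
      double w = exp_rand() / rate;
      double t_next = (ep + 1 < nep) ? t_start[ep + 1] : R_PosInf;
      bool coal = (t + w < t_next);
      double dt = coal ? w : (t_next - t);
      for (int i = 0; i < k; ++i) {
        int m = (int)R::rpois(theta_locus * dt);
        for (int j = 0; j < m; ++j) {
          sites.push_back(members[i]);
          ++n_sites;
        }
      }
      t += dt;
      if (coal) {
        int a = sample_int(k);
        int b = sample_int(k - 1);
        if (b >= a) ++b;
        int lo = (a < b) ? a : b, hi = (a < b) ? b : a;
        members[lo].insert(members[lo].end(), members[hi].begin(),
                           members[hi].end());
        members[hi] = members[k - 1];
        --k;
      }
    }
  }

  List out(n_sites);
  int i = 0;
  for (std::list< std::vector<int> >::iterator it = sites.begin();
       it != sites.end(); ++it, ++i)
    out[i] = IntegerVector(it->begin(), it->end());
  return out;
}

// Two-deme isolation-with-migration simulator. Samples n1 + n2 haploid
// lineages; deme sizes npop1/npop2 up to tdiv (backward in time), then a
// merged ancestral population of size ncur on [tdiv, tsep) and nanc beyond
// when anc_change is true, or nanc throughout when false. m1/m2 are
// per-lineage backward migration rates per generation (lineage currently in
// deme 1 traces back to deme 2 at rate m1, and vice versa). Returns the
// UNFOLDED joint spectrum over derived counts (i in 0..n1) x (j in 0..n2),
// cells (0,0) and (n1,n2) never receive mass.
// [[Rcpp::export(name = ".sim_sfs_two_deme_cpp")]]
NumericMatrix sim_sfs_two_deme_cpp(int n1, int n2,
                                   double npop1, double npop2,
                                   double ncur, double nanc,
                                   double tdiv, double tsep,
                                   double m1, double m2,
                                   bool anc_change,
                                   double theta_rep, int reps,
                                   bool poisson) {
  NumericMatrix counts(n1 + 1, n2 + 1);
  const int n = n1 + n2;
  std::vector<int> a(n), b(n), deme(n);

  for (int r = 0; r < reps; ++r) {
    int k = n;
    for (int i = 0; i < n; ++i) {
      a[i] = (i < n1) ? 1 : 0;
      b[i] = (i < n1) ? 0 : 1;
      deme[i] = (i < n1) ? 0 : 1;
    }
    double t = 0.0;
    bool merged = false;

    while (k > 1) {
      int k1 = 0;
      for (int i = 0; i < k; ++i) k1 += (deme[i] == 0);
      int k2 = k - k1;

      double rc1, rc2, rm1, rm2, t_next;
      if (!merged) {
        rc1 = 0.5 * k1 * (k1 - 1.0) / (2.0 * npop1);
        rc2 = 0.5 * k2 * (k2 - 1.0) / (2.0 * npop2);
        rm1 = k1 * m1;
        rm2 = k2 * m2;
        t_next = tdiv;
      } else {
        double size_now, bound;
        if (anc_change && t < tsep) {
          size_now = ncur;
          bound = tsep;
        } else {
          size_now = nanc;
          bound = R_PosInf;
        }
        rc1 = 0.5 * k * (k - 1.0) / (2.0 * size_now);
        rc2 = rm1 = rm2 = 0.0;
        t_next = bound;
      }
      // fixed two-draw consumption per iteration keeps common-random-number
      // streams aligned across models whose event-rate sets differ (e.g.
      // zero- vs tiny-migration nests)
      double e_draw = exp_rand();
      double u_draw = unif_rand();
      double total = rc1 + rc2 + rm1 + rm2;
      double w = (total > 0.0) ? e_draw / total : R_PosInf;
      bool event = (t + w < t_next);
      double dt = event ? w : (t_next - t);

      if (theta_rep > 0.0 && dt > 0.0) {
        for (int i = 0; i < k; ++i) {
          double m = poisson ? R::rpois(theta_rep * dt) : theta_rep * dt;
          if (m > 0.0) counts(a[i], b[i]) += m;
        }
      }
      t += dt;

      if (!event) {
        if (!merged && t >= tdiv) {
          merged = true;
          for (int i = 0; i < k; ++i) deme[i] = 0;
        }
        continue;
      }

      double u = u_draw * total;
      if (u < rc1 + rc2) {
        // coalescence within deme 0 (u < rc1) or deme 1
        int target = (u < rc1) ? 0 : 1;
        int kt = (target == 0) ? k1 : k2;
        int ia = sample_int(kt);
        int ib = sample_int(kt - 1);
        if (ib >= ia) ++ib;
        // map within-deme indices to lineage indices
        int la = -1, lb = -1, seen = 0;
        for (int i = 0; i < k; ++i) {
          if (deme[i] == target) {
            if (seen == ia) la = i;
            if (seen == ib) lb = i;
            ++seen;
          }
        }
        int lo = (la < lb) ? la : lb, hi = (la < lb) ? lb : la;
        a[lo] += a[hi];
        b[lo] += b[hi];
        a[hi] = a[k - 1];
        b[hi] = b[k - 1];
        deme[hi] = deme[k - 1];
        --k;
      } else if (u < rc1 + rc2 + rm1) {
        // a deme-0 lineage migrates (backward) to deme 1
        int ia = sample_int(k1), seen = 0;
        for (int i = 0; i < k; ++i)
          if (deme[i] == 0 && seen++ == ia) { deme[i] = 1; break; }
      } else {
        int ia = sample_int(k2), seen = 0;
        for (int i = 0; i < k; ++i)
          if (deme[i] == 1 && seen++ == ia) { deme[i] = 0; break; }
      }
    }
  }
  return counts;
}
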