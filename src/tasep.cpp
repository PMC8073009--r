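// Continuous-time exclusion-process (l-TASEP) simulation of ribosome
// traffic on an mRNA lattice in codon units, with open boundaries, a
// termination step at each ORF stop, optional readthrough, and an optional
// second ORF to probe initiation occlusion by terminating ribosomes.
#include <Rcpp.h>
#include <random>
#include <vector>
using namespace Rcpp;

struct Rib {
  int pos;       // leftmost occupied site (1-based), A-site proxy
  int stop;      // stop site of its ORF (0 = readthrough mode: runs to end)
  int orf;       // 1 or 2
};

// [[Rcpp::export(name = ".tasep_run")]]
List tasep_run(int length1, int footprint, double alpha, double k,
               double beta, double gamma, int start2, int length2,
               double alpha2, double t_total, double burnin,
               int seed) {
  if (burnin >= t_total) stop("burn-in must be shorter than total time");
  const int L = std::max(length1, start2 > 0 ? start2 + length2 - 1 : 0);
  const int stop1 = length1;
  const int stop2 = start2 > 0 ? start2 + length2 - 1 : 0;
  std::mt19937_64 rng(seed);
  std::uniform_real_distribution<double> U(0.0, 1.0);

  std::vector<Rib> ribs;  // kept sorted by pos ascending
  std::vector<double> occ(L, 0.0);
  double t = 0.0, t_acc = 0.0, queue_acc = 0.0;
  long completions1 = 0, completions2 = 0, readthroughs = 0;
  long init1 = 0, init2 = 0;
  long cross_first = 0, cross_mid = 0;  // moves across site 2 and mid-lattice
  const int mid = length1 / 2;

  auto site_free = [&](int from, int to) {
    // true if no ribosome overlaps [from, to]
    for (const Rib &r : ribs) {
      int r2 = r.pos + footprint - 1;
      if (r.pos <= to && r2 >= from) return false;
    }
    return true;
  };

  while (t < t_total) {
    // enumerate events
    std::vector<double> rates;
    std::vector<int> kind;   // 0 init1, 1 init2, 2+i move/terminate rib i
    if (alpha > 0 && site_free(1, footprint)) {
      rates.push_back(alpha); kind.push_back(0);
    }
    if (start2 > 0 && alpha2 > 0 && site_free(start2, start2 + footprint - 1)) {
      rates.push_back(alpha2); kind.push_back(1);
    }
    for (size_t i = 0; i < ribs.size(); ++i) {
      const Rib &r = ribs[i];
      if (r.stop > 0 && r.pos == r.stop) {
        double rt = beta + gamma;
        if (rt > 0) { rates.push_back(rt); kind.push_back(2 + (int)i); }
      } else {
        // elongation (or exit at lattice end)
        int next_need = r.pos + footprint;  // site newly covered after move
        bool free_ahead = (r.pos >= L) ? true
          : (next_need > L ? true
             : (i + 1 < ribs.size() ? ribs[i + 1].pos >= next_need + 1
                                    : true));
        // note: only the next ribosome ahead can block (sorted order)
        if (r.pos >= L) free_ahead = true;
        if (free_ahead && k > 0) { rates.push_back(k); kind.push_back(2 + (int)i); }
      }
    }
    double R = 0.0;
    for (double x : rates) R += x;
    if (R <= 0) {  // absorbing state: advance time to the end
      double w = t_total - std::max(t, burnin);
      if (w > 0) {
        t_acc += w;
        for (const Rib &r : ribs)
          for (int sIdx = r.pos; sIdx <= std::min(r.pos + footprint - 1, L); ++sIdx)
            occ[sIdx - 1] += w;
        int q = 0;
        for (int i = (int)ribs.size() - 1; i >= 0; --i) {
          if (ribs[i].orf != 1) continue;
          if (q == 0) {
            if (ribs[i].pos == stop1) q = 1;
            else if (ribs[i].pos > stop1) continue;
            else break;
          } else if (i + 1 < (int)ribs.size() &&
                     ribs[i + 1].pos - ribs[i].pos == footprint) ++q;
          else break;
        }
        queue_acc += w * q;
      }
      t = t_total;
      break;
    }
    std::exponential_distribution<double> E(R);
    double dt = E(rng);
    double t_new = std::min(t + dt, t_total);
    double dt_eff = t_new - t;
    double w_start = std::max(t, burnin);
    if (t_new > burnin) {
      double w = t_new - w_start;
      t_acc += w;
      for (const Rib &r : ribs)
        for (int sIdx = r.pos; sIdx <= std::min(r.pos + footprint - 1, L); ++sIdx)
          occ[sIdx - 1] += w;
      // queue at stop1: contiguous chain of blocked ribosomes ending at stop1
      int q = 0;
      for (int i = (int)ribs.size() - 1; i >= 0; --i) {
        if (ribs[i].orf != 1) continue;
        if (q == 0) {
          if (ribs[i].pos == stop1) q = 1;
          else if (ribs[i].pos > stop1) continue;
          else break;
        } else {
          // previous counted ribosome is directly behind the last one
          if (i + 1 < (int)ribs.size() &&
              ribs[i + 1].pos - ribs[i].pos == footprint &&
              ribs[i].orf == 1)
            ++q;
          else break;
        }
      }
      queue_acc += w * q;
    }
    t = t_new;
    (void)dt_eff;
    if (t >= t_total) break;

    // pick event
    double u = U(rng) * R, acc2 = 0.0;
    int ev = -1;
    for (size_t i = 0; i < rates.size(); ++i) {
      acc2 += rates[i];
      if (u <= acc2) { ev = kind[i]; break; }
    }
    if (ev < 0) ev = kind.back();

    if (ev == 0) {
      Rib r; r.pos = 1; r.stop = stop1; r.orf = 1;
      ribs.insert(ribs.begin(), r);
      if (t >= burnin) ++init1;
    } else if (ev == 1) {
      Rib r; r.pos = start2; r.stop = stop2; r.orf = 2;
      size_t j = 0; while (j < ribs.size() && ribs[j].pos < start2) ++j;
      ribs.insert(ribs.begin() + j, r);
      if (t >= burnin) ++init2;
    } else {
      int i = ev - 2;
      Rib &r = ribs[i];
      if (r.stop > 0 && r.pos == r.stop) {
        // termination vs readthrough
        double u2 = U(rng) * (beta + gamma);
        if (u2 < beta) {
          if (t >= burnin) {
            if (r.orf == 1) ++completions1; else ++completions2;
          }
          ribs.erase(ribs.begin() + i);
        } else {
          if (t >= burnin && r.orf == 1) ++readthroughs;
          r.stop = 0;  // readthrough: elongate to lattice end
        }
      } else {
        if (r.pos + footprint > L && r.pos >= L) {
          ribs.erase(ribs.begin() + i);
        } else if (r.pos >= L) {
          ribs.erase(ribs.begin() + i);
        } else {
          r.pos += 1;
          if (t >= burnin) {
            if (r.pos == 2) ++cross_first;
            if (r.pos == mid + 1) ++cross_mid;
          }
          if (r.pos > L) ribs.erase(ribs.begin() + i);
        }
      }
    }
  }

  double T = t_acc > 0 ? t_acc : 1e-12;
  NumericVector occupancy(L);
  for (int i = 0; i < L; ++i) occupancy[i] = occ[i] / T;
  return List::create(
    _["occupancy"] = occupancy,
    _["time"] = T,
    _["completions1"] = (double)completions1,
    _["completions2"] = (double)completions2,
    _["readthroughs"] = (double)readthroughs,
    _["initiations1"] = (double)init1,
    _["initiations2"] = (double)init2,
    _["cross_first"] = (double)cross_first,
    _["cross_mid"] = (double)cross_mid,
    _["queue_mean"] = queue_acc / T);
}
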