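#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// One replicated interval [s, e] on the global (concatenated-chromosome)
// axis. la/ra say whether the left/right edge is an active fork; edges go
// inactive when the fork is discarded at a chromosome end.
struct Itv {
  double s, e;
  bool la, ra;
};

// Single S-phase of the well-mixed model, fixed time step dt.
//
// Within a step the order is: factor arrivals, firing attempts, fork
// propagation (with passivation, mergers, end discards). The firing
// probability per free factor is 1 - (1 - kon*dt)^Npori with Npori frozen
// at step start; fired origins are chosen without replacement.
//
// All randomness goes through R's RNG (unif_rand / R::rbinom) in a fixed
// draw order, so an R-level re-implementation of the step sees identical
// draws under the same seed.
//
// ori_pos: sorted origin positions on the global axis (kb).
// chrom_ends: cumulative chromosome end coordinates (kb), last = genome length.
// arrivals: sorted factor arrival times (min); length = number of factors.
// [[Rcpp::export]]
List sim_sphase_cpp(NumericVector ori_pos, NumericVector chrom_ends,
                    double v, double kon, NumericVector arrivals, double dt,
                    bool recycle_at_ends, double max_time,
                    bool record_kinetics) {
  const int n_ori = ori_pos.size();
  const int n_chrom = chrom_ends.size();
  const double L_total = n_chrom ? chrom_ends[n_chrom - 1] : 0.0;
  const double eps = 1e-9;

  // origin bookkeeping: 0 potential, 1 fired, 2 passivated
  std::vector<int> status(n_ori, 0);
  std::vector<double> ev_time(n_ori, NA_REAL);
  std::vector<int> pot_idx(n_ori);   // indices of still-potential origins
  std::vector<int> where(n_ori);     // position of origin i in pot_idx
  for (int i = 0; i < n_ori; ++i) { pot_idx[i] = i; where[i] = i; }
  int n_pot = n_ori;

  auto drop_potential = [&](int oi) {
    int j = where[oi], last = n_pot - 1;
    pot_idx[j] = pot_idx[last];
    where[pot_idx[j]] = j;
    n_pot--;
  };

  std::vector<Itv> itv;
  itv.reserve(256);

  // factor pool
  int n_free = 0, bound_halves = 0, lost_halves = 0, spare_halves = 0;
  int n_loaded = 0;
  long n_fired = 0, n_pass = 0, n_merges = 0;
  int arr_ptr = 0;
  const int n_arr = arrivals.size();

  // chromosome of a coordinate: first chrom whose end > x
  auto chrom_of = [&](double x) {
    return (int)(std::upper_bound(chrom_ends.begin(), chrom_ends.end(),
                                  x + 1e-12) - chrom_ends.begin());
  };

  // passivate potential origins with position in [a, b]
  auto passivate_range = [&](double a, double b, double t, int &pass_step) {
    if (b < a) return;
    int lo = (int)(std::lower_bound(ori_pos.begin(), ori_pos.end(), a - eps) -
                   ori_pos.begin());
    for (int k = lo; k < n_ori && ori_pos[k] <= b + eps; ++k) {
      if (status[k] == 0) {
        status[k] = 2;
        ev_time[k] = t;
        drop_potential(k);
        n_pass++; pass_step++;
      }
    }
  };

  std::vector<double> rec_t, rec_nfd, rec_npori, rec_lunrep, rec_fired,
      rec_pass;

  double t = 0.0;
  double l_rep = 0.0;
  bool guard_hit = false;

  while (L_total - l_rep > eps) {
    if (t > max_time) { guard_hit = true; break; }

    // --- arrivals ---
    while (arr_ptr < n_arr && arrivals[arr_ptr] <= t + 1e-12) {
      n_free++; n_loaded++; arr_ptr++;
    }

    const int npori_start = n_pot;
    const int nfd_start = n_free;  // free factors after arrivals, pre-firing
    const double lunrep_start = L_total - l_rep;
    int fired_step = 0, pass_step = 0;

    // --- firing attempts ---
    if (n_free > 0 && npori_start > 0 && kon > 0) {
      double p = 1.0 - std::pow(1.0 - kon * dt, (double)npori_start);
      int k = (int)R::rbinom((double)n_free, p);
      for (int f = 0; f < k && n_pot > 0; ++f) {
        int j = (int)std::floor(unif_rand() * n_pot);
        if (j >= n_pot) j = n_pot - 1;
        int oi = pot_idx[j];
        drop_potential(oi);
        status[oi] = 1;
        ev_time[oi] = t;
        n_fired++; fired_step++;
        n_free--; bound_halves += 2;
        double x = ori_pos[oi];
        Itv nw{x, x, true, true};
        auto pos = std::lower_bound(
            itv.begin(), itv.end(), nw,
            [](const Itv &a, const Itv &b) { return a.s < b.s; });
        itv.insert(pos, nw);
      }
    }

    // --- fork propagation ---
    const double step_len = v * dt;
    for (size_t i = 0; i < itv.size(); ++i) {
      Itv &iv = itv[i];
      int ci = chrom_of(iv.s);
      double cs = ci > 0 ? chrom_ends[ci - 1] : 0.0;
      double ce = chrom_ends[ci];
      if (iv.la) {
        double olds = iv.s;
        iv.s -= step_len;
        if (iv.s <= cs + eps) {
          iv.s = cs;
          iv.la = false;
          bound_halves--;
          if (recycle_at_ends) {
            if (++spare_halves == 2) { spare_halves = 0; n_free++; }
          } else {
            lost_halves++;
          }
        }
        passivate_range(iv.s, olds, t, pass_step);
      }
      if (iv.ra) {
        double olde = iv.e;
        iv.e += step_len;
        if (iv.e >= ce - eps) {
          iv.e = ce;
          iv.ra = false;
          bound_halves--;
          if (recycle_at_ends) {
            if (++spare_halves == 2) { spare_halves = 0; n_free++; }
          } else {
            lost_halves++;
          }
        }
        passivate_range(olde, iv.e, t, pass_step);
      }
    }

    // --- mergers (cascade within the step) ---
    size_t i = 0;
    while (itv.size() > 1 && i + 1 < itv.size()) {
      Itv &a = itv[i];
      Itv &b = itv[i + 1];
      if (chrom_of(a.s) == chrom_of(b.s) && b.s <= a.e + eps) {
        if (a.ra && b.la) {  // two converging forks meet: factor reforms
          n_free++;
          bound_halves -= 2;
          n_merges++;
        }
        a.e = std::max(a.e, b.e);
        a.ra = b.ra;
        itv.erase(itv.begin() + i + 1);
      } else {
        ++i;
      }
    }

    l_rep = 0.0;
    for (auto &iv2 : itv) l_rep += iv2.e - iv2.s;

    if (record_kinetics) {
      rec_t.push_back(t);
      rec_nfd.push_back(nfd_start);
      rec_npori.push_back(npori_start);
      rec_lunrep.push_back(lunrep_start);
      rec_fired.push_back(fired_step);
      rec_pass.push_back(pass_step);
    }

    t += dt;
  }

  if (guard_hit)
    stop("replication did not complete before max_time = %g min "
         "(no firing factors left able to finish?)", max_time);

  IntegerVector st(status.begin(), status.end());
  NumericVector et(ev_time.begin(), ev_time.end());

  List kin = List::create(
      _["time"] = NumericVector(rec_t.begin(), rec_t.end()),
      _["nfd"] = NumericVector(rec_nfd.begin(), rec_nfd.end()),
      _["n_pori"] = NumericVector(rec_npori.begin(), rec_npori.end()),
      _["l_unrep"] = NumericVector(rec_lunrep.begin(), rec_lunrep.end()),
      _["n_fired"] = NumericVector(rec_fired.begin(), rec_fired.end()),
      _["n_passivated"] = NumericVector(rec_pass.begin(), rec_pass.end()));

  return List::create(
      _["kinetics"] = kin, _["status"] = st, _["event_time"] = et,
      _["replication_time"] = t,
      _["n_fired"] = (double)n_fired, _["n_passivated"] = (double)n_pass,
      _["n_merges"] = (double)n_merges, _["n_loaded"] = n_loaded,
      _["n_free_final"] = n_free, _["lost_halves"] = lost_halves);
}
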