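#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Occupancy automaton: asynchronous single-site grand-canonical dynamics on
// a square lattice with open (zero-padded) boundaries.
//
// Rates follow first-order (barrier) kinetics with the transition state at
// the unbound-diffuser level: an association attempt at a valid empty site
// succeeds with  p_ins ~ exp(mu),  mu = ln(C_U a^2)  (arrival limited by the
// diffuser concentration, not by the final binding energy), and a bound
// molecule unbinds with  p_del ~ exp(depth),  where
//   depth = E_pp * n_bonds + dPsi_re  (< 0 for a bound state)
// is its binding energy relative to the unbound diffuser;
// dPsi_re = dPsi_window - 4*psi1 is the membrane rearrangement energy of
// binding, the 4*psi1 term being the deformation an isolated diffuser
// carries in the window bookkeeping. Both exponents are jointly shifted so
// neither exceeds 1, preserving exact detailed balance w.r.t.
//   H = E_pp*B + sum_i n_i psi_i - (mu + 4 psi1) N.
// Proposals are valid only for sites whose occupied-neighbour count is 1..3,
// identically for insertions and removals.
//
// Uses the R RNG: runs are reproducible under set.seed().

static inline int occ_at(const IntegerMatrix &occ, int i, int j, int nx, int ny) {
  if (i < 0 || j < 0 || i >= nx || j >= ny) return 0;
  return occ(i, j);
}

static inline int nb_count(const IntegerMatrix &occ, int i, int j, int nx, int ny) {
  return occ_at(occ, i - 1, j, nx, ny) + occ_at(occ, i + 1, j, nx, ny) +
         occ_at(occ, i, j - 1, nx, ny) + occ_at(occ, i, j + 1, nx, ny);
}

// configuration-energy change of flipping site (i,j), over the 4 windows
// containing it; psi[0..3] are psi_1..psi_4, empty windows carry 0
static double dpsi_flip(const IntegerMatrix &occ, int i, int j, int nx, int ny,
                        const NumericVector &psi, bool insert) {
  double d = 0.0;
  for (int a = i - 1; a <= i; ++a) {
    for (int b = j - 1; b <= j; ++b) {
      int c = occ_at(occ, a, b, nx, ny) + occ_at(occ, a + 1, b, nx, ny) +
              occ_at(occ, a, b + 1, nx, ny) + occ_at(occ, a + 1, b + 1, nx, ny);
      int c_after = insert ? c + 1 : c - 1;
      double e_before = (c >= 1) ? psi[c - 1] : 0.0;
      double e_after = (c_after >= 1) ? psi[c_after - 1] : 0.0;
      d += e_after - e_before;
    }
  }
  return d;
}

// [[Rcpp::export(name = ".automaton_run_cpp")]]
List automaton_run_cpp(IntegerMatrix occ_init, LogicalMatrix frozen,
                       NumericVector psi, double e_pp, double mu,
                       int n_steps, int record_every) {
  int nx = occ_init.nrow(), ny = occ_init.ncol();
  IntegerMatrix occ = clone(occ_init);

  std::vector<int> ev_step, ev_i, ev_j, ev_type, ev_nb;     // all accepted flips
  std::vector<int> cm_i, cm_j, cm_start, cm_end, cm_nb;     // complete events
  std::vector<int> assoc_step(nx * ny, -1), assoc_nb(nx * ny, 0);
  std::vector<char> changed(nx * ny, 0);

  int n_occ = 0;
  for (int k = 0; k < nx * ny; ++k) n_occ += occ[k];
  double sum_occ = 0.0;

  int n_rec = record_every > 0 ? n_steps / record_every : 0;
  IntegerVector states(n_rec);
  int rec_idx = 0;

  for (int step = 0; step < n_steps; ++step) {
    int site = (int)(unif_rand() * nx * ny);
    if (site >= nx * ny) site = nx * ny - 1;
    int i = site % nx, j = site / nx;
    if (!frozen(i, j)) {
      int nb = nb_count(occ, i, j, nx, ny);
      if (nb >= 1 && nb <= 3) {
        bool occupied = occ(i, j) == 1;
        // binding depth of the bound state of this site pair, relative to
        // the unbound diffuser (the common transition level)
        double depth;
        if (occupied) {
          depth = e_pp * nb - dpsi_flip(occ, i, j, nx, ny, psi, false) - 4.0 * psi[0];
        } else {
          depth = e_pp * nb + dpsi_flip(occ, i, j, nx, ny, psi, true) - 4.0 * psi[0];
        }
        double shift = std::max(0.0, std::max(mu, depth));
        double logp = (occupied ? depth : mu) - shift;
        if (logp >= 0.0 || unif_rand() < std::exp(logp)) {
          occ(i, j) = occupied ? 0 : 1;
          n_occ += occupied ? -1 : 1;
          ev_step.push_back(step); ev_i.push_back(i + 1); ev_j.push_back(j + 1);
          ev_type.push_back(occupied ? 0 : 1); ev_nb.push_back(nb);
          if (!occupied) {                       // association
            assoc_step[site] = step; assoc_nb[site] = nb; changed[site] = 0;
          } else {                               // dissociation
            if (assoc_step[site] >= 0 && !changed[site] && nb == assoc_nb[site]) {
              cm_i.push_back(i + 1); cm_j.push_back(j + 1);
              cm_start.push_back(assoc_step[site]); cm_end.push_back(step);
              cm_nb.push_back(nb);
            }
            assoc_step[site] = -1;
          }
          // bond environment of occupied neighbours changed mid-event
          const int di[4] = {-1, 1, 0, 0}, dj[4] = {0, 0, -1, 1};
          for (int q = 0; q < 4; ++q) {
            int pi = i + di[q], pj = j + dj[q];
            if (pi >= 0 && pj >= 0 && pi < nx && pj < ny && occ(pi, pj) == 1) {
              changed[pi + pj * nx] = 1;
            }
          }
        }
      }
    }
    sum_occ += n_occ;
    if (record_every > 0 && (step + 1) % record_every == 0 && rec_idx < n_rec) {
      // state code over non-frozen sites, for small-lattice oracles
      int code = 0, bit = 0;
      for (int k = 0; k < nx * ny; ++k) {
        if (!frozen[k]) { code |= occ[k] << bit; ++bit; }
      }
      states[rec_idx++] = code;
    }
  }

  int ne = ev_step.size(), nc = cm_i.size();
  IntegerMatrix events(ne, 5), complete(nc, 5);
  for (int k = 0; k < ne; ++k) {
    events(k, 0) = ev_step[k]; events(k, 1) = ev_i[k]; events(k, 2) = ev_j[k];
    events(k, 3) = ev_type[k]; events(k, 4) = ev_nb[k];
  }
  for (int k = 0; k < nc; ++k) {
    complete(k, 0) = cm_i[k]; complete(k, 1) = cm_j[k];
    complete(k, 2) = cm_start[k]; complete(k, 3) = cm_end[k];
    complete(k, 4) = cm_nb[k];
  }
  return List::create(_["occupancy"] = occ, _["events"] = events,
                      _["complete_events"] = complete,
                      _["mean_occupied"] = sum_occ / n_steps,
                      _["states"] = states);
}
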