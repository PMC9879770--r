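// Compiled kinetic Monte Carlo engine for the non-reciprocal lattice model.
//
// Conventions shared with the R level:
//  * lattice sigma is an L x L integer matrix (column-major, as in R) with
//    species 0..M, 0 = empty; periodic boundaries in both directions;
//  * reciprocal entries (a, dir, b): dir 1 = H (a immediately left of b),
//    dir 2 = V (a immediately above b); bond energy -eps;
//  * non-reciprocal entries (a, dir, b): dir 1 = NE, 2 = SW, 3 = SE, 4 = NW;
//    the arriving tile s at a site collects weight +lam for each of
//    (left SW s), (s NE right), (s SE down), (up NW s);
//  * acceptance p = min{1, exp(Lambda - dH)}; entropy production adds
//    log p_fwd - log p_rev over accepted moves, p_rev being the acceptance
//    probability of the exact inverse replacement in the post-move state.

#include <Rcpp.h>
#include <cstdint>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------- RNG -----
// xoshiro256++, seeded via splitmix64 from a single integer.  A dedicated
// counter-free generator keeps the per-proposal cost low and makes runs
// reproducible from the run seed alone, independent of R's RNG state.
struct Xoshiro256pp {
  uint64_t s[4];
  explicit Xoshiro256pp(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9E3779B97F4A7C15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform on (0, 1); the +0.5 offset keeps 0 out of range
  inline double unif() {
    return (static_cast<double>(next() >> 11) + 0.5) *
           (1.0 / 9007199254740992.0);
  }
  // uniform integer in [0, n)
  inline int below(int n) {
    return static_cast<int>(unif() * n) % n;
  }
};

// --------------------------------------------------------- lookup maps ----
// Dense (M+1)^2 byte maps per direction code; species 0 rows/cols stay 0
// because tables never involve the empty species.
struct DirMaps {
  int M1;
  std::vector<uint8_t> map[5];  // 1-based dir codes, up to 4 directions
  DirMaps(int M, const IntegerMatrix& entries, int ndir) : M1(M + 1) {
    for (int d = 1; d <= ndir; ++d) map[d].assign((size_t)M1 * M1, 0);
    for (int r = 0; r < entries.nrow(); ++r) {
      int a = entries(r, 0), d = entries(r, 1), b = entries(r, 2);
      map[d][(size_t)a * M1 + b] = 1;
    }
  }
  inline bool at(int d, int a, int b) const {
    return map[d][(size_t)a * M1 + b] != 0;
  }
};

enum { RH = 1, RV = 2 };
enum { NNE = 1, NSW = 2, NSE = 3, NNW = 4 };

// Energy of species s placed at a site with the given neighbour species,
// counting the four incident bonds (each bond will be counted once globally
// because a move only changes bonds incident to one site).
static inline double site_bond_energy(const DirMaps& rec, double eps, int s,
                                      int nl, int nr, int nu, int nd) {
  if (s == 0) return 0.0;
  int c = 0;
  if (nl) c += rec.at(RH, nl, s);
  if (nr) c += rec.at(RH, s, nr);
  if (nu) c += rec.at(RV, nu, s);
  if (nd) c += rec.at(RV, s, nd);
  return -eps * c;
}

static inline double site_lambda(const DirMaps& nrm, double lam, int s,
                                 int nl, int nr, int nu, int nd) {
  if (s == 0 || lam == 0.0) return 0.0;
  int c = 0;
  if (nl) c += nrm.at(NSW, nl, s);
  if (nr) c += nrm.at(NNE, s, nr);
  if (nd) c += nrm.at(NSE, s, nd);
  if (nu) c += nrm.at(NNW, nu, s);
  return lam * c;
}

// Total Hamiltonian H = sum_bonds U^r - mu * n, each bond counted once
// (right and down neighbour of every site, periodic).
static double total_energy_impl(const std::vector<int>& sig, int L, int M,
                                const DirMaps& rec, double eps, double mu) {
  double e = 0.0;
  long n = 0;
  for (int j = 0; j < L; ++j) {
    for (int i = 0; i < L; ++i) {
      int s = sig[i + (size_t)j * L];
      if (s == 0) continue;
      ++n;
      int jr = (j + 1 == L) ? 0 : j + 1;
      int id = (i + 1 == L) ? 0 : i + 1;
      int sr = sig[i + (size_t)jr * L];
      int sd = sig[id + (size_t)j * L];
      if (sr && rec.at(RH, s, sr)) e -= eps;
      if (sd && rec.at(RV, s, sd)) e -= eps;
    }
  }
  return e - mu * n;
}

// Largest specifically connected cluster: occupied sites, 4-neighbour
// adjacency restricted to oriented pairs present in the reciprocal table.
// Returns the label array and the label of the winning cluster (ties broken
// by smallest top-left site in row-major order); labels are assigned by
// row-major scan so the first maximal cluster found wins ties.
static int label_clusters(const std::vector<int>& sig, int L,
                          const DirMaps& rec, std::vector<int>& label,
                          int& best_size) {
  label.assign(sig.size(), -1);
  std::vector<int> stack;
  int best_label = -1;
  best_size = 0;
  int next_label = 0;
  for (int i = 0; i < L; ++i) {        // row-major scan for tie-breaking
    for (int j = 0; j < L; ++j) {
      size_t s0 = i + (size_t)j * L;
      if (sig[s0] == 0 || label[s0] >= 0) continue;
      int lab = next_label++;
      int size = 0;
      stack.clear();
      stack.push_back((int)s0);
      label[s0] = lab;
      while (!stack.empty()) {
        int cur = stack.back();
        stack.pop_back();
        ++size;
        int ci = cur % L, cj = cur / L;
        int s = sig[cur];
        int jl = (cj == 0) ? L - 1 : cj - 1, jr = (cj + 1 == L) ? 0 : cj + 1;
        int iu = (ci == 0) ? L - 1 : ci - 1, id = (ci + 1 == L) ? 0 : ci + 1;
        int nb[4] = {ci + jl * L, ci + jr * L, iu + cj * L, id + cj * L};
        int sp[4] = {sig[nb[0]], sig[nb[1]], sig[nb[2]], sig[nb[3]]};
        bool conn[4] = {
          sp[0] && rec.at(RH, sp[0], s), sp[1] && rec.at(RH, s, sp[1]),
          sp[2] && rec.at(RV, sp[2], s), sp[3] && rec.at(RV, s, sp[3])};
        for (int k = 0; k < 4; ++k) {
          if (conn[k] && label[nb[k]] < 0) {
            label[nb[k]] = lab;
            stack.push_back(nb[k]);
          }
        }
      }
      if (size > best_size) {
        best_size = size;
        best_label = lab;
      }
    }
  }
  return best_label;
}

// Jaccard overlap of the largest specific cluster with each centred pattern,
// both read as sets of (site, species) assignments.
static void cluster_overlaps_impl(const std::vector<int>& sig, int L, int M,
                                  const DirMaps& rec,
                                  const IntegerMatrix& pats, int side,
                                  std::vector<double>& out,
                                  int* cluster_size = nullptr) {
  std::vector<int> label;
  int best_size = 0;
  int best = label_clusters(sig, L, rec, label, best_size);
  int a0 = side / 2;  // 0-based anchor of the centred pattern footprint
  int m = pats.ncol();
  std::vector<int> inter(m, 0);
  if (best >= 0) {
    for (int ic = 0; ic < side; ++ic) {
      for (int jc = 0; jc < side; ++jc) {
        size_t s0 = (a0 + ic) + (size_t)(a0 + jc) * L;
        if (label[s0] != best) continue;
        int sp = sig[s0];
        for (int l = 0; l < m; ++l) {
          if (pats(ic + jc * side, l) == sp) ++inter[l];
        }
      }
    }
  }
  out.resize(m);
  for (int l = 0; l < m; ++l) {
    double uni = best_size + M - inter[l];
    out[l] = (uni > 0) ? inter[l] / uni : 0.0;
  }
  if (cluster_size) *cluster_size = best_size;
}

// ---------------------------------------------------------- exported ------

// [[Rcpp::export]]
double cpp_total_energy(IntegerMatrix sigma, int M, IntegerMatrix recip,
                        double eps, double mu) {
  int L = sigma.nrow();
  std::vector<int> sig(sigma.begin(), sigma.end());
  DirMaps rec(M, recip, 2);
  return total_energy_impl(sig, L, M, rec, eps, mu);
}

// dH of replacing the species at (i, j) (1-based) by new_species
// [[Rcpp::export]]
double cpp_delta_h(IntegerMatrix sigma, int M, IntegerMatrix recip,
                   double eps, double mu, int i, int j, int new_species) {
  int L = sigma.nrow();
  DirMaps rec(M, recip, 2);
  int ci = i - 1, cj = j - 1;
  int jl = (cj == 0) ? L - 1 : cj - 1, jr = (cj + 1 == L) ? 0 : cj + 1;
  int iu = (ci == 0) ? L - 1 : ci - 1, id = (ci + 1 == L) ? 0 : ci + 1;
  int nl = sigma(ci, jl), nr = sigma(ci, jr);
  int nu = sigma(iu, cj), nd = sigma(id, cj);
  int old = sigma(ci, cj);
  double dh = site_bond_energy(rec, eps, new_species, nl, nr, nu, nd) -
              site_bond_energy(rec, eps, old, nl, nr, nu, nd);
  int dn = (new_species != 0) - (old != 0);
  return dh - mu * dn;
}

// Non-reciprocal weight Lambda for the arrival of new_species at (i, j)
// [[Rcpp::export]]
double cpp_lambda(IntegerMatrix sigma, int M, IntegerMatrix nonrecip,
                  double lam, int i, int j, int new_species) {
  int L = sigma.nrow();
  DirMaps nrm(M, nonrecip, 4);
  int ci = i - 1, cj = j - 1;
  int jl = (cj == 0) ? L - 1 : cj - 1, jr = (cj + 1 == L) ? 0 : cj + 1;
  int iu = (ci == 0) ? L - 1 : ci - 1, id = (ci + 1 == L) ? 0 : ci + 1;
  return site_lambda(nrm, lam, new_species, sigma(ci, jl), sigma(ci, jr),
                     sigma(iu, cj), sigma(id, cj));
}

// [[Rcpp::export]]
List cpp_cluster_overlaps(IntegerMatrix sigma, int M, IntegerMatrix recip,
                          IntegerMatrix patterns_flat, int side) {
  int L = sigma.nrow();
  std::vector<int> sig(sigma.begin(), sigma.end());
  DirMaps rec(M, recip, 2);
  std::vector<double> ov;
  int csize = 0;
  cluster_overlaps_impl(sig, L, M, rec, patterns_flat, side, ov, &csize);
  return List::create(_["overlaps"] = NumericVector(ov.begin(), ov.end()),
                      _["cluster_size"] = csize);
}

// Sites (1-based column-major indices) of the largest specific cluster
// [[Rcpp::export]]
IntegerVector cpp_largest_cluster(IntegerMatrix sigma, int M,
                                  IntegerMatrix recip) {
  int L = sigma.nrow();
  std::vector<int> sig(sigma.begin(), sigma.end());
  DirMaps rec(M, recip, 2);
  std::vector<int> label;
  int best_size = 0;
  int best = label_clusters(sig, L, rec, label, best_size);
  std::vector<int> out;
  if (best >= 0) {
    for (size_t k = 0; k < label.size(); ++k) {
      if (label[k] == best) out.push_back((int)k + 1);
    }
  }
  return IntegerVector(out.begin(), out.end());
}

// Main simulation loop.  sweeps * L^2 single-site replacement proposals;
// observables sampled every sample_every sweeps (including sweep 0).
// record_codes: additionally record the full configuration at each sample,
// encoded in base (M+1) (only sensible for tiny systems).
// [[Rcpp::export]]
List cpp_run(IntegerMatrix sigma, int M, IntegerMatrix recip,
             IntegerMatrix nonrecip, double eps, double mu, double lam,
             double sweeps, int sample_every, IntegerMatrix patterns_flat,
             int side, bool track_overlap, bool record_codes, double seed) {
  int L = sigma.nrow();
  long long nsite = (long long)L * L;
  std::vector<int> sig(sigma.begin(), sigma.end());
  DirMaps rec(M, recip, 2);
  DirMaps nrm(M, nonrecip, 4);
  Xoshiro256pp rng((uint64_t)(int64_t)seed);

  long long nsweep = (long long)sweeps;
  int nsamp = (int)(nsweep / sample_every) + 1;
  NumericVector out_sweep(nsamp), out_density(nsamp), out_energy(nsamp),
      out_entropy(nsamp);
  NumericMatrix out_overlap(track_overlap ? nsamp : 0,
                            track_overlap ? patterns_flat.ncol() : 0);
  NumericVector out_codes(record_codes ? nsamp : 0);

  long n = 0;
  for (size_t k = 0; k < sig.size(); ++k) n += (sig[k] != 0);
  double energy = total_energy_impl(sig, L, M, rec, eps, mu);
  double entropy = 0.0;
  long long accepted = 0;
  std::vector<double> ov;

  int isamp = 0;
  auto take_sample = [&](long long sweep) {
    out_sweep[isamp] = (double)sweep;
    out_density[isamp] = (double)n / nsite;
    out_energy[isamp] = energy;
    out_entropy[isamp] = entropy;
    if (track_overlap) {
      cluster_overlaps_impl(sig, L, M, rec, patterns_flat, side, ov);
      for (int l = 0; l < (int)ov.size(); ++l) out_overlap(isamp, l) = ov[l];
    }
    if (record_codes) {
      double code = 0.0, base = 1.0;
      for (size_t k = 0; k < sig.size(); ++k) {
        code += sig[k] * base;
        base *= (M + 1);
      }
      out_codes[isamp] = code;
    }
    ++isamp;
  };
  take_sample(0);

  const bool use_lam = (lam != 0.0) && nonrecip.nrow() > 0;

  // The acceptance exponent x = Lambda - dH only takes values
  // eps*(cn - co) + mu*dn + lam*l over small integer counts (cn, co: bonds
  // gained/held by the new/old species; dn: particle change; l: matched
  // approach arrows), so exp() can be tabulated once.
  auto xof = [&](int dc, int dn, int l) {
    return eps * dc + mu * dn + lam * l;
  };
  double xtab[9 * 3 * 5], ptab[9 * 3 * 5];
  for (int dc = -4; dc <= 4; ++dc) {
    for (int dn = -1; dn <= 1; ++dn) {
      for (int l = 0; l <= 4; ++l) {
        int idx = ((dc + 4) * 3 + (dn + 1)) * 5 + l;
        xtab[idx] = xof(dc, dn, l);
        ptab[idx] = std::exp(std::min(0.0, xtab[idx]));
      }
    }
  }
  // periodic neighbour index tables
  std::vector<int> up(L), dn_(L);
  for (int k = 0; k < L; ++k) {
    up[k] = (k == 0) ? L - 1 : k - 1;
    dn_[k] = (k + 1 == L) ? 0 : k + 1;
  }

  for (long long sweep = 1; sweep <= nsweep; ++sweep) {
    for (long long step = 0; step < nsite; ++step) {
      int sidx = rng.below((int)nsite);
      int ci = sidx % L, cj = sidx / L;
      int old = sig[sidx];
      int prop = rng.below(M);           // {0..M} \ {old}
      if (prop >= old) ++prop;
      int nl = sig[ci + (size_t)up[cj] * L];
      int nr = sig[ci + (size_t)dn_[cj] * L];
      int nu = sig[up[ci] + (size_t)cj * L];
      int nd = sig[dn_[ci] + (size_t)cj * L];
      int cn = 0, co = 0;
      if (prop) {
        if (nl) cn += rec.at(RH, nl, prop);
        if (nr) cn += rec.at(RH, prop, nr);
        if (nu) cn += rec.at(RV, nu, prop);
        if (nd) cn += rec.at(RV, prop, nd);
      }
      if (old) {
        if (nl) co += rec.at(RH, nl, old);
        if (nr) co += rec.at(RH, old, nr);
        if (nu) co += rec.at(RV, nu, old);
        if (nd) co += rec.at(RV, old, nd);
      }
      int lf = 0;
      if (use_lam && prop) {
        if (nl) lf += nrm.at(NSW, nl, prop);
        if (nr) lf += nrm.at(NNE, prop, nr);
        if (nd) lf += nrm.at(NSE, prop, nd);
        if (nu) lf += nrm.at(NNW, nu, prop);
      }
      int ddn = (prop != 0) - (old != 0);
      int idx = ((cn - co + 4) * 3 + (ddn + 1)) * 5 + lf;
      double p = ptab[idx];
      bool accept = (p >= 1.0) || (rng.unif() < p);
      if (accept) {
        double x = xtab[idx];
        double dh = lam * lf - x;        // = dH of the move
        int lr = 0;
        if (use_lam && old) {            // reverse move in post-move state
          if (nl) lr += nrm.at(NSW, nl, old);
          if (nr) lr += nrm.at(NNE, old, nr);
          if (nd) lr += nrm.at(NSE, old, nd);
          if (nu) lr += nrm.at(NNW, nu, old);
        }
        double xr = lam * lr + dh;
        entropy += std::min(0.0, x) - std::min(0.0, xr);
        energy += dh;
        n += ddn;
        sig[sidx] = prop;
        ++accepted;
      }
    }
    if (sweep % sample_every == 0) take_sample(sweep);
    if (sweep % 4096 == 0) Rcpp::checkUserInterrupt();
  }

  IntegerMatrix final_sigma(L, L);
  std::copy(sig.begin(), sig.end(), final_sigma.begin());
  return List::create(
      _["sweep"] = out_sweep, _["density"] = out_density,
      _["energy"] = out_energy, _["entropy"] = out_entropy,
      _["overlap"] = out_overlap, _["codes"] = out_codes,
      _["sigma"] = final_sigma, _["n"] = (double)n,
      _["final_energy"] = energy, _["accepted"] = (double)accepted);
}
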