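#include <Rcpp.h>
using namespace Rcpp;

// One-generation update of the two-sex gamete-pool recursion, iterated
// n_gen times in compiled code.
//
// State is a pair of frequency vectors over m gamete types restricted to
// the segregating support: egg (maternal transmission) and sperm
// (paternal transmission). Each generation:
//   (i)  zygotes = outer product egg x sperm (random mating);
//   (ii) sex assignment (is_female lookup) and viability weighting with
//        the sex-specific fitness matrices WF / WM;
//   (iii) new egg pool = fitness-weighted mix of female gametogenesis
//        distributions, new sperm pool = same over males; both pools
//        renormalised to sum 1.
//
// G is the gametogenesis matrix: row (i * m + j) holds the gamete
// distribution produced by the genotype with maternal haplotype i and
// paternal haplotype j (0-based support indices); rows sum to 1.
//
// record_every > 0 stores the pools at every generation whose global
// index (gen0 + step) is a multiple of record_every, plus the final one.
// conv_tol > 0 enables early termination once the L-infinity change of
// both pools stays below conv_tol for conv_streak consecutive steps.

// [[Rcpp::export]]
List iterate_pools_cpp(NumericVector egg, NumericVector sperm,
                       NumericMatrix WF, NumericMatrix WM,
                       IntegerMatrix is_female, NumericMatrix G,
                       int n_gen, int gen0, int record_every,
                       double conv_tol, int conv_streak) {
  const int m = egg.size();
  const size_t mm = (size_t)m * m;
  if (sperm.size() != m || WF.nrow() != m || WF.ncol() != m ||
      WM.nrow() != m || WM.ncol() != m ||
      is_female.nrow() != m || is_female.ncol() != m ||
      (size_t)G.nrow() != mm || G.ncol() != m) {
    stop("inconsistent state/table dimensions");
  }

  // Flat, cache-friendly copies: genotype row index = i * m + j.
  // gt holds gametogenesis rows contiguously; wf/wm are pre-masked by sex
  // (zero in cells belonging to the other sex), so each genotype cell
  // contributes to exactly one pool.
  std::vector<double> gt(mm * m), wf(mm), wm(mm);
  for (int i = 0; i < m; ++i) {
    for (int j = 0; j < m; ++j) {
      const size_t row = (size_t)i * m + j;
      const bool fem = is_female(i, j) != 0;
      wf[row] = fem ? WF(i, j) : 0.0;
      wm[row] = fem ? 0.0 : WM(i, j);
      for (int k = 0; k < m; ++k) gt[row * m + k] = G(row, k);
    }
  }

  std::vector<double> e(egg.begin(), egg.end()), s(sperm.begin(), sperm.end());
  std::vector<double> ne(m), ns(m);

  std::vector<int> rec_gen;
  std::vector<double> rec_e, rec_s;
  auto record = [&](int gen) {
    rec_gen.push_back(gen);
    rec_e.insert(rec_e.end(), e.begin(), e.end());
    rec_s.insert(rec_s.end(), s.begin(), s.end());
  };

  double max_drift = 0.0;
  int streak = 0, steps_done = 0;
  bool converged = false;

  for (int step = 1; step <= n_gen; ++step) {
    std::fill(ne.begin(), ne.end(), 0.0);
    std::fill(ns.begin(), ns.end(), 0.0);
    double f_tot = 0.0, m_tot = 0.0;
    double zf = 0.0, zm = 0.0;  // raw zygote mass per sex

    for (int i = 0; i < m; ++i) {
      const double ei = e[i];
      if (ei == 0.0) continue;
      const size_t base = (size_t)i * m;
      for (int j = 0; j < m; ++j) {
        const double sj = s[j];
        if (sj == 0.0) continue;
        const double z = ei * sj;
        const size_t row = base + j;
        const double* gr = &gt[row * m];
        const double af = z * wf[row];
        if (af != 0.0) {  // female cell (fitness is strictly positive)
          zf += z; f_tot += af;
          for (int k = 0; k < m; ++k) ne[k] += af * gr[k];
        } else {
          const double am = z * wm[row];
          zm += z; m_tot += am;
          for (int k = 0; k < m; ++k) ns[k] += am * gr[k];
        }
      }
    }

    if (zf <= 0.0 || zm <= 0.0) {
      stop("degenerate state at generation %d: one sex has zero zygote frequency",
           gen0 + step);
    }

    double sum_e = 0.0, sum_s = 0.0;
    for (int k = 0; k < m; ++k) { sum_e += ne[k]; sum_s += ns[k]; }
    const double drift_e = std::abs(sum_e / f_tot - 1.0);
    const double drift_s = std::abs(sum_s / m_tot - 1.0);
    if (drift_e > max_drift) max_drift = drift_e;
    if (drift_s > max_drift) max_drift = drift_s;

    double dmax = 0.0;
    for (int k = 0; k < m; ++k) {
      double v = ne[k] / sum_e;
      if (v < 0.0 && v > -1e-15) v = 0.0;
      double d = std::abs(v - e[k]);
      if (d > dmax) dmax = d;
      e[k] = v;
      v = ns[k] / sum_s;
      if (v < 0.0 && v > -1e-15) v = 0.0;
      d = std::abs(v - s[k]);
      if (d > dmax) dmax = d;
      s[k] = v;
    }

    steps_done = step;
    if (record_every > 0 && (gen0 + step) % record_every == 0 && step < n_gen) {
      record(gen0 + step);
    }

    if (conv_tol > 0.0) {
      streak = (dmax < conv_tol) ? streak + 1 : 0;
      if (streak >= conv_streak) { converged = true; break; }
    }
  }

  if (record_every > 0 && steps_done > 0) record(gen0 + steps_done);

  const int nr = rec_gen.size();
  NumericMatrix rec_egg(nr, m), rec_sperm(nr, m);
  for (int r = 0; r < nr; ++r) {
    for (int k = 0; k < m; ++k) {
      rec_egg(r, k) = rec_e[(size_t)r * m + k];
      rec_sperm(r, k) = rec_s[(size_t)r * m + k];
    }
  }

  return List::create(
    _["egg"] = NumericVector(e.begin(), e.end()),
    _["sperm"] = NumericVector(s.begin(), s.end()),
    _["generations_run"] = steps_done,
    _["converged_early"] = converged,
    _["max_drift"] = max_drift,
    _["rec_gen"] = IntegerVector(rec_gen.begin(), rec_gen.end()),
    _["rec_egg"] = rec_egg, _["rec_sperm"] = rec_sperm);
}
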