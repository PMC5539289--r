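#include <Rcpp.h>
#include <cmath>
#include <string>
#include <vector>
using namespace Rcpp;

// Base encoding: A=0, C=1, G=2, T=3, anything else = -1 (window skipped).
static inline int encode_base(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static std::vector<int> encode_seq(const std::string& s) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = encode_base(s[i]);
  return v;
}

// Site energies E(w) = sum_i E[i, base_{w+i}] for every window w on one
// strand; windows containing a non-ACGT base get NA.
static std::vector<double> window_energies(const std::vector<int>& seq,
                                           const NumericMatrix& E) {
  int L = E.nrow();
  int n = (int)seq.size() - L + 1;
  std::vector<double> out;
  if (n <= 0) return out;
  out.resize(n);
  for (int w = 0; w < n; ++w) {
    double e = 0.0;
    bool ok = true;
    for (int i = 0; i < L; ++i) {
      int b = seq[w + i];
      if (b < 0) { ok = false; break; }
      e += E(i, b);
    }
    out[w] = ok ? e : NA_REAL;
  }
  return out;
}

// Energy matrix for scanning the reverse-complement strand without
// reversing the sequence: Erc[i][b] = E[L-1-i][3-b].
static NumericMatrix revcomp_energy(const NumericMatrix& E) {
  int L = E.nrow();
  NumericMatrix out(L, 4);
  for (int i = 0; i < L; ++i)
    for (int b = 0; b < 4; ++b)
      out(i, b) = E(L - 1 - i, 3 - b);
  return out;
}

// [[Rcpp::export(name = ".scan_window_energies_cpp")]]
List scan_window_energies_cpp(std::string seq, NumericMatrix energies) {
  std::vector<int> s = encode_seq(seq);
  NumericMatrix erc = revcomp_energy(energies);
  std::vector<double> fwd = window_energies(s, energies);
  std::vector<double> rev = window_energies(s, erc);
  return List::create(_["fwd"] = wrap(fwd), _["rev"] = wrap(rev));
}

// Sum of Fermi-Dirac occupancies over valid windows at one mu.
static double occupancy_sum(const std::vector<double>& e, double mu,
                            double beta) {
  double s = 0.0;
  for (size_t i = 0; i < e.size(); ++i) {
    double x = e[i];
    if (ISNAN(x)) continue;
    s += 1.0 / (1.0 + std::exp(beta * (x - mu)));
  }
  return s;
}

// dbA per chemical potential: log total occupancy over both strands.
// Returns -Inf when no valid window exists (caller decides how to treat it).
static std::vector<double> dba_one(const std::vector<int>& seq,
                                   const NumericMatrix& E,
                                   const NumericMatrix& Erc,
                                   const NumericVector& mu, double beta,
                                   bool both_strands) {
  std::vector<double> efwd = window_energies(seq, E);
  std::vector<double> out(mu.size());
  if (both_strands) {
    std::vector<double> erev = window_energies(seq, Erc);
    for (int k = 0; k < mu.size(); ++k)
      out[k] = std::log(occupancy_sum(efwd, mu[k], beta) +
                        occupancy_sum(erev, mu[k], beta));
  } else {
    for (int k = 0; k < mu.size(); ++k)
      out[k] = std::log(occupancy_sum(efwd, mu[k], beta));
  }
  return out;
}

// [[Rcpp::export(name = ".dba_cpp")]]
NumericVector dba_cpp(std::string seq, NumericMatrix energies,
                      NumericVector mu, double beta, bool both_strands) {
  std::vector<int> s = encode_seq(seq);
  NumericMatrix erc = revcomp_energy(energies);
  std::vector<double> d = dba_one(s, energies, erc, mu, beta, both_strands);
  return wrap(d);
}

// Batch delta-dbA for paired sequences: mean over the mu grid of
// dbA(alt) - dbA(ref). Lengths of ref/alt pairs must match (checked in R).
// [[Rcpp::export(name = ".ddba_batch_cpp")]]
NumericVector ddba_batch_cpp(CharacterVector ref_seqs,
                             CharacterVector alt_seqs,
                             NumericMatrix energies, NumericVector mu,
                             double beta, bool both_strands) {
  int n = ref_seqs.size();
  NumericVector out(n);
  NumericMatrix erc = revcomp_energy(energies);
  for (int j = 0; j < n; ++j) {
    std::string rs = as<std::string>(ref_seqs[j]);
    std::string as_ = as<std::string>(alt_seqs[j]);
    if (rs == as_) { out[j] = 0.0; continue; }
    std::vector<int> r = encode_seq(rs);
    std::vector<int> a = encode_seq(as_);
    std::vector<double> dr = dba_one(r, energies, erc, mu, beta, both_strands);
    std::vector<double> da = dba_one(a, energies, erc, mu, beta, both_strands);
    double acc = 0.0;
    for (size_t k = 0; k < dr.size(); ++k) acc += da[k] - dr[k];
    out[j] = acc / (double)dr.size();
  }
  return out;
}

// Batch dbA (mean over mu of dbA) for many sequences against one matrix;
// used by the direct-binding empirical p-value.
// [[Rcpp::export(name = ".dba_batch_cpp")]]
NumericVector dba_batch_cpp(CharacterVector seqs, NumericMatrix energies,
                            NumericVector mu, double beta,
                            bool both_strands) {
  int n = seqs.size();
  NumericVector out(n);
  NumericMatrix erc = revcomp_energy(energies);
  for (int j = 0; j < n; ++j) {
    std::vector<int> s = encode_seq(as<std::string>(seqs[j]));
    std::vector<double> d = dba_one(s, energies, erc, mu, beta, both_strands);
    double acc = 0.0;
    for (size_t k = 0; k < d.size(); ++k) acc += d[k];
    out[j] = acc / (double)d.size();
  }
  return out;
}
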