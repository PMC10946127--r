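#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Extend haplotype grouping one site further and return the updated EHH.
// g holds the current group id of each carrier haplotype; nGroups is
// updated in place. EHH = sum_k C(n_k,2) / C(n,2).
static double extendGroups(const IntegerMatrix &hap,
                           const std::vector<int> &rows,
                           std::vector<int> &g, int &nGroups, int j) {
  int n = rows.size();
  std::vector<int> remap(2 * nGroups, -1);
  std::vector<int> cnt;
  int next = 0;
  for (int i = 0; i < n; ++i) {
    int code = g[i] * 2 + hap(rows[i], j);
    if (remap[code] < 0) {
      remap[code] = next++;
      cnt.push_back(0);
    }
    g[i] = remap[code];
    cnt[g[i]]++;
  }
  nGroups = next;
  double num = 0.0;
  for (int k = 0; k < next; ++k)
    num += (double)cnt[k] * (cnt[k] - 1);
  return num / ((double)n * (n - 1));
}

// EHH decay curve for one core site among the given carrier rows, scanned
// outward in one direction until EHH < cutoff (that point is recorded) or
// the chromosome end. Returns site indices (1-based) and EHH values,
// excluding the core itself (EHH = 1 there by definition).
static void ehhSide(const IntegerMatrix &hap, const std::vector<int> &rows,
                    const IntegerVector &chromId, int core, int dir,
                    double cutoff, std::vector<int> &sites,
                    std::vector<double> &values) {
  int m = hap.ncol();
  std::vector<int> g(rows.size(), 0);
  int nGroups = 1;
  for (int j = core + dir; j >= 0 && j < m; j += dir) {
    if (chromId[j] != chromId[core]) break;
    double e = extendGroups(hap, rows, g, nGroups, j);
    sites.push_back(j + 1);
    values.push_back(e);
    if (e < cutoff) break;
  }
}

// Trapezoidal integral of one side's EHH curve over physical distance,
// anchored at (pos[core], 1).
static double ihhSide(const NumericVector &pos, int core,
                      const std::vector<int> &sites,
                      const std::vector<double> &values) {
  double total = 0.0, lastPos = pos[core], lastVal = 1.0;
  for (size_t k = 0; k < sites.size(); ++k) {
    double p = pos[sites[k] - 1];
    total += 0.5 * (lastVal + values[k]) * std::fabs(p - lastPos);
    lastPos = p;
    lastVal = values[k];
  }
  return total;
}

// [[Rcpp::export(name = ".cppEhhCurve")]]
List cppEhhCurve(IntegerMatrix hap, IntegerVector carrierRows,
                 IntegerVector chromId, int core, double cutoff) {
  std::vector<int> rows(carrierRows.begin(), carrierRows.end());
  for (size_t i = 0; i < rows.size(); ++i) rows[i] -= 1;  // to 0-based
  int c0 = core - 1;
  std::vector<int> sL, sR;
  std::vector<double> vL, vR;
  ehhSide(hap, rows, chromId, c0, -1, cutoff, sL, vL);
  ehhSide(hap, rows, chromId, c0, +1, cutoff, sR, vR);
  return List::create(
      _["leftSites"] = wrap(sL), _["leftEhh"] = wrap(vL),
      _["rightSites"] = wrap(sR), _["rightEhh"] = wrap(vR));
}

static double ihhAllele(const IntegerMatrix &hap,
                        const std::vector<int> &rows,
                        const IntegerVector &chromId,
                        const NumericVector &pos, int core, double cutoff) {
  std::vector<int> sL, sR;
  std::vector<double> vL, vR;
  ehhSide(hap, rows, chromId, core, -1, cutoff, sL, vL);
  ehhSide(hap, rows, chromId, core, +1, cutoff, sR, vR);
  return ihhSide(pos, core, sL, vL) + ihhSide(pos, core, sR, vR);
}

// Population-level iHH at each requested core site: per-allele iHH among
// carriers (alleles with >= 2 carriers), combined as the allele-count
// weighted mean, so sites monomorphic within the population stay defined.
// Returns NA when no allele has two carriers.
// [[Rcpp::export(name = ".cppIhhSites")]]
NumericVector cppIhhSites(IntegerMatrix hap, IntegerVector popRows,
                          IntegerVector chromId, NumericVector pos,
                          IntegerVector coreSites, double cutoff) {
  int nSite = coreSites.size();
  NumericVector out(nSite, NA_REAL);
  std::vector<int> rows(popRows.begin(), popRows.end());
  for (size_t i = 0; i < rows.size(); ++i) rows[i] -= 1;
  for (int s = 0; s < nSite; ++s) {
    int core = coreSites[s] - 1;
    std::vector<int> rows0, rows1;
    for (size_t i = 0; i < rows.size(); ++i) {
      if (hap(rows[i], core) == 1) rows1.push_back(rows[i]);
      else rows0.push_back(rows[i]);
    }
    double num = 0.0, den = 0.0;
    if (rows0.size() >= 2) {
      num += rows0.size() *
             ihhAllele(hap, rows0, chromId, pos, core, cutoff);
      den += rows0.size();
    }
    if (rows1.size() >= 2) {
      num += rows1.size() *
             ihhAllele(hap, rows1, chromId, pos, core, cutoff);
      den += rows1.size();
    }
    if (den > 0) out[s] = num / den;
  }
  return out;
}
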