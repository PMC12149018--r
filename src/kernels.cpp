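#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Haplotype matrices are loci x individuals (column-major: one individual's
// chromosome set is contiguous), alleles stored as raw 0/1.

// Draw one recombinant gamete per progeny from the designated parent.
// Crossovers per chromosome ~ Poisson(genetic length in Morgans), positions
// uniform on the map, no interference. Uses R's RNG (respects set.seed()).
// [[Rcpp::export]]
RawMatrix cpp_gametes(RawMatrix h1, RawMatrix h2, IntegerVector parent_col,
                      NumericVector pos, IntegerVector chr_start,
                      IntegerVector chr_nloci, NumericVector chr_len) {
  const int L = h1.nrow();
  const int np = parent_col.size();
  const int nchr = chr_start.size();
  RawMatrix out(L, np);
  std::vector<double> xpos;
  for (int i = 0; i < np; ++i) {
    const int p = parent_col[i];
    const Rbyte *c1 = &h1(0, p), *c2 = &h2(0, p);
    Rbyte *o = &out(0, i);
    for (int c = 0; c < nchr; ++c) {
      const int s = chr_start[c], m = chr_nloci[c];
      int cur = (unif_rand() < 0.5) ? 0 : 1;
      int nx = (int) R::rpois(chr_len[c]);
      if (nx == 0) {
        const Rbyte *src = cur ? c2 : c1;
        std::copy(src + s, src + s + m, o + s);
      } else {
        xpos.resize(nx);
        for (int k = 0; k < nx; ++k) xpos[k] = unif_rand() * chr_len[c];
        std::sort(xpos.begin(), xpos.end());
        // copy whole segments between crossover breakpoints
        const double *p0 = &pos[s];
        int j = 0;
        for (int k = 0; k <= nx; ++k) {
          const int jend = (k == nx) ? m
            : (int)(std::lower_bound(p0, p0 + m, xpos[k]) - p0);
          if (jend > j) {
            const Rbyte *src = cur ? c2 : c1;
            std::copy(src + s + j, src + s + jend, o + s + j);
            j = jend;
          }
          cur ^= 1;
        }
      }
    }
  }
  return out;
}

// Fused progeny kernel: for each progeny draw one recombinant gamete from
// each designated parent and, while the fresh haplotypes are cache-hot,
// accumulate the raw genetic score (additive + dominance over the QTN) and
// optionally the GEBV (marker effects over the SNPs). Selfing is the case
// parent1 == parent2.
// [[Rcpp::export]]
List cpp_progeny(RawMatrix h1, RawMatrix h2,
                 IntegerVector p1, IntegerVector p2,
                 NumericVector pos, IntegerVector chr_start,
                 IntegerVector chr_nloci, NumericVector chr_len,
                 IntegerVector qtl, NumericVector a, NumericVector d,
                 IntegerVector snp, NumericVector u, bool want_gebv) {
  const int L = h1.nrow();
  const int np = p1.size();
  const int nchr = chr_start.size();
  const int nq = qtl.size(), nm = snp.size();
  RawMatrix o1(L, np), o2(L, np);
  NumericVector gv(np);
  NumericVector gebv(want_gebv ? np : 0);
  std::vector<double> xpos;
  for (int i = 0; i < np; ++i) {
    for (int side = 0; side < 2; ++side) {
      const int p = side ? p2[i] : p1[i];
      const Rbyte *c1 = &h1(0, p), *c2 = &h2(0, p);
      Rbyte *o = side ? &o2(0, i) : &o1(0, i);
      for (int c = 0; c < nchr; ++c) {
        const int s = chr_start[c], m = chr_nloci[c];
        int cur = (unif_rand() < 0.5) ? 0 : 1;
        int nx = (int) R::rpois(chr_len[c]);
        if (nx == 0) {
          const Rbyte *src = cur ? c2 : c1;
          std::copy(src + s, src + s + m, o + s);
        } else {
          xpos.resize(nx);
          for (int k = 0; k < nx; ++k) xpos[k] = unif_rand() * chr_len[c];
          std::sort(xpos.begin(), xpos.end());
          const double *p0 = &pos[s];
          int j = 0;
          for (int k = 0; k <= nx; ++k) {
            const int jend = (k == nx) ? m
              : (int)(std::lower_bound(p0, p0 + m, xpos[k]) - p0);
            if (jend > j) {
              const Rbyte *src = cur ? c2 : c1;
              std::copy(src + s + j, src + s + jend, o + s + j);
              j = jend;
            }
            cur ^= 1;
          }
        }
      }
    }
    const Rbyte *g1 = &o1(0, i), *g2 = &o2(0, i);
    const int *qq = &qtl[0];
    const double *aa = &a[0], *dd = &d[0];
    double v0 = 0.0, v1 = 0.0;
    for (int j = 0; j < nq - 1; j += 2) {
      const int da = (int)g1[qq[j]] + (int)g2[qq[j]];
      const int db = (int)g1[qq[j + 1]] + (int)g2[qq[j + 1]];
      v0 += aa[j] * (da - 1) + dd[j] * (da == 1);
      v1 += aa[j + 1] * (db - 1) + dd[j + 1] * (db == 1);
    }
    if (nq % 2) {
      const int da = (int)g1[qq[nq - 1]] + (int)g2[qq[nq - 1]];
      v0 += aa[nq - 1] * (da - 1) + dd[nq - 1] * (da == 1);
    }
    gv[i] = v0 + v1;
    if (want_gebv) {
      const int *mm = &snp[0];
      const double *uu = &u[0];
      double e0 = 0.0, e1 = 0.0;
      for (int j = 0; j < nm - 1; j += 2) {
        e0 += uu[j] * ((int)g1[mm[j]] + (int)g2[mm[j]] - 1);
        e1 += uu[j + 1] * ((int)g1[mm[j + 1]] + (int)g2[mm[j + 1]] - 1);
      }
      if (nm % 2)
        e0 += uu[nm - 1] * ((int)g1[mm[nm - 1]] + (int)g2[mm[nm - 1]] - 1);
      gebv[i] = e0 + e1;
    }
  }
  return List::create(_["hap1"] = o1, _["hap2"] = o2,
                      _["gv"] = gv, _["gebv"] = gebv);
}

// Raw genetic score: sum over QTN of a*(dosage-1) + d*[heterozygote].
// [[Rcpp::export]]
NumericVector cpp_genetic_values(RawMatrix h1, RawMatrix h2,
                                 IntegerVector qtl, NumericVector a,
                                 NumericVector d) {
  const int n = h1.ncol(), nq = qtl.size(), L = h1.nrow();
  NumericVector out(n);
  const int *qq = &qtl[0];
  const double *aa = &a[0], *dd = &d[0];
  for (int i = 0; i < n; ++i) {
    const Rbyte *c1 = &h1(0, 0) + (R_xlen_t)i * L;
    const Rbyte *c2 = &h2(0, 0) + (R_xlen_t)i * L;
    double v0 = 0.0, v1 = 0.0;
    for (int j = 0; j < nq - 1; j += 2) {
      const int da = (int)c1[qq[j]] + (int)c2[qq[j]];
      const int db = (int)c1[qq[j + 1]] + (int)c2[qq[j + 1]];
      v0 += aa[j] * (da - 1) + dd[j] * (da == 1);
      v1 += aa[j + 1] * (db - 1) + dd[j + 1] * (db == 1);
    }
    if (nq % 2) {
      const int da = (int)c1[qq[nq - 1]] + (int)c2[qq[nq - 1]];
      v0 += aa[nq - 1] * (da - 1) + dd[nq - 1] * (da == 1);
    }
    out[i] = v0 + v1;
  }
  return out;
}

// Marker codes for RRBLUP: individuals x markers, 1 / 0 / -1 for
// A1A1 / A1A2 / A2A2 (i.e. dosage - 1).
// [[Rcpp::export]]
NumericMatrix cpp_marker_codes(RawMatrix h1, RawMatrix h2, IntegerVector idx) {
  const int n = h1.ncol(), m = idx.size(), L = h1.nrow();
  NumericMatrix out(n, m);
  for (int i = 0; i < n; ++i) {
    const Rbyte *c1 = &h1(0, 0) + (R_xlen_t)i * L;
    const Rbyte *c2 = &h2(0, 0) + (R_xlen_t)i * L;
    for (int j = 0; j < m; ++j) {
      const int q = idx[j];
      out(i, j) = (double)((int)c1[q] + (int)c2[q] - 1);
    }
  }
  return out;
}

// Fused GEBV: sum over markers of u * (dosage - 1), without materialising
// the marker-code matrix.
// [[Rcpp::export]]
NumericVector cpp_gebv(RawMatrix h1, RawMatrix h2, IntegerVector idx,
                       NumericVector u) {
  const int n = h1.ncol(), m = idx.size(), L = h1.nrow();
  NumericVector out(n);
  const int *mm = &idx[0];
  const double *uu = &u[0];
  for (int i = 0; i < n; ++i) {
    const Rbyte *c1 = &h1(0, 0) + (R_xlen_t)i * L;
    const Rbyte *c2 = &h2(0, 0) + (R_xlen_t)i * L;
    double v0 = 0.0, v1 = 0.0;
    for (int j = 0; j < m - 1; j += 2) {
      v0 += uu[j] * ((int)c1[mm[j]] + (int)c2[mm[j]] - 1);
      v1 += uu[j + 1] * ((int)c1[mm[j + 1]] + (int)c2[mm[j + 1]] - 1);
    }
    if (m % 2)
      v0 += uu[m - 1] * ((int)c1[mm[m - 1]] + (int)c2[mm[m - 1]] - 1);
    out[i] = v0 + v1;
  }
  return out;
}

// Allele dosage (0/1/2) matrix, individuals x loci.
// [[Rcpp::export]]
IntegerMatrix cpp_dosage(RawMatrix h1, RawMatrix h2, IntegerVector idx) {
  const int n = h1.ncol(), m = idx.size(), L = h1.nrow();
  IntegerMatrix out(n, m);
  for (int i = 0; i < n; ++i) {
    const Rbyte *c1 = &h1(0, 0) + (R_xlen_t)i * L;
    const Rbyte *c2 = &h2(0, 0) + (R_xlen_t)i * L;
    for (int j = 0; j < m; ++j) {
      const int q = idx[j];
      out(i, j) = (int)c1[q] + (int)c2[q];
    }
  }
  return out;
}

// Per-individual fraction of heterozygous loci.
// [[Rcpp::export]]
NumericVector cpp_heterozygosity(RawMatrix h1, RawMatrix h2) {
  const int n = h1.ncol(), L = h1.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    const Rbyte *c1 = &h1(0, 0) + (R_xlen_t)i * L;
    const Rbyte *c2 = &h2(0, 0) + (R_xlen_t)i * L;
    int het = 0;
    for (int j = 0; j < L; ++j) het += (c1[j] != c2[j]);
    out[i] = (double)het / L;
  }
  return out;
}

// Minor-allele count per locus (over both haplotypes).
// [[Rcpp::export]]
IntegerVector cpp_allele_counts(RawMatrix h1, RawMatrix h2) {
  const int n = h1.ncol(), L = h1.nrow();
  IntegerVector cnt(L);
  for (int i = 0; i < n; ++i) {
    const Rbyte *c1 = &h1(0, 0) + (R_xlen_t)i * L;
    const Rbyte *c2 = &h2(0, 0) + (R_xlen_t)i * L;
    for (int j = 0; j < L; ++j) cnt[j] += (int)c1[j] + (int)c2[j];
  }
  for (int j = 0; j < L; ++j) cnt[j] = std::min(cnt[j], 2 * n - cnt[j]);
  return cnt;
}
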