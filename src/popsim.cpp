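#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Haplotypes are stored as a raw matrix with loci in rows and haplotypes in
// columns; individual j (0-based) owns columns 2j and 2j+1. Allele codes are
// 0x00 / 0x01. Loci are ordered by chromosome, positions (in Morgan) sorted
// within chromosome. All randomness uses R's RNG so set.seed() governs.

// Copy one recombinant gamete from the two parental haplotype columns into
// `out`. chr_start has C+1 entries (0-based locus offsets, last = L).
static void make_gamete(const unsigned char* h1, const unsigned char* h2,
                        const IntegerVector& chr_start,
                        const NumericVector& chr_len,
                        const NumericVector& pos,
                        double mu, unsigned char* out) {
  int C = chr_len.size();
  for (int c = 0; c < C; ++c) {
    int lo = chr_start[c], hi = chr_start[c + 1];  // [lo, hi)
    int nx = (int) R::rpois(chr_len[c]);
    const unsigned char* cur = (unif_rand() < 0.5) ? h1 : h2;
    const unsigned char* oth = (cur == h1) ? h2 : h1;
    if (nx == 0) {
      std::memcpy(out + lo, cur + lo, (size_t)(hi - lo));
    } else {
      std::vector<double> xpos(nx);
      for (int k = 0; k < nx; ++k) xpos[k] = unif_rand() * chr_len[c];
      std::sort(xpos.begin(), xpos.end());
      int seg_lo = lo;
      for (int k = 0; k < nx; ++k) {
        // first locus index with pos >= crossover position
        int brk = (int)(std::lower_bound(pos.begin() + lo, pos.begin() + hi,
                                         xpos[k]) - pos.begin());
        if (brk > seg_lo)
          std::memcpy(out + seg_lo, cur + seg_lo, (size_t)(brk - seg_lo));
        seg_lo = brk;
        const unsigned char* tmp = cur; cur = oth; oth = tmp;
      }
      if (hi > seg_lo)
        std::memcpy(out + seg_lo, cur + seg_lo, (size_t)(hi - seg_lo));
    }
    // recurrent mutation: binomial number of flips, uniform positions
    if (mu > 0) {
      int nl = hi - lo;
      int nm = (int) R::rbinom((double) nl, mu);
      for (int k = 0; k < nm; ++k) {
        int p = lo + (int)(unif_rand() * nl);
        if (p >= hi) p = hi - 1;
        out[p] ^= 1;
      }
    }
  }
}

// [[Rcpp::export(name = ".breed_cpp")]]
RawMatrix breed_cpp(RawMatrix parents, IntegerVector sire, IntegerVector dam,
                    IntegerVector chr_start, NumericVector chr_len,
                    NumericVector pos, double mu) {
  int L = parents.nrow();
  int n_off = sire.size();
  if (dam.size() != n_off) stop("sire and dam vectors must have equal length");
  RawMatrix off(L, 2 * n_off);
  unsigned char* pp = (unsigned char*) RAW(parents);
  unsigned char* po = (unsigned char*) RAW(off);
  RNGScope scope;
  for (int j = 0; j < n_off; ++j) {
    int s = sire[j], d = dam[j];  // 0-based individual indices
    make_gamete(pp + (size_t)(2 * s) * L, pp + (size_t)(2 * s + 1) * L,
                chr_start, chr_len, pos, mu, po + (size_t)(2 * j) * L);
    make_gamete(pp + (size_t)(2 * d) * L, pp + (size_t)(2 * d + 1) * L,
                chr_start, chr_len, pos, mu, po + (size_t)(2 * j + 1) * L);
  }
  return off;
}

// Frequency of allele 1 at every locus.
// [[Rcpp::export(name = ".hap_freq_cpp")]]
NumericVector hap_freq_cpp(RawMatrix hap) {
  int L = hap.nrow();
  int H = hap.ncol();
  NumericVector out(L);
  unsigned char* p = (unsigned char*) RAW(hap);
  for (int h = 0; h < H; ++h) {
    const unsigned char* col = p + (size_t) h * L;
    for (int i = 0; i < L; ++i) out[i] += col[i];
  }
  for (int i = 0; i < L; ++i) out[i] /= (double) H;
  return out;
}

// Allele counts (0/1/2) for a subset of loci; rows = individuals.
// loci are 1-based indices.
// [[Rcpp::export(name = ".geno_cpp")]]
IntegerMatrix geno_cpp(RawMatrix hap, IntegerVector loci) {
  int L = hap.nrow();
  int n = hap.ncol() / 2;
  int m = loci.size();
  IntegerMatrix out(n, m);
  unsigned char* p = (unsigned char*) RAW(hap);
  for (int k = 0; k < m; ++k) {
    int i = loci[k] - 1;
    if (i < 0 || i >= L) stop("locus index out of range");
    for (int j = 0; j < n; ++j) {
      out(j, k) = p[(size_t)(2 * j) * L + i] + p[(size_t)(2 * j + 1) * L + i];
    }
  }
  return out;
}

// Haplotype alleles (0/1) for a subset of loci; rows = haplotypes.
// [[Rcpp::export(name = ".hap_subset_cpp")]]
IntegerMatrix hap_subset_cpp(RawMatrix hap, IntegerVector loci) {
  int L = hap.nrow();
  int H = hap.ncol();
  int m = loci.size();
  IntegerMatrix out(H, m);
  unsigned char* p = (unsigned char*) RAW(hap);
  for (int k = 0; k < m; ++k) {
    int i = loci[k] - 1;
    if (i < 0 || i >= L) stop("locus index out of range");
    for (int h = 0; h < H; ++h) out(h, k) = p[(size_t) h * L + i];
  }
  return out;
}

// Numerator relationship matrix by the tabular method. sire/dam are 1-based
// indices into the same vector, 0 = unknown; parents must precede offspring.
// [[Rcpp::export(name = ".amat_cpp")]]
NumericMatrix amat_cpp(IntegerVector sire, IntegerVector dam) {
  int n = sire.size();
  NumericMatrix A(n, n);
  for (int i = 0; i < n; ++i) {
    int s = sire[i] - 1, d = dam[i] - 1;
    if (s >= i || d >= i) stop("parents must precede offspring");
    for (int j = 0; j < i; ++j) {
      double a = 0.0;
      if (s >= 0) a += 0.5 * A(j, s);
      if (d >= 0) a += 0.5 * A(j, d);
      A(i, j) = a;
      A(j, i) = a;
    }
    double f = (s >= 0 && d >= 0) ? 0.5 * A(s, d) : 0.0;
    A(i, i) = 1.0 + f;
  }
  return A;
}
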