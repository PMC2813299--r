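#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Ryser's formula with Gray-code updates: O(2^n * n) for an n x n matrix.
// Entries are non-negative reals (0/1 in practice); result fits a double
// exactly for the counts arising here (<= 9! = 362880).
static double ryser(const double* a, int n) {
  if (n == 0) return 1.0;
  std::vector<double> rowsum(n, 0.0);
  double total = 0.0;
  unsigned long gray = 0;
  unsigned long nsub = 1UL << n;
  for (unsigned long k = 1; k < nsub; ++k) {
    // bit that flips between Gray codes of k-1 and k
    int j = __builtin_ctzl(k);
    unsigned long bit = 1UL << j;
    gray ^= bit;
    if (gray & bit) {
      for (int i = 0; i < n; ++i) rowsum[i] += a[i + j * n];
    } else {
      for (int i = 0; i < n; ++i) rowsum[i] -= a[i + j * n];
    }
    double prod = 1.0;
    for (int i = 0; i < n; ++i) prod *= rowsum[i];
    int pop = __builtin_popcountl(gray);
    // sign (-1)^(n - |S|)
    if ((n - pop) & 1) total -= prod; else total += prod;
  }
  return total;
}

// [[Rcpp::export(name = ".perm_ryser")]]
double perm_ryser_cpp(NumericMatrix A) {
  int n = A.nrow();
  if (A.ncol() != n) stop("matrix must be square");
  if (n > 16) stop("permanent restricted to n <= 16");
  return ryser(REAL(A), n);
}

// Permanent of A with `row` (1-based) forced to each column in turn:
// out[a-1] = perm of A with row `row` replaced by the unit vector e_a,
// i.e. A[row, a] * perm(minor(A, row, a)). Used for per-action posterior
// mass given a stimulus.
// [[Rcpp::export(name = ".perm_cofactors")]]
NumericVector perm_cofactors_cpp(NumericMatrix A, int row) {
  int n = A.nrow();
  if (A.ncol() != n) stop("matrix must be square");
  if (row < 1 || row > n) stop("row out of range");
  int r = row - 1;
  NumericVector out(n);
  std::vector<double> minor_((n - 1) * (n - 1));
  for (int a = 0; a < n; ++a) {
    if (A(r, a) == 0.0) { out[a] = 0.0; continue; }
    int jj = 0;
    for (int j = 0; j < n; ++j) {
      if (j == a) continue;
      int ii = 0;
      for (int i = 0; i < n; ++i) {
        if (i == r) continue;
        minor_[ii + jj * (n - 1)] = A(i, j);
        ++ii;
      }
      ++jj;
    }
    out[a] = A(r, a) * ryser(minor_.data(), n - 1);
  }
  return out;
}

// Brute-force oracle: count permutations of 1..n compatible with the 0/1
// allowance matrix by explicit enumeration (std::next_permutation).
// [[Rcpp::export(name = ".count_compatible_brute")]]
double count_compatible_brute_cpp(NumericMatrix A) {
  int n = A.nrow();
  if (A.ncol() != n) stop("matrix must be square");
  if (n > 10) stop("brute-force enumeration restricted to n <= 10");
  std::vector<int> p(n);
  for (int i = 0; i < n; ++i) p[i] = i;
  double count = 0.0;
  do {
    bool ok = true;
    for (int i = 0; i < n; ++i) {
      if (A(i, p[i]) == 0.0) { ok = false; break; }
    }
    if (ok) count += 1.0;
  } while (std::next_permutation(p.begin(), p.end()));
  return count;
}
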