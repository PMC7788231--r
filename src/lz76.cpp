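#include <Rcpp.h>
using namespace Rcpp;

//' Exhaustive-history Lempel-Ziv (LZ76) word count
//'
//' Counts the number of words in the exhaustive-history parsing of a binary
//' sequence (Kaspar-Schuster scan): the sequence is scanned left to right and
//' the current phrase is extended for as long as it can be reproduced from the
//' history preceding it (self-overlap allowed); each failure starts a new word.
//' A trailing phrase that remains reproducible up to the end of the sequence
//' still counts as one word.
//'
//' @param s integer vector of 0/1 symbols.
//' @return integer word count \code{c(S)}.
//' @examples
//' lzWordCount(c(0L, 1L, 0L, 1L))
//' @export
// [[Rcpp::export]]
int lzWordCount(IntegerVector s) {
  const R_xlen_t n = s.size();
  if (n < 1) stop("sequence must have length >= 1");
  std::vector<unsigned char> buf(n);
  for (R_xlen_t t = 0; t < n; ++t) {
    if (s[t] != 0 && s[t] != 1) stop("sequence must be binary (0/1)");
    buf[t] = static_cast<unsigned char>(s[t]);
  }
  const unsigned char *b = buf.data();
  int c = 1;
  R_xlen_t l = 1, i = 0, k = 1, kmax = 1;
  if (n == 1) return 1;
  for (;;) {
    if (b[i + k - 1] == b[l + k - 1]) {
      ++k;
      if (l + k > n) { ++c; break; }
    } else {
      if (k > kmax) kmax = k;
      ++i;
      if (i == l) {
        ++c;
        l += kmax;
        if (l + 1 > n) break;
        i = 0; k = 1; kmax = 1;
      } else {
        k = 1;
      }
    }
  }
  return c;
}
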