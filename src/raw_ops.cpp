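#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// splice helpers for the simulator's raw-vector genome: plain memcpy,
// avoiding R-level index vectors on multi-megabase sequences

// [[Rcpp::export]]
RawVector raw_insert(RawVector x, int dest, RawVector frag) {
  const R_xlen_t n = x.size(), L = frag.size();
  if (dest < 0 || dest > n) stop("insertion point out of range");
  RawVector out(n + L);
  if (dest > 0) std::memcpy(RAW(out), RAW(x), (size_t)dest);
  if (L > 0) std::memcpy(RAW(out) + dest, RAW(frag), (size_t)L);
  if (n - dest > 0)
    std::memcpy(RAW(out) + dest + L, RAW(x) + dest, (size_t)(n - dest));
  return out;
}

// [[Rcpp::export]]
RawVector raw_delete(RawVector x, int s, int e) {
  const R_xlen_t n = x.size();
  if (s < 0 || e > n || s >= e) stop("invalid deletion span");
  RawVector out(n - (e - s));
  if (s > 0) std::memcpy(RAW(out), RAW(x), (size_t)s);
  if (n - e > 0) std::memcpy(RAW(out) + s, RAW(x) + e, (size_t)(n - e));
  return out;
}
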