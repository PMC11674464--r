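#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// Counter-based uniform generator. Each draw is a pure function of
// (seed, id, process, year), so a given person/process/year consumes the
// same variate in every scenario: scenario comparisons are paired by
// construction (common random numbers) and draws never desynchronise when
// scenarios differ in which events they evaluate.

static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

// [[Rcpp::export]]
NumericVector cr_unif_cpp(double seed, IntegerVector id, int process, int year) {
  R_xlen_t n = id.size();
  NumericVector out(n);
  uint64_t s = splitmix64((uint64_t)(int64_t)seed);
  uint64_t py = splitmix64(s ^ ((uint64_t)(uint32_t)process << 32) ^
                           (uint64_t)(uint32_t)(year + 4096));
  for (R_xlen_t i = 0; i < n; ++i) {
    uint64_t h = splitmix64(py ^ (uint64_t)(uint32_t)id[i]);
    // 53-bit mantissa, strictly inside (0, 1)
    out[i] = ((double)(h >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  return out;
}
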