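#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Exact reversal-distance oracle for signed permutations, by breadth-first
// search over the full state space of n <= 8 elements (2^n * n! states).
//
// States are ranked perfectly: Lehmer code of the magnitudes (mixed radix)
// shifted left by n bits, plus one sign bit per element.  A single BFS from
// the identity yields the distance of every permutation at once: each signed
// reversal is an involution, so the distance from p to the identity equals
// the distance from the identity to p.

static const int kFact[9] = {1, 1, 2, 6, 24, 120, 720, 5040, 40320};

static inline uint32_t encode_state(const int* m, const int* sg, int n) {
  uint32_t lehmer = 0;
  for (int i = 0; i < n; ++i) {
    int c = 0;
    for (int j = i + 1; j < n; ++j)
      if (m[j] < m[i]) ++c;
    lehmer = lehmer * (n - i) + c;
  }
  uint32_t sbits = 0;
  for (int i = 0; i < n; ++i) sbits = (sbits << 1) | (uint32_t)sg[i];
  return (lehmer << n) | sbits;
}

static inline void decode_state(uint32_t code, int n, int* m, int* sg) {
  uint32_t sbits = code & ((1u << n) - 1u);
  uint32_t lehmer = code >> n;
  int c[8];
  for (int i = n - 1; i >= 0; --i) {
    c[i] = lehmer % (n - i);
    lehmer /= (n - i);
  }
  bool used[9] = {false};
  for (int i = 0; i < n; ++i) {
    int skip = c[i], val = 0;
    for (int v = 1; v <= n; ++v) {
      if (!used[v]) {
        if (skip == 0) { val = v; break; }
        --skip;
      }
    }
    used[val] = true;
    m[i] = val;
  }
  for (int i = 0; i < n; ++i)
    sg[i] = (sbits >> (n - 1 - i)) & 1u;
}

// Full distance table (distance to identity) for all signed permutations of
// size n; entry k is the distance of the permutation with rank k.
// [[Rcpp::export]]
IntegerVector bfs_reversal_table(int n) {
  if (n < 1 || n > 8)
    stop("state-space guard: oracle supports n between 1 and 8");
  size_t size = ((size_t)kFact[n]) << n;
  std::vector<uint8_t> dist(size, 255);
  std::vector<uint32_t> cur, nxt;
  int m[8], sg[8], m2[8], sg2[8];
  for (int i = 0; i < n; ++i) { m[i] = i + 1; sg[i] = 0; }
  uint32_t id = encode_state(m, sg, n);
  dist[id] = 0;
  cur.push_back(id);
  uint8_t d = 0;
  while (!cur.empty()) {
    ++d;
    nxt.clear();
    for (size_t q = 0; q < cur.size(); ++q) {
      decode_state(cur[q], n, m, sg);
      for (int i = 0; i < n; ++i) {
        for (int j = i; j < n; ++j) {
          for (int k = 0; k < n; ++k) { m2[k] = m[k]; sg2[k] = sg[k]; }
          for (int a = i, b = j; a <= j; ++a, --b) {
            m2[a] = m[b];
            sg2[a] = 1 - sg[b];
          }
          uint32_t c2 = encode_state(m2, sg2, n);
          if (dist[c2] == 255) {
            dist[c2] = d;
            nxt.push_back(c2);
          }
        }
      }
    }
    cur.swap(nxt);
  }
  IntegerVector out(size);
  for (size_t i = 0; i < size; ++i) out[i] = dist[i];
  return out;
}

// 0-based rank of a signed permutation (vector of signed integers whose
// magnitudes are 1..n), matching the indexing of bfs_reversal_table().
// [[Rcpp::export]]
int encode_signed_perm(IntegerVector p) {
  int n = p.size();
  if (n < 1 || n > 8) stop("encode_signed_perm supports n between 1 and 8");
  int m[8], sg[8];
  for (int i = 0; i < n; ++i) {
    m[i] = p[i] > 0 ? p[i] : -p[i];
    sg[i] = p[i] > 0 ? 0 : 1;
  }
  return (int)encode_state(m, sg, n);
}
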