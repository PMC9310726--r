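#include <Rcpp.h>
#include <unordered_map>

using namespace Rcpp;

// LZ78 word-dictionary parse of a 0/1 sequence.
//
// The dictionary is a trie over {0,1} stored as a flat hash map:
// key = 2*node + bit -> child node id, root = 0.  Scanning extends the
// current phrase while it matches a dictionary entry; on the first
// mismatch the extended phrase is inserted and scanning restarts at the
// root.  A trailing phrase that ends the sequence while still matching a
// dictionary entry counts as one additional phrase.
//
// [[Rcpp::export(name = ".lz78_count")]]
int lz78_count(const IntegerVector& bits) {
  const R_xlen_t n = bits.size();
  if (n == 0) return 0;
  std::unordered_map<long long, int> trie;
  trie.reserve(static_cast<size_t>(n / 4) + 8);
  int L = 0;
  int node = 0;       // root
  int next_id = 1;
  bool open = false;  // a phrase is in progress
  for (R_xlen_t i = 0; i < n; ++i) {
    const int b = bits[i];
    if (b != 0 && b != 1) stop("bits must be 0 or 1");
    const long long key = 2LL * node + b;
    auto it = trie.find(key);
    if (it != trie.end()) {
      node = it->second;
      open = true;
    } else {
      trie.emplace(key, next_id++);
      ++L;
      node = 0;
      open = false;
    }
  }
  if (open) ++L;
  return L;
}
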