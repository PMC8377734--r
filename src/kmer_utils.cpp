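#include <Rcpp.h>
#include <unordered_map>
#include <string>
#include <cstring>

using namespace Rcpp;

static inline int base_code(char c) {
    switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1;
    }
}

// 2-bit encoding of a length-k ACGT string (A=00 < C=01 < G=10 < T=11), so
// lexicographic order of equal-length k-mers equals numeric order of codes
// and the canonical (lexicographic-min) key carries over as min(fwd, rc)
static inline bool encode_kmer(const char *s, int k, uint64_t &out) {
    uint64_t v = 0;
    for (int i = 0; i < k; ++i) {
        int c = base_code(s[i]);
        if (c < 0) return false;
        v = (v << 2) | static_cast<uint64_t>(c);
    }
    out = v;
    return true;
}

// Closed-set exact k-mer counting: every length-k window of every read is
// looked up (under its canonical key when canonical = true) against the fixed
// database key set; only database k-mers are counted, so memory is O(|keys|).
// Windows roll through each read with an incrementally updated forward and
// reverse-complement 2-bit code; requires k <= 32.
// [[Rcpp::export]]
List cpp_count_kmers(CharacterVector reads, CharacterVector keys, int k,
                     bool canonical) {
    if (k < 1 || k > 32) stop("k must be in 1..32");
    std::unordered_map<uint64_t, int> index;
    index.reserve(static_cast<size_t>(keys.size()) * 2);
    for (R_xlen_t i = 0; i < keys.size(); ++i) {
        const char *ks = CHAR(STRING_ELT(keys, i));
        if (static_cast<int>(std::strlen(ks)) != k)
            stop("database key %d does not have length k", (int)(i + 1));
        uint64_t code;
        if (!encode_kmer(ks, k, code))
            stop("database key %d contains a non-ACGT character", (int)(i + 1));
        index.emplace(code, static_cast<int>(i));
    }

    std::vector<int> counts(keys.size(), 0);
    double n_windows = 0, n_valid = 0;
    const uint64_t mask = (k == 32) ? ~uint64_t(0)
                                    : ((uint64_t(1) << (2 * k)) - 1);
    const int rc_shift = 2 * (k - 1);

    for (R_xlen_t r = 0; r < reads.size(); ++r) {
        const char *s = CHAR(STRING_ELT(reads, r));
        int len = static_cast<int>(std::strlen(s));
        if (len < k) continue;
        n_windows += len - k + 1;
        uint64_t fwd = 0, rc = 0;
        int valid = 0;  // consecutive valid bases ending at current position
        for (int j = 0; j < len; ++j) {
            int c = base_code(s[j]);
            if (c < 0) { valid = 0; continue; }
            fwd = ((fwd << 2) | static_cast<uint64_t>(c)) & mask;
            rc = (rc >> 2) |
                (static_cast<uint64_t>(3 - c) << rc_shift);
            if (++valid < k) continue;
            n_valid += 1;
            uint64_t key = (canonical && rc < fwd) ? rc : fwd;
            std::unordered_map<uint64_t, int>::const_iterator it =
                index.find(key);
            if (it != index.end()) counts[it->second] += 1;
        }
    }

    IntegerVector out(keys.size());
    for (R_xlen_t i = 0; i < keys.size(); ++i) out[i] = counts[i];
    return List::create(_["counts"] = out,
                        _["windows_scanned"] = n_windows,
                        _["windows_valid"] = n_valid);
}

// In-place style single-base substitution over a copied read set; positions
// are 1-based (read_idx into reads, pos within the read).
// [[Rcpp::export]]
CharacterVector cpp_inject_errors(CharacterVector reads, IntegerVector read_idx,
                                  IntegerVector pos, CharacterVector base) {
    R_xlen_t n = reads.size();
    std::vector<std::string> v(n);
    for (R_xlen_t i = 0; i < n; ++i) v[i] = CHAR(STRING_ELT(reads, i));
    for (R_xlen_t e = 0; e < read_idx.size(); ++e) {
        int r = read_idx[e] - 1;
        int p = pos[e] - 1;
        if (r < 0 || r >= n) stop("read index out of range");
        if (p < 0 || p >= static_cast<int>(v[r].size()))
            stop("position out of range for read %d", r + 1);
        v[r][p] = CHAR(STRING_ELT(base, e))[0];
    }
    CharacterVector out(n);
    for (R_xlen_t i = 0; i < n; ++i) out[i] = v[i];
    return out;
}
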