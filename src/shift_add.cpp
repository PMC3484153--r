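#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <string>

using namespace Rcpp;

// Bit-parallel shift-add search for all alignments of `pattern` in `text`
// with Hamming distance <= k (Baeza-Yates/Gonnet shift-add with saturating
// per-position counters, the Wu-Manber counting variant).
//
// State word D holds one counter per pattern position, each `width` bits
// wide: after consuming text[j], the counter for pattern prefix length i
// holds the number of mismatches of pattern[0..i-1] against
// text[j-i+1..j], saturated via a sticky overflow word O. The counter low
// part must be able to hold k (width = ceil(log2(k+1)) + 1, min 2), so a
// pattern matches at an alignment iff its top counter is <= k and its
// overflow bit is clear.

static inline int base_index(char c) {
    switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1;
    }
}

// [[Rcpp::export(name = ".shift_add_core")]]
List shift_add_core(std::string pattern, std::string text, int k) {
    const int m = static_cast<int>(pattern.size());
    const int n = static_cast<int>(text.size());
    if (m < 1) stop("shift_add_search: empty pattern");
    if (k < 0) stop("shift_add_search: k must be >= 0");
    int keff = k < m ? k : m;

    int width = 2;  // low part >= 1 bit, plus the overflow bit
    while ((1 << (width - 1)) - 1 < keff) ++width;
    if (m * width > 64) {
        stop("shift_add_search: pattern of length %d with k=%d needs %d "
             "state bits (> 64-bit word capacity); chunk the pattern or "
             "reduce k", m, k, m * width);
    }

    for (int i = 0; i < m; ++i)
        if (base_index(pattern[i]) < 0)
            stop("shift_add_search: pattern has a character outside {A,C,G,T}");

    const int bits = m * width;
    const uint64_t full = (bits == 64) ? ~UINT64_C(0)
                                       : ((UINT64_C(1) << bits) - 1);
    // high (overflow) bit of every counter
    uint64_t high = 0;
    for (int i = 0; i < m; ++i)
        high |= UINT64_C(1) << (i * width + width - 1);

    // B[c]: 1 in counter i iff pattern[i] != c
    uint64_t B[4];
    for (int c = 0; c < 4; ++c) {
        uint64_t b = 0;
        for (int i = 0; i < m; ++i)
            if (base_index(pattern[i]) != c)
                b |= UINT64_C(1) << (i * width);
        B[c] = b;
    }
    // any non-ACGT text character mismatches every pattern position
    uint64_t Bother = 0;
    for (int i = 0; i < m; ++i) Bother |= UINT64_C(1) << (i * width);

    const int top_shift = (m - 1) * width;
    const uint64_t counter_mask = (UINT64_C(1) << (width - 1)) - 1;

    std::vector<int> starts, counts;
    uint64_t D = 0, O = 0;
    for (int j = 0; j < n; ++j) {
        int c = base_index(text[j]);
        uint64_t b = (c >= 0) ? B[c] : Bother;
        D = ((D << width) + b) & full;
        O = ((O << width) | (D & high)) & full;
        D &= ~high;
        if (j >= m - 1) {
            uint64_t cnt = (D >> top_shift) & counter_mask;
            bool over = ((O >> top_shift) & (UINT64_C(1) << (width - 1))) != 0;
            if (!over && cnt <= static_cast<uint64_t>(keff)) {
                starts.push_back(j - m + 2);  // 1-based
                counts.push_back(static_cast<int>(cnt));
            }
        }
    }

    // exact mismatch positions (1-based on the pattern) per hit
    List pos(starts.size());
    for (size_t h = 0; h < starts.size(); ++h) {
        std::vector<int> mm;
        int s0 = starts[h] - 1;
        for (int i = 0; i < m; ++i)
            if (text[s0 + i] != pattern[i]) mm.push_back(i + 1);
        pos[h] = IntegerVector(mm.begin(), mm.end());
    }
    return List::create(_["subject_start"] = IntegerVector(starts.begin(), starts.end()),
                        _["mismatch_count"] = IntegerVector(counts.begin(), counts.end()),
                        _["mismatch_positions"] = pos);
}
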