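#include <Rcpp.h>
#include <set>
#include <cstdint>

// Bottom-s MinHash sketching of canonical k-mers.
//
// k-mers are 2-bit encoded (A=0, C=1, G=2, T=3) with a rolling window; any
// other character resets the window, so k-mers containing N are skipped.
// The canonical form is the lexicographic minimum of the 2-bit codes of a
// k-mer and its reverse complement (identical ordering to string
// comparison under A<C<G<T). Codes are scrambled with the splitmix64
// finalizer seeded by `seed`, then truncated to the top 53 bits so every
// hash is exactly representable as an R double.

static inline uint64_t splitmix64(uint64_t x) {
    x += 0x9E3779B97F4A7C15ULL;
    x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
    x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
    return x ^ (x >> 31);
}

static inline int base_code(char c) {
    switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
    }
}

// [[Rcpp::export(name = ".cpp_sketch_hashes")]]
Rcpp::NumericVector cpp_sketch_hashes(Rcpp::CharacterVector contigs,
                                      int k, int sketch_size, double seed) {
    if (k < 1 || k > 31) Rcpp::stop("k must be between 1 and 31");
    const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
    const uint64_t seed_mix = splitmix64((uint64_t)(int64_t)seed);
    const int shift_rc = 2 * (k - 1);

    // bounded ordered set of the sketch_size smallest distinct hashes
    std::set<uint64_t> bottom;

    for (R_xlen_t i = 0; i < contigs.size(); ++i) {
        const char *s = CHAR(STRING_ELT(contigs, i));
        uint64_t fwd = 0, rc = 0;
        int run = 0;
        for (const char *p = s; *p; ++p) {
            int b = base_code(*p);
            if (b < 0) { run = 0; fwd = 0; rc = 0; continue; }
            fwd = ((fwd << 2) | (uint64_t)b) & mask;
            rc = (rc >> 2) | ((uint64_t)(3 - b) << shift_rc);
            if (++run < k) continue;
            uint64_t canon = fwd < rc ? fwd : rc;
            uint64_t h = splitmix64(canon ^ seed_mix) >> 11; // 53 bits
            if ((int)bottom.size() < sketch_size) {
                bottom.insert(h);
            } else if (h < *bottom.rbegin()) {
                if (bottom.insert(h).second && (int)bottom.size() > sketch_size)
                    bottom.erase(std::prev(bottom.end()));
            }
        }
    }

    Rcpp::NumericVector out(bottom.size());
    R_xlen_t j = 0;
    for (uint64_t h : bottom) out[j++] = (double)h;
    return out;
}
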