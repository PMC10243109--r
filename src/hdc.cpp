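#include <Rcpp.h>
using namespace Rcpp;

// Bit convention throughout: bit position p (0-based) lives in word w = p / 32
// at bit b = p % 32 (little-endian within word). Words are 32-bit patterns
// stored in R integers; all arithmetic reinterprets them as unsigned.

static inline int n_words(int D) { return (D + 31) / 32; }

static inline int popcount32(unsigned int x) {
#if defined(__GNUC__) || defined(__clang__)
    return __builtin_popcount(x);
#else
    x = x - ((x >> 1) & 0x55555555u);
    x = (x & 0x33333333u) + ((x >> 2) & 0x33333333u);
    x = (x + (x >> 4)) & 0x0F0F0F0Fu;
    return (int)((x * 0x01010101u) >> 24);
#endif
}

// [[Rcpp::export]]
IntegerVector cpp_pack_bits(IntegerVector bits) {
    int D = bits.size();
    int W = n_words(D);
    IntegerVector words(W);
    unsigned int *w = reinterpret_cast<unsigned int *>(INTEGER(words));
    for (int p = 0; p < D; ++p) {
        int v = bits[p];
        if (v != 0 && v != 1)
            stop("bit vector must contain only 0 and 1");
        if (v) w[p / 32] |= (1u << (p % 32));
    }
    return words;
}

// [[Rcpp::export]]
IntegerVector cpp_unpack_bits(IntegerVector words, int D) {
    if (words.size() != n_words(D))
        stop("word count does not match ceil(D/32)");
    IntegerVector bits(D);
    const unsigned int *w = reinterpret_cast<const unsigned int *>(INTEGER(words));
    for (int p = 0; p < D; ++p)
        bits[p] = (w[p / 32] >> (p % 32)) & 1u;
    return bits;
}

// One uniform random D-bit HV, packed. Uses R's RNG.
// [[Rcpp::export]]
IntegerVector cpp_random_hv(int D) {
    int W = n_words(D);
    IntegerVector words(W);
    unsigned int *w = reinterpret_cast<unsigned int *>(INTEGER(words));
    for (int p = 0; p < D; ++p)
        if (R::unif_rand() < 0.5) w[p / 32] |= (1u << (p % 32));
    return words;
}

// Chain of n HVs: row 1 uniform random, each next row equals its predecessor
// with exactly `flip` distinct uniformly chosen bits inverted. Rows of the
// returned matrix are packed HVs. Uses R's RNG (set.seed upstream).
// [[Rcpp::export]]
IntegerMatrix cpp_generate_hv_chain(int n, int D, int flip) {
    if (flip < 1 || flip > D) stop("flip count must be in [1, D]");
    if (n < 1) stop("need at least one hypervector");
    int W = n_words(D);
    IntegerMatrix out(n, W);
    std::vector<unsigned int> cur(W, 0u);
    for (int p = 0; p < D; ++p)
        if (R::unif_rand() < 0.5) cur[p / 32] |= (1u << (p % 32));
    for (int w = 0; w < W; ++w) out(0, w) = (int)cur[w];

    std::vector<int> idx(D);
    for (int p = 0; p < D; ++p) idx[p] = p;
    for (int i = 1; i < n; ++i) {
        // partial Fisher-Yates: first `flip` entries of idx are a uniform
        // sample of distinct positions; carrying the permuted state over
        // between steps keeps each step's sample uniform and independent
        for (int k = 0; k < flip; ++k) {
            int j = k + (int)(R::unif_rand() * (D - k));
            if (j >= D) j = D - 1;
            std::swap(idx[k], idx[j]);
            int p = idx[k];
            cur[p / 32] ^= (1u << (p % 32));
        }
        for (int w = 0; w < W; ++w) out(i, w) = (int)cur[w];
    }
    return out;
}

// Majority-bundle encoding of a batch of quantized spectra:
// per spectrum, bind I[bin] XOR L[level] for every peak, then take the
// pointwise majority; exact ties fall back to the tie-break HV bit.
// bins are 0-based codebook rows, levels are 1-based (level j -> row j-1).
// [[Rcpp::export]]
IntegerMatrix cpp_encode_batch(List bins, List levels,
                               IntegerMatrix idWords, IntegerMatrix levelWords,
                               IntegerVector tieWords, int D) {
    int n = bins.size();
    int W = n_words(D);
    if (idWords.ncol() != W || levelWords.ncol() != W || tieWords.size() != W)
        stop("codebook word width does not match D");
    IntegerMatrix out(n, W);
    const unsigned int *tw = reinterpret_cast<const unsigned int *>(INTEGER(tieWords));
    std::vector<int> cnt(D);
    for (int s = 0; s < n; ++s) {
        IntegerVector bi = bins[s];
        IntegerVector le = levels[s];
        int m = bi.size();
        if (m != le.size()) stop("bins and levels length mismatch");
        std::fill(cnt.begin(), cnt.end(), 0);
        for (int k = 0; k < m; ++k) {
            int i = bi[k], j = le[k] - 1;
            if (i < 0 || i >= idWords.nrow())
                stop("bin index out of codebook range");
            if (j < 0 || j >= levelWords.nrow())
                stop("intensity level out of codebook range");
            for (int w = 0; w < W; ++w) {
                unsigned int x = ((unsigned int)idWords(i, w)) ^
                                 ((unsigned int)levelWords(j, w));
                if (!x) continue;
                int base = 32 * w;
                int hi = std::min(32, D - base);
                for (int b = 0; b < hi; ++b)
                    cnt[base + b] += (x >> b) & 1u;
            }
        }
        for (int w = 0; w < W; ++w) {
            unsigned int acc = 0u;
            int base = 32 * w;
            int hi = std::min(32, D - base);
            for (int b = 0; b < hi; ++b) {
                int c2 = 2 * cnt[base + b];
                unsigned int bit;
                if (c2 > m) bit = 1u;
                else if (c2 < m) bit = 0u;
                else bit = (tw[w] >> b) & 1u;
                acc |= bit << b;
            }
            out(s, w) = (int)acc;
        }
    }
    return out;
}

// [[Rcpp::export]]
double cpp_hamming_pair(IntegerVector a, IntegerVector b, int D) {
    if (a.size() != b.size()) stop("hypervector dimension mismatch");
    const unsigned int *pa = reinterpret_cast<const unsigned int *>(INTEGER(a));
    const unsigned int *pb = reinterpret_cast<const unsigned int *>(INTEGER(b));
    long bits = 0;
    for (int w = 0; w < a.size(); ++w) bits += popcount32(pa[w] ^ pb[w]);
    return (double)bits / (double)D;
}

// Condensed normalized-Hamming matrix over rows of a packed HV matrix, in
// stats::dist order: pairs (i, j), i < j, outer loop over i.
// [[Rcpp::export]]
NumericVector cpp_hamming_condensed(IntegerMatrix words, int D) {
    int n = words.nrow(), W = words.ncol();
    if (n < 2) return NumericVector(0);
    NumericVector out((double)n * (n - 1) / 2);
    // copy row-major for cache friendliness
    std::vector<unsigned int> rw((size_t)n * W);
    for (int i = 0; i < n; ++i)
        for (int w = 0; w < W; ++w)
            rw[(size_t)i * W + w] = (unsigned int)words(i, w);
    size_t q = 0;
    for (int i = 0; i < n - 1; ++i) {
        const unsigned int *ri = &rw[(size_t)i * W];
        for (int j = i + 1; j < n; ++j) {
            const unsigned int *rj = &rw[(size_t)j * W];
            long bits = 0;
            for (int w = 0; w < W; ++w) bits += popcount32(ri[w] ^ rj[w]);
            out[q++] = (double)bits / (double)D;
        }
    }
    return out;
}
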