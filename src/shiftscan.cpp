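#include <Rcpp.h>
#include <vector>
#include <string>
#include <cstring>
#include <algorithm>
using namespace Rcpp;

// 2-bit base encoding; -1 for anything outside ACGT
static inline int base_idx(char c) {
    switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1;
    }
}
static const char BASES[4] = {'A', 'C', 'G', 'T'};

// standard codon -> amino acid map, indexed by 16*b1 + 4*b2 + b3 with
// A=0,C=1,G=2,T=3 (translation under the bacterial table is identical
// to the standard table; only start-codon rules differ)
static const char AA_BY_CODON[65] =
    "KNKNTTTTRSRSIIMI"
    "QHQHPPPPRRRRLLLL"
    "EDEDAAAAGGGGVVVV"
    "*Y*YSSSS*CWCLFLF";

// ---- core shuffler on a 2-bit encoded buffer --------------------------
//
// Markov chain of codon swaps between positions encoding the same
// amino acid; a swap is accepted only when the multiset of junction
// dinucleotides it touches is unchanged, so the dinucleotide
// composition of the whole sequence is preserved exactly (internal
// codon dinucleotides travel with their codon). The first codon is
// held fixed.
static void shuffle_encoded(std::vector<unsigned char> &b, double sweeps_mult) {
    int len = (int)b.size();
    int n = len / 3;
    if (n <= 2) return;

    std::vector<unsigned char> aa(n);
    for (int i = 0; i < n; ++i)
        aa[i] = (unsigned char)AA_BY_CODON[16 * b[3 * i] + 4 * b[3 * i + 1] +
                                           b[3 * i + 2]];

    // positions (excluding codon 0) grouped by amino acid
    std::vector<std::vector<int> > groups(128);
    for (int i = 1; i < n; ++i) groups[aa[i]].push_back(i);

    long attempts = (long)(sweeps_mult * n);
    int jpos[4], before[4], after[4];

    for (long t = 0; t < attempts; ++t) {
        int u = 1 + (int)(unif_rand() * (n - 1));
        if (u >= n) u = n - 1;
        const std::vector<int> &grp = groups[aa[u]];
        if (grp.size() < 2) continue;
        int v = grp[(int)(unif_rand() * grp.size())];
        if (v == u) continue;
        if (u > v) std::swap(u, v);

        unsigned char *cu = &b[3 * u], *cv = &b[3 * v];
        if (cu[0] == cv[0] && cu[1] == cv[1] && cu[2] == cv[2]) continue;

        int m = 0;
        jpos[m++] = 3 * u - 1;
        if (3 * u + 3 < len) jpos[m++] = 3 * u + 2;
        jpos[m++] = 3 * v - 1;
        if (3 * v + 3 < len) jpos[m++] = 3 * v + 2;
        // dedup (adjacent codons share the junction 3u+2 == 3v-1)
        std::sort(jpos, jpos + m);
        m = (int)(std::unique(jpos, jpos + m) - jpos);

        for (int k = 0; k < m; ++k)
            before[k] = 4 * b[jpos[k]] + b[jpos[k] + 1];
        for (int k = 0; k < 3; ++k) std::swap(cu[k], cv[k]);
        for (int k = 0; k < m; ++k)
            after[k] = 4 * b[jpos[k]] + b[jpos[k] + 1];

        std::sort(before, before + m);
        std::sort(after, after + m);
        bool ok = true;
        for (int k = 0; k < m; ++k) if (before[k] != after[k]) { ok = false; break; }
        if (!ok)
            for (int k = 0; k < 3; ++k) std::swap(cu[k], cv[k]);
    }
}

static std::vector<unsigned char> encode(const char *s, int len) {
    std::vector<unsigned char> b(len);
    for (int i = 0; i < len; ++i) {
        int x = base_idx(s[i]);
        if (x < 0) stop("sequence contains a base outside {A,C,G,T}");
        b[i] = (unsigned char)x;
    }
    return b;
}

// [[Rcpp::export(name = ".shuffle_codons_cpp")]]
std::string shuffle_codons_cpp(std::string seq, double sweeps_mult = 10.0) {
    int len = (int)seq.size();
    if (len % 3 != 0) stop("sequence length must be a multiple of 3");
    std::vector<unsigned char> b = encode(seq.c_str(), len);
    shuffle_encoded(b, sweeps_mult);
    for (int i = 0; i < len; ++i) seq[i] = BASES[b[i]];
    return seq;
}

// ---- pattern counting -------------------------------------------------

struct PatternLookup {
    int k;
    long mask;
    std::vector<int> table;
};

static PatternLookup build_lookup(CharacterVector patterns) {
    PatternLookup lk;
    int np = patterns.size();
    if (np == 0) stop("no patterns");
    lk.k = LENGTH(STRING_ELT(patterns, 0));
    if (lk.k < 1 || lk.k > 12) stop("pattern length must be in 1..12");
    long size = 1L << (2 * lk.k);
    lk.mask = size - 1;
    lk.table.assign(size, -1);
    for (int p = 0; p < np; ++p) {
        const char *s = CHAR(STRING_ELT(patterns, p));
        if ((int)std::strlen(s) != lk.k)
            stop("patterns must all have the same length");
        long code = 0;
        for (int i = 0; i < lk.k; ++i) {
            int b = base_idx(s[i]);
            if (b < 0) stop("pattern contains a base outside {A,C,G,T}");
            code = (code << 2) | b;
        }
        if (lk.table[code] != -1) stop("duplicate pattern");
        lk.table[code] = p;
    }
    return lk;
}

static void count_encoded(const std::vector<unsigned char> &b,
                          const PatternLookup &lk, IntegerMatrix &counts) {
    long code = 0;
    int valid = 0;
    int len = (int)b.size();
    for (int i = 0; i < len; ++i) {
        code = ((code << 2) | b[i]) & lk.mask;
        ++valid;
        if (valid >= lk.k) {
            int idx = lk.table[code];
            if (idx >= 0) counts(idx, (i - lk.k + 1) % 3) += 1;
        }
    }
}

// [[Rcpp::export(name = ".count_patterns_cpp")]]
IntegerMatrix count_patterns_cpp(CharacterVector seqs, CharacterVector patterns) {
    PatternLookup lk = build_lookup(patterns);
    IntegerMatrix counts(patterns.size(), 3);
    for (int s = 0; s < seqs.size(); ++s) {
        const char *str = CHAR(STRING_ELT(seqs, s));
        int len = (int)std::strlen(str);
        long code = 0;
        int valid = 0;
        for (int i = 0; i < len; ++i) {
            int b = base_idx(str[i]);
            if (b < 0) { valid = 0; code = 0; continue; }
            code = ((code << 2) | b) & lk.mask;
            ++valid;
            if (valid >= lk.k) {
                int idx = lk.table[code];
                if (idx >= 0) counts(idx, (i - lk.k + 1) % 3) += 1;
            }
        }
    }
    return counts;
}

// one dicodon-shuffled replicate of a whole genome, returning the
// per-(pattern, phase) count matrix without materializing the genome
// [[Rcpp::export(name = ".shuffled_counts_cpp")]]
IntegerMatrix shuffled_counts_cpp(CharacterVector genome,
                                  CharacterVector patterns,
                                  double sweeps_mult = 10.0) {
    PatternLookup lk = build_lookup(patterns);
    IntegerMatrix counts(patterns.size(), 3);
    for (int s = 0; s < genome.size(); ++s) {
        const char *str = CHAR(STRING_ELT(genome, s));
        int len = (int)std::strlen(str);
        if (len % 3 != 0) stop("gene length not a multiple of 3");
        std::vector<unsigned char> b = encode(str, len);
        shuffle_encoded(b, sweeps_mult);
        count_encoded(b, lk, counts);
    }
    return counts;
}
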