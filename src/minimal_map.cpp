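#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>

using namespace Rcpp;

// 2-bit encode; -1 for anything outside ACGT (upper case expected)
static inline int base2bit(char c) {
    switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1;
    }
}

static inline char complement(char c) {
    switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
    }
}

static std::string revcomp(const std::string& s) {
    std::string out(s.size(), 'N');
    for (size_t i = 0; i < s.size(); ++i)
        out[s.size() - 1 - i] = complement(s[i]);
    return out;
}

// encode k-mer starting at pos; returns false if it contains a non-ACGT base
static inline bool encode_kmer(const std::string& s, size_t pos, int k, uint64_t& code) {
    code = 0;
    for (int i = 0; i < k; ++i) {
        int b = base2bit(s[pos + i]);
        if (b < 0) return false;
        code = (code << 2) | (uint64_t)b;
    }
    return true;
}

typedef std::unordered_map<uint64_t, std::vector<int> > KmerIndex;

static KmerIndex build_index(const std::string& ref, int k) {
    KmerIndex idx;
    if ((int)ref.size() < k) return idx;
    for (size_t pos = 0; pos + k <= ref.size(); ++pos) {
        uint64_t code;
        if (encode_kmer(ref, pos, k, code))
            idx[code].push_back((int)pos);
    }
    return idx;
}

struct Candidate {
    int start;   // 0-based ref start of the full-read placement
    bool minus;
};

// Ungapped placement of `seq` (already oriented) at ref offset `start`,
// clipped to the reference. Returns aligned length (0 if < k) and match count.
static void score_placement(const std::string& seq, const std::string& ref,
                            int start, int k, int& aln_len, int& matches,
                            int& qs, int& qe) {
    int len = (int)seq.size();
    int s = start < 0 ? -start : 0;          // first aligned read offset
    int e = len;
    if (start + len > (int)ref.size()) e = (int)ref.size() - start;
    aln_len = e - s;
    matches = 0; qs = s; qe = e;
    if (aln_len < k) { aln_len = 0; return; }
    for (int i = s; i < e; ++i)
        if (seq[i] == ref[start + i]) ++matches;
}

// Map reads to a reference by exact k-mer seeding (both strands) and ungapped
// extension, reporting the unique best placement per read. Ties and reads with
// too many mismatches are reported unmapped. Coordinates returned 1-based
// inclusive; read coordinates refer to the read's stored orientation.
// [[Rcpp::export(name = ".minimal_map_cpp")]]
DataFrame minimal_map_cpp(CharacterVector reads, std::string reference,
                          int k, double max_mismatch_frac) {
    int n = reads.size();
    KmerIndex idx = build_index(reference, k);

    IntegerVector read_start(n, NA_INTEGER), read_end(n, NA_INTEGER);
    IntegerVector ref_start(n, NA_INTEGER), ref_end(n, NA_INTEGER);
    CharacterVector strand(n, NA_STRING);
    NumericVector identity(n, NA_REAL);
    LogicalVector mapped(n, false);

    for (int r = 0; r < n; ++r) {
        std::string fwd = as<std::string>(reads[r]);
        int len = (int)fwd.size();
        if (len < k) continue;
        std::string rev = revcomp(fwd);

        // seed offsets: start, middle, end of the read
        std::vector<int> offs;
        offs.push_back(0);
        offs.push_back((len - k) / 2);
        offs.push_back(len - k);

        std::vector<Candidate> cands;
        for (int pass = 0; pass < 2; ++pass) {
            const std::string& seq = pass == 0 ? fwd : rev;
            for (size_t oi = 0; oi < offs.size(); ++oi) {
                int off = offs[oi];
                if (oi > 0 && off == offs[oi - 1]) continue;
                uint64_t code;
                if (!encode_kmer(seq, off, k, code)) continue;
                KmerIndex::const_iterator it = idx.find(code);
                if (it == idx.end()) continue;
                const std::vector<int>& hits = it->second;
                for (size_t h = 0; h < hits.size(); ++h) {
                    Candidate c;
                    c.start = hits[h] - off;
                    c.minus = (pass == 1);
                    bool seen = false;
                    for (size_t j = 0; j < cands.size(); ++j)
                        if (cands[j].start == c.start && cands[j].minus == c.minus) {
                            seen = true; break;
                        }
                    if (!seen) cands.push_back(c);
                }
            }
        }
        if (cands.empty()) continue;

        int best_matches = -1, best_i = -1;
        bool tie = false;
        int best_len = 0, best_qs = 0, best_qe = 0;
        for (size_t ci = 0; ci < cands.size(); ++ci) {
            const std::string& seq = cands[ci].minus ? rev : fwd;
            int aln_len, matches, qs, qe;
            score_placement(seq, reference, cands[ci].start, k,
                            aln_len, matches, qs, qe);
            if (aln_len < k) continue;
            double ident = (double)matches / aln_len;
            if (1.0 - ident > max_mismatch_frac) continue;
            if (matches > best_matches) {
                best_matches = matches; best_i = (int)ci; tie = false;
                best_len = aln_len; best_qs = qs; best_qe = qe;
            } else if (matches == best_matches) {
                tie = true;
            }
        }
        if (best_i < 0 || tie) continue;

        const Candidate& b = cands[best_i];
        mapped[r] = true;
        strand[r] = b.minus ? "-" : "+";
        identity[r] = (double)best_matches / best_len;
        ref_start[r] = b.start + best_qs + 1;           // 1-based
        ref_end[r] = b.start + best_qe;                 // inclusive
        if (!b.minus) {
            read_start[r] = best_qs + 1;
            read_end[r] = best_qe;
        } else {
            read_start[r] = len - best_qe + 1;          // stored orientation
            read_end[r] = len - best_qs;
        }
    }

    return DataFrame::create(
        _["read_start"] = read_start, _["read_end"] = read_end,
        _["ref_start"] = ref_start, _["ref_end"] = ref_end,
        _["strand"] = strand, _["identity"] = identity,
        _["mapped"] = mapped, _["stringsAsFactors"] = false);
}
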