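#include <Rcpp.h>
#include <algorithm>
#include <string>
#include <vector>

using namespace Rcpp;

// Unit-cost Levenshtein distance between a and b.
// If cutoff >= 0 the DP row is abandoned as soon as its minimum exceeds
// cutoff and (cutoff + 1) is returned: callers only need to know the true
// distance when it is <= cutoff.
static int lev_one(const std::string& a, const std::string& b, int cutoff) {
    const int n = (int)a.size();
    const int m = (int)b.size();
    if (cutoff >= 0 && std::abs(n - m) > cutoff) return cutoff + 1;
    if (n == 0) return m;
    if (m == 0) return n;

    std::vector<int> prev(m + 1), cur(m + 1);
    for (int j = 0; j <= m; ++j) prev[j] = j;
    for (int i = 1; i <= n; ++i) {
        cur[0] = i;
        int row_min = cur[0];
        for (int j = 1; j <= m; ++j) {
            int sub = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1);
            int del = prev[j] + 1;
            int ins = cur[j - 1] + 1;
            cur[j] = std::min(sub, std::min(del, ins));
            if (cur[j] < row_min) row_min = cur[j];
        }
        if (cutoff >= 0 && row_min > cutoff) return cutoff + 1;
        std::swap(prev, cur);
    }
    int d = prev[m];
    if (cutoff >= 0 && d > cutoff) return cutoff + 1;
    return d;
}

// [[Rcpp::export(name = ".levenshtein_cpp")]]
IntegerVector levenshtein_cpp(CharacterVector a, CharacterVector b,
                              int cutoff = -1) {
    R_xlen_t n = std::max(a.size(), b.size());
    if (a.size() != b.size() && a.size() != 1 && b.size() != 1)
        stop("'a' and 'b' must have equal length or length 1");
    IntegerVector out(n);
    for (R_xlen_t i = 0; i < n; ++i) {
        std::string sa = as<std::string>(a[a.size() == 1 ? 0 : i]);
        std::string sb = as<std::string>(b[b.size() == 1 ? 0 : i]);
        out[i] = lev_one(sa, sb, cutoff);
    }
    return out;
}

// Sequential seed-linkage clustering: sequences are visited in the order
// given; each joins the earliest-founded family whose seed is within
// 'radius', else founds a new family.  Returns 1-based family ids.
// linkage_any = true compares against every member instead of the seed.
// [[Rcpp::export(name = ".assign_families_cpp")]]
IntegerVector assign_families_cpp(CharacterVector seqs, int radius,
                                  bool linkage_any = false) {
    R_xlen_t n = seqs.size();
    IntegerVector fam(n);
    std::vector<std::string> s(n);
    for (R_xlen_t i = 0; i < n; ++i) s[i] = as<std::string>(seqs[i]);
    std::vector<std::vector<int> > members;  // indices per family
    for (R_xlen_t i = 0; i < n; ++i) {
        int assigned = 0;
        for (size_t f = 0; f < members.size() && !assigned; ++f) {
            if (!linkage_any) {
                if (lev_one(s[i], s[members[f][0]], radius) <= radius)
                    assigned = (int)f + 1;
            } else {
                for (size_t k = 0; k < members[f].size(); ++k) {
                    if (lev_one(s[i], s[members[f][k]], radius) <= radius) {
                        assigned = (int)f + 1;
                        break;
                    }
                }
            }
        }
        if (!assigned) {
            members.push_back(std::vector<int>(1, (int)i));
            assigned = (int)members.size();
        } else {
            members[assigned - 1].push_back((int)i);
        }
        fam[i] = assigned;
    }
    return fam;
}

// Number of substitutions between a fixed flank and the prefix (from_end =
// false) or suffix (from_end = true) of each read.  NA when the read is
// shorter than the flank.
// [[Rcpp::export(name = ".flank_mismatch_cpp")]]
IntegerVector flank_mismatch_cpp(CharacterVector reads, std::string flank,
                                 bool from_end = false) {
    R_xlen_t n = reads.size();
    const int fl = (int)flank.size();
    IntegerVector out(n);
    for (R_xlen_t i = 0; i < n; ++i) {
        std::string r = as<std::string>(reads[i]);
        if ((int)r.size() < fl) {
            out[i] = NA_INTEGER;
            continue;
        }
        int off = from_end ? (int)r.size() - fl : 0;
        int mm = 0;
        for (int j = 0; j < fl; ++j)
            if (r[off + j] != flank[j]) ++mm;
        out[i] = mm;
    }
    return out;
}
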