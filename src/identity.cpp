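#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <string>
#include <unordered_set>
#include <vector>

using namespace Rcpp;

// Full-coverage identity between a shorter sequence S and a longer sequence L.
//
// Alignment model: S is aligned end-to-end; end gaps on L are free.  Scoring
// for the DP is match = +1, mismatch = 0, internal gap column = -1 (either a
// residue of S against a gap, or a residue of L skipped between aligned
// residues of S).  identity = max(score, 0) / length(S).
//
// Consequences used throughout the package:
//   * identity == 1.0  <=>  S is an exact substring of L,
//   * gap columns reduce identity like mismatches do (and slightly more,
//     so ungapped alignments are preferred when equivalent).
static double identity_dp(const std::string& s, const std::string& l) {
    const int n = static_cast<int>(s.size());
    const int m = static_cast<int>(l.size());
    // dp[j] = best score aligning s[0..i) with a suffix-free prefix of l[0..j)
    std::vector<int> prev(m + 1), cur(m + 1);
    for (int j = 0; j <= m; ++j) prev[j] = 0;  // free leading end gap on L
    for (int i = 1; i <= n; ++i) {
        cur[0] = -i;  // S residues before L starts: gap columns, not free
        for (int j = 1; j <= m; ++j) {
            int best = prev[j - 1] + (s[i - 1] == l[j - 1] ? 1 : 0);
            int up = prev[j] - 1;    // s[i-1] against a gap
            int left = cur[j - 1] - 1;  // l[j-1] skipped internally
            if (up > best) best = up;
            if (left > best) best = left;
            cur[j] = best;
        }
        std::swap(prev, cur);
    }
    int best = prev[m];
    for (int j = 0; j <= m; ++j)  // free trailing end gap on L
        if (prev[j] > best) best = prev[j];
    if (best < 0) best = 0;
    return static_cast<double>(best) / static_cast<double>(n);
}

// [[Rcpp::export(name = ".identity_cpp")]]
double identity_cpp(std::string a, std::string b) {
    if (a.empty() || b.empty())
        stop("sequences must be non-empty");
    const std::string& s = (a.size() <= b.size()) ? a : b;
    const std::string& l = (a.size() <= b.size()) ? b : a;
    if (l.find(s) != std::string::npos) return 1.0;  // containment fast path
    return identity_dp(s, l);
}

// Exact threshold decision via banded DP.  An alignment scoring
// >= need = ceil(t*n) has at most g = n - need gap columns, so its path
// satisfies j - i in [-g, (m-n) + 2g] (the free start offset j0 is at most
// m - n + g, and the in-path drift is bounded by the gap count).  Maximising
// over that band is therefore exact for the decision "identity >= t":
// a banded score below `need` proves the full DP is below it too.
static bool identity_at_least(const std::string& s, const std::string& l,
                              double t) {
    const int n = static_cast<int>(s.size());
    const int m = static_cast<int>(l.size());
    const int need = static_cast<int>(std::ceil(t * n - 1e-9));
    if (need <= 0) return true;
    const int g = n - need + 1;  // +1 margin
    const int lo = -g, hi = (m - n) + 2 * g;
    const int W = hi - lo + 1;
    if (W >= m + 1) return identity_dp(s, l) >= t - 1e-12;
    const int NEG = -(1 << 28);
    std::vector<int> prev(W + 2, NEG), cur(W + 2, NEG);
    // row 0: free leading end gap on L at any offset d >= 0
    for (int k = 0; k < W; ++k) {
        int d = lo + k;
        prev[k + 1] = (d >= 0 && d <= m) ? 0 : NEG;
    }
    for (int i = 1; i <= n; ++i) {
        for (int k = 0; k < W; ++k) {
            int d = lo + k;
            int j = i + d;
            if (j < 0 || j > m) { cur[k + 1] = NEG; continue; }
            if (j == 0) { cur[k + 1] = -i; continue; }
            int best = NEG;
            int diag = prev[k + 1];  // (i-1, j-1): same d
            if (diag > NEG)
                best = diag + (s[i - 1] == l[j - 1] ? 1 : 0);
            int up = prev[k + 2];    // (i-1, j): d+1
            if (up > NEG && up - 1 > best) best = up - 1;
            int left = cur[k];       // (i, j-1): d-1
            if (left > NEG && left - 1 > best) best = left - 1;
            cur[k + 1] = best;
        }
        std::swap(prev, cur);
    }
    int best = NEG;  // free trailing end gap on L: max over final column
    for (int k = 0; k < W; ++k)
        if (prev[k + 1] > best) best = prev[k + 1];
    return best >= need;
}

// [[Rcpp::export(name = ".identity_at_least_cpp")]]
bool identity_at_least_cpp(std::string a, std::string b, double threshold) {
    const std::string& s = (a.size() <= b.size()) ? a : b;
    const std::string& l = (a.size() <= b.size()) ? b : a;
    if (l.find(s) != std::string::npos) return true;
    return identity_at_least(s, l, threshold);
}

static const int KMER = 8;

static void kmer_set(const std::string& x, std::unordered_set<uint64_t>& out) {
    const int n = static_cast<int>(x.size());
    if (n < KMER) return;
    for (int i = 0; i + KMER <= n; ++i) {
        uint64_t h = 0;
        for (int j = 0; j < KMER; ++j)
            h = (h << 8) | static_cast<unsigned char>(x[i + j]);
        out.insert(h);
    }
}

// Safe shared-word screen.  If identity(S, L) >= t under the scoring above,
// then matches >= t|S| and (mismatch + gap) columns <= (1-t)|S|, so the
// match columns of S form runs whose k-mers all occur verbatim in L:
//   #(k-mer positions of S found in L) >= t|S| - ((1-t)|S| + 1)(k-1).
// Returning false therefore never discards a pair the DP would accept.
static bool kmer_screen_pass(const std::string& s,
                             const std::unordered_set<uint64_t>& rep_kmers,
                             double threshold) {
    const int n = static_cast<int>(s.size());
    if (n < KMER) return true;  // screen undefined, fall through to DP
    double bound =
        threshold * n - ((1.0 - threshold) * n + 1.0) * (KMER - 1);
    if (bound <= 0) return true;
    const int need = static_cast<int>(std::ceil(bound - 1e-9));
    int found = 0;
    int remaining = n - KMER + 1;
    uint64_t h = 0;
    for (int j = 0; j < KMER; ++j)
        h = (h << 8) | static_cast<unsigned char>(s[j]);
    for (int i = 0;; ++i) {
        if (rep_kmers.count(h)) ++found;
        if (found >= need) return true;
        --remaining;
        if (found + remaining < need) return false;
        if (i + KMER >= n) break;
        h = ((h << 8) | static_cast<unsigned char>(s[i + KMER])) &
            0xFFFFFFFFFFFFFFFFULL;
        // keep only KMER bytes
        h &= (KMER >= 8) ? 0xFFFFFFFFFFFFFFFFULL
                         : ((1ULL << (8 * KMER)) - 1);
    }
    return found >= need;
}

// Greedy incremental clustering.  `seqs` must already be sorted by length
// descending, ties by sequence then by record id (done in R).  Each sequence
// joins the first cluster, in creation order, whose representative it meets
// at >= threshold with full coverage of the shorter sequence; otherwise it
// founds a new cluster.  Returns 1-based cluster ids in creation order.
// [[Rcpp::export(name = ".greedy_cluster_cpp")]]
IntegerVector greedy_cluster_cpp(CharacterVector seqs, double threshold) {
    const int n = seqs.size();
    IntegerVector assign(n);
    std::vector<std::string> reps;
    std::vector<std::unordered_set<uint64_t> > rep_kmers;
    const bool exact = (threshold == 1.0);
    std::string prev_seq;
    int prev_cluster = -1;

    for (int i = 0; i < n; ++i) {
        std::string s = as<std::string>(seqs[i]);
        if (s.empty()) stop("empty sequence at position %d", i + 1);
        if (prev_cluster >= 0 && s == prev_seq) {
            assign[i] = prev_cluster + 1;  // identical to previous record
            continue;
        }
        int hit = -1;
        const int nrep = static_cast<int>(reps.size());
        for (int r = 0; r < nrep; ++r) {
            if (exact) {
                if (reps[r].find(s) != std::string::npos) { hit = r; break; }
            } else {
                if (!kmer_screen_pass(s, rep_kmers[r], threshold)) continue;
                if (reps[r].find(s) != std::string::npos ||
                    identity_at_least(s, reps[r], threshold)) {
                    hit = r; break;
                }
            }
        }
        if (hit < 0) {
            reps.push_back(s);
            rep_kmers.push_back(std::unordered_set<uint64_t>());
            if (!exact) kmer_set(s, rep_kmers.back());
            hit = nrep;
        }
        assign[i] = hit + 1;
        prev_seq = s;
        prev_cluster = hit;
        if (i % 256 == 0) Rcpp::checkUserInterrupt();
    }
    return assign;
}
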