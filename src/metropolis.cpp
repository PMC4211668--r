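#include <Rcpp.h>
using namespace Rcpp;

// Unordered type-pair index for K types, upper-triangular row-major:
// (0,0)=0, (0,1)=1, ..., (0,K-1), (1,1), ...
static inline int pairIdx(int a, int b, int K) {
    if (a > b) std::swap(a, b);
    return a * K - a * (a + 1) / 2 + b;
}

// Count contacts per unordered type pair on a CSR adjacency.
// adj: 0-based concatenated neighbor lists; off: length N+1 offsets;
// types: 0-based type codes.
// [[Rcpp::export(name = ".pair_contact_counts")]]
IntegerVector pair_contact_counts(IntegerVector adj, IntegerVector off,
                                  IntegerVector types, int K) {
    const int N = off.size() - 1;
    const int P = K * (K + 1) / 2;
    IntegerVector cnt(P);
    for (int i = 0; i < N; ++i) {
        for (int e = off[i]; e < off[i + 1]; ++e) {
            int j = adj[e];
            if (j > i) cnt[pairIdx(types[i], types[j], K)]++;
        }
    }
    return cnt;
}

// Energy change E_after - E_before for swapping the types of cells a and b.
// The a-b bond itself (if present) is unchanged because J is symmetric.
static inline double deltaE(const int* adj, const int* off, const int* t,
                            const double* J, int K, int a, int b) {
    const int ta = t[a], tb = t[b];
    double gain = 0.0;
    for (int e = off[a]; e < off[a + 1]; ++e) {
        int n = adj[e];
        if (n == b) continue;
        gain += J[tb * K + t[n]] - J[ta * K + t[n]];
    }
    for (int e = off[b]; e < off[b + 1]; ++e) {
        int n = adj[e];
        if (n == a) continue;
        gain += J[ta * K + t[n]] - J[tb * K + t[n]];
    }
    // E = -sum(J) over contacts, so a gain in summed attraction lowers E.
    return -gain;
}

// [[Rcpp::export(name = ".swap_delta_energy")]]
double swap_delta_energy(IntegerVector adj, IntegerVector off,
                         IntegerVector types, NumericMatrix J,
                         int a, int b) {
    const int K = J.nrow();
    return deltaE(adj.begin(), off.begin(), types.begin(), J.begin(), K,
                  a, b);
}

// Fast internal RNG for the hot loop (xoshiro256+, 53-bit doubles),
// seeded from R's RNG so set.seed() still controls reproducibility.
struct Xoshiro {
    uint64_t s[4];
    explicit Xoshiro(uint64_t seed) {
        // splitmix64 expansion of the seed into the state
        for (int i = 0; i < 4; ++i) {
            seed += 0x9e3779b97f4a7c15ULL;
            uint64_t z = seed;
            z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
            z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
            s[i] = z ^ (z >> 31);
        }
    }
    static inline uint64_t rotl(uint64_t x, int k) {
        return (x << k) | (x >> (64 - k));
    }
    inline uint64_t nextInt() {
        const uint64_t result = s[0] + s[3];
        const uint64_t t = s[1] << 17;
        s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
        s[2] ^= t; s[3] = rotl(s[3], 45);
        return result;
    }
    inline double nextUnif() {
        return (nextInt() >> 11) * 0x1.0p-53;
    }
};

// Metropolis type-swap Monte Carlo on a fixed contact graph.
//
// One sweep = N proposed swaps (N = number of cells). A proposal picks two
// distinct cells uniformly; same-type swaps are no-ops that are always
// accepted. Acceptance probability is min(1, exp(-dE/eF)). After nEquil
// equilibration sweeps the per-pair contact counts are recorded once per
// sweep for nRecord sweeps.
//
// The internal RNG is seeded from R's RNG, so results are reproducible
// via set.seed().
// [[Rcpp::export(name = ".mc_swap_engine")]]
List mc_swap_engine(IntegerVector adj, IntegerVector off, IntegerVector types,
                    NumericMatrix J, double eF, int nEquil, int nRecord,
                    bool recordTypes = false, bool recordCounts = false) {
    const int N = off.size() - 1;
    const int K = J.nrow();
    const int P = K * (K + 1) / 2;
    if (eF <= 0) stop("fluctuation energy eF must be > 0");
    if (nEquil < 0 || nRecord < 1) stop("invalid sweep counts");

    std::vector<int> t(types.begin(), types.end());
    const int* adjp = adj.begin();
    const int* offp = off.begin();
    const double* Jp = J.begin();

    // initial pair counts
    std::vector<long> cnt(P, 0);
    long nEdges = 0;
    for (int i = 0; i < N; ++i)
        for (int e = offp[i]; e < offp[i + 1]; ++e)
            if (adjp[e] > i) {
                cnt[pairIdx(t[i], t[adjp[e]], K)]++;
                nEdges++;
            }

    std::vector<double> sum(P, 0.0), sumsq(P, 0.0);
    IntegerMatrix typesTrace = recordTypes
        ? IntegerMatrix(nRecord, N) : IntegerMatrix(0, 0);
    IntegerMatrix countsTrace = recordCounts
        ? IntegerMatrix(nRecord, P) : IntegerMatrix(0, 0);

    Xoshiro rng((uint64_t)(unif_rand() * 4294967296.0) << 32 |
                (uint64_t)(unif_rand() * 4294967296.0));

    const int totSweeps = nEquil + nRecord;
    long nProp = 0, nAcc = 0;
    for (int s = 0; s < totSweeps; ++s) {
        for (int step = 0; step < N; ++step) {
            int a = (int)(rng.nextUnif() * N); if (a >= N) a = N - 1;
            int b = (int)(rng.nextUnif() * N); if (b >= N) b = N - 1;
            if (a == b) continue;
            nProp++;
            const int ta = t[a], tb = t[b];
            if (ta == tb) { nAcc++; continue; }  // dE = 0, always accepted
            double dE = deltaE(adjp, offp, t.data(), Jp, K, a, b);
            if (dE <= 0 || rng.nextUnif() < std::exp(-dE / eF)) {
                nAcc++;
                for (int e = offp[a]; e < offp[a + 1]; ++e) {
                    int n = adjp[e];
                    if (n == b) continue;
                    cnt[pairIdx(ta, t[n], K)]--;
                    cnt[pairIdx(tb, t[n], K)]++;
                }
                for (int e = offp[b]; e < offp[b + 1]; ++e) {
                    int n = adjp[e];
                    if (n == a) continue;
                    cnt[pairIdx(tb, t[n], K)]--;
                    cnt[pairIdx(ta, t[n], K)]++;
                }
                t[a] = tb; t[b] = ta;
            }
        }
        if (s >= nEquil) {
            int r = s - nEquil;
            for (int p = 0; p < P; ++p) {
                sum[p] += cnt[p];
                sumsq[p] += (double)cnt[p] * cnt[p];
                if (recordCounts) countsTrace(r, p) = (int)cnt[p];
            }
            if (recordTypes)
                for (int i = 0; i < N; ++i) typesTrace(r, i) = t[i];
        }
    }

    NumericVector mean(P), var(P);
    for (int p = 0; p < P; ++p) {
        mean[p] = sum[p] / nRecord;
        double ss = sumsq[p] - nRecord * mean[p] * mean[p];
        var[p] = nRecord > 1 ? std::max(0.0, ss / (nRecord - 1)) : 0.0;
    }

    List out = List::create(
        _["mean"] = mean, _["var"] = var,
        _["finalTypes"] = IntegerVector(t.begin(), t.end()),
        _["nEdges"] = (double)nEdges,
        _["nSamples"] = nRecord,
        _["acceptanceRate"] = nProp > 0 ? (double)nAcc / nProp : NA_REAL);
    if (recordTypes) out["typesTrace"] = typesTrace;
    if (recordCounts) out["countsTrace"] = countsTrace;
    return out;
}
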