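#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Fenwick (binary indexed) tree holding the per-function attachment
// weights k_i^gamma.  Supports O(log D) point update and O(log D)
// inverse-CDF sampling, which keeps the amortized per-arrival cost
// logarithmic in the number of functions.
class WeightTree {
public:
    int cap = 1;                  // power of two >= number of functions
    std::vector<double> tree;     // 1-based

    void build(const std::vector<double>& w) {
        cap = 1;
        while (cap < (int)w.size() || cap < 1) cap <<= 1;
        tree.assign(cap + 1, 0.0);
        for (int i = 0; i < (int)w.size(); ++i) add(i + 1, w[i]);
    }
    void add(int i, double delta) {
        for (; i <= cap; i += i & (-i)) tree[i] += delta;
    }
    // smallest index whose prefix sum reaches `target` (1-based)
    int sample(double target) const {
        int idx = 0;
        for (int bit = cap; bit != 0; bit >>= 1) {
            int next = idx + bit;
            if (next <= cap && tree[next] < target) {
                idx = next;
                target -= tree[next];
            }
        }
        return idx + 1;
    }
};

static inline double pow_checked(double k, double e) {
    double v = std::pow(k, e);
    if (!std::isfinite(v))
        stop("non-finite weight k^exponent for k = %g, exponent = %g", k, e);
    return v;
}

// Core growth loop: single-individual arrivals.  Each arrival either
// creates a new function with probability min(1, p0 / sum_i k_i^theta)
// or joins function i with probability k_i^gamma / sum_j k_j^gamma.
// Running sums are refreshed by full recomputation every
// `rebuild_every` arrivals (0 = never) to bound floating-point drift.
// Uses R's RNG stream; seed with set.seed() before calling.
// [[Rcpp::export]]
List rcpp_simulate_growth(IntegerVector counts0, double p0, double theta,
                          double gamma, int n_final,
                          IntegerVector checkpoints,
                          IntegerVector snapshot_sizes,
                          int rebuild_every = 10000) {
    std::vector<double> counts(counts0.begin(), counts0.end());
    long long N = 0;
    for (double k : counts) N += (long long)k;

    double sum_theta = 0.0, sum_gamma = 0.0;
    std::vector<double> w(counts.size());
    for (size_t i = 0; i < counts.size(); ++i) {
        sum_theta += pow_checked(counts[i], theta);
        w[i] = pow_checked(counts[i], gamma);
        sum_gamma += w[i];
    }
    WeightTree tree;
    tree.build(w);

    int ci = 0, si = 0;
    // skip any checkpoint/snapshot at or below the initial size
    while (ci < checkpoints.size() && checkpoints[ci] <= N) ++ci;
    while (si < snapshot_sizes.size() && snapshot_sizes[si] <= N) ++si;

    std::vector<double> cp_N;
    std::vector<int> cp_D;
    List snaps(snapshot_sizes.size());

    long long arrivals = 0;
    while (N < n_final) {
        double p = (p0 <= 0.0) ? 0.0 : p0 / sum_theta;
        if (p > 1.0) p = 1.0;
        if (unif_rand() < p) {
            counts.push_back(1.0);
            w.push_back(1.0);
            sum_theta += 1.0;
            sum_gamma += 1.0;
            if ((int)w.size() > tree.cap) tree.build(w);
            else tree.add((int)w.size(), 1.0);
        } else {
            double target = unif_rand() * sum_gamma;
            int idx = tree.sample(target);
            if (idx > (int)counts.size()) idx = (int)counts.size();
            double k = counts[idx - 1];
            double d_theta = pow_checked(k + 1.0, theta) - pow_checked(k, theta);
            double d_gamma = pow_checked(k + 1.0, gamma) - pow_checked(k, gamma);
            counts[idx - 1] = k + 1.0;
            sum_theta += d_theta;
            sum_gamma += d_gamma;
            w[idx - 1] += d_gamma;
            tree.add(idx, d_gamma);
        }
        ++N;
        ++arrivals;

        if (rebuild_every > 0 && arrivals % rebuild_every == 0) {
            sum_theta = 0.0;
            sum_gamma = 0.0;
            for (size_t i = 0; i < counts.size(); ++i) {
                sum_theta += pow_checked(counts[i], theta);
                w[i] = pow_checked(counts[i], gamma);
                sum_gamma += w[i];
            }
            tree.build(w);
        }

        while (ci < checkpoints.size() && N == checkpoints[ci]) {
            cp_N.push_back((double)N);
            cp_D.push_back((int)counts.size());
            ++ci;
        }
        while (si < snapshot_sizes.size() && N == snapshot_sizes[si]) {
            snaps[si] = IntegerVector(counts.begin(), counts.end());
            ++si;
        }
    }

    return List::create(
        _["checkpoint_N"] = NumericVector(cp_N.begin(), cp_N.end()),
        _["checkpoint_D"] = IntegerVector(cp_D.begin(), cp_D.end()),
        _["final_counts"] = IntegerVector(counts.begin(), counts.end()),
        _["snapshots"] = snaps,
        _["sum_theta_running"] = sum_theta,
        _["sum_gamma_running"] = sum_gamma);
}

// Repeated draws from the attachment kernel of a *fixed* state, using
// the same weight-tree sampler as the growth loop.  Returns 1-based
// function indices.
// [[Rcpp::export]]
IntegerVector rcpp_draw_attachments(IntegerVector counts, double gamma,
                                    int n_draws) {
    if (counts.size() == 0) stop("empty state");
    std::vector<double> w(counts.size());
    double total = 0.0;
    for (int i = 0; i < counts.size(); ++i) {
        w[i] = pow_checked((double)counts[i], gamma);
        total += w[i];
    }
    WeightTree tree;
    tree.build(w);
    IntegerVector out(n_draws);
    for (int d = 0; d < n_draws; ++d) {
        int idx = tree.sample(unif_rand() * total);
        if (idx > counts.size()) idx = counts.size();
        out[d] = idx;
    }
    return out;
}
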