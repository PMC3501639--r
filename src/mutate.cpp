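#include <Rcpp.h>
using namespace Rcpp;

// Evolve sequences down a genealogy under a reversible substitution model
// given by its spectral decomposition: P(t) = U diag(exp(lambda * t)) Uinv.
// Site s on a branch of b generations uses distance b * site_rate[s]
// (site_rate already folds the per-generation rate and the Gamma multiplier).
// Node indexing as produced by sim_genealogy_cpp: every parent index exceeds
// its children's, root is the last node.

// [[Rcpp::export]]
IntegerMatrix mutate_tree_cpp(IntegerVector parent,
                              NumericVector ntime,
                              int n_tips, int L,
                              NumericVector site_rate,
                              NumericMatrix U,
                              NumericMatrix Uinv,
                              NumericVector lambda,
                              NumericVector freqs)
{
    const int M = parent.size();
    IntegerMatrix seq(M, L);

    int root = M - 1;
    for (int i = 0; i < M; ++i) if (parent[i] == 0) { root = i; break; }

    for (int s = 0; s < L; ++s) {
        double u = unif_rand(), c = 0.0; int b = 3;
        for (int j = 0; j < 4; ++j) { c += freqs[j]; if (u <= c) { b = j; break; } }
        seq(root, s) = b + 1;
    }

    for (int i = M - 2; i >= 0; --i) {
        int p = parent[i] - 1;
        double bl = ntime[p] - ntime[i];
        for (int s = 0; s < L; ++s) {
            double d = bl * site_rate[s];
            double e0 = exp(lambda[0] * d), e1 = exp(lambda[1] * d),
                   e2 = exp(lambda[2] * d), e3 = exp(lambda[3] * d);
            int a = seq(p, s) - 1;
            double u = unif_rand(), c = 0.0; int b = 3;
            for (int j = 0; j < 4; ++j) {
                double pr = U(a, 0) * e0 * Uinv(0, j) + U(a, 1) * e1 * Uinv(1, j)
                          + U(a, 2) * e2 * Uinv(2, j) + U(a, 3) * e3 * Uinv(3, j);
                if (pr > 0) c += pr;
                if (u <= c) { b = j; break; }
            }
            seq(i, s) = b + 1;
        }
    }

    IntegerMatrix out(n_tips, L);
    for (int i = 0; i < n_tips; ++i)
        for (int s = 0; s < L; ++s) out(i, s) = seq(i, s);
    return out;
}
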