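#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Serial (heterochronous) structured coalescent, backward in time.
//
// Continuous-time approximation: within deme d holding k lineages of current
// female effective size N_d, any pair coalesces at rate 1/N_d per generation;
// each lineage in d relocates (backward) to deme e at rate mig(d,e).
// Ancient tips activate when the process reaches their sampling age.
// Scheduled demographic events interrupt the exponential clock.
//
// Event kinds: 1 = size set, 2 = move_lineages(source, sink, prop),
//              3 = migration matrix replacement, 4 = size multiply.
//
// Node numbering (1-based in the returned vectors): tips 1..n in input order,
// internal nodes n+1..2n-1 in coalescence order, so the root is node 2n-1 and
// every parent index exceeds its children's indices.

// [[Rcpp::export]]
List sim_genealogy_cpp(NumericVector deme_sizes0,
                       NumericMatrix mig0,
                       IntegerVector tip_deme,
                       NumericVector tip_age,
                       NumericVector ev_time,
                       IntegerVector ev_kind,
                       IntegerVector ev_i1,
                       IntegerVector ev_i2,
                       NumericVector ev_x,
                       List ev_mat,
                       double time_cap)
{
    const int nd = deme_sizes0.size();
    const int n = tip_deme.size();
    if (n < 2) stop("need at least 2 sampled lineages");
    const int M = 2 * n - 1;
    const double eps = 1e-9;

    std::vector<double> N(deme_sizes0.begin(), deme_sizes0.end());
    NumericMatrix mig = clone(mig0);

    IntegerVector parent(M, 0);
    NumericVector ntime(M);
    IntegerVector ndeme(M);

    std::vector<int> lin;       // active node ids, 1-based
    std::vector<int> lin_deme;  // 0-based deme of each active lineage
    lin.reserve(n); lin_deme.reserve(n);

    std::vector<int> tip_order(n);
    for (int i = 0; i < n; ++i) tip_order[i] = i;
    std::sort(tip_order.begin(), tip_order.end(),
              [&](int a, int b) { return tip_age[a] < tip_age[b]; });

    int next_tip = 0;
    int next_ev = 0;
    const int nev = ev_time.size();
    int next_node = n;          // 0-based index of next internal node
    double t = 0.0;

    for (int iter = 0; ; ++iter) {
        if (iter > 100000000) stop("runaway coalescent simulation");

        while (next_tip < n && tip_age[tip_order[next_tip]] <= t + eps) {
            int i = tip_order[next_tip];
            lin.push_back(i + 1);
            lin_deme.push_back(tip_deme[i] - 1);
            ntime[i] = tip_age[i];
            ndeme[i] = tip_deme[i];
            ++next_tip;
        }
        if ((int)lin.size() == 1 && next_tip >= n) break;

        // per-deme lineage counts and event rates
        std::vector<int> k(nd, 0);
        for (size_t j = 0; j < lin.size(); ++j) k[lin_deme[j]]++;
        std::vector<double> coal(nd, 0.0), migr(nd, 0.0), rowm(nd, 0.0);
        double R = 0.0;
        for (int d = 0; d < nd; ++d) {
            for (int e = 0; e < nd; ++e) if (e != d) rowm[d] += mig(d, e);
            if (k[d] >= 2) {
                if (N[d] <= 0)
                    stop("deme %d has non-positive size while holding lineages", d + 1);
                coal[d] = 0.5 * k[d] * (k[d] - 1.0) / N[d];
            }
            migr[d] = k[d] * rowm[d];
            R += coal[d] + migr[d];
        }

        double t_sched = time_cap;
        if (next_tip < n) t_sched = std::min(t_sched, (double)tip_age[tip_order[next_tip]]);
        if (next_ev < nev) t_sched = std::min(t_sched, (double)ev_time[next_ev]);

        double t_cand = (R > 0) ? t + R::exp_rand() / R : R_PosInf;

        if (t_cand >= t_sched) {
            t = t_sched;
            if (t >= time_cap)
                stop("genealogy incomplete at time cap (%g generations): "
                     "lineages cannot find a common ancestor; check migration "
                     "rates and merge events", time_cap);
            while (next_ev < nev && ev_time[next_ev] <= t + eps) {
                int kind = ev_kind[next_ev];
                if (kind == 1) {
                    N[ev_i1[next_ev] - 1] = ev_x[next_ev];
                } else if (kind == 4) {
                    N[ev_i1[next_ev] - 1] *= ev_x[next_ev];
                } else if (kind == 2) {
                    int src = ev_i1[next_ev] - 1, snk = ev_i2[next_ev] - 1;
                    double prop = ev_x[next_ev];
                    for (size_t j = 0; j < lin.size(); ++j)
                        if (lin_deme[j] == src && unif_rand() < prop)
                            lin_deme[j] = snk;
                } else if (kind == 3) {
                    NumericMatrix nm = ev_mat[next_ev];
                    mig = clone(nm);
                }
                ++next_ev;
            }
            continue;
        }

        t = t_cand;
        double u = unif_rand() * R;
        int chosen = -1; bool is_coal = false;
        for (int d = 0; d < nd; ++d) {
            if (u < coal[d]) { chosen = d; is_coal = true; break; }
            u -= coal[d];
            if (u < migr[d]) { chosen = d; is_coal = false; break; }
            u -= migr[d];
        }
        if (chosen < 0) { chosen = nd - 1; is_coal = (coal[nd - 1] > 0); }

        // indices of active lineages in the chosen deme
        std::vector<int> idx;
        for (size_t j = 0; j < lin.size(); ++j)
            if (lin_deme[j] == chosen) idx.push_back((int)j);

        if (is_coal) {
            int a = (int)(unif_rand() * idx.size()); if (a >= (int)idx.size()) a = idx.size() - 1;
            int b = (int)(unif_rand() * (idx.size() - 1)); if (b >= (int)idx.size() - 1) b = idx.size() - 2;
            if (b >= a) ++b;
            int ja = idx[a], jb = idx[b];
            int id = next_node + 1;          // 1-based id of new internal node
            parent[lin[ja] - 1] = id;
            parent[lin[jb] - 1] = id;
            ntime[next_node] = t;
            ndeme[next_node] = chosen + 1;
            // replace ja with new node, drop jb
            lin[ja] = id; lin_deme[ja] = chosen;
            lin.erase(lin.begin() + jb);
            lin_deme.erase(lin_deme.begin() + jb);
            ++next_node;
        } else {
            int a = (int)(unif_rand() * idx.size()); if (a >= (int)idx.size()) a = idx.size() - 1;
            double u2 = unif_rand() * rowm[chosen];
            int dest = -1;
            for (int e = 0; e < nd; ++e) {
                if (e == chosen) continue;
                if (u2 < mig(chosen, e)) { dest = e; break; }
                u2 -= mig(chosen, e);
            }
            if (dest < 0) for (int e = nd - 1; e >= 0; --e) if (e != chosen) { dest = e; break; }
            lin_deme[idx[a]] = dest;
        }
    }

    return List::create(_["parent"] = parent,
                        _["time"]   = ntime,
                        _["deme"]   = ndeme,
                        _["n_tips"] = n);
}
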