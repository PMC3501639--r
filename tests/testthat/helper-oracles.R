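# Independent oracles and fixture builders used across the test suite.
# Everything here deliberately uses naive enumeration (explicit loops over
# individuals, pairs, spanning trees, windows) so that it shares no code
# with the package's optimised implementations.

random_seq_set <- function(set_id, n, L, n_states = 4L) {
  bases <- c("A", "C", "G", "T")[seq_len(n_states)]
  seqs <- vapply(seq_len(n), function(i)
    paste(sample(bases, L, replace = TRUE), collapse = ""), character(1L))
  names(seqs) <- paste0(set_id, "_", seq_len(n))
  aligned_sample_set(set_id, seqs)
}

# Two-level AMOVA decomposition from an individual-level squared-distance
# matrix, by explicit summation over pairs.
brute_amova2 <- function(d2, pop) {
  N <- nrow(d2)
  pops <- unique(pop)
  P <- length(pops)
  ssd_t <- 0
  for (i in seq_len(N - 1)) for (j in (i + 1):N) ssd_t <- ssd_t + d2[i, j]
  ssd_t <- ssd_t / N
  ssd_wp <- 0
  n_p <- numeric(P)
  for (k in seq_len(P)) {
    idx <- which(pop == pops[k])
    n_p[k] <- length(idx)
    s <- 0
    for (a in seq_along(idx)) for (b in seq_along(idx))
      if (a < b) s <- s + d2[idx[a], idx[b]]
    ssd_wp <- ssd_wp + s / n_p[k]
  }
  ssd_ap <- ssd_t - ssd_wp
  sig_c <- ssd_wp / (N - P)
  n1 <- (N - sum(n_p^2) / N) / (P - 1)
  sig_a <- (ssd_ap / (P - 1) - sig_c) / n1
  tot <- sig_a + sig_c
  list(ssd = c(ap = ssd_ap, wp = ssd_wp, total = ssd_t),
       sigma = c(a = sig_a, c = sig_c),
       phi_st = if (abs(tot) < 1e-300) 0 else sig_a / tot)
}

# Three-level AMOVA (groups of populations) by explicit summation.
brute_amova3 <- function(d2, pop, grp_of_pop) {
  N <- nrow(d2)
  pops <- unique(pop)
  P <- length(pops)
  grp <- grp_of_pop[pops]
  groups <- unique(grp)
  G <- length(groups)
  pair_sum <- function(idx) {
    s <- 0
    for (a in seq_along(idx)) for (b in seq_along(idx))
      if (a < b) s <- s + d2[idx[a], idx[b]]
    s
  }
  ssd_t <- pair_sum(seq_len(N)) / N
  n_p <- vapply(pops, function(p) sum(pop == p), numeric(1))
  names(n_p) <- pops
  ssd_wp <- sum(vapply(pops, function(p)
    pair_sum(which(pop == p)) / sum(pop == p), numeric(1)))
  n_g <- vapply(groups, function(g) sum(pop %in% pops[grp == g]), numeric(1))
  names(n_g) <- groups
  ssd_wg <- sum(vapply(groups, function(g)
    pair_sum(which(pop %in% pops[grp == g])) / n_g[g], numeric(1)))
  ssd_ag <- ssd_t - ssd_wg
  ssd_ap <- ssd_wg - ssd_wp
  sig_c <- ssd_wp / (N - P)
  sum_np2_by_g <- vapply(groups, function(g)
    sum(n_p[pops[grp == g]]^2) / n_g[g], numeric(1))
  n1 <- (N - sum(sum_np2_by_g)) / (P - G)
  sig_b <- (ssd_ap / (P - G) - sig_c) / n1
  n2 <- (sum(sum_np2_by_g) - sum(n_p^2) / N) / (G - 1)
  n3 <- (N - sum(n_g^2) / N) / (G - 1)
  sig_a <- (ssd_ag / (G - 1) - sig_c - n2 * sig_b) / n3
  list(ssd = c(ag = ssd_ag, ap = ssd_ap, wp = ssd_wp),
       sigma = c(a = sig_a, b = sig_b, c = sig_c))
}

# All spanning trees of a complete graph on n nodes by brute enumeration of
# (n-1)-subsets of edges; returns minimal weight and the set of edges
# occurring in at least one / in all minimum spanning trees.
brute_mst_union <- function(D) {
  n <- nrow(D)
  edges <- which(upper.tri(D), arr.ind = TRUE)
  ne <- nrow(edges)
  combos <- combn(ne, n - 1)
  spans <- function(sel) {
    comp <- seq_len(n)
    for (k in sel) {
      i <- edges[k, 1]; j <- edges[k, 2]
      ci <- comp[i]; cj <- comp[j]
      if (ci != cj) comp[comp == cj] <- ci
    }
    length(unique(comp)) == 1
  }
  weights <- apply(combos, 2, function(sel) sum(D[edges[sel, , drop = FALSE]]))
  ok <- apply(combos, 2, spans)
  wmin <- min(weights[ok])
  msts <- combos[, ok & abs(weights - wmin) < 1e-9, drop = FALSE]
  in_some <- sort(unique(as.vector(msts)))
  in_all <- in_some[vapply(in_some, function(e)
    all(apply(msts, 2, function(col) e %in% col)), logical(1))]
  key <- function(k) paste(edges[k, 1], edges[k, 2], sep = "-")
  list(weight = wmin,
       in_some = vapply(in_some, key, character(1)),
       in_all = vapply(in_all, key, character(1)))
}

# Exhaustive shortest-window HPD search.
brute_hpd <- function(x, mass = 0.95) {
  x <- sort(x)
  n <- length(x)
  m <- ceiling(mass * n)
  if (m >= n) return(c(x[1], x[n]))
  best <- c(x[1], x[m]); bw <- x[m] - x[1]
  for (i in 2:(n - m + 1)) {
    w <- x[i + m - 1] - x[i]
    if (w < bw - 1e-15) { bw <- w; best <- c(x[i], x[i + m - 1]) }
  }
  best
}

# Single-deme, modern-tips scenario used in many calibration tests:
# per-site theta = 2 N mu.
single_deme_scenario <- function(n, N, theta_site = 0.01, L = 370L,
                                 generation_time = 52) {
  mu_site <- theta_site / (2 * N)
  demographic_scenario(
    demes = data.frame(id = "A", size = N),
    sampling = data.frame(set_id = "A", deme = "A", n = n, age_gen = 0),
    mutation = hky_model(kappa = 1, base_freqs = rep(0.25, 4),
                         gamma_shape = NULL,
                         rate_per_site_per_my = mu_site * 1e6 / generation_time),
    generation_time = generation_time, length = L)
}

# Two-deme island scenario with whaling-style bottleneck priors; the
# workhorse for rejection/monotonicity tests. Deme size defaults to the
# study-like female effective size (census ~12,000 / 6), which yields
# realistic per-site diversity under the 2-6.3%/my rate prior; sample
# sizes are reduced to desk scale. The ancestral merge is deep relative to
# 2N so that contemporary differentiation is governed by the migration
# rate rather than by residual shared ancestry.
two_deme_scenario <- function(m, N = 2000, n = 30L, L = 370L,
                              bottlenecks = TRUE, merge_gen = 20000) {
  ids <- c("CG", "BCB")
  pri <- if (bottlenecks)
    list(bottlenecks = list(
      list(deme = "CG", residual = c(0.01, 0.29), time = 460 / 52),
      list(deme = "BCB", residual = c(0.05, 0.20), time = 460 / 52)))
  else NULL
  demographic_scenario(
    demes = data.frame(id = ids, size = c(N, N)),
    sampling = data.frame(set_id = ids, deme = ids, n = c(n, n),
                          age_gen = c(0, 0)),
    migration = matrix(c(0, m, m, 0), 2, 2, dimnames = list(ids, ids)),
    events = list(
      list(time = merge_gen, kind = "migration_update",
           matrix = matrix(0, 2, 2, dimnames = list(ids, ids))),
      list(time = merge_gen, kind = "move_lineages", source = "BCB",
           sink = "CG", proportion = 1)),
    mutation = hky_model(rate_per_site_per_my = c(0.02, 0.063)),
    priors = pri, length = L)
}

# Low-divergence sequence sets: mutations scattered on one shared ancestral
# sequence (common to all sets), so Jukes-Cantor distances stay far from
# saturation both within and between sets.
diverged_seq_sets <- function(ids, ns, L, subs = 3L) {
  bases <- c("A", "C", "G", "T")
  anc <- sample(bases, L, replace = TRUE)
  mapply(function(set_id, n) {
    m <- matrix(rep(anc, each = n), nrow = n)
    for (i in seq_len(n)) {
      k <- sample(0:subs, 1)
      if (k > 0) {
        pos <- sample.int(L, k)
        m[i, pos] <- vapply(m[i, pos], function(b)
          sample(setdiff(bases, b), 1), character(1))
      }
    }
    rownames(m) <- paste0(set_id, "_", seq_len(n))
    aligned_sample_set(set_id, m)
  }, ids, ns, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}
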