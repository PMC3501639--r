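# Per-population diversity statistics (Table-1 style summaries).

#' Number of segregating sites
#'
#' Counts retained alignment columns at which at least two different bases
#' are observed within the set (complete-deletion site mask by default).
#'
#' @param x An [aligned_sample_set()] or character matrix of aligned bases.
#' @param site_policy Site mask policy, see [collapse_haplotypes()].
#' @return Integer count `S`.
#' @export
segregating_sites <- function(x, site_policy = "complete") {
  m <- if (inherits(x, "aligned_sample_set")) x$seqs else x
  if (nrow(m) < 2L) stop("need at least 2 sequences")
  m <- m[, site_mask(m, site_policy), drop = FALSE]
  sum(apply(m, 2L, function(col) length(unique(col))) > 1L)
}

#' Haplotype diversity (Nei's unbiased estimator)
#'
#' `Hd = n (1 - sum p_i^2) / (n - 1)`: the probability that two sequences
#' drawn at random differ in haplotype, with small-sample correction.
#'
#' @param counts Integer vector of haplotype counts (or an
#'   [aligned_sample_set()], which is collapsed first).
#' @return Hd in `[0, 1]`; 0 iff monomorphic.
#' @examples
#' haplotype_diversity(c(2, 1, 1))  # 0.8333
#' @export
haplotype_diversity <- function(counts) {
  if (inherits(counts, "aligned_sample_set"))
    counts <- as.integer(collapse_haplotypes(counts)$counts[, 1L])
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n < 2L) stop("need at least 2 sequences")
  p <- counts / n
  n / (n - 1) * (1 - sum(p^2))
}

#' Nucleotide diversity
#'
#' Mean proportion of differing retained sites over all sequence pairs
#' (uncorrected p-distances). Multiply by the retained length for the
#' per-locus scale.
#'
#' @inheritParams segregating_sites
#' @param per_site If `TRUE` (default) return the per-site value.
#' @return Non-negative numeric `pi`.
#' @export
nucleotide_diversity <- function(x, site_policy = "complete", per_site = TRUE) {
  m <- if (inherits(x, "aligned_sample_set")) x$seqs else x
  if (nrow(m) < 2L) stop("need at least 2 sequences")
  m <- m[, site_mask(m, site_policy), drop = FALSE]
  L <- ncol(m)
  keys <- row_keys(m)
  haps <- unique(keys)
  idx <- match(keys, haps)
  cnt <- tabulate(idx, nbins = length(haps))
  hm <- do.call(rbind, strsplit(haps, "", fixed = TRUE))
  D <- hap_hamming(hm)
  n <- nrow(m)
  tot <- as.numeric(cnt %*% D %*% cnt) / 2   # sum over unordered pairs
  pi_locus <- tot / (n * (n - 1) / 2)
  if (per_site) pi_locus / L else pi_locus
}

#' Watterson's theta from segregating sites
#'
#' `theta(S) = S / a_{n-1}` with `a_{n-1} = sum_{i=1}^{n-1} 1/i`, on the
#' per-locus scale; divide by the retained length for per-site units.
#'
#' @param S Number of segregating sites.
#' @param n Number of sequences.
#' @param length Optional retained length; if given, the per-site value is
#'   returned.
#' @return Non-negative numeric theta.
#' @examples
#' watterson_theta(10, 5)  # 4.8
#' @export
watterson_theta <- function(S, n, length = NULL) {
  if (n < 2L) stop("need at least 2 sequences")
  a <- sum(1 / seq_len(n - 1L))
  th <- S / a
  if (!is.null(length)) th <- th / length
  th
}

#' Coalescent confidence interval for haplotype diversity
#'
#' Simulates the standard neutral single-deme coalescent conditioned on the
#' set's sample size and Watterson theta, and returns empirical 2.5/97.5
#' percentiles of haplotype diversity across replicates. This reconstructs
#' the usual coalescent-resampling interval for Hd; it is driven entirely by
#' (n, theta), not by resampling the observed sequences.
#'
#' @param set An [aligned_sample_set()].
#' @param reps Number of coalescent replicates (>= 1000).
#' @param seed Optional RNG seed for reproducibility.
#' @param mass Interval mass (default 0.95).
#' @return Numeric `c(lo, hi)`.
#' @export
hd_confidence_interval <- function(set, reps = 1000L, seed = NULL,
                                   mass = 0.95) {
  if (reps < 1000L) stop("reps must be >= 1000")
  n <- n_samples(set)
  mask <- site_mask(set$seqs)
  L <- length(mask)
  S <- segregating_sites(set)
  theta_locus <- watterson_theta(S, n)
  # scale-free neutral coalescent: fix N and set the per-site rate so that
  # 2 N mu L = theta_locus
  N <- 1000
  mu_site <- theta_locus / (2 * N * L)
  model <- hky_model(kappa = 1, base_freqs = rep(0.25, 4), gamma_shape = NULL)
  dec <- hky_eigen(model)
  hd <- with_seed(seed, {
    vapply(seq_len(reps), function(r) {
      g <- .sim_single_deme(n, N)
      tips <- mutate_tree_cpp(g$parent, g$time, n, L,
                              rep(mu_site, L), dec$U, dec$Uinv,
                              dec$lambda, dec$freqs)
      cnt <- tabulate(match(row_keys(tips), unique(row_keys(tips))))
      haplotype_diversity(cnt)
    }, numeric(1L))
  })
  lo <- (1 - mass) / 2
  unname(quantile(hd, c(lo, 1 - lo), type = 7))
}

#' Table-1 style diversity summary for several sample sets
#'
#' For each set: sample size `N`, segregating sites `S`, haplotype count
#' `H`, haplotype diversity `Hd`, private haplotypes `U` (relative to the
#' pooled collection), per-site nucleotide diversity `pi`, and per-locus
#' Watterson `theta_S`.
#'
#' @param sets List of [aligned_sample_set()] objects.
#' @param site_policy Site mask policy for the per-set statistics.
#' @return A data.frame with one row per set.
#' @export
diversity_summary <- function(sets, site_policy = "complete") {
  if (inherits(sets, "aligned_sample_set")) sets <- list(sets)
  pooled_tab <- collapse_haplotypes(sets, site_policy)
  multi <- length(sets) > 1L
  rows <- lapply(sets, function(s) {
    tab <- collapse_haplotypes(s, site_policy)
    cnt <- as.integer(tab$counts[, 1L])
    S <- segregating_sites(s, site_policy)
    data.frame(set = s$set_id,
               N = n_samples(s),
               S = S,
               H = length(tab$haplotypes),
               Hd = haplotype_diversity(cnt),
               U = if (multi) private_haplotypes(pooled_tab, s$set_id) else NA_integer_,
               pi = nucleotide_diversity(s, site_policy),
               theta_S = watterson_theta(S, n_samples(s)))
  })
  do.call(rbind, rows)
}

#' Singleton haplotypes in the pooled dataset
#'
#' A singleton is a haplotype observed exactly once across all sample sets
#' combined; the fraction of private haplotypes that are singletons is a
#' standard descriptive companion to `U`.
#'
#' @param table A [collapse_haplotypes()] result.
#' @return Logical vector flagging singleton haplotypes.
#' @export
is_singleton <- function(table) rowSums(table$counts) == 1L
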