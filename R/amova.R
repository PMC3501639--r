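# Analysis of molecular variance: hierarchical decomposition of squared
# inter-haplotype distances into among-group, among-population and
# within-population components, with Phi statistics, permutation tests and
# FDR correction.

# Core decomposition on haplotype counts. D2: H x H squared distances;
# C: H x P counts; grp: length-P group assignment (factor-like).
# All sums over individual pairs are evaluated through count weighting:
# sum_{i<j in A} d2_ij = 0.5 * c_A' D2 c_A for the count vector c_A.
.amova_core <- function(D2, C, grp = NULL) {
  P <- ncol(C)
  n_p <- colSums(C)
  if (any(n_p < 2))
    stop("population(s) with fewer than 2 samples (",
         paste(colnames(C)[n_p < 2], collapse = ", "),
         "); merge them with a neighbouring set before AMOVA")
  N <- sum(n_p)
  if (is.null(grp)) grp <- rep("all", P)
  grp <- factor(grp)
  G <- nlevels(grp)

  half_q <- function(cv) 0.5 * as.numeric(crossprod(cv, D2 %*% cv))
  ssd_wp <- sum(vapply(seq_len(P), function(p) half_q(C[, p]) / n_p[p],
                       numeric(1L)))
  ct <- rowSums(C)
  ssd_t <- half_q(ct) / N
  n_g <- tapply(n_p, grp, sum)
  ssd_wg <- sum(vapply(levels(grp), function(g) {
    cg <- rowSums(C[, grp == g, drop = FALSE])
    half_q(cg) / sum(n_p[grp == g])
  }, numeric(1L)))

  df_wp <- N - P
  sig_c <- ssd_wp / df_wp
  safe_ratio <- function(num, den) if (abs(den) < 1e-300) 0 else num / den

  if (G == 1L) {
    ssd_ap <- ssd_t - ssd_wp
    df_ap <- P - 1L
    ms_ap <- ssd_ap / df_ap
    n1 <- (N - sum(n_p^2) / N) / (P - 1)
    sig_a <- (ms_ap - sig_c) / n1
    tot <- sig_a + sig_c
    tab <- data.frame(
      source = c("Among populations", "Within populations", "Total"),
      df = c(df_ap, df_wp, N - 1L),
      SSD = c(ssd_ap, ssd_wp, ssd_t),
      MS = c(ms_ap, sig_c, NA))
    comp <- c(among_populations = sig_a, within_populations = sig_c)
    phi <- c(phi_st = safe_ratio(sig_a, tot))
  } else {
    ssd_ag <- ssd_t - ssd_wg
    ssd_ap <- ssd_wg - ssd_wp
    df_ag <- G - 1L
    df_ap <- P - G
    ms_ag <- ssd_ag / df_ag
    ms_ap <- ssd_ap / df_ap
    sum_np2_by_g <- tapply(n_p^2, grp, sum) / n_g
    n1 <- (N - sum(sum_np2_by_g)) / (P - G)
    sig_b <- (ms_ap - sig_c) / n1
    n2 <- (sum(sum_np2_by_g) - sum(n_p^2) / N) / (G - 1)
    n3 <- (N - sum(n_g^2) / N) / (G - 1)
    sig_a <- (ms_ag - sig_c - n2 * sig_b) / n3
    tot <- sig_a + sig_b + sig_c
    tab <- data.frame(
      source = c("Among groups", "Among populations within groups",
                 "Within populations", "Total"),
      df = c(df_ag, df_ap, df_wp, N - 1L),
      SSD = c(ssd_ag, ssd_ap, ssd_wp, ssd_t),
      MS = c(ms_ag, ms_ap, sig_c, NA))
    comp <- c(among_groups = sig_a, among_populations_within_groups = sig_b,
              within_populations = sig_c)
    phi <- c(phi_ct = safe_ratio(sig_a, tot),
             phi_sc = safe_ratio(sig_b, sig_b + sig_c),
             phi_st = safe_ratio(sig_a + sig_b, tot))
  }
  tot <- sum(comp)
  pct <- if (abs(tot) < 1e-300) rep(0, length(comp)) else 100 * comp / tot
  list(table = tab, components = comp, percent = pct, phi = phi)
}

#' Analysis of molecular variance (AMOVA)
#'
#' Decomposes squared molecular distances between sequences into hierarchical
#' variance components (optionally among groups of populations, among
#' populations, within populations), with Phi fixation indices as component
#' ratios. Distances follow the Arlequin convention: the squared distance
#' between two haplotypes is the model-corrected number of differing sites.
#'
#' @param sets List of [aligned_sample_set()] objects (each a population).
#' @param grouping Optional named character vector mapping `set_id` to a
#'   group label (e.g. `c(HBFB = "Atlantic", BCB = "Pacific")`); `NULL` for
#'   a two-level analysis.
#' @param distance `"jc"`, `"raw"` or `"haplotype"` (see
#'   [seq_distance_matrix()]).
#' @param site_policy `"complete"` or `"pairwise"` site deletion.
#' @return Object of class `amova_result`: `table` (df, SSD, MS),
#'   `components` (variance components), `percent` (percent of total),
#'   `phi` (Phi statistics).
#' @examples
#' a <- aligned_sample_set("A", c(a1 = "AAAA", a2 = "AAAT"))
#' b <- aligned_sample_set("B", c(b1 = "GGAA", b2 = "GGAT"))
#' amova(list(a, b))
#' @export
amova <- function(sets, grouping = NULL, distance = c("jc", "raw", "haplotype"),
                  site_policy = c("complete", "pairwise")) {
  distance <- match.arg(distance)
  site_policy <- match.arg(site_policy)
  if (length(sets) < 2L) stop("need at least 2 populations")
  hi <- hap_indices(sets, if (site_policy == "complete") "complete" else "none")
  hm <- do.call(rbind, strsplit(hi$table$haplotypes, "", fixed = TRUE))
  D2 <- hap_sq_dist(hm, distance, pairwise_deletion = site_policy == "pairwise")
  grp <- NULL
  if (!is.null(grouping)) {
    ids <- colnames(hi$table$counts)
    missing <- setdiff(ids, names(grouping))
    if (length(missing)) stop("no group for set(s): ",
                              paste(missing, collapse = ", "))
    grp <- grouping[ids]
  }
  res <- .amova_core(D2, hi$table$counts, grp)
  res$distance <- distance
  class(res) <- "amova_result"
  res
}

#' @export
print.amova_result <- function(x, digits = 4, ...) {
  cat("AMOVA (", x$distance, " distances)\n", sep = "")
  print(x$table, digits = digits, row.names = FALSE)
  cat("\nVariance components (% of total):\n")
  for (i in seq_along(x$components))
    cat(sprintf("  %-34s %10.6f  (%6.2f%%)\n", names(x$components)[i],
                x$components[i], x$percent[i]))
  cat("\nPhi statistics:\n")
  for (i in seq_along(x$phi))
    cat(sprintf("  %-8s %8.5f\n", names(x$phi)[i], x$phi[i]))
  invisible(x)
}

# Fast two-population Phi from haplotype counts; used by permutation tests
# and the scenario-rejection engine (identical decomposition to .amova_core,
# specialised for speed).
.phi_from_counts <- function(D2, c1, c2) {
  n1 <- sum(c1); n2 <- sum(c2); N <- n1 + n2
  Dc1 <- D2 %*% c1
  Dct <- Dc1 + D2 %*% c2
  sw <- 0.5 * (as.numeric(crossprod(c1, Dc1)) / n1 +
               as.numeric(crossprod(c2, Dct - Dc1)) / n2)
  st <- 0.5 * as.numeric(crossprod(c1 + c2, Dct)) / N
  ssd_ap <- st - sw
  sig_c <- sw / (N - 2)
  n_prime <- N - (n1^2 + n2^2) / N
  sig_a <- (ssd_ap - sig_c) / n_prime
  tot <- sig_a + sig_c
  if (abs(tot) < 1e-300) 0 else sig_a / tot
}

#' Pairwise Phi_ST between two sample sets
#'
#' Two-level AMOVA ratio `sigma2_a / (sigma2_a + sigma2_w)` using molecular
#' distances between haplotypes. Small negative values are reported as
#' computed, not clipped.
#'
#' @param set_a,set_b [aligned_sample_set()] objects.
#' @param distance Distance model (default Jukes-Cantor).
#' @param site_policy Site deletion policy.
#' @return Numeric Phi_ST in `[-1, 1]`.
#' @export
pairwise_phi_st <- function(set_a, set_b, distance = "jc",
                            site_policy = "complete") {
  res <- amova(list(set_a, set_b), distance = distance,
               site_policy = site_policy)
  unname(res$phi["phi_st"])
}

#' Frequency-based F_ST between two sample sets
#'
#' Same decomposition as [pairwise_phi_st()] with the inter-haplotype
#' distance set to 1 for distinct haplotypes and 0 otherwise, so only
#' haplotype frequencies matter.
#'
#' @inheritParams pairwise_phi_st
#' @return Numeric F_ST.
#' @export
frequency_f_st <- function(set_a, set_b, site_policy = "complete") {
  res <- amova(list(set_a, set_b), distance = "haplotype",
               site_policy = site_policy)
  unname(res$phi["phi_st"])
}

#' Permutation test for pairwise differentiation
#'
#' Permutes individual sequences among the two populations (sizes preserved,
#' the Arlequin convention for population-level Phi_ST) and reports
#' `p = (1 + #{perm >= obs}) / (n_perm + 1)`.
#'
#' @param set_a,set_b [aligned_sample_set()] objects.
#' @param statistic `"phi_st"` (default) or `"f_st"`.
#' @param n_perm Number of permutations (>= 100; the reference analysis used
#'   10,000).
#' @param seed Optional RNG seed.
#' @param distance Distance model for `"phi_st"`.
#' @param site_policy Site deletion policy.
#' @return List with `observed`, `p_value`, `n_perm`, `perm_stats`.
#' @export
permutation_test <- function(set_a, set_b, statistic = c("phi_st", "f_st"),
                             n_perm = 1000L, seed = NULL, distance = "jc",
                             site_policy = "complete") {
  statistic <- match.arg(statistic)
  if (n_perm < 100L) stop("n_perm must be >= 100")
  hi <- hap_indices(list(set_a, set_b),
                    if (site_policy == "complete") "complete" else "none")
  hm <- do.call(rbind, strsplit(hi$table$haplotypes, "", fixed = TRUE))
  model <- if (statistic == "f_st") "haplotype" else distance
  D2 <- hap_sq_dist(hm, model, pairwise_deletion = site_policy == "pairwise")
  H <- nrow(hm)
  idx <- hi$idx
  n1 <- hi$sizes[1L]; N <- length(idx)
  ct <- tabulate(idx, nbins = H)
  c1_obs <- tabulate(idx[hi$pop == 1L], nbins = H)
  obs <- .phi_from_counts(D2, c1_obs, ct - c1_obs)
  perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      sel <- sample.int(N, n1)
      c1 <- tabulate(idx[sel], nbins = H)
      .phi_from_counts(D2, c1, ct - c1)
    }, numeric(1L))
  })
  list(observed = obs,
       p_value = (1 + sum(perm >= obs)) / (n_perm + 1),
       n_perm = n_perm, perm_stats = perm, statistic = statistic)
}

#' Benjamini-Hochberg FDR significance flags
#'
#' Step-up false-discovery-rate control at level `q` (default 0.05).
#'
#' @param p_values Numeric vector of p-values.
#' @param q FDR level in (0, 1).
#' @return Logical vector: `TRUE` where the hypothesis is rejected at FDR `q`.
#' @examples
#' fdr_correct(c(0.01, 0.02, 0.04, 0.9))
#' @export
fdr_correct <- function(p_values, q = 0.05) {
  if (length(p_values) == 0L) stop("p_values is empty")
  if (q <= 0 || q >= 1) stop("q must be in (0, 1)")
  p.adjust(p_values, method = "BH") <= q
}

#' All pairwise Phi_ST / F_ST comparisons with permutation tests and FDR
#'
#' @param sets List of [aligned_sample_set()] objects.
#' @param n_perm Permutations per comparison.
#' @param q FDR level applied across the Phi_ST p-values.
#' @param seed Optional RNG seed (comparisons use deterministic substreams).
#' @param distance Distance model for Phi_ST.
#' @return Object of class `pairwise_differentiation`: data.frame with one
#'   row per unordered pair (`set_a`, `set_b`, `phi_st`, `f_st`, `p_value`,
#'   `n_permutations`, `fdr_significant`).
#' @export
pairwise_differentiation <- function(sets, n_perm = 1000L, q = 0.05,
                                     seed = NULL, distance = "jc") {
  stopifnot(length(sets) >= 2L)
  ids <- vapply(sets, `[[`, character(1L), "set_id")
  pairs <- combn(length(sets), 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    pt <- permutation_test(sets[[i]], sets[[j]], "phi_st", n_perm,
                           seed = if (is.null(seed)) NULL else substream_seed(seed, k),
                           distance = distance)
    data.frame(set_a = ids[i], set_b = ids[j],
               phi_st = pt$observed,
               f_st = frequency_f_st(sets[[i]], sets[[j]]),
               p_value = pt$p_value, n_permutations = n_perm)
  })
  out <- do.call(rbind, rows)
  out$fdr_significant <- fdr_correct(out$p_value, q)
  class(out) <- c("pairwise_differentiation", class(out))
  out
}

#' Matrix layout for pairwise differentiation results
#'
#' Returns a square matrix with pairwise Phi_ST values below the diagonal
#' and frequency-based F_ST values above it, the conventional reporting
#' layout for population pairwise distances.
#'
#' @param x A [pairwise_differentiation()] result.
#' @return Numeric matrix with population ids as dimnames and `NA` diagonal.
#' @export
phi_fst_matrix <- function(x) {
  ids <- unique(c(x$set_a, x$set_b))
  m <- matrix(NA_real_, length(ids), length(ids), dimnames = list(ids, ids))
  for (k in seq_len(nrow(x))) {
    i <- match(x$set_a[k], ids); j <- match(x$set_b[k], ids)
    lo <- max(i, j); hi <- min(i, j)
    m[lo, hi] <- x$phi_st[k]   # below diagonal
    m[hi, lo] <- x$f_st[k]     # above diagonal
  }
  m
}
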