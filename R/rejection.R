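# Scenario rejection: simulate per-scenario Phi_ST distributions, form 95%
# highest-posterior-density intervals, and reject scenarios whose intervals
# exclude the observed values. Includes the duplicate-sensitivity analysis.

#' Highest posterior density interval of an empirical sample
#'
#' The shortest contiguous window over the sorted sample containing
#' `ceiling(mass * n)` points; ties are broken toward the lower start
#' index. No density smoothing is involved.
#'
#' @param samples Numeric vector (>= 20 values).
#' @param mass Probability mass in (0, 1), default 0.95.
#' @return Numeric `c(lo, hi)`.
#' @examples
#' hpd_interval(1:100)  # c(1, 95)
#' @export
hpd_interval <- function(samples, mass = 0.95) {
  n <- length(samples)
  if (n < 20L) stop("need at least 20 samples for an HPD interval")
  if (mass <= 0 || mass >= 1) stop("mass must be in (0, 1)")
  x <- sort(samples)
  m <- ceiling(mass * n)
  if (m >= n) return(c(x[1L], x[n]))
  widths <- x[m:n] - x[1:(n - m + 1L)]
  i <- which.min(widths)   # which.min takes the first minimum: lower start
  c(x[i], x[i + m - 1L])
}

# Resolve comparison names like "BCB_vs_PRI" against the sampling labels of
# a scenario; "CG" may be pooled from HBFB+BBDS when not directly sampled.
resolve_comparisons <- function(comparisons, labels) {
  lapply(comparisons, function(cmp) {
    sides <- strsplit(cmp, "_vs_", fixed = TRUE)[[1L]]
    if (length(sides) != 2L)
      stop("comparison '", cmp, "' must be of the form 'A_vs_B'")
    lapply(sides, function(s) {
      if (s %in% labels) return(s)
      if (s == "CG" && all(c("HBFB", "BBDS") %in% labels))
        return(c("HBFB", "BBDS"))
      stop("comparison side '", s, "' not available in scenario sampling (",
           paste(labels, collapse = ", "), ")")
    })
  })
}

#' Simulate per-comparison Phi_ST distributions under a scenario
#'
#' Runs `n_reps` independent replicates of [simulate_dataset()] (drawing
#' prior values anew each replicate) and computes pairwise Phi_ST for each
#' requested comparison using the same Jukes-Cantor machinery as the
#' observed statistics.
#'
#' @param sc A [demographic_scenario()].
#' @param comparisons Character vector like `c("BCB_vs_PRI", "PRI_vs_CG")`;
#'   `"CG"` pools HBFB and BBDS when those are sampled separately.
#' @param n_reps Number of replicates (>= 100).
#' @param seed Optional seed; replicate `r` uses a deterministic substream.
#' @param max_fail Abort if more than this fraction of replicates errors.
#' @return Matrix `n_reps x length(comparisons)` of simulated Phi_ST values.
#' @export
simulate_phi_distributions <- function(sc, comparisons, n_reps = 1000L,
                                       seed = NULL, max_fail = 0.05) {
  if (n_reps < 100L) stop("n_reps must be >= 100")
  validate_scenario(sc)
  sides <- resolve_comparisons(comparisons, sc$sampling$set_id)
  out <- matrix(NA_real_, n_reps, length(comparisons),
                dimnames = list(NULL, comparisons))
  failures <- character(0)
  for (r in seq_len(n_reps)) {
    if (!is.null(seed)) set.seed(substream_seed(seed, r))
    raw <- tryCatch(sim_dataset_raw(sc), error = function(e) e)
    if (inherits(raw, "error")) {
      failures <- c(failures, conditionMessage(raw))
      if (length(failures) > max_fail * n_reps)
        stop("simulation failure rate above ", max_fail, "; first error: ",
             failures[1L])
      next
    }
    out[r, ] <- .phi_set_from_raw(raw$tips, raw$set, sides)
  }
  out[stats::complete.cases(out), , drop = FALSE]
}

# Phi_ST for several comparisons from one replicate's integer tip matrix.
# Haplotypes are collapsed once; each comparison only re-tabulates counts.
.phi_set_from_raw <- function(tips, set_labels, sides) {
  keys <- row_keys(tips)
  haps <- unique(keys)
  idx <- match(keys, haps)
  hm <- tips[match(haps, keys), , drop = FALSE]
  L <- ncol(tips)
  D2 <- jukes_cantor(hap_hamming(hm) / L) * L
  H <- length(haps)
  vapply(sides, function(sd) {
    ra <- set_labels %in% sd[[1L]]
    rb <- set_labels %in% sd[[2L]]
    .phi_from_counts(D2, tabulate(idx[ra], nbins = H),
                     tabulate(idx[rb], nbins = H))
  }, numeric(1L))
}

#' Scenario rejection against observed Phi_ST values
#'
#' The inference engine: simulates the scenario's Phi_ST distributions for
#' the requested comparisons, forms the 95% HPD interval of each, and
#' rejects the scenario if any observed value falls outside its interval
#' (per-comparison verdicts are also reported).
#'
#' @param sc A [demographic_scenario()].
#' @param observed Named numeric vector of observed Phi_ST values; names
#'   are comparisons like `"BCB_vs_PRI"` (the reference analysis used
#'   BCB_vs_BBDS, BCB_vs_CG, BCB_vs_PRI, PRI_vs_BBDS, PRI_vs_CG).
#' @param n_reps Simulation replicates (>= 100; the reference used 10,000).
#' @param seed Optional seed (deterministic substreams per replicate).
#' @param mass HPD mass (default 0.95).
#' @param max_fail Tolerated fraction of failed replicates.
#' @return Object of class `scenario_verdict`: `label`, `comparisons`
#'   (data.frame with observed, lo, hi, median, outside), `decision`
#'   (`"retained"`/`"rejected"`), `rejecting` (comparisons driving a
#'   rejection), and `sim` (the simulated matrix).
#' @export
run_rejection <- function(sc, observed, n_reps = 1000L, seed = NULL,
                          mass = 0.95, max_fail = 0.05) {
  if (is.null(names(observed)) || any(!nzchar(names(observed))))
    stop("observed must be a named vector of comparisons")
  sim <- simulate_phi_distributions(sc, names(observed), n_reps, seed,
                                    max_fail)
  comp <- do.call(rbind, lapply(names(observed), function(cmp) {
    h <- hpd_interval(sim[, cmp], mass)
    data.frame(comparison = cmp, observed = unname(observed[cmp]),
               lo = h[1L], hi = h[2L], median = median(sim[, cmp]),
               outside = observed[cmp] < h[1L] | observed[cmp] > h[2L])
  }))
  rownames(comp) <- NULL
  structure(list(label = if (is.null(sc$label)) "scenario" else sc$label,
                 comparisons = comp,
                 decision = if (any(comp$outside)) "rejected" else "retained",
                 rejecting = comp$comparison[comp$outside],
                 n_reps = nrow(sim), mass = mass, sim = sim),
            class = "scenario_verdict")
}

#' @export
print.scenario_verdict <- function(x, ...) {
  cat("Scenario ", x$label, ": ", toupper(x$decision), " (", x$n_reps,
      " replicates, ", round(100 * x$mass), "% HPD)\n", sep = "")
  print(x$comparisons, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Sensitivity of Phi_ST to duplicated individuals
#'
#' Serially removes up to `k_max` repeated sequences from a sample set
#' (by default one copy at a time of the currently most frequent
#' multi-copy haplotype, emulating undetected recaptures) and recomputes
#' pairwise Phi_ST against every other set, reporting the percent change
#' relative to the full data.
#'
#' @param set The focal [aligned_sample_set()].
#' @param others List of comparison sets.
#' @param k_max Maximum number of removed sequences (default 5).
#' @param candidates Optional character vector of haplotype sequence
#'   strings whose copies should be removed (error if absent from `set`).
#' @param distance Distance model for Phi_ST.
#' @return data.frame with columns `k`, `comparison`, `phi_st`,
#'   `pct_change` (plus the k = 0 baseline rows).
#' @export
duplicate_sensitivity <- function(set, others, k_max = 5L, candidates = NULL,
                                  distance = "jc") {
  if (inherits(others, "aligned_sample_set")) others <- list(others)
  n <- n_samples(set)
  if (k_max >= n) stop("cannot remove ", k_max, " of ", n, " sequences")
  if (!is.null(candidates)) {
    full_keys <- row_keys(set$seqs)
    missing <- setdiff(candidates, full_keys)
    if (length(missing))
      stop("candidate haplotype(s) absent from set '", set$set_id, "'")
  }
  other_ids <- vapply(others, `[[`, character(1L), "set_id")
  base <- vapply(others, function(o) pairwise_phi_st(set, o, distance),
                 numeric(1L))
  out <- data.frame(k = 0L, comparison = paste(set$set_id, "vs", other_ids),
                    phi_st = base, pct_change = 0)
  cur <- set
  for (k in seq_len(k_max)) {
    keys <- row_keys(cur$seqs)
    pool <- if (is.null(candidates)) keys else keys[keys %in% candidates]
    tab <- sort(table(pool), decreasing = TRUE)
    tab <- tab[tab >= 2L]
    if (length(tab) == 0L)
      stop("no repeated sequences left to remove at k = ", k)
    drop_idx <- which(keys == names(tab)[1L])[1L]
    keep <- setdiff(seq_len(n_samples(cur)), drop_idx)
    cur <- aligned_sample_set(cur$set_id,
                              cur$seqs[keep, , drop = FALSE],
                              ages = cur$ages[keep], group = cur$group)
    phi <- vapply(others, function(o) pairwise_phi_st(cur, o, distance),
                  numeric(1L))
    out <- rbind(out, data.frame(
      k = k, comparison = paste(set$set_id, "vs", other_ids),
      phi_st = phi,
      pct_change = ifelse(abs(base) < 1e-12, NA_real_,
                          100 * (phi - base) / abs(base))))
  }
  rownames(out) <- NULL
  out
}
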