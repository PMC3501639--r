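# Study-shaped synthetic data: makes every pipeline stage testable without
# downloading the deposited sequences.

#' Design parameters for study-like synthetic data
#'
#' Defaults emulate the empirical design: six sample sets with sizes
#' 38/176/89/394/24/38, a 370-bp alignment, per-site diversity around 0.01,
#' an ancient set (PRI-like, ~650 ybp) and a heterochronous set
#' (Spitsbergen-like, 30-3000 ybp in cohorts), and enough inter-deme
#' migration that the dominant haplotype is shared across sets.
#'
#' @param sizes Named integer vector of sample sizes.
#' @param length Alignment length in bp.
#' @param theta_site Target per-site diversity `2 N mu`.
#' @param migration Backward migration rate between all deme pairs.
#' @param n_f Female effective size per deme.
#' @param scale Integer divisor applied to `sizes` (>= 1) for reduced-scale
#'   test fixtures.
#' @return A list of design parameters for [generate_study_like()].
#' @export
study_design <- function(sizes = c(PRI = 38L, HBFB = 176L, BBDS = 89L,
                                   BCB = 394L, Okhotsk = 24L,
                                   Spitsbergen = 38L),
                         length = 370L, theta_site = 0.01,
                         migration = 0.05, n_f = 1000, scale = 1L) {
  if (is.null(names(sizes))) stop("sizes must be a named vector")
  sizes <- setNames(pmax(2L, as.integer(ceiling(sizes / scale))),
                    names(sizes))
  stopifnot(length > 0, theta_site > 0, n_f > 0, migration >= 0)
  list(sizes = sizes, length = as.integer(length), theta_site = theta_site,
       migration = migration, n_f = n_f)
}

# Scenario realising a study-like design: one deme per sample set, island
# migration, ancient sampling for the PRI- and Spitsbergen-like sets.
.design_scenario <- function(design, generation_time = 52) {
  ids <- names(design$sizes)
  nd <- length(ids)
  demes <- data.frame(id = ids, size = rep(design$n_f, nd))
  rows <- list()
  for (i in seq_along(ids)) {
    id <- ids[i]; n <- design$sizes[[i]]
    if (id == "PRI") {
      rows[[length(rows) + 1L]] <- data.frame(set_id = id, deme = id, n = n,
                                              age_gen = 650 / generation_time)
    } else if (id == "Spitsbergen") {
      # heterochronous cohorts spanning ~30-3000 ybp
      ages <- c(30, 500, 1500, 3000) / generation_time
      ns <- diff(round(seq(0, n, length.out = 5L)))
      keep <- ns > 0
      rows[[length(rows) + 1L]] <- data.frame(
        set_id = id, deme = id, n = ns[keep], age_gen = ages[keep])
    } else {
      rows[[length(rows) + 1L]] <- data.frame(set_id = id, deme = id, n = n,
                                              age_gen = 0)
    }
  }
  mig <- matrix(design$migration, nd, nd, dimnames = list(ids, ids))
  diag(mig) <- 0
  # island-model mean within-deme coalescent time is nd * N_f irrespective
  # of the migration rate, so scale mu to hit the per-site diversity target
  mu_site_per_gen <- design$theta_site / (2 * design$n_f * nd)
  rate_my <- mu_site_per_gen * 1e6 / generation_time
  model <- hky_model(rate_per_site_per_my = rate_my)
  demographic_scenario(demes, do.call(rbind, rows), migration = mig,
                       generation_time = generation_time, mutation = model,
                       length = design$length)
}

#' Generate study-like aligned sample sets
#'
#' Simulates the design's scenario with the serial coalescent and checks
#' the signature structure of the empirical data: the most frequent
#' haplotype must be shared by (most of) the sample sets. Attempts are
#' repeated with fresh substreams up to `max_retries`; if no attempt
#' satisfies the check the best attempt is returned with a warning.
#'
#' @param design A [study_design()] list.
#' @param seed Optional RNG seed.
#' @param max_retries Resampling cap for the dominant-haplotype check.
#' @param min_shared Minimum number of sets whose most frequent haplotype
#'   equals the globally most frequent one (default: all sets).
#' @return Named list of [aligned_sample_set()] objects, with attribute
#'   `attempts`.
#' @export
generate_study_like <- function(design = study_design(), seed = NULL,
                                max_retries = 20L, min_shared = NULL) {
  sc <- .design_scenario(design)
  n_sets <- length(design$sizes)
  if (is.null(min_shared)) min_shared <- n_sets
  best <- NULL; best_score <- -1L
  for (attempt in seq_len(max_retries)) {
    s <- if (is.null(seed)) NULL else substream_seed(seed, attempt)
    sets <- simulate_dataset(sc, seed = s)
    tab <- collapse_haplotypes(unname(sets))
    dominant <- which.max(rowSums(tab$counts))
    per_set_top <- apply(tab$counts, 2L, which.max)
    score <- sum(per_set_top == dominant)
    if (score > best_score) { best <- sets; best_score <- score }
    if (score >= min_shared) {
      attr(best, "attempts") <- attempt
      return(best)
    }
  }
  warning("dominant-haplotype sharing not achieved in ", max_retries,
          " attempts (best: ", best_score, "/", n_sets,
          " sets); returning best attempt")
  attr(best, "attempts") <- max_retries
  best
}

#' Generate a synthetic multilocus genotype table with planted duplicates
#'
#' Draws allele frequencies per locus, samples genotypes under random
#' mating, then appends exact duplicates and near-duplicates (1-2
#' mismatching loci) of existing rows to exercise the recapture screen.
#'
#' @param n Number of distinct individuals.
#' @param n_loci Number of microsatellite loci (default 21).
#' @param dup_pairs Number of planted exact duplicate pairs.
#' @param near_dup_pairs Number of planted near-duplicate pairs (each
#'   mismatching at 1 or 2 loci).
#' @param n_alleles Range of allele counts per locus.
#' @param seed Optional RNG seed.
#' @return A [genotype_table()] with attribute `truth` (data.frame of
#'   planted pairs and their mismatch counts).
#' @export
generate_genotypes <- function(n, n_loci = 21L, dup_pairs = 0L,
                               near_dup_pairs = 0L, n_alleles = c(3L, 8L),
                               seed = NULL) {
  stopifnot(n_loci >= 1L, n >= 2L)
  with_seed(seed, {
    al <- matrix(NA_integer_, n, 2L * n_loci)
    for (l in seq_len(n_loci)) {
      k <- sample(n_alleles[1L]:n_alleles[2L], 1L)
      p <- rexp(k); p <- p / sum(p)
      al[, 2L * l - 1L] <- sample.int(k, n, replace = TRUE, prob = p)
      al[, 2L * l] <- sample.int(k, n, replace = TRUE, prob = p)
    }
    ids <- sprintf("ind%03d", seq_len(n))
    truth <- data.frame(id_a = character(0), id_b = character(0),
                        n_mismatch = integer(0))
    extra <- list(); extra_ids <- character(0)
    plant <- function(src, mism) {
      row <- al[src, ]
      if (mism > 0L) {
        loci <- sample.int(n_loci, mism)
        for (l in loci) row[2L * l - 1L] <- row[2L * l - 1L] + 100L
      }
      row
    }
    for (d in seq_len(dup_pairs)) {
      src <- sample.int(n, 1L)
      extra[[length(extra) + 1L]] <- plant(src, 0L)
      id <- sprintf("dup%02d", d); extra_ids <- c(extra_ids, id)
      truth <- rbind(truth, data.frame(id_a = ids[src], id_b = id,
                                       n_mismatch = 0L))
    }
    for (d in seq_len(near_dup_pairs)) {
      src <- sample.int(n, 1L)
      mism <- sample(1:2, 1L)
      extra[[length(extra) + 1L]] <- plant(src, mism)
      id <- sprintf("near%02d", d); extra_ids <- c(extra_ids, id)
      truth <- rbind(truth, data.frame(id_a = ids[src], id_b = id,
                                       n_mismatch = mism))
    }
    if (length(extra)) al <- rbind(al, do.call(rbind, extra))
    g <- genotype_table(c(ids, extra_ids), al)
    attr(g, "truth") <- truth
    g
  })
}
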