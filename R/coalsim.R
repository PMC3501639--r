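# Serial (heterochronous) coalescent simulation over multiple demes.

#' Convert a census population size to a female effective size
#'
#' Applies the standard chain for matrilineal (mtDNA) simulations: a 1:1
#' male:female ratio, a 1.5:1 ratio of all individuals to adults, and an
#' Ne/N ratio of 0.5, i.e. `N_f = census / 6`.
#'
#' @param census_N Census population size (> 0).
#' @return Rounded female effective size (>= 1).
#' @examples
#' census_to_female_ne(12000)  # 2000
#' @export
census_to_female_ne <- function(census_N) {
  if (census_N <= 0) stop("census size must be positive")
  nf <- census_N * (1 / 1.5) * 0.5 * 0.5
  if (nf < 1) stop("census size ", census_N,
                   " implies a female effective size below 1")
  round(nf)
}

#' Construct a demographic scenario
#'
#' A scenario bundles everything the serial coalescent needs: demes with
#' female effective sizes, sampling events (possibly ancient), historical
#' events (size changes, lineage movements/divergences, migration-matrix
#' updates, all in generations backward from the present), a backward
#' migration matrix, the generation time, a mutation model, and optional
#' whaling-bottleneck priors drawn once per simulated replicate.
#'
#' @param demes data.frame with columns `id` (character) and `size` (female
#'   effective size at present, or pre-whaling size for demes carrying a
#'   bottleneck prior).
#' @param sampling data.frame with columns `set_id`, `deme`, `n`,
#'   `age_gen` (sampling age in generations before present; 0 = modern).
#' @param migration Square backward migration matrix (per-generation
#'   probability that a lineage in row-deme originated in column-deme);
#'   default no migration. Dimnames must match deme ids.
#' @param events List of historical events, each a list with `time`
#'   (generations) and `kind` one of `"size_change"` (fields `deme` and
#'   `size` or `multiplier`), `"move_lineages"` (fields `source`, `sink`,
#'   `proportion`), `"migration_update"` (field `matrix`).
#' @param generation_time Generation time in years (default 52, the bowhead
#'   whale value used throughout).
#' @param mutation A [hky_model()].
#' @param priors Optional list with element `bottlenecks`: a list of
#'   `list(deme =, residual = c(lo, hi), time =)` entries. Per replicate a
#'   residual fraction is drawn uniformly; the deme's present size becomes
#'   `residual * size` and a size-change event at `time` restores `size`.
#' @param length Sequence length in bp for simulated datasets (default 370).
#' @param time_cap Hard cap on coalescent time in generations; exceeding it
#'   (e.g. disconnected demes with no merge event) is an error.
#' @return Object of class `demographic_scenario`.
#' @export
demographic_scenario <- function(demes, sampling, migration = NULL,
                                 events = list(), generation_time = 52,
                                 mutation = hky_model(), priors = NULL,
                                 length = 370, time_cap = 1e7) {
  demes$id <- as.character(demes$id)
  sampling$set_id <- as.character(sampling$set_id)
  sampling$deme <- as.character(sampling$deme)
  nd <- nrow(demes)
  if (is.null(migration)) {
    migration <- matrix(0, nd, nd, dimnames = list(demes$id, demes$id))
  }
  sc <- structure(list(demes = demes, sampling = sampling,
                       migration = migration, events = events,
                       generation_time = generation_time,
                       mutation = mutation, priors = priors,
                       length = length, time_cap = time_cap,
                       label = NULL),
                  class = "demographic_scenario")
  validate_scenario(sc)
  sc
}

#' Validate a demographic scenario
#'
#' Checks sizes, migration-matrix rows, event ordering and deme references;
#' errors on the first violation.
#'
#' @param sc A [demographic_scenario()].
#' @return Invisibly `TRUE`.
#' @export
validate_scenario <- function(sc) {
  d <- sc$demes
  if (any(d$size <= 0)) stop("deme sizes must be positive")
  if (anyDuplicated(d$id)) stop("duplicate deme ids")
  m <- sc$migration
  if (!all(dim(m) == nrow(d))) stop("migration matrix dimension mismatch")
  if (any(m < 0)) stop("negative migration rates")
  diag(m) <- 0
  if (any(rowSums(m) > 1)) stop("migration row sums exceed 1 per generation")
  s <- sc$sampling
  if (any(!s$deme %in% d$id))
    stop("sampling refers to unknown deme(s): ",
         paste(setdiff(s$deme, d$id), collapse = ", "))
  if (any(s$n < 1) || any(s$age_gen < 0)) stop("invalid sampling event")
  if (sum(s$n) < 2) stop("need at least 2 sampled lineages in total")
  times <- vapply(sc$events, `[[`, numeric(1L), "time")
  if (length(times) && (any(times < 0) || is.unsorted(times)))
    stop("event times must be non-negative and ordered")
  for (ev in sc$events) {
    if (!ev$kind %in% c("size_change", "move_lineages", "migration_update"))
      stop("unknown event kind '", ev$kind, "'")
    if (ev$kind == "size_change" && !any(c("size", "multiplier") %in% names(ev)))
      stop("size_change event needs 'size' or 'multiplier'")
    if (ev$kind == "move_lineages" &&
        (!all(c("source", "sink", "proportion") %in% names(ev)) ||
         ev$proportion < 0 || ev$proportion > 1))
      stop("move_lineages event needs source, sink and proportion in [0,1]")
  }
  if (!is.null(sc$priors$bottlenecks)) {
    for (b in sc$priors$bottlenecks) {
      if (!b$deme %in% d$id) stop("bottleneck prior for unknown deme ", b$deme)
      if (any(b$residual <= 0) || any(b$residual > 1))
        stop("bottleneck residual fractions must be in (0, 1]")
    }
  }
  invisible(TRUE)
}

#' @export
print.demographic_scenario <- function(x, ...) {
  cat("Demographic scenario", if (!is.null(x$label)) paste0(" '", x$label, "'"),
      ": ", nrow(x$demes), " deme(s), ", sum(x$sampling$n),
      " sampled lineages, ", length(x$events), " event(s)\n", sep = "")
  invisible(x)
}

# Draw per-replicate prior values and return a concrete scenario plus the
# drawn parameters. Bottleneck: present size = residual * configured size,
# restored by a size_change at the bottleneck time (backward).
realize_scenario <- function(sc) {
  drawn <- list()
  r <- sc$mutation$rate_per_site_per_my
  drawn$rate_per_site_per_my <- if (length(r) == 2L) runif(1, r[1], r[2]) else r
  if (!is.null(sc$priors$bottlenecks)) {
    extra <- list()
    for (b in sc$priors$bottlenecks) {
      frac <- runif(1, b$residual[1], b$residual[2])
      drawn$residual[[b$deme]] <- frac
      i <- match(b$deme, sc$demes$id)
      hist_size <- sc$demes$size[i]
      sc$demes$size[i] <- max(1, frac * hist_size)
      extra[[length(extra) + 1L]] <- list(time = b$time, kind = "size_change",
                                          deme = b$deme, size = hist_size)
    }
    sc$events <- c(sc$events, extra)
    ord <- order(vapply(sc$events, `[[`, numeric(1L), "time"))
    sc$events <- sc$events[ord]
  }
  sc$priors <- NULL
  list(scenario = sc, params = drawn)
}

# Encode events for the C++ simulator.
encode_events <- function(sc) {
  ev <- sc$events
  n <- length(ev)
  out <- list(time = numeric(n), kind = integer(n), i1 = integer(n),
              i2 = integer(n), x = numeric(n), mat = vector("list", max(n, 1L)))
  ids <- sc$demes$id
  for (k in seq_len(n)) {
    e <- ev[[k]]
    out$time[k] <- e$time
    if (e$kind == "size_change") {
      out$i1[k] <- match(e$deme, ids)
      if (!is.null(e$size)) { out$kind[k] <- 1L; out$x[k] <- e$size }
      else { out$kind[k] <- 4L; out$x[k] <- e$multiplier }
    } else if (e$kind == "move_lineages") {
      out$kind[k] <- 2L
      out$i1[k] <- match(e$source, ids)
      out$i2[k] <- match(e$sink, ids)
      out$x[k] <- e$proportion
    } else {
      out$kind[k] <- 3L
      m <- e$matrix
      if (!is.null(dimnames(m))) m <- m[ids, ids]
      out$mat[[k]] <- m
    }
  }
  out
}

#' Simulate a gene genealogy under a scenario
#'
#' Runs the backward-in-time serial coalescent: within a deme of current
#' size `N` every lineage pair coalesces at rate `1/N` per generation,
#' lineages relocate according to the backward migration matrix, ancient
#' tips enter the genealogy at their sampling ages, and historical events
#' fire at their scheduled times. Bottleneck priors, if any, are drawn
#' before simulating.
#'
#' @param sc A [demographic_scenario()].
#' @param seed Optional RNG seed.
#' @return Object of class `gene_genealogy`: `parent` (0 for the root),
#'   `time` (node times in generations), `deme` per node, `n_tips`,
#'   `tip_set` (sampling-event label per tip), `tip_age`, and `params`
#'   (prior values drawn, if any).
#' @export
simulate_genealogy <- function(sc, seed = NULL) {
  validate_scenario(sc)
  with_seed(seed, {
    rz <- realize_scenario(sc)
    g <- .simulate_genealogy_realized(rz$scenario)
    g$params <- rz$params
    g
  })
}

.simulate_genealogy_realized <- function(sc) {
  s <- sc$sampling
  tip_deme <- rep(match(s$deme, sc$demes$id), s$n)
  tip_age <- rep(s$age_gen, s$n)
  tip_set <- rep(s$set_id, s$n)
  enc <- encode_events(sc)
  m <- sc$migration
  diag(m) <- 0
  res <- sim_genealogy_cpp(sc$demes$size, m, as.integer(tip_deme), tip_age,
                           enc$time, enc$kind, enc$i1, enc$i2, enc$x, enc$mat,
                           sc$time_cap)
  structure(list(parent = res$parent, time = res$time, deme = res$deme,
                 n_tips = res$n_tips, tip_set = tip_set, tip_age = tip_age,
                 deme_ids = sc$demes$id),
            class = "gene_genealogy")
}

#' @export
print.gene_genealogy <- function(x, ...) {
  cat("Gene genealogy: ", x$n_tips, " tips, TMRCA = ",
      signif(max(x$time), 5), " generations\n", sep = "")
  invisible(x)
}

#' Time to the most recent common ancestor
#' @param g A [simulate_genealogy()] result.
#' @return TMRCA in generations.
#' @export
tmrca <- function(g) max(g$time)

#' Total branch length of a genealogy
#' @param g A [simulate_genealogy()] result.
#' @return Sum of branch lengths in generations.
#' @export
total_branch_length <- function(g) {
  nonroot <- which(g$parent > 0L)
  sum(g$time[g$parent[nonroot]] - g$time[nonroot])
}

#' Convert a genealogy to an ape phylo tree
#'
#' Branch lengths are in generations; ancient tips end above the present,
#' so the tree is ultrametric only when all tips are modern.
#'
#' @param g A [simulate_genealogy()] result.
#' @return An `ape::phylo` object (export with [ape::write.tree()]).
#' @export
genealogy_to_phylo <- function(g) {
  n <- g$n_tips
  M <- 2L * n - 1L
  # ape numbering: tips 1..n, root n+1, later internals downward from 2n-1
  map <- c(seq_len(n), 3L * n - ((n + 1L):M))
  nonroot <- which(g$parent > 0L)
  edge <- cbind(map[g$parent[nonroot]], map[nonroot])
  len <- g$time[g$parent[nonroot]] - g$time[nonroot]
  phy <- list(edge = edge, edge.length = len,
              tip.label = paste0(g$tip_set, "_", seq_len(n)),
              Nnode = n - 1L)
  class(phy) <- "phylo"
  ape::reorder.phylo(phy, "cladewise")
}

# Minimal single-deme constant-size coalescent (modern tips); fast path for
# calibration loops and Hd confidence intervals.
.sim_single_deme <- function(n, N) {
  res <- sim_genealogy_cpp(N, matrix(0, 1, 1), rep(1L, n), rep(0, n),
                           numeric(0), integer(0), integer(0), integer(0),
                           numeric(0), list(NULL), 1e9)
  list(parent = res$parent, time = res$time)
}

#' Evolve sequences along a genealogy (HKY+Gamma)
#'
#' Draws the root sequence from the stationary base frequencies, site rate
#' multipliers from the Gamma distribution, and evolves every branch under
#' the exact HKY transition probabilities at per-site per-generation rate
#' `mu_g = rate_per_site_per_my * generation_time / 1e6`.
#'
#' @param g A [simulate_genealogy()] result.
#' @param model A [hky_model()].
#' @param length Number of sites.
#' @param generation_time Generation time in years.
#' @param rate_per_site_per_my Substitution rate to use; defaults to the
#'   model's fixed rate (a prior range here is an error -- draw it first, as
#'   [simulate_dataset()] does).
#' @param seed Optional RNG seed.
#' @return Named list of [aligned_sample_set()] objects, one per sampling
#'   event label, with ages in years attached.
#' @export
apply_mutations <- function(g, model, length, generation_time = 52,
                            rate_per_site_per_my = NULL, seed = NULL) {
  if (is.null(rate_per_site_per_my)) {
    r <- model$rate_per_site_per_my
    if (base::length(r) == 2L)
      stop("model carries a rate prior; pass an explicit rate or use simulate_dataset()")
    rate_per_site_per_my <- r
  }
  tips <- with_seed(seed, .mutate_raw(g, model, length, generation_time,
                                      rate_per_site_per_my))
  tips_to_sets(tips, g, generation_time)
}

.mutate_raw <- function(g, model, length, generation_time, rate) {
  mu_g <- rate * generation_time / 1e6
  dec <- hky_eigen(model)
  site_rate <- mu_g * gamma_site_rates(length, model$gamma_shape)
  mutate_tree_cpp(g$parent, g$time, g$n_tips, as.integer(length),
                  site_rate, dec$U, dec$Uinv, dec$lambda, dec$freqs)
}

# Split an integer tip matrix into aligned_sample_set objects by tip label.
tips_to_sets <- function(tips, g, generation_time) {
  chr <- seq_int_to_char(tips)
  sets <- lapply(unique(g$tip_set), function(lbl) {
    rows <- which(g$tip_set == lbl)
    m <- chr[rows, , drop = FALSE]
    rownames(m) <- paste0(lbl, "_", seq_along(rows))
    ages <- g$tip_age[rows] * generation_time
    names(ages) <- rownames(m)
    aligned_sample_set(lbl, m, ages = ages)
  })
  names(sets) <- unique(g$tip_set)
  sets
}

#' Simulate a full genetic dataset under a scenario
#'
#' One replicate of the serial-coalescent pipeline: draw prior values
#' (mutation rate, bottleneck residuals), simulate the genealogy, mutate
#' sequences, and return one sample set per sampling event -- the simulated
#' analogue of the empirical data.
#'
#' @param sc A [demographic_scenario()].
#' @param seed Optional RNG seed.
#' @return Named list of [aligned_sample_set()] objects with an attribute
#'   `params` holding the drawn prior values.
#' @export
simulate_dataset <- function(sc, seed = NULL) {
  raw <- with_seed(seed, sim_dataset_raw(sc))
  sets <- tips_to_sets(raw$tips, raw$genealogy, sc$generation_time)
  attr(sets, "params") <- raw$params
  sets
}

# Low-level single replicate: integer tip matrix plus labels (fast path for
# the rejection engine); uses the current RNG stream.
sim_dataset_raw <- function(sc) {
  rz <- realize_scenario(sc)
  g <- .simulate_genealogy_realized(rz$scenario)
  tips <- .mutate_raw(g, sc$mutation, sc$length, sc$generation_time,
                      rz$params$rate_per_site_per_my)
  list(tips = tips, set = g$tip_set, genealogy = g, params = rz$params)
}
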