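# The 36-scenario demographic design bank: three basic timings of
# Atlantic-Pacific gene flow x four between-stock structures x three
# migration rates, with whaling-bottleneck priors.
#
# The timing parameters and deme sizes shipped here are documented
# reconstructions (the original appendix values are not reproduced in the
# main text); every number is overridable through the config list / YAML.

#' Default configuration for the scenario bank
#'
#' Returns the full parameter list consumed by [enumerate_scenarios()]:
#' pre-whaling census sizes (converted to female effective sizes via
#' [census_to_female_ne()]), the three migration rates, the timing (in
#' generations backward) at which Atlantic-Pacific gene flow existed under
#' each basic scenario, whaling-bottleneck residual priors, sampling sizes
#' and ages, and the mutation model. All values are reconstructions chosen
#' to be biologically plausible for bowhead whales and are meant to be
#' overridden where better information exists.
#'
#' @return Named list of configuration entries.
#' @export
default_scenario_config <- function() {
  list(
    generation_time = 52,
    length = 370,
    # pre-whaling census sizes; CG is the pooled Canada-Greenland stock
    census = list(HBFB = 680, BBDS = 12000, BCB = 16000, PRI = 3000,
                  ancestral = 30000),
    migration_rates = c(0.1, 0.01, 0.001),
    # backward time (generations) at which inter-basin gene flow switches on:
    # timing 1 = flow only before the late-Holocene ice plugs (~3 kya);
    # timing 2 = flow until the Little Ice Age onset (~400 ybp);
    # timing 3 = contemporary gene flow (active at present)
    timing_gen = list(`1` = 3000 / 52, `2` = 400 / 52, `3` = 0),
    ancestral_merge_gen = 2000,
    # whaling encoded as one bottleneck: modern size = residual * pre-whaling
    # size, restored at the onset of commercial whaling (~460 ybp)
    whaling_time_gen = 460 / 52,
    residual = list(HBFB = c(0.01, 0.68), BBDS = c(0.01, 0.29),
                    CG = c(0.01, 0.29), BCB = c(0.05, 0.20)),
    pri_age_years = 650,
    sample_sizes = list(PRI = 38, HBFB = 176, BBDS = 89, BCB = 394),
    mutation = hky_model(),
    time_cap = 1e7
  )
}

#' Read a scenario configuration from YAML
#'
#' Reads a YAML file of overrides and merges it over
#' [default_scenario_config()] (top-level and one nested level by name).
#'
#' @param path YAML file.
#' @return Configuration list.
#' @export
read_scenario_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_scenario_config()
  for (k in names(user)) {
    if (k %in% names(cfg) && is.list(cfg[[k]]) && is.list(user[[k]])) {
      for (k2 in names(user[[k]])) cfg[[k]][[k2]] <- user[[k]][[k2]]
    } else {
      cfg[[k]] <- user[[k]]
    }
  }
  cfg
}

.cfg_get <- function(cfg, field, sub = NULL, label = "") {
  v <- cfg[[field]]
  if (!is.null(sub)) v <- v[[sub]]
  if (is.null(v))
    stop("scenario ", label, ": missing config field '",
         field, if (!is.null(sub)) paste0("$", sub), "'")
  v
}

#' Empirical sampling template
#'
#' The sample sizes and ages of the four Canadian-Arctic sample sets used
#' by the demographic simulations: ancient PRI (38 samples at ~650 ybp, the
#' midpoint of the 500-800 ybp site occupation) and the modern HBFB, BBDS
#' and BCB biopsy sets.
#'
#' @param generation_time Years per generation (converts ages to
#'   generations).
#' @param pooled If `TRUE`, HBFB and BBDS are pooled into Canada-Greenland
#'   (`CG`, n = 265).
#' @return data.frame with `set_id`, `n`, `age_years`, `age_gen`.
#' @export
empirical_sampling_template <- function(generation_time = 52, pooled = FALSE) {
  if (pooled) {
    d <- data.frame(set_id = c("PRI", "CG", "BCB"),
                    n = c(38L, 265L, 394L),
                    age_years = c(650, 0, 0))
  } else {
    d <- data.frame(set_id = c("PRI", "HBFB", "BBDS", "BCB"),
                    n = c(38L, 176L, 89L, 394L),
                    age_years = c(650, 0, 0, 0))
  }
  d$age_gen <- d$age_years / generation_time
  d
}

# Build one concrete scenario of the bank.
build_bank_scenario <- function(timing, structure, m, cfg) {
  label <- paste0(timing, structure)
  gt <- .cfg_get(cfg, "generation_time", label = label)
  pri_age <- .cfg_get(cfg, "pri_age_years", label = label) / gt
  nf <- function(stock) {
    census <- if (stock == "CG" && is.null(cfg$census$CG))
      .cfg_get(cfg, "census", "HBFB", label) +
        .cfg_get(cfg, "census", "BBDS", label)
    else .cfg_get(cfg, "census", stock, label)
    census_to_female_ne(census)
  }
  sizes <- .cfg_get(cfg, "sample_sizes", label = label)

  atl <- switch(structure,
                A = c("HBFB", "BBDS"),
                B = "CG", C = c("CG", "PRI"), D = "CG")
  demes <- data.frame(id = c(atl, "BCB"),
                      size = c(vapply(atl, nf, numeric(1L)), nf("BCB")))

  sampling <- switch(structure,
    A = data.frame(set_id = c("PRI", "HBFB", "BBDS", "BCB"),
                   deme = c("BBDS", "HBFB", "BBDS", "BCB"),
                   n = c(sizes$PRI, sizes$HBFB, sizes$BBDS, sizes$BCB),
                   age_gen = c(pri_age, 0, 0, 0)),
    B = data.frame(set_id = c("PRI", "CG", "BCB"),
                   deme = c("CG", "CG", "BCB"),
                   n = c(sizes$PRI, sizes$HBFB + sizes$BBDS, sizes$BCB),
                   age_gen = c(pri_age, 0, 0)),
    C = data.frame(set_id = c("PRI", "CG", "BCB"),
                   deme = c("PRI", "CG", "BCB"),
                   n = c(sizes$PRI, sizes$HBFB + sizes$BBDS, sizes$BCB),
                   age_gen = c(pri_age, 0, 0)),
    D = data.frame(set_id = c("PRI", "CG", "BCB"),
                   deme = c("BCB", "CG", "BCB"),
                   n = c(sizes$PRI, sizes$HBFB + sizes$BBDS, sizes$BCB),
                   age_gen = c(pri_age, 0, 0)))

  ids <- demes$id
  nd <- length(ids)
  # intra-basin pairs always exchange at m; inter-basin (anything x BCB)
  # only while the timing window allows
  full_m <- matrix(m, nd, nd, dimnames = list(ids, ids))
  diag(full_m) <- 0
  present_m <- full_m
  t_flow <- .cfg_get(cfg, "timing_gen", as.character(timing), label)
  if (t_flow > 0) {
    present_m[ids != "BCB", "BCB"] <- 0
    present_m["BCB", ids != "BCB"] <- 0
  }

  events <- list()
  if (t_flow > 0)
    events <- c(events, list(list(time = t_flow, kind = "migration_update",
                                  matrix = full_m)))
  t_merge <- .cfg_get(cfg, "ancestral_merge_gen", label = label)
  zero_m <- matrix(0, nd, nd, dimnames = list(ids, ids))
  events <- c(events,
              list(list(time = t_merge, kind = "migration_update",
                        matrix = zero_m)),
              lapply(ids[-1L], function(d)
                list(time = t_merge, kind = "move_lineages",
                     source = d, sink = ids[1L], proportion = 1)),
              list(list(time = t_merge, kind = "size_change", deme = ids[1L],
                        size = nf("ancestral"))))

  t_wh <- .cfg_get(cfg, "whaling_time_gen", label = label)
  res <- .cfg_get(cfg, "residual", label = label)
  bn_demes <- intersect(ids, names(res))
  bn_demes <- setdiff(bn_demes, "PRI")   # ancient PRI samples predate whaling
  priors <- list(bottlenecks = lapply(bn_demes, function(d)
    list(deme = d, residual = res[[d]], time = t_wh)))

  sc <- demographic_scenario(
    demes = demes, sampling = sampling, migration = present_m,
    events = events, generation_time = gt,
    mutation = .cfg_get(cfg, "mutation", label = label),
    priors = priors,
    length = .cfg_get(cfg, "length", label = label),
    time_cap = .cfg_get(cfg, "time_cap", label = label))
  sc$label <- paste0(label, "_m", m)
  sc$timing <- timing
  sc$structure <- structure
  sc$migration_rate <- m
  sc
}

#' Enumerate the 36-scenario demographic design bank
#'
#' Deterministically builds all combinations of three basic timings of
#' Atlantic-Pacific gene flow (1: flow only before the late-Holocene ice
#' plugs; 2: flow until the Little Ice Age onset; 3: contemporary flow),
#' four between-stock structures (A: HBFB and BBDS separate with the
#' ancient PRI samples drawn within BBDS; B: pooled Canada-Greenland;
#' C: PRI as a separate population; D: PRI ancestral to BCB), and three
#' migration rates (default 0.1, 0.01, 0.001). Each scenario carries
#' whaling-bottleneck priors on the modern stocks.
#'
#' @param config Configuration list, see [default_scenario_config()].
#' @return Named list of 36 [demographic_scenario()] objects with labels
#'   like `"3C_m0.1"`.
#' @export
enumerate_scenarios <- function(config = default_scenario_config()) {
  ms <- .cfg_get(config, "migration_rates", label = "bank")
  bank <- list()
  for (timing in 1:3)
    for (structure in c("A", "B", "C", "D"))
      for (m in ms) {
        sc <- build_bank_scenario(timing, structure, m, config)
        bank[[sc$label]] <- sc
      }
  bank
}

#' Design table of a scenario bank
#'
#' @param bank Result of [enumerate_scenarios()].
#' @return data.frame with one row per scenario (label, timing, structure,
#'   migration rate, demes, total samples).
#' @export
scenario_design_table <- function(bank) {
  do.call(rbind, lapply(bank, function(sc) data.frame(
    label = sc$label, timing = sc$timing, structure = sc$structure,
    m = sc$migration_rate, demes = paste(sc$demes$id, collapse = "+"),
    n_samples = sum(sc$sampling$n))))
}
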