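test_that("census to female effective size follows the demographic chain", {
  expect_equal(census_to_female_ne(12000), 2000)
  expect_equal(census_to_female_ne(6), 1)
  expect_error(census_to_female_ne(4), "below 1")
  expect_error(census_to_female_ne(0), "positive")
})

test_that("scenario validation catches structural errors", {
  demes <- data.frame(id = c("A", "B"), size = c(100, 100))
  samp <- data.frame(set_id = c("A", "B"), deme = c("A", "B"),
                     n = c(3, 3), age_gen = c(0, 0))
  expect_silent(demographic_scenario(demes, samp))
  expect_error(demographic_scenario(data.frame(id = "A", size = -1),
                                    samp[1, ]), "positive")
  bad_m <- matrix(c(0, 0.6, 0.6, 0), 2, 2)
  expect_error(demographic_scenario(demes, samp,
    migration = bad_m * 2), "exceed 1")
  expect_error(demographic_scenario(demes,
    data.frame(set_id = "X", deme = "X", n = 3, age_gen = 0)), "unknown deme")
  expect_error(demographic_scenario(demes, samp,
    events = list(list(time = 5, kind = "teleport"))), "unknown event")
  expect_error(demographic_scenario(demes, samp,
    events = list(list(time = 5, kind = "move_lineages", source = "A",
                       sink = "B", proportion = 2))), "proportion")
})

test_that("ancient tips enter the genealogy exactly at their ages", {
  sc <- demographic_scenario(
    demes = data.frame(id = "A", size = 200),
    sampling = data.frame(set_id = c("old", "new"), deme = "A",
                          n = c(3, 4), age_gen = c(12.5, 0)))
  g <- simulate_genealogy(sc, seed = 4)
  tip_times <- g$time[seq_len(g$n_tips)]
  expect_equal(unname(tip_times[g$tip_set == "old"]), rep(12.5, 3))
  expect_equal(unname(tip_times[g$tip_set == "new"]), rep(0, 4))
  # parent times strictly exceed child times
  nonroot <- which(g$parent > 0)
  expect_true(all(g$time[g$parent[nonroot]] > g$time[nonroot]))
})

test_that("disconnected demes fail at the time cap with a clear error", {
  sc <- demographic_scenario(
    demes = data.frame(id = c("A", "B"), size = c(50, 50)),
    sampling = data.frame(set_id = c("A", "B"), deme = c("A", "B"),
                          n = c(2, 2), age_gen = c(0, 0)),
    time_cap = 1e5)
  expect_error(simulate_genealogy(sc, seed = 1), "time cap")
})

test_that("pairwise coalescence times match the analytic haploid rate", {
  set.seed(61)
  tm <- replicate(3000, max(icefloe:::.sim_single_deme(2, 400)$time))
  expect_equal(mean(tm), 400, tolerance = 0.06)
  # total branch length for n = 5: E[L] = 2 N sum_{i=1}^{4} 1/i
  sc <- single_deme_scenario(5, 300)
  set.seed(62)
  tl <- replicate(2000, total_branch_length(simulate_genealogy(sc)))
  expect_equal(mean(tl), 2 * 300 * sum(1 / (1:4)), tolerance = 0.08)
})

test_that("a bottleneck strictly shortens coalescent times", {
  base <- demographic_scenario(
    demes = data.frame(id = "A", size = 1000),
    sampling = data.frame(set_id = "A", deme = "A", n = 10, age_gen = 0))
  crash <- demographic_scenario(
    demes = data.frame(id = "A", size = 1000),
    sampling = data.frame(set_id = "A", deme = "A", n = 10, age_gen = 0),
    events = list(list(time = 50, kind = "size_change", deme = "A",
                       size = 10)))
  set.seed(63)
  t_base <- replicate(400, tmrca(simulate_genealogy(base)))
  t_crash <- replicate(400, tmrca(simulate_genealogy(crash)))
  expect_lt(mean(t_crash), 0.5 * mean(t_base))
})

test_that("zero mutation rate reproduces the root everywhere", {
  sc <- single_deme_scenario(6, 100)
  g <- simulate_genealogy(sc, seed = 5)
  sets <- apply_mutations(g, sc$mutation, length = 50,
                          rate_per_site_per_my = 0, seed = 6)
  m <- sets[[1]]$seqs
  expect_true(all(m == rep(m[1, ], each = nrow(m))))
})

test_that("divergence under kappa=1/equal frequencies matches the JC oracle", {
  # hand-built genealogy: two tips joined at T generations
  Tgen <- 40000
  g <- structure(list(parent = c(3L, 3L, 0L), time = c(0, 0, Tgen),
                      deme = c(1L, 1L, 1L), n_tips = 2L,
                      tip_set = c("a", "a"), tip_age = c(0, 0)),
                 class = "gene_genealogy")
  model <- hky_model(kappa = 1, base_freqs = rep(0.25, 4), gamma_shape = NULL,
                     rate_per_site_per_my = 0.05)
  gen_time <- 52
  mu_g <- 0.05 * gen_time / 1e6
  set.seed(71)
  p_hat <- mean(replicate(40, {
    s <- apply_mutations(g, model, length = 370, generation_time = gen_time)
    mean(s[[1]]$seqs[1, ] != s[[1]]$seqs[2, ])
  }))
  p_exp <- 0.75 * (1 - exp(-8 / 3 * mu_g * Tgen))  # JC at distance 2 mu T
  expect_equal(p_hat, p_exp, tolerance = 0.05)
})

test_that("HKY transition probabilities are a valid stochastic semigroup", {
  model <- hky_model(kappa = 7, base_freqs = c(0.35, 0.2, 0.1, 0.35))
  dec <- icefloe:::hky_eigen(model)
  for (t in c(0, 0.01, 0.5, 3)) {
    P <- dec$U %*% diag(exp(dec$lambda * t)) %*% dec$Uinv
    expect_equal(rowSums(P), rep(1, 4), tolerance = 1e-12)
    expect_true(all(P >= -1e-12))
    # detailed balance of the reversible chain
    expect_equal(dec$freqs * P, t(dec$freqs * P), tolerance = 1e-12)
  }
  # matrix exponential oracle at t = 0.7
  Pe <- dec$U %*% diag(exp(dec$lambda * 0.7)) %*% dec$Uinv
  series <- diag(4); term <- diag(4)
  for (k in 1:60) { term <- term %*% (dec$Q * 0.7) / k; series <- series + term }
  expect_equal(Pe, series, tolerance = 1e-10)
})

test_that("simulated datasets honour the sampling template and priors", {
  tpl <- empirical_sampling_template()
  expect_equal(tpl$n, c(38L, 176L, 89L, 394L))
  expect_equal(tpl$age_gen[tpl$set_id == "PRI"], 12.5)
  sc <- demographic_scenario(
    demes = data.frame(id = c("ATL", "BCB"), size = c(400, 400)),
    sampling = data.frame(set_id = c("PRI", "BBDS", "HBFB", "BCB"),
                          deme = c("ATL", "ATL", "ATL", "BCB"),
                          n = c(10, 8, 12, 14), age_gen = c(12.5, 0, 0, 0)),
    migration = matrix(c(0, 0.05, 0.05, 0), 2, 2,
                       dimnames = list(c("ATL", "BCB"), c("ATL", "BCB"))),
    mutation = hky_model(rate_per_site_per_my = c(0.02, 0.063)),
    length = 120)
  sets <- simulate_dataset(sc, seed = 8)
  expect_named(sets, c("PRI", "BBDS", "HBFB", "BCB"))
  expect_equal(vapply(sets, n_samples, integer(1L)),
               c(PRI = 10L, BBDS = 8L, HBFB = 12L, BCB = 14L))
  expect_equal(unname(sets$PRI$ages), rep(12.5 * 52, 10))
  pars <- attr(sets, "params")
  expect_gte(pars$rate_per_site_per_my, 0.02)
  expect_lte(pars$rate_per_site_per_my, 0.063)
  # determinism under seed
  sets2 <- simulate_dataset(sc, seed = 8)
  expect_identical(sets$BCB$seqs, sets2$BCB$seqs)
})

test_that("mutation-rate prior draws are uniform over replicates", {
  sc <- two_deme_scenario(0.1)
  set.seed(9)
  rates <- replicate(500, icefloe:::realize_scenario(sc)$params$rate_per_site_per_my)
  ks <- stats::ks.test(rates, "punif", 0.02, 0.063)
  expect_gt(ks$p.value, 0.01)
})

test_that("genealogies convert to valid phylo trees", {
  sc <- single_deme_scenario(8, 200)
  g <- simulate_genealogy(sc, seed = 10)
  phy <- genealogy_to_phylo(g)
  expect_s3_class(phy, "phylo")
  expect_equal(ape::Ntip(phy), 8L)
  expect_true(all(phy$edge.length >= 0))
  expect_true(ape::is.ultrametric(phy, tol = 1e-8))  # all tips modern
  expect_equal(sum(phy$edge.length), total_branch_length(g), tolerance = 1e-9)
  # newick round trip
  nwk <- tempfile(fileext = ".nwk")
  ape::write.tree(phy, nwk)
  back <- ape::read.tree(nwk)
  expect_equal(ape::Ntip(back), 8L)
})
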