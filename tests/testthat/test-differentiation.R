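test_that("Jukes-Cantor distance has the closed form and domain", {
  expect_equal(jukes_cantor(0), 0)
  expect_equal(jukes_cantor(0.05), -0.75 * log(1 - 4 * 0.05 / 3))
  expect_equal(round(jukes_cantor(0.05), 5), 0.05174)
  expect_error(jukes_cantor(0.75), "undefined")
  expect_error(jukes_cantor(-0.1), "non-negative")
  p <- seq(0.01, 0.7, by = 0.01)
  expect_true(all(jukes_cantor(p) >= p))
})

test_that("AMOVA equals the brute-force decomposition (two-level)", {
  set.seed(11)
  for (rep in 1:60) {
    P <- sample(2:3, 1)
    n_p <- sample(2:5, P, replace = TRUE)
    while (sum(n_p) > 12) n_p <- sample(2:5, P, replace = TRUE)
    sets <- lapply(seq_len(P), function(k)
      random_seq_set(paste0("P", k), n_p[k], 10, n_states = 2L))
    res <- amova(sets, distance = "raw")
    D <- seq_distance_matrix(sets, model = "raw")$matrix
    pop <- rep(seq_len(P), n_p)
    bf <- brute_amova2(D, pop)
    expect_equal(unname(res$components), unname(bf$sigma), tolerance = 1e-12)
    expect_equal(unname(res$phi["phi_st"]), bf$phi_st, tolerance = 1e-12)
    expect_equal(sum(res$percent), 100, tolerance = 1e-8)
    expect_equal(res$table$df[nrow(res$table)], sum(n_p) - 1L)
  }
})

test_that("AMOVA equals the brute-force decomposition (three-level)", {
  set.seed(12)
  for (rep in 1:30) {
    n_p <- sample(2:4, 4, replace = TRUE)
    sets <- lapply(1:4, function(k)
      random_seq_set(paste0("P", k), n_p[k], 10, n_states = 2L))
    grouping <- c(P1 = "g1", P2 = "g1", P3 = "g2", P4 = "g2")
    res <- amova(sets, grouping = grouping, distance = "raw")
    D <- seq_distance_matrix(sets, model = "raw")$matrix
    bf <- brute_amova3(D, rep(paste0("P", 1:4), n_p), grouping)
    expect_equal(unname(res$components), unname(bf$sigma), tolerance = 1e-12)
    expect_equal(unname(res$table$SSD[1:3]), unname(bf$ssd), tolerance = 1e-12)
    expect_equal(sum(res$table$df[1:3]), sum(n_p) - 1L)
  }
})

test_that("AMOVA sums of squares agree with vegan's adonis2 partition", {
  set.seed(13)
  sets <- lapply(1:3, function(k) random_seq_set(paste0("P", k), 5, 20))
  res <- amova(sets, distance = "raw")
  D <- seq_distance_matrix(sets, model = "raw")$matrix
  pop <- factor(rep(1:3, each = 5))
  # adonis2 operates on distances whose squares are the AMOVA squared
  # distances
  av <- vegan::adonis2(stats::as.dist(sqrt(D)) ~ pop, permutations = 0)
  expect_equal(res$table$SSD[1], av$SumOfSqs[1], tolerance = 1e-10)
  expect_equal(res$table$SSD[2], av$SumOfSqs[2], tolerance = 1e-10)
})

test_that("Phi_ST hits its boundary and degenerate values", {
  x <- aligned_sample_set("X", c(x1 = "AAAA", x2 = "AAAA"))
  y <- aligned_sample_set("Y", c(y1 = "TTAA", y2 = "TTAA"))
  expect_equal(pairwise_phi_st(x, y), 1)
  expect_equal(pairwise_phi_st(x, x), 0)  # all identical: 0/0 -> 0
  # literally duplicated composition: non-positive (estimator unclipped)
  z <- aligned_sample_set("Z", c(z1 = "AAAA", z2 = "TTAA"))
  z2 <- aligned_sample_set("Z2", c(w1 = "AAAA", w2 = "TTAA"))
  expect_lte(pairwise_phi_st(z, z2), 0)
  expect_gte(pairwise_phi_st(z, z2), -1)
  single <- aligned_sample_set("S", c(s = "AAAA"))
  expect_error(amova(list(single, y)), "merge")
})

test_that("Phi_ST is invariant to relabeling samples and bases", {
  set.seed(21)
  sets_ab <- diverged_seq_sets(c("A", "B"), c(6, 5), 40)
  a <- sets_ab[[1]]; b <- sets_ab[[2]]
  phi <- pairwise_phi_st(a, b)
  # shuffle sample order within populations
  perm <- sample(n_samples(a))
  a2 <- aligned_sample_set("A", a$seqs[perm, ], ages = a$ages[perm])
  expect_equal(pairwise_phi_st(a2, b), phi)
  # global base relabeling (A<->T, C<->G) preserves all Hamming distances
  swap <- c(A = "T", C = "G", G = "C", T = "A")
  relab <- function(s) aligned_sample_set(s$set_id,
    matrix(swap[s$seqs], nrow(s$seqs), dimnames = dimnames(s$seqs)))
  expect_equal(pairwise_phi_st(relab(a), relab(b)), phi)
})

test_that("frequency F_ST ignores molecular distance between haplotypes", {
  x <- aligned_sample_set("X", c(x1 = "AAAA", x2 = "AAAA"))
  y <- aligned_sample_set("Y", c(y1 = "TTAA", y2 = "TTAA"))
  expect_equal(frequency_f_st(x, y), 1)
  z <- aligned_sample_set("Z", c(z1 = "AAAA", z2 = "TTAA"))
  z2 <- aligned_sample_set("Z2", c(w1 = "AAAA", w2 = "TTAA"))
  expect_lte(frequency_f_st(z, z2), 0)
  # F_ST depends only on the identity partition: mutating one fixed
  # haplotype further away must not change it
  y_far <- aligned_sample_set("Y", c(y1 = "TTGG", y2 = "TTGG"))
  expect_equal(frequency_f_st(x, y), frequency_f_st(x, y_far))
})

test_that("permutation test p-values behave at the extremes and under seeds", {
  x <- aligned_sample_set("X", c(x1 = "AAAAAA", x2 = "AAAAAT",
                                 x3 = "AAAAAA", x4 = "AAAAAT"))
  y <- aligned_sample_set("Y", c(y1 = "TTAAAA", y2 = "TTAAAT",
                                 y3 = "TTAAAA", y4 = "TTAAAT"))
  pt <- permutation_test(x, y, n_perm = 200, seed = 9)
  expect_equal(pt$observed, pairwise_phi_st(x, y), tolerance = 1e-12)
  expect_gte(pt$p_value, 1 / 201)
  expect_lte(pt$p_value, 1)
  pt2 <- permutation_test(x, y, n_perm = 200, seed = 9)
  expect_identical(pt$p_value, pt2$p_value)
  expect_error(permutation_test(x, y, n_perm = 50), ">= 100")
})

test_that("Benjamini-Hochberg step-up keeps the documented rejections", {
  expect_true(all(fdr_correct(rep(0.001, 15))))
  # step-up at q = 0.05: thresholds i*q/m = (.0125, .025, .0375, .05);
  # 0.04 > 0.0375 and 0.9 > 0.05, so only ranks 1-2 are kept
  expect_equal(fdr_correct(c(0.01, 0.02, 0.04, 0.9)),
               c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(fdr_correct(c(0.01, 0.02, 0.037, 0.9)),
               c(TRUE, TRUE, TRUE, FALSE))
  expect_false(any(fdr_correct(rep(1, 5))))
  expect_error(fdr_correct(numeric(0)), "empty")
  expect_error(fdr_correct(0.5, q = 1.2), "q must")
})

test_that("pairwise differentiation table and matrix layout are consistent", {
  set.seed(23)
  sets <- diverged_seq_sets(c("A", "B", "C"), c(6, 5, 4), 25)
  pd <- pairwise_differentiation(sets, n_perm = 100, seed = 3)
  expect_equal(nrow(pd), 3L)
  expect_true(all(pd$p_value >= 0 & pd$p_value <= 1))
  m <- phi_fst_matrix(pd)
  expect_equal(dim(m), c(3L, 3L))
  expect_true(all(is.na(diag(m))))
  # lower triangle = Phi_ST, upper = F_ST
  expect_equal(m["B", "A"], pd$phi_st[pd$set_a == "A" & pd$set_b == "B"])
  expect_equal(m["A", "B"], pd$f_st[pd$set_a == "A" & pd$set_b == "B"])
})

test_that("pairwise site deletion keeps per-pair comparable sites", {
  # N at site 2 of b: complete deletion drops the column for everyone;
  # pairwise deletion only excludes it for pairs involving b
  hm <- rbind(strsplit("ACGT", "")[[1]],
              strsplit("ANGT", "")[[1]],
              strsplit("ACGA", "")[[1]])
  D_pw <- icefloe:::hap_sq_dist(hm, "jc", pairwise_deletion = TRUE)
  expect_equal(D_pw[1, 2], 0)                       # identical on 3 shared sites
  expect_equal(D_pw[2, 3], jukes_cantor(1 / 3) * 3) # 1 of 3 shared sites
  expect_equal(D_pw[1, 3], jukes_cantor(1 / 4) * 4) # all 4 sites compared
  a <- aligned_sample_set("A", c(a1 = "ACGT", a2 = "ANGT"))
  b <- aligned_sample_set("B", c(b1 = "ACGA", b2 = "ACGA"))
  phi <- pairwise_phi_st(a, b, site_policy = "pairwise")
  expect_true(is.finite(phi))
})
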