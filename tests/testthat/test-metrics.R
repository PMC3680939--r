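# Module-level statistics: co-expression nulls, NACC and its tests,
# activity scores, conservation and dichotomization.

simple_dataset <- function(G = 50, n = 40, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(rnorm(G * n), G, n,
                dimnames = list(sprintf("g%03d", 1:G), sprintf("s%03d", 1:n)))
    expression_dataset("D1", m)
  })
}

test_that("module co-expression equals the mean pairwise correlation", {
  ds <- simple_dataset()
  # genes with identical values: mean r = 1
  ds$values["g002", ] <- ds$values["g001", ]
  ds$values["g003", ] <- ds$values["g001", ]
  mod <- gene_module("ident", c("g001", "g002", "g003"))
  res <- module_coexpression(mod, ds, n_random = 0)
  expect_equal(res$mean_pairwise_r, 1)
  # two-gene module: summary is that single pair's correlation
  pair <- gene_module("pair", c("g010", "g011"))
  res2 <- module_coexpression(pair, ds, n_random = 0)
  expect_equal(res2$mean_pairwise_r,
               cor(ds$values["g010", ], ds$values["g011", ]))
  expect_error(module_coexpression(gene_module("gone", c("nope1", "nope2")), ds),
               "missing")
})

test_that("co-expression empirical p is add-one corrected and null-uniform", {
  ds <- simple_dataset(G = 80, n = 30, seed = 3)
  mod <- gene_module("m", sprintf("g%03d", 1:5))
  res <- module_coexpression(mod, ds, n_random = 99, seed = 2)
  expect_equal(res$empirical_p,
               (1 + sum(res$null_mean_r >= res$mean_pairwise_r)) / 100)
  expect_gt(res$empirical_p, 0)
  # under the null (random module in independent data) p is uniform
  ps <- withr::with_seed(8, {
    sapply(1:200, function(i) {
      genes <- sample(rownames(ds$values), 5)
      module_coexpression(gene_module("r", genes), ds,
                          n_random = 60, seed = i)$empirical_p
    })
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
  expect_lt(abs(mean(ps) - 0.5), 0.1)
})

test_that("nacc counts qualifying pairs over possible pairs", {
  genes <- sprintf("g%d", 1:5)
  w <- matrix(NA_real_, 5, 5, dimnames = list(genes, genes))
  w[upper.tri(w)] <- 0.1
  # make exactly 4 pairs qualify at cutoff 0.5
  w[1, 2] <- w[1, 3] <- w[2, 3] <- w[4, 5] <- 0.9
  w[lower.tri(w)] <- t(w)[lower.tri(w)]
  expect_equal(nacc(genes, w, 0.5), 0.4)         # 4 of 10
  expect_equal(nacc(genes[1:3], w, 0.5), 1)       # all 3 pairs qualify
  expect_equal(nacc(genes, w, 0.95), 0)           # none qualify
  expect_error(nacc("g1", w, 0.5), "at least 2")
  expect_error(nacc(c("g1", "zz"), w, 0.5), "absent")
})

test_that("nacc equals a brute-force pair count on random fixtures", {
  withr::with_seed(21, {
    for (i in 1:30) {
      w <- random_weight_matrix(12, p_na = runif(1, 0.1, 0.6))
      genes <- sample(rownames(w), sample(2:8, 1))
      cutoff <- runif(1, 0.1, 0.9)
      expect_equal(nacc(genes, w, cutoff), brute_nacc(genes, w, cutoff))
    }
  })
})

test_that("nacc profiles are non-increasing and cross-only counts A-B pairs", {
  gA <- c("a1", "a2", "a3"); gB <- c("b1", "b2", "b3")
  genes <- c(gA, gB)
  w <- matrix(0.8, 6, 6, dimnames = list(genes, genes))
  diag(w) <- NA_real_
  prof <- nacc_profile(gA, gB, w, combine_mode = "cross_only")
  expect_equal(prof$nacc, rep(1, 5))  # all 9 cross pairs qualify everywhere
  # union mode counts all 15 pairs of the combined set
  w["a1", "a2"] <- w["a2", "a1"] <- 0.1
  prof_u <- nacc_profile(gA, gB, w, combine_mode = "union")
  expect_equal(prof_u$nacc[1], 14 / 15)
  # cross-only unaffected by a within-A change
  expect_equal(nacc_profile(gA, gB, w, combine_mode = "cross_only")$nacc[1], 1)
  expect_error(nacc_profile(gA, c("a1", "b1"), w, combine_mode = "cross_only"),
               "overlap")
  # monotone non-increasing for arbitrary random inputs
  withr::with_seed(31, {
    for (i in 1:10) {
      wr <- random_weight_matrix(15, p_na = 0.3)
      genes <- sample(rownames(wr), 6)
      p <- nacc_profile(genes[1:3], genes[4:6], wr, combine_mode = "cross_only")
      expect_true(all(diff(p$nacc) <= 0))
      p2 <- nacc_profile(genes, NULL, wr)
      expect_true(all(diff(p2$nacc) <= 0))
    }
  })
})

test_that("planted cross-module coupling shows up in cross-only NACC", {
  mk <- function(tau, seed) {
    cfg <- synthetic_cohort_config(
      n_datasets = 2, samples_per_dataset = 200, n_genes = 80,
      modules = data.frame(size = c(15, 15), rho = c(0.8, 0.8)),
      cross_couplings = if (tau > 0)
        data.frame(module_i = 1, module_j = 2, tau_base = tau, tau_alt = tau),
      alt_fraction = 0, seed = seed)
    generate_cohort(cfg)
  }
  coupled <- mk(0.7, 41)
  uncoupled <- mk(0, 42)
  nacc_at <- function(sim) {
    corr <- sample_correlation(pool_cohort(sim$cohort))
    nacc_cross_profile <- nacc_profile(sim$truth$module_genes[[1]],
                                       sim$truth$module_genes[[2]],
                                       corr, cutoffs = c(0.5),
                                       combine_mode = "cross_only")
    nacc_cross_profile$nacc[1]
  }
  # tau = 0.7 -> expected cross-gene r = 0.7 * 0.8 = 0.56 > 0.5 for most pairs
  expect_gt(nacc_at(coupled), 0.5)
  expect_lt(nacc_at(uncoupled), 0.05)
})

test_that("subgroup NACC test is seeded and calibrated against its null", {
  sim <- generate_cohort(synthetic_cohort_config(
    n_datasets = 2, samples_per_dataset = 100, n_genes = 60,
    modules = data.frame(size = c(12, 12), rho = c(0.8, 0.8)),
    alt_fraction = 0, seed = 17))
  samples <- colnames(pool_cohort(sim$cohort))
  small <- samples[1:40]; large <- samples[41:200]
  gA <- sim$truth$module_genes[[1]]; gB <- sim$truth$module_genes[[2]]
  r1 <- subgroup_nacc_test(gA, gB, sim$cohort, small, large,
                           cutoffs = c(0.3, 0.5), n_resample = 50, seed = 6,
                           combine_mode = "cross_only")
  r2 <- subgroup_nacc_test(gA, gB, sim$cohort, small, large,
                           cutoffs = c(0.3, 0.5), n_resample = 50, seed = 6,
                           combine_mode = "cross_only")
  expect_identical(r1$p_values, r2$p_values)
  expect_length(r1$p_values, 2L)
  expect_true(all(r1$p_values > 0 & r1$p_values <= 1))
  expect_length(r1$null_mean, 2L)
  expect_error(subgroup_nacc_test(gA, gB, sim$cohort, samples[1:150],
                                  samples[151:200], n_resample = 10),
               "larger")
})

test_that("covariate-dependent coupling is detected, absent coupling is not", {
  cfg <- synthetic_cohort_config(
    n_datasets = 2, samples_per_dataset = 200, n_genes = 60,
    modules = data.frame(size = c(15, 15), rho = c(0.8, 0.8)),
    cross_couplings = data.frame(module_i = 1, module_j = 2,
                                 tau_base = 0, tau_alt = 0.8),
    alt_fraction = 0.25, seed = 55)
  sim <- generate_cohort(cfg)
  ann <- pool_annotations(sim$cohort)
  mut <- ann$sample_id[ann$tp53_status == "mutant"]
  wt <- ann$sample_id[ann$tp53_status == "wildtype"]
  res <- subgroup_nacc_test(sim$truth$module_genes[[1]],
                            sim$truth$module_genes[[2]],
                            sim$cohort, mut, wt,
                            cutoffs = c(0.3, 0.4, 0.5, 0.6),
                            n_resample = 200, seed = 7,
                            combine_mode = "cross_only")
  expect_true(all(res$p_values < 0.05))
  # the mutant-sample interconnectivity exceeds the wildtype null band
  expect_true(all(res$nacc > res$null_mean + 2 * res$null_sd))
})

test_that("quartile NACC splits evenly and tracks a coupling gradient", {
  ds <- simple_dataset(G = 40, n = 37, seed = 5)
  out <- quartile_nacc(sprintf("g%03d", 1:5), sprintf("g%03d", 6:10),
                       ds, "g020", cutoffs = c(0.3, 0.5))
  sizes <- lengths(out$quartile_samples)
  expect_equal(sum(sizes), 37L)
  expect_lte(diff(range(sizes)), 1L)
  expect_length(out$quartiles, 4L)
  expect_s3_class(out$reference, "NACCProfile")
  expect_error(quartile_nacc(sprintf("g%03d", 1:5), sprintf("g%03d", 6:10),
                             ds, "missing_gene"), "not present")
  # gradient scenario: coupling only in low-stratifier samples.  Build a
  # dataset by concatenating coupled (alt) and uncoupled samples and a
  # stratifier gene lower in the coupled half.
  cfg <- synthetic_cohort_config(
    n_datasets = 2, samples_per_dataset = 120, n_genes = 50,
    modules = data.frame(size = c(10, 10), rho = c(0.85, 0.85)),
    cross_couplings = data.frame(module_i = 1, module_j = 2,
                                 tau_base = 0, tau_alt = 0.85),
    alt_fraction = 0.5, seed = 66)
  sim <- generate_cohort(cfg)
  pooled <- pool_cohort(sim$cohort)
  strat <- ifelse(sim$truth$covariate[colnames(pooled)] == "mutant",
                  rnorm(ncol(pooled), -2), rnorm(ncol(pooled), 2))
  pooled <- rbind(pooled, strat = strat)
  ds2 <- expression_dataset("mix", pooled)
  out2 <- quartile_nacc(sim$truth$module_genes[[1]],
                        sim$truth$module_genes[[2]],
                        ds2, "strat", cutoffs = c(0.4, 0.5),
                        combine_mode = "cross_only")
  # lowest quartile (coupled samples) far more interconnected than highest
  expect_gt(out2$quartiles[[1]]$nacc[1], out2$quartiles[[4]]$nacc[1] + 0.3)
})

test_that("rank-mean activity scores behave like per-sample mean ranks", {
  ds <- simple_dataset(G = 30, n = 10, seed = 2)
  all_mod <- gene_module("all", rownames(ds$values))
  sc <- activity_scores(all_mod, ds)
  # module = all genes: score = (G+1)/(2G) in every sample
  expect_equal(unname(sc$scores["all", ]), rep(31 / 60, 10))
  # monotone transform of one sample leaves its scores unchanged
  mod <- gene_module("m", rownames(ds$values)[1:8])
  s1 <- activity_scores(mod, ds)
  ds2 <- ds
  ds2$values[, 3] <- exp(2 * ds2$values[, 3]) + 5
  s2 <- activity_scores(mod, ds2)
  expect_identical(s1$scores[, 3], s2$scores[, 3])
  # gene order within the module is irrelevant
  s3 <- activity_scores(gene_module("m", rev(mod$gene_ids)), ds)
  expect_equal(unname(s1$scores), unname(s3$scores))
  # scores live in (0, 1]
  expect_true(all(s1$scores > 0 & s1$scores <= 1))
  # expression_sum mode: plain per-sample sums
  s4 <- activity_scores(mod, ds, mode = "expression_sum")
  expect_equal(unname(s4$scores["m", ]),
               unname(colSums(ds$values[mod$gene_ids, ])))
  # <50% present genes is an error; >=50% scores the present subset
  sparse <- gene_module("h", c(rownames(ds$values)[1:2],
                               "zz1", "zz2", "zz3", "zz4"))
  expect_error(activity_scores(sparse, ds), "50%")
  most <- gene_module("p", c(rownames(ds$values)[1:5], "zz1"))
  expect_warning(s5 <- activity_scores(most, ds), "5/6")
  expect_equal(s5$n_genes_used, 5L)
})

test_that("activity scores recover planted per-sample module amplitudes", {
  sim <- generate_cohort(synthetic_cohort_config(
    n_datasets = 1, samples_per_dataset = 200, n_genes = 500,
    modules = data.frame(size = 20, rho = 0.8), seed = 12))
  mod <- gene_module("m1", sim$truth$module_genes[[1]])
  sc <- activity_scores(mod, sim$cohort)
  amplitude <- sim$truth$factors[colnames(sc$scores), 1]
  expect_gt(cor(sc$scores["m1", ], amplitude, method = "spearman"), 0.9)
})

test_that("gene-module Spearman correlation matches a rank oracle", {
  sim <- generate_cohort(synthetic_cohort_config(
    n_datasets = 1, samples_per_dataset = 150, n_genes = 200,
    modules = data.frame(size = 15, rho = 0.8), seed = 23))
  ds <- sim$cohort$datasets[[1]]
  mod <- gene_module("m1", sim$truth$module_genes[[1]])
  sc <- activity_scores(mod, ds)
  # a monotone transform of the score vector correlates perfectly
  ds_t <- ds
  ds_t$values["g0200", ] <- exp(sc$scores["m1", ])
  expect_equal(gene_module_correlation(sc, "m1", "g0200", ds_t), 1)
  # an independent background gene correlates near zero
  rho_bg <- gene_module_correlation(sc, "m1", "g0150", ds)
  expect_lt(abs(rho_bg), 0.25)
  # a gene loaded on the module factor: positive rho, equal to the oracle
  rho_loaded <- gene_module_correlation(sc, "m1", "g0001", ds)
  oracle <- cor(rank(sc$scores["m1", ]), rank(ds$values["g0001", ]))
  expect_equal(rho_loaded, oracle)
  expect_gt(rho_loaded, 0.5)
  # constant gene is flagged
  ds$values["g0199", ] <- 1
  expect_error(gene_module_correlation(sc, "m1", "g0199", ds), "constant")
})

test_that("conserved cores keep only edges present in both matrices", {
  genes <- sprintf("g%d", 1:6)
  w1 <- matrix(0.9, 6, 6, dimnames = list(genes, genes)); diag(w1) <- NA
  mod <- gene_module("m", genes)
  # identical matrices: the whole module is the core
  cc <- module_conservation(mod, w1, w1, 0.5)
  expect_setequal(cc$core_genes, genes)
  # no conserved edges: empty core
  w2 <- matrix(0.1, 6, 6, dimnames = list(genes, genes)); diag(w2) <- NA
  cc2 <- module_conservation(mod, w1, w2, 0.5)
  expect_length(cc2$core_genes, 0L)
  expect_equal(nrow(cc2$conserved_edges), 0L)
  # partial conservation: only a sub-block correlated in the second matrix
  w3 <- w2
  w3[1:3, 1:3] <- 0.9; diag(w3) <- NA
  cc3 <- module_conservation(mod, w1, w3, 0.5)
  expect_setequal(cc3$core_genes, genes[1:3])
  # genes absent from one matrix are dropped with a warning
  w4 <- w1[1:5, 1:5]
  expect_warning(cc4 <- module_conservation(mod, w1, w4, 0.5), "absent")
  expect_setequal(cc4$core_genes, genes[1:5])
})

test_that("planted two-cohort scenario yields exactly the shared core", {
  # 20-gene module in the source cohort; only 5 of those genes share a
  # factor in the second cohort
  src <- generate_cohort(synthetic_cohort_config(
    n_datasets = 2, samples_per_dataset = 150, n_genes = 100,
    modules = data.frame(size = 20, rho = 0.8), seed = 71))
  oth <- generate_cohort(synthetic_cohort_config(
    n_datasets = 2, samples_per_dataset = 150, n_genes = 100,
    modules = data.frame(size = 5, rho = 0.8), seed = 72))
  mod <- gene_module("source", src$truth$module_genes[[1]])
  core_truth <- oth$truth$module_genes[[1]]  # g0001..g0005
  corr_src <- loo_min_correlation(src$cohort)
  corr_oth <- loo_min_correlation(oth$cohort)
  cc <- module_conservation(mod, corr_src, corr_oth, 0.5)
  expect_setequal(cc$core_genes, core_truth)
})

test_that("dichotomization labels samples against the module mean", {
  sc <- structure(list(scores = matrix(c(1, 2, 3), 1,
                                       dimnames = list("m", c("s1", "s2", "s3"))),
                       scoring_mode = "rank_mean", n_genes_used = 3L),
                  class = "ModuleActivityScores")
  expect_equal(unname(dichotomize_scores(sc, "m")),
               c("below", "below", "above"))
  # all-equal scores: everything "below" (strict >)
  sc$scores[] <- 5
  expect_equal(unname(dichotomize_scores(sc, "m")), rep("below", 3))
  # affine invariance
  sc$scores <- matrix(c(1, 2, 3), 1, dimnames = list("m", c("s1", "s2", "s3")))
  sc2 <- sc; sc2$scores <- 10 * sc$scores + 7
  expect_identical(dichotomize_scores(sc, "m"), dichotomize_scores(sc2, "m"))
  expect_error(dichotomize_scores(sc, "nope"), "unknown module")
})
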