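test_that("generation is deterministic for a fixed spec and seed", {
  spec <- cohort_spec(n_modules = 3, module_size = 4, n_background = 20,
                      n_samples = 50, n_pairs = 12, seed = 77)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a$abundance$values, b$abundance$values)
  expect_identical(a$abundance$mask, b$abundance$mask)
  expect_identical(unclass(a$terms), unclass(b$terms))
  expect_identical(a$pairs, b$pairs)
  c <- generate_cohort(cohort_spec(n_modules = 3, module_size = 4,
                                   n_background = 20, n_samples = 50,
                                   n_pairs = 12, seed = 78))
  expect_false(identical(a$abundance$values, c$abundance$values))
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(generate_cohort(cohort_spec(n_modules = 1, module_size = 2,
                                        n_background = 2, n_samples = 10,
                                        n_pairs = 0, n_decoy_terms = 0,
                                        seed = 5)))
  expect_identical(runif(1), before)
})

test_that("copula calibration hits the target within-module Spearman", {
  spec <- cohort_spec(n_modules = 1, module_size = 10, rho_within = 0.6,
                      n_background = 0, n_samples = 2000,
                      missing = list(type = "none"),
                      n_decoy_terms = 0, n_pairs = 0, seed = 101)
  cm <- spearman_matrix(generate_cohort(spec)$abundance)
  within <- cm$rho[upper.tri(cm$rho)]
  expect_lt(abs(mean(within) - 0.6), 0.03)
})

test_that("a module-free cohort is null: off-diagonal correlations near zero", {
  spec <- cohort_spec(n_modules = 0, n_background = 200, n_samples = 300,
                      missing = list(type = "none"), n_decoy_terms = 0,
                      n_pairs = 0, seed = 55)
  cm <- spearman_matrix(generate_cohort(spec)$abundance)
  expect_lte(mean(abs(cm$rho[upper.tri(cm$rho)])), 0.05)
})

test_that("term map and pair list reflect the planted structure", {
  co <- generate_cohort(cohort_spec(n_modules = 4, module_size = 6,
                                    n_background = 40, n_samples = 30,
                                    n_decoy_terms = 7, decoy_size = 6,
                                    n_pairs = 60, within_fraction = 0.75,
                                    seed = 8))
  mod_terms <- co$terms[startsWith(names(co$terms), "MOD")]
  expect_identical(unname(lapply(mod_terms, sort)),
                   unname(lapply(co$truth$module_members, sort)))
  expect_equal(sum(startsWith(names(co$terms), "RND")), 7L)
  expect_equal(nrow(co$pairs), 60L)
  expect_equal(sum(co$truth$pair_within), round(60 * 0.75))
  # pair truth agrees with module membership
  mo <- co$truth$module
  ma <- mo[co$pairs$gene_a]; mb <- mo[co$pairs$gene_b]
  same <- !is.na(ma) & !is.na(mb) & ma == mb
  expect_identical(unname(same), co$truth$pair_within)
})

test_that("uniform and abundance-dependent missingness behave as configured", {
  u <- generate_cohort(cohort_spec(n_modules = 0, n_background = 100,
                                   n_samples = 200,
                                   missing = list(type = "uniform", rate = 0.1),
                                   n_decoy_terms = 0, n_pairs = 0, seed = 3))
  rate <- mean(u$abundance$mask)
  expect_lt(abs(rate - 0.1), 3 * sqrt(0.1 * 0.9 / (100 * 200)) + 1e-3)
  # abundance-dependent: missingness concentrates in low-intensity proteins
  a <- generate_cohort(cohort_spec(n_modules = 0, n_background = 100,
                                   n_samples = 200, seed = 3))
  miss_by_prot <- rowMeans(a$abundance$mask)
  mu_proxy <- apply(a$abundance$values, 1, stats::median, na.rm = TRUE)
  expect_lt(stats::cor(mu_proxy, miss_by_prot, method = "spearman",
                       use = "complete.obs"), -0.5)
})

test_that("noiseless depletion is exact; null depletion is centred", {
  g <- generate_depletion(30, 5, fold = 1.74, noise_sd = 0, seed = 1)
  L <- log2(g$experiment$intensities)
  lfc <- rowMeans(L[, 1:4]) - rowMeans(L[, 5:8])
  expect_equal(unname(lfc[g$members]), rep(log2(1.74), 5), tolerance = 1e-12)
  expect_equal(unname(lfc[setdiff(rownames(L), g$members)]), rep(0, 25),
               tolerance = 1e-12)
  g0 <- generate_depletion(200, 0, fold = 1, noise_sd = 0.2, seed = 2)
  d0 <- differential_abundance(g0$experiment)
  expect_lt(abs(mean(d0$log2fc)), 0.05)
  expect_error(generate_depletion(5, 6), "set_size")
})

test_that("sparsity panel detection follows its binomial model", {
  full <- generate_sparsity_panel(50, c(A = 0, B = 1), seed = 4)
  expect_true(all(full$mask["A", ]))
  expect_false(any(full$mask["B", ]))
  p <- 69 / 1172
  sp <- generate_sparsity_panel(1172, c(X = p), seed = 10)
  detected <- sum(!sp$mask["X", ])
  expect_lt(abs(detected - 1172 * p), 3 * sqrt(1172 * p * (1 - p)))
  expect_error(generate_sparsity_panel(10, c(A = 1.2)), "probabilities")
})

test_that("an emitted cohort re-reads to exactly the generated truth", {
  co <- generate_cohort(cohort_spec(n_modules = 2, module_size = 3,
                                    n_background = 10, n_samples = 25,
                                    n_decoy_terms = 3, n_pairs = 7,
                                    within_fraction = 0.7, seed = 42))
  dir <- tempfile()
  write_cohort(co, dir)
  ab <- read_abundance_table(file.path(dir, "abundance.tsv"))
  expect_identical(ab$values, co$abundance$values)
  expect_identical(ab$mask, co$abundance$mask)
  tm <- read_term_map(file.path(dir, "terms.tsv"))
  expect_identical(unclass(tm)[sort(names(tm))],
                   lapply(unclass(co$terms), sort)[sort(names(co$terms))])
  ps <- read_pair_list(file.path(dir, "pairs.csv"))
  expect_identical(ps, co$pairs)
  tr <- read.delim(file.path(dir, "truth_modules.tsv"))
  expect_identical(tr$protein_id, names(co$truth$module))
  expect_identical(tr$module, unname(co$truth$module))
})

test_that("infeasible specs are rejected", {
  expect_error(cohort_spec(n_modules = 1, module_size = 1), ">= 2")
  expect_error(cohort_spec(rho_within = 1), "rho_within")
  expect_error(cohort_spec(n_samples = 1), "2 samples")
  expect_error(cohort_spec(missing = list(type = "uniform", rate = 1)),
               "rate")
})
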