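test_that("comimic pair enumeration counts within-ring pairs", {
  r4 <- setNames(c("x", "x", "y", "y"), paste0("s", 1:4))
  expect_equal(nrow(comimic_pairs(r4)), 2L)
  r1 <- setNames(rep("x", 4), paste0("s", 1:4))
  expect_equal(nrow(comimic_pairs(r1)), 6L)
  expect_warning(comimic_pairs(setNames(c("x", "x", "y"), paste0("s", 1:3))),
                 "singleton")
})

test_that("similarity test is exact for extreme and degenerate layouts", {
  sp <- paste0("s", 1:8)
  rings <- setNames(rep(c("a", "b", "c", "d"), each = 2), sp)
  # co-mimetic pairs carry the k smallest distances -> floor p
  pf_pairs <- utils::combn(sort(sp), 2)
  comim <- rings[pf_pairs[1, ]] == rings[pf_pairs[2, ]]
  vals <- numeric(ncol(pf_pairs))
  vals[comim] <- seq(0.01, 0.04, length.out = sum(comim))
  vals[!comim] <- seq(1, 2, length.out = sum(!comim))
  d <- dist_from_pairs(sort(sp), vals)
  res <- similarity_test(d, rings, n_rand = 199, seed = 1)
  expect_equal(res$p_plus_one, 1 / 200)
  # all-equal distances: observed equals every null mean, ties give p = 1
  d1 <- dist_from_pairs(sort(sp), rep(0.5, 28))
  res1 <- similarity_test(d1, rings, n_rand = 99, seed = 2)
  expect_equal(res1$p_plus_one, 1)
  expect_error(similarity_test(d, rings, ring = "missing"),
               "fewer than 2|has fewer")
})

test_that("similarity test is invariant to adding a constant to distances", {
  set.seed(91)
  sp <- paste0("s", 1:10)
  rings <- setNames(rep(c("a", "b"), each = 5), sp)
  d <- dist_from_pairs(sp, runif(45))
  r1 <- similarity_test(d, rings, n_rand = 199, seed = 7)
  r2 <- similarity_test(d + 10 - diag(10, 10), rings, n_rand = 199, seed = 7)
  expect_equal(r1$p_raw, r2$p_raw)
  expect_equal(r2$observed - r1$observed, 10)
})

test_that("phylogeny-corrected test behaves at the perfect-fit boundary", {
  tr <- simulate_tree(12, seed = 95)
  pd <- patristic_distances(tr)
  rings <- setNames(rep(c("a", "b", "c"), each = 4), tr$tip.label)
  # phenotypic distance exactly linear in phylogenetic distance
  d <- 0.3 + 2 * pd; diag(d) <- 0
  res <- phylo_corrected_test(d, pd, rings, n_rand = 199, seed = 1)
  expect_equal(res$observed, 0, tolerance = 1e-10)
  expect_gt(res$p_plus_one, 0.5)  # ties resolve non-significant
})

test_that("OLS residuals of the pairwise regression sum to zero", {
  set.seed(97)
  tr <- simulate_tree(15, seed = 97)
  pd <- patristic_distances(tr)
  rings <- setNames(rep(c("a", "b", "c"), each = 5), tr$tip.label)
  d <- dist_from_pairs(tr$tip.label, runif(choose(15, 2)))
  res <- phylo_corrected_test(d[tr$tip.label, tr$tip.label], pd, rings,
                              n_rand = 9, seed = 1)
  # reconstruct residuals exactly as the test does
  pairs <- utils::combn(sort(tr$tip.label), 2)
  y <- d[cbind(pairs[1, ], pairs[2, ])]
  x <- pd[cbind(pairs[1, ], pairs[2, ])]
  r <- stats::residuals(stats::lm(y ~ x))
  expect_lt(abs(sum(r)), 1e-10)
  expect_equal(attr(res, "slope"), unname(coef(stats::lm(y ~ x))[2]),
               tolerance = 1e-10)
})

test_that("sharing tests count co-mimetic pairs with the same level", {
  sp <- paste0("s", 1:8)
  rings <- setNames(rep(c("a", "b"), each = 4), sp)
  # trait identical within rings, distinct between -> floor p
  tr1 <- setNames(rep(c("LF", "P"), each = 4), sp)
  res <- sharing_similarity_test(tr1, rings, n_rand = 199, seed = 1)
  expect_equal(res$observed, 12)  # 2 rings x C(4,2)
  expect_equal(res$p_plus_one, 1 / 200)
  # constant trait: degenerate, p = 1 with a warning
  expect_warning(
    resc <- sharing_similarity_test(setNames(rep("LF", 8), sp), rings,
                                    n_rand = 99, seed = 2),
    "constant")
  expect_equal(resc$p_raw, 1)
})

test_that("sharing convergence test flags complete separation", {
  tr <- simulate_tree(10, seed = 99)
  pd <- patristic_distances(tr)
  rings <- setNames(rep(c("a", "b"), each = 5), tr$tip.label)
  res <- sharing_convergence_test(setNames(rep("LF", 10), tr$tip.label),
                                  pd, rings, n_rand = 99, seed = 1)
  expect_equal(res$flag, "complete separation")
  expect_true(is.na(res$p_plus_one))
})

test_that("density convergence test reaches the floor for ring-constant
           densities", {
  tr <- simulate_tree(20, seed = 103)
  pd <- patristic_distances(tr)
  rings <- setNames(rep(paste0("r", 1:4), each = 5), tr$tip.label)
  set.seed(7)
  dens <- setNames(as.numeric(factor(rings)) * 10 + rnorm(20, 0, 0.01),
                   names(rings))
  res <- density_convergence_test(dens, pd, rings, n_rand = 199, seed = 1)
  expect_equal(res$similarity$p_plus_one, 1 / 200)
  expect_s3_class(res$convergence, "perm_test")
})

test_that("Holm adjustment matches the hand-computed example and dominates", {
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm_adjust(0.2), 0.2)
  expect_identical(holm_adjust(numeric(0)), numeric(0))
  set.seed(11)
  p <- runif(20)
  h <- holm_adjust(p)
  expect_true(all(h >= p) && all(h <= 1))
})

test_that("p-values are uniform when pair values carry no shared-species
           structure", {
  # with iid pair values every pair subset behaves like a uniform random
  # subset, the case in which the randomisation is exact
  set.seed(113)
  sp <- sprintf("s%02d", 1:20)
  pvals <- replicate(300, {
    rings <- setNames(sample(rep(letters[1:4], each = 5)), sp)
    d <- dist_from_pairs(sp, runif(choose(20, 2)))
    similarity_test(d, rings, n_rand = 99,
                    seed = sample.int(1e6, 1))$p_raw
  })
  # p values sit on the discrete (c/99) grid, so silence the ties warning
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_gt(mean(pvals <= 0.1), 0.05)
})

test_that("the suite produces the full bookkeeping of test rows", {
  b <- generate_study(study_config(n_species = 16,
                                   ring_sizes = setNames(rep(4, 4),
                                                         paste0("r", 1:4)),
                                   spots_per_species = 2, seed = 5))
  pd <- patristic_distances(b$tree)
  systems <- list(generate_sensitivity_set("UVS"),
                  generate_sensitivity_set("VS"))
  illums <- list(generate_illuminant("forest_shade"),
                 generate_illuminant("large_gap"))
  contrasts <- list()
  for (vs in systems) for (il in illums) for (sp in 1:2) {
    sel <- Filter(function(s) s$spot_id == sp, b$spectra)
    contrasts[[length(contrasts) + 1L]] <- contrast_matrix(sel, il, vs)
  }
  suite <- run_convergence_suite(contrasts, phylo_d = pd, rings = b$rings,
                                 n_rand = 49, seed = 3, per_ring = FALSE)
  # 2 spots x 2 layers x 4 models x 2 corrections -> 32 global rows
  expect_equal(nrow(suite), 32L)
  expect_true(all(suite$scope == "global"))
  expect_true(all(suite$p_holm >= suite$p_plus_one - 1e-12, na.rm = TRUE))
  expect_true(all(suite$p_plus_one >= 1 / 50))
})

test_that("suite results are reproducible from the master seed", {
  b <- generate_study(five_ring_config(seed = 21, alpha = 3, n_species = 20))
  pd <- patristic_distances(b$tree)
  ct <- list(contrast_matrix(b$spectra, generate_illuminant("large_gap"),
                             generate_sensitivity_set("UVS")))
  s1 <- run_convergence_suite(ct, phylo_d = pd, rings = b$rings,
                              n_rand = 99, seed = 13)
  s2 <- run_convergence_suite(ct, phylo_d = pd, rings = b$rings,
                              n_rand = 99, seed = 13)
  expect_identical(s1$p_plus_one, s2$p_plus_one)
  expect_identical(s1$observed, s2$observed)
})
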