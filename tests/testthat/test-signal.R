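test_that("Pagel's lambda recovers the generating signal level", {
  set.seed(31)
  lam_bm <- replicate(30, {
    tr <- simulate_tree(80)
    pagel_lambda(tr, simulate_bm(tr))$estimate
  })
  lam_iid <- replicate(30, {
    tr <- simulate_tree(80)
    pagel_lambda(tr, setNames(rnorm(80), tr$tip.label))$estimate
  })
  expect_gt(mean(lam_bm > 0.9), 0.85)
  expect_gt(mean(lam_iid < 0.1), 0.85)
  # intermediate lambda recovered on average
  lam_half <- replicate(40, {
    tr <- simulate_tree(96)
    C <- lambda_transform(phylo_vcv(tr), 0.5)
    x <- setNames(drop(crossprod(chol(C + diag(1e-10, 96)), rnorm(96))),
                  tr$tip.label)
    pagel_lambda(tr, x)$estimate
  })
  expect_lt(abs(mean(lam_half) - 0.5), 0.15)
})

test_that("lambda handles degenerate inputs", {
  st <- star_tree(10)
  res <- pagel_lambda(st, setNames(rnorm(10), st$tip.label))
  expect_equal(res$estimate, 0)
  expect_equal(res$p_value, 1)
  expect_true(res$degenerate)
  tr <- simulate_tree(10, seed = 2)
  expect_error(pagel_lambda(tr, setNames(rep(1, 10), tr$tip.label)),
               "variance")
})

test_that("lambda and K are invariant to affine transformation", {
  tr <- simulate_tree(32, seed = 5)
  x <- simulate_bm(tr, seed = 6)
  for (f in list(function(z) 3 * z - 7, function(z) -0.2 * z + 100)) {
    expect_equal(pagel_lambda(tr, f(x))$estimate,
                 pagel_lambda(tr, x)$estimate, tolerance = 1e-8)
    expect_equal(blomberg_k(tr, f(x), n_perm = 3, seed = 1)$estimate,
                 blomberg_k(tr, x, n_perm = 3, seed = 1)$estimate,
                 tolerance = 1e-8)
  }
})

test_that("Blomberg's K is calibrated at 1 under Brownian motion", {
  set.seed(41)
  kv <- replicate(60, {
    tr <- simulate_tree(64)
    blomberg_k(tr, simulate_bm(tr), n_perm = 19)$estimate
  })
  expect_gt(mean(kv), 0.85); expect_lt(mean(kv), 1.15)
  # shuffled data: K well below 1 and usually non-significant
  tr <- simulate_tree(64, seed = 42)
  res <- replicate(30, {
    x <- simulate_bm(tr)
    r <- blomberg_k(tr, setNames(sample(x), names(x)), n_perm = 99)
    c(r$estimate, r$p_value)
  })
  expect_lt(mean(res[1, ]), 0.5)
  expect_gt(mean(res[2, ] > 0.05), 0.8)
  # star tree: defined value, degenerate flag
  st <- star_tree(12)
  rs <- blomberg_k(st, setNames(rnorm(12), st$tip.label), n_perm = 9,
                   seed = 1)
  expect_true(is.finite(rs$estimate))
  expect_equal(rs$estimate, 1, tolerance = 1e-8)
  expect_true(rs$degenerate)
})

test_that("delta separates clade-structured from shuffled traits", {
  tr <- simulate_tree(40, seed = 51)
  clade_tips <- NULL
  for (nd in 41:(40 + tr$Nnode)) {
    tps <- ape::extract.clade(tr, nd)$tip.label
    if (length(tps) %in% 12:20) { clade_tips <- tps; break }
  }
  states <- setNames(ifelse(tr$tip.label %in% clade_tips, "A", "B"),
                     tr$tip.label)
  mc <- list(iterations = 3000, burn_in = 0.1, thinning = 5)
  obs <- delta_categorical(tr, states, mcmc = mc, n_rand = 19, seed = 1)
  expect_lte(obs$p_value, 0.05)
  expect_gt(obs$estimate, obs$null_mean)
  shuf <- delta_categorical(tr, setNames(sample(states), tr$tip.label),
                            mcmc = mc, n_rand = 19, seed = 2)
  expect_gt(shuf$p_value, 0.05)
  # boundary sanity: constant but one tip still yields a finite delta
  one_off <- setNames(c("A", rep("B", 39)), tr$tip.label)
  res <- delta_categorical(tr, one_off, mcmc = mc, n_rand = 4, seed = 3)
  expect_true(is.finite(res$estimate))
  expect_error(delta_categorical(tr, setNames(rep("A", 40), tr$tip.label)),
               "single-state")
})

test_that("Fritz-Purvis D flags stronger-than-Brownian clumping", {
  tr <- simulate_tree(40, seed = 61)
  clade_tips <- NULL
  for (nd in 41:(40 + tr$Nnode)) {
    tps <- ape::extract.clade(tr, nd)$tip.label
    if (length(tps) %in% 15:25) { clade_tips <- tps; break }
  }
  x <- setNames(as.integer(tr$tip.label %in% clade_tips), tr$tip.label)
  res <- fritz_purvis_d(tr, x, n_sim = 200, seed = 1)
  expect_lt(res$estimate, 0.3)
  expect_lte(res$p_random, 0.05)
  expect_error(fritz_purvis_d(tr, setNames(rep(1L, 40), tr$tip.label)),
               "both states")
})

test_that("phylogenetic ANOVA matches the parametric test on a star tree", {
  st <- star_tree(30)
  set.seed(71)
  y <- setNames(rnorm(30), st$tip.label)
  g <- setNames(rep(letters[1:3], 10), st$tip.label)
  pa <- phylo_anova(st, y, g, n_sim = 2000, seed = 2)
  pf <- stats::anova(stats::lm(y ~ factor(g)))$`Pr(>F)`[1]
  expect_equal(pa$p_value, pf, tolerance = 0.05)
  # perfect separation: maximal F, minimal p
  y2 <- setNames(as.numeric(factor(g)), st$tip.label)
  pa2 <- phylo_anova(st, y2, g, n_sim = 99, seed = 3)
  expect_equal(pa2$p_value, 1 / 100)
  expect_error(phylo_anova(st, y, setNames(c("a", rep("b", 29)),
                                           st$tip.label)),
               "fewer than 2")
})

test_that("permutation p-values respect the (count+1)/(n+1) floor", {
  tr <- simulate_tree(24, seed = 81)
  x <- simulate_bm(tr, seed = 82)
  for (np in c(9, 49)) {
    p <- blomberg_k(tr, x, n_perm = np, seed = 1)$p_value
    expect_gte(p, 1 / (np + 1)); expect_lte(p, 1)
  }
})
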