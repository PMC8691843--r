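make_traits <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(species_id = sprintf("sp%02d", 1:n),
             scale_type = sample(c("LE", "LF", "P"), n, replace = TRUE),
             scale_density = runif(n, 100, 600),
             scale_length = runif(n, 50, 250),
             scale_width = runif(n, 20, 80),
             nanostructure_density = runif(n, 5, 60),
             stringsAsFactors = FALSE)
}

test_that("design matrices use treatment coding and marginality", {
  tra <- data.frame(species_id = c("a", "b", "c"),
                    scale_type = c("LF", "LE", "P"),
                    scale_density = c(1, 2, 3),
                    nanostructure_density = c(4, 5, 6))
  dm <- design_matrix(tra, "scale_type")
  expect_equal(ncol(dm$X), 3L)  # intercept + 2 dummies, LE is reference
  expect_true(all(c("scale_typeLF", "scale_typeP") %in% colnames(dm$X)))
  dm2 <- design_matrix(tra, c("scale_density", "nanostructure_density",
                              "scale_density:nanostructure_density"))
  expect_equal(unname(dm2$X[, "scale_density:nanostructure_density"]),
               tra$scale_density * tra$nanostructure_density)
  expect_error(design_matrix(tra, c("scale_density",
                                    "scale_density:nanostructure_density")),
               "marginality")
  expect_error(design_matrix(tra, "unknown_var"), "unknown")
  tra$scale_density[2] <- NA
  expect_error(design_matrix(tra, "scale_density"), "b")
})

test_that("PGLS with lambda 0 equals ordinary least squares", {
  tr <- simulate_tree(40, seed = 7)
  traits <- make_traits(40, seed = 8)
  y <- setNames(0.1 + 0.002 * traits$scale_density + rnorm(40, 0, 0.1),
                traits$species_id)
  dm <- design_matrix(traits, c("scale_type", "scale_density"))
  f0 <- pgls_fit(tr, y, dm, lambda = 0)
  ols <- stats::lm.fit(dm$X[tr$tip.label, ], y[tr$tip.label])
  expect_equal(unname(coef(f0)), unname(ols$coefficients), tolerance = 1e-8)
})

test_that("PGLS with lambda 1 equals the independent-contrasts regression", {
  for (seed in 1:5) {
    tr <- simulate_tree(30, seed = seed)
    x <- simulate_bm(tr, seed = seed + 100)
    y <- 1.5 * x + simulate_bm(tr, 0.5, seed = seed + 200)
    X <- cbind("(Intercept)" = 1, x = x)
    rownames(X) <- names(x)
    slope <- coef(pgls_fit(tr, y, X, lambda = 1))["x"]
    px <- ape::pic(x[tr$tip.label], tr)
    py <- ape::pic(y[tr$tip.label], tr)
    expect_equal(unname(slope), sum(px * py) / sum(px^2), tolerance = 1e-6)
  }
})

test_that("PGLS agrees with nlme GLS under a fixed-lambda correlation", {
  skip_if_not_installed("nlme")
  tr <- simulate_tree(50, seed = 7)
  x <- simulate_bm(tr, seed = 8)
  y <- 2 * x + simulate_bm(tr, seed = 9)
  X <- cbind("(Intercept)" = 1, x = x); rownames(X) <- names(x)
  df <- data.frame(y = y[tr$tip.label], x = x[tr$tip.label],
                   sp = tr$tip.label)
  ref <- nlme::gls(y ~ x, data = df,
                   correlation = ape::corPagel(0.7, tr, form = ~sp,
                                               fixed = TRUE),
                   method = "ML")
  f <- pgls_fit(tr, y, X, lambda = 0.7)
  expect_equal(unname(coef(f)), unname(coef(ref)), tolerance = 1e-8)
  expect_equal(f$log_likelihood, as.numeric(stats::logLik(ref)),
               tolerance = 1e-8)
})

test_that("lambda profile recovers phylogenetic structure in residuals", {
  set.seed(15)
  hits <- replicate(20, {
    tr <- simulate_tree(64)
    x <- setNames(runif(64), tr$tip.label)
    y <- 2 * x + simulate_bm(tr, 1)
    X <- cbind("(Intercept)" = 1, x = x); rownames(X) <- names(x)
    f <- pgls_fit(tr, y, X, lambda = "ML")
    c(f$lambda > 0.8, abs(coef(f)["x"] - 2) < 1)
  })
  expect_gt(mean(hits[1, ]), 0.7)
  expect_gt(mean(hits[2, ]), 0.9)
  # star tree: lambda unidentifiable, flagged, fit equals OLS
  st <- star_tree(20)
  ys <- setNames(rnorm(20), st$tip.label)
  Xs <- cbind("(Intercept)" = 1, x = runif(20)); rownames(Xs) <- st$tip.label
  fs <- pgls_fit(st, ys, Xs, lambda = "ML")
  expect_match(fs$flag, "unidentifiable")
  expect_equal(unname(coef(fs)),
               unname(stats::lm.fit(Xs, ys)$coefficients), tolerance = 1e-8)
})

test_that("AICc follows its formula and exceeds AIC", {
  expect_equal(aicc(list(log_likelihood = -230, k = 5, n = 62)),
               460 + 10 + 60 / 56, tolerance = 1e-10)
  expect_error(aicc(list(log_likelihood = -10, k = 10, n = 11)),
               "undefined")
  expect_error(aicc(list(log_likelihood = -10, k = 1, n = 20)), "k")
  for (k in 2:6) {
    a <- aicc(list(log_likelihood = -100, k = k, n = 40))
    expect_gt(a, -2 * -100 + 2 * k)
  }
})

test_that("model enumeration respects exclusions and marginality", {
  expect_length(enumerate_models(c("A", "B", "C")), 8L)
  expect_length(enumerate_models(c("A", "B", "C"),
                                 exclusions = list(c("A", "B"))), 6L)
  m5 <- enumerate_models(c("A", "B"), "A:B")
  expect_length(m5, 5L)
  expect_true(any(vapply(m5, function(s) setequal(s, c("A", "B", "A:B")),
                         logical(1))))
  # triple interaction implies all mains and pairwise products
  mt <- enumerate_models(c("A", "B", "C"), c("A:B", "A:C", "B:C", "A:B:C"))
  full <- mt[[length(mt)]]
  expect_true(setequal(full, c("A", "B", "C", "A:B", "A:C", "B:C", "A:B:C")))
  expect_error(enumerate_models(c("A", "B"), exclusions = list(c("A", "Z"))),
               "unknown")
})

test_that("model selection keeps the delta-AICc window and is order-stable", {
  tr <- simulate_tree(40, seed = 31)
  traits <- make_traits(40, seed = 32)
  y <- setNames(0.004 * traits$scale_density +
                  0.3 * (traits$scale_type == "P") +
                  rnorm(40, 0, 0.15), traits$species_id)
  models <- enumerate_models(c("scale_type", "scale_density",
                               "nanostructure_density"))
  fits <- fit_model_set(tr, y, traits, models, lambda = 0)
  sel <- select_models(fits, delta = 2)
  expect_true(all(sel$aicc_table$delta_aicc[
    seq_along(sel$retained)] < 2))
  # shuffling candidate order leaves the retained set unchanged
  perm <- sample(length(fits))
  sel2 <- select_models(fits[perm], delta = 2)
  expect_setequal(names(sel2$retained), names(sel$retained))
  # adding a pure-noise column never lowers the likelihood
  f_small <- fits[["scale_density"]]
  f_big <- fits[["scale_density + nanostructure_density"]]
  expect_gte(f_big$log_likelihood, f_small$log_likelihood - 1e-8)
  expect_length(select_models(fits["scale_density"])$retained, 1L)
})

test_that("selection recovers the generating terms at strong effects", {
  set.seed(51)
  hit <- replicate(15, {
    tr <- simulate_tree(50)
    traits <- make_traits(50, seed = sample.int(1e6, 1))
    y <- setNames(0.5 * (traits$scale_type == "P") -
                    0.2 * (traits$scale_type == "LF") +
                    0.004 * traits$scale_density + rnorm(50, 0, 0.1),
                  traits$species_id)
    models <- enumerate_models(c("scale_type", "scale_density",
                                 "nanostructure_density", "scale_width"))
    sel <- select_models(fit_model_set(tr, y, traits, models, lambda = 0))
    all(vapply(sel$retained, function(f)
      all(c("scale_type", "scale_density") %in% f$terms), logical(1)))
  })
  expect_gt(mean(hit), 0.8)
})
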