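test_that("pigment template peaks at lambda_max and falls off both flanks", {
  p <- pigment_template(563)
  g <- canonical_grid()
  expect_equal(p$sensitivity[g == 563], 1.0, tolerance = 2e-3)
  expect_equal(max(p$sensitivity), 1.0)
  expect_lt(p$sensitivity[g == 450], p$sensitivity[g == 520])
  expect_error(pigment_template(250), "300")

  # curves at 371 and 563 cross strictly between their peaks
  a <- pigment_template(371)$sensitivity
  b <- pigment_template(563)$sensitivity
  diff_sign <- sign(a - b)
  crossings <- g[which(diff(diff_sign) != 0)]
  expect_true(any(crossings > 371 & crossings < 563))
})

test_that("quantum catch integrates T*I*S and is linear in each factor", {
  il <- generate_illuminant("flat")
  box <- rep(0, 401); box[canonical_grid() >= 400 & canonical_grid() <= 500] <- 1
  r <- receptor_sensitivity("box", 450, box)
  q1 <- quantum_catch(const_spec(1), il, r)
  expect_equal(q1, 100, tolerance = 1.01)   # box area, up to edge discretisation
  # halving T halves Q; doubling I doubles Q
  expect_equal(quantum_catch(const_spec(0.5), il, r), q1 / 2)
  il2 <- illuminant_spectrum("flat2", rep(2, 401))
  expect_equal(quantum_catch(const_spec(1), il2, r), 2 * q1)
  # opaque spectrum flags a zero catch
  dark <- const_spec(0)
  expect_warning(quantum_catch(dark, il, r), "zero quantum catch")
})

test_that("receptor noise follows neural-noise density scaling", {
  uvs <- generate_sensitivity_set("UVS")
  e <- receptor_noise(uvs)
  expect_equal(unname(e["L"]), 0.1)           # reference = most abundant cone
  expect_equal(unname(e["UVS"]), 0.1 * sqrt(2.7 / 1), tolerance = 1e-10)
  expect_equal(unname(e["UVS"]), 0.16432, tolerance = 1e-4)
  # equal densities: all noises equal the Weber fraction
  eq <- receptor_set(lapply(c(370, 450, 550, 600), pigment_template),
                     rep(2, 4))
  expect_equal(unname(receptor_noise(eq)), rep(0.1, 4))
})

test_that("chromatic contrast matches its closed forms and the oracle", {
  # dichromat closed form
  di <- receptor_set(lapply(c(400, 560), pigment_template), c(1, 1))
  a <- make_catch(c(1, 1)); b <- make_catch(exp(-c(0.05, -0.05)))
  # df = (0.05, -0.05): |df1 - df2| / (0.1 sqrt 2)
  expect_equal(chromatic_contrast(a, b, di), 0.1 / (0.1 * sqrt(2)),
               tolerance = 1e-10)
  expect_equal(chromatic_contrast(a, a, di), 0)

  # tetrachromat vs independent quadratic-form oracle
  uvs <- generate_sensitivity_set("UVS")
  e <- receptor_noise(uvs)
  set.seed(7)
  for (i in 1:50) {
    qa <- exp(rnorm(4)); qb <- exp(rnorm(4))
    expect_equal(chromatic_contrast(make_catch(qa), make_catch(qb), uvs),
                 rnl_quadform_oracle(log(qa) - log(qb), e),
                 tolerance = 1e-10)
  }
  expect_error(chromatic_contrast(make_catch(c(1, 1)), a, uvs), "mismatch")
  neg_catch <- suppressWarnings(make_catch(c(1, -1, 1, 1)))
  expect_error(chromatic_contrast(neg_catch, make_catch(rep(1, 4)), uvs),
               "non-positive")
})

test_that("dS is illuminant-scale invariant and scales as 1/e", {
  uvs <- generate_sensitivity_set("UVS")
  il <- generate_illuminant("forest_shade")
  il10 <- illuminant_spectrum("x10", il$irradiance * 10)
  set.seed(21)
  v1 <- runif(401, 0.1, 0.9); v2 <- runif(401, 0.1, 0.9)
  s1 <- transmittance_spectrum("a", 1, canonical_grid(), v1)
  s2 <- transmittance_spectrum("b", 1, canonical_grid(), v2)
  d1 <- chromatic_contrast(receptor_catch(s1, il, uvs),
                           receptor_catch(s2, il, uvs), uvs)
  d2 <- chromatic_contrast(receptor_catch(s1, il10, uvs),
                           receptor_catch(s2, il10, uvs), uvs)
  expect_equal(d1, d2, tolerance = 1e-10)

  # equal-noise receptor sets: halving e doubles dS
  mk_set <- function(w) receptor_set(lapply(c(370, 450, 550, 600),
                                            pigment_template),
                                     rep(1, 4), weber_chromatic = w)
  ca <- make_catch(exp(rnorm(4))); cb <- make_catch(exp(rnorm(4)))
  expect_equal(chromatic_contrast(ca, cb, mk_set(0.05)),
               2 * chromatic_contrast(ca, cb, mk_set(0.1)),
               tolerance = 1e-10)
})

test_that("tetrachromatic dS collapses to the dichromatic form when two
           receptors carry near-infinite noise", {
  # receptors 2 and 3 are duplicated channels drowned in noise: densities
  # scaled so e_2, e_3 ~ 1e6 while e_1, e_4 = 0.1
  base <- lapply(c(370, 450, 550, 600), pigment_template)
  eta_big <- 0.1^2 / 1e6^2   # e_i = w sqrt(eta_ref/eta_i)
  quad <- receptor_set(base, c(1, eta_big, eta_big, 1),
                       weber_chromatic = 0.1)
  di <- receptor_set(base[c(1, 4)], c(1, 1), weber_chromatic = 0.1)
  set.seed(3)
  qa <- exp(rnorm(4)); qb <- exp(rnorm(4))
  expect_equal(chromatic_contrast(make_catch(qa), make_catch(qb), quad),
               chromatic_contrast(make_catch(qa[c(1, 4)]),
                                  make_catch(qb[c(1, 4)]), di),
               tolerance = 1e-4)
})

test_that("achromatic contrast is a scaled log catch ratio", {
  uvs <- generate_sensitivity_set("UVS")
  a <- make_catch(c(1, 1, 1, exp(1))); b <- make_catch(c(1, 1, 1, 1))
  expect_equal(achromatic_contrast(a, b, uvs), 5)  # ln(e)/0.2
  expect_equal(achromatic_contrast(b, a, uvs),
               achromatic_contrast(a, b, uvs))
  expect_equal(achromatic_contrast(a, a, uvs), 0)
  expect_error(achromatic_contrast(make_catch(c(1, 1, 1, 0)), b, uvs),
               "non-positive")
})

test_that("contrast tables are symmetric with one value per pair", {
  uvs <- generate_sensitivity_set("UVS")
  il <- generate_illuminant("large_gap")
  set.seed(11)
  sp <- lapply(letters[1:3], function(s)
    transmittance_spectrum(s, 1, canonical_grid(), runif(401, 0.2, 0.8)))
  ct <- contrast_matrix(sp, il, uvs)
  expect_equal(nrow(pair_table(ct$dS)), 3L)  # C(3,2)
  expect_true(isSymmetric(ct$dS) && isSymmetric(ct$dL))
  expect_equal(diag(ct$dS), setNames(rep(0, 3), letters[1:3]))
  # identical spectra give zero contrasts
  twin <- list(const_spec(0.5, "a"), const_spec(0.5, "b"))
  ct2 <- contrast_matrix(twin, il, uvs)
  expect_equal(ct2$dS["a", "b"], 0, tolerance = 1e-12)
  expect_equal(ct2$dL["a", "b"], 0, tolerance = 1e-12)
})
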