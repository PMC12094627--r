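test_that("liability model summaries follow normal-distribution theory", {
  m <- liability_model(0.5)
  expect_equal(m$t, 0)
  expect_equal(m$i, dnorm(0) / 0.5)

  m <- liability_model(0.05)
  expect_equal(m$t, 1.6448536, tolerance = 1e-6)
  expect_equal(m$i, 2.0627128, tolerance = 1e-6)
  expect_equal(m$z, dnorm(m$t), tolerance = 1e-12)

  # selection intensity always exceeds the threshold, and i - t shrinks
  # toward zero as the disorder becomes rarer
  Ks <- c(0.2, 0.1, 0.05, 0.01, 0.001)
  gaps <- vapply(Ks, function(K) { m <- liability_model(K); m$i - m$t },
                 numeric(1))
  expect_true(all(gaps > 0))
  expect_true(all(diff(gaps) < 0))

  expect_error(liability_model(0), "inside")
  expect_error(liability_model(1.2), "inside")
})

test_that("Reich-corrected familiality matches frozen and limiting values", {
  expect_equal(reich_familiality(0.05, 0.05, 0.5)$h_f, 0, tolerance = 1e-10)
  est <- reich_familiality(0.05, 0.113, 0.5)
  expect_equal(est$falconer, 0.4209277, tolerance = 1e-5)
  # exact bivariate-normal inversion gives rho = 0.2231733 for these inputs
  expect_equal(est$h_f, 0.2231733 / 0.5, tolerance = 0.02)
  expect_error(reich_familiality(0.05, 0.113, 0.3), "a_R")
})

test_that("familiality is strictly increasing in the relative prevalence", {
  KRs <- seq(0.05, 0.3, by = 0.01)
  hs <- vapply(KRs, function(kr) reich_familiality(0.05, kr, 0.5)$h_f,
               numeric(1))
  expect_true(all(diff(hs) > 0))
})

test_that("exact forward/inverse liability calculators agree with scipy-frozen values", {
  expect_equal(exact_relative_prevalence(0, 0.05, 0.08), 0.08, tolerance = 1e-10)
  expect_equal(exact_relative_prevalence(0.21, 0.05, 0.05), 0.1083531,
               tolerance = 1e-6)
  # comonotone limit: conditional prevalence -> 1 for equal margins
  expect_equal(exact_relative_prevalence(1, 0.05, 0.05), 1)
  expect_equal(exact_rho(0.05, 0.05, 0.113), 0.2231733, tolerance = 1e-6)
  expect_equal(exact_rho(0.05, 0.08, 0.08), 0, tolerance = 1e-8)
  # with unequal margins the comonotone bound caps the conditional prevalence
  expect_error(exact_rho(0.5, 0.05, 0.2), "attainable")
})

test_that("forward and inverse calculators are mutual inverses", {
  set.seed(7)
  for (k in 1:20) {
    rho <- runif(1, -0.9, 0.95)
    Kp <- runif(1, 0.01, 0.3); Kr <- runif(1, 0.01, 0.3)
    kc <- exact_relative_prevalence(rho, Kp, Kr)
    expect_equal(exact_rho(Kp, Kr, kc), rho, tolerance = 1e-6)
  }
})

test_that("cross-disorder familial correlation has the required fixed points", {
  # no familial excess of b in relatives of a-probands -> r_f = 0
  z <- familial_correlation(0.05, 0.15, 0.15, 0.5, 0.42, 0.35)
  expect_equal(z$r_f, 0, tolerance = 1e-10)
  # the self-correlation of a disorder is 1: K_b_given_relA equals the
  # same-trait relative prevalence implied by h
  h <- 0.4
  kr <- exact_relative_prevalence(0.5 * h, 0.05, 0.05)
  hh <- reich_familiality(0.05, kr, 0.5)$h_f
  self <- familial_correlation(0.05, 0.05, kr, 0.5, hh, hh)
  expect_equal(self$r_f, 1, tolerance = 0.01)
  expect_error(familial_correlation(0.05, 0.15, 0.2, 0.5, 0, 0.3), "positive")
})

test_that("clipping of familial correlations is flagged", {
  z <- familial_correlation(0.05, 0.05, 0.4, 0.5, 0.1, 0.1)
  expect_equal(z$r_f, 1)
  expect_true("clipped" %in% z$flag)
  expect_gt(z$r_f_raw, 1)
})

test_that("degree combination is an inverse-variance weighted mean", {
  expect_equal(combine_degrees(0.4, 0.01, 0.2, 0.03)$estimate, 0.35)
  expect_equal(combine_degrees(0.3, 0.02, 0.3, 0.05)$estimate, 0.3)
  one <- combine_degrees(0.4, 0.01, NA, NA)
  expect_equal(one$estimate, 0.4)
  expect_equal(one$flag, "first_degree_only")
  expect_error(combine_degrees(NA, NA, NA, NA), "missing")
})

test_that("bivariate orthant probability matches closed forms", {
  expect_equal(pbvnorm_upper(0, 0, 0.5), 1 / 3, tolerance = 1e-10)
  # arcsine law at zero thresholds
  for (r in c(-0.9, -0.3, 0.2, 0.7, 0.99))
    expect_equal(pbvnorm_upper(0, 0, r), 0.25 + asin(r) / (2 * pi),
                 tolerance = 1e-10)
  expect_equal(pbvnorm_upper(1.2, -0.4, 0),
               pnorm(1.2, lower.tail = FALSE) * pnorm(-0.4, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(pbvnorm_upper(1, 2, -1), 0)
  expect_equal(pbvnorm_upper(-1, -1, -1), pnorm(1) - pnorm(-1), tolerance = 1e-12)
})
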