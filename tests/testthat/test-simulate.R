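test_that("family covariance assembles relatedness, residual and spousal parts", {
  # single person, one disorder: unit variance regardless of h
  expect_equal(build_family_covariance(matrix(1, 1, 1),
                                       matrix(0.4, 1, 1), matrix(0.6, 1, 1)),
               matrix(1, 1, 1))
  # sibling pair: off-diagonal 0.5 * h
  A <- matrix(c(1, 0.5, 0.5, 1), 2)
  S2 <- build_family_covariance(A, matrix(0.4, 1, 1), matrix(0.6, 1, 1))
  expect_equal(S2[1, 2], 0.2)
  expect_equal(diag(S2), c(1, 1))
  # two disorders: cross-person cross-disorder term 0.5*sqrt(h_p h_q)*r_f
  h <- c(0.4, 0.4); rf <- matrix(c(1, 0.97, 0.97, 1), 2)
  F_mat <- outer(sqrt(h), sqrt(h)) * rf
  E_mat <- outer(sqrt(1 - h), sqrt(1 - h)) * diag(2)
  S4 <- build_family_covariance(A, F_mat, E_mat)
  expect_equal(S4[1, 4], 0.5 * sqrt(0.4 * 0.4) * 0.97)  # = 0.194
  expect_equal(diag(S4), rep(1, 4))
  # an overlarge spousal term breaks positive semidefiniteness: strong
  # within-person residual correlation plus near-perfect same-disorder
  # spousal correlation is jointly impossible
  Ssp <- matrix(c(0, 1, 1, 0), 2)
  E_res <- matrix(c(1, 0.1, 0.1, 1), 2)
  expect_error(build_family_covariance(diag(2), matrix(0, 2, 2), E_res,
                                       spousal = c(0.95, 0.95), S = Ssp),
               "positive semidefinite")
})

test_that("simulated prevalence matches the target within Monte-Carlo error", {
  co <- quick_sim(n_families = 20000, prevalence = 0.05, familiality = 0.3,
                  seed = 31)
  n <- sum(!is.na(co$D1))
  mcse <- sqrt(0.05 * 0.95 / n)  # conservative: ignores family clustering
  expect_lt(abs(mean(co$D1, na.rm = TRUE) - 0.05), 5 * mcse)
})

test_that("sex- and age-shifted liabilities keep the marginal prevalence", {
  cfg <- sim_config(n_families = 20000, prevalence = 0.08, familiality = 0.3,
                    sex_effect = 0.5, age_effect = c(0.3, 0.1), seed = 32)
  co <- simulate_cohort(cfg)
  expect_lt(abs(mean(co$D1, na.rm = TRUE) - 0.08), 0.005)
  # and the configured sex effect shows as a prevalence difference
  pf <- mean(co$D1[co$sex == "female"], na.rm = TRUE)
  pm <- mean(co$D1[co$sex == "male"], na.rm = TRUE)
  expect_gt(pf, pm)
})

test_that("simulation is deterministic given the seed", {
  a <- quick_sim(n_families = 200, seed = 77)
  b <- quick_sim(n_families = 200, seed = 77)
  expect_identical(a, b)
  c <- quick_sim(n_families = 200, seed = 78)
  expect_false(identical(a, c))
})

test_that("zero familiality yields no familial aggregation", {
  co <- quick_sim(n_families = 15000, prevalence = 0.1, familiality = 0,
                  seed = 33)
  pr <- first_degree_pairs(co)
  xt <- exposure_table(co, pr, "D1")
  lam <- crude_lambda(xt)
  expect_lt(abs(lam - 1), 0.08)
})

test_that("sibling tetrachoric concordance tracks 0.5 * h under the generator", {
  co <- quick_sim(n_families = 30000, prevalence = 0.1, familiality = 0.4,
                  seed = 34)
  pr <- first_degree_pairs(co)
  sib <- pr[pr$relationship == "full-sibling", ]
  est <- tetrachoric_mle(pair_table(sib, co, "D1"))
  expect_lt(abs(est$rho - 0.2), 0.04)
})

test_that("cross-disorder cross-sibling concordance tracks 0.5*sqrt(h h')*r_f", {
  cfg <- sim_config(n_families = 30000, prevalence = c(0.1, 0.1),
                    familiality = c(0.4, 0.4),
                    familial_corr = matrix(c(1, 0.97, 0.97, 1), 2),
                    structure = list(n_children = c(`2` = 1), p_third_gen = 0),
                    seed = 35)
  co <- simulate_cohort(cfg)
  pr <- first_degree_pairs(co)
  sib <- pr[pr$relationship == "full-sibling", ]
  est <- tetrachoric_mle(pair_table(sib, co, "D1", "D2"))
  expect_lt(abs(est$rho - 0.194), 0.04)
})

test_that("spousal liability correlation induces spousal concordance", {
  cfg <- sim_config(n_families = 30000, prevalence = 0.1, familiality = 0.3,
                    spousal_corr = 0.3,
                    structure = list(n_children = c(`1` = 1), p_third_gen = 0),
                    seed = 36)
  co <- simulate_cohort(cfg)
  sp <- relative_pairs(build_pedigree(co), "spouse")
  est <- tetrachoric_mle(pair_table(sp, co, "D1"))
  expect_lt(abs(est$rho - 0.3), 0.05)
})

test_that("selective dropout preserves the base rate for the unexposed", {
  co <- quick_sim(n_families = 5000, prevalence = 0.1, familiality = 0.3,
                  seed = 37)
  out <- apply_selective_dropout(co, or = 0.5, seed = 38)
  pr <- first_degree_pairs(co)
  xt <- exposure_table(co, pr, "D1")
  unexposed <- xt$person_id[xt$exposed == 0 & xt$n_relatives > 0]
  p_unexp <- mean(out$participation_w2[out$person_id %in% unexposed])
  expect_lt(abs(p_unexp - 0.8), 0.03)
  # exposed participate less
  exposed <- xt$person_id[xt$exposed == 1]
  expect_lt(mean(out$participation_w2[out$person_id %in% exposed]), p_unexp)
  expect_error(apply_selective_dropout(co, or = -1), "positive")
  # OR = 1 leaves participation rates at base level for everyone
  out1 <- apply_selective_dropout(co, or = 1, seed = 39)
  p_exp1 <- mean(out1$participation_w2[out1$person_id %in% exposed])
  expect_lt(abs(p_exp1 - 0.8), 0.03)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(prevalence = 1.2), "prevalence")
  expect_error(sim_config(prevalence = c(0.1, 0.1), familiality = c(0.5, 0.5),
                          familial_corr = matrix(c(1, 2, 2, 1), 2)),
               "symmetric|semidefinite")
})
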