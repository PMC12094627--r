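test_that("exposure tables encode affected relatives from their own records", {
  co <- toy_cohort()
  pr <- relative_pairs(build_pedigree(co))
  xt <- exposure_table(co, pr, "D1")
  row <- function(id) xt[xt$person_id == id, ]
  # C2's first-degree relatives: FA (case), MO, C1 (case)
  expect_equal(row("C2")$exposed, 1)
  expect_equal(row("C2")$n_relatives, 3)
  # the singleton is retained, unexposed, with no relatives
  expect_equal(row("LONE")$exposed, 0)
  expect_equal(row("LONE")$n_relatives, 0)
  # a relative with missing status creates no exposure and is not counted:
  # G1's D2 analysis: parents C1 (control) and S1 (case)
  xt2 <- exposure_table(co, pr, "D2")
  expect_equal(xt2[xt2$person_id == "G1", ]$exposed, 1)
  co3 <- co; co3$D2[co3$person_id == "S1"] <- NA
  xt3 <- exposure_table(co3, pr, "D2")
  expect_equal(xt3[xt3$person_id == "G1", ]$exposed, 0)
  expect_equal(xt3[xt3$person_id == "G1", ]$n_relatives, 1)
  # rows with missing outcome are dropped (LONE has D2 = NA)
  expect_false("LONE" %in% xt2$person_id)
  expect_error(exposure_table(co, pr, "NOPE"), "unknown disorder")
})

test_that("relative-class filters orient parent/offspring correctly", {
  co <- toy_cohort()
  pr <- relative_pairs(build_pedigree(co))
  # exposure from parents: C1's parents are FA (case) and MO (control)
  xt_par <- exposure_table(co, pr, "D1", relative_class = "parent")
  expect_equal(xt_par[xt_par$person_id == "C1", ]$exposed, 1)
  expect_equal(xt_par[xt_par$person_id == "FA", ]$n_relatives, 0)
  # exposure from offspring: FA's children are C1 (case) and C2 (control)
  xt_off <- exposure_table(co, pr, "D1", relative_class = "offspring")
  expect_equal(xt_off[xt_off$person_id == "FA", ]$exposed, 1)
  expect_equal(xt_off[xt_off$person_id == "C1", ]$n_relatives, 1)  # G1
  # spouse exposure
  xt_sp <- exposure_table(co, pr, "D1", relative_class = "spouse")
  expect_equal(xt_sp[xt_sp$person_id == "MO", ]$exposed, 1)
  expect_equal(xt_sp[xt_sp$person_id == "C2", ]$n_relatives, 0)
})

test_that("with an intercept the mean fitted probability equals the prevalence", {
  co <- quick_sim(n_families = 1500, prevalence = 0.08, familiality = 0.4,
                  seed = 41)
  xt <- exposure_table(co, first_degree_pairs(co), "D1")
  m <- fit_disease_model(xt)
  expect_equal(mean(fitted(m$fit)), mean(xt$outcome), tolerance = 1e-10)
})

test_that("exposure-only marginal lambda equals the crude prevalence ratio", {
  co <- quick_sim(n_families = 1500, prevalence = 0.08, familiality = 0.4,
                  seed = 42)
  xt <- exposure_table(co, first_degree_pairs(co), "D1")
  m <- fit_disease_model(xt, adjust = FALSE)
  est <- marginal_lambda(m)
  expect_equal(est$lambda, crude_lambda(xt), tolerance = 1e-10)
  expect_true(est$ci_low <= est$lambda && est$lambda <= est$ci_high)
  expect_equal(est$lambda, est$p_exposed / est$p_pop, tolerance = 1e-12)
})

test_that("degenerate exposure tables are rejected with informative errors", {
  co <- quick_sim(n_families = 300, prevalence = 0.05, seed = 43)
  xt <- exposure_table(co, first_degree_pairs(co), "D1")
  xt_allcase <- xt; xt_allcase$outcome <- 1L
  expect_error(fit_disease_model(xt_allcase), "constant")
  xt_noexp <- xt; xt_noexp$exposed <- 0L
  expect_error(fit_disease_model(xt_noexp), "constant")
})

test_that("duplicating rows leaves coefficients and clustered variance alone", {
  co <- quick_sim(n_families = 800, prevalence = 0.1, familiality = 0.4,
                  seed = 44)
  xt <- exposure_table(co, first_degree_pairs(co), "D1")
  m1 <- fit_disease_model(xt)
  xt2 <- rbind(xt, xt)
  attr(xt2, "relative_class") <- "first-degree"
  m2 <- fit_disease_model(xt2)
  expect_equal(coef(m2$fit), coef(m1$fit), tolerance = 1e-6)
  # same clusters twice: the clustered sandwich is unchanged, while the
  # independence sandwich would halve -- clustering is really being used
  expect_equal(m2$vcov, m1$vcov, tolerance = 1e-4)
  v_indep1 <- sandwich::vcovHC(m1$fit, type = "HC0")
  v_indep2 <- sandwich::vcovHC(m2$fit, type = "HC0")
  expect_equal(v_indep2, v_indep1 / 2, tolerance = 1e-4)
})

test_that("lambda estimates are invariant to row order and family relabeling", {
  co <- quick_sim(n_families = 800, prevalence = 0.1, familiality = 0.4,
                  seed = 45)
  pr <- first_degree_pairs(co)
  l1 <- marginal_lambda(fit_disease_model(exposure_table(co, pr, "D1")))
  co2 <- co[sample.int(nrow(co)), ]
  attr(co2, "disorders") <- attr(co, "disorders")
  map <- setNames(sprintf("fam%04d", seq_along(unique(co$family_id))),
                  sample(unique(co$family_id)))
  co2$family_id <- unname(map[co2$family_id])
  pr2 <- first_degree_pairs(co2)
  l2 <- marginal_lambda(fit_disease_model(exposure_table(co2, pr2, "D1")))
  expect_equal(l2$lambda, l1$lambda, tolerance = 1e-8)
  expect_equal(l2$se, l1$se, tolerance = 1e-8)
})

test_that("the lambda matrix covers all ordered disorder pairs and absorbs failures", {
  cfg <- sim_config(n_families = 1200, prevalence = c(0.08, 0.08),
                    familiality = c(0.4, 0.4),
                    familial_corr = matrix(c(1, 0.6, 0.6, 1), 2),
                    structure = list(n_children = c(`2` = 1), p_third_gen = 0),
                    seed = 46)
  co <- simulate_cohort(cfg)
  pr <- first_degree_pairs(co)
  lm2 <- lambda_matrix(co, pr, relative_class = "first-degree")
  expect_equal(nrow(lm2), 4)
  expect_true(all(is.na(lm2$error)))
  # a constant disorder fails its cells but the matrix completes
  co$D3 <- 0L
  attr(co, "disorders") <- c("D1", "D2", "D3")
  lm3 <- lambda_matrix(co, pr, relative_class = "first-degree")
  expect_equal(nrow(lm3), 9)
  expect_true(any(!is.na(lm3$error)))
  expect_true(all(is.finite(lm3$lambda[is.na(lm3$error)])))
})

test_that("participation regression detects absence of selective dropout", {
  co <- quick_sim(n_families = 4000, prevalence = 0.1, familiality = 0.3,
                  seed = 47)
  pr <- first_degree_pairs(co)
  est <- participation_model(co, pr, wave = 2)
  expect_lt(abs(est$or - 1), 0.1)
  expect_true(est$ci_low < 1 && est$ci_high > 1)
  co_const <- co; co_const$participation_w2 <- TRUE
  expect_error(participation_model(co_const, pr, wave = 2), "does not vary")
})
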