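# Shared fixtures and independent oracles, built in code.

# A hand-built three-generation family plus a singleton:
#   family A: father FA + mother MO (cohabiting spouses), children C1, C2;
#   C1 cohabits with S1 (not declared, shares child G1) -> spouse by shared
#   child; G1 is the grandchild.
#   family B: one unlinked person.
toy_cohort <- function() {
  df <- data.frame(
    family_id = c(rep("A", 6), "B"),
    person_id = c("FA", "MO", "C1", "C2", "S1", "G1", "LONE"),
    father_id = c(NA, NA, "FA", "FA", NA, "C1", NA),
    mother_id = c(NA, NA, "MO", "MO", NA, "S1", NA),
    spouse_id = c("MO", "FA", NA, NA, NA, NA, NA),
    cohabiting = c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE, FALSE),
    sex = c("male", "female", "male", "female", "female", "male", "female"),
    age = c(62, 60, 34, 31, 33, 19, 45),
    participation_w1 = TRUE, participation_w2 = TRUE, participation_w3 = TRUE,
    D1 = c(1L, 0L, 1L, 0L, 0L, 1L, 0L),
    D2 = c(0L, 1L, 0L, 0L, 1L, 0L, NA),
    stringsAsFactors = FALSE)
  attr(df, "disorders") <- c("D1", "D2")
  df
}

# Small nuclear-family simulation used across tests.
quick_sim <- function(n_families = 2000, prevalence = 0.05, familiality = 0.4,
                      seed = 1, n_children = 2, ...) {
  cfg <- sim_config(n_families = n_families, prevalence = prevalence,
                    familiality = familiality,
                    structure = list(n_children = stats::setNames(1, n_children),
                                     p_third_gen = 0),
                    seed = seed, ...)
  simulate_cohort(cfg)
}

first_degree_pairs <- function(cohort) {
  relative_pairs(build_pedigree(cohort), c("parent-offspring", "full-sibling"))
}

# Independent brute-force tetrachoric: grid search over rho with cell
# probabilities accumulated by trapezoidal integration of the bivariate
# normal density in rho (dP11/drho equals the density at the thresholds).
# Deliberately different machinery from the package's Gauss-Legendre MLE.
grid_tetrachoric <- function(counts, step = 1e-4, limit = 0.999) {
  counts <- as.matrix(counts)
  n <- sum(counts)
  pa <- sum(counts[1, ]) / n
  pb <- sum(counts[, 1]) / n
  ta <- qnorm(1 - pa); tb <- qnorm(1 - pb)
  rhos <- seq(-limit, limit, by = step)
  dens <- exp(-(ta^2 - 2 * ta * tb * rhos + tb^2) / (2 * (1 - rhos^2))) /
    (2 * pi * sqrt(1 - rhos^2))
  i0 <- which.min(abs(rhos))   # rho = 0 on the grid
  p11 <- numeric(length(rhos))
  p11[i0] <- (1 - pnorm(ta)) * (1 - pnorm(tb))
  if (i0 < length(rhos)) {
    inc <- (dens[-1] + dens[-length(dens)]) / 2 * step
    p11[(i0 + 1):length(rhos)] <- p11[i0] + cumsum(inc[i0:(length(rhos) - 1)])
    if (i0 > 1)
      p11[(i0 - 1):1] <- p11[i0] - cumsum(rev(inc[1:(i0 - 1)]))
  }
  p10 <- pa - p11; p01 <- pb - p11; p00 <- 1 - pa - pb + p11
  ll <- counts[1, 1] * log(pmax(p11, 1e-12)) +
    counts[1, 2] * log(pmax(p10, 1e-12)) +
    counts[2, 1] * log(pmax(p01, 1e-12)) +
    counts[2, 2] * log(pmax(p00, 1e-12))
  rhos[which.max(ll)]
}

# Crude prevalence-ratio oracle for the exposure-only lambda.
crude_lambda <- function(xt) {
  mean(xt$outcome[xt$exposed == 1]) / mean(xt$outcome)
}
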