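# Marginal recurrence-risk ratios (lambda_R) by logistic regression with
# plug-in standardization, cluster-robust variance and delta-method CIs.

.RELATIVE_CLASSES <- c("first-degree", "sibling", "parent", "offspring",
                       "second-degree", "spouse")

# Subset pairs to the requested relative class and orient them as
# (person, relative). Parent-offspring pairs are stored parent-first, so
# class "parent" (relatives are parents) takes relative_id as the person.
.class_pairs <- function(pairs, relative_class) {
  switch(relative_class,
    "first-degree" = {
      p <- pairs[pairs$relationship %in% c("parent-offspring", "full-sibling"), ]
      data.frame(person = c(p$proband_id, p$relative_id),
                 relative = c(p$relative_id, p$proband_id),
                 stringsAsFactors = FALSE)
    },
    "sibling" = {
      p <- pairs[pairs$relationship == "full-sibling", ]
      data.frame(person = c(p$proband_id, p$relative_id),
                 relative = c(p$relative_id, p$proband_id),
                 stringsAsFactors = FALSE)
    },
    "parent" = {
      p <- pairs[pairs$relationship == "parent-offspring", ]
      data.frame(person = p$relative_id, relative = p$proband_id,
                 stringsAsFactors = FALSE)
    },
    "offspring" = {
      p <- pairs[pairs$relationship == "parent-offspring", ]
      data.frame(person = p$proband_id, relative = p$relative_id,
                 stringsAsFactors = FALSE)
    },
    "second-degree" = {
      p <- pairs[pairs$degree == "2", ]
      data.frame(person = c(p$proband_id, p$relative_id),
                 relative = c(p$relative_id, p$proband_id),
                 stringsAsFactors = FALSE)
    },
    "spouse" = {
      p <- pairs[pairs$relationship == "spouse", ]
      data.frame(person = c(p$proband_id, p$relative_id),
                 relative = c(p$relative_id, p$proband_id),
                 stringsAsFactors = FALSE)
    },
    stop("unknown relative class: ", relative_class))
}

#' Per-person exposure table for a recurrence-risk analysis
#'
#' For each cohort member, determines whether at least one relative of the
#' requested class is a case for the exposure disorder (from the relatives'
#' own records), counts relatives of that class with non-missing status,
#' and attaches the outcome status and covariates. Persons with no
#' relatives of the class in the data are retained with `exposed = 0`,
#' `n_relatives = 0`; relatives with missing status create no exposure and
#' are not counted. Rows with missing outcome are dropped.
#'
#' @param cohort Cohort table.
#' @param pairs Pair table from [relative_pairs()].
#' @param exposure_disorder Disorder defining exposure (affected relative).
#' @param outcome_disorder Disorder analyzed as outcome (defaults to the
#'   exposure disorder).
#' @param relative_class One of `"first-degree"`, `"sibling"`, `"parent"`,
#'   `"offspring"`, `"second-degree"`, `"spouse"`.
#' @return `data.frame`: `person_id`, `outcome`, `exposed`, `n_relatives`,
#'   `age`, `sex`, `cluster` (family id).
#' @export
exposure_table <- function(cohort, pairs, exposure_disorder,
                           outcome_disorder = exposure_disorder,
                           relative_class = "first-degree") {
  relative_class <- match.arg(relative_class, .RELATIVE_CLASSES)
  disorders <- attr(cohort, "disorders") %||%
    intersect(c(exposure_disorder, outcome_disorder), names(cohort))
  for (dis in c(exposure_disorder, outcome_disorder))
    if (!dis %in% names(cohort)) stop("unknown disorder code: ", dis)
  cp <- .class_pairs(pairs, relative_class)
  rel_status <- cohort[[exposure_disorder]][match(cp$relative, cohort$person_id)]
  pi <- match(cp$person, cohort$person_id)
  n <- nrow(cohort)
  exposed <- n_rel <- integer(n)
  known <- !is.na(rel_status)
  # spouse analyses adjust for presence of a spouse in the data (the count
  # regardless of status); other classes count relatives with known status
  n_rel <- if (relative_class == "spouse") tabulate(pi, nbins = n) else
    tabulate(pi[known], nbins = n)
  case_rel <- known & rel_status == 1L
  exposed <- as.integer(tabulate(pi[case_rel], nbins = n) > 0)
  out <- data.frame(person_id = cohort$person_id,
                    outcome = cohort[[outcome_disorder]],
                    exposed = exposed, n_relatives = n_rel,
                    age = cohort$age, sex = cohort$sex,
                    cluster = cohort$family_id, stringsAsFactors = FALSE)
  out <- out[!is.na(out$outcome), ]
  rownames(out) <- NULL
  attr(out, "relative_class") <- relative_class
  attr(out, "exposure_disorder") <- exposure_disorder
  attr(out, "outcome_disorder") <- outcome_disorder
  out
}

#' Fit the disease logistic model with cluster-robust covariance
#'
#' Regresses outcome status on the affected-relative indicator, adjusting
#' for age, age squared (age centred before squaring) and sex, plus the
#' number of relatives of the class in the data (or, for spouse analyses,
#' the presence-of-spouse indicator, which the count reduces to).
#' Coefficient covariance uses the clustered sandwich estimator with
#' families as clusters.
#'
#' @param xt Exposure table from [exposure_table()].
#' @param adjust Include the age, sex and family-size covariates (default
#'   TRUE). With `adjust = FALSE` the model is exposure-only, in which case
#'   the marginal lambda equals the crude prevalence ratio exactly.
#' @return List of class `disease_model`: `fit` (a `glm`), `vcov`
#'   (cluster-robust), `xt`.
#' @export
fit_disease_model <- function(xt, adjust = TRUE) {
  lab <- paste0(attr(xt, "exposure_disorder") %||% "?", " -> ",
                attr(xt, "outcome_disorder") %||% "?")
  if (length(unique(xt$outcome)) < 2)
    stop("outcome is constant for ", lab)
  if (length(unique(xt$exposed)) < 2)
    stop("exposure is constant for ", lab)
  xt$agec <- xt$age - mean(xt$age)
  form <- if (!adjust) outcome ~ exposed
  else if (length(unique(xt$sex)) < 2)
    outcome ~ exposed + agec + I(agec^2) + n_relatives
  else outcome ~ exposed + agec + I(agec^2) + sex + n_relatives
  fit <- stats::glm(form, family = stats::binomial(), data = xt)
  if (!fit$converged || any(abs(stats::coef(fit)) > 20))
    stop("logistic model did not converge (possible separation) for ", lab)
  V <- sandwich::vcovCL(fit, cluster = xt$cluster)
  structure(list(fit = fit, vcov = V, xt = xt), class = "disease_model")
}

#' Marginal recurrence-risk ratio by plug-in standardization
#'
#' Computes the marginal lambda_R from a fitted disease model: the
#' population prevalence `p_pop` is the mean predicted probability at the
#' observed covariates, the exposed prevalence `p_exposed` the mean
#' prediction with every person's affected-relative indicator set to 1
#' (other covariates unchanged), and `lambda = p_exposed / p_pop`. The 95%
#' Wald interval on the ratio scale uses the delta method through both
#' plug-in means with the cluster-robust coefficient covariance.
#'
#' @param model A `disease_model` from [fit_disease_model()].
#' @param level Confidence level (default 0.95).
#' @return Object of class `lambda_estimate`: one-row `data.frame` with
#'   `lambda`, `ci_low`, `ci_high`, `se`, `p_pop`, `p_exposed`, `n_total`,
#'   `n_exposed` and the analysis labels.
#' @export
marginal_lambda <- function(model, level = 0.95) {
  fit <- model$fit; xt <- model$xt
  X0 <- stats::model.matrix(fit)
  X1 <- X0
  X1[, "exposed"] <- 1
  beta <- stats::coef(fit)
  lam_fun <- function(b) {
    p0 <- mean(plogis(drop(X0 %*% b)))
    p1 <- mean(plogis(drop(X1 %*% b)))
    c(p0 = p0, p1 = p1, lambda = p1 / p0)
  }
  est <- lam_fun(beta)
  if (est[["p0"]] <= 0) stop("population prevalence estimate is zero")
  # numerically differentiated gradient of the ratio w.r.t. coefficients
  h <- 1e-6 * pmax(1, abs(beta))
  grad <- vapply(seq_along(beta), function(j) {
    bp <- beta; bm <- beta
    bp[j] <- bp[j] + h[j]; bm[j] <- bm[j] - h[j]
    (lam_fun(bp)[["lambda"]] - lam_fun(bm)[["lambda"]]) / (2 * h[j])
  }, numeric(1))
  se <- sqrt(drop(t(grad) %*% model$vcov %*% grad))
  z <- qnorm(1 - (1 - level) / 2)
  res <- data.frame(
    exposure = attr(xt, "exposure_disorder") %||% NA_character_,
    outcome = attr(xt, "outcome_disorder") %||% NA_character_,
    relative_class = attr(xt, "relative_class") %||% NA_character_,
    lambda = est[["lambda"]],
    ci_low = max(0, est[["lambda"]] - z * se),
    ci_high = est[["lambda"]] + z * se,
    se = se, p_pop = est[["p0"]], p_exposed = est[["p1"]],
    n_total = nrow(xt), n_exposed = sum(xt$exposed == 1),
    stringsAsFactors = FALSE)
  class(res) <- c("lambda_estimate", class(res))
  res
}

#' Recurrence-risk ratio matrix over disorder pairs
#'
#' Runs [exposure_table()], [fit_disease_model()] and [marginal_lambda()]
#' for every ordered (exposure, outcome) disorder combination, including
#' exposure = outcome (familial aggregation). Per-cell failures are
#' recorded in an `error` column and do not abort the remaining cells.
#'
#' @param cohort Cohort table.
#' @param pairs Pair table.
#' @param disorders Disorder codes (default: the cohort's).
#' @param relative_class Relative class for all cells.
#' @return `data.frame` with one row per combination.
#' @export
lambda_matrix <- function(cohort, pairs, disorders = attr(cohort, "disorders"),
                          relative_class = "first-degree") {
  grid <- expand.grid(exposure = disorders, outcome = disorders,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(k) {
    res <- tryCatch({
      xt <- exposure_table(cohort, pairs, grid$exposure[k], grid$outcome[k],
                           relative_class)
      est <- marginal_lambda(fit_disease_model(xt))
      est$error <- NA_character_
      est
    }, error = function(e) {
      data.frame(exposure = grid$exposure[k], outcome = grid$outcome[k],
                 relative_class = relative_class, lambda = NA_real_,
                 ci_low = NA_real_, ci_high = NA_real_, se = NA_real_,
                 p_pop = NA_real_, p_exposed = NA_real_,
                 n_total = NA_integer_, n_exposed = NA_integer_,
                 error = conditionMessage(e), stringsAsFactors = FALSE)
    })
    res
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Participation (selective-dropout) sensitivity regression
#'
#' Logistic regression of wave participation on having an affected
#' first-degree relative, adjusted for age, sex, the number of relatives
#' participating in that wave and (optionally) the person's own disease
#' status, with family-clustered sandwich variance. Recovers the
#' participation odds ratio of a selective-dropout mechanism.
#'
#' @param cohort Cohort table.
#' @param pairs Pair table.
#' @param wave Wave index (2 or 3).
#' @param disorders Disorder set defining the affected-relative exposure
#'   (default: all of the cohort's disorders).
#' @param adjust_own_status Include the person's own (any-disorder) status
#'   as a covariate (default TRUE).
#' @param level Confidence level.
#' @return One-row `data.frame`: `or`, `ci_low`, `ci_high`, `se_log_or`,
#'   `n`, `n_exposed`, `wave`.
#' @export
participation_model <- function(cohort, pairs, wave = 2,
                                disorders = attr(cohort, "disorders"),
                                adjust_own_status = TRUE, level = 0.95) {
  part <- cohort[[paste0("participation_w", wave)]]
  if (length(unique(part)) < 2)
    stop("participation in wave ", wave, " does not vary")
  status <- as.matrix(cohort[disorders])
  any_case <- rowSums(status, na.rm = TRUE) > 0
  cp <- .class_pairs(pairs, "first-degree")
  pi <- match(cp$person, cohort$person_id)
  ri <- match(cp$relative, cohort$person_id)
  n <- nrow(cohort)
  exposed <- tabulate(pi[any_case[ri]], nbins = n) > 0
  rel_part <- part[ri]
  n_rel_part <- tabulate(pi[isTRUE_v(rel_part)], nbins = n)
  df <- data.frame(part = as.integer(part), exposed = as.integer(exposed),
                   agec = cohort$age - mean(cohort$age), sex = cohort$sex,
                   n_rel_part = n_rel_part, own = as.integer(any_case),
                   cluster = cohort$family_id)
  form <- part ~ exposed + agec + sex + n_rel_part
  if (adjust_own_status) form <- stats::update(form, . ~ . + own)
  fit <- stats::glm(form, family = stats::binomial(), data = df)
  V <- sandwich::vcovCL(fit, cluster = df$cluster)
  b <- stats::coef(fit)[["exposed"]]
  se <- sqrt(V["exposed", "exposed"])
  z <- qnorm(1 - (1 - level) / 2)
  data.frame(wave = wave, or = exp(b), ci_low = exp(b - z * se),
             ci_high = exp(b + z * se), se_log_or = se,
             n = nrow(df), n_exposed = sum(exposed))
}
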