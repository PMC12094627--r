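# Synthetic three-generation cohort generation under a multivariate
# liability-threshold model.

#' Simulation configuration
#'
#' Assembles and validates the full generative specification for
#' [simulate_cohort()]. Disease status arises from a latent multivariate
#' normal liability: for a family the joint covariance over
#' (member x disorder) is `A (x) F + I (x) E + S (x) diag(spousal_corr)`,
#' where `A` holds pairwise relatedness weights (0.5 first-degree, 0.25
#' second-degree), `F` is the familial covariance
#' (`F_pp = h_p`, `F_pq = sqrt(h_p h_q) r_f(p,q)`), `E` the residual
#' covariance (`E_pp = 1 - h_p`, off-diagonals scaled by `residual_corr`)
#' and `S` marks spouse pairs. Every liability has unit total variance.
#'
#' @param n_families Number of families to generate.
#' @param disorders Character vector of disorder codes.
#' @param prevalence Per-disorder population prevalence `K` in (0, 1).
#' @param familiality Per-disorder familiality `h_f` in `[0, 1)`.
#' @param familial_corr Symmetric familial correlation matrix `r_f`, unit
#'   diagonal (default identity).
#' @param residual_corr Symmetric residual correlation matrix, unit diagonal
#'   (default identity).
#' @param spousal_corr Per-disorder liability correlation between spouses in
#'   `[0, 1)` (default 0; phenotypic, not transmitted to offspring).
#' @param structure List: `n_children`, a named probability vector over
#'   sibship sizes; `p_third_gen`, probability that a family extends to a
#'   third generation (eldest child gains a spouse and 1-2 children).
#' @param sex_effect Per-disorder liability shift of females relative to
#'   males (default 0); thresholds are recalibrated so the marginal
#'   prevalence stays at `K`.
#' @param age_effect Per-disorder list/vector `c(linear, quadratic)` on
#'   standardized age (default 0); thresholds recalibrated likewise.
#' @param dropout List: `or`, participation odds ratio for persons with an
#'   affected first-degree relative (1 = no selective dropout); `base`,
#'   baseline participation probabilities for waves 2 and 3.
#' @param assessed_waves Named list mapping disorders to the waves (subset
#'   of 1:3) in which they are assessed; default all three.
#' @param aux List of auxiliary-flag parameters: `p_somatic_case`,
#'   `p_somatic_control` (prevalence of a somatic-exclusion flag in cases /
#'   controls), `p_duration6` (probability a case's symptom duration is at
#'   least six months), `p_interference` (probability a case reports
#'   interference with daily activities).
#' @param seed Integer seed; all randomness flows from it.
#' @return Object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_families = 1000,
                       disorders = NULL,
                       prevalence = 0.05,
                       familiality = 0.4,
                       familial_corr = NULL,
                       residual_corr = NULL,
                       spousal_corr = 0,
                       structure = list(n_children = c(`1` = 0.35, `2` = 0.45,
                                                       `3` = 0.20),
                                        p_third_gen = 0.15),
                       sex_effect = 0,
                       age_effect = 0,
                       dropout = list(or = 1, base = c(w2 = 0.8, w3 = 0.75)),
                       assessed_waves = NULL,
                       aux = list(p_somatic_case = 0.25,
                                  p_somatic_control = 0.05,
                                  p_duration6 = 0.75,
                                  p_interference = 0.8),
                       seed = 1L) {
  d <- max(length(prevalence), length(familiality), length(disorders))
  if (is.null(disorders)) disorders <- paste0("D", seq_len(d))
  prevalence <- rep_len(prevalence, d)
  familiality <- rep_len(familiality, d)
  spousal_corr <- rep_len(spousal_corr, d)
  sex_effect <- rep_len(sex_effect, d)
  if (is.numeric(age_effect) && length(age_effect) <= 2)
    age_effect <- rep(list(rep_len(age_effect, 2)), d)
  if (is.null(familial_corr)) familial_corr <- diag(d)
  if (is.null(residual_corr)) residual_corr <- diag(d)
  if (is.null(assessed_waves))
    assessed_waves <- stats::setNames(rep(list(1:3), d), disorders)
  stopifnot(n_families >= 1, all(prevalence > 0 & prevalence < 1),
            all(familiality >= 0 & familiality < 1),
            all(spousal_corr >= 0 & spousal_corr < 1),
            nrow(familial_corr) == d, nrow(residual_corr) == d,
            abs(sum(structure$n_children) - 1) < 1e-8)
  if (any(abs(diag(familial_corr) - 1) > 1e-12) ||
      any(abs(familial_corr - t(familial_corr)) > 1e-12))
    stop("familial_corr must be symmetric with unit diagonal")
  Fm <- outer(sqrt(familiality), sqrt(familiality)) * familial_corr
  Em <- outer(sqrt(1 - familiality), sqrt(1 - familiality)) * residual_corr
  for (nm in c("Fm", "Em")) {
    ev <- eigen(get(nm), symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-10)
      stop(sprintf("%s covariance is not positive semidefinite (min eigenvalue %.3g)",
                   if (nm == "Fm") "familial" else "residual", min(ev)))
  }
  if (is.null(dropout$base)) dropout$base <- c(w2 = 0.8, w3 = 0.75)
  if (is.null(dropout$or)) dropout$or <- 1
  structure(list(n_families = as.integer(n_families), disorders = disorders,
                 prevalence = prevalence, familiality = familiality,
                 familial_corr = familial_corr, residual_corr = residual_corr,
                 F = Fm, E = Em, spousal_corr = spousal_corr,
                 structure = structure, sex_effect = sex_effect,
                 age_effect = age_effect, dropout = dropout,
                 assessed_waves = assessed_waves, aux = aux,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Run code with a private RNG stream without clobbering the caller's state.
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else on.exit(rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# Family template: roles, generations, relatedness matrix A and spouse
# indicator S for a family with k children and (optionally) a third
# generation of g grandchildren borne by the eldest child and their spouse.
.family_template <- function(k, g) {
  roles <- c("father", "mother", paste0("child", seq_len(k)))
  gen <- c(1, 1, rep(2, k))
  if (g > 0) {
    roles <- c(roles, "spouse1", paste0("grandchild", seq_len(g)))
    gen <- c(gen, 2, rep(3, g))
  }
  m <- length(roles)
  A <- matrix(0, m, m)
  childs <- 2 + seq_len(k)
  A[1, childs] <- A[childs, 1] <- 0.5
  A[2, childs] <- A[childs, 2] <- 0.5
  if (k > 1) for (i in childs) for (j in childs) if (i != j) A[i, j] <- 0.5
  S <- matrix(0, m, m)
  S[1, 2] <- S[2, 1] <- 1
  if (g > 0) {
    sp <- 2 + k + 1
    gks <- sp + seq_len(g)
    A[3, gks] <- A[gks, 3] <- 0.5          # eldest child is their parent
    A[sp, gks] <- A[gks, sp] <- 0.5
    A[1, gks] <- A[gks, 1] <- 0.25         # grandparents
    A[2, gks] <- A[gks, 2] <- 0.25
    if (k > 1) for (i in childs[-1]) A[i, gks] <- A[gks, i] <- 0.25  # avuncular
    if (g > 1) for (i in gks) for (j in gks) if (i != j) A[i, j] <- 0.5
    S[3, sp] <- S[sp, 3] <- 1
  }
  diag(A) <- 1
  list(roles = roles, gen = gen, A = A, S = S, k = k, g = g, m = m)
}

#' Joint liability covariance for one family template
#'
#' Builds the covariance of the stacked liabilities (member-major, disorder
#' within member): `A (x) F + I (x) E + S (x) diag(spousal)`, where `A` is
#' the relatedness matrix of the template, `S` its spouse indicator, and
#' `F`, `E` the familial and residual covariance matrices. The result is
#' checked for positive semidefiniteness; a spousal term large enough to
#' break it is rejected with the smallest eigenvalue reported.
#'
#' @param A Relatedness matrix (unit diagonal, pairwise `a_R` off-diagonal).
#' @param F_mat Familial covariance (`F_pp = h_p`).
#' @param E_mat Residual covariance (`E_pp = 1 - h_p`).
#' @param spousal Per-disorder spousal liability correlation.
#' @param S Spouse indicator matrix matching `A` (default: none).
#' @return Covariance matrix of dimension `nrow(A) * nrow(F_mat)`.
#' @export
build_family_covariance <- function(A, F_mat, E_mat, spousal = 0,
                                    S = matrix(0, nrow(A), nrow(A))) {
  d <- nrow(F_mat)
  spousal <- rep_len(spousal, d)
  Sigma <- kronecker(A, F_mat) + kronecker(diag(nrow(A)), E_mat) +
    kronecker(S, diag(spousal, d))
  Sigma <- (Sigma + t(Sigma)) / 2
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10)
    stop(sprintf("family covariance is not positive semidefinite (min eigenvalue %.3g); the spousal correlation may be too large", min(ev)))
  Sigma
}

#' Simulate a three-generation family cohort
#'
#' Draws per-family multivariate-normal liabilities under the configured
#' covariance, assigns case status by per-disorder thresholds calibrated so
#' the marginal prevalence matches the target (accounting for any sex/age
#' liability shifts), attaches per-wave participation and auxiliary flags,
#' and returns a person table in the schema accepted by [build_pedigree()].
#' Identical configuration and seed reproduce the table exactly.
#'
#' @param config A [sim_config()].
#' @return `data.frame` of persons with attribute `"disorders"`.
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) stop("config must come from sim_config()")
  cfg <- config
  .with_seed(cfg$seed, {
    n <- cfg$n_families
    d <- length(cfg$disorders)
    ks <- as.integer(sample(names(cfg$structure$n_children), n, replace = TRUE,
                            prob = cfg$structure$n_children))
    third <- runif(n) < cfg$structure$p_third_gen
    gs <- ifelse(third, sample(1:2, n, replace = TRUE), 0L)
    key <- paste(ks, gs)
    fam_of <- person_rows <- list()
    L_list <- list()
    for (kk in unique(key)) {
      idx <- which(key == kk)
      tpl <- .family_template(ks[idx[1]], gs[idx[1]])
      Sigma <- build_family_covariance(tpl$A, cfg$F, cfg$E, cfg$spousal_corr,
                                       tpl$S)
      U <- chol(Sigma)
      nf <- length(idx)
      Z <- matrix(rnorm(nf * tpl$m * d), nf) %*% U
      rows <- .template_rows(tpl, idx)
      L <- matrix(t(Z), ncol = d, byrow = TRUE)  # person-major rows
      L_list[[kk]] <- L
      person_rows[[kk]] <- rows
    }
    persons <- do.call(rbind, person_rows)
    L <- do.call(rbind, L_list)
    ord <- order(persons$fam, persons$member)
    persons <- persons[ord, ]
    L <- L[ord, , drop = FALSE]
    np <- nrow(persons)
    sex <- persons$sex
    age <- persons$age
    zage <- (age - mean(age)) / stats::sd(age)
    underlying <- matrix(NA, np, d)
    for (p in seq_len(d)) {
      shift <- cfg$sex_effect[p] * ifelse(sex == "female", 0.5, -0.5) +
        cfg$age_effect[[p]][1] * zage + cfg$age_effect[[p]][2] * (zage^2 - 1)
      K <- cfg$prevalence[p]
      t_p <- if (all(shift == 0)) qnorm(K, lower.tail = FALSE) else
        uniroot(function(t) mean(pnorm(t - shift, lower.tail = FALSE)) - K,
                c(-10, 10), tol = 1e-10)$root
      underlying[, p] <- (L[, p] + shift) > t_p
    }
    part <- cbind(rep(TRUE, np),
                  runif(np) < cfg$dropout$base[["w2"]],
                  runif(np) < cfg$dropout$base[["w3"]])
    colnames(part) <- paste0("participation_w", 1:3)
    out <- data.frame(family_id = persons$family_id,
                      person_id = persons$person_id,
                      father_id = persons$father_id,
                      mother_id = persons$mother_id,
                      spouse_id = persons$spouse_id,
                      cohabiting = persons$cohabiting,
                      sex = sex, age = round(age, 1),
                      part, stringsAsFactors = FALSE)
    for (p in seq_len(d))
      out[[cfg$disorders[p]]] <- as.integer(underlying[, p])
    any_case <- rowSums(underlying) > 0
    out$somatic_flag <- runif(np) <
      ifelse(any_case, cfg$aux$p_somatic_case, cfg$aux$p_somatic_control)
    for (p in seq_len(d)) {
      dis <- cfg$disorders[p]
      dur <- rep(NA_real_, np); intf <- rep(NA, np)
      cs <- which(underlying[, p])
      if (length(cs)) {
        long <- runif(length(cs)) < cfg$aux$p_duration6
        dur[cs] <- ifelse(long, 6 + stats::rpois(length(cs), 6),
                          sample(1:5, length(cs), replace = TRUE))
        intf[cs] <- runif(length(cs)) < cfg$aux$p_interference
      }
      out[[paste0(dis, "_duration")]] <- dur
      out[[paste0(dis, "_interference")]] <- as.logical(intf)
    }
    attr(out, "disorders") <- cfg$disorders
    attr(out, "assessed_waves") <- cfg$assessed_waves
    attr(out, "dropout_base") <- cfg$dropout$base
    out <- .apply_observation(out)
    if (cfg$dropout$or != 1)
      out <- apply_selective_dropout(out, or = cfg$dropout$or,
                                     seed = cfg$seed + 1L)
    rownames(out) <- NULL
    out
  })
}

# Person-level rows for one template applied to a set of family indices:
# ids, links, sex, age, cohabitation. Vectorized over families.
.template_rows <- function(tpl, fam_idx) {
  nf <- length(fam_idx)
  m <- tpl$m
  fam <- rep(fam_idx, each = m)
  member <- rep(seq_len(m), nf)
  pid <- sprintf("F%05d_%d", fam, member)
  mk <- function(j) sprintf("F%05d_%d", fam_idx, j)
  father_id <- mother_id <- spouse_id <- rep(NA_character_, nf * m)
  cohab <- rep(FALSE, nf * m)
  sex <- rep(NA_character_, nf * m)
  sel <- function(j) which(member == j)
  sex[sel(1)] <- "male"; sex[sel(2)] <- "female"
  spouse_id[sel(1)] <- mk(2); spouse_id[sel(2)] <- mk(1)
  cohab[sel(1)] <- cohab[sel(2)] <- TRUE
  childs <- 2 + seq_len(tpl$k)
  for (j in childs) {
    father_id[sel(j)] <- mk(1); mother_id[sel(j)] <- mk(2)
    sex[sel(j)] <- sample(c("male", "female"), nf, replace = TRUE)
  }
  gen <- tpl$gen
  if (tpl$g > 0) {
    sp <- 2 + tpl$k + 1
    sex[sel(sp)] <- ifelse(sex[sel(3)] == "male", "female", "male")
    spouse_id[sel(3)] <- mk(sp); spouse_id[sel(sp)] <- mk(3)
    cohab[sel(3)] <- cohab[sel(sp)] <- TRUE
    gks <- sp + seq_len(tpl$g)
    for (j in gks) {
      c1_male <- sex[sel(3)] == "male"
      father_id[sel(j)] <- ifelse(c1_male, mk(3), mk(sp))
      mother_id[sel(j)] <- ifelse(c1_male, mk(sp), mk(3))
      sex[sel(j)] <- sample(c("male", "female"), nf, replace = TRUE)
    }
  }
  age_mean <- c(58, 30, 19)[gen]
  age_sd <- c(7, 6, 1)[gen]
  age <- pmax(18, rnorm(nf * m, age_mean[member], age_sd[member]))
  data.frame(fam = fam, member = member, family_id = sprintf("F%05d", fam),
             person_id = pid, father_id = father_id, mother_id = mother_id,
             spouse_id = spouse_id, cohabiting = cohab, sex = sex, age = age,
             stringsAsFactors = FALSE)
}

# Observed status: a disorder's status is known iff the person participated
# in at least one wave in which it is assessed; otherwise missing. The
# aggregated definition is "case in any participated wave".
.apply_observation <- function(cohort) {
  waves <- attr(cohort, "assessed_waves")
  part <- as.matrix(cohort[paste0("participation_w", 1:3)])
  for (dis in attr(cohort, "disorders")) {
    w <- waves[[dis]] %||% (1:3)
    seen <- rowSums(part[, w, drop = FALSE], na.rm = TRUE) > 0
    cohort[[dis]][!seen] <- NA_integer_
  }
  cohort
}

#' Apply selective dropout to later assessment waves
#'
#' Redraws wave-2 and wave-3 participation from a logistic model in which
#' persons with at least one affected first-degree relative participate at
#' odds `or` relative to the baseline; the baseline participation rate is
#' preserved for the unexposed. Disorder statuses that become unobserved
#' (no participation in any assessing wave) are set to missing.
#'
#' @param cohort Cohort table (from [simulate_cohort()] or equivalent; needs
#'   the pedigree link columns).
#' @param or Participation odds ratio for the exposed; must be positive.
#' @param waves Waves to redraw (default 2 and 3).
#' @param base Named baseline participation probabilities (`w2`, `w3`);
#'   defaults to the cohort's `"dropout_base"` attribute.
#' @param seed Integer seed.
#' @return The cohort with updated participation and observed statuses.
#' @export
apply_selective_dropout <- function(cohort, or, waves = c(2, 3),
                                    base = attr(cohort, "dropout_base"),
                                    seed = 1L) {
  if (!is.numeric(or) || or <= 0) stop("dropout odds ratio must be positive")
  if (is.null(base)) base <- c(w2 = 0.8, w3 = 0.75)
  ped <- build_pedigree(cohort)
  fd <- relative_pairs(ped, c("parent-offspring", "full-sibling"))
  status <- as.matrix(cohort[attr(cohort, "disorders")])
  any_case <- rowSums(status, na.rm = TRUE) > 0
  idx_p <- match(fd$proband_id, cohort$person_id)
  idx_r <- match(fd$relative_id, cohort$person_id)
  exposed <- logical(nrow(cohort))
  exposed[idx_p[any_case[idx_r]]] <- TRUE
  exposed[idx_r[any_case[idx_p]]] <- TRUE
  .with_seed(seed, {
    for (w in waves) {
      b <- base[[paste0("w", w)]]
      p <- plogis(qlogis(b) + log(or) * exposed)
      cohort[[paste0("participation_w", w)]] <- runif(nrow(cohort)) < p
    }
  })
  .apply_observation(cohort)
}
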