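# Cohort-level familiality and familial-correlation estimation: pair-based
# conditional prevalences -> Reich-corrected liability estimators, with a
# cluster bootstrap over families.

.degree_pairs <- function(pairs, degree = c("first", "second")) {
  degree <- match.arg(degree)
  if (degree == "first")
    pairs[pairs$relationship %in% c("parent-offspring", "full-sibling"), ]
  else
    pairs[pairs$degree == "2", ]
}

# Per-family sufficient statistics for prevalence and pair-concordance
# estimates, so that a cluster bootstrap reduces to reweighting rows.
# Columns (per disorder pair a, b):
#   nst_a, ncase_a, nst_b, ncase_b       person-level status counts
#   den_ab, num_ab                       double-entered (A-proband, B-relative)
#   den_ba, num_ba                       the reverse direction
.family_counts <- function(cohort, pairs, disorder_a, disorder_b = disorder_a) {
  fam <- factor(cohort$family_id)
  sa <- cohort[[disorder_a]]; sb <- cohort[[disorder_b]]
  person <- cbind(nst_a = !is.na(sa), ncase_a = isTRUE_v(sa == 1),
                  nst_b = !is.na(sb), ncase_b = isTRUE_v(sb == 1))
  pc <- rowsum(person + 0, fam)
  ia <- match(pairs$proband_id, cohort$person_id)
  ib <- match(pairs$relative_id, cohort$person_id)
  # double entry: both orderings of every pair
  i1 <- c(ia, ib); i2 <- c(ib, ia)
  pfam <- factor(cohort$family_id[i1], levels = levels(fam))
  a1 <- sa[i1]; b2 <- sb[i2]   # proband scored on a, relative on b
  b1 <- sb[i1]; a2 <- sa[i2]
  pairc <- cbind(den_ab = isTRUE_v(a1 == 1) & !is.na(b2),
                 num_ab = isTRUE_v(a1 == 1) & isTRUE_v(b2 == 1),
                 den_ba = isTRUE_v(b1 == 1) & !is.na(a2),
                 num_ba = isTRUE_v(b1 == 1) & isTRUE_v(a2 == 1),
                 den_aa = isTRUE_v(a1 == 1) & !is.na(a2),
                 num_aa = isTRUE_v(a1 == 1) & isTRUE_v(a2 == 1),
                 den_bb = isTRUE_v(b1 == 1) & !is.na(b2),
                 num_bb = isTRUE_v(b1 == 1) & isTRUE_v(b2 == 1))
  qc <- rowsum(pairc + 0, pfam)
  m <- matrix(0, nlevels(fam), 12,
              dimnames = list(levels(fam),
                              c(colnames(pc), colnames(pairc))))
  m[rownames(pc), 1:4] <- pc
  m[rownames(qc), 5:12] <- qc
  m
}

# Point estimators on summed counts. Return NULL on degenerate sums.
.h_pt <- function(nst, ncase, den, num, a_R) {
  K <- ncase / nst
  K_R <- num / den
  if (!is.finite(K) || !is.finite(K_R) || K <= 0 || K >= 1 ||
      K_R <= 0 || K_R >= 1) return(NULL)
  est <- reich_familiality(K, K_R, a_R)
  list(h_f = est$h_f, falconer = est$falconer, K = K, K_R = K_R,
       flag = est$flag)
}

.h_from_counts <- function(cnt, a_R) {
  .h_pt(cnt[["nst_a"]], cnt[["ncase_a"]], cnt[["den_ab"]], cnt[["num_ab"]], a_R)
}

.rf_from_counts <- function(cnt, a_R) {
  Ka <- cnt[["ncase_a"]] / cnt[["nst_a"]]
  Kb <- cnt[["ncase_b"]] / cnt[["nst_b"]]
  ha <- .h_pt(cnt[["nst_a"]], cnt[["ncase_a"]], cnt[["den_aa"]],
              cnt[["num_aa"]], a_R)
  hb <- .h_pt(cnt[["nst_b"]], cnt[["ncase_b"]], cnt[["den_bb"]],
              cnt[["num_bb"]], a_R)
  if (is.null(ha) || is.null(hb)) return(NULL)
  if (ha$h_f <= 0 || hb$h_f <= 0) return(NULL)
  KbA <- cnt[["num_ab"]] / cnt[["den_ab"]]
  KaB <- cnt[["num_ba"]] / cnt[["den_ba"]]
  if (!is.finite(KbA) || !is.finite(KaB) ||
      KbA <= 0 || KbA >= 1 || KaB <= 0 || KaB >= 1) return(NULL)
  fab <- familial_correlation(Ka, Kb, KbA, a_R, ha$h_f, hb$h_f)
  fba <- familial_correlation(Kb, Ka, KaB, a_R, hb$h_f, ha$h_f)
  raw <- (fab$r_f_raw + fba$r_f_raw) / 2
  flag <- unique(c(fab$flag, fba$flag))
  if (abs(raw) > 1 && !"clipped" %in% flag) flag <- c(flag, "clipped")
  list(r_f = min(1, max(-1, raw)), r_f_raw = raw,
       rho_cross = (fab$rho_cross + fba$rho_cross) / 2,
       h_a = ha$h_f, h_b = hb$h_f, K_a = Ka, K_b = Kb, flag = flag)
}

.cluster_boot_counts <- function(counts, stat_fun, B, seed, level) {
  nc <- nrow(counts)
  reps <- .with_seed(seed, {
    vapply(seq_len(B), function(b) {
      w <- tabulate(sample.int(nc, nc, replace = TRUE), nbins = nc)
      r <- stat_fun(colSums(counts * w))
      if (is.null(r)) NA_real_ else r
    }, numeric(1))
  })
  fail <- mean(!is.finite(reps))
  if (fail > 0.2)
    stop(sprintf("bootstrap statistic failed on %.0f%% of replicates", 100 * fail))
  reps <- reps[is.finite(reps)]
  alpha <- (1 - level) / 2
  list(ci = unname(stats::quantile(reps, c(alpha, 1 - alpha))),
       se = stats::sd(reps), var = stats::var(reps), B = length(reps))
}

#' Estimate familiality of a disorder from a family cohort
#'
#' Computes the population prevalence `K` (all persons with known status)
#' and the pair-based conditional prevalence `K_R` — the prevalence among
#' relatives of affected probands, tabulated over double-entered relative
#' pairs of the requested degree — and applies the Reich-corrected
#' liability-threshold estimator [reich_familiality()]. Confidence
#' intervals come from a cluster bootstrap resampling whole families.
#' Negative estimates are reported with a flag, not clipped.
#'
#' @param cohort Cohort table.
#' @param pairs Pair table from [relative_pairs()].
#' @param disorder Disorder code.
#' @param degree `"first"` (parent-offspring + full siblings, `a_R` 0.5) or
#'   `"second"` (half-siblings, grandparent-grandchild, avuncular,
#'   `a_R` 0.25).
#' @param B Bootstrap replicates (default 200).
#' @param seed Integer seed.
#' @param level Confidence level.
#' @return One-row `data.frame`: `disorder`, `degree`, `h_f`, `falconer`,
#'   `ci_low`, `ci_high`, `se`, `var`, `K`, `K_R`, `n_pair_entries`,
#'   `n_families`, `flag`.
#' @export
familiality_estimate <- function(cohort, pairs, disorder,
                                 degree = "first", B = 200, seed = 1L,
                                 level = 0.95) {
  dp <- .degree_pairs(pairs, degree)
  a_R <- if (degree == "first") 0.5 else 0.25
  if (!nrow(dp)) stop("no relative pairs of degree ", degree)
  counts <- .family_counts(cohort, dp, disorder)
  tot <- colSums(counts)
  pt <- .h_from_counts(tot, a_R)
  if (is.null(pt))
    stop("familiality is undefined: degenerate prevalence for ", disorder)
  bs <- .cluster_boot_counts(counts, function(cnt) {
    r <- .h_from_counts(cnt, a_R); if (is.null(r)) NULL else r$h_f
  }, B, seed, level)
  data.frame(disorder = disorder, degree = degree, h_f = pt$h_f,
             falconer = pt$falconer, ci_low = bs$ci[1], ci_high = bs$ci[2],
             se = bs$se, var = bs$var, K = pt$K, K_R = pt$K_R,
             n_pair_entries = unname(tot[["den_ab"]]),
             n_families = nrow(counts),
             flag = paste(pt$flag, collapse = ","),
             stringsAsFactors = FALSE)
}

#' Estimate familiality combining first- and second-degree relatives
#'
#' Runs [familiality_estimate()] per degree and combines the estimates by
#' inverse-variance weighting ([combine_degrees()]); if one degree has no
#' usable pairs the other is returned with a flag.
#'
#' @inheritParams familiality_estimate
#' @return One-row `data.frame` with the combined `h_f`, its bootstrap-based
#'   `se`, and the per-degree components.
#' @export
familiality_combined <- function(cohort, pairs, disorder, B = 200, seed = 1L,
                                 level = 0.95) {
  f1 <- tryCatch(familiality_estimate(cohort, pairs, disorder, "first",
                                      B, seed, level),
                 error = function(e) NULL)
  f2 <- tryCatch(familiality_estimate(cohort, pairs, disorder, "second",
                                      B, seed + 1L, level),
                 error = function(e) NULL)
  cmb <- combine_degrees(if (is.null(f1)) NA else f1$h_f,
                         if (is.null(f1)) NA else f1$var,
                         if (is.null(f2)) NA else f2$h_f,
                         if (is.null(f2)) NA else f2$var)
  z <- qnorm(1 - (1 - level) / 2)
  data.frame(disorder = disorder, h_f = cmb$estimate,
             se = sqrt(cmb$variance),
             ci_low = cmb$estimate - z * sqrt(cmb$variance),
             ci_high = cmb$estimate + z * sqrt(cmb$variance),
             h_f_first = if (is.null(f1)) NA_real_ else f1$h_f,
             h_f_second = if (is.null(f2)) NA_real_ else f2$h_f,
             flag = paste(cmb$flag %||% "", collapse = ","),
             stringsAsFactors = FALSE)
}

#' Estimate the familial correlation between two disorders
#'
#' Pair-based cross-disorder analogue of [familiality_estimate()]: the
#' prevalence of disorder `b` among relatives of `a`-probands (and vice
#' versa) is tabulated over double-entered pairs, converted to a
#' cross-relative liability correlation by the Reich-style inversion, and
#' scaled by `a_R * sqrt(h_a * h_b)` with the familialities estimated from
#' the same pairs. Both proband directions are computed and averaged; the
#' estimate is clipped to `[-1, 1]` (flagged) and the bootstrap interval
#' truncated likewise.
#'
#' @inheritParams familiality_estimate
#' @param disorder_a,disorder_b Disorder codes.
#' @return One-row `data.frame`: `disorder_a`, `disorder_b`, `degree`,
#'   `r_f`, `r_f_raw`, `rho_cross`, `ci_low`, `ci_high`, `se`, `var`,
#'   `h_a`, `h_b`, `flag`.
#' @export
familial_correlation_estimate <- function(cohort, pairs, disorder_a,
                                          disorder_b, degree = "first",
                                          B = 200, seed = 1L, level = 0.95) {
  dp <- .degree_pairs(pairs, degree)
  a_R <- if (degree == "first") 0.5 else 0.25
  if (!nrow(dp)) stop("no relative pairs of degree ", degree)
  counts <- .family_counts(cohort, dp, disorder_a, disorder_b)
  tot <- colSums(counts)
  pt <- .rf_from_counts(tot, a_R)
  if (is.null(pt))
    stop("familial correlation is undefined for ", disorder_a, " / ", disorder_b)
  bs <- .cluster_boot_counts(counts, function(cnt) {
    r <- .rf_from_counts(cnt, a_R); if (is.null(r)) NULL else r$r_f_raw
  }, B, seed, level)
  data.frame(disorder_a = disorder_a, disorder_b = disorder_b, degree = degree,
             r_f = pt$r_f, r_f_raw = pt$r_f_raw, rho_cross = pt$rho_cross,
             ci_low = max(-1, bs$ci[1]), ci_high = min(1, bs$ci[2]),
             se = bs$se, var = bs$var, h_a = pt$h_a, h_b = pt$h_b,
             flag = paste(pt$flag, collapse = ","),
             stringsAsFactors = FALSE)
}

#' Cluster-bootstrap confidence interval for an arbitrary cohort statistic
#'
#' Resamples whole families with replacement, rebuilds a valid cohort
#' (resampled family copies get fresh identifiers so pedigree construction
#' still works), applies `statistic` to each replicate and returns the
#' percentile interval. Errors if the statistic fails on more than 20% of
#' replicates.
#'
#' @param statistic Function taking a cohort `data.frame` and returning a
#'   single number.
#' @param cohort Cohort table.
#' @param B Replicates (at least 50).
#' @param seed Integer seed.
#' @param level Confidence level.
#' @return List: `ci_low`, `ci_high`, `se`, `replicates`.
#' @export
bootstrap_ci <- function(statistic, cohort, B = 200, seed = 1L, level = 0.95) {
  if (B < 50) stop("B must be at least 50")
  fams <- split(seq_len(nrow(cohort)), cohort$family_id)
  nf <- length(fams)
  link_cols <- intersect(c("person_id", "father_id", "mother_id", "spouse_id"),
                         names(cohort))
  reps <- .with_seed(seed, {
    vapply(seq_len(B), function(b) {
      pick <- sample.int(nf, nf, replace = TRUE)
      blocks <- lapply(seq_along(pick), function(k) {
        blk <- cohort[fams[[pick[k]]], , drop = FALSE]
        blk$family_id <- sprintf("bf%06d", k)
        for (col in link_cols)
          blk[[col]] <- ifelse(is.na(blk[[col]]), NA_character_,
                               paste0("bf", k, ":", blk[[col]]))
        blk
      })
      boot_cohort <- do.call(rbind, blocks)
      attr(boot_cohort, "disorders") <- attr(cohort, "disorders")
      attr(boot_cohort, "assessed_waves") <- attr(cohort, "assessed_waves")
      tryCatch(as.numeric(statistic(boot_cohort)), error = function(e) NA_real_)
    }, numeric(1))
  })
  fail <- mean(!is.finite(reps))
  if (fail > 0.2)
    stop(sprintf("statistic failed on %.0f%% of bootstrap replicates", 100 * fail))
  ok <- reps[is.finite(reps)]
  alpha <- (1 - level) / 2
  ci <- unname(stats::quantile(ok, c(alpha, 1 - alpha)))
  list(ci_low = ci[1], ci_high = ci[2], se = stats::sd(ok), replicates = ok)
}
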