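#' Liability-threshold model summary for a prevalence
#'
#' Under the liability-threshold model a standard-normal liability underlies
#' disease status and individuals above a threshold are affected. Given the
#' population prevalence `K` this returns the threshold `t = qnorm(1 - K)`,
#' the normal density `z` at the threshold, and the selection intensity
#' `i = z / K`, the mean liability of affected individuals.
#'
#' @param K Population prevalence, strictly inside (0, 1).
#' @return An object of class `liability_model`: list with `K`, `t`, `z`, `i`.
#' @examples
#' liability_model(0.05)  # t ~ 1.645, i ~ 2.063
#' @export
liability_model <- function(K) {
  if (!is.numeric(K) || length(K) != 1L || is.na(K) || K <= 0 || K >= 1)
    stop("K must be a single probability strictly inside (0, 1)")
  t <- qnorm(K, lower.tail = FALSE)
  z <- dnorm(t)
  structure(list(K = K, t = t, z = z, i = z / K), class = "liability_model")
}

#' @export
print.liability_model <- function(x, ...) {
  cat(sprintf("Liability-threshold model: K = %.4g, t = %.4f, z = %.4f, i = %.4f\n",
              x$K, x$t, x$z, x$i))
  invisible(x)
}

# Reich-style approximate liability correlation between a proband trait and a
# relative trait, from prevalence summaries. Probands are selected on trait A
# (prevalence K_proband, so threshold t_a and selection intensity i_a); the
# relative's trait has population prevalence K_relative (threshold t_b) and
# conditional prevalence K_conditional among relatives of probands (threshold
# t_R). The liability of the relative trait given proband affection is
# approximated as normal with mean rho * i_a and variance 1 - rho^2 * k_a,
# k_a = i_a * (i_a - t_a), and the implied
#   t_R = (t_b - rho * i_a) / sqrt(1 - rho^2 * k_a)
# is inverted for rho in closed form (quadratic; the root continuous in
# K_conditional at rho = 0 is taken). For K_proband == K_relative this
# reduces exactly to the classic Reich same-trait expression
#   rho = (t - t_R * sqrt(1 - (1 - t/i)(t^2 - t_R^2))) / (i + t_R^2 (i - t)).
.reich_rho <- function(K_proband, K_relative, K_conditional) {
  for (p in c(K_proband, K_relative, K_conditional))
    if (!is.finite(p) || p <= 0 || p >= 1)
      stop("prevalences must lie strictly inside (0, 1)")
  la <- liability_model(K_proband)
  tb <- qnorm(K_relative, lower.tail = FALSE)
  tR <- qnorm(K_conditional, lower.tail = FALSE)
  ia <- la$i
  ka <- ia * (ia - la$t)
  denom <- ia^2 + tR^2 * ka
  disc <- tb^2 * ia^2 - denom * (tb^2 - tR^2)
  falconer <- (tb - tR) / ia
  if (disc < 0)
    return(list(rho = falconer, falconer = falconer, flag = "falconer_fallback"))
  list(rho = (tb * ia - sqrt(disc)) / denom, falconer = falconer, flag = NULL)
}

#' Familiality from population and relative prevalences (Reich-corrected)
#'
#' Estimates familiality `h_f` (the proportion of liability variance due to
#' familial effects) from the population prevalence `K` and the prevalence
#' `K_R` of the disorder among relatives of affected probands, for a relative
#' class with relatedness weight `a_R` (0.5 first-degree, 0.25 second-degree).
#' The pairwise liability correlation is obtained by the Reich--James--Morris
#' corrected inversion of the threshold relation and divided by `a_R`; the
#' first-order Falconer value `(t - t_R) / (a_R i)` is returned alongside for
#' diagnostics. A negative radicand in the correction (possible for extreme
#' inputs) triggers a flagged fallback to the Falconer value.
#'
#' @param K Population prevalence in (0, 1).
#' @param K_R Prevalence among relatives of affected probands, in (0, 1).
#' @param a_R Relatedness weight, 0.5 or 0.25.
#' @return Object of class `familiality`: list with `h_f`, `falconer`, `rho`
#'   (the pairwise liability correlation `a_R * h_f`), inputs, and `flag`.
#' @examples
#' reich_familiality(0.05, 0.113, 0.5)  # Falconer component ~ 0.42
#' @export
reich_familiality <- function(K, K_R, a_R) {
  if (!a_R %in% c(0.5, 0.25)) stop("a_R must be 0.5 or 0.25")
  r <- .reich_rho(K, K, K_R)
  structure(list(h_f = r$rho / a_R, falconer = r$falconer / a_R,
                 rho = r$rho, K = K, K_R = K_R, a_R = a_R, flag = r$flag),
            class = "familiality")
}

#' @export
print.familiality <- function(x, ...) {
  cat(sprintf("Familiality h_f = %.4f (Falconer %.4f), K = %.4g, K_R = %.4g, a_R = %.2f%s\n",
              x$h_f, x$falconer, x$K, x$K_R, x$a_R,
              if (!is.null(x$flag)) paste0(" [", x$flag, "]") else ""))
  invisible(x)
}

#' Exact conditional prevalence in relatives under the liability model
#'
#' For a bivariate standard-normal liability with correlation `rho`, returns
#' `P(relative affected | proband affected)` where the proband trait has
#' prevalence `K_proband` and the relative trait `K_relative`. This is the
#' exact forward computation the Reich approximation targets, and serves as
#' its oracle.
#'
#' @param rho Liability correlation, `|rho| <= 1`.
#' @param K_proband,K_relative Prevalences in (0, 1).
#' @return Conditional prevalence (scalar, vectorized over `rho`).
#' @examples
#' exact_relative_prevalence(0.21, 0.05, 0.05)  # ~ 0.11
#' @export
exact_relative_prevalence <- function(rho, K_proband, K_relative) {
  tp <- qnorm(K_proband, lower.tail = FALSE)
  tr <- qnorm(K_relative, lower.tail = FALSE)
  pbvnorm_upper(tp, tr, rho) / K_proband
}

#' Exact liability correlation from a conditional prevalence
#'
#' Numerically inverts [exact_relative_prevalence()]: finds the unique `rho`
#' such that relatives of probands (trait prevalence `K_proband`) show the
#' relative trait (prevalence `K_relative`) at rate `K_conditional`.
#' Root-finding is bracketed on `(-1, 1)` and polished to a residual below
#' 1e-8 on the prevalence scale.
#'
#' @param K_proband,K_relative,K_conditional Prevalences in (0, 1).
#' @return The liability correlation `rho`.
#' @examples
#' exact_rho(0.05, 0.05, exact_relative_prevalence(0.21, 0.05, 0.05))
#' @export
exact_rho <- function(K_proband, K_relative, K_conditional) {
  f <- function(r) exact_relative_prevalence(r, K_proband, K_relative) - K_conditional
  eps <- 1e-12
  if (f(-1 + eps) > 0 || f(1 - eps) < 0)
    stop("K_conditional is not attainable for these marginal prevalences")
  r <- uniroot(f, c(-1 + eps, 1 - eps), tol = 1e-12)$root
  if (abs(f(r)) > 1e-8)
    stop("root-finding did not reach the requested tolerance")
  r
}

#' Cross-disorder familial correlation from prevalence summaries
#'
#' Estimates the familial correlation `r_f` between disorders `a` and `b`
#' from the prevalence of disorder `b` among relatives of probands affected
#' by disorder `a`. The cross-relative cross-trait liability correlation
#' `rho_cross` is obtained by the Reich-style inversion (proband selection on
#' `a`, relative threshold for `b`) and scaled by the expected familial
#' sharing: `r_f = rho_cross / (a_R * sqrt(h_a * h_b))`, clipped to
#' `[-1, 1]` with a flag when clipping occurs.
#'
#' @param K_a,K_b Population prevalences of the two disorders.
#' @param K_b_given_relA Prevalence of disorder `b` among relatives of
#'   `a`-probands.
#' @param a_R Relatedness weight (0.5 or 0.25).
#' @param h_a,h_b Familialities of the two disorders (both > 0).
#' @return Object of class `familial_correlation`: list with `r_f`,
#'   `rho_cross`, inputs and `flag`.
#' @examples
#' familial_correlation(0.05, 0.15, 0.18, 0.5, 0.42, 0.35)
#' @export
familial_correlation <- function(K_a, K_b, K_b_given_relA, a_R, h_a, h_b) {
  if (!a_R %in% c(0.5, 0.25)) stop("a_R must be 0.5 or 0.25")
  if (!is.finite(h_a) || !is.finite(h_b) || h_a <= 0 || h_b <= 0)
    stop("familialities h_a and h_b must both be positive")
  r <- .reich_rho(K_a, K_b, K_b_given_relA)
  raw <- r$rho / (a_R * sqrt(h_a * h_b))
  flag <- r$flag
  if (abs(raw) > 1) flag <- c(flag, "clipped")
  structure(list(r_f = pmin(1, pmax(-1, raw)), r_f_raw = raw,
                 rho_cross = r$rho, K_a = K_a, K_b = K_b,
                 K_b_given_relA = K_b_given_relA, a_R = a_R,
                 h_a = h_a, h_b = h_b, flag = flag),
            class = "familial_correlation")
}

#' @export
print.familial_correlation <- function(x, ...) {
  cat(sprintf("Familial correlation r_f = %.4f (rho_cross = %.4f)%s\n",
              x$r_f, x$rho_cross,
              if (length(x$flag)) paste0(" [", paste(x$flag, collapse = ","), "]") else ""))
  invisible(x)
}

#' Inverse-variance combination of per-degree estimates
#'
#' Combines a first-degree and a second-degree estimate of the same quantity
#' (familiality or familial correlation) by inverse-variance weighting. If
#' one estimate is missing the other is passed through with a flag.
#'
#' @param est_first,est_second Point estimates (may be `NA`).
#' @param var_first,var_second Their variances (e.g. bootstrap).
#' @return List with `estimate`, `variance`, `flag`.
#' @examples
#' combine_degrees(0.4, 0.01, 0.2, 0.03)  # 0.35
#' @export
combine_degrees <- function(est_first, var_first, est_second, var_second) {
  ok1 <- is.finite(est_first) && is.finite(var_first) && var_first > 0
  ok2 <- is.finite(est_second) && is.finite(var_second) && var_second > 0
  if (!ok1 && !ok2) stop("both per-degree estimates are missing")
  if (!ok2) return(list(estimate = est_first, variance = var_first,
                        flag = "first_degree_only"))
  if (!ok1) return(list(estimate = est_second, variance = var_second,
                        flag = "second_degree_only"))
  w1 <- 1 / var_first; w2 <- 1 / var_second
  list(estimate = (w1 * est_first + w2 * est_second) / (w1 + w2),
       variance = 1 / (w1 + w2), flag = NULL)
}
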