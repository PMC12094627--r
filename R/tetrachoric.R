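# Tetrachoric correlation from paired binary data with family-cluster-aware
# uncertainty (two-step MLE + cluster bootstrap).

#' Build a 2x2 pair table for two disorders over relative pairs
#'
#' Tabulates the joint case status of relative pairs for two (possibly
#' identical) disorders. Pairs with a missing status on either side are
#' dropped. For symmetric configurations — sibling pairs, or the same
#' disorder on both sides — each pair is double-entered (both orderings),
#' flagged in the result; parent-offspring trios contribute two pairs
#' sharing one cluster id, so clustering is preserved. For cross-disorder
#' parent-offspring tables both role assignments (parent scored on `a` with
#' child on `b`, and vice versa) are entered, which symmetrizes the table.
#'
#' @param pairs Pair table from [relative_pairs()], already restricted to
#'   the relation of interest (e.g. full siblings, or parent-offspring).
#' @param cohort Cohort table.
#' @param disorder_a,disorder_b Disorder codes.
#' @param double_enter Force double entry on or off; default chooses it
#'   for symmetric configurations as described.
#' @return Object of class `pair_table`: list with `counts` (2x2 matrix,
#'   rows = first member case/control, columns = second member),
#'   `x`, `y` (per-entry statuses), `cluster` (per-entry nuclear-family id),
#'   `double_entered`, `n_pairs`, `n_clusters`.
#' @export
pair_table <- function(pairs, cohort, disorder_a, disorder_b = disorder_a,
                       double_enter = NULL) {
  for (dis in c(disorder_a, disorder_b))
    if (!dis %in% names(cohort)) stop("unknown disorder code: ", dis)
  sym_relation <- all(pairs$relationship != "parent-offspring")
  if (is.null(double_enter))
    double_enter <- sym_relation || identical(disorder_a, disorder_b) ||
      any(pairs$relationship == "parent-offspring")
  ia <- match(pairs$proband_id, cohort$person_id)
  ib <- match(pairs$relative_id, cohort$person_id)
  x <- cohort[[disorder_a]][ia]; y <- cohort[[disorder_b]][ib]
  cl <- pairs$cluster_id
  if (double_enter) {
    x2 <- cohort[[disorder_b]][ia]; y2 <- cohort[[disorder_a]][ib]
    x <- c(x, y2); y <- c(y, x2); cl <- c(cl, cl)
  }
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]; cl <- cl[ok]
  if (!length(x)) stop("no relative pairs with both statuses observed")
  counts <- matrix(c(sum(x == 1 & y == 1), sum(x == 1 & y == 0),
                     sum(x == 0 & y == 1), sum(x == 0 & y == 0)),
                   2, 2, byrow = TRUE,
                   dimnames = list(c("case", "control"), c("case", "control")))
  structure(list(counts = counts, x = x, y = y, cluster = cl,
                 double_entered = double_enter,
                 n_pairs = if (double_enter) length(x) / 2 else length(x),
                 n_clusters = length(unique(cl)),
                 disorder_a = disorder_a, disorder_b = disorder_b),
            class = "pair_table")
}

#' Two-step tetrachoric maximum-likelihood estimate
#'
#' Estimates the latent bivariate-normal correlation underlying a 2x2 table.
#' Thresholds are fixed at the normal quantiles of the observed margins
#' (two-step estimator); `rho` maximizes the multinomial likelihood of the
#' table, with cell probabilities from the bivariate-normal orthant
#' probability. A zero cell triggers a continuity correction (+0.5 to every
#' cell, flagged); solutions at the boundary are returned as +/-1 with a
#' flag rather than an error.
#'
#' @param tab A `pair_table`, or a 2x2 matrix of counts
#'   (rows/cols = case, control).
#' @return Object of class `tetrachoric`: list with `rho`, `thresholds`,
#'   `counts`, `n`, `flag`.
#' @export
tetrachoric_mle <- function(tab) {
  counts <- if (inherits(tab, "pair_table")) tab$counts else as.matrix(tab)
  if (!all(dim(counts) == c(2, 2)) || any(counts < 0))
    stop("counts must be a 2x2 non-negative table")
  if (sum(counts > 0) < 2)
    stop("at least two non-empty cells are required")
  flag <- character(0)
  if (any(counts == 0)) {
    counts <- counts + 0.5
    flag <- "continuity_correction"
  }
  n <- sum(counts)
  pa <- sum(counts[1, ]) / n   # margin: first member case
  pb <- sum(counts[, 1]) / n
  if (pa <= 0 || pa >= 1 || pb <= 0 || pb >= 1)
    stop("a margin is empty: tetrachoric correlation is undefined")
  ta <- qnorm(pa, lower.tail = FALSE)
  tb <- qnorm(pb, lower.tail = FALSE)
  negll <- function(rho) {
    p11 <- pbvnorm_upper(ta, tb, rho)
    p10 <- pa - p11; p01 <- pb - p11; p00 <- 1 - pa - pb + p11
    p <- pmax(c(p11, p10, p01, p00), 1e-12)
    -sum(c(counts[1, 1], counts[1, 2], counts[2, 1], counts[2, 2]) * log(p))
  }
  opt <- stats::optimize(negll, c(-0.9999, 0.9999), tol = 1e-9)
  rho <- opt$minimum
  if (abs(rho) > 0.999) {
    rho <- sign(rho)
    flag <- c(flag, "boundary")
  }
  structure(list(rho = rho, thresholds = c(ta, tb),
                 counts = counts, n = n, flag = flag),
            class = "tetrachoric")
}

#' @export
print.tetrachoric <- function(x, ...) {
  cat(sprintf("Tetrachoric rho = %.4f (thresholds %.3f, %.3f; n = %g)%s\n",
              x$rho, x$thresholds[1], x$thresholds[2], x$n,
              if (length(x$flag)) paste0(" [", paste(x$flag, collapse = ","), "]")
              else ""))
  invisible(x)
}

#' Family-clustered tetrachoric correlation
#'
#' Point estimate from the two-step MLE on the full pair table; standard
#' error and percentile confidence interval from a cluster bootstrap that
#' resamples nuclear families with replacement, respecting within-family
#' dependence (double-entered orderings and trio pairs move with their
#' cluster).
#'
#' @param pairs Pair table restricted to the relation of interest.
#' @param cohort Cohort table.
#' @param disorder_a,disorder_b Disorder codes.
#' @param B Bootstrap replicates (default 500).
#' @param seed Integer seed for the bootstrap.
#' @param level Confidence level.
#' @return Object of class `tetrachoric` with added `se`, `ci_low`,
#'   `ci_high`, `n_pairs`, `n_clusters`, `B`.
#' @export
clustered_tetrachoric <- function(pairs, cohort, disorder_a,
                                  disorder_b = disorder_a, B = 500,
                                  seed = 1L, level = 0.95) {
  tab <- pair_table(pairs, cohort, disorder_a, disorder_b)
  if (tab$n_clusters < 2) stop("at least two clusters are required")
  est <- tetrachoric_mle(tab)
  # per-cluster 2x2 cell counts, so a bootstrap replicate is a weighted sum
  cell <- factor(paste(tab$x, tab$y), levels = c("1 1", "1 0", "0 1", "0 0"))
  cl <- factor(tab$cluster)
  per_cluster <- table(cl, cell)  # n_clusters x 4
  per_cluster <- matrix(as.numeric(per_cluster), ncol = 4)
  nc <- nrow(per_cluster)
  boot <- .with_seed(seed, {
    vapply(seq_len(B), function(b) {
      w <- tabulate(sample.int(nc, nc, replace = TRUE), nbins = nc)
      cnt <- colSums(per_cluster * w)
      m <- matrix(cnt, 2, 2, byrow = TRUE)
      tryCatch(tetrachoric_mle(m)$rho, error = function(e) NA_real_)
    }, numeric(1))
  })
  boot <- boot[is.finite(boot)]
  alpha <- (1 - level) / 2
  ci <- if (length(boot) >= 2)
    unname(stats::quantile(boot, c(alpha, 1 - alpha))) else c(NA_real_, NA_real_)
  est$se <- if (length(boot) >= 2) stats::sd(boot) else NA_real_
  est$ci_low <- ci[1]; est$ci_high <- ci[2]
  est$n_pairs <- tab$n_pairs; est$n_clusters <- tab$n_clusters
  est$double_entered <- tab$double_entered
  est$disorder_a <- disorder_a; est$disorder_b <- disorder_b
  est$B <- length(boot)
  est
}
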