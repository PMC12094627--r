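# End-to-end orchestration: simulate/read -> pairs -> lambda_R /
# tetrachoric / familiality / familial correlation -> CSV outputs, with the
# three sensitivity analyses and a reproducibility manifest.

#' Exclude cases with somatic conditions mimicking a functional disorder
#'
#' For every disorder in `exclusion_map`, persons who are cases of that
#' disorder and carry any of its mapped flags have that disorder's status
#' set to missing (they drop out of the disorder's analyses); all other
#' rows are untouched.
#'
#' @param cohort Cohort table.
#' @param exclusion_map Named list: disorder code -> character vector of
#'   logical flag columns (e.g. `list(CFS = "somatic_flag")`).
#' @return The cohort with statuses masked.
#' @export
apply_exclusions <- function(cohort, exclusion_map) {
  for (dis in names(exclusion_map)) {
    if (!dis %in% names(cohort)) stop("unknown disorder code: ", dis)
    flags <- exclusion_map[[dis]]
    missing_flags <- setdiff(flags, names(cohort))
    if (length(missing_flags))
      stop("unknown flag column(s): ", paste(missing_flags, collapse = ", "))
    flagged <- rep(FALSE, nrow(cohort))
    for (fl in flags) flagged <- flagged | isTRUE_v(cohort[[fl]])
    drop <- isTRUE_v(cohort[[dis]] == 1L) & flagged
    cohort[[dis]][drop] <- NA_integer_
  }
  cohort
}

#' Align diagnostic strictness across functional disorders
#'
#' Redefines case status to additionally require a symptom duration of at
#' least six months and interference with daily activities; controls are
#' unchanged. Requires `<disorder>_duration` (months) and
#' `<disorder>_interference` columns for cases.
#'
#' @param cohort Cohort table.
#' @param disorders Disorders to realign.
#' @return The cohort with redefined statuses.
#' @export
apply_severity_alignment <- function(cohort, disorders) {
  for (dis in disorders) {
    dcol <- paste0(dis, "_duration"); icol <- paste0(dis, "_interference")
    if (!all(c(dcol, icol) %in% names(cohort)))
      stop("duration/interference flags absent for ", dis)
    case <- isTRUE_v(cohort[[dis]] == 1L)
    keep <- case & isTRUE_v(cohort[[dcol]] >= 6) & isTRUE_v(cohort[[icol]])
    cohort[[dis]][case & !keep] <- 0L
  }
  cohort
}

#' Run the full family-aggregation analysis pipeline
#'
#' Simulates (or loads) a cohort, enumerates relative pairs, and produces
#' the full analysis surface: recurrence-risk-ratio matrices per relative
#' class (including spouses), sibling and parent-offspring tetrachoric
#' matrices, familiality and familial-correlation tables, and the
#' participation sensitivity regressions, each written as a long CSV
#' together with a JSON run manifest. Stage failures are recorded in the
#' manifest; independent stages still run. Identical configuration and
#' seed reproduce identical outputs.
#'
#' @param config List (or path to a YAML file) with elements:
#'   `cohort` (path to a cohort CSV) or `simulation` (arguments for
#'   [sim_config()]); `classes` (relative classes for the lambda stage,
#'   default `c("first-degree", "spouse")`); `boot` (bootstrap replicates,
#'   default 500); `seed` (mandatory when simulating or bootstrapping);
#'   `out_dir` (output directory); optional `sensitivity` list with
#'   `dropout_or`, `exclusion_map`, `severity_disorders`; optional
#'   `stages` character vector to restrict which stages run
#'   (`"lambda"`, `"tetrachoric"`, `"familiality"`, `"famcorr"`,
#'   `"participation"`).
#' @return Invisibly, a list of the result tables plus the manifest.
#' @export
run_all <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  out_dir <- config$out_dir %||% "."
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  boot <- config$boot %||% 500
  stages <- config$stages %||%
    c("lambda", "tetrachoric", "familiality", "famcorr", "participation")
  if ((!is.null(config$simulation) || boot > 0) && is.null(config$seed))
    stop("seed is mandatory when simulation or bootstrap is enabled")
  seed <- as.integer(config$seed %||% 1L)
  manifest <- list(seed = seed, boot = boot, stages = stages,
                   r_version = as.character(getRversion()),
                   package_version = as.character(utils::packageVersion("famliab")),
                   errors = list())
  note_error <- function(stage, e) {
    manifest$errors[[stage]] <<- conditionMessage(e)
    NULL
  }
  if (!is.null(config$cohort)) {
    cohort <- read_cohort(config$cohort)
    manifest$cohort <- config$cohort
  } else {
    sim_args <- config$simulation %||% list()
    sim_args$seed <- seed
    cfg <- do.call(sim_config, sim_args)
    cohort <- simulate_cohort(cfg)
    manifest$simulation <- sim_args
  }
  sens <- config$sensitivity %||% list()
  if (!is.null(sens$dropout_or))
    cohort <- apply_selective_dropout(cohort, or = sens$dropout_or,
                                      seed = seed + 101L)
  if (!is.null(sens$exclusion_map))
    cohort <- apply_exclusions(cohort, sens$exclusion_map)
  if (!is.null(sens$severity_disorders))
    cohort <- apply_severity_alignment(cohort, sens$severity_disorders)
  disorders <- attr(cohort, "disorders")
  ped <- build_pedigree(cohort)
  pairs <- relative_pairs(ped)
  write_cohort(cohort, file.path(out_dir, "cohort.csv"))
  utils::write.csv(pairs, file.path(out_dir, "pairs.csv"), row.names = FALSE,
                   na = "")
  results <- list(cohort = cohort, pairs = pairs)
  if ("lambda" %in% stages) {
    classes <- config$classes %||% c("first-degree", "spouse")
    lam <- tryCatch(
      do.call(rbind, lapply(classes, function(cl)
        lambda_matrix(cohort, pairs, disorders, cl))),
      error = function(e) note_error("lambda", e))
    if (!is.null(lam)) {
      utils::write.csv(lam, file.path(out_dir, "lambda.csv"),
                       row.names = FALSE, na = "")
      results$lambda <- lam
    }
  }
  if ("tetrachoric" %in% stages) {
    for (rel in c("sibling", "parent_offspring")) {
      sub <- if (rel == "sibling")
        pairs[pairs$relationship == "full-sibling", ]
      else pairs[pairs$relationship == "parent-offspring", ]
      tet <- tryCatch({
        grid <- expand.grid(a = seq_along(disorders), b = seq_along(disorders))
        grid <- grid[grid$a <= grid$b, ]
        do.call(rbind, lapply(seq_len(nrow(grid)), function(k) {
          da <- disorders[grid$a[k]]; db <- disorders[grid$b[k]]
          r <- tryCatch(clustered_tetrachoric(sub, cohort, da, db, B = boot,
                                              seed = seed + 7L),
                        error = function(e) NULL)
          if (is.null(r))
            data.frame(disorder_a = da, disorder_b = db, relation = rel,
                       rho = NA_real_, se = NA_real_, ci_low = NA_real_,
                       ci_high = NA_real_, n_pairs = NA_real_,
                       n_clusters = NA_real_, flags = "failed")
          else
            data.frame(disorder_a = da, disorder_b = db, relation = rel,
                       rho = r$rho, se = r$se, ci_low = r$ci_low,
                       ci_high = r$ci_high, n_pairs = r$n_pairs,
                       n_clusters = r$n_clusters,
                       flags = paste(r$flag, collapse = ","))
        }))
      }, error = function(e) note_error(paste0("tetrachoric_", rel), e))
      if (!is.null(tet)) {
        utils::write.csv(tet, file.path(out_dir, paste0("rtet_", rel, ".csv")),
                         row.names = FALSE, na = "")
        results[[paste0("rtet_", rel)]] <- tet
      }
    }
  }
  if ("familiality" %in% stages) {
    hf <- tryCatch(
      do.call(rbind, lapply(disorders, function(d)
        familiality_combined(cohort, pairs, d, B = boot, seed = seed + 11L))),
      error = function(e) note_error("familiality", e))
    if (!is.null(hf)) {
      utils::write.csv(hf, file.path(out_dir, "familiality.csv"),
                       row.names = FALSE, na = "")
      results$familiality <- hf
    }
  }
  if ("famcorr" %in% stages && length(disorders) > 1) {
    fc <- tryCatch({
      grid <- utils::combn(disorders, 2)
      do.call(rbind, lapply(seq_len(ncol(grid)), function(k)
        tryCatch(familial_correlation_estimate(cohort, pairs, grid[1, k],
                                               grid[2, k], "first",
                                               B = boot, seed = seed + 13L),
                 error = function(e)
                   data.frame(disorder_a = grid[1, k], disorder_b = grid[2, k],
                              degree = "first", r_f = NA_real_,
                              r_f_raw = NA_real_, rho_cross = NA_real_,
                              ci_low = NA_real_, ci_high = NA_real_,
                              se = NA_real_, var = NA_real_, h_a = NA_real_,
                              h_b = NA_real_, flag = conditionMessage(e)))))
    }, error = function(e) note_error("famcorr", e))
    if (!is.null(fc)) {
      utils::write.csv(fc, file.path(out_dir, "famcorr.csv"),
                       row.names = FALSE, na = "")
      results$famcorr <- fc
    }
  }
  if ("participation" %in% stages) {
    pp <- tryCatch(
      do.call(rbind, lapply(c(2, 3), function(w)
        tryCatch(participation_model(cohort, pairs, wave = w),
                 error = function(e)
                   data.frame(wave = w, or = NA_real_, ci_low = NA_real_,
                              ci_high = NA_real_, se_log_or = NA_real_,
                              n = NA_integer_, n_exposed = NA_integer_)))),
      error = function(e) note_error("participation", e))
    if (!is.null(pp)) {
      utils::write.csv(pp, file.path(out_dir, "participation.csv"),
                       row.names = FALSE, na = "")
      results$participation <- pp
    }
  }
  manifest$outputs <- list.files(out_dir)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  results$manifest <- manifest
  invisible(results)
}
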