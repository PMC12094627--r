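#' Read a phenotype/pedigree table
#'
#' Reads a delimited (comma or tab) person table with one row per cohort
#' member. Required columns: `family_id`, `person_id`, `father_id`,
#' `mother_id`, `spouse_id`, `cohabiting`, `sex`, `age`,
#' `participation_w1`..`participation_w3`, plus one column per disorder
#' (values `case`/`control`/`missing` or `1`/`0`/`NA`) and any auxiliary
#' flag columns. Empty link fields become `NA`.
#'
#' @param path Path to the file. Delimiter is sniffed from the header line.
#' @param disorders Optional character vector naming the disorder columns;
#'   by default every column that is not structural is treated as a disorder
#'   or auxiliary column and disorder columns are those whose values are
#'   limited to case/control/missing codes.
#' @return A `data.frame` with normalized types; disorder status columns are
#'   integer 0/1/NA, attribute `"disorders"` lists their names.
#' @export
read_cohort <- function(path, disorders = NULL) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, na.strings = c("", "NA"),
                          colClasses = "character")
  structural <- c("family_id", "person_id", "father_id", "mother_id",
                  "spouse_id", "cohabiting", "sex", "age",
                  "participation_w1", "participation_w2", "participation_w3")
  missing_cols <- setdiff(c("family_id", "person_id"), names(df))
  if (length(missing_cols))
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  for (col in c("cohabiting", paste0("participation_w", 1:3)))
    if (col %in% names(df)) df[[col]] <- .parse_logical(df[[col]])
  if ("age" %in% names(df)) df$age <- as.numeric(df$age)
  other <- setdiff(names(df), structural)
  if (is.null(disorders)) {
    is_status <- vapply(other, function(col) {
      v <- df[[col]]
      all(is.na(v) | v %in% c("case", "control", "missing", "0", "1",
                              "TRUE", "FALSE"))
    }, logical(1))
    disorders <- other[is_status & !grepl("_duration$|_interference$|^somatic", other)]
  }
  for (col in disorders) df[[col]] <- .parse_status(df[[col]])
  for (col in grep("_interference$|^somatic", other, value = TRUE))
    df[[col]] <- .parse_logical(df[[col]])
  for (col in grep("_duration$", other, value = TRUE))
    df[[col]] <- as.numeric(df[[col]])
  attr(df, "disorders") <- disorders
  df
}

.parse_logical <- function(v) {
  if (is.logical(v)) return(v)
  out <- rep(NA, length(v))
  out[v %in% c("1", "TRUE", "true", "yes")] <- TRUE
  out[v %in% c("0", "FALSE", "false", "no")] <- FALSE
  as.logical(out)
}

.parse_status <- function(v) {
  if (is.numeric(v)) return(as.integer(v))
  out <- rep(NA_integer_, length(v))
  out[v %in% c("case", "1", "TRUE")] <- 1L
  out[v %in% c("control", "0", "FALSE")] <- 0L
  out
}

#' Write a cohort table to CSV
#'
#' Inverse of [read_cohort()]: status columns are written as 0/1 with empty
#' fields for missing, so a written table reads back identically.
#'
#' @param cohort Cohort `data.frame`.
#' @param path Output path.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' Build a pedigree from a person table
#'
#' Validates identifiers and parent links and assembles the lookup structures
#' used by relationship classification and pair enumeration. Persons with no
#' links are retained as singletons. Parent identifiers that do not resolve
#' to a row of the table are dropped with a warning (the person is kept).
#'
#' @param records Cohort `data.frame` as produced by [read_cohort()] or
#'   [simulate_cohort()].
#' @return An object of class `pedigree`.
#' @export
build_pedigree <- function(records) {
  if (anyDuplicated(records$person_id))
    stop("duplicate person_id: ",
         paste(unique(records$person_id[duplicated(records$person_id)]), collapse = ", "))
  id <- as.character(records$person_id)
  fa <- as.character(records$father_id %||% rep(NA, nrow(records)))
  mo <- as.character(records$mother_id %||% rep(NA, nrow(records)))
  fa[!(fa %in% id)] <- NA
  mo[!(mo %in% id)] <- NA
  if (!is.null(records$father_id)) {
    bad <- !is.na(records$father_id) & is.na(fa) |
           !is.na(records$mother_id) & is.na(mo)
    if (any(bad))
      warning(sum(bad), " parent link(s) do not resolve and were dropped")
  }
  fa_idx <- match(fa, id)
  mo_idx <- match(mo, id)
  .check_ancestry_cycles(id, fa_idx, mo_idx)
  ped <- structure(list(persons = records, id = id,
                        father = fa_idx, mother = mo_idx,
                        disorders = attr(records, "disorders")),
                   class = "pedigree")
  ped
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Depth-first walk over parent edges; errors with the offending chain if a
# person is its own ancestor.
.check_ancestry_cycles <- function(id, fa, mo) {
  n <- length(id)
  state <- integer(n)  # 0 unvisited, 1 in progress, 2 done
  for (s in seq_len(n)) {
    if (state[s] != 0L) next
    stack <- s; path <- integer(0)
    while (length(stack)) {
      v <- stack[length(stack)]
      if (v < 0L) {  # marker: finished node -v
        state[-v] <- 2L
        path <- path[-length(path)]
        stack <- stack[-length(stack)]
        next
      }
      if (state[v] == 1L) {
        chain <- id[c(path[which(path == v):length(path)], v)]
        stop("ancestry cycle: ", paste(chain, collapse = " -> "))
      }
      if (state[v] == 2L) { stack <- stack[-length(stack)]; next }
      state[v] <- 1L
      path <- c(path, v)
      stack[length(stack)] <- -v
      for (p in c(fa[v], mo[v]))
        if (!is.na(p)) {
          if (state[p] == 1L) {
            chain <- id[c(path[which(path == p):length(path)], p)]
            stop("ancestry cycle: ", paste(chain, collapse = " -> "))
          }
          if (state[p] == 0L) stack <- c(stack, p)
        }
    }
  }
  invisible(TRUE)
}

#' @export
print.pedigree <- function(x, ...) {
  cat(sprintf("Pedigree: %d persons in %d families, %d parent links\n",
              length(x$id), length(unique(x$persons$family_id)),
              sum(!is.na(x$father)) + sum(!is.na(x$mother))))
  if (length(x$disorders))
    cat("Disorders:", paste(x$disorders, collapse = ", "), "\n")
  invisible(x)
}

.RELATIONSHIPS <- data.frame(
  relationship = c("parent-offspring", "full-sibling", "half-sibling",
                   "grandparent-grandchild", "avuncular", "spouse", "none"),
  degree = c("1", "1", "2", "2", "2", "spouse", "none"),
  a_R = c(0.5, 0.5, 0.25, 0.25, 0.25, NA, NA),
  stringsAsFactors = FALSE)

.relationship_row <- function(rel) {
  .RELATIONSHIPS[match(rel, .RELATIONSHIPS$relationship), ]
}

#' Classify the relationship between two persons
#'
#' Returns the closest supported relationship class (parent-offspring,
#' full sibling, half sibling, grandparent-grandchild, avuncular, spouse)
#' between two pedigree members, with its degree and relatedness weight
#' `a_R` (0.5 first-degree, 0.25 second-degree). Pairs related only through
#' unsupported classes (e.g. cousins, in-laws) return `"none"`. Only
#' biological links count; the result is symmetric in its arguments.
#'
#' @param ped A `pedigree`.
#' @param a,b Person identifiers; must differ.
#' @return One-row `data.frame`: `proband_id`, `relative_id`,
#'   `relationship`, `degree`, `a_R`.
#' @export
classify_relationship <- function(ped, a, b) {
  ia <- match(as.character(a), ped$id)
  ib <- match(as.character(b), ped$id)
  if (is.na(ia) || is.na(ib)) stop("unknown person id")
  if (ia == ib) stop("cannot classify a person against itself")
  rel <- .classify_idx(ped, ia, ib)
  cbind(data.frame(proband_id = as.character(a), relative_id = as.character(b),
                   stringsAsFactors = FALSE),
        .relationship_row(rel))
}

.parents_of <- function(ped, i) {
  p <- c(ped$father[i], ped$mother[i]); p[!is.na(p)]
}

.classify_idx <- function(ped, ia, ib) {
  pa <- .parents_of(ped, ia); pb <- .parents_of(ped, ib)
  if (ia %in% pb || ib %in% pa) return("parent-offspring")
  fa <- ped$father; mo <- ped$mother
  shared_f <- !is.na(fa[ia]) && !is.na(fa[ib]) && fa[ia] == fa[ib]
  shared_m <- !is.na(mo[ia]) && !is.na(mo[ib]) && mo[ia] == mo[ib]
  if (shared_f && shared_m) return("full-sibling")
  if (xor(shared_f, shared_m) &&
      (!is.na(fa[ia]) || !is.na(mo[ia])) && (!is.na(fa[ib]) || !is.na(mo[ib]))) {
    # one shared parent; the other parent differs or is unknown on one side
    other_a <- if (shared_f) mo[ia] else fa[ia]
    other_b <- if (shared_f) mo[ib] else fa[ib]
    if (!identical(other_a, other_b) || (is.na(other_a) && is.na(other_b)))
      return("half-sibling")
  }
  gpa <- unique(unlist(lapply(pa, .parents_of, ped = ped)))
  gpb <- unique(unlist(lapply(pb, .parents_of, ped = ped)))
  if (ia %in% gpb || ib %in% gpa) return("grandparent-grandchild")
  # avuncular: one is a full sibling of the other's parent
  for (p in pb) if (.is_full_sib(ped, ia, p)) return("avuncular")
  for (p in pa) if (.is_full_sib(ped, ib, p)) return("avuncular")
  if (.is_spouse_pair(ped, ia, ib)) return("spouse")
  "none"
}

.is_full_sib <- function(ped, i, j) {
  fa <- ped$father; mo <- ped$mother
  !is.na(fa[i]) && !is.na(fa[j]) && fa[i] == fa[j] &&
    !is.na(mo[i]) && !is.na(mo[j]) && mo[i] == mo[j]
}

.is_spouse_pair <- function(ped, ia, ib) {
  df <- ped$persons
  if (is.null(df$cohabiting) || is.null(df$spouse_id)) return(FALSE)
  cohab <- isTRUE(df$cohabiting[ia]) && isTRUE(df$cohabiting[ib])
  declared <- (!is.na(df$spouse_id[ia]) && df$spouse_id[ia] == ped$id[ib]) ||
              (!is.na(df$spouse_id[ib]) && df$spouse_id[ib] == ped$id[ia])
  fa <- ped$father; mo <- ped$mother
  share_child <- any(!is.na(fa) & !is.na(mo) &
                     ((fa == ia & mo == ib) | (fa == ib & mo == ia)))
  cohab && (declared || share_child)
}

# Nuclear-family key of person i in their role as offspring: family plus both
# parent ids. Used as the clustering unit for pair-level analyses.
.nuclear_key <- function(ped, i) {
  paste(ped$persons$family_id[i],
        ifelse(is.na(ped$father[i]), ".", ped$id[ped$father[i]]),
        ifelse(is.na(ped$mother[i]), ".", ped$id[ped$mother[i]]),
        sep = "/")
}

#' Enumerate relative pairs by class
#'
#' Lists every unordered pair of pedigree members falling in one of the
#' requested relationship classes, exactly once, sorted lexicographically by
#' identifiers so output is reproducible byte-for-byte. Parent-offspring
#' pairs are oriented with the parent as `proband_id`; all other classes are
#' oriented by sort order. `cluster_id` identifies the nuclear family the
#' pair belongs to (offspring's nuclear family for parent-offspring and
#' sibling pairs, the linking parent's for grandparent/avuncular pairs), so
#' parent-offspring trios yield two pairs sharing one `cluster_id`.
#'
#' @param ped A `pedigree`.
#' @param classes Character vector of relationship labels to include; any of
#'   `"parent-offspring"`, `"full-sibling"`, `"half-sibling"`,
#'   `"grandparent-grandchild"`, `"avuncular"`, `"spouse"`. Default: all
#'   biological classes plus spouses.
#' @return `data.frame`: `proband_id`, `relative_id`, `relationship`,
#'   `degree`, `a_R`, `cluster_id`.
#' @export
relative_pairs <- function(ped, classes = .RELATIONSHIPS$relationship[1:6]) {
  if (length(classes))
    classes <- match.arg(classes, .RELATIONSHIPS$relationship[1:6],
                         several.ok = TRUE)
  out <- list()
  id <- ped$id; fa <- ped$father; mo <- ped$mother
  has_child <- which(!is.na(fa) | !is.na(mo))
  if ("parent-offspring" %in% classes) {
    child <- c(which(!is.na(fa)), which(!is.na(mo)))
    parent <- c(fa[!is.na(fa)], mo[!is.na(mo)])
    out$po <- data.frame(proband_id = id[parent], relative_id = id[child],
                         relationship = "parent-offspring",
                         cluster_id = .nuclear_key(ped, child),
                         stringsAsFactors = FALSE)
  }
  sib_groups <- NULL
  if (any(c("full-sibling", "avuncular") %in% classes)) {
    both <- which(!is.na(fa) & !is.na(mo))
    key <- paste(fa[both], mo[both])
    sib_groups <- split(both, key)
    sib_groups <- sib_groups[lengths(sib_groups) >= 2L]
  }
  if ("full-sibling" %in% classes && length(sib_groups)) {
    pairs <- do.call(cbind, lapply(sib_groups, function(g) utils::combn(g, 2L)))
    out$fs <- data.frame(proband_id = id[pairs[1, ]], relative_id = id[pairs[2, ]],
                         relationship = "full-sibling",
                         cluster_id = .nuclear_key(ped, pairs[1, ]),
                         stringsAsFactors = FALSE)
  }
  if ("half-sibling" %in% classes) {
    hs <- list()
    for (side in c("father", "mother")) {
      par <- if (side == "father") fa else mo
      kids <- which(!is.na(par))
      grp <- split(kids, par[kids])
      grp <- grp[lengths(grp) >= 2L]
      if (length(grp)) {
        pr <- do.call(cbind, lapply(grp, function(g) utils::combn(g, 2L)))
        hs[[side]] <- pr
      }
    }
    if (length(hs)) {
      pr <- do.call(cbind, hs)
      keep <- vapply(seq_len(ncol(pr)), function(j) {
        i1 <- pr[1, j]; i2 <- pr[2, j]
        shared_f <- !is.na(fa[i1]) && !is.na(fa[i2]) && fa[i1] == fa[i2]
        shared_m <- !is.na(mo[i1]) && !is.na(mo[i2]) && mo[i1] == mo[i2]
        xor(shared_f, shared_m)
      }, logical(1))
      pr <- pr[, keep, drop = FALSE]
      if (ncol(pr)) {
        key <- paste(pmin(pr[1, ], pr[2, ]), pmax(pr[1, ], pr[2, ]))
        pr <- pr[, !duplicated(key), drop = FALSE]
      }
      if (ncol(pr))
        out$hs <- data.frame(proband_id = id[pr[1, ]], relative_id = id[pr[2, ]],
                             relationship = "half-sibling",
                             cluster_id = paste0("hs:", pmin(pr[1, ], pr[2, ]),
                                                 "-", pmax(pr[1, ], pr[2, ])),
                             stringsAsFactors = FALSE)
    }
  }
  if ("grandparent-grandchild" %in% classes) {
    gg <- list()
    for (gside in c("father", "mother")) {
      mid <- if (gside == "father") fa else mo       # child -> middle parent
      kids <- which(!is.na(mid))
      for (pside in c("father", "mother")) {
        gp <- (if (pside == "father") fa else mo)[mid[kids]]
        ok <- !is.na(gp)
        if (any(ok))
          gg[[paste(gside, pside)]] <-
            data.frame(proband_id = id[gp[ok]], relative_id = id[kids[ok]],
                       relationship = "grandparent-grandchild",
                       cluster_id = .nuclear_key(ped, mid[kids][ok]),
                       stringsAsFactors = FALSE)
      }
    }
    if (length(gg)) out$gg <- do.call(rbind, gg)
  }
  if ("avuncular" %in% classes && length(sib_groups)) {
    av <- list()
    for (g in sib_groups) {
      for (j in seq_along(g)) {
        sibs <- g[-j]
        kids <- which((!is.na(fa) & fa == g[j]) | (!is.na(mo) & mo == g[j]))
        if (length(kids) && length(sibs)) {
          grid <- expand.grid(aunt = sibs, kid = kids)
          av[[length(av) + 1L]] <-
            data.frame(proband_id = id[grid$aunt], relative_id = id[grid$kid],
                       relationship = "avuncular",
                       cluster_id = .nuclear_key(ped, grid$aunt),
                       stringsAsFactors = FALSE)
        }
      }
    }
    if (length(av)) out$av <- do.call(rbind, av)
  }
  if ("spouse" %in% classes) {
    sp <- spouse_pairs(ped)
    if (nrow(sp)) out$sp <- sp
  }
  if (!length(out))
    return(data.frame(proband_id = character(0), relative_id = character(0),
                      relationship = character(0), degree = character(0),
                      a_R = numeric(0), cluster_id = character(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rr <- .relationship_row(res$relationship)
  res$degree <- rr$degree
  res$a_R <- rr$a_R
  res <- res[, c("proband_id", "relative_id", "relationship", "degree",
                 "a_R", "cluster_id")]
  # orientation fixed for parent-offspring; sort others so each unordered
  # pair appears once in a canonical order
  flip <- res$relationship != "parent-offspring" &
    res$proband_id > res$relative_id
  tmp <- res$proband_id[flip]
  res$proband_id[flip] <- res$relative_id[flip]
  res$relative_id[flip] <- tmp
  res <- res[order(res$relationship, res$proband_id, res$relative_id), ]
  rownames(res) <- NULL
  res
}

#' Spouse pairs
#'
#' A pair is emitted iff both members cohabit and they either declared each
#' other as spouses or share a child in the data. Same-sex pairs are
#' allowed. Each pair appears once, members sorted by identifier.
#'
#' @param ped A `pedigree`.
#' @return `data.frame` in the [relative_pairs()] schema.
#' @export
spouse_pairs <- function(ped) {
  df <- ped$persons
  empty <- data.frame(proband_id = character(0), relative_id = character(0),
                      relationship = character(0), cluster_id = character(0),
                      stringsAsFactors = FALSE)
  if (is.null(df$cohabiting)) return(empty)
  cand <- list()
  if (!is.null(df$spouse_id)) {
    i <- which(!is.na(df$spouse_id))
    j <- match(as.character(df$spouse_id[i]), ped$id)
    ok <- !is.na(j)
    cand$declared <- cbind(i[ok], j[ok])
  }
  fa <- ped$father; mo <- ped$mother
  both <- which(!is.na(fa) & !is.na(mo))
  if (length(both)) cand$shared <- unique(cbind(fa[both], mo[both]))
  if (!length(cand)) return(empty)
  pr <- do.call(rbind, cand)
  pr <- cbind(pmin(pr[, 1], pr[, 2]), pmax(pr[, 1], pr[, 2]))
  pr <- pr[!duplicated(pr), , drop = FALSE]
  cohab <- isTRUE_v(df$cohabiting[pr[, 1]]) & isTRUE_v(df$cohabiting[pr[, 2]])
  pr <- pr[cohab, , drop = FALSE]
  if (!nrow(pr)) return(empty)
  data.frame(proband_id = ped$id[pr[, 1]], relative_id = ped$id[pr[, 2]],
             relationship = "spouse",
             cluster_id = paste0("sp:", ped$id[pr[, 1]], "-", ped$id[pr[, 2]]),
             stringsAsFactors = FALSE)
}

isTRUE_v <- function(x) !is.na(x) & x
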