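test_that("pedigree construction validates identifiers and keeps singletons", {
  co <- toy_cohort()
  ped <- build_pedigree(co)
  expect_s3_class(ped, "pedigree")
  expect_equal(length(ped$id), 7)
  expect_true("LONE" %in% ped$id)

  dup <- rbind(co, co[1, ])
  expect_error(build_pedigree(dup), "duplicate person_id")

  cyc <- co
  cyc$father_id[cyc$person_id == "FA"] <- "G1"  # FA -> ... -> G1 -> FA
  expect_error(build_pedigree(cyc), "ancestry cycle")

  self <- co
  self$father_id[self$person_id == "C2"] <- "C2"
  expect_error(build_pedigree(self), "ancestry cycle")
})

test_that("relationship classification covers all supported classes", {
  ped <- build_pedigree(toy_cohort())
  cls <- function(a, b) classify_relationship(ped, a, b)

  po <- cls("FA", "C1")
  expect_equal(po$relationship, "parent-offspring")
  expect_equal(po$degree, "1"); expect_equal(po$a_R, 0.5)
  expect_equal(cls("C1", "C2")$relationship, "full-sibling")
  gg <- cls("FA", "G1")
  expect_equal(gg$relationship, "grandparent-grandchild")
  expect_equal(gg$degree, "2"); expect_equal(gg$a_R, 0.25)
  expect_equal(cls("C2", "G1")$relationship, "avuncular")
  expect_equal(cls("FA", "MO")$relationship, "spouse")
  expect_true(is.na(cls("FA", "MO")$a_R))
  expect_equal(cls("C1", "S1")$relationship, "spouse")  # shared child, cohabiting
  expect_equal(cls("FA", "LONE")$relationship, "none")
  expect_equal(cls("MO", "S1")$relationship, "none")    # in-laws unsupported
  expect_error(cls("FA", "FA"), "itself")
})

test_that("classification is symmetric and degrees partition", {
  ped <- build_pedigree(toy_cohort())
  ids <- ped$id
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (i >= j) next
    ab <- classify_relationship(ped, ids[i], ids[j])
    ba <- classify_relationship(ped, ids[j], ids[i])
    expect_identical(ab$relationship, ba$relationship)
    expect_identical(ab$a_R, ba$a_R)
    if (ab$degree == "1") expect_true(ab$a_R == 0.5)
    if (ab$degree == "2") expect_true(ab$a_R == 0.25)
  }
})

test_that("half siblings are second degree", {
  co <- data.frame(family_id = "H",
                   person_id = c("P1", "P2", "P3", "K1", "K2"),
                   father_id = c(NA, NA, NA, "P1", "P1"),
                   mother_id = c(NA, NA, NA, "P2", "P3"),
                   spouse_id = NA_character_, cohabiting = FALSE,
                   sex = c("male", "female", "female", "male", "male"),
                   age = c(50, 48, 47, 20, 19),
                   stringsAsFactors = FALSE)
  ped <- build_pedigree(co)
  hs <- classify_relationship(ped, "K1", "K2")
  expect_equal(hs$relationship, "half-sibling")
  expect_equal(hs$a_R, 0.25)
  pr <- relative_pairs(ped, "half-sibling")
  expect_equal(nrow(pr), 1)
})

test_that("pair enumeration is combinatorially complete and deterministic", {
  ped <- build_pedigree(toy_cohort())
  pr <- relative_pairs(ped)
  # nuclear part: FA,MO x C1,C2 plus C1,S1 x G1 parent-offspring
  expect_equal(sum(pr$relationship == "parent-offspring"), 6)
  expect_equal(sum(pr$relationship == "full-sibling"), 1)
  expect_equal(sum(pr$relationship == "grandparent-grandchild"), 2)
  expect_equal(sum(pr$relationship == "avuncular"), 1)
  expect_equal(sum(pr$relationship == "spouse"), 2)
  # each unordered pair exactly once
  key <- paste(pmin(pr$proband_id, pr$relative_id),
               pmax(pr$proband_id, pr$relative_id))
  expect_false(any(duplicated(key)))
  # deterministic byte-for-byte
  expect_identical(pr, relative_pairs(ped))
  expect_equal(nrow(relative_pairs(ped, character(0))), 0)
})

test_that("enumeration agrees with brute-force all-pairs classification", {
  co <- quick_sim(n_families = 30, seed = 5)
  cfg3 <- sim_config(n_families = 20, seed = 6,
                     structure = list(n_children = c(`2` = 0.5, `3` = 0.5),
                                      p_third_gen = 0.6))
  for (cohort in list(co, simulate_cohort(cfg3))) {
    ped <- build_pedigree(cohort)
    pr <- relative_pairs(ped)
    ids <- ped$id
    brute <- list()
    for (i in seq_along(ids)) for (j in seq_along(ids)) {
      if (i >= j) next
      r <- classify_relationship(ped, ids[i], ids[j])
      if (r$relationship != "none")
        brute[[length(brute) + 1L]] <- paste(
          pmin(ids[i], ids[j]), pmax(ids[i], ids[j]), r$relationship)
    }
    enum <- paste(pmin(pr$proband_id, pr$relative_id),
                  pmax(pr$proband_id, pr$relative_id), pr$relationship)
    expect_setequal(enum, unlist(brute))
  }
})

test_that("pair counts scale as expected on nuclear families", {
  co <- quick_sim(n_families = 1000, seed = 2)
  pr <- first_degree_pairs(co)
  expect_equal(sum(pr$relationship == "parent-offspring"), 4000)
  expect_equal(sum(pr$relationship == "full-sibling"), 1000)
  # parent-offspring trios: both parents' pairs with one child share a cluster
  po <- pr[pr$relationship == "parent-offspring", ]
  expect_true(all(table(po$cluster_id) == 4))  # 2 children x 2 parents
})

test_that("spouse pairs require cohabitation plus declaration or shared child", {
  co <- toy_cohort()
  ped <- build_pedigree(co)
  sp <- spouse_pairs(ped)
  key <- paste(sp$proband_id, sp$relative_id)
  expect_setequal(key, c("FA MO", "C1 S1"))
  # declared spouses not cohabiting -> no pair
  co2 <- co
  co2$cohabiting[co2$person_id == "MO"] <- FALSE
  expect_false("FA MO" %in% with(spouse_pairs(build_pedigree(co2)),
                                 paste(proband_id, relative_id)))
  # shared child alone (not cohabiting) -> no pair
  co3 <- co
  co3$cohabiting[co3$person_id %in% c("C1", "S1")] <- FALSE
  expect_false(any(grepl("C1", spouse_pairs(build_pedigree(co3))$proband_id)))
})

test_that("cohort tables round-trip through CSV", {
  co <- quick_sim(n_families = 20, seed = 9)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  back <- read_cohort(path)
  expect_equal(back$D1, co$D1)
  expect_equal(back$person_id, co$person_id)
  expect_equal(attr(back, "disorders"), attr(co, "disorders"))
  expect_equal(nrow(relative_pairs(build_pedigree(back))),
               nrow(relative_pairs(build_pedigree(co))))
})
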