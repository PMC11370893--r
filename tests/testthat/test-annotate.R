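min_consensus <- function(species, direction = "enriched", n_diseases = 1L) {
  tibble::tibble(species = species, direction_class = direction,
                 n_diseases = n_diseases, multi_disease = n_diseases >= 2)
}

test_that("annotation fields map and default correctly", {
  cons <- min_consensus(c("Oral anaerobe", "Uncurated species"))
  asg <- tibble::tibble(species = "Oral anaerobe", assigned_site = "oral")
  bact <- tibble::tibble(species = "Oral anaerobe", bacteremia = "yes")
  aero <- tibble::tibble(species = "Oral anaerobe",
                         category = "obligate anaerobe")
  ann <- merge_annotations(cons, asg, bact, aero)
  expect_equal(nrow(ann), 2)

  oa <- ann[ann$species == "Oral anaerobe", ]
  expect_equal(oa$bacteremia, "yes")
  expect_equal(oa$aerotolerance, "nonaerotolerant")
  expect_equal(oa$habitat_class, "extra-intestinal")
  expect_true(oa$oral_flag)

  # absent curation: bacteremia defaults to "no", aerotolerance to unknown,
  # site to indeterminate
  un <- ann[ann$species == "Uncurated species", ]
  expect_equal(un$bacteremia, "no")
  expect_equal(un$aerotolerance, "unknown")
  expect_equal(un$assigned_site, "indeterminate")
  expect_equal(un$habitat_class, "indeterminate")
  expect_false(un$oral_flag)
})

test_that("aerotolerance categories map onto the binary classes", {
  cats <- c("aerobe", "facultative/aerotolerant anaerobe",
            "obligate anaerobe", "unclassified anaerobe")
  cons <- min_consensus(sprintf("Cat species %d", 1:4))
  aero <- tibble::tibble(species = cons$species, category = cats)
  empty <- tibble::tibble(species = character(0), bacteremia = character(0))
  asg <- tibble::tibble(species = cons$species, assigned_site = "gut")
  ann <- merge_annotations(cons, asg, empty, aero)
  expect_equal(ann$aerotolerance,
               c("aerotolerant", "aerotolerant", "nonaerotolerant", "unknown"))
  expect_equal(unique(ann$habitat_class), "intestinal")
})

test_that("the join is loss-free and rejects duplicate keys", {
  cons <- min_consensus(sprintf("Join species %02d", 1:20))
  asg <- tibble::tibble(species = cons$species[1:10], assigned_site = "gut")
  bact <- tibble::tibble(species = cons$species[3], bacteremia = "yes")
  aero <- tibble::tibble(species = cons$species[5],
                         category = "aerobe")
  ann <- merge_annotations(cons, asg, bact, aero)
  expect_equal(nrow(ann), nrow(cons))
  expect_setequal(ann$species, cons$species)

  dup_bact <- dplyr::bind_rows(bact, bact)
  expect_error(merge_annotations(cons, asg, dup_bact, aero), "duplicate")
  expect_error(
    merge_annotations(cons, asg,
                      tibble::tibble(species = "x", bacteremia = "maybe"),
                      aero),
    "yes/no")
})

test_that("the summary grid reproduces the example data marginals", {
  dat <- example_signature_data()
  ann <- merge_annotations(consolidate(dat$records), dat$assignments,
                           dat$bacteremia, dat$aerotolerance)
  s <- table1_summary(ann)
  cell <- function(dir, grp, cat) {
    r <- s[s$direction_class == dir & s$disease_group == grp &
             s$category == cat, ]
    c(r$count, r$percent)
  }
  expect_equal(cell("enriched", "total", "total")[1], 163)
  expect_equal(cell("enriched", "total", "bacteremia"), c(105, 64.4))
  expect_equal(cell("enriched", "total", "aerotolerant"), c(65, 39.9))
  expect_equal(cell("enriched", "total", "oral"), c(51, 31.3))
  expect_equal(cell("enriched", "total", "extra-intestinal"), c(68, 41.7))
  expect_equal(cell("enriched", "1 disease", "bacteremia"), c(61, 55.0))
  expect_equal(cell("enriched", ">=2 diseases", "bacteremia"), c(44, 84.6))
  expect_equal(cell("depleted", "total", "total")[1], 98)
  expect_equal(cell("depleted", "total", "bacteremia"), c(16, 16.3))
  expect_equal(cell("depleted", "total", "aerotolerant"), c(9, 9.2))
  expect_equal(cell("depleted", "total", "oral"), c(2, 2.0))
  expect_equal(cell("depleted", "total", "extra-intestinal"), c(7, 7.1))
  expect_equal(cell("depleted", ">=2 diseases", "bacteremia"), c(5, 14.7))

  label <- s$label[s$direction_class == "enriched" &
                     s$disease_group == "total" & s$category == "bacteremia"]
  expect_equal(label, "105 (64.4%)")

  # every percentage matches independent arithmetic at one decimal,
  # rounding halves away from zero
  manual <- sign(s$count / s$total) *
    floor(abs(100 * s$count / s$total) * 10 + 0.5) / 10
  expect_equal(s$percent, manual)
})

test_that("summary counts are row-order invariant and exclude inconsistents", {
  dat <- example_signature_data()
  ann <- merge_annotations(consolidate(dat$records), dat$assignments,
                           dat$bacteremia, dat$aerotolerance)
  shuffled <- ann[withr::with_seed(2, sample(nrow(ann))), ]
  expect_equal(table1_summary(shuffled), table1_summary(ann))
  totals <- table1_summary(ann)
  expect_equal(sum(totals$count[totals$category == "total" &
                                  totals$disease_group == "total"]),
               163 + 98) # the 12 inconsistent species are not tabulated
})

test_that("an all-depleted input zeroes the enriched column", {
  cons <- min_consensus(sprintf("Dep species %d", 1:5), direction = "depleted")
  empty_b <- tibble::tibble(species = character(0), bacteremia = character(0))
  empty_a <- tibble::tibble(species = character(0), category = character(0))
  asg <- tibble::tibble(species = cons$species, assigned_site = "gut")
  s <- table1_summary(merge_annotations(cons, asg, empty_b, empty_a))
  expect_true(all(s$count[s$direction_class == "enriched"] == 0))
  expect_true(all(is.na(s$percent[s$direction_class == "enriched"])))
})
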