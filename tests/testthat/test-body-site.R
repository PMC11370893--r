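test_that("site profiles match hand-computed values on a toy matrix", {
  mats <- list(
    gut = rbind(`Species A` = c(0.5, 0.3), `Species B` = c(0, 0.1),
                `Species C` = c(0, 0)),
    oral = rbind(`Species A` = c(0.02, 0), `Species B` = c(0.6, 0.4),
                 `Species C` = c(0, 0)),
    vagina = rbind(`Species A` = c(0, 0), `Species B` = c(0, 0),
                   `Species C` = c(0.9, 0.7)),
    skin = rbind(`Species A` = c(0, 0), `Species B` = c(0, 0),
                 `Species C` = c(0, 0))
  )
  prof <- compute_site_profiles(abundance_from_matrices(mats))
  a <- prof[prof$species == "Species A", ]
  expect_equal(a$f_gut, 1); expect_equal(a$a_gut, 0.4)
  expect_equal(a$f_oral, 0.5); expect_equal(a$a_oral, 0.01)
  expect_equal(a$gut_oral_ratio, 40)
  b <- prof[prof$species == "Species B", ]
  expect_equal(b$f_gut, 0.5); expect_equal(b$a_gut, 0.05)
  expect_equal(b$a_oral, 0.5); expect_equal(b$gut_oral_ratio, 0.1)
  c3 <- prof[prof$species == "Species C", ]
  expect_equal(c3$f_skin, 0); expect_equal(c3$a_vagina, 0.8)
  expect_true(is.na(c3$gut_oral_ratio))
})

test_that("profiles equal a brute-force per-sample loop", {
  abund <- simulate_abundance_matrix(
    niche_sim_params(n_species_per_site = 2, n_samples = 15), seed = 4)
  prof <- compute_site_profiles(abund, detection_threshold = 1e-4)
  for (sp in unique(abund$species)) {
    for (st in c("gut", "oral", "vagina", "skin")) {
      v <- abund$abundance[abund$species == sp & abund$site == st]
      expect_identical(prof[[paste0("f_", st)]][prof$species == sp],
                       mean(v > 1e-4))
      expect_identical(prof[[paste0("a_", st)]][prof$species == sp], mean(v))
    }
  }
})

test_that("profiles are invariant to sample permutation and f=0 iff a=0", {
  abund <- simulate_abundance_matrix(
    niche_sim_params(n_species_per_site = 2, n_samples = 10), seed = 6)
  shuffled <- abund[withr::with_seed(1, sample(nrow(abund))), ]
  expect_equal(compute_site_profiles(shuffled), compute_site_profiles(abund))
  prof <- compute_site_profiles(abund)
  for (st in c("gut", "oral", "vagina", "skin")) {
    f <- prof[[paste0("f_", st)]]; a <- prof[[paste0("a_", st)]]
    expect_identical(f == 0, a == 0)
  }
})

make_profile <- function(f, a) {
  ratio <- if (a[1] == 0 && a[2] == 0) NA_real_ else
    if (a[2] == 0) Inf else a[1] / a[2]
  tibble::tibble(species = "X",
                 f_gut = f[1], f_oral = f[2], f_vagina = f[3], f_skin = f[4],
                 a_gut = a[1], a_oral = a[2], a_vagina = a[3], a_skin = a[4],
                 gut_oral_ratio = ratio)
}

test_that("the primary rule assigns the concordant argmax site", {
  asg <- assign_body_site(make_profile(c(0.9, 0.2, 0, 0),
                                       c(0.02, 0.001, 0, 0)))
  expect_equal(asg$assigned_site, "gut") # ratio 20 is outside [0.1, 10]
  expect_equal(asg$confidence_flag, "primary-rule")

  vag <- assign_body_site(make_profile(c(0, 0, 0.8, 0.1),
                                       c(0, 0, 0.3, 0.01)))
  expect_equal(vag$assigned_site, "vagina")
  expect_equal(vag$confidence_flag, "primary-rule")

  # oral winner with gut undetected: ratio 0 never triggers ambiguity
  oral <- assign_body_site(make_profile(c(0, 0.7, 0, 0), c(0, 0.2, 0, 0)))
  expect_equal(oral$assigned_site, "oral")
  expect_equal(oral$confidence_flag, "primary-rule")
})

test_that("fallback flags fire in their fixed precedence order", {
  nd <- assign_body_site(make_profile(c(0, 0, 0, 0), c(0, 0, 0, 0)))
  expect_equal(nd$confidence_flag, "not-detected")
  expect_equal(nd$assigned_site, "indeterminate")

  lf <- assign_body_site(make_profile(c(0.03, 0.01, 0, 0),
                                      c(0.001, 0.0001, 0, 0)))
  expect_equal(lf$confidence_flag, "low-frequency")

  dis <- assign_body_site(make_profile(c(0.9, 0.4, 0, 0),
                                       c(0.001, 0.3, 0, 0)))
  expect_equal(dis$confidence_flag, "discordant")

  # tied frequency argmax also reads as discordant
  tie <- assign_body_site(make_profile(c(0.5, 0.5, 0, 0),
                                       c(0.2, 0.1, 0, 0)))
  expect_equal(tie$confidence_flag, "discordant")

  amb <- assign_body_site(make_profile(c(0.9, 0.4, 0, 0),
                                       c(0.02, 0.01, 0, 0))) # ratio 2
  expect_equal(amb$confidence_flag, "ambiguous-gut-oral")
  # the band is inclusive and only gut/oral winners are affected
  edge <- assign_body_site(make_profile(c(0.9, 0.4, 0, 0), c(0.1, 0.01, 0, 0)))
  expect_equal(edge$confidence_flag, "ambiguous-gut-oral") # ratio exactly 10
  vag <- assign_body_site(make_profile(c(0.1, 0.05, 0.9, 0),
                                       c(0.001, 0.001, 0.3, 0))) # ratio 1
  expect_equal(vag$confidence_flag, "primary-rule")
  expect_equal(vag$assigned_site, "vagina")
})

test_that("raising gut abundance never moves an assignment away from gut", {
  base <- make_profile(c(0.9, 0.3, 0, 0), c(0.005, 0.01, 0, 0))
  before <- assign_body_site(base)
  expect_false(before$assigned_site == "gut" &&
                 before$confidence_flag == "primary-rule")
  for (mult in c(2, 10, 100)) {
    up <- base
    up$a_gut <- base$a_gut * mult
    up$gut_oral_ratio <- up$a_gut / up$a_oral
    after <- assign_body_site(up)
    expect_true(after$assigned_site %in% c("gut", "indeterminate"))
  }
  final <- base
  final$a_gut <- 0.5; final$gut_oral_ratio <- 50
  expect_equal(assign_body_site(final)$assigned_site, "gut")
})

test_that("secondary evidence resolves indeterminate species by weighted vote", {
  asg <- assign_body_site(make_profile(c(0.03, 0.01, 0, 0),
                                       c(0.001, 0.0001, 0, 0)))
  one_row <- tibble::tibble(species = "X", source = "eHOMD",
                            claimed_site = "oral", weight = 1)
  res <- resolve_with_secondary_evidence(asg, one_row)
  expect_equal(res$assigned_site, "oral")
  expect_equal(res$confidence_flag, "secondary-evidence")
  expect_equal(res$evidence_source, "external-evidence-table")

  tied <- tibble::tibble(species = "X",
                         source = c("eHOMD", "isolation"),
                         claimed_site = c("oral", "gut"), weight = 1)
  expect_equal(resolve_with_secondary_evidence(asg, tied)$assigned_site,
               "multi")

  none <- tibble::tibble(species = character(0), source = character(0),
                         claimed_site = character(0), weight = numeric(0))
  expect_identical(resolve_with_secondary_evidence(asg, none), asg)

  bad <- dplyr::mutate(one_row, claimed_site = "lung")
  expect_error(resolve_with_secondary_evidence(asg, bad), "unknown site")

  # primary-rule assignments are never overridden
  prim <- assign_body_site(make_profile(c(0.9, 0.2, 0, 0),
                                        c(0.02, 0.001, 0, 0)))
  res2 <- resolve_with_secondary_evidence(prim, one_row)
  expect_equal(res2$assigned_site, "gut")
  expect_equal(res2$confidence_flag, "primary-rule")
})

test_that("planted niches are recovered on separated synthetic profiles", {
  hits <- 0; total <- 0
  for (seed in 1:5) {
    params <- niche_sim_params(n_species_per_site = 3, n_samples = 200)
    abund <- simulate_abundance_matrix(params, seed = seed)
    prof <- compute_site_profiles(abund)
    asg <- assign_body_site(prof)
    truth <- dplyr::distinct(params, species, home_site)
    joined <- dplyr::inner_join(asg, truth, by = "species")
    hits <- hits + sum(joined$assigned_site == joined$home_site &
                         joined$confidence_flag == "primary-rule")
    total <- total + nrow(joined)
  }
  expect_gte(hits / total, 0.99)
})
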