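#' Per-species frequency and mean relative abundance by body site
#'
#' For every species in a multi-body-site abundance table, computes at each
#' site the detection frequency (fraction of that site's samples with
#' abundance above `detection_threshold`) and the average relative abundance
#' (arithmetic mean over all of the site's samples, absences contributing 0),
#' plus the gut/oral abundance ratio used to flag ambiguous niche calls.
#'
#' @param abundance Long abundance tibble with columns `species`, `sample`,
#'   `site`, `abundance` — the format produced by
#'   [simulate_abundance_matrix()] and [read_abundance_table()]. Explicit
#'   zeros must be present (every species x sample pair has a row).
#' @param detection_threshold Abundance strictly above which a species counts
#'   as detected. Default 0: any nonzero abundance is a detection.
#' @return A tibble with one row per species: `species`, frequency columns
#'   `f_gut`, `f_oral`, `f_vagina`, `f_skin`, mean-abundance columns `a_gut`,
#'   `a_oral`, `a_vagina`, `a_skin` (sites absent from the data yield 0), and
#'   `gut_oral_ratio` = `a_gut / a_oral` (`Inf` when only the oral mean is 0,
#'   `NA` when both are 0).
#' @examples
#' abund <- simulate_abundance_matrix(
#'   niche_sim_params(n_species_per_site = 1, n_samples = 20), seed = 1)
#' compute_site_profiles(abund)
#' @export
compute_site_profiles <- function(abundance, detection_threshold = 0) {
  .assert_cols(abundance, c("species", "sample", "site", "abundance"),
               "abundance")
  if (nrow(abundance) == 0) stop("site with zero samples", call. = FALSE)

  prof <- abundance |>
    dplyr::summarise(
      f = mean(.data$abundance > detection_threshold),
      a = mean(.data$abundance),
      .by = c("species", "site")
    ) |>
    tidyr::pivot_wider(names_from = "site", values_from = c("f", "a"),
                       names_sep = "_", values_fill = 0)
  # guarantee all four canonical site columns exist
  for (s in .gutsig_sites) {
    for (p in c("f", "a")) {
      col <- paste(p, s, sep = "_")
      if (!col %in% names(prof)) prof[[col]] <- 0
    }
  }
  prof |>
    dplyr::mutate(
      gut_oral_ratio = dplyr::case_when(
        .data$a_gut == 0 & .data$a_oral == 0 ~ NA_real_,
        .data$a_oral == 0 ~ Inf,
        TRUE ~ .data$a_gut / .data$a_oral
      )
    ) |>
    dplyr::select("species", dplyr::all_of(paste0("f_", .gutsig_sites)),
                  dplyr::all_of(paste0("a_", .gutsig_sites)),
                  "gut_oral_ratio") |>
    dplyr::arrange(.data$species)
}

#' Assign each species a typical body site from its site profile
#'
#' Primary rule: the site with both the highest detection frequency and the
#' highest average relative abundance is designated the species' typical body
#' site (`confidence_flag = "primary-rule"`). A species falls back to
#' `indeterminate` when any of the following holds, checked in this fixed
#' order with the first match recorded as the flag:
#'
#' 1. `not-detected` — zero frequency at every site;
#' 2. `low-frequency` — the highest frequency across the four sites is below
#'    `min_frequency` (default 5%);
#' 3. `discordant` — the frequency argmax and the abundance argmax disagree
#'    (or either argmax is tied);
#' 4. `ambiguous-gut-oral` — the winning site is gut or oral but the
#'    gut/oral mean-abundance ratio lies inside `ratio_bounds` (default
#'    \[0.1, 10\], inclusive), so neither habitat clearly dominates. A ratio
#'    of 0 or `Inf` (one habitat undetected, the other dominant) never
#'    triggers this; winners in vagina or skin are unaffected.
#'
#' @param profiles Output of [compute_site_profiles()].
#' @param min_frequency Minimum winning frequency for a primary-rule call.
#' @param ratio_bounds Length-2 numeric, the ambiguous gut/oral ratio band.
#' @return A tibble: `species`, `assigned_site` (`gut`/`oral`/`vagina`/`skin`
#'   or `indeterminate`), `confidence_flag`, `evidence_source`
#'   (`"HMP-like-profile"`), plus the input profile columns.
#' @examples
#' prof <- tibble::tibble(species = "X",
#'   f_gut = 0.9, f_oral = 0.2, f_vagina = 0, f_skin = 0,
#'   a_gut = 0.02, a_oral = 0.001, a_vagina = 0, a_skin = 0,
#'   gut_oral_ratio = 20)
#' assign_body_site(prof)
#' @export
assign_body_site <- function(profiles, min_frequency = 0.05,
                             ratio_bounds = c(0.1, 10)) {
  f_cols <- paste0("f_", .gutsig_sites)
  a_cols <- paste0("a_", .gutsig_sites)
  .assert_cols(profiles, c("species", f_cols, a_cols, "gut_oral_ratio"),
               "profiles")
  stopifnot(length(ratio_bounds) == 2, ratio_bounds[1] <= ratio_bounds[2])

  one <- function(f, a, ratio) {
    if (max(f) == 0) return(c("indeterminate", "not-detected"))
    if (max(f) < min_frequency) return(c("indeterminate", "low-frequency"))
    win_f <- .gutsig_sites[f == max(f)]
    win_a <- .gutsig_sites[a == max(a)]
    if (length(win_f) != 1 || length(win_a) != 1 || win_f != win_a) {
      return(c("indeterminate", "discordant"))
    }
    if (win_f %in% c("gut", "oral") && !is.na(ratio) && is.finite(ratio) &&
        ratio >= ratio_bounds[1] && ratio <= ratio_bounds[2]) {
      return(c("indeterminate", "ambiguous-gut-oral"))
    }
    c(win_f, "primary-rule")
  }

  fm <- as.matrix(profiles[f_cols])
  am <- as.matrix(profiles[a_cols])
  calls <- vapply(seq_len(nrow(profiles)),
                  function(i) one(fm[i, ], am[i, ],
                                  profiles$gut_oral_ratio[i]),
                  character(2))
  profiles |>
    dplyr::mutate(
      assigned_site = calls[1, ],
      confidence_flag = calls[2, ],
      evidence_source = "HMP-like-profile",
      .after = "species"
    )
}

#' Resolve indeterminate site assignments with curated secondary evidence
#'
#' Species the profile-based rule could not place (any flag other than
#' `primary-rule`) are resolved by weighted voting over a curated evidence
#' table — database membership, reference-cohort profiles, isolation sources,
#' literature reports. A unique top-weighted site wins
#' (`confidence_flag = "secondary-evidence"`); a tie yields `multi`
#' (associated with multiple body sites); species with no evidence rows are
#' returned unchanged. Primary-rule assignments are never overridden.
#'
#' @param assignments Output of [assign_body_site()].
#' @param evidence Data frame with columns `species`, `source`,
#'   `claimed_site` (one of gut, oral, vagina, skin, other, food), `weight`
#'   (positive number; suggested convention: reference-cohort profile 2,
#'   database membership 1, isolation source 1).
#' @return The assignments tibble with resolved rows updated
#'   (`evidence_source = "external-evidence-table"`).
#' @export
resolve_with_secondary_evidence <- function(assignments, evidence) {
  .assert_cols(assignments, c("species", "assigned_site", "confidence_flag"),
               "assignments")
  .assert_cols(evidence, c("species", "source", "claimed_site", "weight"),
               "evidence")
  ok_sites <- c(.gutsig_sites, "other", "food")
  bad <- setdiff(unique(evidence$claimed_site), ok_sites)
  if (length(bad) > 0) {
    stop(sprintf("unknown site label(s) in evidence: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  votes <- evidence |>
    dplyr::summarise(total = sum(.data$weight),
                     .by = c("species", "claimed_site"))
  resolve <- function(sp) {
    v <- votes[votes$species == sp, ]
    if (nrow(v) == 0) return(NULL)
    top <- v$claimed_site[v$total == max(v$total)]
    if (length(top) == 1) top else "multi"
  }
  out <- assignments
  idx <- which(out$confidence_flag != "primary-rule")
  for (i in idx) {
    site <- resolve(out$species[i])
    if (!is.null(site)) {
      out$assigned_site[i] <- site
      out$confidence_flag[i] <- "secondary-evidence"
      out$evidence_source[i] <- "external-evidence-table"
    }
  }
  out
}
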