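#' Merge consensus, site assignments, and curated annotations
#'
#' Joins the per-species direction consensus with body-site assignments and
#' the curated bacteremia and aerotolerance tables into one master annotation
#' table, the input of [table1_summary()] and [run_comparison_battery()].
#' The join is keyed on the consensus species set and loss-free: every
#' consensus species appears exactly once. Missing curation defaults
#' conservatively — bacteremia to `"no"` (the curated flag records
#' literature-reported positive blood cultures only, so absence of a report
#' means no flag), aerotolerance to `"unknown"`, site to `"indeterminate"`.
#'
#' Aerotolerance categories map as: `aerobe` and `facultative/aerotolerant
#' anaerobe` to `aerotolerant`; `obligate anaerobe` to `nonaerotolerant`;
#' `unclassified anaerobe` (and anything else) to `unknown`. Habitat class
#' derives from the assigned site: gut is `intestinal`; oral, vagina, skin,
#' other, and food origins are `extra-intestinal`; `multi` and
#' `indeterminate` pass through.
#'
#' @param consensus Output of [consolidate()].
#' @param assignments Data frame with columns `species`, `assigned_site`
#'   (e.g. from [assign_body_site()], possibly after
#'   [resolve_with_secondary_evidence()]).
#' @param bacteremia Data frame with columns `species`, `bacteremia`
#'   (`"yes"`/`"no"`).
#' @param aerotolerance Data frame with columns `species`, `category`
#'   (curated category, see Details).
#' @return A tibble with one row per consensus species: `species`,
#'   `direction_class`, `n_diseases`, `multi_disease`, `bacteremia`,
#'   `aerotolerance`, `assigned_site`, `habitat_class`, `oral_flag`.
#' @export
merge_annotations <- function(consensus, assignments, bacteremia,
                              aerotolerance) {
  .assert_cols(consensus, c("species", "direction_class", "n_diseases",
                            "multi_disease"), "consensus")
  .assert_cols(assignments, c("species", "assigned_site"), "assignments")
  .assert_cols(bacteremia, c("species", "bacteremia"), "bacteremia table")
  .assert_cols(aerotolerance, c("species", "category"), "aerotolerance table")
  .assert_no_dup(consensus$species, "species in consensus")
  .assert_no_dup(assignments$species, "species in assignments")
  .assert_no_dup(bacteremia$species, "species in bacteremia table")
  .assert_no_dup(aerotolerance$species, "species in aerotolerance table")
  bad <- setdiff(unique(bacteremia$bacteremia), c("yes", "no"))
  if (length(bad) > 0) {
    stop(sprintf("bacteremia must be yes/no, got: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }

  consensus |>
    dplyr::select("species", "direction_class", "n_diseases",
                  "multi_disease") |>
    dplyr::left_join(
      dplyr::select(assignments, "species", "assigned_site"), by = "species") |>
    dplyr::left_join(
      dplyr::select(bacteremia, "species", "bacteremia"), by = "species") |>
    dplyr::left_join(
      dplyr::select(aerotolerance, "species", "category"), by = "species") |>
    dplyr::mutate(
      assigned_site = dplyr::coalesce(.data$assigned_site, "indeterminate"),
      bacteremia = dplyr::coalesce(.data$bacteremia, "no"),
      aerotolerance = dplyr::case_when(
        .data$category %in% c("aerobe", "facultative/aerotolerant anaerobe") ~
          "aerotolerant",
        .data$category %in% "obligate anaerobe" ~ "nonaerotolerant",
        TRUE ~ "unknown"
      ),
      habitat_class = dplyr::case_when(
        .data$assigned_site == "gut" ~ "intestinal",
        .data$assigned_site %in% .gutsig_extra_sites ~ "extra-intestinal",
        .data$assigned_site == "multi" ~ "multi",
        TRUE ~ "indeterminate"
      ),
      oral_flag = .data$assigned_site == "oral"
    ) |>
    dplyr::select("species", "direction_class", "n_diseases",
                  "multi_disease", "bacteremia", "aerotolerance",
                  "assigned_site", "habitat_class", "oral_flag")
}

#' Proportions of species properties by direction and disease count
#'
#' Cross-tabulates the annotated species by direction class (enriched vs
#' depleted; inconsistent species are excluded) and disease-count group
#' (total, exactly 1 disease, at least 2 diseases), counting within each cell
#' the species flagged for bacteremia, aerotolerance, oral habitat, and
#' extra-intestinal habitat. Percentages use the direction x disease-group
#' species total as denominator and are rounded half away from zero to one
#' decimal.
#'
#' @param annotations Output of [merge_annotations()].
#' @return A tidy tibble with one row per direction x disease-group x
#'   category: `direction_class`, `disease_group` (`"total"`, `"1 disease"`,
#'   `">=2 diseases"`), `category` (`"total"`, `"bacteremia"`,
#'   `"aerotolerant"`, `"oral"`, `"extra-intestinal"`), `count`, `total`
#'   (the cell denominator), `percent`, and `label` (`"105 (64.4%)"` style).
#' @export
table1_summary <- function(annotations) {
  .assert_cols(annotations, c("species", "direction_class", "n_diseases",
                              "bacteremia", "aerotolerance", "habitat_class",
                              "oral_flag"), "annotations")
  if (nrow(annotations) == 0) stop("empty annotations", call. = FALSE)
  ann <- dplyr::filter(annotations,
                       .data$direction_class %in% .gutsig_directions)

  groups <- list(
    "total" = function(x) rep(TRUE, nrow(x)),
    "1 disease" = function(x) x$n_diseases == 1,
    ">=2 diseases" = function(x) x$n_diseases >= 2
  )
  cats <- list(
    "total" = function(x) rep(TRUE, nrow(x)),
    "bacteremia" = function(x) x$bacteremia == "yes",
    "aerotolerant" = function(x) x$aerotolerance == "aerotolerant",
    "oral" = function(x) x$oral_flag,
    "extra-intestinal" = function(x) x$habitat_class == "extra-intestinal"
  )

  rows <- purrr::map(.gutsig_directions, function(dir) {
    sub_dir <- ann[ann$direction_class == dir, ]
    purrr::map(names(groups), function(g) {
      sub <- sub_dir[groups[[g]](sub_dir), ]
      purrr::map(names(cats), function(cat) {
        cnt <- sum(cats[[cat]](sub))
        tibble(direction_class = dir, disease_group = g, category = cat,
               count = cnt, total = nrow(sub))
      }) |> dplyr::bind_rows()
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()

  rows |>
    dplyr::mutate(
      percent = ifelse(.data$total > 0,
                       round_half_away(100 * .data$count / .data$total, 1),
                       NA_real_),
      label = ifelse(
        .data$category == "total", as.character(.data$count),
        sprintf("%d (%s%%)", .data$count,
                formatC(.data$percent, format = "f", digits = 1)))
    )
}
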