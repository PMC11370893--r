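#' Consolidate per-study signature records into per-species consensus
#'
#' Collapses the (study, disease, species, direction) assertions of several
#' meta-studies into one row per canonical species, classifying each species
#' as `enriched` (enriched in at least one disease, depleted in none),
#' `depleted` (the converse), or `inconsistent` (both). The three classes
#' partition the species set. Duplicate assertions (same species, disease,
#' direction from multiple studies) collapse idempotently: a disease counts
#' once per direction.
#'
#' The pooled multiple-disease label (`md_label`, default `"MD"`) is treated
#' as one disease on input but implies association with at least two
#' diseases, so a species carrying it gets `n_diseases = max(k, 2)` where k
#' is its count of named (non-MD) diseases — a lower bound, since the pooled
#' study's internal disease list is unknown and may overlap the named ones.
#'
#' @param records Data frame of signature records with columns `study_id`,
#'   `disease`, `species`, `direction` (`"enriched"`/`"depleted"`).
#' @param synonym_map Optional synonym map passed to
#'   [canonicalize_species()].
#' @param md_label Disease label of the pooled multiple-disease meta-study.
#' @return A tibble with one row per species: `species`,
#'   `diseases_enriched` and `diseases_depleted` (list columns of disease
#'   labels), `direction_class`, `n_diseases`, `multi_disease`.
#' @examples
#' recs <- tibble::tibble(
#'   study_id = c("A", "B", "C"),
#'   disease = c("CRC", "UC", "CD"),
#'   species = c("Fusobacterium nucleatum", "Fusobacterium nucleatum",
#'               "Enterococcus faecium"),
#'   direction = c("enriched", "enriched", "depleted")
#' )
#' consolidate(recs)
#' @export
consolidate <- function(records, synonym_map = NULL, md_label = "MD") {
  .assert_cols(records, c("study_id", "disease", "species", "direction"),
               "records")
  bad <- setdiff(unique(records$direction), .gutsig_directions)
  if (length(bad) > 0) {
    stop(sprintf("unknown direction token(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  records |>
    dplyr::mutate(species = canonicalize_species(.data$species, synonym_map)) |>
    dplyr::summarise(
      diseases_enriched =
        list(sort(unique(.data$disease[.data$direction == "enriched"]))),
      diseases_depleted =
        list(sort(unique(.data$disease[.data$direction == "depleted"]))),
      .by = "species"
    ) |>
    dplyr::mutate(
      direction_class = dplyr::case_when(
        lengths(.data$diseases_enriched) > 0 &
          lengths(.data$diseases_depleted) > 0 ~ "inconsistent",
        lengths(.data$diseases_enriched) > 0 ~ "enriched",
        TRUE ~ "depleted"
      ),
      n_diseases = purrr::map2_int(
        .data$diseases_enriched, .data$diseases_depleted,
        function(e, d) {
          all_d <- union(e, d)
          k <- length(setdiff(all_d, md_label))
          if (md_label %in% all_d) max(k, 2L) else k
        }
      ),
      multi_disease = .data$n_diseases >= 2L
    ) |>
    dplyr::arrange(.data$species)
}

#' Extract signatures shared across at least a fraction of diseases
#'
#' Returns the species enriched (or depleted) in at least
#' `ceiling(threshold_fraction * n_total_diseases)` diseases. Only the pure
#' direction classes qualify; inconsistent species are never returned.
#'
#' @param consensus Output of [consolidate()].
#' @param n_total_diseases Number of diseases in the study universe
#'   (default 6: CRC, UC, CD, IBS, PC, COVID-19).
#' @param threshold_fraction Fraction of diseases required, in (0, 1\];
#'   default 1/2 ("at least half of the diseases").
#' @return A tibble with columns `species`, `direction_class`, `n_diseases`,
#'   one row per shared signature species.
#' @export
shared_signatures <- function(consensus, n_total_diseases = 6,
                              threshold_fraction = 0.5) {
  if (n_total_diseases < 1) stop("n_total_diseases must be >= 1", call. = FALSE)
  if (!(threshold_fraction > 0 && threshold_fraction <= 1)) {
    stop("threshold_fraction must be in (0, 1]", call. = FALSE)
  }
  k_min <- ceiling(threshold_fraction * n_total_diseases)
  consensus |>
    dplyr::filter(.data$direction_class %in% .gutsig_directions,
                  .data$n_diseases >= k_min) |>
    dplyr::select("species", "direction_class", "n_diseases") |>
    dplyr::arrange(.data$direction_class, .data$species)
}

#' Cross-meta-study overlap histogram for one disease
#'
#' For all studies reporting a given disease, counts how many species were
#' reported by exactly k studies, k = 1..K — a direct measure of signature
#' reproducibility between meta-studies of the same disease.
#'
#' @param records Data frame of signature records (see [consolidate()]).
#' @param disease Disease label to subset on.
#' @return A tibble with one row per k: `k`, `n_species`, and `percent`
#'   (share of the disease's unique species, rounded half away from zero to
#'   one decimal). `n_species` sums to the disease's unique species count.
#' @examples
#' recs <- simulate_signature_studies(4, c(36, 12, 3, 4), seed = 1)
#' study_overlap_histogram(recs, "CRC")
#' @export
study_overlap_histogram <- function(records, disease) {
  .assert_cols(records, c("study_id", "disease", "species"), "records")
  sub <- records[records$disease == disease, ]
  if (nrow(sub) == 0) {
    stop(sprintf("no records for disease '%s'", disease), call. = FALSE)
  }
  n_studies <- dplyr::n_distinct(sub$study_id)
  per_species <- dplyr::summarise(
    sub, k = dplyr::n_distinct(.data$study_id), .by = "species")
  counts <- vapply(seq_len(n_studies),
                   function(k) sum(per_species$k == k), integer(1))
  tibble(
    k = seq_len(n_studies),
    n_species = counts,
    percent = round_half_away(100 * counts / nrow(per_species), 1)
  )
}
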