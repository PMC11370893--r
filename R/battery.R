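# binary factor definitions shared by the comparison battery: positive level
# first, plus the exclusion rule the factor carries (species without a
# defined level drop only from comparisons that use the factor)
.battery_factors <- function() {
  list(
    direction = list(
      levels = c("enriched", "depleted"),
      value = function(x) x$direction_class,
      exclude = function(x) dplyr::case_when(
        !x$direction_class %in% c("enriched", "depleted") ~
          "inconsistent-direction",
        TRUE ~ NA_character_)
    ),
    bacteremia = list(
      levels = c("yes", "no"),
      value = function(x) x$bacteremia,
      exclude = function(x) rep(NA_character_, nrow(x))
    ),
    aerotolerance = list(
      levels = c("aerotolerant", "nonaerotolerant"),
      value = function(x) x$aerotolerance,
      exclude = function(x) dplyr::case_when(
        x$aerotolerance == "unknown" ~ "aerotolerance-unknown",
        TRUE ~ NA_character_)
    ),
    habitat = list(
      levels = c("extra-intestinal", "intestinal"),
      value = function(x) x$habitat_class,
      exclude = function(x) dplyr::case_when(
        x$habitat_class == "multi" ~ "multi-site",
        x$habitat_class == "indeterminate" ~ "site-indeterminate",
        TRUE ~ NA_character_)
    ),
    oral = list(
      levels = c("oral", "non-oral"),
      value = function(x) ifelse(x$oral_flag, "oral", "non-oral"),
      exclude = function(x) dplyr::case_when(
        x$habitat_class == "multi" ~ "multi-site",
        x$habitat_class == "indeterminate" ~ "site-indeterminate",
        TRUE ~ NA_character_)
    ),
    n_diseases = list(
      levels = c(">=2 diseases", "1 disease"),
      value = function(x) ifelse(x$multi_disease, ">=2 diseases", "1 disease"),
      exclude = function(x) rep(NA_character_, nrow(x))
    )
  )
}

#' Define one 2x2 enrichment comparison
#'
#' A comparison specification names a row factor, a column factor, and an
#' optional stratum filter; [run_comparison_battery()] turns each spec into a
#' 2x2 table and an exact test. Available factors (positive level listed
#' first):
#'
#' * `direction` — enriched vs depleted (inconsistent species excluded);
#' * `bacteremia` — yes vs no;
#' * `aerotolerance` — aerotolerant vs nonaerotolerant (unknown excluded);
#' * `habitat` — extra-intestinal vs intestinal (multi-site and
#'   indeterminate species excluded);
#' * `oral` — oral vs non-oral (same site exclusions as `habitat`);
#' * `n_diseases` — at least 2 diseases vs exactly 1.
#'
#' Exclusion rules travel with the factors, not the battery: a species with
#' unknown aerotolerance drops only from comparisons involving
#' `aerotolerance`, a multi-site species only from `habitat`/`oral`
#' comparisons.
#'
#' @param comparison_id Short unique identifier for the comparison.
#' @param row_factor,col_factor Factor names from the list above. The 2x2
#'   cell `a` counts species positive on both.
#' @param stratum Optional filter expression over annotation columns, as a
#'   string (e.g. `'direction_class == "enriched"'`), or `NULL` for the full
#'   table.
#' @return A `comparison_spec` object (a named list).
#' @seealso [default_comparison_battery()], [run_comparison_battery()]
#' @export
comparison_spec <- function(comparison_id, row_factor, col_factor,
                            stratum = NULL) {
  known <- names(.battery_factors())
  if (!row_factor %in% known || !col_factor %in% known) {
    stop(sprintf("factors must be one of: %s", paste(known, collapse = ", ")),
         call. = FALSE)
  }
  if (row_factor == col_factor) {
    stop("row and column factors must differ", call. = FALSE)
  }
  structure(
    list(comparison_id = comparison_id, row_factor = row_factor,
         col_factor = col_factor, stratum = stratum),
    class = "comparison_spec"
  )
}

#' The default battery of stratified enrichment comparisons
#'
#' The pre-registered set of 2x2 comparisons contrasting disease-enriched and
#' disease-depleted signature species on bacteremia, body-site habitat, oral
#' residence, and aerotolerance — each overall and within the relevant strata
#' — plus the within-direction comparisons of aerotolerance and disease count
#' against bacteremia and of habitat against aerotolerance.
#'
#' @return A list of [comparison_spec()] objects.
#' @export
default_comparison_battery <- function() {
  s <- comparison_spec
  enr <- 'direction_class == "enriched"'
  dep <- 'direction_class == "depleted"'
  list(
    s("direction_x_bacteremia", "direction", "bacteremia"),
    s("direction_x_bacteremia_extraintestinal", "direction", "bacteremia",
      'habitat_class == "extra-intestinal"'),
    s("direction_x_bacteremia_gut", "direction", "bacteremia",
      'habitat_class == "intestinal"'),
    s("direction_x_bacteremia_aerotolerant", "direction", "bacteremia",
      'aerotolerance == "aerotolerant"'),
    s("direction_x_bacteremia_nonaerotolerant", "direction", "bacteremia",
      'aerotolerance == "nonaerotolerant"'),
    s("direction_x_bacteremia_1disease", "direction", "bacteremia",
      "!multi_disease"),
    s("direction_x_bacteremia_md", "direction", "bacteremia",
      "multi_disease"),
    s("direction_x_extraintestinal", "direction", "habitat"),
    s("direction_x_extraintestinal_bacteremia", "direction", "habitat",
      'bacteremia == "yes"'),
    s("direction_x_extraintestinal_nonbacteremia", "direction", "habitat",
      'bacteremia == "no"'),
    s("direction_x_extraintestinal_aerotolerant", "direction", "habitat",
      'aerotolerance == "aerotolerant"'),
    s("direction_x_extraintestinal_nonaerotolerant", "direction", "habitat",
      'aerotolerance == "nonaerotolerant"'),
    s("direction_x_extraintestinal_1disease", "direction", "habitat",
      "!multi_disease"),
    s("direction_x_extraintestinal_md", "direction", "habitat",
      "multi_disease"),
    s("direction_x_oral", "direction", "oral"),
    s("direction_x_oral_bacteremia", "direction", "oral",
      'bacteremia == "yes"'),
    s("direction_x_oral_nonbacteremia", "direction", "oral",
      'bacteremia == "no"'),
    s("direction_x_oral_aerotolerant", "direction", "oral",
      'aerotolerance == "aerotolerant"'),
    s("direction_x_oral_nonaerotolerant", "direction", "oral",
      'aerotolerance == "nonaerotolerant"'),
    s("direction_x_oral_1disease", "direction", "oral", "!multi_disease"),
    s("direction_x_oral_md", "direction", "oral", "multi_disease"),
    s("direction_x_aerotolerant", "direction", "aerotolerance"),
    s("direction_x_aerotolerant_1disease", "direction", "aerotolerance",
      "!multi_disease"),
    s("direction_x_aerotolerant_md", "direction", "aerotolerance",
      "multi_disease"),
    s("aerotolerance_x_bacteremia_enriched", "aerotolerance", "bacteremia",
      enr),
    s("aerotolerance_x_bacteremia_depleted", "aerotolerance", "bacteremia",
      dep),
    s("md_x_bacteremia_enriched", "n_diseases", "bacteremia", enr),
    s("md_x_bacteremia_depleted", "n_diseases", "bacteremia", dep),
    s("habitat_x_aerotolerance_enriched", "habitat", "aerotolerance", enr),
    s("habitat_x_aerotolerance_depleted", "habitat", "aerotolerance", dep),
    s("habitat_x_bacteremia_enriched", "habitat", "bacteremia", enr),
    s("habitat_x_bacteremia_depleted", "habitat", "bacteremia", dep)
  )
}

#' Run a battery of stratified 2x2 exact tests
#'
#' Applies each [comparison_spec()] to the annotated species table: filters
#' to the spec's stratum, drops species excluded by either factor's rule
#' (logging species and reason), assembles the 2x2 table, and runs
#' [fisher_exact_2x2()]. A comparison whose filtered table has an empty row
#' or column margin is flagged `degenerate` and reports no odds ratio or
#' p-value rather than a conventional placeholder.
#'
#' @param annotations Output of [merge_annotations()].
#' @param specs List of [comparison_spec()] objects; default
#'   [default_comparison_battery()].
#' @return A tibble with one row per spec, class `comparison_battery`:
#'   `comparison_id`, `row_factor`, `col_factor`, `stratum`, cells `a`, `b`,
#'   `c`, `d` (`a` = positive on both factors), `odds_ratio`, `p_value`,
#'   `degenerate`, `n_used`, `n_excluded`, and `excluded` (list column of
#'   species/reason tibbles).
#' @examples
#' dat <- example_signature_data()
#' ann <- merge_annotations(consolidate(dat$records), dat$assignments,
#'                          dat$bacteremia, dat$aerotolerance)
#' run_comparison_battery(ann)[1, ]
#' @export
run_comparison_battery <- function(annotations,
                                   specs = default_comparison_battery()) {
  if (nrow(annotations) == 0) stop("empty annotations", call. = FALSE)
  if (inherits(specs, "comparison_spec")) specs <- list(specs)
  factors <- .battery_factors()

  rows <- purrr::map(specs, function(sp) {
    stopifnot(inherits(sp, "comparison_spec"))
    sub <- annotations
    if (!is.null(sp$stratum)) {
      sub <- dplyr::filter(sub, !!rlang::parse_expr(sp$stratum))
    }
    rf <- factors[[sp$row_factor]]
    cf <- factors[[sp$col_factor]]
    reason <- dplyr::coalesce(rf$exclude(sub), cf$exclude(sub))
    excluded <- tibble(species = sub$species[!is.na(reason)],
                       reason = reason[!is.na(reason)])
    kept <- sub[is.na(reason), ]
    rv <- rf$value(kept)
    cv <- cf$value(kept)
    a <- sum(rv == rf$levels[1] & cv == cf$levels[1])
    b <- sum(rv == rf$levels[1] & cv == cf$levels[2])
    cc <- sum(rv == rf$levels[2] & cv == cf$levels[1])
    d <- sum(rv == rf$levels[2] & cv == cf$levels[2])
    degenerate <- (a + b == 0) || (cc + d == 0) || (a + cc == 0) ||
      (b + d == 0)
    if (degenerate) {
      or <- NA_real_; p <- NA_real_
    } else {
      ft <- fisher_exact_2x2(a, b, cc, d)
      or <- ft$odds_ratio; p <- ft$p_value
    }
    tibble(
      comparison_id = sp$comparison_id,
      row_factor = sp$row_factor, col_factor = sp$col_factor,
      stratum = sp$stratum %||% "all",
      a = a, b = b, c = cc, d = d,
      odds_ratio = or, p_value = p, degenerate = degenerate,
      n_used = nrow(kept), n_excluded = nrow(excluded),
      excluded = list(excluded)
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("comparison_battery", class(out))
  out
}

#' @rdname run_comparison_battery
#' @param x A `comparison_battery` tibble.
#' @param ... Unused.
#' @method glance comparison_battery
#' @export
glance.comparison_battery <- function(x, ...) {
  tibble(
    n_comparisons = nrow(x),
    n_degenerate = sum(x$degenerate),
    n_significant_05 = sum(x$p_value < 0.05, na.rm = TRUE)
  )
}
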