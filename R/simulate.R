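#' Build a per-site, per-species simulation parameter table
#'
#' Convenience constructor for the parameter table consumed by
#' [simulate_abundance_matrix()]. Each species is given a "home" body site
#' where it is prevalent and abundant, and low prevalence/abundance elsewhere,
#' emulating the strong niche structure of human-associated bacteria across
#' gut, oral cavity, vagina, and skin.
#'
#' Defaults plant a clearly separated niche signal: prevalence 0.9 in the home
#' site versus 0.01 elsewhere, and a log-abundance gap of `log(1000)` so the
#' home-site mean relative abundance exceeds the away-site mean by well over
#' two orders of magnitude.
#'
#' @param n_species_per_site Number of species assigned to each of the four
#'   sites as their home.
#' @param n_samples Samples simulated per site.
#' @param home_prevalence,away_prevalence Detection probability of a species
#'   in its home site and in the other three sites.
#' @param home_log_mean,away_log_mean Log-scale location of the
#'   pre-normalization abundance draw (dimensionless) at home and away.
#' @param log_sd Log-scale standard deviation (> 0), shared by all draws.
#' @return A tibble with columns `site`, `n_samples`, `species`, `prevalence`,
#'   `log_mean`, `log_sd`, and `home_site` (the planted truth, carried along
#'   for classifier benchmarking).
#' @examples
#' params <- niche_sim_params(n_species_per_site = 2, n_samples = 10)
#' dplyr::count(params, site)
#' @export
niche_sim_params <- function(n_species_per_site = 5, n_samples = 200,
                             home_prevalence = 0.9, away_prevalence = 0.01,
                             home_log_mean = log(1000), away_log_mean = 0,
                             log_sd = 1) {
  species <- tibble(
    species = sprintf("Species %s %03d",
                      rep(.gutsig_sites, each = n_species_per_site),
                      seq_len(4L * n_species_per_site)),
    home_site = rep(.gutsig_sites, each = n_species_per_site)
  )
  tidyr::crossing(site = .gutsig_sites, species) |>
    dplyr::mutate(
      n_samples = n_samples,
      prevalence = ifelse(.data$site == .data$home_site,
                          home_prevalence, away_prevalence),
      log_mean = ifelse(.data$site == .data$home_site,
                        home_log_mean, away_log_mean),
      log_sd = log_sd
    ) |>
    dplyr::select("site", "n_samples", "species", "prevalence",
                  "log_mean", "log_sd", "home_site")
}

#' Simulate a site-structured relative-abundance matrix
#'
#' Draws, for every sample of every body site, a zero-inflated log-normal
#' composition: each species is present with its site-specific prevalence,
#' and when present its pre-normalization abundance is log-normal with the
#' site-specific location and scale. Per-sample abundances are then closed to
#' sum to exactly 1. If any sample would have zero total mass, a background
#' filler taxon (`"unclassified"`) absorbs the entire unit mass of those
#' samples (and is 0 elsewhere), so normalization never divides by zero.
#'
#' The zero-inflated log-normal is a deliberately minimal compositional model:
#' the downstream body-site classifier consumes only per-site detection
#' frequency and mean relative abundance, so any heavy-tailed presence/absence
#' model with controllable prevalence suffices.
#'
#' @param params Parameter tibble with columns `site`, `n_samples`, `species`,
#'   `prevalence`, `log_mean`, `log_sd` — one row per site x species (see
#'   [niche_sim_params()]). `n_samples` must be constant within a site;
#'   `prevalence` in \[0, 1\]; `log_sd` > 0.
#' @param seed Integer seed; the output is a pure function of `params` and
#'   `seed` (the caller's RNG state is untouched).
#' @return A long tibble with one row per site x sample x species:
#'   columns `species`, `sample`, `site`, `abundance` (relative abundance in
#'   \[0, 1\]; every sample sums to 1). Explicit zeros are kept.
#' @examples
#' params <- niche_sim_params(n_species_per_site = 1, n_samples = 5)
#' abund <- simulate_abundance_matrix(params, seed = 1)
#' dplyr::summarise(abund, total = sum(abundance), .by = sample)
#' @export
simulate_abundance_matrix <- function(params, seed) {
  .assert_cols(params, c("site", "n_samples", "species", "prevalence",
                         "log_mean", "log_sd"), "params")
  if (nrow(params) == 0) stop("empty species set", call. = FALSE)
  if (!all(params$prevalence >= 0 & params$prevalence <= 1)) {
    stop("prevalence must be in [0, 1]", call. = FALSE)
  }
  if (!all(params$log_sd > 0)) stop("log_sd must be > 0", call. = FALSE)
  if (!all(params$n_samples >= 1)) stop("n_samples must be >= 1", call. = FALSE)
  per_site <- dplyr::distinct(params, .data$site, .data$n_samples)
  .assert_no_dup(per_site$site, "site labels (n_samples differs within site)")
  species <- unique(params$species)
  sites <- unique(params$site)
  # every species needs a parameter row at every site
  key <- with(params, paste(site, species))
  .assert_no_dup(key, "site x species parameter rows")
  if (length(key) != length(sites) * length(species)) {
    stop("species set must be shared across all sites", call. = FALSE)
  }

  grids <- withr::with_seed(seed, lapply(seq_len(nrow(per_site)), function(i) {
    s <- per_site$site[i]
    n <- per_site$n_samples[i]
    p <- params[params$site == s, ]
    p <- p[match(species, p$species), ] # fixed draw order
    grid <- tidyr::crossing(
      sample = sprintf("%s_s%04d", s, seq_len(n)),
      species = species
    )
    pv <- p$prevalence[match(grid$species, p$species)]
    mu <- p$log_mean[match(grid$species, p$species)]
    sg <- p$log_sd[match(grid$species, p$species)]
    present <- stats::rbinom(nrow(grid), 1L, pv)
    mass <- present * stats::rlnorm(nrow(grid), mu, sg)
    grid$site <- s
    grid$mass <- mass
    grid
  }))
  long <- dplyr::bind_rows(grids)

  totals <- dplyr::summarise(long, total = sum(.data$mass),
                             .by = c("sample", "site"))
  if (any(totals$total == 0)) {
    filler <- dplyr::mutate(
      totals,
      species = "unclassified",
      mass = ifelse(.data$total == 0, 1, 0)
    ) |>
      dplyr::select("sample", "species", "site", "mass")
    long <- dplyr::bind_rows(long, filler)
  }
  long |>
    dplyr::mutate(abundance = .data$mass / sum(.data$mass),
                  .by = "sample") |>
    dplyr::select("species", "sample", "site", "abundance") |>
    dplyr::arrange(.data$site, .data$sample, .data$species)
}

# property probability in the enriched class implied by a target odds ratio
# against a baseline probability: solves odds(p)/odds(baseline) = target_or
implied_property_prob <- function(baseline_p, target_or) {
  odds <- target_or * baseline_p / (1 - baseline_p)
  odds / (1 + odds)
}

#' Simulate an annotation table with a planted direction-property odds ratio
#'
#' Generates species records in which a binary property (e.g. reported
#' bacteremia) is linked to the direction class (enriched vs depleted) with a
#' known odds ratio, for parameter-recovery and calibration testing of the
#' exact-test machinery. Direction is Bernoulli(`p_enriched`); the property
#' probability is `baseline_p` in the depleted class and, in the enriched
#' class, the probability whose odds are `target_or` times the baseline odds.
#'
#' Defaults mirror the magnitudes seen in cross-disease compilations of gut
#' signature species: about 62% of species enriched, a 16.3% property rate
#' among depleted species, and a direction-property odds ratio near 9.
#'
#' @param n_species Number of species to generate.
#' @param p_enriched Probability a species is disease-enriched, in (0, 1).
#' @param target_or Planted odds ratio (> 0, finite).
#' @param baseline_p Property probability in the depleted class, in (0, 1).
#' @param seed Integer seed.
#' @return A tibble with columns `species`, `direction`
#'   (`"enriched"`/`"depleted"`), and `property` (logical).
#' @examples
#' tab <- simulate_annotated_species(200, seed = 1)
#' table(tab$direction, tab$property)
#' @export
simulate_annotated_species <- function(n_species, p_enriched = 0.62,
                                       target_or = 9.2, baseline_p = 0.163,
                                       seed = 1) {
  stopifnot(n_species >= 1)
  if (!(p_enriched > 0 && p_enriched < 1) ||
      !(baseline_p > 0 && baseline_p < 1)) {
    stop("probabilities must be in (0, 1)", call. = FALSE)
  }
  if (!(target_or > 0) || !is.finite(target_or)) {
    stop("target_or must be a positive finite number", call. = FALSE)
  }
  p_enr <- implied_property_prob(baseline_p, target_or)
  if (!(p_enr > 0 && p_enr < 1)) {
    stop("implied enriched-class probability outside (0, 1)", call. = FALSE)
  }
  withr::with_seed(seed, {
    direction <- ifelse(stats::rbinom(n_species, 1L, p_enriched) == 1L,
                        "enriched", "depleted")
    prop_p <- ifelse(direction == "enriched", p_enr, baseline_p)
    tibble(
      species = sprintf("Simulated species %05d", seq_len(n_species)),
      direction = direction,
      property = stats::rbinom(n_species, 1L, prop_p) == 1L
    )
  })
}

#' Simulate per-study signature tables with a planted overlap design
#'
#' Builds the signature records of several meta-studies of one disease such
#' that the cross-study overlap histogram — how many species are reported by
#' exactly k of the studies — is exactly the planted design. Used to study
#' cross-meta-study reproducibility of signature species.
#'
#' @param n_studies Number of meta-studies (>= 1).
#' @param overlap_design Integer vector of length at most `n_studies`;
#'   element k is the number of species reported by exactly k studies.
#' @param disease Disease label attached to every record.
#' @param direction Direction attached to every record (the overlap question
#'   ignores direction).
#' @param seed Integer seed; which particular k-subset of studies reports a
#'   species is drawn at random, the counts are exact by construction.
#' @return A tibble of signature records: `study_id`, `disease`, `species`,
#'   `direction`.
#' @examples
#' recs <- simulate_signature_studies(4, c(36, 12, 3, 4), seed = 1)
#' study_overlap_histogram(recs, "CRC")
#' @export
simulate_signature_studies <- function(n_studies, overlap_design,
                                       disease = "CRC",
                                       direction = "enriched", seed = 1) {
  stopifnot(n_studies >= 1)
  if (length(overlap_design) > n_studies) {
    stop("overlap design references more studies than exist", call. = FALSE)
  }
  if (any(overlap_design < 0) || sum(overlap_design) == 0) {
    stop("overlap design must plant at least one species", call. = FALSE)
  }
  studies <- sprintf("study%02d", seq_len(n_studies))
  k_per_species <- rep(seq_along(overlap_design), overlap_design)
  recs <- withr::with_seed(seed, purrr::map2(
    seq_along(k_per_species), k_per_species,
    function(i, k) {
      tibble(
        study_id = sort(sample(studies, k)),
        disease = disease,
        species = sprintf("%s signature species %03d", disease, i),
        direction = direction
      )
    }))
  dplyr::bind_rows(recs)
}
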