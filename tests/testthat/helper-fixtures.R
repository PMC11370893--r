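# small in-code fixtures shared across test files

# long abundance tibble from a named site -> (species x sample) matrix list;
# each matrix has species as rownames, columns are samples of that site
abundance_from_matrices <- function(mats) {
  purrr::imap(mats, function(m, site) {
    tibble::as_tibble(as.data.frame(m), rownames = "species") |>
      tidyr::pivot_longer(-species, names_to = "sample",
                          values_to = "abundance") |>
      dplyr::mutate(site = site, sample = paste(site, sample, sep = "_"))
  }) |>
    dplyr::bind_rows() |>
    dplyr::select(species, sample, site, abundance)
}

# random signature records for property-style tests
random_records <- function(n_species = 40, n_studies = 5, seed = 1) {
  withr::with_seed(seed, {
    n <- n_species * 2
    tibble::tibble(
      study_id = sample(sprintf("study%02d", seq_len(n_studies)), n,
                        replace = TRUE),
      disease = sample(setdiff(default_diseases(), "MD"), n, replace = TRUE),
      species = sample(sprintf("Random species %03d", seq_len(n_species)), n,
                       replace = TRUE),
      direction = sample(c("enriched", "depleted"), n, replace = TRUE,
                         prob = c(0.7, 0.3))
    )
  })
}

write_tsv_tmp <- function(df, name) {
  path <- tempfile(pattern = name, fileext = ".tsv")
  readr::write_tsv(df, path)
  path
}
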