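#' Read a species-by-sample abundance table with body-site metadata
#'
#' Reads a tab-separated abundance matrix (first column the species name,
#' remaining columns one per sample) together with a sample metadata table
#' mapping each sample to its body site, and returns the validated long
#' format used throughout the package. Abundance units are auto-detected per
#' file: if any sample column sums to more than 1.5 the values are taken as
#' percentages (0–100) and divided by 100, otherwise as proportions; the
#' choice is reported via `message()`.
#'
#' Validation is strict and positional: a sample missing from the metadata, a
#' non-numeric or negative abundance, or a per-sample sum above 1 + 1e-9 is
#' an error naming the offending sample (and species, for cell-level
#' problems). No silent coercion.
#'
#' @param path Path to the abundance TSV (header row of sample identifiers).
#' @param metadata_path Path to a TSV with columns `sample` and `site`
#'   (gut, oral, vagina, or skin).
#' @param synonym_map Optional synonym map passed to
#'   [canonicalize_species()].
#' @return A long tibble with columns `species`, `sample`, `site`,
#'   `abundance` (proportions; explicit zeros kept).
#' @seealso [write_abundance_table()] for the inverse.
#' @export
read_abundance_table <- function(path, metadata_path, synonym_map = NULL) {
  raw <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()))
  if (ncol(raw) < 2) stop("abundance table has no sample columns",
                          call. = FALSE)
  names(raw)[1] <- "species"
  raw$species <- canonicalize_species(raw$species, synonym_map)
  .assert_no_dup(raw$species, "species identifiers")
  .assert_no_dup(names(raw)[-1], "sample identifiers")

  meta <- readr::read_tsv(metadata_path, col_types = readr::cols(
    .default = readr::col_character()))
  .assert_cols(meta, c("sample", "site"), "sample metadata")
  .assert_no_dup(meta$sample, "samples in metadata")
  bad_site <- setdiff(unique(meta$site), .gutsig_sites)
  if (length(bad_site) > 0) {
    stop(sprintf("unknown body site(s) in metadata: %s",
                 paste(bad_site, collapse = ", ")), call. = FALSE)
  }
  missing <- setdiff(names(raw)[-1], meta$sample)
  if (length(missing) > 0) {
    stop(sprintf("sample(s) missing from metadata: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }

  long <- tidyr::pivot_longer(raw, -"species", names_to = "sample",
                              values_to = "raw")
  num <- suppressWarnings(as.numeric(long$raw))
  bad <- which(is.na(num) & !is.na(long$raw))
  if (length(bad) > 0) {
    stop(sprintf("non-numeric abundance '%s' at species '%s', sample '%s'",
                 long$raw[bad[1]], long$species[bad[1]], long$sample[bad[1]]),
         call. = FALSE)
  }
  neg <- which(num < 0)
  if (length(neg) > 0) {
    stop(sprintf("negative abundance %s at species '%s', sample '%s'",
                 long$raw[neg[1]], long$species[neg[1]], long$sample[neg[1]]),
         call. = FALSE)
  }
  long$abundance <- num

  sums <- dplyr::summarise(long, total = sum(.data$abundance),
                           .by = "sample")
  if (any(sums$total > 1.5)) {
    message("abundance units detected as percentages (0-100); dividing by 100")
    long$abundance <- long$abundance / 100
    sums$total <- sums$total / 100
  } else {
    message("abundance units detected as proportions (0-1)")
  }
  over <- sums$sample[sums$total > 1 + 1e-9]
  if (length(over) > 0) {
    stop(sprintf("sample(s) with abundance sum above 1: %s",
                 paste(over, collapse = ", ")), call. = FALSE)
  }

  long |>
    dplyr::left_join(meta, by = "sample") |>
    dplyr::select("species", "sample", "site", "abundance")
}

#' Write an abundance table and its sample metadata
#'
#' Inverse of [read_abundance_table()]: writes the species-by-sample TSV
#' (proportions) and the sample-to-site metadata TSV.
#'
#' @param abundance Long abundance tibble (`species`, `sample`, `site`,
#'   `abundance`).
#' @param path,metadata_path Output TSV paths.
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(abundance, path, metadata_path) {
  .assert_cols(abundance, c("species", "sample", "site", "abundance"),
               "abundance")
  wide <- abundance |>
    dplyr::select("species", "sample", "abundance") |>
    tidyr::pivot_wider(names_from = "sample", values_from = "abundance",
                       values_fill = 0)
  readr::write_tsv(wide, path)
  meta <- dplyr::distinct(abundance, .data$sample, .data$site)
  readr::write_tsv(meta, metadata_path)
  invisible(path)
}

#' Read per-meta-study signature tables
#'
#' Reads one or more TSV files of signature records (columns `study_id`,
#' `disease`, `species`, `direction`) and concatenates them in input order.
#' Direction tokens other than `enriched`/`depleted` and disease labels
#' outside the vocabulary are rejected.
#'
#' @param paths Character vector of TSV paths.
#' @param diseases Accepted disease vocabulary; extend it to admit labels
#'   beyond [default_diseases()].
#' @param synonym_map Optional synonym map passed to
#'   [canonicalize_species()].
#' @return A tibble of signature records.
#' @export
read_signature_tables <- function(paths, diseases = default_diseases(),
                                  synonym_map = NULL) {
  tabs <- purrr::map(paths, function(p) {
    tab <- readr::read_tsv(p, col_types = readr::cols(
      .default = readr::col_character()))
    if (nrow(tab) == 0) stop(sprintf("empty signature table: %s", p),
                             call. = FALSE)
    .assert_cols(tab, c("study_id", "disease", "species", "direction"),
                 sprintf("signature table %s", p))
    bad_dir <- setdiff(unique(tab$direction), .gutsig_directions)
    if (length(bad_dir) > 0) {
      stop(sprintf("unknown direction token(s) in %s: %s (use enriched/depleted)",
                   p, paste(bad_dir, collapse = ", ")), call. = FALSE)
    }
    bad_dis <- setdiff(unique(tab$disease), diseases)
    if (length(bad_dis) > 0) {
      stop(sprintf("disease label(s) in %s outside the vocabulary: %s",
                   p, paste(bad_dis, collapse = ", ")), call. = FALSE)
    }
    tab
  })
  dplyr::bind_rows(tabs) |>
    dplyr::mutate(species = canonicalize_species(.data$species, synonym_map))
}

#' Write a signature-record table
#'
#' @param records Tibble of signature records.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_signature_table <- function(records, path) {
  .assert_cols(records, c("study_id", "disease", "species", "direction"),
               "records")
  readr::write_tsv(records, path)
  invisible(path)
}

#' Read a species synonym map
#'
#' @param path TSV with columns `synonym` and `canonical`.
#' @return A tibble usable as the `synonym_map` argument of the readers and
#'   of [canonicalize_species()].
#' @export
read_synonym_map <- function(path) {
  map <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()))
  .assert_cols(map, c("synonym", "canonical"), "synonym map")
  map
}

# iTOL legend colors/shapes for the annotation strip
.itol_direction_colors <- c(enriched = "#d62728", depleted = "#1f77b4",
                            inconsistent = "#8c564b")

#' Export species annotations as an iTOL color-strip dataset
#'
#' Writes a DATASET_COLORSTRIP annotation file loadable in iTOL against a
#' phylogeny whose leaf labels are the species names. The strip color encodes
#' the direction class (red enriched, blue depleted, brown inconsistent); the
#' per-species label field carries the bacteremia flag, aerotolerance class,
#' and assigned body site as `key:value` codes, so all four attributes travel
#' on one data line per species. Building or rendering the tree itself is out
#' of scope.
#'
#' @param annotations Output of [merge_annotations()] (non-empty).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_itol_annotation <- function(annotations, path) {
  .assert_cols(annotations, c("species", "direction_class", "bacteremia",
                              "aerotolerance", "assigned_site"),
               "annotations")
  if (nrow(annotations) == 0) stop("empty annotations", call. = FALSE)
  if (any(grepl("\t", annotations$species))) {
    stop("species name contains the iTOL field separator (tab)",
         call. = FALSE)
  }
  header <- c(
    "DATASET_COLORSTRIP",
    "SEPARATOR TAB",
    "DATASET_LABEL\tsignature species annotation",
    "COLOR\t#d62728",
    "COLOR_BRANCHES\t0",
    paste0("LEGEND_TITLE\tdirection"),
    paste0("LEGEND_SHAPES\t", paste(rep(1, 3), collapse = "\t")),
    paste0("LEGEND_COLORS\t",
           paste(.itol_direction_colors, collapse = "\t")),
    paste0("LEGEND_LABELS\t",
           paste(names(.itol_direction_colors), collapse = "\t")),
    "BORDER_WIDTH\t0.5",
    "DATA"
  )
  color <- unname(.itol_direction_colors[annotations$direction_class])
  color[is.na(color)] <- "#999999"
  label <- sprintf("bacteremia:%s|aerotolerance:%s|site:%s",
                   annotations$bacteremia, annotations$aerotolerance,
                   annotations$assigned_site)
  data_lines <- paste(annotations$species, color, label, sep = "\t")
  writeLines(c(header, data_lines), path)
  invisible(path)
}
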