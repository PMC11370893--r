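#' @importFrom rlang .data %||%
#' @importFrom tibble tibble as_tibble
NULL

# controlled vocabularies shared across modules
.gutsig_sites <- c("gut", "oral", "vagina", "skin")
.gutsig_extra_sites <- c("oral", "vagina", "skin", "other", "food")
.gutsig_diseases <- c("CRC", "UC", "CD", "IBS", "PC", "COVID-19", "MD")
.gutsig_directions <- c("enriched", "depleted")

#' Default disease vocabulary
#'
#' The controlled vocabulary of disease labels accepted by
#' [read_signature_tables()] and [consolidate()]: colorectal cancer (CRC),
#' ulcerative colitis (UC), Crohn's disease (CD), irritable bowel syndrome
#' (IBS), pancreatic cancer (PC), COVID-19, and MD, the "multiple diseases"
#' label used for a meta-study that pools several diseases.
#'
#' @return A character vector of disease labels.
#' @export
default_diseases <- function() .gutsig_diseases

# round half away from zero at `digits` decimals; base round() is banker's
round_half_away <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Canonicalize species names
#'
#' Trims and collapses whitespace, then maps former or variant names to their
#' canonical name through an optional synonym map. Meta-studies report species
#' under both current and former names, so all readers and the compiler pass
#' names through this normalization.
#'
#' @param x Character vector of species names.
#' @param synonym_map Optional data frame with columns `synonym` and
#'   `canonical`; names matching `synonym` (after whitespace normalization)
#'   are replaced by `canonical`. `NULL` leaves names unmapped.
#' @return Character vector of canonical names, same length as `x`.
#' @examples
#' canonicalize_species(c("  Eubacterium   dolichum "),
#'   synonym_map = data.frame(
#'     synonym = "Eubacterium dolichum",
#'     canonical = "Amedibacillus dolichus"
#'   ))
#' @export
canonicalize_species <- function(x, synonym_map = NULL) {
  out <- gsub("\\s+", " ", trimws(x))
  if (!is.null(synonym_map)) {
    stopifnot(all(c("synonym", "canonical") %in% names(synonym_map)))
    syn <- gsub("\\s+", " ", trimws(synonym_map$synonym))
    hit <- match(out, syn)
    out[!is.na(hit)] <- synonym_map$canonical[hit[!is.na(hit)]]
  }
  out
}

.assert_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

.assert_no_dup <- function(keys, what) {
  dup <- unique(keys[duplicated(keys)])
  if (length(dup) > 0) {
    stop(sprintf("duplicate %s: %s", what,
                 paste(utils::head(dup, 5), collapse = ", ")), call. = FALSE)
  }
  invisible(keys)
}
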