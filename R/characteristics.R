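#' Clinical characteristics used for severity annotation
#'
#' The ten severity-related clinical characteristics a phenotype may directly
#' cause (or, for congenital onset, exhibit). The order returned here is the
#' canonical order used in prompts, CSV columns and reports.
#'
#' @return Character vector of length 10.
#' @export
#' @examples
#' characteristics()
characteristics <- function() {
  c(
    "intellectual_disability",
    "death",
    "impaired_mobility",
    "physical_malformations",
    "blindness",
    "sensory_impairments",
    "immunodeficiency",
    "cancer",
    "reduced_fertility",
    "congenital_onset"
  )
}

#' Frequency vocabulary
#'
#' The four-level response vocabulary describing how often a phenotype
#' directly causes a clinical characteristic, in increasing order of
#' frequency. The numeric encoding is the position in this vector minus one:
#' never = 0, rarely = 1, often = 2, always = 3.
#'
#' @return Character vector `c("never", "rarely", "often", "always")`.
#' @export
frequency_levels <- function() {
  c("never", "rarely", "often", "always")
}

#' Numeric code of a frequency word
#'
#' Maps frequency words to their numeric codes (never = 0, rarely = 1,
#' often = 2, always = 3). Matching is case-insensitive; unknown words
#' are an error.
#'
#' @param frequency Character vector of frequency words.
#' @return Integer vector of codes in 0..3.
#' @export
#' @examples
#' frequency_code(c("never", "Always"))
frequency_code <- function(frequency) {
  f <- normalize_frequency(frequency)
  match(f, frequency_levels()) - 1L
}

# Lower-case and validate frequency words; NA passes through.
normalize_frequency <- function(frequency) {
  f <- tolower(trimws(as.character(frequency)))
  bad <- !is.na(f) & !(f %in% frequency_levels())
  if (any(bad)) {
    stop(
      "unrecognised frequency word(s): ",
      paste(unique(f[bad]), collapse = ", "),
      call. = FALSE
    )
  }
  f
}

# Column names of the wide annotation table.
freq_cols <- function() paste0(characteristics(), "_freq")
just_cols <- function() paste0(characteristics(), "_justification")

annotation_cols <- function() {
  c(
    "hpo_id", "hpo_name", "replicate",
    as.vector(rbind(freq_cols(), just_cols()))
  )
}
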