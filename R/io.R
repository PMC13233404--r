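#' Read an annotation table from CSV
#'
#' The annotation CSV dialect has one row per (phenotype, replicate):
#' columns `hpo_id`, `hpo_name`, `replicate`, then for each clinical
#' characteristic, in the canonical order of [characteristics()], a
#' `<characteristic>_freq` column restricted to the four frequency words
#' (case-insensitive on read, stored lower case) and a
#' `<characteristic>_justification` column. Files are UTF-8 and quoted per
#' RFC 4180, so commas and quotes in justifications round-trip.
#'
#' @param path Path to a CSV file.
#' @return An annotation tibble. Malformed rows abort with the offending
#'   row number; missing columns abort naming the column.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path,
                               call. = FALSE)
  df <- suppressWarnings(readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_character(),
    replicate = readr::col_integer()
  ), progress = FALSE))
  missing <- setdiff(annotation_cols(), names(df))
  if (length(missing)) {
    stop("annotation CSV is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (cl in just_cols()) {
    df[[cl]][is.na(df[[cl]])] <- ""
  }
  for (cl in freq_cols()) {
    f <- tolower(trimws(df[[cl]]))
    bad <- which(is.na(f) | !(f %in% frequency_levels()))
    if (length(bad)) {
      stop("row ", bad[1], ", column ", cl, ": invalid frequency \"",
           df[[cl]][bad[1]], "\"", call. = FALSE)
    }
    df[[cl]] <- f
  }
  if (anyNA(df$replicate)) {
    stop("row ", which(is.na(df$replicate))[1],
         ": replicate must be a positive integer", call. = FALSE)
  }
  new_annotation_set(df)
}

#' Write an annotation table to CSV
#'
#' Canonical column order, rows sorted by (term id, replicate); output is
#' byte-identical across runs for identical input.
#'
#' @param set An annotation tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(set, path) {
  set <- new_annotation_set(set, provenance = attr(set, "provenance"))
  out <- tibble::as_tibble(set)[order(set$hpo_id, set$replicate),
                                annotation_cols()]
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
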