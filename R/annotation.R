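#' Default prompt template
#'
#' The prompt sent to an annotator for a batch of (at most two) phenotypes.
#' It enumerates the ten clinical characteristics, the four frequency words,
#' requires a justification for every response, instructs the annotator to
#' ignore indirect effects, and fixes the line-oriented response grammar
#' `<phenotype name> | <characteristic>: <frequency> - <justification>`.
#' The `{phenotypes}` placeholder is filled by [build_prompt()].
#'
#' @return A single string containing the `{phenotypes}` placeholder.
#' @export
default_prompt_template <- function() {
  paste(
    "You are annotating phenotypes from a phenotype ontology.",
    "For each phenotype listed below, state how frequently the phenotype",
    "DIRECTLY causes each of the following clinical characteristics:",
    paste(characteristics(), collapse = ", "), ".",
    "Answer with exactly one of the four frequency words:",
    paste(frequency_levels(), collapse = ", "), ".",
    "Do not consider indirect effects: report only characteristics the",
    "phenotype itself directly causes.",
    "Provide a brief justification for every response.",
    "Respond with one line per phenotype and characteristic, formatted as:",
    "<phenotype name> | <characteristic>: <frequency> - <justification>",
    "Phenotypes:",
    "{phenotypes}",
    sep = "\n"
  )
}

#' Build an annotation prompt for a batch of phenotypes
#'
#' @param phenotypes Data frame with columns `hpo_id` and `hpo_name`; at most
#'   two rows (one query never covers more than two phenotypes).
#' @param template Prompt template containing the `{phenotypes}` placeholder.
#' @return The prompt string; phenotype names appear as `- <name>` lines.
#' @export
build_prompt <- function(phenotypes, template = default_prompt_template()) {
  stopifnot(is.data.frame(phenotypes),
            all(c("hpo_id", "hpo_name") %in% names(phenotypes)))
  n <- nrow(phenotypes)
  if (n < 1L || n > 2L) {
    stop("a prompt covers one or two phenotypes, got ", n, call. = FALSE)
  }
  if (!grepl("{phenotypes}", template, fixed = TRUE)) {
    stop("template lacks the {phenotypes} placeholder", call. = FALSE)
  }
  slot <- paste0("- ", phenotypes$hpo_name, collapse = "\n")
  sub("{phenotypes}", slot, template, fixed = TRUE)
}

## ---- response grammar ------------------------------------------------------

#' Serialise annotations to the response grammar
#'
#' Inverse of [parse_response()]: renders one line per phenotype and
#' characteristic in the form
#' `<phenotype name> | <characteristic>: <frequency> - <justification>`.
#' Used by the bundled annotators and by round-trip tests.
#'
#' @param records Data frame with columns `hpo_name`, `characteristic`,
#'   `frequency`, `justification`.
#' @return A single response string.
#' @export
render_response <- function(records) {
  stopifnot(all(c("hpo_name", "characteristic", "frequency", "justification")
                %in% names(records)))
  paste(sprintf("%s | %s: %s - %s",
                records$hpo_name, records$characteristic,
                records$frequency, records$justification),
        collapse = "\n")
}

#' Parse an annotator response
#'
#' Parses the line-oriented response grammar and returns a validated
#' annotation table. Every expected phenotype must be present with all ten
#' characteristics exactly once; unknown characteristic or frequency tokens
#' are rejected with the offending line number.
#'
#' @param text Response string.
#' @param expected Data frame with columns `hpo_id`, `hpo_name`: the
#'   phenotypes the prompt asked about.
#' @return An annotation tibble (one row per phenotype, `replicate = 1`)
#'   in the wide layout described in [read_annotations()].
#' @export
parse_response <- function(text, expected) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!nzchar(trimws(text))) stop("empty response", call. = FALSE)
  stopifnot(all(c("hpo_id", "hpo_name") %in% names(expected)))

  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  keep <- nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- trimws(lines[keep])

  pat <- "^(.*\\S)\\s*\\|\\s*([A-Za-z_]+)\\s*:\\s*([A-Za-z]+)\\s*-\\s*(.*)$"
  ok <- grepl(pat, lines)
  if (any(!ok)) {
    stop("line ", lineno[which(!ok)[1]], " does not match the response grammar: ",
         lines[which(!ok)[1]], call. = FALSE)
  }
  nm <- sub(pat, "\\1", lines)
  ch <- tolower(sub(pat, "\\2", lines))
  fr <- tolower(sub(pat, "\\3", lines))
  ju <- sub(pat, "\\4", lines)

  bad_ch <- !(ch %in% characteristics())
  if (any(bad_ch)) {
    stop("line ", lineno[which(bad_ch)[1]], ": unknown characteristic token \"",
         ch[which(bad_ch)[1]], "\"", call. = FALSE)
  }
  bad_fr <- !(fr %in% frequency_levels())
  if (any(bad_fr)) {
    stop("line ", lineno[which(bad_fr)[1]], ": unrecognised frequency token \"",
         fr[which(bad_fr)[1]], "\"", call. = FALSE)
  }

  long <- tibble::tibble(hpo_name = nm, characteristic = ch,
                         frequency = fr, justification = ju)
  out <- vector("list", nrow(expected))
  for (i in seq_len(nrow(expected))) {
    blk <- long[tolower(long$hpo_name) == tolower(expected$hpo_name[i]), ]
    if (nrow(blk) == 0L) {
      stop("response is missing phenotype \"", expected$hpo_name[i], "\"",
           call. = FALSE)
    }
    viol <- validate_annotation(blk)
    if (length(viol)) {
      stop("invalid block for \"", expected$hpo_name[i], "\": ",
           paste(viol, collapse = "; "), call. = FALSE)
    }
    row <- c(list(hpo_id = expected$hpo_id[i],
                  hpo_name = expected$hpo_name[i],
                  replicate = 1L),
             stats::setNames(as.list(blk$frequency[match(characteristics(),
                                                         blk$characteristic)]),
                             freq_cols()),
             stats::setNames(as.list(blk$justification[match(characteristics(),
                                                             blk$characteristic)]),
                             just_cols()))
    out[[i]] <- tibble::as_tibble(row)[, annotation_cols()]
  }
  new_annotation_set(dplyr::bind_rows(out))
}

#' Validate one phenotype's characteristic annotations
#'
#' @param block Data frame with columns `characteristic`, `frequency` (and
#'   optionally `justification`) for a single phenotype.
#' @return Character vector of violations; empty when the block is valid
#'   (all ten characteristics exactly once, frequencies in the vocabulary).
#' @export
validate_annotation <- function(block) {
  viol <- character(0)
  dup <- unique(block$characteristic[duplicated(block$characteristic)])
  if (length(dup)) {
    viol <- c(viol, paste0("duplicate characteristic: ", dup))
  }
  missing <- setdiff(characteristics(), block$characteristic)
  if (length(missing)) {
    viol <- c(viol, paste0("missing characteristic: ", missing))
  }
  unknown <- setdiff(block$characteristic, characteristics())
  if (length(unknown)) {
    viol <- c(viol, paste0("unknown characteristic: ", unknown))
  }
  badf <- !(tolower(block$frequency) %in% frequency_levels())
  if (any(badf)) {
    viol <- c(viol, paste0("invalid frequency: ", block$frequency[badf]))
  }
  viol
}

## ---- annotation sets -------------------------------------------------------

# Canonical zero-row annotation table.
empty_annotation_set <- function() {
  tibble::as_tibble(stats::setNames(
    c(list(character(0), character(0), integer(0)),
      rep(list(character(0)), 20L)),
    annotation_cols()))
}

# Tag a wide annotation table with its class and check uniqueness.
new_annotation_set <- function(df, provenance = NULL) {
  df <- tibble::as_tibble(df)
  if (nrow(df) == 0L) df <- empty_annotation_set()
  missing <- setdiff(annotation_cols(), names(df))
  if (length(missing)) {
    stop("annotation table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df <- df[, annotation_cols()]
  df$replicate <- as.integer(df$replicate)
  key <- paste(df$hpo_id, df$replicate)
  if (anyDuplicated(key)) {
    stop("duplicate (phenotype, replicate) pairs: ",
         paste(unique(key[duplicated(key)]), collapse = ", "), call. = FALSE)
  }
  for (cl in freq_cols()) df[[cl]] <- normalize_frequency(df[[cl]])
  if (!is.null(provenance)) attr(df, "provenance") <- provenance
  class(df) <- c("annotation_set", class(tibble::tibble()))
  df
}

#' Annotate ontology terms through a pluggable annotator
#'
#' Drives batch annotation: terms are batched (at most two per prompt), each
#' batch is rendered with [build_prompt()], sent to the annotator, and the
#' response parsed and validated with [parse_response()]. A batch whose
#' response fails to parse is retried up to `max_retries` times and then
#' recorded as a permanent failure; failures never raise.
#'
#' @param ont A `phenotype_ontology`.
#' @param term_ids Term ids to annotate.
#' @param annotator A function mapping a prompt string to a response string,
#'   e.g. from [mock_annotator()], [random_annotator()] or
#'   [planted_annotator()].
#' @param batch_size Phenotypes per prompt (1 or 2).
#' @param replicates Number of independent annotation passes: a single count
#'   applied to all terms, or a named vector keyed by term id.
#' @param max_retries Retries per failed batch.
#' @param seed Optional integer seed (the annotator may consume randomness).
#' @param template Prompt template.
#' @return An annotation tibble with one row per (term, replicate). The
#'   `provenance` attribute records the annotator label and seed; the
#'   `failures` attribute is a tibble of permanently failed
#'   (term, replicate) pairs with the last error message.
#' @export
annotate_terms <- function(ont, term_ids, annotator, batch_size = 2,
                           replicates = 1L, max_retries = 2L, seed = NULL,
                           template = default_prompt_template()) {
  term_ids <- check_term(ont, term_ids)
  stopifnot(batch_size %in% 1:2, is.function(annotator))
  if (!is.null(seed)) set.seed(seed)

  if (length(replicates) == 1L && is.null(names(replicates))) {
    replicates <- stats::setNames(rep(as.integer(replicates),
                                      length(term_ids)), term_ids)
  }
  replicates <- replicates[term_ids]

  records <- list()
  failures <- list()
  for (r in seq_len(max(replicates, 1L))) {
    ids_r <- term_ids[replicates >= r]
    if (!length(ids_r)) next
    batches <- split(ids_r, ceiling(seq_along(ids_r) / batch_size))
    for (batch in batches) {
      expected <- tibble::tibble(hpo_id = batch,
                                 hpo_name = term_name(ont, batch))
      prompt <- build_prompt(expected, template)
      res <- NULL
      last_err <- NULL
      for (attempt in seq_len(max_retries + 1L)) {
        res <- tryCatch(
          parse_response(annotator(prompt), expected),
          error = function(e) {
            last_err <<- conditionMessage(e)
            NULL
          }
        )
        if (!is.null(res)) break
      }
      if (is.null(res)) {
        failures[[length(failures) + 1L]] <- tibble::tibble(
          hpo_id = batch, replicate = r, error = last_err)
      } else {
        res$replicate <- r
        records[[length(records) + 1L]] <- res
      }
    }
  }

  out <- if (length(records)) dplyr::bind_rows(records) else
    empty_annotation_set()
  set <- new_annotation_set(
    out,
    provenance = list(
      annotator = attr(annotator, "label") %||% "custom",
      seed = seed
    )
  )
  attr(set, "failures") <- if (length(failures)) {
    dplyr::bind_rows(failures)
  } else {
    tibble::tibble(hpo_id = character(0), replicate = integer(0),
                   error = character(0))
  }
  set
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Pull the "- <name>" list slot back out of a rendered prompt.
prompt_phenotypes <- function(prompt) {
  lines <- strsplit(prompt, "\n", fixed = TRUE)[[1]]
  sub("^- ", "", grep("^- ", lines, value = TRUE))
}

# Shared response builder for the bundled annotators: freq_fun(name, char)
# must return one frequency word.
respond <- function(prompt, freq_fun, indirect_fun = NULL) {
  nms <- prompt_phenotypes(prompt)
  rows <- expand.grid(characteristic = characteristics(), hpo_name = nms,
                      stringsAsFactors = FALSE)[, 2:1]
  rows$frequency <- mapply(freq_fun, rows$hpo_name, rows$characteristic,
                           USE.NAMES = FALSE)
  rows$justification <- sprintf("%s %s causes %s.", rows$hpo_name,
                                rows$frequency,
                                gsub("_", " ", rows$characteristic))
  if (!is.null(indirect_fun)) {
    hit <- mapply(indirect_fun, rows$hpo_name, rows$characteristic,
                  USE.NAMES = FALSE)
    rows$justification[hit] <- sprintf(
      "%s does not directly cause %s, although it is a risk factor.",
      rows$hpo_name[hit], gsub("_", " ", rows$characteristic[hit]))
  }
  render_response(rows)
}

#' Deterministic mock annotator
#'
#' A network-free test double. Responses conform to the grammar and are a
#' pure function of (phenotype name, characteristic, seed), so the same
#' prompt always yields a byte-identical response. Keyword rules override
#' individual answers: a rule fires when its keyword occurs
#' (case-insensitively) in the phenotype name.
#'
#' @param seed Integer mixed into the name hash.
#' @param rules Named list: keyword -> `c(characteristic, frequency)`.
#' @return An annotator function (prompt string -> response string).
#' @export
#' @examples
#' ann <- mock_annotator(rules = list(lethal = c("death", "always")))
mock_annotator <- function(seed = 0L, rules = list()) {
  f <- function(prompt) {
    respond(prompt, function(nm, ch) {
      for (kw in names(rules)) {
        rule <- rules[[kw]]
        if (grepl(tolower(kw), tolower(nm), fixed = TRUE) &&
            identical(rule[[1]], ch)) {
          return(normalize_frequency(rule[[2]]))
        }
      }
      h <- sum(utf8ToInt(paste(nm, ch))) * 131L + as.integer(seed) * 17L
      frequency_levels()[h %% 4L + 1L]
    })
  }
  structure(f, label = sprintf("mock(seed=%d)", as.integer(seed)))
}

#' Uniform-random annotator
#'
#' Draws every frequency independently and uniformly from the four-word
#' vocabulary using the R random number generator, so repeated annotation of
#' the same phenotype gives independent replicates. Used to measure chance
#' consistency levels.
#'
#' @return An annotator function.
#' @export
random_annotator <- function() {
  f <- function(prompt) {
    respond(prompt, function(nm, ch) sample(frequency_levels(), 1L))
  }
  structure(f, label = "uniform-random")
}

#' Planted-truth annotator
#'
#' Simulates an annotator with a known recall: for phenotypes planted in a
#' characteristic's truth set, the response is "often" or "always" with
#' probability `1 - epsilon` (and "never"/"rarely" otherwise); all other
#' answers are drawn from `background`, a probability vector over the four
#' frequency words.
#'
#' @param truth_names Named list: characteristic -> character vector of
#'   phenotype names planted as true positives.
#' @param epsilon Miss probability for planted answers, in \[0, 1\].
#' @param background Probability weights over never/rarely/often/always for
#'   non-planted answers.
#' @return An annotator function.
#' @export
planted_annotator <- function(truth_names, epsilon = 0,
                              background = c(0.55, 0.25, 0.13, 0.07)) {
  stopifnot(epsilon >= 0, epsilon <= 1, length(background) == 4L)
  f <- function(prompt) {
    respond(prompt, function(nm, ch) {
      planted <- ch %in% names(truth_names) &&
        tolower(nm) %in% tolower(truth_names[[ch]])
      if (planted) {
        grp <- if (stats::runif(1) < epsilon) c("never", "rarely") else
          c("often", "always")
        sample(grp, 1L)
      } else {
        sample(frequency_levels(), 1L, prob = background)
      }
    })
  }
  structure(f, label = sprintf("planted(epsilon=%g)", epsilon))
}
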