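#' Default severity weights
#'
#' The per-characteristic severity weights on a 1--6 scale (6 most severe)
#' used to convert frequency codes into weighted severity values. Derived
#' from the four-tier importance ranking of clinical characteristics
#' elicited from healthcare professionals by Lazarin and colleagues.
#'
#' @return Named integer vector, one weight per characteristic.
#' @export
#' @examples
#' default_severity_weights()
default_severity_weights <- function() {
  c(
    intellectual_disability = 5L,
    death = 6L,
    impaired_mobility = 4L,
    physical_malformations = 3L,
    blindness = 4L,
    sensory_impairments = 3L,
    immunodeficiency = 3L,
    cancer = 3L,
    reduced_fertility = 1L,
    congenital_onset = 1L
  )[characteristics()]
}

#' Default severity tiers
#'
#' The tier (1 = most severe, 4 = least severe) of each clinical
#' characteristic, used only by the severity-class decision tree. Congenital
#' onset carries no tier and is ignored by classification, although it does
#' contribute to the composite severity score.
#'
#' @return Named integer vector; `congenital_onset` is `NA`.
#' @export
default_tier_map <- function() {
  c(
    intellectual_disability = 1L,
    death = 1L,
    impaired_mobility = 2L,
    physical_malformations = 2L,
    blindness = 3L,
    sensory_impairments = 3L,
    immunodeficiency = 3L,
    cancer = 3L,
    reduced_fertility = 4L,
    congenital_onset = NA_integer_
  )[characteristics()]
}

#' Severity class labels
#'
#' The four severity classes in decreasing order of severity. The ordering
#' is used to break ties when several decision-tree rules fire.
#'
#' @return `c("Profound", "Severe", "Moderate", "Mild")`.
#' @export
severity_classes <- function() {
  c("Profound", "Severe", "Moderate", "Mild")
}

check_weights <- function(weights) {
  if (!all(characteristics() %in% names(weights)) ||
      any(is.na(weights[characteristics()])) ||
      any(weights[characteristics()] <= 0)) {
    stop("weights must be a named positive vector covering all ten ",
         "characteristics", call. = FALSE)
  }
  weights[characteristics()]
}

#' Weighted severity value of one annotation
#'
#' The numeric frequency code (never = 0, rarely = 1, often = 2, always = 3)
#' multiplied by the characteristic's severity weight. With the default
#' weights this reproduces the 10 x 4 grid of weighted scores.
#'
#' @param characteristic Characteristic name(s).
#' @param frequency Frequency word(s), case-insensitive.
#' @param weights Severity weights, as [default_severity_weights()].
#' @return Numeric vector of weighted values.
#' @export
#' @examples
#' weighted_value("death", "always")       # 18
#' weighted_value("reduced_fertility", "often")  # 2
weighted_value <- function(characteristic, frequency,
                           weights = default_severity_weights()) {
  weights <- check_weights(weights)
  bad <- !(characteristic %in% characteristics())
  if (any(bad)) {
    stop("unknown characteristic: ",
         paste(unique(characteristic[bad]), collapse = ", "), call. = FALSE)
  }
  as.numeric(weights[characteristic]) * frequency_code(frequency)
}

# Theoretical maximum raw sum: all characteristics at "always".
max_raw_sum <- function(weights = default_severity_weights()) {
  sum(check_weights(weights)) * 3L
}

#' Composite severity score of one phenotype annotation
#'
#' Multiplies each characteristic's frequency code by its severity weight,
#' sums over all ten characteristics, and normalises by the theoretical
#' maximum (every characteristic "always") onto a 0--100 scale, where 100 is
#' the most severe phenotype possible.
#'
#' @param pa A one-row annotation table (wide layout) or a named vector /
#'   list of frequency words keyed by characteristic.
#' @param weights Severity weights.
#' @return A list with `weighted` (named vector of weighted values),
#'   `raw_sum`, `raw_mean` and `nss` (the normalised 0--100 score).
#' @export
#' @examples
#' freqs <- stats::setNames(rep("never", 10), characteristics())
#' freqs["death"] <- "always"
#' composite_score(freqs)$nss  # 100 * 18 / 99
composite_score <- function(pa, weights = default_severity_weights()) {
  weights <- check_weights(weights)
  if (is.data.frame(pa)) {
    stopifnot(nrow(pa) == 1L)
    freqs <- stats::setNames(
      vapply(freq_cols(), function(cl) pa[[cl]][1], character(1)),
      characteristics())
  } else {
    freqs <- unlist(pa)
    missing <- setdiff(characteristics(), names(freqs))
    if (length(missing)) {
      stop("missing characteristic(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    freqs <- freqs[characteristics()]
  }
  w <- weighted_value(characteristics(), freqs, weights)
  names(w) <- characteristics()
  raw_sum <- sum(w)
  list(
    weighted = w,
    raw_sum = raw_sum,
    raw_mean = raw_sum / length(w),
    nss = 100 * raw_sum / max_raw_sum(weights)
  )
}

#' Severity class of one phenotype annotation
#'
#' Tier-based decision tree over the characteristics a phenotype "often" or
#' "always" causes (congenital onset, having no tier, is ignored):
#' more than one Tier-1 characteristic gives "Profound"; exactly one Tier-1,
#' or three or more Tier-2/Tier-3 characteristics, gives "Severe"; at least
#' one Tier-2 characteristic gives "Moderate"; otherwise "Mild". When
#' several rules fire, the most severe class wins.
#'
#' @inheritParams composite_score
#' @param tiers Tier map, as [default_tier_map()].
#' @return One of `"Profound"`, `"Severe"`, `"Moderate"`, `"Mild"`.
#' @export
classify_severity <- function(pa, tiers = default_tier_map()) {
  if (is.data.frame(pa)) {
    stopifnot(nrow(pa) == 1L)
    freqs <- stats::setNames(
      vapply(freq_cols(), function(cl) pa[[cl]][1], character(1)),
      characteristics())
  } else {
    freqs <- unlist(pa)[characteristics()]
  }
  high <- characteristics()[normalize_frequency(freqs) %in% c("often", "always")]
  tiers <- tiers[characteristics()]
  n1 <- sum(tiers[high] == 1L, na.rm = TRUE)
  n2 <- sum(tiers[high] == 2L, na.rm = TRUE)
  n23 <- sum(tiers[high] %in% c(2L, 3L), na.rm = TRUE)
  if (n1 > 1L) return("Profound")
  if (n1 == 1L || n23 >= 3L) return("Severe")
  if (n2 >= 1L) return("Moderate")
  "Mild"
}

#' Score and classify every record of an annotation set
#'
#' Replicates are scored independently: the output has one row per input
#' row, with the per-characteristic frequencies and weighted values, the raw
#' weighted sum and mean, the 0--100 normalised severity score (`nss`) and
#' the severity class.
#'
#' @param set An annotation tibble (wide layout).
#' @param weights Severity weights.
#' @param tiers Tier map for classification.
#' @return A tibble with columns `hpo_id`, `hpo_name`, `replicate`, the ten
#'   `<characteristic>_freq` columns, ten `<characteristic>_weighted`
#'   columns, `raw_sum`, `raw_mean`, `nss` and `severity_class` (ordered
#'   factor Mild < Moderate < Severe < Profound).
#' @export
score_annotations <- function(set, weights = default_severity_weights(),
                              tiers = default_tier_map()) {
  weights <- check_weights(weights)
  base <- tibble::as_tibble(set)[, c("hpo_id", "hpo_name", "replicate",
                                     freq_cols())]
  codes <- vapply(freq_cols(), function(cl) frequency_code(base[[cl]]),
                  integer(nrow(base)))
  if (nrow(base) == 0L) {
    codes <- matrix(integer(0), nrow = 0, ncol = 10)
  }
  if (nrow(base) == 1L) codes <- matrix(codes, nrow = 1)
  wmat <- sweep(codes, 2L, as.numeric(weights), `*`)
  colnames(wmat) <- paste0(characteristics(), "_weighted")
  out <- dplyr::bind_cols(base, tibble::as_tibble(wmat))
  out$raw_sum <- rowSums(wmat)
  out$raw_mean <- out$raw_sum / 10
  out$nss <- 100 * out$raw_sum / max_raw_sum(weights)
  cls <- character(nrow(out))
  for (i in seq_len(nrow(out))) {
    cls[i] <- classify_severity(base[i, ], tiers)
  }
  out$severity_class <- factor(cls, levels = rev(severity_classes()),
                               ordered = TRUE)
  out
}

#' Rank scored phenotypes by severity
#'
#' Stable sort of a scored table by the normalised severity score, ties
#' broken by term id in lexicographic order.
#'
#' @param scored A table from [score_annotations()].
#' @param descending Most severe first?
#' @return The reordered table.
#' @export
rank_phenotypes <- function(scored, descending = TRUE) {
  ord <- if (descending) {
    order(-scored$nss, scored$hpo_id, scored$replicate)
  } else {
    order(scored$nss, scored$hpo_id, scored$replicate)
  }
  scored[ord, ]
}

#' Collapse replicates to a consensus annotation
#'
#' Optional consensus mode: per (phenotype, characteristic), the modal
#' frequency across replicates, ties resolved towards the more severe
#' (higher-coded) frequency. Justifications are taken from the first
#' replicate. Off the default path: replicates are normally scored
#' independently.
#'
#' @param set An annotation tibble.
#' @return An annotation tibble with one row per phenotype (`replicate = 1`).
#' @export
consensus_annotations <- function(set) {
  split_rows <- split(seq_len(nrow(set)), set$hpo_id)
  rows <- lapply(split_rows, function(idx) {
    sub <- set[idx, ]
    row <- sub[which.min(sub$replicate), ]
    for (cl in freq_cols()) {
      tab <- table(factor(sub[[cl]], levels = frequency_levels()))
      best <- names(tab)[tab == max(tab)]
      row[[cl]] <- best[length(best)]  # highest code among modal values
    }
    row$replicate <- 1L
    row
  })
  new_annotation_set(dplyr::bind_rows(rows),
                     provenance = attr(set, "provenance"))
}
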