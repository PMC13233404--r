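#' Replicate-consistency rates per characteristic
#'
#' Over phenotypes annotated more than once, computes two agreement metrics
#' per clinical characteristic. The lenient metric collapses the vocabulary
#' into two groups ("always"/"often" and "never"/"rarely") and calls a
#' phenotype consistent when all its replicate annotations fall in one
#' group. The stringent metric requires all replicates to be identical.
#'
#' @param set An annotation tibble containing at least one phenotype with
#'   two or more replicates.
#' @return A tibble with columns `characteristic`, `n_duplicated`,
#'   `lenient_rate`, `stringent_rate`.
#' @export
consistency_rates <- function(set) {
  dup_ids <- names(which(table(set$hpo_id) >= 2L))
  if (!length(dup_ids)) {
    stop("no phenotype has two or more replicates", call. = FALSE)
  }
  sub <- set[set$hpo_id %in% dup_ids, ]
  high <- c("often", "always")
  res <- lapply(characteristics(), function(ch) {
    f <- sub[[paste0(ch, "_freq")]]
    by_term <- split(f, sub$hpo_id)
    lenient <- vapply(by_term, function(v) {
      g <- v %in% high
      all(g) || all(!g)
    }, logical(1))
    stringent <- vapply(by_term, function(v) length(unique(v)) == 1L,
                        logical(1))
    tibble::tibble(
      characteristic = ch,
      n_duplicated = length(by_term),
      lenient_rate = mean(lenient),
      stringent_rate = mean(stringent)
    )
  })
  dplyr::bind_rows(res)
}

#' Chance level of replicate consistency
#'
#' Exact probability that `k` independent uniform draws over the four
#' frequency words are consistent: for the lenient metric all draws must
#' fall in one of the two frequency groups (`2 * (1/2)^k`); for the
#' stringent metric all draws must be identical (`4 * (1/4)^k`). With two
#' replicates these are the 1/2 and 1/4 chance lines.
#'
#' @param k Number of replicates (at least 2).
#' @param metric `"lenient"` or `"stringent"`.
#' @return A probability.
#' @export
#' @examples
#' chance_consistency(2, "lenient")    # 0.5
#' chance_consistency(2, "stringent")  # 0.25
chance_consistency <- function(k, metric = c("lenient", "stringent")) {
  metric <- match.arg(metric)
  if (k < 2) stop("k must be at least 2", call. = FALSE)
  if (metric == "lenient") 2 * (1 / 2)^k else 4 * (1 / 4)^k
}

#' True positive rate against ontology truth sets
#'
#' For each characteristic with a truth set, the denominator is the truth-set
#' members actually present in the annotation set (first replicate by
#' default, or the consensus), and a member counts as a hit when it is
#' annotated "often" or "always" for that characteristic.
#'
#' @param set An annotation tibble.
#' @param truth Named list: characteristic -> term ids, as from
#'   [build_truth_sets()].
#' @param use_consensus Collapse replicates with [consensus_annotations()]
#'   instead of keeping the first replicate?
#' @return A tibble with columns `characteristic`, `n_truth` (denominator),
#'   `n_hit` and `recall` (`NA` when the denominator is empty).
#' @export
true_positive_rate <- function(set, truth, use_consensus = FALSE) {
  if (!nrow(set)) stop("annotation set is empty", call. = FALSE)
  one <- if (use_consensus) {
    consensus_annotations(set)
  } else {
    dplyr::slice_min(dplyr::group_by(tibble::as_tibble(set), .data$hpo_id),
                     .data$replicate, n = 1, with_ties = FALSE)
  }
  res <- lapply(names(truth), function(ch) {
    members <- one[one$hpo_id %in% truth[[ch]], ]
    n <- nrow(members)
    hits <- sum(members[[paste0(ch, "_freq")]] %in% c("often", "always"))
    tibble::tibble(
      characteristic = ch,
      n_truth = n,
      n_hit = hits,
      recall = if (n > 0) hits / n else NA_real_
    )
  })
  dplyr::bind_rows(res)
}

#' Flag annotations whose justification indicates indirect causation
#'
#' Case-insensitive substring scan of every justification for phrases such
#' as "indirectly" or "does not directly", which signal that the annotator
#' described an indirect effect despite being told to ignore them. One flag
#' is emitted per (phenotype, replicate, characteristic, pattern) hit.
#'
#' @param set An annotation tibble.
#' @param patterns Character vector of phrases to scan for.
#' @return A tibble with columns `hpo_id`, `replicate`, `characteristic`,
#'   `matched_pattern`.
#' @export
flag_indirect <- function(set,
                          patterns = c("indirectly", "does not directly")) {
  flags <- list()
  for (ch in characteristics()) {
    ju <- tolower(set[[paste0(ch, "_justification")]])
    for (p in patterns) {
      hit <- which(grepl(tolower(p), ju, fixed = TRUE))
      if (length(hit)) {
        flags[[length(flags) + 1L]] <- tibble::tibble(
          hpo_id = set$hpo_id[hit],
          replicate = set$replicate[hit],
          characteristic = ch,
          matched_pattern = p
        )
      }
    }
  }
  if (!length(flags)) {
    return(tibble::tibble(hpo_id = character(0), replicate = integer(0),
                          characteristic = character(0),
                          matched_pattern = character(0)))
  }
  out <- dplyr::bind_rows(flags)
  dplyr::arrange(out, .data$hpo_id, .data$replicate, .data$characteristic,
                 .data$matched_pattern)
}

#' Reassign indirect-causation annotations to "never"
#'
#' Sets the frequency of every flagged (phenotype, replicate,
#' characteristic) to "never", leaving everything else unchanged. Because
#' weights are positive, no severity score (and no severity class) can
#' increase under reassignment.
#'
#' @param set An annotation tibble.
#' @param flags Flags from [flag_indirect()] computed on `set`.
#' @return The modified annotation tibble.
#' @export
reassign_indirect <- function(set, flags) {
  if (!nrow(flags)) return(set)
  key <- paste(set$hpo_id, set$replicate)
  for (ch in unique(flags$characteristic)) {
    fk <- flags[flags$characteristic == ch, ]
    rows <- match(paste(fk$hpo_id, fk$replicate), key)
    if (anyNA(rows)) {
      stop("flag references a record absent from the set: ",
           paste(paste(fk$hpo_id, fk$replicate)[is.na(rows)], collapse = ", "),
           call. = FALSE)
    }
    set[[paste0(ch, "_freq")]][rows] <- "never"
  }
  set
}

#' Pairwise Pearson correlations between severity metrics
#'
#' Correlations between the numerically encoded frequencies of the ten
#' clinical characteristics and the composite severity score. Zero-variance
#' columns yield `NA` entries (never coerced to 0).
#'
#' @param scored A table from [score_annotations()] (at least 3 rows).
#' @return An 11 x 11 symmetric correlation matrix (ten characteristics
#'   plus `nss`).
#' @export
metric_correlations <- function(scored) {
  if (nrow(scored) < 3L) {
    stop("need at least 3 records to correlate", call. = FALSE)
  }
  codes <- vapply(freq_cols(), function(cl) frequency_code(scored[[cl]]),
                  integer(nrow(scored)))
  colnames(codes) <- characteristics()
  m <- cbind(codes, nss = scored$nss)
  suppressWarnings(stats::cor(m, method = "pearson"))
}

#' Congenital-onset composition of each ontology branch
#'
#' For every branch (direct child of the ontology root), the proportion of
#' its member phenotypes annotated always/often/rarely/never congenital.
#' First replicates are used; a phenotype under several branches counts once
#' in each. Branches are ordered by decreasing proportion of
#' always-congenital phenotypes.
#'
#' @param set An annotation tibble.
#' @param ont The `phenotype_ontology` the annotations refer to.
#' @return A tibble with columns `branch_id`, `branch_name`, `n_terms`, and
#'   `always`, `often`, `rarely`, `never` proportions (each row sums to 1).
#' @export
congenital_by_branch <- function(set, ont) {
  if (!nrow(set)) stop("annotation set is empty", call. = FALSE)
  one <- dplyr::slice_min(dplyr::group_by(tibble::as_tibble(set), .data$hpo_id),
                          .data$replicate, n = 1, with_ties = FALSE)
  one <- dplyr::ungroup(one)
  known <- one[one$hpo_id %in% ont$terms$id, ]
  rows <- lapply(ont$branch_roots, function(b) {
    members <- known[vapply(known$hpo_id,
                            function(id) b %in% branch_of(ont, id),
                            logical(1)), ]
    if (!nrow(members)) return(NULL)
    tab <- table(factor(members$congenital_onset_freq,
                        levels = frequency_levels()))
    p <- as.numeric(tab) / nrow(members)
    tibble::tibble(
      branch_id = b,
      branch_name = term_name(ont, b),
      n_terms = nrow(members),
      never = p[1], rarely = p[2], often = p[3], always = p[4]
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out)) out <- out[order(-out$always, out$branch_id), ]
  out
}

#' Association between ontology depth and replicate consistency
#'
#' Tests whether annotation consistency improves for more specific (deeper)
#' terms. The unit of analysis is the (phenotype, characteristic) pair: for
#' every duplicated phenotype, each of the ten characteristics is scored as
#' consistent or not across its replicates (under the chosen metric) and
#' paired with the phenotype's depth. The function reports the Spearman rank
#' correlation between depth and the 0/1 consistency indicator, and a
#' Pearson chi-square test with Cramer's V on the depth-level x
#' consistent/inconsistent contingency table.
#'
#' @param set An annotation tibble with duplicated phenotypes.
#' @param ont The ontology supplying term depths.
#' @param metric `"stringent"` or `"lenient"`.
#' @return A list: `n` (number of pairs), `spearman_rho`, `spearman_p`,
#'   `chi_square`, `df`, `cramers_v`, `chi_p`, and the `table` tested.
#' @export
depth_consistency_association <- function(set, ont,
                                          metric = c("stringent", "lenient")) {
  metric <- match.arg(metric)
  dup_ids <- names(which(table(set$hpo_id) >= 2L))
  dup_ids <- intersect(dup_ids, ont$terms$id)
  if (!length(dup_ids)) {
    stop("no duplicated phenotypes with known depth", call. = FALSE)
  }
  sub <- set[set$hpo_id %in% dup_ids, ]
  high <- c("often", "always")
  consistent_one <- function(v) {
    if (metric == "stringent") length(unique(v)) == 1L else {
      g <- v %in% high
      all(g) || all(!g)
    }
  }
  cons_mat <- vapply(dup_ids, function(id) {
    rows <- sub[sub$hpo_id == id, ]
    vapply(freq_cols(), function(cl) consistent_one(rows[[cl]]), logical(1))
  }, logical(10))
  term_d <- term_depth(ont, dup_ids)
  keep <- !is.na(term_d)
  cons <- as.vector(cons_mat[, keep, drop = FALSE])
  depth <- rep(term_d[keep], each = 10L)
  if (length(unique(depth)) < 2L) {
    stop("all duplicated phenotypes share one depth level", call. = FALSE)
  }
  sp <- suppressWarnings(
    stats::cor.test(depth, as.integer(cons), method = "spearman"))
  tab <- table(depth = depth, consistent = factor(cons, c(FALSE, TRUE)))
  chi <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  n <- sum(tab)
  v <- sqrt(as.numeric(chi$statistic) / (n * (min(dim(tab)) - 1)))
  list(
    n = n,
    spearman_rho = unname(sp$estimate),
    spearman_p = sp$p.value,
    chi_square = unname(as.numeric(chi$statistic)),
    df = unname(as.numeric(chi$parameter)),
    cramers_v = v,
    chi_p = chi$p.value,
    table = tab
  )
}

#' Concordance between severity class and severity score
#'
#' Effect size of severity class on the continuous severity score: one-way
#' between-groups omega squared,
#' `(SSb - dfb * MSw) / (SSt + MSw)`, with the F-test p-value. Values near 1
#' mean the categorical classes recover almost all of the variance of the
#' continuous score.
#'
#' @param scored A table from [score_annotations()] with at least two
#'   populated classes.
#' @return A list: `omega_squared`, `f_statistic`, `df_between`, `df_within`,
#'   `p_value`, and per-class mean scores (`class_means`).
#' @export
class_score_concordance <- function(scored) {
  cls <- droplevels(factor(scored$severity_class, levels = severity_classes()))
  if (nlevels(cls) < 2L) {
    stop("need at least two populated severity classes", call. = FALSE)
  }
  fit <- stats::aov(scored$nss ~ cls)
  tab <- summary(fit)[[1]]
  ssb <- tab["cls", "Sum Sq"]
  ssw <- tab["Residuals", "Sum Sq"]
  dfb <- tab["cls", "Df"]
  msw <- tab["Residuals", "Mean Sq"]
  sst <- ssb + ssw
  omega <- (ssb - dfb * msw) / (sst + msw)
  means <- tapply(scored$nss, factor(scored$severity_class,
                                     rev(severity_classes())), mean)
  list(
    omega_squared = unname(omega),
    f_statistic = tab["cls", "F value"],
    df_between = dfb,
    df_within = tab["Residuals", "Df"],
    p_value = tab["cls", "Pr(>F)"],
    class_means = means
  )
}
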