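#' Specification for synthetic fixtures
#'
#' Collects the knobs of the toy-ontology and annotation generators in one
#' validated list. Defaults emulate the statistical structure of a
#' large-scale LLM annotation study: roughly half of phenotypes never cause
#' most characteristics while congenital onset is common, a small subset of
#' phenotypes is annotated in duplicate, justifications occasionally describe
#' indirect causation, and truth-set members are annotated often/always with
#' probability `1 - epsilon`.
#'
#' @param n_branches Number of branches under the root.
#' @param terms_per_branch Terms generated below each branch root.
#' @param max_depth Maximum term depth (root = 0).
#' @param seed Integer seed; every generated object is deterministic in it.
#' @param marginals Named list: characteristic -> probability vector over
#'   never/rarely/often/always. Unnamed characteristics use the default.
#' @param dup_fraction Fraction of terms annotated more than once.
#' @param n_replicates Replicates for the duplicated subset.
#' @param indirect_rate Probability that a justification describes indirect
#'   causation.
#' @param epsilon Miss probability for planted truth-set members.
#' @param plant_truth Plant often/always answers for truth-set members?
#' @param latent_rho Correlation of each characteristic's latent score with a
#'   per-phenotype latent severity (0 disables; positive values induce
#'   correlated characteristics and a spread of severity classes).
#' @param p_multi_parent Probability a term gets a second parent in its own
#'   branch (creates diamonds).
#' @param p_cross_branch Probability a term gets an additional parent in a
#'   different branch (creates multi-branch membership).
#' @param prefix Term-id prefix of the toy ontology.
#' @return A validated list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_branches = 10, terms_per_branch = 30,
                         max_depth = 6, seed = 42,
                         marginals = list(),
                         dup_fraction = 0.05, n_replicates = 2,
                         indirect_rate = 0.03, epsilon = 0.03,
                         plant_truth = TRUE, latent_rho = 0,
                         p_multi_parent = 0.1, p_cross_branch = 0.05,
                         prefix = "TOY") {
  base <- c(never = 0.55, rarely = 0.25, often = 0.13, always = 0.07)
  congenital <- c(never = 0.217, rarely = 0.18, often = 0.25, always = 0.353)
  defaults <- stats::setNames(rep(list(base), 10), characteristics())
  defaults$congenital_onset <- congenital
  for (ch in names(marginals)) {
    stopifnot(ch %in% characteristics())
    defaults[[ch]] <- stats::setNames(as.numeric(marginals[[ch]]),
                                      frequency_levels())
  }
  for (ch in characteristics()) {
    p <- defaults[[ch]]
    if (length(p) != 4L || any(p < 0) || abs(sum(p) - 1) > 1e-8) {
      stop("marginals for ", ch, " must be 4 non-negative numbers summing to 1",
           call. = FALSE)
    }
  }
  stopifnot(
    n_branches >= 1, terms_per_branch >= 0, max_depth >= 1,
    dup_fraction >= 0, dup_fraction <= 1, n_replicates >= 1,
    indirect_rate >= 0, indirect_rate <= 1,
    epsilon >= 0, epsilon <= 1,
    latent_rho >= 0, latent_rho < 1
  )
  structure(
    list(n_branches = as.integer(n_branches),
         terms_per_branch = as.integer(terms_per_branch),
         max_depth = as.integer(max_depth), seed = as.integer(seed),
         marginals = defaults, dup_fraction = dup_fraction,
         n_replicates = as.integer(n_replicates),
         indirect_rate = indirect_rate, epsilon = epsilon,
         plant_truth = isTRUE(plant_truth), latent_rho = latent_rho,
         p_multi_parent = p_multi_parent, p_cross_branch = p_cross_branch,
         prefix = prefix),
    class = "fixture_spec"
  )
}

# Branch names are chosen so the default benchmark queries match: each
# benchmarked characteristic gets a non-empty truth set on the toy ontology.
toy_branch_names <- function(n) {
  base <- c(
    "Intellectual disability",
    "Gait disturbance",
    "Physical malformation",
    "Blindness",
    "Abnormality of vision",
    "Immunodeficiency",
    "Cancer",
    "Decreased fertility",
    "Abnormality of prenatal development or birth",
    "Constitutional symptom"
  )
  if (n <= length(base)) return(base[seq_len(n)])
  c(base, paste("Branch", seq_len(n - length(base)), "phenotypes"))
}

#' Generate a toy phenotype ontology
#'
#' Builds a small acyclic ontology: one root ("Phenotypic abnormality"),
#' `n_branches` branch roots named so that the default benchmark queries
#' match them, and `terms_per_branch` descendant terms per branch arranged
#' in a random DAG (occasional diamonds and cross-branch parents). A branch
#' named "Blindness" always contains a "Congenital night blindness" term so
#' that exclusion filters have something to exclude. Deterministic per seed.
#'
#' @param spec A [fixture_spec()].
#' @return A `phenotype_ontology`.
#' @export
make_toy_ontology <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  mk_id <- function(i) sprintf("%s:%07d", spec$prefix, i)

  ids <- mk_id(1L); nms <- "Phenotypic abnormality"
  obs <- FALSE; parents <- list(character(0))
  depth <- 0L
  branch_names <- toy_branch_names(spec$n_branches)
  branch_ids <- character(spec$n_branches)
  nxt <- 2L
  for (b in seq_len(spec$n_branches)) {
    branch_ids[b] <- mk_id(nxt)
    ids <- c(ids, branch_ids[b]); nms <- c(nms, branch_names[b])
    obs <- c(obs, FALSE); parents <- c(parents, list(mk_id(1L)))
    depth <- c(depth, 1L)
    nxt <- nxt + 1L
  }
  for (b in seq_len(spec$n_branches)) {
    in_branch <- branch_ids[b]
    in_depth <- 1L
    for (i in seq_len(spec$terms_per_branch)) {
      eligible <- in_branch[in_depth < spec$max_depth]
      par <- if (length(eligible) == 1L) eligible else sample(eligible, 1L)
      par_depth <- in_depth[match(par, in_branch)]
      extra <- character(0)
      others <- setdiff(in_branch[in_depth < spec$max_depth], par)
      if (length(others) && stats::runif(1) < spec$p_multi_parent) {
        extra <- if (length(others) == 1L) others else sample(others, 1L)
      }
      if (spec$n_branches > 1L && stats::runif(1) < spec$p_cross_branch) {
        extra <- c(extra, sample(branch_ids[-b], 1L))
      }
      nm <- if (branch_names[b] == "Blindness" && i == 1L) {
        "Congenital night blindness"
      } else {
        sprintf("%s subtype %d", branch_names[b], i)
      }
      id <- mk_id(nxt)
      ids <- c(ids, id); nms <- c(nms, nm); obs <- c(obs, FALSE)
      parents <- c(parents, list(unique(c(par, extra))))
      d <- par_depth + 1L
      depth <- c(depth, d)
      in_branch <- c(in_branch, id)
      in_depth <- c(in_depth, d)
      nxt <- nxt + 1L
    }
  }
  names(parents) <- ids
  new_phenotype_ontology(
    tibble::tibble(id = ids, name = nms, definition = NA_character_,
                   obsolete = obs),
    parents,
    root_name = "Phenotypic abnormality"
  )
}

#' Simulate an annotation set over an ontology
#'
#' Draws a frequency for every (term, characteristic) from the per-
#' characteristic marginals via a Gaussian copula: each phenotype carries a
#' latent severity, and with `latent_rho > 0` all characteristics of a
#' phenotype are shifted together, inducing realistic positive correlations
#' while preserving the marginals. Truth-set members are then overridden to
#' "often"/"always" with probability `1 - epsilon`. A random subset of
#' phenotypes is annotated `n_replicates` times (replicates share the latent
#' severity but draw independent noise). Justifications are templated, with
#' indirect-causation phrasing injected at `indirect_rate`.
#'
#' @param ont A `phenotype_ontology`.
#' @param spec A [fixture_spec()].
#' @param truth Optional named list characteristic -> term ids; by default
#'   the truth sets implied by [default_benchmark_spec()] on `ont`.
#' @return An annotation tibble (provenance label `"simulated"`).
#' @export
simulate_annotations <- function(ont, spec = fixture_spec(), truth = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed + 1L)
  term_ids <- setdiff(ont$terms$id[!ont$terms$obsolete], ont$root)
  n_terms <- length(term_ids)
  if (!n_terms) stop("ontology has no annotatable terms", call. = FALSE)

  if (is.null(truth) && spec$plant_truth) {
    truth <- build_truth_sets(ont, default_benchmark_spec())
  }

  n_dup <- round(spec$dup_fraction * n_terms)
  dup <- if (n_dup > 0) sample(term_ids, n_dup) else character(0)
  reps <- ifelse(term_ids %in% dup, spec$n_replicates, 1L)

  rec_term <- rep.int(term_ids, reps)
  rec_rep <- unlist(lapply(reps, seq_len), use.names = FALSE)
  n_rec <- length(rec_term)

  q <- stats::rnorm(n_terms)                    # latent severity per term
  q_rec <- q[match(rec_term, term_ids)]
  rho <- spec$latent_rho

  freq_mat <- matrix("", nrow = n_rec, ncol = 10,
                     dimnames = list(NULL, characteristics()))
  for (ch in characteristics()) {
    eps <- stats::rnorm(n_rec)
    u <- stats::pnorm(rho * q_rec + sqrt(1 - rho^2) * eps)
    cum <- cumsum(spec$marginals[[ch]])[1:3]
    code <- findInterval(u, cum)                # 0..3
    if (spec$plant_truth && ch %in% names(truth) && length(truth[[ch]])) {
      planted <- rec_term %in% truth[[ch]]
      if (any(planted)) {
        np <- sum(planted)
        miss <- stats::runif(np) < spec$epsilon
        hi <- 2L + stats::rbinom(np, 1L, 0.5)   # often / always
        lo <- stats::rbinom(np, 1L, 0.5)        # never / rarely
        code[planted] <- ifelse(miss, lo, hi)
      }
    }
    freq_mat[, ch] <- frequency_levels()[code + 1L]
  }

  nm_rec <- term_name(ont, rec_term)
  out <- tibble::tibble(hpo_id = rec_term, hpo_name = nm_rec,
                        replicate = rec_rep)
  patterns <- c("indirectly", "does not directly")
  for (ch in characteristics()) {
    f <- freq_mat[, ch]
    label <- gsub("_", " ", ch)
    ju <- sprintf("%s %s causes %s.", nm_rec, f, label)
    ind <- stats::runif(n_rec) < spec$indirect_rate
    if (any(ind)) {
      pat <- sample(patterns, sum(ind), replace = TRUE)
      ju[ind] <- ifelse(
        pat == "indirectly",
        sprintf("%s indirectly contributes to %s.", nm_rec[ind], label),
        sprintf("%s does not directly cause %s, although it is a risk factor.",
                nm_rec[ind], label)
      )
    }
    out[[paste0(ch, "_freq")]] <- f
    out[[paste0(ch, "_justification")]] <- ju
  }
  new_annotation_set(out, provenance = list(annotator = "simulated",
                                            seed = spec$seed))
}

#' Write an ontology as OBO
#'
#' Serialises a `phenotype_ontology` back to OBO 1.2 (`[Term]` stanzas with
#' `id`, `name`, `is_a` and `is_obsolete` lines), so fixtures can be reused
#' across tools.
#'
#' @param ont A `phenotype_ontology`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(ont, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (i in seq_len(nrow(ont$terms))) {
    id <- ont$terms$id[i]
    lines <- c("[Term]",
               paste0("id: ", id),
               paste0("name: ", ont$terms$name[i]))
    for (p in ont$parents[[id]]) {
      lines <- c(lines, paste0("is_a: ", p, " ! ", term_name(ont, p)))
    }
    if (ont$terms$obsolete[i]) lines <- c(lines, "is_obsolete: true")
    writeLines(c(lines, ""), con)
  }
  invisible(path)
}

#' Write an ontology as obographs JSON
#'
#' @inheritParams write_obo
#' @return `path`, invisibly.
#' @export
write_obographs <- function(ont, path) {
  uri <- function(id) {
    paste0("http://purl.obolibrary.org/obo/", sub(":", "_", id, fixed = TRUE))
  }
  nodes <- lapply(seq_len(nrow(ont$terms)), function(i) {
    nd <- list(id = uri(ont$terms$id[i]), lbl = ont$terms$name[i],
               type = "CLASS")
    if (ont$terms$obsolete[i]) nd$meta <- list(deprecated = TRUE)
    nd
  })
  edges <- list()
  for (id in names(ont$parents)) {
    for (p in ont$parents[[id]]) {
      edges[[length(edges) + 1L]] <- list(sub = uri(id), pred = "is_a",
                                          obj = uri(p))
    }
  }
  doc <- list(graphs = list(list(nodes = nodes, edges = edges)))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
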