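test_that("consistency metrics group the vocabulary as specified", {
  set <- make_set(
    make_record("HP:0000002", "A", 1, death = "always", cancer = "always"),
    make_record("HP:0000002", "A", 2, death = "often", cancer = "always"),
    make_record("HP:0000003", "B", 1, death = "never", cancer = "rarely"),
    make_record("HP:0000003", "B", 2, death = "rarely", cancer = "often"),
    make_record("HP:0000004", "C", 1)  # singleton: excluded everywhere
  )
  rep <- consistency_rates(set)
  expect_equal(rep$n_duplicated, rep(2L, 10))
  d <- rep[rep$characteristic == "death", ]
  # (always, often) and (never, rarely) are lenient-consistent only
  expect_equal(d$lenient_rate, 1)
  expect_equal(d$stringent_rate, 0)
  k <- rep[rep$characteristic == "cancer", ]
  # (always, always) consistent under both; (rarely, often) under neither
  expect_equal(k$lenient_rate, 0.5)
  expect_equal(k$stringent_rate, 0.5)
  # untouched characteristics are identical across replicates
  other <- rep[rep$characteristic == "blindness", ]
  expect_equal(other$stringent_rate, 1)
  expect_true(all(rep$stringent_rate <= rep$lenient_rate))
  expect_error(consistency_rates(make_set(make_record("HP:0000002", "A", 1))),
               "no phenotype")
})

test_that("chance consistency matches exact enumeration", {
  expect_identical(chance_consistency(2, "lenient"), 0.5)
  expect_identical(chance_consistency(2, "stringent"), 0.25)
  expect_error(chance_consistency(1), "at least 2")

  # enumeration oracle over all 4^k outcomes
  for (k in 2:4) {
    draws <- as.matrix(expand.grid(rep(list(1:4), k)))
    high <- draws >= 3
    lenient <- mean(apply(high, 1, function(v) all(v) || all(!v)))
    stringent <- mean(apply(draws, 1, function(v) length(unique(v)) == 1))
    expect_equal(chance_consistency(k, "lenient"), lenient)
    expect_equal(chance_consistency(k, "stringent"), stringent)
  }
  expect_equal(chance_consistency(3, "stringent"), 1 / 16)
})

test_that("true positive rate counts often/always among present truth members", {
  hit_words <- rep(c("often", "always"), length.out = 7)
  rows <- lapply(1:8, function(i) {
    make_record(sprintf("HP:%07d", i), sprintf("T%d", i), 1,
                cancer = if (i <= 7) hit_words[i] else "rarely")
  })
  set <- make_set(rows)
  truth <- list(cancer = sprintf("HP:%07d", 1:9))  # HP:0000009 not annotated
  rep <- true_positive_rate(set, truth)
  expect_equal(rep$n_truth, 8)   # absent member excluded from denominator
  expect_equal(rep$n_hit, 7)
  expect_equal(rep$recall, 0.875)

  # empty denominator is missing, not zero
  rep2 <- true_positive_rate(set, list(blindness = "HP:9999999"))
  expect_true(is.na(rep2$recall))

  # only the first replicate counts by default
  set2 <- make_set(
    make_record("HP:0000001", "T", 1, cancer = "never"),
    make_record("HP:0000001", "T", 2, cancer = "always")
  )
  expect_equal(true_positive_rate(set2, list(cancer = "HP:0000001"))$recall, 0)
})

test_that("indirect-causation flags are substring hits on justifications", {
  set <- make_set(
    dplyr::mutate(
      make_record("HP:0000002", "Obesity", 1, cancer = "never"),
      cancer_justification =
        "Obesity does not directly cause cancer, although it is a risk factor"),
    dplyr::mutate(
      make_record("HP:0000003", "Palsy", 1, impaired_mobility = "always"),
      impaired_mobility_justification = "directly causes paralysis"),
    make_record("HP:0000004", "Empty", 1)
  )
  flags <- flag_indirect(set)
  expect_equal(nrow(flags), 1)
  expect_equal(flags$hpo_id, "HP:0000002")
  expect_equal(flags$characteristic, "cancer")
  expect_equal(flags$matched_pattern, "does not directly")

  # case-insensitive, both default patterns, custom patterns honoured
  set2 <- make_set(
    dplyr::mutate(make_record("HP:0000005", "X", 1),
                  death_justification = "INDIRECTLY lethal at best")
  )
  expect_equal(flag_indirect(set2)$matched_pattern, "indirectly")
  expect_equal(nrow(flag_indirect(set2, patterns = "via secondary")), 0)
})

test_that("reassignment to never only lowers scores and classes", {
  set <- make_set(
    dplyr::mutate(
      make_record("HP:0000002", "A", 1, death = "always", cancer = "often"),
      death_justification = "A indirectly shortens lifespan"),
    make_record("HP:0000003", "B", 1, death = "always")
  )
  flags <- flag_indirect(set)
  expect_equal(nrow(flags), 1)
  before <- score_annotations(set)
  after <- score_annotations(reassign_indirect(set, flags))
  expect_equal(before$nss[1] - after$nss[1], 100 * 18 / 99)
  expect_equal(after$nss[2], before$nss[2])  # unflagged record untouched
  expect_identical(reassign_indirect(set, flags[0, ]), set)

  bad <- flags
  bad$hpo_id <- "HP:9999999"
  expect_error(reassign_indirect(set, bad), "absent")

  # property on simulated data: nss never increases, classes never escalate
  spec <- fixture_spec(n_branches = 5, terms_per_branch = 30, seed = 8,
                       indirect_rate = 0.3, latent_rho = 0.5)
  sim <- simulate_annotations(make_toy_ontology(spec), spec)
  fl <- flag_indirect(sim)
  expect_gt(nrow(fl), 0)
  b <- score_annotations(sim)
  a <- score_annotations(reassign_indirect(sim, fl))
  expect_true(all(a$nss <= b$nss))
  expect_true(all(a$severity_class <= b$severity_class))
})

test_that("metric correlations match the textbook formula", {
  pearson <- function(x, y) {  # independent oracle
    n <- length(x)
    (sum(x * y) - n * mean(x) * mean(y)) /
      sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  }
  lv <- frequency_levels()
  d_codes <- c(0, 1, 2, 3, 3)
  c_codes <- c(0, 0, 1, 2, 3)
  rows <- lapply(1:5, function(i) {
    make_record(sprintf("HP:%07d", i), "t", 1,
                death = lv[d_codes[i] + 1], cancer = lv[c_codes[i] + 1])
  })
  scored <- score_annotations(make_set(rows))
  m <- metric_correlations(scored)
  expect_equal(dim(m), c(11, 11))
  expect_equal(m["death", "death"], 1)
  expect_equal(m["death", "cancer"], pearson(d_codes, c_codes),
               tolerance = 1e-12)
  expect_equal(m["cancer", "death"], m["death", "cancer"])
  expect_equal(m["death", "nss"], pearson(d_codes, scored$nss),
               tolerance = 1e-12)
  # zero-variance columns give missing entries, not zero
  expect_true(is.na(m["blindness", "death"]))
  expect_error(metric_correlations(scored[1:2, ]), "at least 3")
})

test_that("congenital composition is per branch and sums to one", {
  path <- withr::local_tempfile(fileext = ".obo")
  writeLines(paste(
    toy_obo_text(),
    "[Term]", "id: HP:0000009", "name: Fertility-linked ear anomaly",
    "is_a: HP:0000002", "is_a: HP:0000005", "",
    sep = "\n"), path)
  ont <- load_ontology(path)
  set <- make_set(
    make_record("HP:0000002", "Ear malformation", 1, congenital_onset = "always"),
    make_record("HP:0000004", "Heart", 1, congenital_onset = "always"),
    make_record("HP:0000003", "Fertility", 1, congenital_onset = "never"),
    make_record("HP:0000005", "Males", 1, congenital_onset = "rarely"),
    make_record("HP:0000009", "Linked", 1, congenital_onset = "always")
  )
  tab <- congenital_by_branch(set, ont)
  a <- tab[tab$branch_id == "HP:0000002", ]
  expect_equal(a$n_terms, 3)  # multi-branch HP:0000009 counts here too
  expect_equal(a$always, 1)
  expect_equal(a$never + a$rarely + a$often, 0)
  b <- tab[tab$branch_id == "HP:0000003", ]
  expect_equal(b$n_terms, 3)  # ...and here
  expect_equal(unname(unlist(b[, c("never", "rarely", "often", "always")])),
               c(1 / 3, 1 / 3, 0, 1 / 3))
  expect_equal(tab$never + tab$rarely + tab$often + tab$always, rep(1, 2))
  # ordered by descending always-proportion
  expect_equal(tab$branch_id, c("HP:0000002", "HP:0000003"))
})

test_that("depth-consistency association recovers perfect and null signals", {
  ont <- toy_ontology()
  # depth-1 terms fully inconsistent, deeper terms fully consistent
  mk <- function(id, consistent) {
    nm <- id
    r1 <- make_record(id, nm, 1)
    r2 <- if (consistent) make_record(id, nm, 2) else {
      do.call(make_record, c(list(id, nm, 2),
                             stats::setNames(as.list(rep("always", 10)),
                                             characteristics())))
    }
    dplyr::bind_rows(r1, r2)
  }
  set <- make_set(
    mk("HP:0000002", FALSE), mk("HP:0000003", FALSE),
    mk("HP:0000004", TRUE), mk("HP:0000005", TRUE), mk("HP:0000006", TRUE)
  )
  res <- depth_consistency_association(set, ont, metric = "stringent")
  expect_equal(res$n, 50)  # 5 phenotypes x 10 characteristics
  expect_equal(res$cramers_v, 1)
  expect_equal(res$chi_square, res$n)  # V = sqrt(chi2 / n) = 1
  expect_gt(res$spearman_rho, 0.99)

  # chi-square agrees with the hand formula on its own contingency table
  tab <- res$table
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(res$chi_square, sum((tab - expected)^2 / expected))

  # null case: consistency independent of depth
  spec <- fixture_spec(n_branches = 5, terms_per_branch = 40, seed = 13,
                       dup_fraction = 1, n_replicates = 2, plant_truth = FALSE)
  ont2 <- make_toy_ontology(spec)
  sim <- simulate_annotations(ont2, spec)
  null <- depth_consistency_association(sim, ont2)
  expect_lt(abs(null$spearman_rho), 0.1)

  expect_error(depth_consistency_association(set[1:2, ], ont), "duplicated")
})

test_that("omega squared matches a hand-built ANOVA table", {
  # 12 records, 3 populated classes
  nss <- c(10, 12, 11, 9, 30, 32, 28, 31, 55, 58, 54, 57)
  cls <- rep(c("Mild", "Moderate", "Severe"), each = 4)
  scored <- tibble::tibble(
    nss = nss,
    severity_class = factor(cls, levels = rev(severity_classes()),
                            ordered = TRUE)
  )
  res <- class_score_concordance(scored)
  # independent ANOVA arithmetic
  gm <- mean(nss)
  means <- tapply(nss, cls, mean)
  ssb <- sum(4 * (means - gm)^2)
  ssw <- sum((nss - means[cls])^2)
  msw <- ssw / (12 - 3)
  omega <- (ssb - 2 * msw) / (ssb + ssw + msw)
  expect_equal(res$omega_squared, omega, tolerance = 1e-10)
  expect_gt(res$omega_squared, 0.9)
  expect_lt(res$p_value, 1e-6)
  expect_equal(unname(res$class_means["Mild"]), mean(nss[1:4]))

  # zero within-class variance approaches the upper boundary
  b <- tibble::tibble(
    nss = rep(c(0, 50, 100), each = 4),
    severity_class = factor(rep(c("Mild", "Moderate", "Severe"), each = 4),
                            levels = rev(severity_classes()), ordered = TRUE))
  expect_gt(class_score_concordance(b)$omega_squared, 0.99)

  # identical class distributions give an effect near zero
  set.seed(2)
  n0 <- tibble::tibble(
    nss = rnorm(300, 50, 10),
    severity_class = factor(sample(c("Mild", "Moderate", "Severe"), 300,
                                   replace = TRUE),
                            levels = rev(severity_classes()), ordered = TRUE))
  expect_lt(abs(class_score_concordance(n0)$omega_squared), 0.05)

  one <- scored[scored$severity_class == "Mild", ]
  expect_error(class_score_concordance(one), "two populated")
})
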