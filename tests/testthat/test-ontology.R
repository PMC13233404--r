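test_that("OBO loading recovers terms, root and branches", {
  ont <- toy_ontology()
  expect_s3_class(ont, "phenotype_ontology")
  expect_equal(nrow(ont$terms), 7)
  expect_equal(ont$root, "HP:0000001")
  expect_equal(ont$branch_roots, c("HP:0000002", "HP:0000003"))
  expect_false(any(ont$terms$obsolete))
})

test_that("loader rejects cycles and unresolvable roots", {
  path <- withr::local_tempfile(fileext = ".obo")
  writeLines(paste(
    "[Term]", "id: HP:0000001", "name: Phenotypic abnormality", "",
    "[Term]", "id: HP:0000002", "name: A", "is_a: HP:0000001",
    "is_a: HP:0000003", "",
    "[Term]", "id: HP:0000003", "name: B", "is_a: HP:0000002", "",
    sep = "\n"), path)
  expect_error(load_ontology(path), "cycle")

  path2 <- withr::local_tempfile(fileext = ".obo")
  writeLines(toy_obo_text(), path2)
  expect_error(load_ontology(path2, root_name = "No such term"), "not found")
})

test_that("obsolete terms are flagged and excluded from traversal", {
  path <- withr::local_tempfile(fileext = ".obo")
  writeLines(paste(
    toy_obo_text(),
    "[Term]", "id: HP:0000008", "name: Retired fertility term",
    "is_a: HP:0000003", "is_obsolete: true", "",
    sep = "\n"), path)
  ont <- load_ontology(path)
  expect_true(ont$terms$obsolete[ont$terms$id == "HP:0000008"])
  expect_false("HP:0000008" %in% descendants(ont, "HP:0000003"))
  expect_false("HP:0000008" %in% find_terms(ont, "Retired fertility term"))
})

test_that("OBO and obographs serialisations load identically", {
  ont <- make_toy_ontology(fixture_spec(n_branches = 4, terms_per_branch = 8,
                                        seed = 11))
  obo <- withr::local_tempfile(fileext = ".obo")
  json <- withr::local_tempfile(fileext = ".json")
  write_obo(ont, obo)
  write_obographs(ont, json)
  a <- load_ontology(obo)
  b <- load_ontology(json)
  expect_equal(a$terms[order(a$terms$id), ], b$terms[order(b$terms$id), ])
  expect_equal(lapply(a$parents, sort), lapply(b$parents[names(a$parents)], sort))
  expect_equal(a$root, b$root)
  expect_equal(a$branch_roots, b$branch_roots)
  # and both agree with the in-memory original
  expect_equal(a$terms[order(a$terms$id), ],
               ont$terms[order(ont$terms$id), ])
})

test_that("descendants matches a brute-force BFS oracle", {
  ont <- toy_ontology()
  parents <- ont$parents
  # leaf
  expect_equal(descendants(ont, "HP:0000004", include_self = TRUE),
               "HP:0000004")
  expect_equal(descendants(ont, "HP:0000004"), character(0))
  # chain and diamond: HP:0000007 reached via two paths, appears once
  d3 <- descendants(ont, "HP:0000003")
  expect_equal(d3, bf_descendants(parents, "HP:0000003"))
  expect_equal(sum(d3 == "HP:0000007"), 1)
  # full agreement on every term
  for (id in ont$terms$id) {
    expect_equal(descendants(ont, id, include_self = TRUE),
                 bf_descendants(parents, id, include_self = TRUE))
  }
  expect_error(descendants(ont, "HP:9999999"), "unknown term")
})

test_that("descendants are monotone along edges", {
  ont <- make_toy_ontology(fixture_spec(n_branches = 3, terms_per_branch = 15,
                                        seed = 5))
  for (id in ont$terms$id) {
    for (p in ont$parents[[id]]) {
      expect_true(all(descendants(ont, id, include_self = TRUE) %in%
                        descendants(ont, p, include_self = TRUE)))
    }
  }
})

test_that("term depth is the shortest parent-path to the root", {
  ont <- toy_ontology()
  expect_equal(term_depth(ont, "HP:0000001"), 0L)
  expect_equal(term_depth(ont, "HP:0000004"), 2L)
  expect_equal(term_depth(ont, "HP:0000007"), 3L)
  for (id in ont$terms$id) {
    expect_equal(term_depth(ont, id), bf_depth(ont$parents, id, ont$root))
  }
  # shortest-path recurrence: depth(child) = min over parents + 1
  ont2 <- make_toy_ontology(fixture_spec(n_branches = 3, terms_per_branch = 20,
                                         seed = 9))
  for (id in setdiff(ont2$terms$id, ont2$root)) {
    expect_equal(term_depth(ont2, id),
                 min(term_depth(ont2, ont2$parents[[id]])) + 1L)
  }
})

test_that("branch membership follows ancestor closure", {
  ont <- toy_ontology()
  expect_equal(branch_of(ont, "HP:0000002"), "HP:0000002")
  expect_equal(branch_of(ont, "HP:0000007"), "HP:0000003")
  expect_equal(branch_of(ont, "HP:0000001"), character(0))
  # term with parents in two branches belongs to both
  path <- withr::local_tempfile(fileext = ".obo")
  writeLines(paste(
    toy_obo_text(),
    "[Term]", "id: HP:0000009", "name: Fertility-linked ear anomaly",
    "is_a: HP:0000002", "is_a: HP:0000005", "",
    sep = "\n"), path)
  ont2 <- load_ontology(path)
  expect_equal(branch_of(ont2, "HP:0000009"),
               c("HP:0000002", "HP:0000003"))
  # invariant over all terms below the root
  for (id in descendants(ont2, ont2$root)) {
    b <- branch_of(ont2, id)
    expect_true(length(b) >= 1 && all(b %in% ont2$branch_roots))
  }
})

test_that("name queries match case-insensitively in both modes", {
  ont <- toy_ontology()
  expect_equal(find_terms(ont, "decreased FERTILITY", "exact"), "HP:0000003")
  expect_equal(find_terms(ont, "malformation", "substring"),
               c("HP:0000002", "HP:0000004"))
  expect_equal(find_terms(ont, "zzz", "substring"), character(0))
  expect_error(find_terms(ont, ""), "non-empty")
})

test_that("truth sets union descendants of matched queries minus exclusions", {
  ont <- toy_ontology()
  spec <- list(
    reduced_fertility = list(
      queries = data.frame(query = "Decreased fertility", mode = "exact"),
      exclusions = character(0)),
    cancer = list(
      queries = data.frame(query = "Cancer", mode = "exact"),
      exclusions = character(0))
  )
  ts <- build_truth_sets(ont, spec)
  expect_equal(ts$reduced_fertility,
               c("HP:0000003", "HP:0000005", "HP:0000006", "HP:0000007"))
  expect_equal(ts$cancer, character(0))

  # the default spec's blindness exclusions remove night blindness
  ont2 <- make_toy_ontology(fixture_spec(n_branches = 4, terms_per_branch = 6,
                                         seed = 2))
  ts2 <- build_truth_sets(ont2, default_benchmark_spec())
  night <- find_terms(ont2, "Congenital night blindness", "exact")
  expect_length(night, 1)
  expect_true(night %in% descendants(ont2, find_terms(ont2, "Blindness", "exact"),
                                     include_self = TRUE))
  expect_false(night %in% ts2$blindness)
  expect_true(length(ts2$blindness) > 0)
})
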