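# Shared fixtures, built in code.

# Seven-term ontology with two branches and a diamond:
#   HP:0000001 Phenotypic abnormality (root)
#   +- HP:0000002 Ear malformation
#   |  +- HP:0000004 Malformation of the heart
#   +- HP:0000003 Decreased fertility
#      +- HP:0000005 Decreased fertility in males
#      +- HP:0000006 Decreased fertility in females
#         +- HP:0000007 Severe fertility defect (also child of HP:0000005)
toy_obo_text <- function() {
  paste(
    "format-version: 1.2",
    "",
    "[Term]", "id: HP:0000001", "name: Phenotypic abnormality", "",
    "[Term]", "id: HP:0000002", "name: Ear malformation",
    "is_a: HP:0000001 ! Phenotypic abnormality", "",
    "[Term]", "id: HP:0000003", "name: Decreased fertility",
    "is_a: HP:0000001 ! Phenotypic abnormality", "",
    "[Term]", "id: HP:0000004", "name: Malformation of the heart",
    "is_a: HP:0000002 ! Ear malformation", "",
    "[Term]", "id: HP:0000005", "name: Decreased fertility in males",
    "is_a: HP:0000003 ! Decreased fertility", "",
    "[Term]", "id: HP:0000006", "name: Decreased fertility in females",
    "is_a: HP:0000003 ! Decreased fertility", "",
    "[Term]", "id: HP:0000007", "name: Severe fertility defect",
    "is_a: HP:0000005", "is_a: HP:0000006", "",
    sep = "\n"
  )
}

toy_ontology <- function() {
  path <- withr::local_tempfile(fileext = ".obo",
                                .local_envir = parent.frame())
  writeLines(toy_obo_text(), path)
  load_ontology(path)
}

# One wide annotation row; unnamed characteristics default to "never".
make_record <- function(hpo_id, hpo_name = hpo_id, replicate = 1L, ...,
                        justification = "") {
  freqs <- stats::setNames(rep("never", 10), characteristics())
  over <- list(...)
  stopifnot(all(names(over) %in% characteristics()))
  freqs[names(over)] <- unlist(over)
  row <- tibble::tibble(hpo_id = hpo_id, hpo_name = hpo_name,
                        replicate = as.integer(replicate))
  for (ch in characteristics()) {
    row[[paste0(ch, "_freq")]] <- unname(freqs[ch])
    row[[paste0(ch, "_justification")]] <- justification
  }
  row
}

make_set <- function(...) {
  phenosev:::new_annotation_set(dplyr::bind_rows(...))
}

# Brute-force graph oracles, independent of the igraph-backed implementation.
bf_descendants <- function(parents, id, include_self = FALSE) {
  children <- function(x) names(parents)[vapply(parents, function(p) x %in% p,
                                                logical(1))]
  seen <- character(0)
  queue <- id
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    for (kid in children(cur)) {
      if (!(kid %in% seen)) {
        seen <- c(seen, kid)
        queue <- c(queue, kid)
      }
    }
  }
  if (include_self) sort(unique(c(seen, id))) else sort(unique(seen))
}

bf_depth <- function(parents, id, root) {
  if (id == root) return(0L)
  best <- Inf
  for (p in parents[[id]]) {
    best <- min(best, 1L + bf_depth(parents, p, root))
  }
  as.integer(best)
}

# The published 10 x 4 grid of weighted severity values.
weight_grid <- function() {
  m <- rbind(
    death = c(18, 12, 6, 0),
    intellectual_disability = c(15, 10, 5, 0),
    impaired_mobility = c(12, 8, 4, 0),
    blindness = c(12, 8, 4, 0),
    physical_malformations = c(9, 6, 3, 0),
    sensory_impairments = c(9, 6, 3, 0),
    immunodeficiency = c(9, 6, 3, 0),
    cancer = c(9, 6, 3, 0),
    reduced_fertility = c(3, 2, 1, 0),
    congenital_onset = c(3, 2, 1, 0)
  )
  colnames(m) <- c("always", "often", "rarely", "never")
  m
}

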