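#' @importFrom rlang .data
NULL

#' Load a phenotype ontology from OBO or obographs JSON
#'
#' Reads an ontology file in OBO 1.2/1.4 format (`[Term]` stanzas with `id:`,
#' `name:`, `def:`, `is_a:` and `is_obsolete:` lines) or in obographs JSON
#' (`nodes` / `edges`, `is_a` edges only) and returns a `phenotype_ontology`
#' object. Only `is_a` relations are used; the term graph must be acyclic.
#'
#' The root is resolved by case-insensitive exact match of `root_name`
#' against term names. The direct children of the root are taken as the
#' ontology branches (for the Human Phenotype Ontology, pass
#' `root_name = "Phenotypic abnormality"` so that branches are the familiar
#' top-level abnormality categories). Obsolete terms are retained but
#' flagged, and are excluded from traversal results and truth sets.
#'
#' @param path Path to an `.obo` or obographs `.json` file. The format is
#'   detected from the first non-blank character (`{` means JSON).
#' @param root_name Name of the term whose children define the branches.
#' @return A `phenotype_ontology` object: a list with elements `terms`
#'   (tibble with columns `id`, `name`, `definition`, `obsolete`), `parents`
#'   (named list of parent id vectors), `graph` (igraph, edges child ->
#'   parent), `root` and `branch_roots` (term ids).
#' @export
#' @examples
#' ont <- make_toy_ontology(fixture_spec(n_branches = 3, terms_per_branch = 5))
#' ont
load_ontology <- function(path, root_name = "Phenotypic abnormality") {
  if (!file.exists(path)) stop("ontology file not found: ", path, call. = FALSE)
  first <- substr(trimws(readLines(path, n = 1L, warn = FALSE)), 1L, 1L)
  parsed <- if (identical(first, "{")) {
    parse_obographs(path)
  } else {
    parse_obo(path)
  }
  new_phenotype_ontology(parsed$terms, parsed$parents, root_name = root_name)
}

# Constructor shared by the loaders and the fixture generator.
new_phenotype_ontology <- function(terms, parents, root_name) {
  stopifnot(is.data.frame(terms), all(c("id", "name") %in% names(terms)))
  terms$id <- normalize_term_id(terms$id)
  if (anyDuplicated(terms$id)) {
    stop("duplicate term ids: ",
         paste(unique(terms$id[duplicated(terms$id)]), collapse = ", "),
         call. = FALSE)
  }
  if (is.null(terms$definition)) terms$definition <- NA_character_
  if (is.null(terms$obsolete)) terms$obsolete <- FALSE
  terms <- tibble::as_tibble(terms[, c("id", "name", "definition", "obsolete")])

  parents <- lapply(parents, normalize_term_id)
  parents <- parents[terms$id]
  names(parents) <- terms$id
  known <- terms$id
  parents <- lapply(parents, function(p) {
    p <- unique(p[!is.na(p)])
    unknown <- setdiff(p, known)
    if (length(unknown)) {
      warning("dropping is_a edges to unknown terms: ",
              paste(unknown, collapse = ", "), call. = FALSE)
    }
    intersect(p, known)
  })

  # edges child -> parent
  edge_df <- data.frame(
    from = rep(names(parents), lengths(parents)),
    to = unlist(parents, use.names = FALSE)
  )
  g <- igraph::graph_from_data_frame(edge_df, directed = TRUE,
                                     vertices = data.frame(name = terms$id))
  if (!igraph::is_dag(g)) {
    stop("cycle detected in is_a relations", call. = FALSE)
  }

  hit <- which(tolower(terms$name) == tolower(root_name) & !terms$obsolete)
  if (length(hit) == 0L) {
    stop("root term not found: ", root_name, call. = FALSE)
  }
  if (length(hit) > 1L) {
    stop("root name is ambiguous: ", root_name, " matches ",
         paste(terms$id[hit], collapse = ", "), call. = FALSE)
  }
  root <- terms$id[hit]

  kids <- igraph::neighbors(g, root, mode = "in")$name
  branch_roots <- sort(setdiff(kids, terms$id[terms$obsolete]))

  structure(
    list(terms = terms, parents = parents, graph = g,
         root = root, branch_roots = branch_roots),
    class = "phenotype_ontology"
  )
}

#' @export
print.phenotype_ontology <- function(x, ...) {
  cat("<phenotype_ontology> ", nrow(x$terms), " terms (",
      sum(x$terms$obsolete), " obsolete), root ", x$root, " (",
      term_name(x, x$root), "), ", length(x$branch_roots), " branches\n",
      sep = "")
  invisible(x)
}

# Normalise a term id: upper-case prefix before the colon.
normalize_term_id <- function(id) {
  ifelse(is.na(id), NA_character_,
         sub("^([^:]+):", "\\U\\1:", as.character(id), perl = TRUE))
}

term_name <- function(ont, id) {
  ont$terms$name[match(id, ont$terms$id)]
}

check_term <- function(ont, id) {
  id <- normalize_term_id(id)
  missing <- setdiff(id, ont$terms$id)
  if (length(missing)) {
    stop("unknown term id(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  id
}

obsolete_ids <- function(ont) ont$terms$id[ont$terms$obsolete]

## ---- parsers -------------------------------------------------------------

parse_obo <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  starts <- grep("^\\[", lines)
  term_starts <- which(lines == "[Term]")
  ids <- character(0); nms <- character(0); defs <- character(0)
  obs <- logical(0); parents <- list()
  bounds <- c(starts, length(lines) + 1L)
  for (s in term_starts) {
    e <- bounds[match(s, bounds) + 1L] - 1L
    block <- lines[(s + 1L):e]
    get1 <- function(tag) {
      v <- sub(paste0("^", tag, ": *"), "", grep(paste0("^", tag, ": "), block, value = TRUE))
      if (length(v)) v[[1]] else NA_character_
    }
    id <- get1("id")
    if (is.na(id)) next
    nm <- get1("name")
    def <- get1("def")
    if (!is.na(def)) def <- sub('^"(.*)".*$', "\\1", def)
    is_a <- sub("^is_a: *", "", grep("^is_a: ", block, value = TRUE))
    is_a <- trimws(sub("!.*$", "", is_a))  # strip trailing "! label" comments
    ids <- c(ids, id)
    nms <- c(nms, if (is.na(nm)) id else nm)
    defs <- c(defs, def)
    obs <- c(obs, identical(get1("is_obsolete"), "true"))
    parents[[id]] <- is_a
  }
  if (!length(ids)) stop("no [Term] stanzas found: not a parseable OBO file",
                         call. = FALSE)
  list(terms = tibble::tibble(id = ids, name = nms, definition = defs,
                              obsolete = obs),
       parents = parents)
}

parse_obographs <- function(path) {
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) stop("unparseable obographs JSON: ",
                                           conditionMessage(e), call. = FALSE))
  graphs <- doc$graphs
  if (is.null(graphs) || !length(graphs)) {
    stop("obographs JSON contains no graphs", call. = FALSE)
  }
  gr <- graphs[[1]]
  curie <- function(x) sub("^.*[/#]([A-Za-z0-9]+)_([0-9]+)$", "\\1:\\2", x)
  nodes <- gr$nodes
  ids <- character(0); nms <- character(0); defs <- character(0); obs <- logical(0)
  for (nd in nodes) {
    if (!is.null(nd$type) && !identical(nd$type, "CLASS")) next
    id <- curie(nd$id)
    ids <- c(ids, id)
    nms <- c(nms, if (is.null(nd$lbl)) id else nd$lbl)
    def <- nd$meta$definition$val
    defs <- c(defs, if (is.null(def)) NA_character_ else def)
    dep <- isTRUE(nd$meta$deprecated)
    obs <- c(obs, dep)
  }
  parents <- stats::setNames(vector("list", length(ids)), ids)
  for (ed in gr$edges) {
    if (!identical(ed$pred, "is_a")) next
    child <- curie(ed$sub); parent <- curie(ed$obj)
    if (child %in% ids) parents[[child]] <- c(parents[[child]], parent)
  }
  if (!length(ids)) stop("obographs JSON contains no class nodes", call. = FALSE)
  list(terms = tibble::tibble(id = ids, name = nms, definition = defs,
                              obsolete = obs),
       parents = parents)
}

## ---- DAG queries ---------------------------------------------------------

#' Descendants of a term
#'
#' Transitive closure of a term under the child (`is_a`-inverse) relation.
#' Obsolete terms are excluded from the result.
#'
#' @param ont A `phenotype_ontology`.
#' @param id A term id.
#' @param include_self Include `id` itself in the result?
#' @return Character vector of term ids (sorted, deduplicated).
#' @export
descendants <- function(ont, id, include_self = FALSE) {
  id <- check_term(ont, id)
  # edges run child -> parent, so descendants are vertices that reach `id`
  v <- igraph::subcomponent(ont$graph, id, mode = "in")$name
  if (!include_self) v <- setdiff(v, id)
  sort(setdiff(v, obsolete_ids(ont)))
}

# Ancestors-or-self (internal); follows parent edges.
ancestors <- function(ont, id, include_self = TRUE) {
  id <- check_term(ont, id)
  v <- igraph::subcomponent(ont$graph, id, mode = "out")$name
  if (!include_self) v <- setdiff(v, id)
  v
}

#' Branch membership of a term
#'
#' The branch roots (direct children of the ontology root) that are
#' ancestors-or-self of `id`. A term under several branches of the DAG
#' belongs to each of them; the ontology root itself belongs to none.
#'
#' @inheritParams descendants
#' @return Character vector of branch-root term ids (possibly empty).
#' @export
branch_of <- function(ont, id) {
  id <- check_term(ont, id)
  sort(intersect(ancestors(ont, id, include_self = TRUE), ont$branch_roots))
}

#' Depth of a term
#'
#' Length of the shortest parent-path from `id` to the ontology root; the
#' root has depth 0. Terms that do not reach the root get depth `NA`.
#'
#' @inheritParams descendants
#' @return Non-negative integer (or `NA` for disconnected terms).
#' @export
term_depth <- function(ont, id) {
  id <- check_term(ont, id)
  d <- igraph::distances(ont$graph, v = id, to = ont$root, mode = "out")[, 1]
  out <- as.integer(d)
  out[is.infinite(d)] <- NA_integer_
  unname(out)
}

#' Find terms by name
#'
#' Case-insensitive match of a query against term names. `exact` matches the
#' full name; `substring` matches anywhere in the name. Obsolete terms are
#' never returned.
#'
#' @param ont A `phenotype_ontology`.
#' @param query Non-empty query string.
#' @param mode `"exact"` or `"substring"`.
#' @return Character vector of matching term ids (possibly empty).
#' @export
find_terms <- function(ont, query, mode = c("exact", "substring")) {
  mode <- match.arg(mode)
  if (!nzchar(query)) stop("query must be non-empty", call. = FALSE)
  nm <- tolower(ont$terms$name)
  q <- tolower(query)
  hit <- if (mode == "exact") nm == q else grepl(q, nm, fixed = TRUE)
  sort(ont$terms$id[hit & !ont$terms$obsolete])
}

## ---- benchmark truth sets ------------------------------------------------

#' Default benchmark specification
#'
#' The ontology name queries that define, per clinical characteristic, the
#' branches whose descendants reliably indicate that characteristic (the
#' truth sets used for recall benchmarking). Full term names are matched
#' exactly; lower-case fragments are matched as substrings. Blindness
#' carries exclusion filters so that colour and night blindness, which are
#' not causes of complete blindness, never enter its truth set. Death and
#' congenital onset have no ontology-derived truth set.
#'
#' @return A named list (one element per benchmarked characteristic), each
#'   with `queries` (data frame with columns `query`, `mode`) and
#'   `exclusions` (character vector of substring filters).
#' @export
default_benchmark_spec <- function() {
  q <- function(...) {
    m <- matrix(c(...), ncol = 2, byrow = TRUE)
    data.frame(query = m[, 1], mode = m[, 2], stringsAsFactors = FALSE)
  }
  list(
    intellectual_disability = list(
      queries = q("Intellectual disability", "exact",
                  "Mental deterioration", "exact"),
      exclusions = character(0)),
    impaired_mobility = list(
      queries = q("Gait disturbance", "exact",
                  "Diminished movement", "exact",
                  "mobility", "substring"),
      exclusions = character(0)),
    physical_malformations = list(
      queries = q("malformation", "substring"),
      exclusions = character(0)),
    blindness = list(
      queries = q("blindness", "substring"),
      exclusions = c("color", "colour", "night blindness")),
    sensory_impairments = list(
      queries = q("Abnormality of vision", "exact",
                  "Abnormality of the sense of smell", "exact",
                  "Abnormality of taste sensation", "exact",
                  "Somatic sensory dysfunction", "exact",
                  "Hearing abnormality", "exact"),
      exclusions = character(0)),
    immunodeficiency = list(
      queries = q("Immunodeficiency", "exact",
                  "Impaired antigen-specific response", "exact"),
      exclusions = character(0)),
    cancer = list(
      queries = q("Cancer", "exact",
                  "malignant", "substring",
                  "carcinoma", "substring"),
      exclusions = character(0)),
    reduced_fertility = list(
      queries = q("Decreased fertility", "exact",
                  "Hypogonadism", "exact"),
      exclusions = character(0))
  )
}

validate_benchmark_spec <- function(spec) {
  if (!is.list(spec) || is.null(names(spec)) ||
      !all(names(spec) %in% characteristics())) {
    stop("benchmark spec must be a named list keyed by clinical characteristic",
         call. = FALSE)
  }
  for (ch in names(spec)) {
    el <- spec[[ch]]
    if (!is.data.frame(el$queries) ||
        !all(c("query", "mode") %in% names(el$queries)) ||
        !all(el$queries$mode %in% c("exact", "substring"))) {
      stop("benchmark spec for ", ch,
           ": queries must have columns query and mode (exact|substring)",
           call. = FALSE)
    }
  }
  invisible(spec)
}

#' Build per-characteristic truth sets from an ontology
#'
#' For each characteristic in the benchmark spec, unions the
#' descendants-or-self of every term matched by its queries, then removes
#' terms whose names contain any exclusion substring (case-insensitive).
#'
#' @param ont A `phenotype_ontology`.
#' @param spec A benchmark spec, as from [default_benchmark_spec()].
#' @return Named list: characteristic -> character vector of term ids.
#' @export
build_truth_sets <- function(ont, spec = default_benchmark_spec()) {
  validate_benchmark_spec(spec)
  lapply(spec, function(el) {
    matched <- as.character(unique(unlist(Map(
      function(q, m) find_terms(ont, q, m),
      el$queries$query, el$queries$mode
    ), use.names = FALSE)))
    members <- as.character(unique(unlist(
      lapply(matched, descendants, ont = ont, include_self = TRUE),
      use.names = FALSE
    )))
    if (length(el$exclusions) && length(members)) {
      nm <- tolower(term_name(ont, members))
      drop <- Reduce(`|`, lapply(tolower(el$exclusions),
                                 function(p) grepl(p, nm, fixed = TRUE)),
                     accumulate = FALSE)
      members <- members[!drop]
    }
    sort(members)
  })
}

#' Read / write a benchmark spec as JSON
#'
#' @param path File path.
#' @return `read_benchmark_spec` returns the spec list;
#'   `write_benchmark_spec` returns `path` invisibly.
#' @export
read_benchmark_spec <- function(path) {
  spec <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  spec <- lapply(spec, function(el) {
    list(queries = as.data.frame(el$queries),
         exclusions = as.character(unlist(el$exclusions)))
  })
  validate_benchmark_spec(spec)
  spec
}

#' @rdname read_benchmark_spec
#' @param spec A benchmark spec list.
#' @export
write_benchmark_spec <- function(spec, path) {
  validate_benchmark_spec(spec)
  jsonlite::write_json(spec, path, dataframe = "columns", auto_unbox = FALSE,
                       pretty = TRUE)
  invisible(path)
}
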