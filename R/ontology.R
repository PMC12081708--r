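#' Relation weights for typed ontology edges
#'
#' The hybrid semantic-contribution model propagates weight along the
#' ancestor DAG of a term, attenuating by a factor that depends on the kind
#' of relation an edge carries: `is_a` edges transmit 0.8, `part_of` edges
#' 0.6 and `regulates` edges (including positive/negative regulation,
#' collapsed at load time) 0.7.
#'
#' @param is_a,part_of,regulates attenuation factors, each in (0, 1].
#' @return A named numeric vector of class `relation_weights`.
#' @examples
#' relation_weights()
#' relation_weights(is_a = 0.9)
#' @export
relation_weights <- function(is_a = 0.8, part_of = 0.6, regulates = 0.7) {
  w <- c(is_a = is_a, part_of = part_of, regulates = regulates)
  if (!is.numeric(w) || anyNA(w) || any(w <= 0) || any(w > 1))
    stop("relation weights must lie in (0, 1]", call. = FALSE)
  structure(w, class = c("relation_weights", "numeric"))
}

.RELATION_KINDS <- c("is_a", "part_of", "regulates")

#' Construct an ontology graph from typed child-parent relations
#'
#' @param relations data.frame with columns `child`, `parent`, `relation`
#'   (each relation one of `is_a`, `part_of`, `regulates`; edges point from
#'   the more specific term to the more general one).
#' @param terms optional character vector of term identifiers; terms that
#'   appear in no relation (isolated roots) can only enter through this.
#' @param namespace optional named character vector mapping terms to one of
#'   `"BP"`, `"CC"`, `"MF"`; unnamed terms default to `"BP"`.
#' @return An object of class `ontology_graph` with fields `terms`,
#'   `relations`, `roots` and `namespace`.
#' @export
ontology_graph <- function(relations, terms = NULL, namespace = NULL) {
  relations <- as.data.frame(relations, stringsAsFactors = FALSE)
  if (!all(c("child", "parent", "relation") %in% names(relations)))
    stop("`relations` needs columns child, parent, relation", call. = FALSE)
  relations$child <- as.character(relations$child)
  relations$parent <- as.character(relations$parent)
  relations$relation <- as.character(relations$relation)
  bad <- setdiff(unique(relations$relation), .RELATION_KINDS)
  if (length(bad))
    stop("unsupported relation kind(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  terms <- sort(unique(c(relations$child, relations$parent, terms)))
  if (!length(terms)) stop("ontology has no terms", call. = FALSE)

  relations <- unique(relations[, c("child", "parent", "relation")])
  if (any(relations$child == relations$parent))
    stop("self-relations are not allowed", call. = FALSE)

  if (nrow(relations)) {
    g <- igraph::graph_from_data_frame(
      relations[, c("child", "parent")], directed = TRUE,
      vertices = data.frame(name = terms)
    )
    if (!igraph::is_dag(g))
      stop("ontology relations contain a cycle", call. = FALSE)
  }

  roots <- setdiff(terms, unique(relations$child))
  ns <- rep("BP", length(terms))
  names(ns) <- terms
  if (!is.null(namespace)) {
    namespace <- namespace[intersect(names(namespace), terms)]
    ok <- namespace %in% c("BP", "CC", "MF")
    ns[names(namespace)[ok]] <- namespace[ok]
  }

  # parent adjacency, precomputed once: term -> integer row indices
  parent_index <- split(seq_len(nrow(relations)), relations$child)

  structure(
    list(terms = terms, relations = relations, roots = roots,
         namespace = ns, parent_index = parent_index),
    class = "ontology_graph"
  )
}

#' @export
print.ontology_graph <- function(x, ...) {
  cat("ontology_graph:", length(x$terms), "terms,",
      nrow(x$relations), "relations,", length(x$roots), "root(s)\n")
  invisible(x)
}

#' Parse an OBO-format ontology
#'
#' Reads `[Term]` stanzas from OBO 1.2/1.4 text, keeping `id`, `alt_id`,
#' `namespace`, `is_a` and `relationship` lines. Obsolete terms are dropped,
#' `alt_id`s are remapped to their canonical term, and the regulation
#' variants (`regulates`, `positively_regulates`, `negatively_regulates`)
#' are collapsed onto a single `regulates` relation. Any other relationship
#' kind is ignored with a message reporting the count.
#'
#' @param source path to an OBO file, or a character vector of OBO lines.
#' @return An [ontology_graph()].
#' @export
load_ontology <- function(source) {
  lines <- if (length(source) == 1L && file.exists(source))
    readLines(source, warn = FALSE) else source

  ns_map <- c("biological_process" = "BP", "cellular_component" = "CC",
              "molecular_function" = "MF", BP = "BP", CC = "CC", MF = "MF")

  in_term <- FALSE
  cur <- NULL
  stanzas <- list()
  flush <- function() if (!is.null(cur)) stanzas[[length(stanzas) + 1L]] <<- cur
  for (k in seq_along(lines)) {
    line <- trimws(lines[k])
    if (line == "") next
    if (startsWith(line, "[")) {
      flush(); cur <- NULL
      in_term <- identical(line, "[Term]")
      if (in_term) cur <- list(line = k, id = NA_character_,
                               alt_id = character(), namespace = NA_character_,
                               obsolete = FALSE, edges = list())
      next
    }
    if (!in_term) next
    if (!grepl(":", line, fixed = TRUE))
      stop("malformed OBO line ", k, ": ", line, call. = FALSE)
    key <- sub(":.*$", "", line)
    val <- trimws(sub("^[^:]+:", "", line))
    val <- trimws(sub("!.*$", "", val))   # strip trailing comments
    if (key == "id") {
      if (val == "") stop("malformed OBO stanza at line ", k,
                          ": empty id", call. = FALSE)
      cur$id <- val
    } else if (key == "alt_id") {
      cur$alt_id <- c(cur$alt_id, val)
    } else if (key == "namespace") {
      cur$namespace <- unname(ns_map[val])
    } else if (key == "is_obsolete") {
      cur$obsolete <- identical(val, "true")
    } else if (key == "is_a") {
      cur$edges[[length(cur$edges) + 1L]] <- c("is_a", val)
    } else if (key == "relationship") {
      parts <- strsplit(val, "[[:space:]]+")[[1]]
      if (length(parts) < 2L)
        stop("malformed relationship at line ", k, ": ", line, call. = FALSE)
      kind <- parts[1]
      if (grepl("regulates$", kind)) kind <- "regulates"
      cur$edges[[length(cur$edges) + 1L]] <- c(kind, parts[2])
    }
  }
  flush()

  if (!length(stanzas)) stop("no [Term] stanzas found", call. = FALSE)
  bad <- vapply(stanzas, function(s) is.na(s$id), logical(1))
  if (any(bad))
    stop("[Term] stanza at line ", stanzas[[which(bad)[1]]]$line,
         " has no id", call. = FALSE)

  stanzas <- stanzas[!vapply(stanzas, `[[`, logical(1), "obsolete")]
  if (!length(stanzas)) stop("all terms are obsolete", call. = FALSE)

  ids <- vapply(stanzas, `[[`, character(1), "id")
  alt <- unlist(lapply(stanzas, function(s) {
    if (length(s$alt_id)) stats::setNames(rep(s$id, length(s$alt_id)), s$alt_id)
  }))
  canon <- function(x) ifelse(x %in% names(alt), unname(alt[x]), x)

  rel <- do.call(rbind, lapply(stanzas, function(s) {
    if (!length(s$edges)) return(NULL)
    e <- do.call(rbind, s$edges)
    data.frame(child = s$id, parent = e[, 2], relation = e[, 1],
               stringsAsFactors = FALSE)
  }))
  dropped <- 0L
  if (!is.null(rel)) {
    keep <- rel$relation %in% .RELATION_KINDS
    dropped <- sum(!keep)
    rel <- rel[keep, , drop = FALSE]
    rel$parent <- canon(rel$parent)
  } else {
    rel <- data.frame(child = character(), parent = character(),
                      relation = character(), stringsAsFactors = FALSE)
  }
  if (dropped)
    message("load_ontology: ignored ", dropped,
            " relationship(s) of unsupported kind")

  # parents pointing at terms we dropped as obsolete (or never saw) are cut
  known <- rel$parent %in% ids & rel$child %in% ids
  rel <- rel[known, , drop = FALSE]

  ns <- vapply(stanzas, `[[`, character(1), "namespace")
  names(ns) <- ids
  ns <- ns[!is.na(ns)]

  ontology_graph(rel, terms = ids, namespace = ns)
}

#' Read a simplified TSV ontology (child, relation, parent)
#'
#' @param path tab-separated file with three columns and no header.
#' @return An [ontology_graph()].
#' @export
load_ontology_tsv <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE,
                         col.names = c("child", "relation", "parent"))
  ontology_graph(d[, c("child", "parent", "relation")])
}

#' Ancestor DAG of a term
#'
#' Extracts `DAG_A = (A, T_A, E_A)`: the focus term `A`, the set `T_A` of
#' `A` and all its ancestors reachable through any relation kind, and the
#' relations `E_A` induced among them.
#'
#' @param graph an [ontology_graph()].
#' @param term a term identifier in `graph`.
#' @return Object of class `term_dag` with fields `focus`, `members`,
#'   `edges`.
#' @export
ancestor_dag <- function(graph, term) {
  stopifnot(inherits(graph, "ontology_graph"))
  if (!term %in% graph$terms)
    stop("unknown term: ", term, call. = FALSE)
  members <- character()
  frontier <- term
  while (length(frontier)) {
    members <- c(members, frontier)
    idx <- unlist(graph$parent_index[frontier], use.names = FALSE)
    frontier <- setdiff(unique(graph$relations$parent[idx]), members)
  }
  members <- sort(unique(members))
  e <- graph$relations
  edges <- e[e$child %in% members & e$parent %in% members, , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(focus = term, members = members, edges = edges),
            class = "term_dag")
}

#' Semantic contribution of each ancestor to a focus term
#'
#' The focus term contributes 1; every root of the ontology contributes 0;
#' any other ancestor `t` contributes the maximum, over DAG children `t'` of
#' `t` (i.e. members adjacent to `t` on a path from the focus), of the edge
#' weight times the child's contribution — equivalently, the largest product
#' of relation weights along any path from the focus up to `t`. When the
#' focus itself is a root, the focus clause wins and it scores 1.
#'
#' @param dag a [term_dag][ancestor_dag()].
#' @param weights a [relation_weights()] vector.
#' @return Named numeric vector over `dag$members`, values in `[0, 1]`.
#' @export
semantic_contribution <- function(dag, weights = relation_weights()) {
  stopifnot(inherits(dag, "term_dag"))
  members <- dag$members
  s <- stats::setNames(rep(NA_real_, length(members)), members)
  s[dag$focus] <- 1
  e <- dag$edges
  w <- unname(weights[e$relation])
  # children within the DAG: rows grouped by parent
  kids <- split(seq_len(nrow(e)), e$parent)
  visit <- function(t) {
    if (!is.na(s[t])) return(s[t])
    rows <- kids[[t]]
    # every non-focus member is an ancestor of the focus, so has >= 1 child
    val <- max(w[rows] * vapply(e$child[rows], visit, numeric(1)))
    s[t] <<- val
    val
  }
  for (t in members) visit(t)
  dag_roots <- setdiff(members, e$child)
  s[setdiff(dag_roots, dag$focus)] <- 0
  s
}

#' Semantic value of a term
#'
#' Sum of the semantic contributions over the term's ancestor DAG; at least
#' 1 because the focus always contributes 1.
#'
#' @inheritParams semantic_contribution
#' @export
semantic_value <- function(dag, weights = relation_weights()) {
  sum(semantic_contribution(dag, weights))
}

#' Semantic similarity between two terms
#'
#' `SS(A, B)` is the summed contribution of the shared ancestors (counted
#' from both sides) divided by the sum of the two semantic values. It is
#' symmetric, lies in `[0, 1]`, equals 1 for identical terms and 0 for terms
#' with disjoint ancestor sets (e.g. different aspects).
#'
#' @param dagA,dagB [term_dag][ancestor_dag()]s from the same ontology.
#' @param weights a [relation_weights()] vector.
#' @export
term_similarity <- function(dagA, dagB, weights = relation_weights()) {
  sA <- semantic_contribution(dagA, weights)
  sB <- semantic_contribution(dagB, weights)
  shared <- intersect(dagA$members, dagB$members)
  if (!length(shared)) return(0)
  (sum(sA[shared]) + sum(sB[shared])) / (sum(sA) + sum(sB))
}

#' Memoized term-similarity source
#'
#' DAG extraction dominates the cost of term similarity, so pairwise values
#' are served from a cache keyed by term pair. The cache is bound to one
#' ontology and one weight vector; build a new source if the weights change.
#'
#' @param graph an [ontology_graph()].
#' @param weights a [relation_weights()] vector.
#' @return A function `(a, b) -> SS(a, b)` with class `ss_source`.
#' @export
ss_source <- function(graph, weights = relation_weights()) {
  stopifnot(inherits(graph, "ontology_graph"))
  dags <- new.env(parent = emptyenv())
  contrib <- new.env(parent = emptyenv())
  pair <- new.env(parent = emptyenv())
  get_dag <- function(t) {
    if (is.null(dags[[t]])) dags[[t]] <- ancestor_dag(graph, t)
    dags[[t]]
  }
  get_contrib <- function(t) {
    if (is.null(contrib[[t]]))
      contrib[[t]] <- semantic_contribution(get_dag(t), weights)
    contrib[[t]]
  }
  f <- function(a, b) {
    if (a == b) return(1)
    key <- if (a < b) paste0(a, "\r", b) else paste0(b, "\r", a)
    v <- pair[[key]]
    if (!is.null(v)) return(v)
    sA <- get_contrib(a)
    sB <- get_contrib(b)
    shared <- intersect(names(sA), names(sB))
    v <- if (length(shared))
      (sum(sA[shared]) + sum(sB[shared])) / (sum(sA) + sum(sB)) else 0
    pair[[key]] <- v
    v
  }
  structure(f, class = c("ss_source", "function"))
}

#' Pairwise term-similarity table
#'
#' @param graph an [ontology_graph()].
#' @param terms terms to tabulate (default: all in the ontology).
#' @param weights a [relation_weights()] vector.
#' @return data.frame with columns `termA`, `termB`, `SS` over all unordered
#'   pairs (including self-pairs).
#' @export
term_similarity_table <- function(graph, terms = graph$terms,
                                  weights = relation_weights()) {
  ss <- ss_source(graph, weights)
  terms <- sort(unique(terms))
  idx <- which(upper.tri(diag(length(terms)), diag = TRUE), arr.ind = TRUE)
  data.frame(
    termA = terms[idx[, 1]], termB = terms[idx[, 2]],
    SS = mapply(function(i, j) ss(terms[i], terms[j]), idx[, 1], idx[, 2]),
    stringsAsFactors = FALSE
  )
}

#' Write a term-pair similarity table as TSV (6-decimal SS)
#'
#' @param table output of [term_similarity_table()].
#' @param path destination file.
#' @export
write_ss_table <- function(table, path) {
  out <- table
  out$SS <- sprintf("%.6f", out$SS)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
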