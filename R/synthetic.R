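#' Specification of a planted-complex benchmark
#'
#' Describes a fully synthetic bundle emulating the structure of a curated
#' yeast benchmark: a planted-partition PPI graph, a tree-shaped toy
#' ontology with one branch designated per complex, and protein annotations
#' drawn mostly from the home branch, so that intra-complex functional
#' similarity statistically exceeds inter-complex similarity — the working
#' assumption of the detection algorithm.
#'
#' @param sizes complex sizes (default four complexes of eight proteins).
#' @param p_in probability of an edge between proteins of the same planted
#'   complex (a spanning tree additionally guarantees intra connectivity).
#' @param p_out probability of an edge between complexes; must be below
#'   `p_in`.
#' @param depth ontology depth below the root along each branch.
#' @param branching children per internal ontology term.
#' @param coherence probability that an annotation is drawn from the
#'   complex's home branch rather than a random other branch.
#' @param terms_per_protein annotation draws per protein.
#' @param unannotated_fraction fraction of proteins (rounded count) left
#'   without annotations.
#' @param multiparent if `TRUE`, adds random `part_of` cross-edges so the
#'   ontology is a proper multi-parent DAG rather than a tree.
#' @param seed master seed; all randomness derives from it.
#' @return Object of class `planted_spec`.
#' @export
planted_spec <- function(sizes = rep(8, 4), p_in = 0.6, p_out = 0.02,
                         depth = 3, branching = 3, coherence = 0.9,
                         terms_per_protein = 3, unannotated_fraction = 0,
                         multiparent = FALSE, seed = 1) {
  stopifnot(length(sizes) >= 1, all(sizes >= 1),
            p_out >= 0, p_out < p_in, p_in <= 1,
            coherence >= 0, coherence <= 1,
            depth >= 1, branching >= 1, terms_per_protein >= 1,
            unannotated_fraction >= 0, unannotated_fraction <= 1)
  if (length(sizes) < 2 && coherence < 1)
    stop("need at least two complexes for off-branch annotation draws",
         call. = FALSE)
  structure(list(sizes = as.integer(sizes), p_in = p_in, p_out = p_out,
                 depth = as.integer(depth), branching = as.integer(branching),
                 coherence = coherence,
                 terms_per_protein = as.integer(terms_per_protein),
                 unannotated_fraction = unannotated_fraction,
                 multiparent = isTRUE(multiparent), seed = as.integer(seed)),
            class = "planted_spec")
}

.go_id <- function(i) sprintf("GO:%07d", i)

# balanced K-branch ontology; returns the graph plus per-branch leaf pools
.make_toy_ontology <- function(K, depth, branching, multiparent = FALSE) {
  counter <- 1L
  nxt <- function() { counter <<- counter + 1L; .go_id(counter) }
  root <- .go_id(1L)
  edges <- list()
  leaf_pools <- vector("list", K)
  for (b in seq_len(K)) {
    level <- nxt()
    edges[[length(edges) + 1L]] <-
      data.frame(child = level, parent = root, relation = "is_a")
    frontier <- level
    d <- 1L
    while (d < depth) {
      nxt_frontier <- character()
      for (t in frontier) for (j in seq_len(branching)) {
        id <- nxt()
        edges[[length(edges) + 1L]] <-
          data.frame(child = id, parent = t, relation = "is_a")
        nxt_frontier <- c(nxt_frontier, id)
      }
      frontier <- nxt_frontier
      d <- d + 1L
    }
    leaf_pools[[b]] <- frontier
  }
  rel <- do.call(rbind, edges)
  if (multiparent && K >= 2) {
    # one random part_of cross-edge per branch, leaf -> another branch root
    branch_roots <- rel$child[rel$parent == root]
    for (b in seq_len(K)) {
      leaf <- leaf_pools[[b]][sample.int(length(leaf_pools[[b]]), 1)]
      target <- branch_roots[-b][sample.int(K - 1, 1)]
      rel <- rbind(rel, data.frame(child = leaf, parent = target,
                                   relation = "part_of"))
    }
  }
  list(graph = ontology_graph(rel, terms = root), pools = leaf_pools,
       root = root)
}

#' Generate a planted-complex benchmark bundle
#'
#' Draws the planted-partition network (per-complex spanning tree plus
#' Bernoulli intra edges at `p_in` and inter edges at `p_out`), the toy
#' ontology, coherent annotations, and the reference catalog (= the planted
#' complexes). Deterministic given `spec$seed`.
#'
#' @param spec a [planted_spec()].
#' @return List of class `planted_bundle` with elements `network`,
#'   `catalog`, `ontology`, `annotations`, `spec`.
#' @export
generate_planted <- function(spec) {
  stopifnot(inherits(spec, "planted_spec"))
  .with_seed(spec$seed, {
    K <- length(spec$sizes)
    n <- sum(spec$sizes)
    proteins <- sprintf(paste0("P%0", max(3, nchar(n)), "d"), seq_len(n))
    block <- rep(seq_len(K), spec$sizes)
    members <- split(seq_len(n), block)

    edges <- list()
    for (b in seq_len(K)) {
      v <- members[[b]]
      s <- length(v)
      if (s >= 2) {
        for (i in 2:s)   # random spanning tree: attach to an earlier member
          edges[[length(edges) + 1L]] <- c(v[sample.int(i - 1, 1)], v[i])
        pairs <- utils::combn(v, 2)
        draw <- stats::runif(ncol(pairs)) < spec$p_in
        for (c in which(draw))
          edges[[length(edges) + 1L]] <- pairs[, c]
      }
    }
    if (K >= 2 && spec$p_out > 0) {
      for (b1 in 1:(K - 1)) for (b2 in (b1 + 1):K) {
        grid <- expand.grid(members[[b1]], members[[b2]])
        draw <- stats::runif(nrow(grid)) < spec$p_out
        for (r in which(draw))
          edges[[length(edges) + 1L]] <- c(grid[r, 1], grid[r, 2])
      }
    }
    em <- do.call(rbind, edges)
    network <- ppi_network(cbind(proteins[em[, 1]], proteins[em[, 2]]),
                           proteins = proteins)

    onto <- .make_toy_ontology(K, spec$depth, spec$branching,
                               spec$multiparent)

    sets <- vector("list", n)
    for (i in seq_len(n)) {
      home <- block[i]
      terms <- character(spec$terms_per_protein)
      for (d in seq_len(spec$terms_per_protein)) {
        pool <- if (K == 1 || stats::runif(1) < spec$coherence)
          onto$pools[[home]]
        else {
          other <- if (K == 2) setdiff(1:2, home) else
            setdiff(seq_len(K), home)[sample.int(K - 1, 1)]
          onto$pools[[other]]
        }
        terms[d] <- pool[sample.int(length(pool), 1)]
      }
      sets[[i]] <- sort(unique(terms))
    }
    n_un <- round(spec$unannotated_fraction * n)
    if (n_un > 0)
      for (i in sample.int(n, n_un)) sets[[i]] <- character()
    annotations <- structure(stats::setNames(sets, proteins),
                             class = "annotation_set")

    catalog <- structure(
      stats::setNames(lapply(members, function(v) proteins[v]),
                      paste0("C", seq_len(K))),
      class = "complex_catalog")

    structure(list(network = network, catalog = catalog,
                   ontology = onto$graph, annotations = annotations,
                   spec = spec),
              class = "planted_bundle")
  })
}

#' Write an ontology graph as OBO text
#'
#' Emits one `[Term]` stanza per term with `is_a` and `relationship` lines;
#' round-trips through [load_ontology()].
#'
#' @param graph an [ontology_graph()].
#' @param path destination file.
#' @export
write_obo <- function(graph, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  ns_long <- c(BP = "biological_process", CC = "cellular_component",
               MF = "molecular_function")
  for (t in graph$terms) {
    writeLines("[Term]", con)
    writeLines(paste0("id: ", t), con)
    writeLines(paste0("namespace: ", ns_long[[graph$namespace[[t]]]]), con)
    rows <- graph$relations[graph$relations$child == t, , drop = FALSE]
    if (nrow(rows)) {
      rows <- rows[order(rows$parent), , drop = FALSE]
      for (r in seq_len(nrow(rows))) {
        if (rows$relation[r] == "is_a")
          writeLines(paste0("is_a: ", rows$parent[r]), con)
        else
          writeLines(paste0("relationship: ", rows$relation[r], " ",
                            rows$parent[r]), con)
      }
    }
    writeLines("", con)
  }
  invisible(path)
}

#' Write a two-column annotation TSV (protein, term)
#'
#' @param annotations an [annotation_set][load_annotations()].
#' @param path destination file.
#' @export
write_annotations <- function(annotations, path) {
  prot <- rep(names(annotations), lengths(annotations))
  term <- unlist(annotations, use.names = FALSE)
  writeLines(paste(prot, term, sep = "\t"), path)
  invisible(path)
}

#' Write a planted bundle to disk as plain-text fixtures
#'
#' Creates `edge_list.tsv`, `nodes.txt`, `ontology.obo`, `annotations.tsv`
#' and `catalog.txt` under `directory`; files round-trip losslessly through
#' the package loaders and are byte-identical for identical seeds.
#'
#' @param bundle a [generate_planted()] result.
#' @param directory output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_fixture <- function(bundle, directory) {
  stopifnot(inherits(bundle, "planted_bundle"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  write_edge_list(bundle$network, file.path(directory, "edge_list.tsv"))
  writeLines(bundle$network$proteins, file.path(directory, "nodes.txt"))
  write_obo(bundle$ontology, file.path(directory, "ontology.obo"))
  write_annotations(bundle$annotations,
                    file.path(directory, "annotations.tsv"))
  write_complex_catalog(bundle$catalog, file.path(directory, "catalog.txt"))
  invisible(directory)
}

#' Load a fixture directory written by [write_fixture()]
#'
#' @param directory fixture directory.
#' @return A `planted_bundle`-shaped list (without the generating spec).
#' @export
load_fixture <- function(directory) {
  structure(list(
    network = load_edge_list(file.path(directory, "edge_list.tsv"),
                             node_list = file.path(directory, "nodes.txt")),
    catalog = load_complex_catalog(file.path(directory, "catalog.txt")),
    ontology = load_ontology(file.path(directory, "ontology.obo")),
    annotations = load_annotations(file.path(directory, "annotations.tsv")),
    spec = NULL
  ), class = "planted_bundle")
}
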