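#' Construct an undirected PPI network
#'
#' Edges are stored as lexicographically ordered protein pairs, one row per
#' interaction, deduplicated, self-loops dropped with a warning. Isolated
#' proteins are retained through `proteins`.
#'
#' @param edges two-column character matrix or data.frame of interacting
#'   protein pairs.
#' @param proteins optional identifiers to include even when they occur in
#'   no interaction.
#' @return Object of class `ppi_network` with fields `proteins` (sorted) and
#'   `edges` (m x 2 character matrix, rows sorted).
#' @export
ppi_network <- function(edges, proteins = NULL) {
  edges <- as.matrix(edges)
  if (length(edges) && ncol(edges) != 2)
    stop("`edges` must have two columns", call. = FALSE)
  storage.mode(edges) <- "character"
  if (nrow(edges)) {
    loops <- edges[, 1] == edges[, 2]
    if (any(loops)) {
      warning(sum(loops), " self-loop(s) dropped", call. = FALSE)
      edges <- edges[!loops, , drop = FALSE]
    }
    swap <- edges[, 1] > edges[, 2]
    edges[swap, ] <- edges[swap, 2:1]
    edges <- unique(edges)
    edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  }
  proteins <- sort(unique(c(as.character(edges), as.character(proteins))))
  if (!length(proteins)) stop("network has no proteins", call. = FALSE)
  dimnames(edges) <- NULL
  net <- structure(list(proteins = proteins, edges = edges, nbrs = NULL),
                   class = "ppi_network")
  net$nbrs <- .neighbor_index_build(net)
  net
}

#' @export
print.ppi_network <- function(x, ...) {
  cat("ppi_network:", length(x$proteins), "proteins,",
      nrow(x$edges), "interactions\n")
  invisible(x)
}

#' @export
as.matrix.ppi_network <- function(x, ...) {
  n <- length(x$proteins)
  A <- matrix(0L, n, n, dimnames = list(x$proteins, x$proteins))
  if (nrow(x$edges)) {
    i <- match(x$edges[, 1], x$proteins)
    j <- match(x$edges[, 2], x$proteins)
    A[cbind(i, j)] <- 1L
    A[cbind(j, i)] <- 1L
  }
  A
}

#' Convert a PPI network to an igraph graph
#'
#' @param network a [ppi_network()].
#' @return An undirected [igraph::graph] whose vertex order follows
#'   `network$proteins` (isolated proteins included).
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "ppi_network"))
  igraph::graph_from_data_frame(
    as.data.frame(network$edges, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = network$proteins)
  )
}

# neighbor lists as integer indices into proteins (cached at construction)
.neighbor_index <- function(network) {
  if (!is.null(network$nbrs)) return(network$nbrs)
  .neighbor_index_build(network)
}

.neighbor_index_build <- function(network) {
  n <- length(network$proteins)
  nbrs <- vector("list", n)
  for (k in seq_len(n)) nbrs[[k]] <- integer()
  if (nrow(network$edges)) {
    i <- match(network$edges[, 1], network$proteins)
    j <- match(network$edges[, 2], network$proteins)
    for (k in seq_along(i)) {
      nbrs[[i[k]]] <- c(nbrs[[i[k]]], j[k])
      nbrs[[j[k]]] <- c(nbrs[[j[k]]], i[k])
    }
    nbrs <- lapply(nbrs, sort)
  }
  nbrs
}

#' Read an edge list (two whitespace-separated protein columns)
#'
#' @param source path or character vector of lines.
#' @param node_list optional path (or vector) naming additional proteins,
#'   one per line, so that isolated proteins survive.
#' @return A [ppi_network()].
#' @export
load_edge_list <- function(source, node_list = NULL) {
  lines <- if (length(source) == 1L && file.exists(source))
    readLines(source, warn = FALSE) else source
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(trimws(lines), "[[:space:]]+")
  bad <- which(lengths(fields) != 2L)
  if (length(bad))
    stop("edge-list line ", bad[1], " does not have two fields: ",
         lines[bad[1]], call. = FALSE)
  edges <- do.call(rbind, fields)
  nodes <- NULL
  if (!is.null(node_list)) {
    nodes <- if (length(node_list) == 1L && file.exists(node_list))
      readLines(node_list, warn = FALSE) else node_list
    nodes <- trimws(nodes[nzchar(trimws(nodes))])
  }
  ppi_network(edges, proteins = nodes)
}

#' Write an edge list (bit-stable: ordered pairs, ordered rows)
#'
#' @param network a [ppi_network()].
#' @param path destination file.
#' @export
write_edge_list <- function(network, path) {
  writeLines(paste(network$edges[, 1], network$edges[, 2], sep = "\t"), path)
  invisible(path)
}

#' Basic network statistics
#'
#' @param network a [ppi_network()].
#' @return data.frame with one row: `m` (interactions),
#'   `degree_one_count` (proteins with exactly one interaction) and
#'   `avg_degree` (`2m/n`, interactions per protein).
#' @export
network_stats <- function(network) {
  stopifnot(inherits(network, "ppi_network"))
  n <- length(network$proteins)
  if (n < 1) stop("empty network", call. = FALSE)
  m <- nrow(network$edges)
  deg <- igraph::degree(as_igraph(network))
  data.frame(m = m, degree_one_count = sum(deg == 1), avg_degree = 2 * m / n)
}

#' Intra- and inter-complex degree of a protein
#'
#' Splits a protein's interactions into those staying inside its complex and
#' those leaving it; the two always sum to the protein's degree.
#'
#' @param network a [ppi_network()].
#' @param protein a protein identifier.
#' @param clustering a [clustering][decode()] aligned with
#'   `network$proteins`.
#' @return Named numeric vector `c(intra = , inter = )`.
#' @export
partition_degrees <- function(network, protein, clustering) {
  v <- match(protein, network$proteins)
  if (is.na(v)) stop("unknown protein: ", protein, call. = FALSE)
  m <- clustering$membership
  if (length(m) != length(network$proteins))
    stop("clustering is not aligned with the network", call. = FALSE)
  nb <- .neighbor_index(network)[[v]]
  intra <- sum(m[nb] == m[v])
  c(intra = intra, inter = length(nb) - intra)
}

#' Specification of a network noise treatment
#'
#' @param mode `"add"` (spurious interactions) or `"delete"` (true ones).
#' @param targeting `"random"`, `"high_degree"` (alterations anchored at the
#'   currently highest-degree protein) or `"low_degree"`.
#' @param proportion fraction `p` of the original edge count to alter;
#'   `round(p * m)` edges are added or removed.
#' @param replicates number of replicate networks drawn per treatment.
#' @param seed base random seed; replicate `r` uses `seed + r - 1`.
#' @return Object of class `noise_spec`.
#' @export
noise_spec <- function(mode = c("add", "delete"),
                       targeting = c("random", "high_degree", "low_degree"),
                       proportion, replicates = 10, seed = 1) {
  mode <- match.arg(mode)
  targeting <- match.arg(targeting)
  stopifnot(is.numeric(proportion), proportion >= 0, proportion <= 1,
            replicates >= 1)
  structure(list(mode = mode, targeting = targeting,
                 proportion = proportion, replicates = as.integer(replicates),
                 seed = as.integer(seed)),
            class = "noise_spec")
}

#' Perturb a network by adding or deleting interactions
#'
#' Alters exactly `round(p * m)` edges of the input network and returns a
#' new network over the same protein set (deletions may isolate proteins;
#' they stay in the vertex set so `n` is constant across noise levels).
#' Random targeting draws edges/non-edges uniformly; degree targeting
#' anchors each single alteration at the protein with the currently
#' highest (or lowest) degree, ties broken by identifier order, with
#' degrees re-evaluated after every alteration. The input is never mutated
#' and identical specs (including seed) give byte-identical edge lists.
#'
#' @param network a [ppi_network()].
#' @param spec a [noise_spec()]; `spec$seed` is used directly (replicate
#'   fan-out is done by [perturb_replicates()]).
#' @return A new [ppi_network()].
#' @export
perturb <- function(network, spec) {
  stopifnot(inherits(network, "ppi_network"), inherits(spec, "noise_spec"))
  n <- length(network$proteins)
  m <- nrow(network$edges)
  k <- round(spec$proportion * m)
  if (spec$mode == "delete" && k > m)
    stop("cannot delete ", k, " of ", m, " edges", call. = FALSE)
  if (k == 0) return(network)

  ei <- match(network$edges[, 1], network$proteins)
  ej <- match(network$edges[, 2], network$proteins)
  key <- function(i, j) ifelse(i < j, (i - 1) * n + j, (j - 1) * n + i)
  present <- new.env(parent = emptyenv(), size = m + k)
  for (r in seq_len(m)) assign(as.character(key(ei[r], ej[r])), TRUE,
                               envir = present)
  has_edge <- function(i, j)
    !is.null(get0(as.character(key(i, j)), envir = present))
  deg <- tabulate(c(ei, ej), nbins = n)
  nbrs <- .neighbor_index(network)

  add_one <- function(i, j) {
    assign(as.character(key(i, j)), TRUE, envir = present)
    ei[m + 1] <<- min(i, j); ej[m + 1] <<- max(i, j); m <<- m + 1
    deg[i] <<- deg[i] + 1L; deg[j] <<- deg[j] + 1L
    nbrs[[i]] <<- c(nbrs[[i]], j); nbrs[[j]] <<- c(nbrs[[j]], i)
  }
  del_row <- function(r) {
    i <- ei[r]; j <- ej[r]
    rm(list = as.character(key(i, j)), envir = present)
    ei <<- ei[-r]; ej <<- ej[-r]; m <<- m - 1
    deg[i] <<- deg[i] - 1L; deg[j] <<- deg[j] - 1L
    nbrs[[i]] <<- setdiff(nbrs[[i]], j); nbrs[[j]] <<- setdiff(nbrs[[j]], i)
  }

  run <- function() {
    for (step in seq_len(k)) {
      if (spec$mode == "add") {
        if (m >= n * (n - 1) / 2)
          stop("graph is complete; cannot add an edge", call. = FALSE)
        if (spec$targeting == "random") {
          repeat {
            i <- sample.int(n, 1); j <- sample.int(n, 1)
            if (i != j && !has_edge(i, j)) break
          }
          add_one(i, j)
        } else {
          ord <- if (spec$targeting == "high_degree")
            order(-deg, seq_len(n)) else order(deg, seq_len(n))
          for (v in ord) {
            cand <- setdiff(seq_len(n), c(v, nbrs[[v]]))
            if (length(cand)) {
              add_one(v, cand[sample.int(length(cand), 1)])
              break
            }
          }
        }
      } else {
        if (spec$targeting == "random") {
          del_row(sample.int(m, 1))
        } else {
          dd <- ifelse(deg > 0, deg, NA)   # only proteins that still interact
          v <- if (spec$targeting == "high_degree")
            order(-deg, seq_len(n))[1] else order(dd, seq_len(n))[1]
          u <- nbrs[[v]][sample.int(length(nbrs[[v]]), 1)]
          r <- which((ei == min(v, u)) & (ej == max(v, u)))
          del_row(r)
        }
      }
    }
  }
  .with_seed(spec$seed, run())

  ppi_network(cbind(network$proteins[ei], network$proteins[ej]),
              proteins = network$proteins)
}

#' Draw replicate perturbed networks
#'
#' @param network a [ppi_network()].
#' @param spec a [noise_spec()]; replicate `r` is perturbed with seed
#'   `spec$seed + r - 1`.
#' @return List of `spec$replicates` networks.
#' @export
perturb_replicates <- function(network, spec) {
  lapply(seq_len(spec$replicates), function(r) {
    s <- spec
    s$seed <- spec$seed + r - 1L
    perturb(network, s)
  })
}

# run code under a temporary RNG state; restores the caller's stream
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}
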