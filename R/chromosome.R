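#' Locus-based adjacency chromosomes
#'
#' A candidate clustering is encoded as an integer vector of length `n`:
#' locus `i` (protein `P_i`) holds the index of one of its network
#' neighbours (the allele). The undirected graph whose edges are the
#' locus-allele pairs decomposes into connected components, which are the
#' complexes. Isolated proteins carry a self-referencing sentinel allele and
#' always decode to singletons. Every operator in this file maps feasible
#' chromosomes (allele in N(P_i)) to feasible chromosomes.
#'
#' @param network a [ppi_network()].
#' @return A feasible chromosome: integer vector of class `chromosome`, each
#'   allele drawn uniformly from the locus's neighbours.
#' @export
random_chromosome <- function(network) {
  nbrs <- .neighbor_index(network)
  n <- length(nbrs)
  alleles <- integer(n)
  for (i in seq_len(n)) {
    nb <- nbrs[[i]]
    alleles[i] <- if (length(nb)) nb[sample.int(length(nb), 1)] else i
  }
  structure(alleles, class = "chromosome")
}

.check_feasible <- function(alleles, nbrs) {
  for (i in seq_along(alleles)) {
    a <- alleles[i]
    if (a == i) {
      if (length(nbrs[[i]]))
        stop("infeasible allele at locus ", i,
             ": self-sentinel on a non-isolated protein", call. = FALSE)
    } else if (!a %in% nbrs[[i]]) {
      stop("infeasible allele at locus ", i, call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Decode a chromosome into a clustering
#'
#' The complexes are the connected components of the locus-allele graph.
#'
#' @param chromosome a feasible [chromosome][random_chromosome()].
#' @param network the network the chromosome was built on.
#' @return Object of class `clustering`: `membership` (integer vector,
#'   complexes numbered 1..K in order of their smallest member),
#'   `complexes` (list of integer vectors), `K`, and `proteins`.
#' @export
decode <- function(chromosome, network) {
  nbrs <- .neighbor_index(network)
  alleles <- as.integer(chromosome)
  if (length(alleles) != length(nbrs))
    stop("chromosome length does not match the network", call. = FALSE)
  .check_feasible(alleles, nbrs)
  n <- length(alleles)
  g <- igraph::make_undirected_graph(rbind(seq_len(n), alleles), n = n)
  memb <- igraph::components(g)$membership
  clustering_from_membership(memb, network$proteins)
}

#' Build a clustering object from a membership vector
#'
#' @param membership integer vector assigning each protein to a complex.
#' @param proteins optional protein identifiers, same length.
#' @return A `clustering` (see [decode()]).
#' @export
clustering_from_membership <- function(membership, proteins = NULL) {
  # first-appearance renumbering == numbering by smallest member index
  membership <- as.integer(factor(membership, levels = unique(membership)))
  complexes <- split(seq_along(membership), membership)
  names(complexes) <- NULL
  structure(list(membership = membership, complexes = complexes,
                 K = length(complexes), proteins = proteins),
            class = "clustering")
}

#' @export
print.clustering <- function(x, ...) {
  cat("clustering:", length(x$membership), "proteins in", x$K, "complexes",
      "(sizes:", paste(lengths(x$complexes), collapse = " "), ")\n")
  invisible(x)
}

#' Complexes as protein identifier sets
#'
#' @param clustering a [clustering][decode()] carrying protein names.
#' @return Named-free list of character vectors.
#' @export
as_protein_sets <- function(clustering) {
  stopifnot(inherits(clustering, "clustering"))
  if (is.null(clustering$proteins))
    stop("clustering carries no protein identifiers", call. = FALSE)
  lapply(clustering$complexes, function(idx) clustering$proteins[idx])
}

#' Uniform crossover of two chromosomes
#'
#' With probability `pc` the child takes, gene by gene, the first parent's
#' allele when the per-gene uniform draw is at most 0.5 and the second
#' parent's otherwise; with probability `1 - pc` the child is a copy of the
#' first parent. Both sources are feasible alleles, so the child is
#' feasible by construction.
#'
#' @param parent1,parent2 feasible chromosomes over the same network.
#' @param pc crossover probability (Table-style default 0.8).
#' @return A child [chromosome][random_chromosome()].
#' @export
uniform_crossover <- function(parent1, parent2, pc = 0.8) {
  if (length(parent1) != length(parent2))
    stop("parents come from different networks", call. = FALSE)
  child <- as.integer(parent1)
  if (stats::runif(1) <= pc) {
    chi <- stats::runif(length(child))
    take2 <- chi > 0.5
    child[take2] <- as.integer(parent2)[take2]
  }
  structure(child, class = "chromosome")
}

#' Functional-similarity-based protein translocation (FS-PTO)
#'
#' The guided mutation. The chromosome is decoded once; proteins are then
#' scanned in ascending index order. For each protein the summed functional
#' similarity to its own complex (`F_Intra`) and to every other complex
#' (`F_Inter`) is computed from the current working membership. A protein
#' whose best `F_Inter` strictly exceeds its `F_Intra` is *weak*; if its
#' per-protein uniform draw is at most `pm`, it is reassigned to the
#' arg-max complex. In the genotype the move re-points the protein's allele
#' to its highest-similarity network neighbour inside the target complex;
#' when the target holds no neighbour of the protein the move is skipped, so
#' feasibility is preserved. Membership updates take effect immediately
#' (sequential semantics); the input chromosome is untouched.
#'
#' @param chromosome a feasible [chromosome][random_chromosome()].
#' @param network the underlying [ppi_network()].
#' @param fsm functional similarity matrix aligned with
#'   `network$proteins`.
#' @param pm per-protein mutation probability (default 0.2).
#' @return A new chromosome; attribute `"moves"` is a data.frame logging
#'   each accepted move (`protein`, `from`, `to`, `f_intra`, `f_inter`).
#' @export
fs_pto <- function(chromosome, network, fsm, pm = 0.2) {
  nbrs <- .neighbor_index(network)
  n <- length(nbrs)
  alleles <- as.integer(chromosome)
  cl <- decode(chromosome, network)
  m <- cl$membership
  K <- cl$K
  diag_fs <- diag(unclass(fsm))

  # comp_sums[k, j] = sum of FS between protein j and members of complex k
  comp_sums <- rowsum(unclass(fsm), group = m, reorder = TRUE)
  sizes <- tabulate(m, nbins = K)

  r <- stats::runif(n)
  moves <- list()
  for (j in seq_len(n)) {
    a <- m[j]
    f_intra <- comp_sums[a, j] - diag_fs[j]
    others <- which(sizes > 0)
    others <- others[others != a]
    if (!length(others)) next
    f_inter <- comp_sums[others, j]
    best <- max(f_inter)
    if (!(best > f_intra && r[j] <= pm)) next
    b <- others[which.max(f_inter)]          # first max: smallest complex id
    inside <- intersect(nbrs[[j]], which(m == b))
    if (!length(inside)) next                # no feasible genotype realization
    alleles[j] <- inside[which.max(fsm[j, inside])]
    comp_sums[a, ] <- comp_sums[a, ] - fsm[j, ]
    comp_sums[b, ] <- comp_sums[b, ] + fsm[j, ]
    sizes[a] <- sizes[a] - 1L
    sizes[b] <- sizes[b] + 1L
    m[j] <- b
    moves[[length(moves) + 1L]] <-
      data.frame(protein = j, from = a, to = b,
                 f_intra = f_intra, f_inter = best)
  }
  out <- structure(alleles, class = "chromosome")
  attr(out, "moves") <- if (length(moves)) do.call(rbind, moves) else
    data.frame(protein = integer(), from = integer(), to = integer(),
               f_intra = numeric(), f_inter = numeric())
  out
}
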