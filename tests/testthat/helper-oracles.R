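# Independent brute-force oracles used to cross-check the implementation.

# Max-product path weight from the focus to every ancestor, by exhaustive
# path enumeration over the full relation table; roots forced to 0.
oracle_contribution <- function(graph, focus, weights = relation_weights()) {
  rel <- graph$relations
  best <- stats::setNames(1, focus)
  visit <- function(t, w) {
    rows <- which(rel$child == t)
    for (r in rows) {
      p <- rel$parent[r]
      wp <- w * unname(weights[rel$relation[r]])
      if (!(p %in% names(best)) || wp > best[p]) best[p] <<- wp
      visit(p, wp)
    }
  }
  visit(focus, 1)
  roots <- setdiff(names(best), rel$child)
  best[setdiff(roots, focus)] <- 0
  best
}

# All set partitions of 1..n as membership vectors (restricted growth).
all_partitions <- function(n) {
  res <- list()
  rec <- function(prefix, maxlab) {
    if (length(prefix) == n) {
      res[[length(res) + 1L]] <<- prefix
      return(invisible())
    }
    for (lab in seq_len(maxlab + 1L)) rec(c(prefix, lab), max(maxlab, lab))
  }
  rec(integer(0), 0L)
  res
}

# Naive per-definition evaluation of both objectives, written straight from
# the formulas with explicit loops (no shared code with the package).
oracle_objectives <- function(membership, fsm, eps = 1e-6) {
  n <- length(membership)
  labs <- sort(unique(membership))
  K <- length(labs)
  is_intra <- is_inter <- numeric(n)
  for (v in seq_len(n)) {
    for (u in seq_len(n)) {
      if (u == v) next
      if (membership[u] == membership[v]) is_intra[v] <- is_intra[v] + fsm[v, u]
      else is_inter[v] <- is_inter[v] + fsm[v, u]
    }
  }
  intra_total <- 0
  inter_total <- 0
  for (k in labs) {
    ck <- which(membership == k)
    s <- length(ck)
    v_k <- sum(is_intra[ck])
    r_k <- 0
    for (v in ck) if (is_intra[v] > is_inter[v])
      r_k <- r_k + is_intra[v] / (is_intra[v] + is_inter[v])
    d_k <- 0
    if (s >= 2) {
      pr <- utils::combn(ck, 2)
      for (c in seq_len(ncol(pr)))
        d_k <- d_k + (1 - fsm[pr[1, c], pr[2, c]])
    }
    d_k <- d_k / s
    intra_total <- intra_total + (s^2 - (v_k + r_k)) / s + d_k
    ratio_sum <- 0
    weak <- 0
    for (v in ck) {
      r <- if (is_intra[v] > 0) is_inter[v] / is_intra[v]
      else if (is_inter[v] == 0) 0 else is_inter[v] / eps
      ratio_sum <- ratio_sum + r
      if (is_inter[v] > is_intra[v]) weak <- weak + 1
    }
    inter_total <- inter_total + ratio_sum / s + weak
  }
  c(ics_intra = intra_total, ics_inter = K * inter_total)
}

# Random acyclic toy ontology: term i's parents have smaller index.
random_ontology <- function(n_terms, seed) {
  set.seed(seed)
  terms <- sprintf("T%02d", seq_len(n_terms))
  rel <- NULL
  for (i in 2:n_terms) {
    n_par <- sample.int(min(2, i - 1), 1)
    pars <- sample.int(i - 1, n_par)
    rel <- rbind(rel, data.frame(
      child = terms[i], parent = terms[pars],
      relation = sample(c("is_a", "part_of", "regulates"), n_par,
                        replace = TRUE)))
  }
  ontology_graph(rel)
}

# Random symmetric FS matrix with unit diagonal.
random_fsm <- function(n, seed) {
  set.seed(seed)
  m <- matrix(stats::runif(n * n), n)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  dimnames(m) <- list(sprintf("p%d", 1:n), sprintf("p%d", 1:n))
  m
}

# Small two-block toy used by operator tests: two triangles plus a bridge.
two_triangle_network <- function() {
  ppi_network(rbind(
    c("p1", "p2"), c("p1", "p3"), c("p2", "p3"),
    c("p4", "p5"), c("p4", "p6"), c("p5", "p6"),
    c("p3", "p4")))
}

# Block FS matrix: high similarity within planted blocks, low across.
block_fsm <- function(blocks, hi = 0.8, lo = 0.1) {
  n <- length(blocks)
  m <- matrix(lo, n, n)
  same <- outer(blocks, blocks, "==")
  m[same] <- hi
  diag(m) <- 1
  dimnames(m) <- list(sprintf("p%d", 1:n), sprintf("p%d", 1:n))
  m
}
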