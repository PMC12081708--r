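# Two conflicting semantic objectives over a partition, both minimized:
# intra-complex compactness and inter-complex separation. All per-protein
# quantities are sums of BMA functional similarity (IS_Intra = similarity to
# own complex, IS_Inter = similarity to the rest of the network).

# per-protein intra/inter sums, vectorized over the whole partition
.is_split <- function(membership, fsm) {
  fsm <- unclass(fsm)
  n <- length(membership)
  comp_sums <- rowsum(fsm, group = membership, reorder = TRUE)
  d <- diag(fsm)
  intra <- comp_sums[cbind(membership, seq_len(n))] - d
  inter <- colSums(fsm) - d - intra
  list(intra = intra, inter = inter,
       K = nrow(comp_sums), sizes = tabulate(membership))
}

# ratio with the zero-division conventions: 0/0 -> 0, x/0 -> x/eps
.safe_ratio <- function(num, den, eps = 1e-6) {
  ifelse(den > 0, num / den, ifelse(num == 0, 0, num / eps))
}

#' Per-complex semantic statistics
#'
#' For one complex `C_k`: its size; the semantic volume `V_k` (total
#' intra-complex similarity, summed over members); the high-similarity
#' contribution `R_k` (members whose intra similarity strictly exceeds
#' their inter similarity add `intra / (intra + inter)`); the cohesiveness
#' `D_k` (mean-per-member sum of semantic distances `1 - FS` over unordered
#' member pairs); and the weak-member count (members whose inter-complex
#' similarity strictly exceeds their intra-complex similarity).
#'
#' @param complex the complex, as protein identifiers or indices; must be
#'   one of the clustering's complexes.
#' @param clustering a [clustering][decode()].
#' @param fsm functional similarity matrix aligned with the clustering.
#' @return List with `size`, `volume`, `high_sim_contribution`,
#'   `cohesiveness`, `weak`.
#' @export
complex_stats <- function(complex, clustering, fsm) {
  idx <- .fsm_index(fsm, complex)
  hit <- which(vapply(clustering$complexes,
                      function(c) setequal(c, idx), logical(1)))
  if (!length(hit))
    stop("`complex` is not a complex of the clustering", call. = FALSE)
  is <- .is_split(clustering$membership, fsm)
  v <- sort(idx)
  intra <- is$intra[v]
  inter <- is$inter[v]
  s <- length(v)
  volume <- sum(intra)
  strong <- intra > inter
  r_k <- sum(.safe_ratio(intra[strong], (intra + inter)[strong]))
  d_k <- (choose(s, 2) - volume / 2) / s
  list(size = s, volume = volume, high_sim_contribution = r_k,
       cohesiveness = d_k, weak = sum(inter > intra))
}

#' Intra-complex semantic compactness objective (minimized)
#'
#' Sums, over complexes, `(|C_k|^2 - (V_k + R_k)) / |C_k| + D_k`. Compact,
#' semantically coherent complexes with many high-similarity members score
#' low; an all-singleton partition with zero similarity scores `n`.
#'
#' @param clustering a [clustering][decode()].
#' @param fsm functional similarity matrix aligned with the clustering.
#' @export
ics_intra <- function(clustering, fsm) {
  m <- clustering$membership
  is <- .is_split(m, fsm)
  s <- is$sizes
  volume <- as.numeric(rowsum(is$intra, m, reorder = TRUE))
  strong <- is$intra > is$inter
  rcontrib <- numeric(length(m))
  rcontrib[strong] <- is$intra[strong] / (is$intra + is$inter)[strong]
  r_k <- as.numeric(rowsum(rcontrib, m, reorder = TRUE))
  d_k <- (choose(s, 2) - volume / 2) / s
  sum((s^2 - (volume + r_k)) / s + d_k)
}

#' Inter-complex semantic separation objective (minimized)
#'
#' `K` times the sum, over complexes, of the size-normalized total
#' inter/intra similarity ratio plus the weak-member count. Ratios follow
#' the conventions `0/0 = 0` and `x/0 = x / eps`.
#'
#' @inheritParams ics_intra
#' @param eps finite stand-in denominator for proteins with positive inter
#'   but zero intra similarity.
#' @export
ics_inter <- function(clustering, fsm, eps = 1e-6) {
  m <- clustering$membership
  is <- .is_split(m, fsm)
  if (is$K == 1) return(0)
  ratio <- .safe_ratio(is$inter, is$intra, eps)
  per_k <- as.numeric(rowsum(ratio, m, reorder = TRUE)) / is$sizes
  weak_k <- as.numeric(rowsum(as.numeric(is$inter > is$intra), m,
                              reorder = TRUE))
  is$K * sum(per_k + weak_k)
}

#' Both objectives at once
#'
#' Shares the per-protein intra/inter split between the two objectives, so
#' it is cheaper than calling [ics_intra()] and [ics_inter()] separately.
#'
#' @inheritParams ics_inter
#' @return Named numeric vector `c(ics_intra = , ics_inter = )`.
#' @export
objective_vector <- function(clustering, fsm, eps = 1e-6) {
  m <- clustering$membership
  is <- .is_split(m, fsm)
  s <- is$sizes
  volume <- as.numeric(rowsum(is$intra, m, reorder = TRUE))
  strong <- is$intra > is$inter
  rcontrib <- numeric(length(m))
  rcontrib[strong] <- is$intra[strong] / (is$intra + is$inter)[strong]
  r_k <- as.numeric(rowsum(rcontrib, m, reorder = TRUE))
  d_k <- (choose(s, 2) - volume / 2) / s
  intra_obj <- sum((s^2 - (volume + r_k)) / s + d_k)
  inter_obj <- if (is$K == 1) 0 else {
    ratio <- .safe_ratio(is$inter, is$intra, eps)
    per_k <- as.numeric(rowsum(ratio, m, reorder = TRUE)) / s
    weak_k <- as.numeric(rowsum(as.numeric(is$inter > is$intra), m,
                                reorder = TRUE))
    is$K * sum(per_k + weak_k)
  }
  c(ics_intra = intra_obj, ics_inter = inter_obj)
}
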