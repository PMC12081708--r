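#' Load protein annotations (GAF 2.x or two-column TSV)
#'
#' Builds the per-protein union of annotated terms across the three GO
#' aspects. GAF rows whose qualifier contains `NOT` are skipped, duplicate
#' protein-term pairs are collapsed, and — when an ontology is supplied —
#' annotations to terms absent from it are dropped with a warning (the
#' protein is kept, possibly with an empty term set).
#'
#' @param source path to a GAF 2.x file (lines with >= 15 tab-separated
#'   columns, `!` comments allowed) or a headerless two-column TSV
#'   (`protein<TAB>term`).
#' @param ontology optional [ontology_graph()] used to filter unknown terms.
#' @param gaf_id_column GAF column holding the protein identifier
#'   (default 3, the DB object symbol).
#' @return Named list of class `annotation_set`: protein -> character vector
#'   of term identifiers.
#' @export
load_annotations <- function(source, ontology = NULL, gaf_id_column = 3) {
  lines <- if (length(source) == 1L && file.exists(source))
    readLines(source, warn = FALSE) else source
  lines <- lines[!startsWith(lines, "!") & nzchar(trimws(lines))]
  if (!length(lines)) stop("no usable annotation rows", call. = FALSE)

  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  is_gaf <- stats::median(nf) >= 15

  if (is_gaf) {
    skipped <- 0L
    rows <- lapply(fields, function(f) {
      if (length(f) < 15) { skipped <<- skipped + 1L; return(NULL) }
      if (grepl("\\bNOT\\b", f[4])) return(NULL)
      c(f[gaf_id_column], f[5])
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (skipped) message("load_annotations: skipped ", skipped,
                         " malformed GAF row(s)")
  } else {
    # whitespace-separated two-column table
    fields <- strsplit(trimws(lines), "[[:space:]]+")
    ok <- lengths(fields) == 2L
    if (any(!ok)) message("load_annotations: skipped ", sum(!ok),
                          " malformed row(s)")
    rows <- fields[ok]
  }
  if (!length(rows)) stop("no usable annotation rows", call. = FALSE)

  prot <- vapply(rows, `[`, character(1), 1)
  term <- vapply(rows, `[`, character(1), 2)
  if (!is.null(ontology)) {
    known <- term %in% ontology$terms
    if (any(!known))
      warning(sum(!known), " annotation(s) to terms absent from the ",
              "ontology dropped", call. = FALSE)
    keep_prot <- unique(prot)        # protein survives even if all dropped
    prot <- prot[known]; term <- term[known]
    sets <- lapply(split(term, factor(prot, levels = keep_prot)),
                   function(x) sort(unique(x)))
  } else {
    sets <- lapply(split(term, prot), function(x) sort(unique(x)))
  }
  structure(sets, class = "annotation_set")
}

#' Maximum cross-pair term similarity between two annotation sets
#'
#' @param termsA,termsB character vectors of term identifiers.
#' @param ss a pairwise similarity function, typically an [ss_source()].
#' @return The maximum `SS(A, B)` over all cross pairs, or `NA_real_` when
#'   either set is empty (the undefined-similarity signal; matrix builders
#'   map it to 0).
#' @export
fs_max <- function(termsA, termsB, ss) {
  if (!length(termsA) || !length(termsB)) return(NA_real_)
  best <- 0
  for (a in termsA) for (b in termsB) {
    v <- ss(a, b)
    if (v > best) best <- v
  }
  best
}

#' Best-match-average (BMA) functional similarity
#'
#' Each term of the first protein is matched with its most similar term of
#' the second, and vice versa; the matched similarities are summed and
#' divided by the total number of terms. Symmetric and bounded by the
#' largest cross-pair similarity.
#'
#' @inheritParams fs_max
#' @return BMA score in `[0, 1]`, or `NA_real_` when either set is empty.
#' @export
fs_bma <- function(termsA, termsB, ss) {
  if (!length(termsA) || !length(termsB)) return(NA_real_)
  m <- outer(termsA, termsB, Vectorize(function(a, b) ss(a, b)))
  m <- matrix(m, nrow = length(termsA))
  (sum(apply(m, 1, max)) + sum(apply(m, 2, max))) /
    (length(termsA) + length(termsB))
}

#' Build the protein-by-protein functional similarity matrix
#'
#' Precomputes all pairwise BMA similarities once. Proteins without
#' annotations get all-zero rows and columns, diagonal included — the
#' conservative no-evidence value; annotated proteins have diagonal 1.
#'
#' @param proteins ordered character vector of protein identifiers.
#' @param annotations an [annotation_set][load_annotations()]; proteins
#'   missing from it count as unannotated.
#' @param ontology an [ontology_graph()].
#' @param weights a [relation_weights()] vector.
#' @return Symmetric numeric matrix of class `fs_matrix` with `proteins` as
#'   dimnames, values in `[0, 1]`.
#' @export
build_fs_matrix <- function(proteins, annotations, ontology,
                            weights = relation_weights()) {
  stopifnot(length(proteins) > 0)
  proteins <- as.character(proteins)
  sets <- lapply(proteins, function(p) {
    t <- annotations[[p]]
    if (is.null(t)) character() else intersect(t, ontology$terms)
  })
  ss <- ss_source(ontology, weights)

  # term-level similarity matrix over the terms actually used
  used <- sort(unique(unlist(sets)))
  S <- diag(length(used))
  dimnames(S) <- list(used, used)
  if (length(used) > 1) {
    for (i in seq_len(length(used) - 1L)) for (j in (i + 1L):length(used)) {
      v <- ss(used[i], used[j])
      S[i, j] <- v; S[j, i] <- v
    }
  }

  n <- length(proteins)
  fsm <- matrix(0, n, n, dimnames = list(proteins, proteins))
  annotated <- lengths(sets) > 0
  for (i in seq_len(n)) {
    if (!annotated[i]) next
    fsm[i, i] <- 1
    if (i == n) next
    for (j in (i + 1L):n) {
      if (!annotated[j]) next
      sub <- S[sets[[i]], sets[[j]], drop = FALSE]
      v <- (sum(apply(sub, 1, max)) + sum(apply(sub, 2, max))) /
        (length(sets[[i]]) + length(sets[[j]]))
      fsm[i, j] <- v; fsm[j, i] <- v
    }
  }
  structure(fsm, class = c("fs_matrix", class(fsm)))
}

#' Write / read a functional similarity matrix as TSV
#'
#' The TSV carries a header row of protein identifiers and one labelled row
#' per protein.
#'
#' @param fsm matrix from [build_fs_matrix()].
#' @param path file path.
#' @export
write_fs_matrix <- function(fsm, path) {
  utils::write.table(format(unclass(fsm), digits = 10), path, sep = "\t",
                     quote = FALSE, col.names = NA)
  invisible(path)
}

#' @rdname write_fs_matrix
#' @export
read_fs_matrix <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                   row.names = 1, check.names = FALSE))
  structure(m, class = c("fs_matrix", class(m)))
}

.fsm_index <- function(fsm, id) {
  i <- if (is.character(id)) match(id, rownames(fsm)) else as.integer(id)
  if (anyNA(i) || any(i < 1) || any(i > nrow(fsm)))
    stop("unknown protein: ", paste(id[is.na(i)], collapse = ", "),
         call. = FALSE)
  i
}

#' Summed functional similarity of a protein to its own complex
#'
#' `F_Intra(v, C)`: the sum of BMA similarities between `v` and every other
#' member of its complex (the self term is excluded). A singleton complex
#' scores 0.
#'
#' @param protein a protein identifier (or index into `fsm`).
#' @param complex the protein's complex, as identifiers or indices; must
#'   contain `protein`.
#' @param fsm matrix from [build_fs_matrix()].
#' @export
intra_similarity <- function(protein, complex, fsm) {
  v <- .fsm_index(fsm, protein)
  members <- .fsm_index(fsm, complex)
  if (!v %in% members)
    stop("protein is not a member of the complex", call. = FALSE)
  sum(fsm[v, setdiff(members, v)])
}

#' Summed functional similarity of a protein to all other complexes
#'
#' `F_Inter(v)`: the sum of BMA similarities between `v` and every protein
#' outside its complex. With a single complex this is 0 for every protein.
#'
#' @param protein a protein identifier (or index into `fsm`).
#' @param clustering a [clustering][decode()] whose proteins index `fsm`.
#' @param fsm matrix from [build_fs_matrix()].
#' @export
inter_similarity <- function(protein, clustering, fsm) {
  v <- .fsm_index(fsm, protein)
  m <- clustering$membership
  if (length(m) != nrow(fsm))
    stop("clustering and fs matrix are not index-aligned", call. = FALSE)
  sum(fsm[v, which(m != m[v])])
}
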