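#' Jaccard overlap between two protein sets
#'
#' @param reference,predicted non-empty character vectors of protein
#'   identifiers.
#' @return `|intersection| / |union|` in `[0, 1]`.
#' @export
jaccard <- function(reference, predicted) {
  if (!length(reference) || !length(predicted))
    stop("jaccard needs two non-empty sets", call. = FALSE)
  reference <- unique(reference)
  predicted <- unique(predicted)
  length(intersect(reference, predicted)) /
    length(union(reference, predicted))
}

#' Read / write a complex catalog (one complex per line)
#'
#' MIPS-style files: whitespace-separated protein identifiers, optionally
#' preceded by a complex name and a colon.
#'
#' @param source path or character vector of lines.
#' @return Named list of character vectors, class `complex_catalog`.
#' @export
load_complex_catalog <- function(source) {
  lines <- if (length(source) == 1L && file.exists(source))
    readLines(source, warn = FALSE) else source
  lines <- trimws(lines[nzchar(trimws(lines))])
  if (!length(lines)) stop("empty complex catalog", call. = FALSE)
  nm <- character(length(lines))
  body <- lines
  named <- grepl("^[^[:space:]]+:", lines)
  nm[named] <- sub(":.*$", "", lines[named])
  body[named] <- sub("^[^[:space:]]+:[[:space:]]*", "", lines[named])
  nm[!named] <- paste0("complex_", which(!named))
  sets <- lapply(strsplit(body, "[[:space:]]+"), unique)
  if (any(!lengths(sets))) stop("catalog contains an empty complex",
                                call. = FALSE)
  structure(stats::setNames(sets, nm), class = "complex_catalog")
}

#' @rdname load_complex_catalog
#' @param catalog list of protein sets (named or not).
#' @param path destination file.
#' @param names whether to write `name:` prefixes.
#' @export
write_complex_catalog <- function(catalog, path, names = FALSE) {
  body <- vapply(catalog, paste, character(1), collapse = "\t")
  if (names && !is.null(base::names(catalog)))
    body <- paste0(base::names(catalog), ":\t", body)
  writeLines(body, path)
  invisible(path)
}

#' Score a predicted clustering against a reference catalog
#'
#' A reference complex counts as recovered when some predicted complex
#' overlaps it with Jaccard at least `delta`, and a predicted complex
#' counts as correct when it matches some reference complex the same way
#' (many-to-many: no assignment step). Recall is the recovered fraction of
#' the reference, precision the correct fraction of the prediction, and the
#' F-score their harmonic mean. Reference complexes are first restricted to
#' the analyzed protein universe; complexes emptied by the restriction are
#' dropped with a message.
#'
#' @param predicted a [clustering][decode()] with protein names, or a list
#'   of protein sets.
#' @param benchmark a [complex_catalog][load_complex_catalog()] or list of
#'   protein sets.
#' @param delta Jaccard matching threshold in `(0, 1]` (default 0.2).
#' @param universe proteins of the analyzed network; defaults to the union
#'   of the predicted complexes.
#' @return Object of class `match_report`: the Jaccard matrix
#'   (benchmark x predicted), the matched flags, `recall`, `precision`,
#'   `f_score` and `delta`.
#' @export
evaluate_complexes <- function(predicted, benchmark, delta = 0.2,
                               universe = NULL) {
  stopifnot(delta > 0, delta <= 1)
  if (inherits(predicted, "clustering")) predicted <- as_protein_sets(predicted)
  predicted <- lapply(predicted, unique)
  benchmark <- lapply(benchmark, unique)
  if (is.null(universe)) universe <- unique(unlist(predicted))

  restricted <- lapply(benchmark, intersect, universe)
  emptied <- !lengths(restricted)
  if (any(emptied))
    message("evaluate_complexes: ", sum(emptied),
            " benchmark complex(es) have no protein in the network; dropped")
  restricted <- restricted[!emptied]
  if (!length(restricted))
    stop("no benchmark complex intersects the network", call. = FALSE)

  if (!length(predicted) || !sum(lengths(predicted))) {
    message("evaluate_complexes: empty prediction; precision set to 0")
    return(structure(list(jaccard = matrix(0, length(restricted), 0),
                          matched_benchmark = rep(FALSE, length(restricted)),
                          matched_predicted = logical(0),
                          recall = 0, precision = 0, f_score = 0,
                          delta = delta),
                     class = "match_report"))
  }

  J <- outer(seq_along(restricted), seq_along(predicted),
             Vectorize(function(i, j) jaccard(restricted[[i]], predicted[[j]])))
  J <- matrix(J, nrow = length(restricted))
  matched_b <- apply(J, 1, function(x) any(x >= delta))
  matched_p <- apply(J, 2, function(x) any(x >= delta))
  recall <- mean(matched_b)
  precision <- mean(matched_p)
  f <- if (recall + precision > 0)
    2 * recall * precision / (recall + precision) else 0
  structure(list(jaccard = J, matched_benchmark = matched_b,
                 matched_predicted = matched_p, recall = recall,
                 precision = precision, f_score = f, delta = delta),
            class = "match_report")
}

#' @export
print.match_report <- function(x, ...) {
  cat(sprintf("match_report (delta = %g): recall %.4f, precision %.4f, F %.4f\n",
              x$delta, x$recall, x$precision, x$f_score))
  invisible(x)
}

#' Average match reports over independent runs
#'
#' Recall, precision and F-score are averaged arithmetically; the F-score
#' is the mean of the per-run F-scores, not the harmonic mean of the
#' averaged recall and precision (the two differ on asymmetric inputs).
#'
#' @param reports list of [match_report][evaluate_complexes()]s sharing one
#'   `delta`.
#' @return A `match_report` carrying the averaged scores (no Jaccard
#'   matrix).
#' @export
average_over_runs <- function(reports) {
  stopifnot(length(reports) >= 1)
  deltas <- vapply(reports, `[[`, numeric(1), "delta")
  if (length(unique(deltas)) != 1)
    stop("reports were computed at different delta thresholds", call. = FALSE)
  structure(list(jaccard = NULL,
                 matched_benchmark = NULL, matched_predicted = NULL,
                 recall = mean(vapply(reports, `[[`, numeric(1), "recall")),
                 precision = mean(vapply(reports, `[[`, numeric(1), "precision")),
                 f_score = mean(vapply(reports, `[[`, numeric(1), "f_score")),
                 delta = deltas[1], runs = length(reports)),
            class = "match_report")
}
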