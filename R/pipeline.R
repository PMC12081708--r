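#' Run the detect-then-evaluate experiment with run averaging
#'
#' Runs the evolutionary search `runs` times (run `r` seeded with
#' `seed + r - 1`), selects one clustering per run with
#' [select_solution()], scores it against the benchmark catalog at `delta`,
#' and averages the per-run reports. Deterministic given the master seed.
#'
#' @param network a [ppi_network()].
#' @param benchmark a [complex_catalog][load_complex_catalog()].
#' @param fsm precomputed functional similarity matrix; alternatively pass
#'   `ontology` + `annotations` to build it here.
#' @param ontology,annotations used to build `fsm` when it is `NULL`.
#' @param config a [moead_config()]; `config$runs` is the default number of
#'   runs.
#' @param delta Jaccard matching threshold.
#' @param runs number of independent runs.
#' @param seed master seed.
#' @param weights relation weights for the similarity build.
#' @return List of class `experiment_result`: `per_run` (data.frame with
#'   run, seed, K, recall, precision, f_score), `average` (averaged
#'   [match_report][average_over_runs()]), `reports`, `clusterings`.
#' @export
run_experiment <- function(network, benchmark, fsm = NULL, ontology = NULL,
                           annotations = NULL, config = moead_config(),
                           delta = 0.2, runs = config$runs, seed = 1,
                           weights = relation_weights()) {
  if (is.null(fsm)) {
    if (is.null(ontology) || is.null(annotations))
      stop("supply either `fsm` or both `ontology` and `annotations`",
           call. = FALSE)
    fsm <- build_fs_matrix(network$proteins, annotations, ontology, weights)
  }
  reports <- vector("list", runs)
  clusterings <- vector("list", runs)
  rows <- vector("list", runs)
  for (r in seq_len(runs)) {
    run_seed <- seed + r - 1L
    res <- run_moead(network, fsm, config, seed = run_seed)
    cl <- select_solution(res)
    rep <- evaluate_complexes(cl, benchmark, delta = delta,
                              universe = network$proteins)
    reports[[r]] <- rep
    clusterings[[r]] <- cl
    rows[[r]] <- data.frame(run = r, seed = run_seed, K = cl$K,
                            recall = rep$recall, precision = rep$precision,
                            f_score = rep$f_score)
  }
  structure(list(per_run = do.call(rbind, rows),
                 average = average_over_runs(reports),
                 reports = reports, clusterings = clusterings,
                 delta = delta, seed = seed),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("experiment_result over", nrow(x$per_run), "run(s):\n")
  print(x$per_run, row.names = FALSE)
  cat(sprintf("average: recall %.4f, precision %.4f, F %.4f\n",
              x$average$recall, x$average$precision, x$average$f_score))
  invisible(x)
}

#' Robustness suite over a noise grid
#'
#' For every cell of the (mode x targeting x proportion) grid, draws
#' `replicates` perturbed networks, runs [run_experiment()] on each (the
#' similarity matrix is topology-free and is reused unchanged), and
#' averages recall/precision/F across replicates. Also reports the
#' replicate-averaged network statistics per cell.
#'
#' @param network the clean [ppi_network()].
#' @param benchmark reference catalog.
#' @param fsm functional similarity matrix aligned with the clean network.
#' @param modes,targetings,proportions grid axes (defaults: both modes, all
#'   three targetings, proportions 0.1 to 0.5).
#' @param replicates perturbed networks per cell (study protocol: 10).
#' @param runs_per_replicate evolutionary runs per perturbed network
#'   (desk-scale default 5).
#' @param config a [moead_config()].
#' @param delta Jaccard matching threshold.
#' @param seed master seed; replicate and run seeds derive from it.
#' @return data.frame keyed by (mode, targeting, proportion) with averaged
#'   `m`, `degree_one_count`, `avg_degree`, `recall`, `precision`,
#'   `f_score`.
#' @export
run_robustness <- function(network, benchmark, fsm,
                           modes = c("add", "delete"),
                           targetings = c("random", "high_degree",
                                          "low_degree"),
                           proportions = seq(0.1, 0.5, by = 0.1),
                           replicates = 10, runs_per_replicate = 5,
                           config = moead_config(), delta = 0.2, seed = 1) {
  grid <- expand.grid(mode = modes, targeting = targetings,
                      proportion = proportions, stringsAsFactors = FALSE)
  out <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    spec <- noise_spec(grid$mode[g], grid$targeting[g], grid$proportion[g],
                       replicates = replicates,
                       seed = seed + (g - 1L) * replicates)
    nets <- perturb_replicates(network, spec)
    stats <- do.call(rbind, lapply(nets, network_stats))
    res <- lapply(seq_along(nets), function(r)
      run_experiment(nets[[r]], benchmark, fsm = fsm, config = config,
                     delta = delta, runs = runs_per_replicate,
                     seed = seed + g * 1000L + r))
    avg <- average_over_runs(lapply(res, `[[`, "average"))
    out[[g]] <- data.frame(
      mode = grid$mode[g], targeting = grid$targeting[g],
      proportion = grid$proportion[g],
      m = mean(stats$m), degree_one_count = mean(stats$degree_one_count),
      avg_degree = mean(stats$avg_degree),
      recall = avg$recall, precision = avg$precision, f_score = avg$f_score)
  }
  do.call(rbind, out)
}
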