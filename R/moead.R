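#' Configuration of the decomposition-based evolutionary driver
#'
#' Defaults follow the study protocol: population 100, 100 generations
#' (10,000 offspring evaluations), crossover probability 0.8, mutation
#' probability 0.2, 30 independent runs. The neighbourhood size and
#' scalarization are canonical MOEA/D choices: Tchebycheff decomposition
#' with ideal-point tracking and a mating/replacement neighbourhood of 20
#' subproblems (capped at the population size).
#'
#' @param mu population size (= number of scalar subproblems).
#' @param generations number of generations.
#' @param pc uniform-crossover probability.
#' @param pm FS-PTO per-protein mutation probability.
#' @param neighborhood subproblem neighbourhood size `T`.
#' @param runs independent runs used by the experiment pipeline.
#' @param eps zero-division guard passed to [ics_inter()].
#' @param seed optional default seed for [run_moead()].
#' @return Object of class `moead_config`.
#' @export
moead_config <- function(mu = 100, generations = 100, pc = 0.8, pm = 0.2,
                         neighborhood = 20, runs = 30, eps = 1e-6,
                         seed = NULL) {
  cfg <- list(mu = as.integer(mu), generations = as.integer(generations),
              pc = pc, pm = pm,
              neighborhood = as.integer(min(neighborhood, mu)),
              runs = as.integer(runs), eps = eps, seed = seed)
  if (cfg$mu < 2 || cfg$generations < 1)
    stop("need mu >= 2 and generations >= 1", call. = FALSE)
  if (cfg$pc < 0 || cfg$pc > 1 || cfg$pm < 0 || cfg$pm > 1)
    stop("pc and pm must lie in [0, 1]", call. = FALSE)
  if (cfg$neighborhood < 2)
    stop("neighbourhood size must be at least 2", call. = FALSE)
  structure(cfg, class = "moead_config")
}

# strict Pareto domination for minimization
.dominates <- function(a, b) all(a <= b) && any(a < b)

.archive_update <- function(arch_obj, arch_sol, obj, sol) {
  if (nrow(arch_obj)) {
    dominated_new <- apply(arch_obj, 1, function(x) {
      all(x <= obj) # dominated or duplicate
    })
    if (any(dominated_new)) return(list(obj = arch_obj, sol = arch_sol))
    keep <- !apply(arch_obj, 1, function(x) .dominates(obj, x))
    arch_obj <- arch_obj[keep, , drop = FALSE]
    arch_sol <- arch_sol[keep]
  }
  list(obj = rbind(arch_obj, obj), sol = c(arch_sol, list(sol)))
}

#' Run the GO-informed multi-objective evolutionary search
#'
#' MOEA/D over `mu` Tchebycheff subproblems with uniformly spread
#' two-objective weight vectors and a maintained ideal point. Each
#' generation visits every subproblem once: two parents are drawn from its
#' neighbourhood, recombined by [uniform_crossover()], mutated by
#' [fs_pto()], evaluated on ([ics_intra()], [ics_inter()]), and the
#' offspring replaces any neighbour whose scalarized value it improves. An
#' external archive collects all nondominated solutions encountered.
#' Exactly `mu * generations` offspring evaluations are performed; given a
#' seed the run is fully reproducible.
#'
#' @param network a [ppi_network()].
#' @param fsm functional similarity matrix aligned with
#'   `network$proteins`.
#' @param config a [moead_config()].
#' @param seed integer seed (falls back to `config$seed`; `NULL` continues
#'   the caller's random stream).
#' @return Object of class `moead_result`: `archive_objectives` (matrix
#'   with columns `ics_intra`, `ics_inter`), `archive_chromosomes`,
#'   `network`, `config`, `evaluations`.
#' @export
run_moead <- function(network, fsm, config = moead_config(), seed = NULL) {
  stopifnot(inherits(network, "ppi_network"), inherits(config, "moead_config"))
  if (nrow(fsm) != length(network$proteins))
    stop("network and fs matrix are not index-aligned", call. = FALSE)
  if (is.null(seed)) seed <- config$seed

  .with_seed(seed, {
    mu <- config$mu
    lambda <- cbind(seq(0, 1, length.out = mu), seq(1, 0, length.out = mu))
    dist <- as.matrix(stats::dist(lambda))
    B <- t(apply(dist, 1, function(d) order(d)[seq_len(config$neighborhood)]))

    pop <- replicate(mu, random_chromosome(network), simplify = FALSE)
    obj <- t(vapply(pop, function(ch)
      objective_vector(decode(ch, network), fsm, config$eps), numeric(2)))
    z <- apply(obj, 2, min)

    arch_obj <- matrix(numeric(), 0, 2)
    arch_sol <- list()
    for (i in seq_len(mu)) {
      upd <- .archive_update(arch_obj, arch_sol, obj[i, ], pop[[i]])
      arch_obj <- upd$obj; arch_sol <- upd$sol
    }

    tcheby <- function(f, lam) max(lam * (f - z), na.rm = FALSE)

    evals <- 0L
    for (gen in seq_len(config$generations)) {
      for (i in seq_len(mu)) {
        mates <- B[i, sample.int(config$neighborhood, 2)]
        child <- uniform_crossover(pop[[mates[1]]], pop[[mates[2]]], config$pc)
        child <- fs_pto(child, network, fsm, config$pm)
        attr(child, "moves") <- NULL
        f <- objective_vector(decode(child, network), fsm, config$eps)
        evals <- evals + 1L
        z <- pmin(z, f)
        for (j in B[i, ]) {
          if (tcheby(f, lambda[j, ]) <= tcheby(obj[j, ], lambda[j, ])) {
            pop[[j]] <- child
            obj[j, ] <- f
          }
        }
        upd <- .archive_update(arch_obj, arch_sol, f, child)
        arch_obj <- upd$obj; arch_sol <- upd$sol
      }
    }
    dimnames(arch_obj) <- list(NULL, c("ics_intra", "ics_inter"))
    structure(list(archive_objectives = arch_obj,
                   archive_chromosomes = arch_sol,
                   network = network, config = config, seed = seed,
                   evaluations = evals),
              class = "moead_result")
  })
}

#' @export
print.moead_result <- function(x, ...) {
  cat("moead_result:", nrow(x$archive_objectives),
      "nondominated solutions after", x$evaluations, "evaluations\n")
  invisible(x)
}

#' Pick one clustering from the nondominated archive
#'
#' Knee-point proxy: both objectives are min-max normalized over the
#' archive and the member with the smallest normalized sum is decoded.
#' Ties break lexicographically on the raw objective vector.
#'
#' @param result a [run_moead()] result with a non-empty archive.
#' @return The selected [clustering][decode()].
#' @export
select_solution <- function(result) {
  stopifnot(inherits(result, "moead_result"))
  obj <- result$archive_objectives
  if (!nrow(obj)) stop("empty archive", call. = FALSE)
  rng <- apply(obj, 2, range)
  span <- rng[2, ] - rng[1, ]
  norm <- sweep(obj, 2, rng[1, ])
  norm <- sweep(norm, 2, ifelse(span > 0, span, 1), "/")
  score <- rowSums(norm)
  best <- which(score == min(score))
  if (length(best) > 1)
    best <- best[order(obj[best, 1], obj[best, 2])[1]]
  decode(result$archive_chromosomes[[best]], result$network)
}
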