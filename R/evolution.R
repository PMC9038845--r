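#' Generation configuration
#'
#' Fixes the per-generation composition. In the standard phase with base
#' population `n` (default 100): the `0.4n` best models are recombined
#' into `0.2n` children, the `0.2n` best are mutated into `0.2n`
#' children, the `0.4n` worst are discarded, and `0.6n` fresh random
#' models complete the next generation (`0.2n + 0.2n + 0.6n = n`). In the
#' warm-start phase the population is halved to `0.5n` with `0.2n`
#' recombined, `0.1n` mutated, and the remaining `0.2n` random.
#'
#' @param n Base population size; fractions of `n` must come out integral
#'   and even where pairing demands it (n divisible by 10 suffices).
#' @param phase `"standard"` or `"warm_start"`.
#' @param max_generations Hard cap on generations (default 500).
#' @param window,tol Plateau detection parameters, see [has_plateaued()].
#' @param k_cap Optional fold cap forwarded to [adaptive_k()].
#' @return A `generation_config` with the resolved per-generation counts.
#' @export
generation_config <- function(n = 100L, phase = c("standard", "warm_start"),
                              max_generations = 500L, window = 20L,
                              tol = 1e-4, k_cap = NULL) {
  phase <- match.arg(phase)
  n <- as.integer(n)
  if (n %% 10L != 0L || n < 10L) {
    stop("base population must be a positive multiple of 10")
  }
  counts <- if (phase == "standard") {
    list(pop = n, parents = as.integer(0.4 * n),
         recombined = as.integer(0.2 * n), mutated = as.integer(0.2 * n),
         random = as.integer(0.6 * n))
  } else {
    list(pop = as.integer(0.5 * n), parents = as.integer(0.4 * n),
         recombined = as.integer(0.2 * n), mutated = as.integer(0.1 * n),
         random = as.integer(0.5 * n - 0.3 * n))
  }
  stopifnot(counts$recombined + counts$mutated + counts$random == counts$pop)
  structure(
    c(list(n = n, phase = phase, max_generations = as.integer(max_generations),
           window = as.integer(window), tol = tol, k_cap = k_cap), counts),
    class = "generation_config"
  )
}

#' Rank an evaluated population by fitness
#'
#' Stable ascending sort on BIC (lower is better). Ties are broken by
#' fewer selected features, then by original position. Failed fits carry
#' infinite BIC and therefore always rank last.
#'
#' @param population List of `evaluated_model` objects.
#' @return The population reordered best-first.
#' @export
rank_models <- function(population) {
  bics <- vapply(population, `[[`, numeric(1), "bic")
  nfeat <- vapply(population, function(m) length(m$chromosome$features),
                  numeric(1))
  population[order(bics, nfeat, seq_along(population))]
}

round_half_up <- function(x) floor(x + 0.5)

#' Recombine ranked parents into child chromosomes
#'
#' Parents are paired by rank (1 & 2, 3 & 4, ...). Each pair yields one
#' child whose hyperparameter values are the arithmetic means of the
#' parents' values (integer parameters rounded half-up, then clamped to
#' their range). The child inherits the higher-ranked parent's feature
#' set, so feature sets of the best models are carried forward.
#'
#' @param ranked_parents List of `evaluated_model`, best first, even count.
#' @param space The [search_space()].
#' @return List of `length(ranked_parents) / 2` chromosomes with
#'   provenance `"recombined"`.
#' @export
recombine <- function(ranked_parents, space) {
  np <- length(ranked_parents)
  if (np %% 2L != 0L) stop("parent count must be even")
  lapply(seq_len(np / 2L), function(i) {
    a <- ranked_parents[[2L * i - 1L]]$chromosome
    b <- ranked_parents[[2L * i]]$chromosome
    vals <- vapply(space$hyperparameters, function(hp) {
      v <- (a$hyperparameters[[hp$name]] + b$hyperparameters[[hp$name]]) / 2
      if (hp$integer) v <- round_half_up(v)
      min(max(v, hp$low), hp$high)
    }, numeric(1))
    new_chromosome(vals, a$features, "recombined")
  })
}

#' Mutate top models into child chromosomes
#'
#' One child per input model: every hyperparameter is shifted by plus or
#' minus its configured mutation step (independent random sign per
#' parameter), clamped to its range. The feature set is unchanged.
#'
#' @param top_models List of `evaluated_model` to mutate.
#' @param space The [search_space()].
#' @return List of chromosomes with provenance `"mutated"`.
#' @export
mutate_models <- function(top_models, space) {
  lapply(top_models, function(m) {
    ch <- m$chromosome
    vals <- vapply(space$hyperparameters, function(hp) {
      sign <- if (stats::runif(1) < 0.5) -1 else 1
      v <- ch$hyperparameters[[hp$name]] + sign * hp$shift
      min(max(v, hp$low), hp$high)
    }, numeric(1))
    new_chromosome(vals, ch$features, "mutated")
  })
}

#' Advance the population by one generation
#'
#' Ranks the evaluated population, recombines the top `parents` models,
#' mutates the top `mutated` models, discards the rest, draws `random`
#' fresh chromosomes from the (possibly constrained) pool, and evaluates
#' all new candidates.
#'
#' @param population Evaluated population (size `config$pop`).
#' @param space The [search_space()] to draw fresh chromosomes from.
#' @param config A [generation_config()].
#' @param X,y Training data (full columns; evaluation restricts them).
#' @param handle An [inner_model()] handle.
#' @return The next evaluated population, size `config$pop`, with
#'   provenance composition exactly `recombined/mutated/random`.
#' @export
generation_step <- function(population, space, config, X, y, handle) {
  if (length(population) != config$pop) {
    stop("population size ", length(population), " != configured ", config$pop)
  }
  ranked <- rank_models(population)
  children <- c(
    recombine(ranked[seq_len(config$parents)], space),
    mutate_models(ranked[seq_len(config$mutated)], space),
    lapply(seq_len(config$random), function(i) random_chromosome(space))
  )
  lapply(children, function(ch) {
    evaluate_chromosome(ch, X, y, handle, k_cap = config$k_cap)
  })
}

#' Append a generation's best models to the convergence queue
#'
#' The queue retains, per completed generation, the fitness, chromosome
#' and metrics of the 3 best models; it is what plateau detection
#' monitors.
#'
#' @param queue List of per-generation entries (possibly empty).
#' @param population Evaluated population.
#' @return The queue with one more entry (3 best models, BIC ascending;
#'   fewer with a warning if the population is smaller than 3).
#' @export
update_queue <- function(queue, population) {
  ranked <- rank_models(population)
  take <- min(3L, length(ranked))
  if (take < 3L) warning("population smaller than 3; queue entry truncated")
  entry <- lapply(ranked[seq_len(take)], function(m) {
    list(bic = m$bic, chromosome = m$chromosome, metrics = m$metrics)
  })
  c(queue, list(entry))
}

queue_best_per_generation <- function(queue) {
  vapply(queue, function(entry) entry[[1L]]$bic, numeric(1))
}

#' Plateau (convergence) detection
#'
#' The run has plateaued when the best fitness observed over the whole
#' history improved by less than `tol * |best|` relative to the best
#' observed before the last `window` generations — i.e. the trailing
#' window contributed no meaningful improvement.
#'
#' @param queue The convergence queue (or a numeric vector of
#'   per-generation best fitness values).
#' @param window Trailing window length in generations (>= 2).
#' @param tol Relative improvement threshold.
#' @return `TRUE`/`FALSE`; always `FALSE` until more than `window`
#'   generations have completed.
#' @export
has_plateaued <- function(queue, window = 20L, tol = 1e-4) {
  stopifnot(window >= 2)
  best <- if (is.numeric(queue)) queue else queue_best_per_generation(queue)
  g <- length(best)
  if (g <= window) return(FALSE)
  best_all <- min(best)
  best_before <- min(best[seq_len(g - window)])
  improvement <- best_before - best_all
  improvement < tol * max(abs(best_all), .Machine$double.eps)
}

archive_key <- function(chromosome) {
  paste(
    paste(sort(chromosome$features), collapse = ","),
    paste(signif(chromosome$hyperparameters, 12), collapse = ","),
    sep = "|"
  )
}

update_archive <- function(archive, population, size = 100L) {
  for (m in population) {
    if (!is.finite(m$bic)) next
    key <- archive_key(m$chromosome)
    cur <- archive[[key]]
    if (is.null(cur) || m$bic < cur$bic) archive[[key]] <- m
  }
  if (length(archive) > size) {
    bics <- vapply(archive, `[[`, numeric(1), "bic")
    archive <- archive[order(bics)[seq_len(size)]]
  }
  archive
}

#' Run the standard evolutionary phase to convergence
#'
#' Initializes a random population and iterates [generation_step()] until
#' the fitness plateaus ([has_plateaued()]) or `max_generations` is hit,
#' maintaining the convergence queue, a per-generation best-fitness
#' trace, and an elitist archive of the `archive_size` lowest-BIC
#' distinct models encountered anywhere in the run.
#'
#' @param X,y Training data; `X` a named-column numeric matrix.
#' @param space A [search_space()].
#' @param config A [generation_config()] (standard phase).
#' @param handle An [inner_model()] handle.
#' @param seed Optional integer seed; when given, the whole run is
#'   reproducible.
#' @param archive_size Number of elite models retained (default 100).
#' @param verbose Emit one log line per generation.
#' @return A `run_result`: `queue`, `trace` (best BIC per generation),
#'   `archive` (BIC-ascending list of `evaluated_model`), `population`,
#'   `generations`, `converged`, `config`, `seed`.
#' @export
run_standard_phase <- function(X, y, space, config, handle, seed = NULL,
                               archive_size = 100L, verbose = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(config$phase %in% c("standard", "warm_start"))
  population <- lapply(init_population(space, config$pop), function(ch) {
    evaluate_chromosome(ch, X, y, handle, k_cap = config$k_cap)
  })
  queue <- update_queue(list(), population)
  archive <- update_archive(list(), population, archive_size)
  gen <- 1L
  while (gen < config$max_generations &&
         !has_plateaued(queue, config$window, config$tol)) {
    population <- generation_step(population, space, config, X, y, handle)
    queue <- update_queue(queue, population)
    archive <- update_archive(archive, population, archive_size)
    gen <- gen + 1L
    if (verbose) {
      bics <- vapply(population, `[[`, numeric(1), "bic")
      prov <- table(vapply(population, function(m) m$chromosome$provenance,
                           character(1)))
      message(sprintf("gen %d | best %.4f | median %.4f | %s", gen,
                      min(bics), stats::median(bics[is.finite(bics)]),
                      paste(names(prov), prov, sep = "=", collapse = " ")))
    }
  }
  archive <- archive[order(vapply(archive, `[[`, numeric(1), "bic"))]
  structure(
    list(queue = queue, trace = queue_best_per_generation(queue),
         archive = unname(archive), population = population,
         generations = gen,
         converged = has_plateaued(queue, config$window, config$tol),
         config = config, seed = seed),
    class = "run_result"
  )
}

#' @exportS3Method base::print
print.run_result <- function(x, ...) {
  cat("Evolutionary run:", x$generations, "generations",
      if (x$converged) "(converged)" else "(unconverged)", "\n")
  cat("Best BIC:", format(min(x$trace)), "| archive size:",
      length(x$archive), "\n")
  invisible(x)
}
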