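#' Aggregate per-feature importances over an elite archive
#'
#' For each feature in the pool: the mean of the absolute importance over
#' the archived models that selected it, and 0 for features no archived
#' model selected. Ranking is by importance descending, ties broken by
#' feature name, so the table is deterministic.
#'
#' @param archive Non-empty list of `evaluated_model` (e.g. the best-100
#'   archive of [run_standard_phase()]).
#' @param feature_pool Features to tabulate; defaults to every feature
#'   appearing in the archive.
#' @return Data frame with columns `feature`, `importance`, `rank`,
#'   sorted by rank.
#' @export
aggregate_importance <- function(archive, feature_pool = NULL) {
  if (length(archive) == 0L) stop("archive is empty")
  sums <- counts <- numeric(0)
  for (m in archive) {
    imp <- abs(m$importances)
    for (f in names(imp)) {
      sums[f] <- (if (is.na(sums[f])) 0 else sums[f]) + imp[[f]]
      counts[f] <- (if (is.na(counts[f])) 0 else counts[f]) + 1
    }
  }
  pool <- if (is.null(feature_pool)) sort(names(sums)) else feature_pool
  imp <- vapply(pool, function(f) {
    if (!is.na(counts[f]) && counts[f] > 0) sums[[f]] / counts[[f]] else 0
  }, numeric(1))
  ord <- order(-imp, pool)
  out <- data.frame(feature = pool[ord], importance = unname(imp[ord]),
                    rank = seq_along(pool), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Elbow of a performance-vs-feature-count curve
#'
#' Reduces the points to their upper envelope (best performance per
#' distinct feature count), then returns the feature count whose envelope
#' point lies farthest (perpendicular distance) from the chord joining
#' the envelope's first and last points — the point where marginal gain
#' per added feature collapses. If the envelope is affine (all distances
#' below 1e-9) the smallest feature count is returned.
#'
#' @param points Data frame (or list) with numeric `feature_count` and
#'   `performance` (oriented so larger is better: accuracy for
#'   classification, r-squared for regression).
#' @return Integer elbow feature count.
#' @export
find_elbow <- function(points) {
  fc <- as.numeric(points$feature_count)
  perf <- as.numeric(points$performance)
  stopifnot(length(fc) == length(perf))
  counts <- sort(unique(fc))
  if (length(counts) < 3L) stop("need at least 3 distinct feature counts")
  env <- vapply(counts, function(k) max(perf[fc == k]), numeric(1))
  x1 <- counts[1L]; y1 <- env[1L]
  x2 <- counts[length(counts)]; y2 <- env[length(env)]
  chord <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
  d <- abs((y2 - y1) * counts - (x2 - x1) * env + x2 * y1 - y2 * x1) / chord
  if (max(d) < 1e-9) return(as.integer(counts[1L]))
  as.integer(counts[which.max(d)])
}

#' Build the warm-start feature-constraint plan
#'
#' The base importance threshold is the aggregated importance of the
#' elbow-th ranked feature; the schedule adds 0--4 standard deviations
#' (population denominator, over the nonzero aggregated importances) to
#' it, giving five non-decreasing thresholds at which the feature pool is
#' successively constrained.
#'
#' @param table Importance table from [aggregate_importance()].
#' @param elbow Elbow feature count from [find_elbow()].
#' @return A `warm_start_plan`: `elbow_feature_count`, `base_threshold`,
#'   `sd`, `thresholds` (length 5).
#' @export
make_warm_start_plan <- function(table, elbow) {
  if (elbow > nrow(table)) stop("elbow exceeds the number of ranked features")
  base <- table$importance[table$rank == elbow]
  nz <- table$importance[table$importance > 0]
  sdv <- if (length(nz)) sqrt(mean((nz - mean(nz))^2)) else 0
  if (sdv == 0) warning("zero importance spread: all five thresholds identical")
  structure(
    list(elbow_feature_count = as.integer(elbow), base_threshold = base,
         sd = sdv, thresholds = base + 0:4 * sdv),
    class = "warm_start_plan"
  )
}

#' Run the recursive warm-start phase
#'
#' For each of the plan's five thresholds, constrains the feature pool to
#' features whose aggregated importance meets the threshold (stages with
#' an empty pool are skipped), reruns the evolutionary loop at half
#' population (composition `0.2n` recombined / `0.1n` mutated / `0.2n`
#' random per generation), and returns the stage whose best model has the
#' lowest BIC. Pools across stages are nested by construction.
#'
#' @param X,y Training data.
#' @param space The full [search_space()] (pool and subset bounds are
#'   re-derived per stage).
#' @param table Importance table from [aggregate_importance()].
#' @param plan A [make_warm_start_plan()].
#' @param config A [generation_config()] with `phase = "warm_start"`.
#' @param handle An [inner_model()] handle.
#' @param seed Optional integer seed.
#' @return The winning stage's `run_result`, with `$stage` (1--5),
#'   `$threshold` and `$pool` recorded, plus `$stages` summarising every
#'   stage run.
#' @export
run_warm_start <- function(X, y, space, table, plan, config, handle,
                           seed = NULL) {
  stopifnot(inherits(plan, "warm_start_plan"))
  if (config$phase != "warm_start") stop("config must use the warm_start phase")
  if (!is.null(seed)) set.seed(seed)
  best <- NULL
  stages <- list()
  for (s in seq_along(plan$thresholds)) {
    thr <- plan$thresholds[s]
    pool <- table$feature[table$importance >= thr]
    if (length(pool) == 0L) {
      stages[[s]] <- list(stage = s, threshold = thr, pool_size = 0L,
                          skipped = TRUE)
      next
    }
    stage_space <- search_space(space$hyperparameters, pool,
                               subset_min = space$subset_min,
                               subset_max = min(space$subset_max, length(pool)))
    res <- run_standard_phase(X, y, stage_space, config, handle, seed = NULL)
    res$stage <- s
    res$threshold <- thr
    res$pool <- pool
    stages[[s]] <- list(stage = s, threshold = thr,
                        pool_size = length(pool), skipped = FALSE,
                        best_bic = min(res$trace),
                        generations = res$generations)
    if (is.null(best) || min(res$trace) < min(best$trace)) best <- res
  }
  if (is.null(best)) stop("all warm-start stages had empty feature pools")
  best$stages <- stages
  best
}

#' Full two-phase evolutionary optimization
#'
#' Convenience wrapper: standard phase to plateau, importance
#' aggregation over the elite archive, elbow analysis of performance vs.
#' feature count, warm-start plan, then the five-stage constrained
#' warm-start phase at half population.
#'
#' @param X,y Training data.
#' @param space A [search_space()].
#' @param handle An [inner_model()] handle.
#' @param n Base population size.
#' @param seed Optional integer seed covering both phases.
#' @param warm_start Run the second phase (default `TRUE`).
#' @param ... Further arguments to [generation_config()] (e.g. `window`,
#'   `tol`, `max_generations`, `k_cap`).
#' @return List with `standard` (phase-1 `run_result`), and when the
#'   second phase ran: `importance` table, `elbow`, `plan`, `warm`
#'   (winning stage `run_result`), and `best` — the lowest-BIC evaluated
#'   model over both phases.
#' @export
run_iel <- function(X, y, space, handle, n = 100L, seed = NULL,
                    warm_start = TRUE, ...) {
  if (!is.null(seed)) set.seed(seed)
  cfg <- generation_config(n = n, phase = "standard", ...)
  std <- run_standard_phase(X, y, space, cfg, handle, seed = NULL)
  out <- list(standard = std, best = std$archive[[1L]])
  if (!warm_start) return(out)
  table <- aggregate_importance(std$archive, space$feature_pool)
  metric <- if (handle$task == "classification") "accuracy" else "r2"
  pts <- data.frame(
    feature_count = vapply(std$archive,
                           function(m) length(m$chromosome$features), numeric(1)),
    performance = vapply(std$archive, function(m) m$metrics[[metric]],
                         numeric(1))
  )
  out$importance <- table
  if (length(unique(pts$feature_count)) < 3L) return(out)
  out$elbow <- find_elbow(pts)
  out$plan <- make_warm_start_plan(table, out$elbow)
  wcfg <- generation_config(n = n, phase = "warm_start", ...)
  out$warm <- run_warm_start(X, y, space, table, out$plan, wcfg, handle,
                             seed = NULL)
  cand <- c(list(std$archive[[1L]]), list(out$warm$archive[[1L]]))
  out$best <- cand[[which.min(vapply(cand, `[[`, numeric(1), "bic"))]]
  out
}
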