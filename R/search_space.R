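#' Define a tunable hyperparameter
#'
#' A hyperparameter is described by an inclusive range, a fixed mutation
#' step (the amount by which its value is nudged up or down during the
#' mutation operator), whether it is integer-valued, and the default used
#' by the untuned baseline model.
#'
#' @param name Unique identifier, e.g. `"learning_rate"`.
#' @param low,high Inclusive bounds of the search range (`low < high`).
#' @param shift Mutation step, `0 < shift <= high - low`.
#' @param integer Logical; when `TRUE` the parameter only takes integer
#'   values and is sampled/mutated on the integer grid.
#' @param default Baseline value, must lie in `[low, high]`.
#' @return An object of class `hp_spec`.
#' @export
hp_spec <- function(name, low, high, shift, integer = FALSE, default = low) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!(low < high)) stop("hp_spec '", name, "': low must be < high")
  if (!(shift > 0 && shift <= high - low)) {
    stop("hp_spec '", name, "': shift must be in (0, high - low]")
  }
  if (default < low || default > high) {
    stop("hp_spec '", name, "': default outside [low, high]")
  }
  structure(
    list(name = name, low = low, high = high, shift = shift,
         integer = isTRUE(integer), default = default),
    class = "hp_spec"
  )
}

#' Define the joint hyperparameter / feature search space
#'
#' The space over which candidate solutions ("chromosomes") are drawn: a
#' list of hyperparameter ranges plus a pool of candidate features and
#' bounds on how many features a single model may select.
#'
#' @param hyperparameters List of [hp_spec()] objects with unique names.
#' @param feature_pool Character vector of candidate feature names.
#' @param subset_min,subset_max Bounds on the selected-subset size; the
#'   upper bound is clamped to the pool size.
#' @return An object of class `search_space`.
#' @export
search_space <- function(hyperparameters, feature_pool,
                         subset_min = 1L, subset_max = 50L) {
  stopifnot(length(feature_pool) >= 1L, !anyDuplicated(feature_pool))
  if (!all(vapply(hyperparameters, inherits, logical(1), "hp_spec"))) {
    stop("hyperparameters must be a list of hp_spec objects")
  }
  nms <- vapply(hyperparameters, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("hyperparameter names must be unique")
  names(hyperparameters) <- nms
  subset_min <- as.integer(subset_min)
  subset_max <- min(as.integer(subset_max), length(feature_pool))
  if (subset_min < 1L || subset_min > subset_max) {
    stop("require 1 <= subset_min <= subset_max (after clamping to pool)")
  }
  structure(
    list(hyperparameters = hyperparameters,
         feature_pool = as.character(feature_pool),
         subset_min = subset_min, subset_max = subset_max),
    class = "search_space"
  )
}

#' Built-in search-space profiles for the three inner learners
#'
#' Ships the ranges, mutation shifts and baseline defaults for the three
#' supported model families:
#' \describe{
#'   \item{`"net"`}{Adam-trained feedforward network: learning rate
#'     1e-5--0.01 (shift 1e-4, default 1e-3), beta1 0.9--0.999 (shift
#'     1e-3, default 0.9), beta2 0.9--0.999 (shift 1e-3, default 0.999).}
#'   \item{`"tree"`}{Gradient-boosted trees: maximum depth 2--10 (integer,
#'     shift 1, default 6), node-partition threshold gamma 0--1e-5 (shift
#'     1e-7, default 0), L1 penalty alpha 0.1--0.9 (shift 1e-3, default
#'     0.1; the library default of 0 lies below the tuning range, so the
#'     baseline model is constructed with alpha 0 directly, see
#'     [run_default_baseline()]).}
#'   \item{`"linear"`}{Elastic net: L1 and L2 penalty weights each
#'     0--1 (shift 0.01, default 0.15).}
#' }
#'
#' @param kind One of `"linear"`, `"tree"`, `"net"`.
#' @param feature_pool Candidate feature names.
#' @param subset_min,subset_max Subset-size bounds (default 1--50).
#' @return A [search_space()].
#' @export
builtin_space <- function(kind = c("linear", "tree", "net"), feature_pool,
                          subset_min = 1L, subset_max = 50L) {
  kind <- match.arg(kind)
  hps <- switch(kind,
    net = list(
      hp_spec("learning_rate", 1e-5, 0.01, 1e-4, default = 0.001),
      hp_spec("beta1", 0.9, 0.999, 0.001, default = 0.9),
      hp_spec("beta2", 0.9, 0.999, 0.001, default = 0.999)
    ),
    tree = list(
      hp_spec("max_depth", 2, 10, 1, integer = TRUE, default = 6),
      hp_spec("gamma", 0, 1e-5, 1e-7, default = 0),
      hp_spec("alpha", 0.1, 0.9, 0.001, default = 0.1)
    ),
    linear = list(
      hp_spec("l1", 0, 1, 0.01, default = 0.15),
      hp_spec("l2", 0, 1, 0.01, default = 0.15)
    )
  )
  search_space(hps, feature_pool, subset_min, subset_max)
}

#' Baseline (default-settings) hyperparameter values of a profile
#'
#' @param kind Model family, as in [builtin_space()].
#' @return Named numeric vector of library-default hyperparameter values.
#'   Note the tree booster's default L1 penalty is 0 even though the
#'   tuning range starts at 0.1.
#' @export
default_values <- function(kind = c("linear", "tree", "net")) {
  kind <- match.arg(kind)
  switch(kind,
    net    = c(learning_rate = 0.001, beta1 = 0.9, beta2 = 0.999),
    tree   = c(max_depth = 6, gamma = 0, alpha = 0),
    linear = c(l1 = 0.15, l2 = 0.15)
  )
}

#' Construct a chromosome
#'
#' Bundles a named hyperparameter vector, a feature subset, and a
#' provenance tag (`"random"`, `"recombined"`, `"mutated"`, or
#' `"default"`) into the candidate-solution object used throughout the
#' evolutionary loop.
#'
#' @param values Named numeric vector of hyperparameter values.
#' @param features Character vector of selected feature names.
#' @param provenance How the chromosome was created.
#' @return A `chromosome` object.
#' @export
new_chromosome <- function(values, features, provenance) {
  structure(
    list(hyperparameters = values, features = as.character(features),
         provenance = provenance),
    class = "chromosome"
  )
}

#' Draw one random chromosome from a search space
#'
#' Each hyperparameter is drawn uniformly from its range (uniform over the
#' integer grid when integer-valued). The subset size is drawn uniformly
#' from `[subset_min, min(subset_max, pool size)]` and that many features
#' are sampled from the pool without replacement.
#'
#' @param space A [search_space()].
#' @return A `chromosome`: named hyperparameter values, a feature subset,
#'   and provenance `"random"`.
#' @export
random_chromosome <- function(space) {
  stopifnot(inherits(space, "search_space"))
  if (length(space$feature_pool) == 0L) stop("feature pool is empty")
  vals <- vapply(space$hyperparameters, function(hp) {
    if (hp$integer) {
      grid <- seq.int(ceiling(hp$low), floor(hp$high))
      grid[sample.int(length(grid), 1L)]
    } else {
      stats::runif(1, hp$low, hp$high)
    }
  }, numeric(1))
  hi <- min(space$subset_max, length(space$feature_pool))
  size <- if (space$subset_min >= hi) hi else
    sample(seq.int(space$subset_min, hi), 1L)
  feats <- space$feature_pool[sample.int(length(space$feature_pool), size)]
  new_chromosome(vals, feats, "random")
}

#' Initialize a random population
#'
#' @param space A [search_space()].
#' @param n Population size (>= 1).
#' @return List of `n` independently drawn chromosomes. Duplicates are
#'   permitted (no uniqueness is enforced).
#' @export
init_population <- function(space, n) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("population size must be >= 1")
  lapply(seq_len(n), function(i) random_chromosome(space))
}

validate_chromosome <- function(chromosome, space) {
  stopifnot(inherits(chromosome, "chromosome"))
  for (hp in space$hyperparameters) {
    v <- chromosome$hyperparameters[[hp$name]]
    if (is.null(v) || v < hp$low || v > hp$high) {
      stop("hyperparameter '", hp$name, "' missing or out of range")
    }
  }
  nf <- length(chromosome$features)
  if (nf < 1L || nf > space$subset_max) stop("feature subset size out of bounds")
  if (!all(chromosome$features %in% space$feature_pool)) {
    stop("chromosome uses features outside the pool")
  }
  invisible(TRUE)
}
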