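test_that("ranking sorts by fitness with documented tie-breaks", {
  pool <- paste0("f", 1:20)
  pop <- list(stub_model(3, pool[1:5]), stub_model(1, pool[1:2]),
              stub_model(2, pool[1:3]))
  expect_equal(vapply(rank_models(pop), `[[`, numeric(1), "bic"), c(1, 2, 3))
  # tie on fitness: fewer features first
  tied <- list(stub_model(1, pool[1:10]), stub_model(1, pool[1:3]))
  expect_length(rank_models(tied)[[1]]$chromosome$features, 3)
  # failed fits always last
  mixed <- list(stub_model(Inf, pool[1]), stub_model(5, pool[1:2]))
  expect_equal(rank_models(mixed)[[1]]$bic, 5)
})

test_that("recombination averages paired parents and carries elite features", {
  sp <- builtin_space("net", paste0("f", 1:10))
  p1 <- stub_model(1, c("f1", "f2"),
                   hp = c(learning_rate = 0.002, beta1 = 0.95, beta2 = 0.99))
  p2 <- stub_model(2, c("f3"),
                   hp = c(learning_rate = 0.004, beta1 = 0.91, beta2 = 0.95))
  kids <- recombine(list(p1, p2), sp)
  expect_length(kids, 1)
  expect_equal(unname(kids[[1]]$hyperparameters["learning_rate"]), 0.003)
  expect_equal(kids[[1]]$features, c("f1", "f2"))  # higher-ranked parent
  expect_equal(kids[[1]]$provenance, "recombined")
  # identical parents -> identical child
  kids2 <- recombine(list(p1, p1), sp)
  expect_equal(kids2[[1]]$hyperparameters, p1$chromosome$hyperparameters)
  expect_equal(kids2[[1]]$features, p1$chromosome$features)
  # 40 parents -> 20 children; every child inside its parents' interval
  set.seed(61)
  parents <- rank_models(lapply(1:40, function(i) {
    ch <- random_chromosome(sp)
    stub_model(runif(1), ch$features, hp = ch$hyperparameters)
  }))
  kids40 <- recombine(parents, sp)
  expect_length(kids40, 20)
  for (i in seq_along(kids40)) {
    a <- parents[[2 * i - 1]]$chromosome$hyperparameters
    b <- parents[[2 * i]]$chromosome$hyperparameters
    k <- kids40[[i]]$hyperparameters
    expect_true(all(k >= pmin(a, b) - 1e-12 & k <= pmax(a, b) + 1e-12))
  }
  expect_error(recombine(parents[1:3], sp), "even")
  # integer parameters round half-up
  spt <- builtin_space("tree", paste0("f", 1:10))
  t1 <- stub_model(1, "f1", hp = c(max_depth = 7, gamma = 0, alpha = 0.5))
  t2 <- stub_model(2, "f2", hp = c(max_depth = 8, gamma = 0, alpha = 0.5))
  expect_equal(unname(recombine(list(t1, t2), spt)[[1]]$hyperparameters["max_depth"]), 8)
})

test_that("mutation shifts every parameter by exactly its step, with clamping", {
  sp <- builtin_space("net", paste0("f", 1:10))
  m <- stub_model(1, c("f1", "f4"),
                  hp = c(learning_rate = 0.005, beta1 = 0.95, beta2 = 0.95))
  set.seed(62)
  for (r in 1:20) {
    kid <- mutate_models(list(m), sp)[[1]]
    expect_equal(abs(kid$hyperparameters[["learning_rate"]] - 0.005), 1e-4)
    expect_equal(abs(kid$hyperparameters[["beta1"]] - 0.95), 1e-3)
    expect_equal(kid$features, c("f1", "f4"))
    expect_equal(kid$provenance, "mutated")
  }
  # tree depth 7 moves to 6 or 8
  spt <- builtin_space("tree", paste0("f", 1:10))
  mt <- stub_model(1, "f1", hp = c(max_depth = 7, gamma = 5e-6, alpha = 0.5))
  kids <- replicate(30, mutate_models(list(mt), spt)[[1]]$hyperparameters[["max_depth"]])
  expect_setequal(unique(kids), c(6, 8))
  # upper-bound clamp: learning rate at 0.01 with a + draw stays 0.01
  hi <- stub_model(1, "f1", hp = c(learning_rate = 0.01, beta1 = 0.9, beta2 = 0.9))
  lrs <- replicate(30, mutate_models(list(hi), sp)[[1]]$hyperparameters[["learning_rate"]])
  expect_true(all(lrs <= 0.01))
  expect_true(any(lrs == 0.01))
})

test_that("a standard generation has the exact provenance composition", {
  d <- small_regression(seed = 63, n = 60, p = 8)
  h <- inner_model("linear", "regression")
  sp <- linear_space(colnames(d$X))
  for (n_base in c(10L, 20L)) {
    cfg <- generation_config(n = n_base, phase = "standard", k_cap = 3)
    set.seed(64)
    pop <- lapply(init_population(sp, cfg$pop), function(ch) {
      evaluate_chromosome(ch, d$X, d$y, h, k_cap = 3)
    })
    nxt <- generation_step(pop, sp, cfg, d$X, d$y, h)
    expect_length(nxt, n_base)
    prov <- table(vapply(nxt, function(m) m$chromosome$provenance, character(1)))
    expect_equal(unname(prov["recombined"]), as.integer(0.2 * n_base))
    expect_equal(unname(prov["mutated"]), as.integer(0.2 * n_base))
    expect_equal(unname(prov["random"]), as.integer(0.6 * n_base))
  }
  expect_error(generation_step(list(), generation_config(10), d$X, d$y, h))
})

test_that("a warm-start generation halves the population with its own mix", {
  cfg <- generation_config(n = 100, phase = "warm_start")
  expect_equal(cfg$pop, 50L)
  expect_equal(cfg$recombined, 20L)
  expect_equal(cfg$mutated, 10L)
  expect_equal(cfg$random, 20L)
  d <- small_regression(seed = 65, n = 60, p = 8)
  h <- inner_model("linear", "regression")
  sp <- linear_space(colnames(d$X))
  cfg10 <- generation_config(n = 10, phase = "warm_start", k_cap = 3)
  set.seed(66)
  pop <- lapply(init_population(sp, cfg10$pop), function(ch) {
    evaluate_chromosome(ch, d$X, d$y, h, k_cap = 3)
  })
  nxt <- generation_step(pop, sp, cfg10, d$X, d$y, h)
  expect_length(nxt, 5L)
  prov <- table(vapply(nxt, function(m) m$chromosome$provenance, character(1)))
  expect_equal(as.vector(prov[c("recombined", "mutated", "random")]),
               c(2L, 1L, 2L))
})

test_that("the convergence queue grows by the three best models per generation", {
  pool <- paste0("f", 1:5)
  pop <- lapply(c(4, 2, 7, 1), function(b) stub_model(b, pool[1:2]))
  q <- update_queue(list(), pop)
  expect_length(q, 1)
  expect_equal(vapply(q[[1]], `[[`, numeric(1), "bic"), c(1, 2, 4))
  q <- update_queue(q, pop)
  expect_length(q, 2)
  expect_warning(update_queue(list(), pop[1:2]), "smaller than 3")
})

test_that("plateau detection matches hand-traced sequences", {
  # constant sequence of at least window generations: plateaued
  expect_true(has_plateaued(rep(5, 25), window = 20))
  # strictly improving by 1% per generation: not plateaued
  expect_false(has_plateaued(100 * 0.99^(0:39), window = 20, tol = 1e-4))
  # improving for 30 generations then flat: flips at exactly 30 + window
  seqv <- c(100 - (1:30) * 2, rep(40, 50))
  window <- 10
  flips <- vapply(seq_along(seqv), function(g) {
    has_plateaued(seqv[1:g], window = window)
  }, logical(1))
  expect_equal(which(flips)[1], 30 + window)
  # too few generations: always false
  expect_false(has_plateaued(rep(1, 10), window = 20))
})

test_that("a seeded run conserves population size and archives the true elite", {
  d <- small_regression(seed = 67, n = 80, p = 10, informative = 2)
  h <- inner_model("linear", "regression")
  sp <- linear_space(colnames(d$X))
  cfg <- generation_config(n = 10, window = 4, k_cap = 3, max_generations = 12)
  res <- run_standard_phase(d$X, d$y, sp, cfg, h, seed = 68, archive_size = 15)
  expect_length(res$population, 10)
  expect_length(res$queue, res$generations)
  # running minimum of the trace is non-increasing
  expect_true(all(diff(cummin(res$trace)) <= 0))
  # archive sorted ascending and bounded
  bics <- vapply(res$archive, `[[`, numeric(1), "bic")
  expect_true(!is.unsorted(bics))
  expect_lte(length(res$archive), 15)
  # same seed, same data -> identical result
  res2 <- run_standard_phase(d$X, d$y, sp, cfg, h, seed = 68, archive_size = 15)
  expect_identical(res$trace, res2$trace)
  expect_identical(res$archive[[1]], res2$archive[[1]])
  # hitting the generation cap without plateau flags unconverged
  cfg2 <- generation_config(n = 10, window = 50, k_cap = 3, max_generations = 3)
  res3 <- run_standard_phase(d$X, d$y, sp, cfg2, h, seed = 68)
  expect_false(res3$converged)
  expect_equal(res3$generations, 3L)
})
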