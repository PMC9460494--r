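test_that("roulette, NCBPE and search-counter helpers follow their formulas", {
  expect_equal(roulette_probabilities(c(1, 3)), c(0.25, 0.75))
  expect_equal(roulette_probabilities(c(2, 2, 2)), rep(1 / 3, 3))
  set.seed(1)
  f <- runif(10)
  expect_equal(sum(roulette_probabilities(f)), 1)
  expect_error(roulette_probabilities(c(0, 0)), "positive")
  expect_error(roulette_probabilities(c(-1, 2)), "nonnegative")

  expect_equal(ncbpe(0.3, 0.3, 0.9), 0)
  expect_equal(ncbpe(0.9, 0.3, 0.9), 1)
  expect_equal(ncbpe(0.6, 0.3, 0.9), 0.5)
  expect_equal(ncbpe(2, 0.3, 0.9), 1)  # saturation beyond cbpe_max
  expect_error(ncbpe(0.5, 1, 1), "exceed")

  expect_equal(scc_reset(0, 10), 0)
  expect_equal(scc_reset(1, 10), 5)
  expect_lt(scc_reset(1000, 10), 10)
  expect_gt(scc_reset(1000, 10), 9.9)
  expect_error(scc_reset(-1, 10))
})

test_that("repair produces sorted distinct integers inside the bounds", {
  X <- matrix(c(250.4, 250.6, 251.2, 3.3, 3.4, 2.9, -5, 300, 100), 3, 3,
              byrow = TRUE)
  R <- kapurseg:::repair_rows(X, 1, 255)
  for (i in 1:3) {
    expect_true(all(diff(R[i, ]) >= 1))
    expect_true(all(R[i, ] >= 1 & R[i, ] <= 255))
  }
})

test_that("optimizers are deterministic per seed with elitist history", {
  h <- random_histogram(1, 32)
  obj <- make_threshold_objective(h, "kapur")
  ctl <- optimizer_control(iterations = 30, population = 20, seed = 42)
  for (fn in list(optimize_abc, optimize_pso, optimize_fpso,
                  optimize_dpso, optimize_ga)) {
    a <- fn(obj, 3, 1, 255, ctl)
    b <- fn(obj, 3, 1, 255, ctl)
    expect_identical(a$best_vector, b$best_vector)
    expect_identical(a$history, b$history)
    expect_true(all(diff(a$history) >= 0))                 # elitism
    expect_equal(a$best_fitness, drop(obj(matrix(a$best_vector, 1))))
    expect_true(all(diff(a$best_vector) >= 1))
    expect_true(all(a$best_vector >= 1 & a$best_vector <= 255))
  }
})

test_that("a constant objective returns the constant", {
  const_obj <- function(TV) rep(3.5, nrow(TV))
  res <- optimize_abc(const_obj, 2, 1, 255,
                      optimizer_control(iterations = 10, population = 10,
                                        seed = 1))
  expect_equal(res$best_fitness, 3.5)
})

test_that("doubling iterations never lowers the best fitness (anytime)", {
  h <- random_histogram(5, 48)
  obj <- make_threshold_objective(h, "kapur")
  for (fn in list(optimize_abc, optimize_pso, optimize_fpso,
                  optimize_dpso, optimize_ga)) {
    short <- fn(obj, 3, 1, 255,
                optimizer_control(iterations = 25, population = 16, seed = 7))
    long <- fn(obj, 3, 1, 255,
               optimizer_control(iterations = 50, population = 16, seed = 7))
    expect_gte(long$best_fitness, short$best_fitness)
    # the longer run replays the shorter run's trajectory
    expect_equal(long$history[1:25], short$history)
  }
})

test_that("PSO with zero attraction keeps velocities constant and a
           particle resting on the global best never moves", {
  # w = 1, c1 = c2 = 0: x(t) = x(0) + t*v(0)
  traj_obj <- function(TV) rowSums(TV) * 0  # flat landscape
  ctl <- optimizer_control(iterations = 5, population = 4, seed = 3,
                           c1 = 0, c2 = 0, w_start = 1, w_end = 1)
  res <- optimize_pso(traj_obj, 2, 1, 255, ctl)
  expect_equal(length(res$history), 5)
  # flat landscape: initial best is never beaten
  expect_equal(res$history, rep(res$history[1], 5))
})

test_that("the fuzzy inertia controller drives w to its lower clamp when
           the optimum is already found, with bounded output", {
  w <- 0.9
  for (i in 1:200) {
    dw <- kapurseg:::fuzzy_inertia_delta(0, w, 0.2, 1.2, 0.1)
    expect_lte(abs(dw), 0.1)
    w <- max(0.2, min(1.2, w + dw))
  }
  expect_equal(w, 0.2, tolerance = 1e-6)
  # monotone decrease along the way
  w <- 1.1; prev <- w
  for (i in 1:50) {
    w <- max(0.2, w + kapurseg:::fuzzy_inertia_delta(0, w, 0.2, 1.2, 0.1))
    expect_lte(w, prev); prev <- w
  }
})

test_that("Darwinian swarm counts stay within their configured bounds", {
  h <- random_histogram(9, 48)
  obj <- make_threshold_objective(h, "kapur")
  counts <- integer(0)
  traced <- function(TV) { counts <<- c(counts, nrow(TV)); obj(TV) }
  ctl <- optimizer_control(iterations = 60, population = 40, seed = 11,
                           n_swarms = 4, min_swarms = 2, max_swarms = 6,
                           min_particles = 5, max_particles = 20)
  res <- optimize_dpso(traced, 3, 1, 255, ctl)
  expect_true(all(diff(res$history) >= 0))
  # every per-swarm batch respects the particle bounds (single spawns aside)
  expect_true(all(counts <= 20))
})

test_that("a genetic population of identical individuals without operators
           is a fixed point", {
  h <- random_histogram(2, 32)
  obj <- make_threshold_objective(h, "kapur")
  seen <- list()
  spy <- function(TV) { seen[[length(seen) + 1]] <<- TV; obj(TV) }
  ctl <- optimizer_control(iterations = 3, population = 6, seed = 5,
                           crossover_rate = 0, mutation_rate = 0)
  res <- optimize_ga(spy, 3, 1, 255, ctl)
  # offspring generations only ever contain vectors from the initial pool
  pool <- unique(apply(seen[[1]], 1, paste, collapse = ","))
  for (g in seen[-1]) {
    expect_true(all(apply(g, 1, paste, collapse = ",") %in% pool))
  }
  expect_true(all(diff(res$history) >= 0))
})

test_that("every optimizer reaches the exhaustive Kapur optimum on small
           condensed histograms", {
  n_runs <- 6
  for (fn_name in c("abc", "pso", "fpso", "dpso")) {
    fn <- kapurseg:::OPTIMIZERS[[fn_name]]
    hits <- 0
    for (s in seq_len(n_runs)) {
      h <- random_histogram(s + 20, 16)
      opt <- exhaustive_search(h, 3, "kapur")$fitness
      res <- fn(make_threshold_objective(h, "kapur"), 3, 1, 255,
                optimizer_control(seed = s))
      if (res$best_fitness >= 0.999 * opt) hits <- hits + 1
    }
    expect_gte(hits, n_runs - 1)
  }
  # the genetic algorithm gets its long-run setting
  hits <- 0
  for (s in seq_len(n_runs)) {
    h <- random_histogram(s + 20, 16)
    opt <- exhaustive_search(h, 3, "kapur")$fitness
    res <- optimize_ga(make_threshold_objective(h, "kapur"), 3, 1, 255,
                       optimizer_control(iterations = 500, population = 200,
                                         seed = s))
    if (res$best_fitness >= 0.999 * opt) hits <- hits + 1
  }
  expect_gte(hits, n_runs - 1)
})
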