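# Population metaheuristics maximizing a batch objective over ordered
# integer vectors (thresholds or PTS vertices): artificial bee colony,
# particle swarm (plain, fuzzy-adaptive-inertia, Darwinian multi-swarm)
# and a generational genetic algorithm.
#
# Candidate encoding: unordered real vectors internally, repaired to
# sorted distinct integers inside the bounds at every evaluation, which
# keeps the continuous dynamics smooth while the objective sees a valid
# ordered threshold vector.

#' Optimizer configuration
#'
#' @param iterations number of iterations (default 100, the standard
#'   benchmark setting; the genetic algorithm is conventionally also run
#'   at 500).
#' @param population population size (default 50; 200 for the long
#'   genetic-algorithm setting).
#' @param seed RNG seed; `NULL` uses the current stream.
#' @param c1,c2 PSO cognitive/social acceleration constants.
#' @param w_start,w_end PSO inertia weight, decayed linearly from
#'   `w_start` to `w_end` over `w_decay_iters` iterations. The decay
#'   horizon is fixed (not tied to `iterations`) so that a longer run
#'   replays a shorter one exactly under the same seed.
#' @param w_decay_iters decay horizon in iterations.
#' @param v_clamp_frac velocity clamp as a fraction of the search range.
#' @param limit ABC abandonment limit (attempts without improvement
#'   before a food source is re-scouted).
#' @param n_swarms,min_swarms,max_swarms Darwinian PSO initial/minimum/
#'   maximum swarm counts.
#' @param min_particles,max_particles Darwinian PSO per-swarm size bounds.
#' @param scc_max Darwinian PSO stagnancy threshold (search-counter
#'   ceiling).
#' @param crossover_rate,mutation_rate genetic-algorithm single-point
#'   crossover and per-gene uniform-reset mutation rates.
#' @param fpso_w_min,fpso_w_max inertia clamp for the fuzzy controller.
#' @param fpso_step half-width of the fuzzy controller's output support
#'   (maximum |delta w| per iteration).
#' @return list of class `optimizer_control`.
#' @export
optimizer_control <- function(iterations = 100L, population = 50L,
                              seed = NULL,
                              c1 = 2, c2 = 2,
                              w_start = 0.9, w_end = 0.4,
                              w_decay_iters = 100L,
                              v_clamp_frac = 0.2,
                              limit = 50L,
                              n_swarms = 4L, min_swarms = 2L, max_swarms = 6L,
                              min_particles = 10L, max_particles = 50L,
                              scc_max = 10,
                              crossover_rate = 0.8, mutation_rate = 0.1,
                              fpso_w_min = 0.2, fpso_w_max = 1.2,
                              fpso_step = 0.1) {
  if (iterations < 1) stopf("iterations must be >= 1")
  if (population < 2) stopf("population must be >= 2")
  structure(as.list(environment()), class = "optimizer_control")
}

repair_rows <- function(X, lower, upper) {
  d <- ncol(X)
  R <- round_half_up(X)
  R[R < lower] <- lower
  R[R > upper] <- upper
  if (d > 1) {
    R <- matrix(R[order(row(R), R)], nrow(R), d, byrow = TRUE)  # row-wise sort
    for (j in 2:d) R[, j] <- pmax(R[, j], R[, j - 1] + 1)
    R[, d] <- pmin(R[, d], upper)
    for (j in (d - 1):1) R[, j] <- pmin(R[, j], R[, j + 1] - 1)
  }
  storage.mode(R) <- "integer"
  R
}

init_population <- function(n, dim, lower, upper) {
  matrix(stats::runif(n * dim, lower, upper), n, dim)
}

opt_result <- function(method, best_vector, best_fitness, history,
                       evaluations, seed) {
  structure(list(method = method,
                 best_vector = as.integer(best_vector),
                 best_fitness = best_fitness,
                 history = history,
                 evaluations = evaluations,
                 seed = seed),
            class = "opt_result")
}

#' @export
print.opt_result <- function(x, ...) {
  cat(sprintf("<%s> best fitness %.6f at [%s] (%d evaluations)\n",
              x$method, x$best_fitness,
              paste(x$best_vector, collapse = ", "), x$evaluations))
  invisible(x)
}

#' Roulette (fitness-proportional) selection probabilities
#'
#' `p_i = f_i / sum(f)`. Inputs must be nonnegative with at least one
#' positive entry; callers with possibly negative fitness are expected to
#' shift by the minimum first (the genetic algorithm does).
#'
#' @param fitness nonnegative fitness values.
#' @return probability vector summing to 1.
#' @export
roulette_probabilities <- function(fitness) {
  if (any(fitness < 0)) stopf("fitness values must be nonnegative")
  s <- sum(fitness)
  if (s <= 0) stopf("at least one fitness value must be positive")
  fitness / s
}

#' Normalized current best performance evaluation
#'
#' `(cbpe - cbpe_min) / (cbpe_max - cbpe_min)`, clipped to `[0, 1]`:
#' any solution at or beyond `cbpe_max` saturates at 1. This is the
#' progress input of the fuzzy inertia controller (CBPE is on a
#' minimization scale; the optimizers feed it the negated fitness).
#'
#' @param cbpe current best performance evaluation.
#' @param cbpe_min the true (or best-known) minimum.
#' @param cbpe_max a sub-optimal reference value.
#' @return value in `[0, 1]`.
#' @export
ncbpe <- function(cbpe, cbpe_min, cbpe_max) {
  if (cbpe_max <= cbpe_min) stopf("cbpe_max must exceed cbpe_min")
  clip01((cbpe - cbpe_min) / (cbpe_max - cbpe_min))
}

#' Darwinian search-counter reset value
#'
#' After the `n_kill`-th particle deletion a stagnating swarm's search
#' counter restarts at `scc_max * (1 - 1/(n_kill + 1))`, approaching the
#' stagnancy ceiling from below so repeated punishment accelerates.
#'
#' @param n_kill number of particles deleted so far (>= 0).
#' @param scc_max stagnancy ceiling.
#' @return reset value in `[0, scc_max)`.
#' @export
scc_reset <- function(n_kill, scc_max) {
  if (n_kill < 0) stopf("n_kill must be >= 0")
  scc_max * (1 - 1 / (n_kill + 1))
}

trimf <- function(x, a, b, c) {
  ifelse(x <= a | x >= c, ifelse(x == b, 1, 0),
         ifelse(x <= b,
                if (b > a) (x - a) / (b - a) else 1,
                if (c > b) (c - x) / (c - b) else 1))
}

# Mamdani-style 3x3 controller: inputs NCBPE in [0,1] and the current
# inertia (normalized to its clamp range), output delta-w in
# [-step, step]. Rules: low NCBPE (near the optimum) always shrinks w to
# exploit; high NCBPE with low w grows w to explore, but high w is pulled
# back; medium progress holds w unless it is already high.
fuzzy_inertia_delta <- function(ncbpe_val, w, w_min, w_max, step) {
  memb <- function(x) c(low = trimf(x, 0, 0, 0.5),
                        med = trimf(x, 0, 0.5, 1),
                        high = trimf(x, 0.5, 1, 1))
  a <- memb(clip01(ncbpe_val))
  b <- memb(clip01((w - w_min) / (w_max - w_min)))
  rules <- matrix(c(-1, -1, -1,   # NCBPE low
                     0,  0, -1,   # NCBPE medium
                     1,  0, -1),  # NCBPE high
                  3, 3, byrow = TRUE)
  act <- outer(a, b, pmin)
  step * sum(act * rules) / sum(act)
}

# Shared PSO engine; `adaptive_w = TRUE` gives the fuzzy variant.
pso_engine <- function(objective, dim, lower, upper, control, adaptive_w,
                       method) {
  ctl <- control
  with_opt_seed(ctl$seed, {
    n <- ctl$population
    X <- init_population(n, dim, lower, upper)
    V <- init_population(n, dim, -(upper - lower) * 0.1, (upper - lower) * 0.1)
    vmax <- ctl$v_clamp_frac * (upper - lower)
    F <- objective(repair_rows(X, lower, upper))
    evals <- n
    P <- X; Pf <- F
    g <- which.max(Pf)
    gb_x <- P[g, ]; gb_f <- Pf[g]
    worst0 <- min(F)
    w <- ctl$w_start
    history <- numeric(ctl$iterations)
    for (t in seq_len(ctl$iterations)) {
      if (adaptive_w) {
        w <- min(ctl$fpso_w_max, max(ctl$fpso_w_min, w))
      } else {
        frac <- if (ctl$w_decay_iters > 1) min(1, (t - 1) / (ctl$w_decay_iters - 1)) else 1
        w <- ctl$w_start - (ctl$w_start - ctl$w_end) * frac
      }
      r1 <- matrix(stats::runif(n * dim), n, dim)
      r2 <- matrix(stats::runif(n * dim), n, dim)
      V <- w * V + ctl$c1 * r1 * (P - X) +
        ctl$c2 * r2 * (matrix(gb_x, n, dim, byrow = TRUE) - X)
      V <- pmin(pmax(V, -vmax), vmax)
      X <- pmin(pmax(X + V, lower), upper)
      F <- objective(repair_rows(X, lower, upper))
      evals <- evals + n
      imp <- F > Pf
      P[imp, ] <- X[imp, ]; Pf[imp] <- F[imp]
      iter_best <- max(F)
      g <- which.max(Pf)
      if (Pf[g] > gb_f) { gb_f <- Pf[g]; gb_x <- P[g, ] }
      if (adaptive_w) {
        prog <- if (gb_f > worst0)
          ncbpe(-iter_best, -gb_f, -worst0) else 0
        w <- w + fuzzy_inertia_delta(prog, w, ctl$fpso_w_min,
                                     ctl$fpso_w_max, ctl$fpso_step)
        w <- min(ctl$fpso_w_max, max(ctl$fpso_w_min, w))
      }
      history[t] <- gb_f
    }
    best <- repair_rows(matrix(gb_x, 1), lower, upper)
    opt_result(method, best[1, ], objective(best), history, evals, ctl$seed)
  })
}

#' Particle swarm optimization over ordered integer vectors
#'
#' Velocity update `v = w v + c1 r1 (p_i - x) + c2 r2 (p_g - x)` with a
#' linearly decaying inertia weight, velocity clamping, and repair to
#' sorted distinct integers at evaluation.
#'
#' @param objective batch objective: function(integer matrix, one
#'   candidate per row) -> fitness vector (maximized).
#' @param dim vector length.
#' @param lower,upper inclusive integer bounds.
#' @param control an [optimizer_control()].
#' @return an `opt_result`: `best_vector`, `best_fitness`, per-iteration
#'   `history` (non-decreasing), `evaluations`, `seed`.
#' @export
optimize_pso <- function(objective, dim, lower, upper,
                         control = optimizer_control()) {
  if (dim < 1) stopf("dim must be >= 1")
  pso_engine(objective, dim, lower, upper, control, FALSE, "pso")
}

#' Fuzzy-adaptive-inertia particle swarm optimization
#'
#' PSO whose inertia weight is retuned every iteration by a two-input
#' (normalized progress, current inertia) one-output (inertia change)
#' Mamdani controller with a 3x3 rule base over triangular low/medium/
#' high sets; the inertia is clamped to `[fpso_w_min, fpso_w_max]`.
#' When the swarm sits at the best-known optimum (progress 0) the
#' controller monotonically drives the inertia to its lower clamp.
#'
#' @inheritParams optimize_pso
#' @return an `opt_result`.
#' @export
optimize_fpso <- function(objective, dim, lower, upper,
                          control = optimizer_control()) {
  if (dim < 1) stopf("dim must be >= 1")
  pso_engine(objective, dim, lower, upper, control, TRUE, "fpso")
}

#' Artificial bee colony optimization
#'
#' The colony splits evenly into employed and onlooker bees over
#' `population/2` food sources. Employed bees perturb one coordinate of
#' their source toward a random other source (`x_j + phi (x_j - x_kj)`,
#' `phi ~ U(-1,1)`) with greedy acceptance; onlookers re-sample sources
#' fitness-proportionally and perturb likewise; sources failing to
#' improve for `limit` attempts are abandoned and re-scouted uniformly.
#' The best solution ever evaluated is kept elitistly.
#'
#' @inheritParams optimize_pso
#' @return an `opt_result`.
#' @export
optimize_abc <- function(objective, dim, lower, upper,
                         control = optimizer_control()) {
  if (dim < 1) stopf("dim must be >= 1")
  ctl <- control
  with_opt_seed(ctl$seed, {
    sn <- max(2L, floor(ctl$population / 2))
    X <- init_population(sn, dim, lower, upper)
    F <- objective(repair_rows(X, lower, upper))
    evals <- sn
    trial <- integer(sn)
    g <- which.max(F); gb_x <- X[g, ]; gb_f <- F[g]
    history <- numeric(ctl$iterations)

    perturb <- function(idx) {
      m <- length(idx)
      k <- vapply(idx, function(i) sample(setdiff(seq_len(sn), i), 1L), 1L)
      j <- sample.int(dim, m, replace = TRUE)
      V <- X[idx, , drop = FALSE]
      phi <- stats::runif(m, -1, 1)
      V[cbind(seq_len(m), j)] <- V[cbind(seq_len(m), j)] +
        phi * (V[cbind(seq_len(m), j)] - X[cbind(k, j)])
      pmin(pmax(V, lower), upper)
    }

    for (t in seq_len(ctl$iterations)) {
      # employed phase
      V <- perturb(seq_len(sn))
      Fv <- objective(repair_rows(V, lower, upper)); evals <- evals + sn
      acc <- Fv > F
      X[acc, ] <- V[acc, ]; F[acc] <- Fv[acc]
      trial <- ifelse(acc, 0L, trial + 1L)
      # onlooker phase: fitness-proportional source choice
      shifted <- F - min(F) + 1e-12
      sel <- sample.int(sn, sn, replace = TRUE,
                        prob = roulette_probabilities(shifted))
      V <- perturb(sel)
      Fv <- objective(repair_rows(V, lower, upper)); evals <- evals + sn
      for (m in seq_len(sn)) {
        i <- sel[m]
        if (Fv[m] > F[i]) { X[i, ] <- V[m, ]; F[i] <- Fv[m]; trial[i] <- 0L }
        else trial[i] <- trial[i] + 1L
      }
      # elitist bookkeeping before any abandonment
      g <- which.max(F)
      if (F[g] > gb_f) { gb_f <- F[g]; gb_x <- X[g, ] }
      # scout phase
      burnt <- which(trial > ctl$limit)
      if (length(burnt) > 0) {
        X[burnt, ] <- init_population(length(burnt), dim, lower, upper)
        F[burnt] <- objective(repair_rows(X[burnt, , drop = FALSE],
                                          lower, upper))
        evals <- evals + length(burnt)
        trial[burnt] <- 0L
        g <- which.max(F)
        if (F[g] > gb_f) { gb_f <- F[g]; gb_x <- X[g, ] }
      }
      history[t] <- gb_f
    }
    best <- repair_rows(matrix(gb_x, 1), lower, upper)
    opt_result("abc", best[1, ], objective(best), history, evals, ctl$seed)
  })
}

#' Darwinian (multi-swarm) particle swarm optimization
#'
#' Several PSO swarms evolve in parallel under natural selection: a swarm
#' that improves its best is rewarded with an extra particle; a swarm
#' stagnating past the search-counter ceiling loses its worst particle
#' and its counter restarts per [scc_reset()]; a swarm shrinking below
#' the minimum size is deleted (down to `min_swarms`); and whenever a
#' swarm finds a new global best a fresh swarm spawns with probability
#' `f / NS` (`f ~ U(0,1)`, `NS` = current swarm count) up to
#' `max_swarms`.
#'
#' @inheritParams optimize_pso
#' @return an `opt_result`.
#' @export
optimize_dpso <- function(objective, dim, lower, upper,
                          control = optimizer_control()) {
  if (dim < 1) stopf("dim must be >= 1")
  ctl <- control
  with_opt_seed(ctl$seed, {
    per <- max(ctl$min_particles, floor(ctl$population / ctl$n_swarms))
    vmax <- ctl$v_clamp_frac * (upper - lower)
    evals <- 0L

    new_swarm <- function(n) {
      X <- init_population(n, dim, lower, upper)
      F <- objective(repair_rows(X, lower, upper))
      evals <<- evals + n
      list(X = X,
           V = init_population(n, dim, -(upper - lower) * 0.1,
                               (upper - lower) * 0.1),
           P = X, Pf = F,
           sb_f = max(F), sb_x = X[which.max(F), ],
           scc = 0, n_kill = 0L)
    }

    swarms <- lapply(seq_len(ctl$n_swarms), function(i) new_swarm(per))
    gb_f <- -Inf; gb_x <- NULL
    for (s in swarms) if (s$sb_f > gb_f) { gb_f <- s$sb_f; gb_x <- s$sb_x }
    history <- numeric(ctl$iterations)

    for (t in seq_len(ctl$iterations)) {
      frac <- if (ctl$w_decay_iters > 1) min(1, (t - 1) / (ctl$w_decay_iters - 1)) else 1
      w <- ctl$w_start - (ctl$w_start - ctl$w_end) * frac
      spawned <- list()
      drop_idx <- integer(0)
      for (si in seq_along(swarms)) {
        s <- swarms[[si]]
        n <- nrow(s$X)
        r1 <- matrix(stats::runif(n * dim), n, dim)
        r2 <- matrix(stats::runif(n * dim), n, dim)
        s$V <- w * s$V + ctl$c1 * r1 * (s$P - s$X) +
          ctl$c2 * r2 * (matrix(s$sb_x, n, dim, byrow = TRUE) - s$X)
        s$V <- pmin(pmax(s$V, -vmax), vmax)
        s$X <- pmin(pmax(s$X + s$V, lower), upper)
        F <- objective(repair_rows(s$X, lower, upper))
        evals <- evals + n
        imp <- F > s$Pf
        s$P[imp, ] <- s$X[imp, ]; s$Pf[imp] <- F[imp]
        improved <- max(s$Pf) > s$sb_f
        if (improved) {
          g <- which.max(s$Pf)
          s$sb_f <- s$Pf[g]; s$sb_x <- s$P[g, ]
          s$scc <- 0
          if (nrow(s$X) < ctl$max_particles) {  # reward: spawn a particle
            x <- init_population(1L, dim, lower, upper)
            f <- objective(repair_rows(x, lower, upper)); evals <- evals + 1L
            s$X <- rbind(s$X, x); s$V <- rbind(s$V, 0 * x)
            s$P <- rbind(s$P, x); s$Pf <- c(s$Pf, f)
          }
          if (s$sb_f > gb_f) {
            gb_f <- s$sb_f; gb_x <- s$sb_x
            ns_now <- length(swarms) + length(spawned)
            if (ns_now < ctl$max_swarms &&
                stats::runif(1) < stats::runif(1) / ns_now) {
              spawned <- c(spawned, list(new_swarm(ctl$min_particles)))
            }
          }
        } else {
          s$scc <- s$scc + 1
          if (s$scc > ctl$scc_max) {  # punish: delete the worst particle
            worst <- which.min(s$Pf)
            keep <- setdiff(seq_len(nrow(s$X)), worst)
            s$X <- s$X[keep, , drop = FALSE]
            s$V <- s$V[keep, , drop = FALSE]
            s$P <- s$P[keep, , drop = FALSE]
            s$Pf <- s$Pf[keep]
            s$n_kill <- s$n_kill + 1L
            s$scc <- scc_reset(s$n_kill, ctl$scc_max)
            if (nrow(s$X) < ctl$min_particles) drop_idx <- c(drop_idx, si)
          }
        }
        swarms[[si]] <- s
      }
      if (length(drop_idx) > 0) {
        n_after <- length(swarms) + length(spawned) - length(drop_idx)
        if (n_after >= ctl$min_swarms) {
          swarms <- swarms[-drop_idx]
        } else {
          # cannot drop below the swarm floor: re-seed the dying swarms
          for (si in drop_idx) swarms[[si]] <- new_swarm(per)
        }
      }
      swarms <- c(swarms, spawned)
      history[t] <- gb_f
    }
    best <- repair_rows(matrix(gb_x, 1), lower, upper)
    opt_result("dpso", best[1, ], objective(best), history, evals, ctl$seed)
  })
}

#' Genetic-algorithm optimization
#'
#' Generational GA with roulette selection on (min-shifted) fitness,
#' single-point crossover on the sorted vector, per-gene uniform-reset
#' mutation, elitism of one, and sort/clip/dedupe repair of offspring.
#'
#' @inheritParams optimize_pso
#' @return an `opt_result`.
#' @export
optimize_ga <- function(objective, dim, lower, upper,
                        control = optimizer_control()) {
  if (dim < 1) stopf("dim must be >= 1")
  ctl <- control
  with_opt_seed(ctl$seed, {
    n <- ctl$population
    X <- repair_rows(init_population(n, dim, lower, upper), lower, upper)
    F <- objective(X)
    evals <- n
    g <- which.max(F); gb_x <- X[g, ]; gb_f <- F[g]
    history <- numeric(ctl$iterations)
    for (t in seq_len(ctl$iterations)) {
      shifted <- F - min(F)
      prob <- if (sum(shifted) > 0) roulette_probabilities(shifted)
              else rep(1 / n, n)
      kids <- matrix(0, n - 1L, dim)
      for (m in seq_len(n - 1L)) {
        pa <- sample.int(n, 2L, replace = TRUE, prob = prob)
        child <- X[pa[1], ]
        if (dim > 1 && stats::runif(1) < ctl$crossover_rate) {
          cut <- sample.int(dim - 1L, 1L)
          child <- c(X[pa[1], seq_len(cut)], X[pa[2], (cut + 1):dim])
        }
        mut <- stats::runif(dim) < ctl$mutation_rate
        if (any(mut))
          child[mut] <- stats::runif(sum(mut), lower, upper)
        kids[m, ] <- child
      }
      kids <- repair_rows(kids, lower, upper)
      Fk <- objective(kids)
      evals <- evals + n - 1L
      X <- rbind(matrix(gb_x, 1), kids)   # elitism of 1
      F <- c(gb_f, Fk)
      g <- which.max(F)
      if (F[g] > gb_f) { gb_f <- F[g]; gb_x <- X[g, ] }
      history[t] <- gb_f
    }
    best <- repair_rows(matrix(gb_x, 1), lower, upper)
    opt_result("ga", best[1, ], objective(best), history, evals, ctl$seed)
  })
}

OPTIMIZERS <- list(abc = optimize_abc, pso = optimize_pso,
                   fpso = optimize_fpso, dpso = optimize_dpso,
                   ga = optimize_ga)
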