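#' Genetic-algorithm configuration
#'
#' Hyperparameters of the constrained GA that searches the open 2-simplex for
#' the minimal-amplitude weight tern.  Defaults follow the published protocol
#' where one is given (population 80, mutation probability 0.1) and documented
#' package choices elsewhere (tournament selection of size 2, elite count 2,
#' relative-improvement stopping rule).
#'
#' @param population_size Number of chromosomes per generation (>= 3,
#'   default 80).
#' @param mutation_probability Per-chromosome probability of a permutation
#'   mutation (default 0.1).
#' @param elite_count Number of fittest chromosomes copied unchanged into the
#'   next generation (default 2).
#' @param max_generations Hard cap on generations (default 500).
#' @param convergence_window Number of consecutive generations over which best
#'   fitness must improve by more than `convergence_tolerance` to keep running
#'   (default 30).
#' @param convergence_tolerance Minimal fitness improvement counted as
#'   progress (default 1e-6).
#' @param crossover_single_point_share Probability of choosing single-point
#'   crossover over averaging crossover for each selected parent pair
#'   (default 0.5).
#' @param fitness_floor Amplitude floor passed to [wct_fitness()] (V).
#' @param seed Integer seed for all of the run's randomness, or `NULL` to use
#'   the current RNG state.
#' @return An object of class `ga_config`.
#' @export
ga_config <- function(population_size = 80L,
                      mutation_probability = 0.1,
                      elite_count = 2L,
                      max_generations = 500L,
                      convergence_window = 30L,
                      convergence_tolerance = 1e-6,
                      crossover_single_point_share = 0.5,
                      fitness_floor = 1e-12,
                      seed = NULL) {
  population_size <- as.integer(population_size)
  elite_count <- as.integer(elite_count)
  max_generations <- as.integer(max_generations)
  convergence_window <- as.integer(convergence_window)
  if (is.na(population_size) || population_size < 3L) {
    stop("config error: population_size must be >= 3", call. = FALSE)
  }
  if (!is.numeric(mutation_probability) || mutation_probability < 0 ||
      mutation_probability > 1) {
    stop("config error: mutation_probability must lie in [0, 1]", call. = FALSE)
  }
  if (is.na(elite_count) || elite_count < 0L || elite_count >= population_size) {
    stop("config error: elite_count must satisfy 0 <= elite_count < population_size",
         call. = FALSE)
  }
  if (is.na(max_generations) || max_generations < 1L) {
    stop("config error: max_generations must be >= 1", call. = FALSE)
  }
  if (is.na(convergence_window) || convergence_window < 1L) {
    stop("config error: convergence_window must be >= 1", call. = FALSE)
  }
  if (!is.numeric(convergence_tolerance) || convergence_tolerance < 0) {
    stop("config error: convergence_tolerance must be >= 0", call. = FALSE)
  }
  if (!is.numeric(crossover_single_point_share) ||
      crossover_single_point_share < 0 || crossover_single_point_share > 1) {
    stop("config error: crossover_single_point_share must lie in [0, 1]",
         call. = FALSE)
  }
  if (!is.numeric(fitness_floor) || fitness_floor <= 0) {
    stop("config error: fitness_floor must be > 0", call. = FALSE)
  }
  if (!is.null(seed)) seed <- as.integer(seed)
  structure(
    list(population_size = population_size,
         mutation_probability = mutation_probability,
         elite_count = elite_count,
         max_generations = max_generations,
         convergence_window = convergence_window,
         convergence_tolerance = convergence_tolerance,
         crossover_single_point_share = crossover_single_point_share,
         fitness_floor = fitness_floor,
         seed = seed),
    class = "ga_config"
  )
}

#' @export
print.ga_config <- function(x, ...) {
  cat(sprintf(
    "<ga_config> pop %d, mutation %.3g, elites %d, max gen %d, seed %s\n",
    x$population_size, x$mutation_probability, x$elite_count,
    x$max_generations, if (is.null(x$seed)) "<none>" else x$seed))
  invisible(x)
}

#' Initialize a GA population
#'
#' Exactly one chromosome is the WCT chromosome (1/3, 1/3, 1/3); all others
#' are drawn uniformly on the open simplex (symmetric Dirichlet with unit
#' concentration, sampled as normalized unit-rate exponentials, then
#' boundary-repaired).
#'
#' @param cfg A [ga_config()].  `cfg$seed`, when set, makes the draw
#'   reproducible.
#' @return A list of `cfg$population_size` [weight_tern()] objects; the first
#'   is the exact uniform tern.
#' @export
init_population <- function(cfg) {
  stopifnot(inherits(cfg, "ga_config"))
  with_preserved_seed(cfg$seed, random_population(cfg$population_size))
}

# one uniform tern followed by npop - 1 Dirichlet(1,1,1) draws
random_population <- function(npop) {
  pop <- vector("list", npop)
  pop[[1L]] <- uniform_tern()
  for (i in seq.int(2L, npop)) {
    pop[[i]] <- repair_tern(stats::rexp(3L))
  }
  pop
}

#' Single-point crossover of two terns
#'
#' A cut position (after the first or second gene) is drawn uniformly and the
#' children swap tails.  The tail swap breaks the sum-to-one constraint, so
#' each raw child is repaired by [repair_tern()] (clip into the open interval,
#' renormalize).
#'
#' @param p1,p2 Parent [weight_tern()]s.
#' @return A list of two valid `weight_tern` children.
#' @examples
#' set.seed(1)
#' crossover_single_point(weight_tern(0.2, 0.3, 0.5), weight_tern(0.5, 0.3, 0.2))
#' @export
crossover_single_point <- function(p1, p2) {
  stopifnot(inherits(p1, "weight_tern"), inherits(p2, "weight_tern"))
  cut <- sample.int(2L, 1L)
  a <- unclass(p1); b <- unclass(p2)
  c1 <- c(a[seq_len(cut)], b[seq.int(cut + 1L, 3L)])
  c2 <- c(b[seq_len(cut)], a[seq.int(cut + 1L, 3L)])
  list(repair_tern(c1), repair_tern(c2))
}

#' Averaging crossover of two terns
#'
#' The component-wise midpoint of the parents.  The midpoint of two points on
#' the simplex stays on the simplex, so no repair is needed.
#'
#' @param p1,p2 Parent [weight_tern()]s.
#' @return One `weight_tern` child.
#' @export
crossover_averaging <- function(p1, p2) {
  stopifnot(inherits(p1, "weight_tern"), inherits(p2, "weight_tern"))
  m <- (unclass(p1) + unclass(p2)) / 2
  weight_tern(m[1L], m[2L], m[3L])
}

# the five non-identity permutations of three positions
.PERM3 <- matrix(c(1L, 3L, 2L,
                   2L, 1L, 3L,
                   2L, 3L, 1L,
                   3L, 1L, 2L,
                   3L, 2L, 1L), ncol = 3L, byrow = TRUE)

#' Permutation mutation
#'
#' With the given probability the chromosome's three weights are reordered by
#' a uniformly drawn non-identity permutation; otherwise it is returned
#' unchanged.  Permutations preserve both the open interval and the
#' sum-to-one constraint automatically, which is why this operator suits the
#' simplex-constrained search: it jumps between faces of the simplex without
#' ever producing an infeasible chromosome.
#'
#' @param w A [weight_tern()].
#' @param probability Mutation probability in `[0, 1]` (protocol default 0.1).
#' @return A valid `weight_tern`.
#' @export
mutate_permutation <- function(w, probability = 0.1) {
  stopifnot(inherits(w, "weight_tern"))
  if (!is.numeric(probability) || probability < 0 || probability > 1) {
    stop("parameter error: probability must lie in [0, 1]", call. = FALSE)
  }
  if (probability > 0 && stats::runif(1L) < probability) {
    p <- .PERM3[sample.int(5L, 1L), ]
    v <- unclass(w)[p]
    return(weight_tern(v[1L], v[2L], v[3L]))
  }
  w
}

#' Tournament selection of parent pairs
#'
#' Each parent is the fitter of two individuals drawn uniformly with
#' replacement (tournament of size 2); ties are broken uniformly at random.
#' Tournament selection is used because the log-scale fitness can be negative,
#' which breaks naive roulette-wheel weighting.
#'
#' @param population List of [weight_tern()]s.
#' @param fitnesses Numeric vector of finite fitness values, one per
#'   individual.
#' @param n_pairs Number of parent pairs to draw.
#' @return An integer matrix with `n_pairs` rows and two columns of indices
#'   into `population`.
#' @export
select_parents <- function(population, fitnesses, n_pairs) {
  n <- length(population)
  if (n < 1L) {
    stop("structural error: empty population", call. = FALSE)
  }
  if (length(fitnesses) != n || !all(is.finite(fitnesses))) {
    stop("structural error: fitnesses must be finite and match the population",
         call. = FALSE)
  }
  pick_one <- function() {
    ij <- sample.int(n, 2L, replace = TRUE)
    fi <- fitnesses[ij[1L]]; fj <- fitnesses[ij[2L]]
    if (fi > fj) ij[1L]
    else if (fj > fi) ij[2L]
    else ij[sample.int(2L, 1L)]
  }
  out <- matrix(0L, nrow = n_pairs, ncol = 2L)
  for (k in seq_len(n_pairs)) {
    out[k, 1L] <- pick_one()
    out[k, 2L] <- pick_one()
  }
  out
}

# Aggregate M-WCT amplitude (mean |trace|) for every column of a 3 x N weight
# matrix, vectorized across the population: X is n_samples x 3.
population_amplitudes <- function(X, W) {
  colMeans(abs(X %*% W))
}

recording_matrix <- function(rec) {
  cbind(rec$phi_L, rec$phi_R, rec$phi_F)
}

#' Run the genetic algorithm on a recording
#'
#' Generational loop: evaluate the fitness of every chromosome's M-WCT trace;
#' copy the `elite_count` fittest unchanged; re-insert the exact WCT
#' chromosome (1/3, 1/3, 1/3) into every generation; fill the remainder by
#' tournament selection followed by one of the two crossover operators (chosen
#' per pair with probability `crossover_single_point_share`) and permutation
#' mutation.  The run stops when the best fitness has improved by less than
#' `convergence_tolerance` over `convergence_window` consecutive generations,
#' or at `max_generations`.
#'
#' Because the WCT chromosome is present in every generation and elitism never
#' discards the best individual, the returned best fitness is always at least
#' the fitness of the plain WCT: the minimized terminal can never be worse
#' than the terminal it replaces.
#'
#' @param rec A [limb_recording()].
#' @param cfg A [ga_config()].
#' @return An object of class `ga_result` with elements `best_tern`,
#'   `best_fitness`, `best_amplitude` (mean |M-WCT| in V), `fitness_trajectory`
#'   (per-generation best, non-decreasing), `generations_used`, `mwct_trace`,
#'   `mode = "global"` and `config`.
#' @examples
#' sim <- generate_recording(synth_params(duration = 2, seed = 7))
#' res <- run_ga(sim$recording, ga_config(max_generations = 60, seed = 1))
#' res$best_tern
#' @export
run_ga <- function(rec, cfg = ga_config()) {
  stopifnot(inherits(rec, "limb_recording"), inherits(cfg, "ga_config"))
  X <- recording_matrix(rec)
  with_preserved_seed(cfg$seed, run_ga_impl(rec, X, cfg))
}

run_ga_impl <- function(rec, X, cfg) {
  npop <- cfg$population_size
  pop <- random_population(npop)

  traj <- numeric(cfg$max_generations)
  best_tern <- NULL
  best_fit <- -Inf
  gen <- 0L

  repeat {
    gen <- gen + 1L
    W <- vapply(pop, unclass, numeric(3L))           # 3 x npop
    amps <- population_amplitudes(X, W)
    fits <- fitness_from_amplitude(pmax(amps, cfg$fitness_floor))

    gbest <- which.max(fits)
    if (fits[gbest] > best_fit) {
      best_fit <- fits[gbest]
      best_tern <- pop[[gbest]]
    }
    traj[gen] <- best_fit

    converged <- gen > cfg$convergence_window &&
      (traj[gen] - traj[gen - cfg$convergence_window]) < cfg$convergence_tolerance
    if (converged || gen >= cfg$max_generations) break

    ord <- order(fits, decreasing = TRUE)
    nxt <- vector("list", npop)
    nxt[seq_len(cfg$elite_count)] <- pop[ord[seq_len(cfg$elite_count)]]
    nxt[[cfg$elite_count + 1L]] <- uniform_tern()    # WCT chromosome preserved
    filled <- cfg$elite_count + 1L

    while (filled < npop) {
      pair <- select_parents(pop, fits, 1L)
      p1 <- pop[[pair[1L, 1L]]]; p2 <- pop[[pair[1L, 2L]]]
      kids <- if (stats::runif(1L) < cfg$crossover_single_point_share) {
        crossover_single_point(p1, p2)
      } else {
        list(crossover_averaging(p1, p2))
      }
      for (k in kids) {
        if (filled >= npop) break
        filled <- filled + 1L
        nxt[[filled]] <- mutate_permutation(k, cfg$mutation_probability)
      }
    }
    pop <- nxt
  }

  structure(
    list(best_tern = best_tern,
         best_fitness = best_fit,
         best_amplitude = mean(abs(compute_mwct(rec, best_tern)$values)),
         fitness_trajectory = traj[seq_len(gen)],
         generations_used = gen,
         mwct_trace = compute_mwct(rec, best_tern),
         mode = "global",
         config = cfg),
    class = "ga_result"
  )
}

#' @export
print.ga_result <- function(x, ...) {
  cat(sprintf(
    paste0("<ga_result> mode %s: best tern (%.4f, %.4f, %.4f), ",
           "fitness %.4f (mean|M-WCT| = %.3g V), %d generations\n"),
    x$mode, x$best_tern[["alpha"]], x$best_tern[["beta"]],
    x$best_tern[["gamma"]], x$best_fitness, x$best_amplitude,
    x$generations_used))
  invisible(x)
}

#' Run the GA per window and average the weights
#'
#' Splits the recording into non-overlapping windows of `window_seconds`,
#' minimizes each window independently and additionally reports the
#' across-window component-wise average tern (renormalized to sum one).  This
#' reproduces the "average across the full excerpt" reporting mode; the
#' primary, physically interpretable mode remains one tern per excerpt
#' ([run_ga()]), since a single tern is what maps to fixed replacement
#' resistors.
#'
#' @param rec A [limb_recording()].
#' @param cfg A [ga_config()]; window `i` runs with seed `cfg$seed + i - 1`
#'   when a seed is set.
#' @param window_seconds Window length in seconds; must fit at least one full
#'   window into the recording.
#' @return An object of class `ga_windowed_result`: list with `window_results`
#'   (one `ga_result` per window), `average_tern`, `window_seconds` and
#'   `mode = "windowed"`.
#' @export
run_ga_windowed <- function(rec, cfg = ga_config(), window_seconds) {
  stopifnot(inherits(rec, "limb_recording"), inherits(cfg, "ga_config"))
  if (!is.numeric(window_seconds) || length(window_seconds) != 1L ||
      !is.finite(window_seconds) || window_seconds <= 0) {
    stop("parameter error: window_seconds must be a single positive number",
         call. = FALSE)
  }
  win_n <- as.integer(round(window_seconds * rec$sample_rate))
  if (win_n < 2L || win_n > rec$n_samples) {
    stop("parameter error: window longer than recording (or shorter than 2 samples)",
         call. = FALSE)
  }
  n_win <- rec$n_samples %/% win_n
  results <- vector("list", n_win)
  for (i in seq_len(n_win)) {
    idx <- seq.int((i - 1L) * win_n + 1L, i * win_n)
    sub <- limb_recording(rec$phi_L[idx], rec$phi_R[idx], rec$phi_F[idx],
                          rec$sample_rate,
                          subject_id = sprintf("%s[w%d]", rec$subject_id, i))
    wcfg <- cfg
    if (!is.null(cfg$seed)) {
      wcfg$seed <- as.integer((as.double(cfg$seed) + i - 1) %%
                                (.Machine$integer.max - 1))
    }
    results[[i]] <- run_ga(sub, wcfg)
  }
  terns <- vapply(results, function(r) unclass(r$best_tern), numeric(3L))
  avg <- rowMeans(terns)
  avg <- avg / sum(avg)
  structure(
    list(window_results = results,
         average_tern = weight_tern(avg[1L], avg[2L], avg[3L]),
         window_seconds = window_seconds,
         n_windows = n_win,
         mode = "windowed"),
    class = "ga_windowed_result"
  )
}

#' @export
print.ga_windowed_result <- function(x, ...) {
  cat(sprintf(
    "<ga_windowed_result> %d windows of %g s, average tern (%.4f, %.4f, %.4f)\n",
    x$n_windows, x$window_seconds, x$average_tern[["alpha"]],
    x$average_tern[["beta"]], x$average_tern[["gamma"]]))
  invisible(x)
}

#' Brute-force grid-search oracle
#'
#' Independent verification baseline for the GA: exhaustively evaluates the
#' aggregate amplitude mean |M-WCT| on the lattice
#' \eqn{\{(i s, j s, 1 - i s - j s)\}} over the simplex.  Lattice points on
#' the closed-simplex boundary are pushed through the same boundary repair the
#' GA uses, so the candidate set is never empty even at coarse steps.
#' Deterministic: ties resolve to the first candidate in row-major `(i, j)`
#' order.
#'
#' @param rec A [limb_recording()].
#' @param step Grid spacing in `(0, 0.5]` (default 0.02).
#' @return A list with `tern` (the lattice minimizer as a [weight_tern()]),
#'   `aggregate_amplitude` (mean |M-WCT| in V) and `n_candidates`.
#' @export
grid_search_oracle <- function(rec, step = 0.02) {
  stopifnot(inherits(rec, "limb_recording"))
  if (!is.numeric(step) || length(step) != 1L || !is.finite(step) ||
      step <= 0 || step > 0.5) {
    stop("parameter error: step must lie in (0, 0.5]", call. = FALSE)
  }
  m <- as.integer(floor(1 / step + 1e-9))
  cand <- list()
  for (i in 0:m) {
    for (j in 0:(m - i)) {
      a <- i * step; b <- j * step; g <- 1 - a - b
      if (g < -1e-12) next
      cand[[length(cand) + 1L]] <- unclass(repair_tern(c(a, b, max(g, 0))))
    }
  }
  W <- vapply(cand, identity, numeric(3L))
  W <- W[, !duplicated(t(W)), drop = FALSE]
  X <- recording_matrix(rec)
  amps <- population_amplitudes(X, W)
  k <- which.min(amps)
  list(tern = weight_tern(W[1L, k], W[2L, k], W[3L, k]),
       aggregate_amplitude = amps[k],
       n_candidates = ncol(W))
}
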