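test_that("ga_config validates its hyperparameters", {
  expect_s3_class(ga_config(), "ga_config")
  expect_equal(ga_config()$population_size, 80L)
  expect_equal(ga_config()$mutation_probability, 0.1)
  expect_error(ga_config(population_size = 2), "population_size")
  expect_error(ga_config(mutation_probability = 1.5), "mutation_probability")
  expect_error(ga_config(elite_count = 80), "elite_count")
  expect_error(ga_config(max_generations = 0), "max_generations")
})

test_that("init_population has the right size, the WCT chromosome, and only valid terns", {
  pop <- init_population(ga_config(seed = 11))
  expect_length(pop, 80L)
  uni <- vapply(pop, function(w) all(unclass(w) == 1 / 3), logical(1))
  expect_equal(sum(uni), 1L)   # exactly one exact WCT chromosome
  expect_true(all(vapply(pop, is_valid_tern, logical(1))))

  # seeded draws are reproducible
  expect_identical(init_population(ga_config(seed = 11)), pop)
})

test_that("single-point crossover swaps tails and repairs onto the simplex", {
  p1 <- weight_tern(0.2, 0.3, 0.5)
  p2 <- weight_tern(0.5, 0.3, 0.2)

  # identical parents reproduce themselves (up to repair renormalization)
  set.seed(5)
  same <- crossover_single_point(p1, p1)
  expect_equal(unclass(same[[1]]), unclass(p1), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(unclass(same[[2]]), unclass(p1), tolerance = 1e-12,
               ignore_attr = TRUE)

  # hand-derived repair arithmetic for both possible cut positions
  hand_repair <- function(v) {
    v <- pmin(pmax(v, 1e-6), 1 - 2e-6)
    v / sum(v)
  }
  for (seed in 1:6) {
    set.seed(seed)
    cut <- sample.int(2L, 1L)
    set.seed(seed)
    kids <- crossover_single_point(p1, p2)
    raw1 <- c(unclass(p1)[seq_len(cut)], unclass(p2)[seq.int(cut + 1L, 3L)])
    raw2 <- c(unclass(p2)[seq_len(cut)], unclass(p1)[seq.int(cut + 1L, 3L)])
    expect_equal(as.numeric(unclass(kids[[1]])), hand_repair(raw1),
                 tolerance = 1e-15, ignore_attr = TRUE)
    expect_equal(as.numeric(unclass(kids[[2]])), hand_repair(raw2),
                 tolerance = 1e-15, ignore_attr = TRUE)
    if (cut == 1L) {
      # the worked example: (0.2, 0.3, 0.2) renormalizes to (2/7, 3/7, 2/7)
      expect_equal(as.numeric(unclass(kids[[1]])), c(2, 3, 2) / 7,
                   tolerance = 1e-12, ignore_attr = TRUE)
    }
    expect_true(is_valid_tern(kids[[1]]) && is_valid_tern(kids[[2]]))
  }
})

test_that("averaging crossover is the exact midpoint and stays on the simplex", {
  p1 <- weight_tern(0.2, 0.3, 0.5)
  p2 <- weight_tern(0.4, 0.5, 0.1)
  child <- crossover_averaging(p1, p2)
  expect_equal(as.numeric(unclass(child)), c(0.3, 0.4, 0.3),
               ignore_attr = TRUE)
  expect_identical(unclass(crossover_averaging(p1, p1)), unclass(p1))
  expect_equal(sum(unclass(child)), 1)
})

test_that("permutation mutation preserves the component multiset", {
  w <- weight_tern(0.2, 0.3, 0.5)

  # probability 0 -> identity; probability 1 -> never the identity permutation
  set.seed(1)
  expect_identical(mutate_permutation(w, 0), w)
  for (s in 1:30) {
    set.seed(s)
    m <- mutate_permutation(w, 1)
    expect_setequal(round(as.numeric(unclass(m)), 12),
                    round(as.numeric(unclass(w)), 12))
    expect_false(identical(as.numeric(unclass(m)), as.numeric(unclass(w))))
  }

  # the uniform tern is invariant under every permutation
  set.seed(2)
  expect_equal(unclass(mutate_permutation(uniform_tern(), 1)),
               unclass(uniform_tern()))
})

test_that("tournament selection prefers the fittest at the enumerated rate", {
  pop <- init_population(ga_config(population_size = 4, seed = 3))
  fits <- c(0.1, 0.9, 0.4, 0.2)   # individual 2 is strictly best

  # exact tournament probability for the best of N = 4: 1/N * (2 - 1/N) = 7/16,
  # from enumerating the 16 equally likely ordered draws
  set.seed(42)
  pairs <- select_parents(pop, fits, 8000L)
  phat <- mean(pairs == 2L)
  expect_lt(abs(phat - 7 / 16), 0.02)
  expect_gt(phat, 1 / 4)   # strictly better than uniform

  # degenerate population: single individual always selected
  one <- select_parents(pop[1], 0.5, 10L)
  expect_true(all(one == 1L))

  # ties are broken at random, not positionally
  set.seed(7)
  tied <- select_parents(pop[1:2], c(0.5, 0.5), 2000L)
  expect_gt(mean(tied == 1L), 0.4)
  expect_lt(mean(tied == 1L), 0.6)

  # deterministic under a fixed seed
  set.seed(9); a <- select_parents(pop, fits, 50L)
  set.seed(9); b <- select_parents(pop, fits, 50L)
  expect_identical(a, b)

  expect_error(select_parents(list(), numeric(0), 1L), "empty population")
  expect_error(select_parents(pop, c(1, NA, 1, 1), 1L), "finite")
})

test_that("run_ga is elitist, never worse than the WCT, and seed-deterministic", {
  sim <- quick_synth(seed = 21)
  rec <- sim$recording
  res <- run_ga(rec, quick_ga_config(seed = 31))

  expect_s3_class(res, "ga_result")
  expect_true(is_valid_tern(res$best_tern))
  expect_true(all(diff(res$fitness_trajectory) >= 0))
  expect_lte(res$generations_used, 120L)

  wct_amp <- mean(abs(compute_wct(rec)$values))
  expect_lte(res$best_amplitude, wct_amp)
  expect_gte(res$best_fitness, wct_fitness(compute_wct(rec)))

  res2 <- run_ga(rec, quick_ga_config(seed = 31))
  expect_identical(res, res2)

  # recovers the planted tern on a short, lightly noisy excerpt
  expect_lt(max(abs(unclass(res$best_tern) - unclass(sim$planted_tern))), 0.05)
})

test_that("windowed mode degenerates to the global run and averages terns validly", {
  sim <- quick_synth(seed = 22)
  cfg <- quick_ga_config(seed = 32)

  wres <- run_ga_windowed(sim$recording, cfg, window_seconds = duration(sim$recording))
  expect_equal(wres$n_windows, 1L)
  expect_true(is_valid_tern(wres$average_tern))

  # the single window sees the whole recording (modulo the subject label)
  gres <- run_ga(sim$recording, cfg)
  expect_equal(unclass(wres$window_results[[1]]$best_tern),
               unclass(gres$best_tern))
  expect_equal(wres$window_results[[1]]$fitness_trajectory,
               gres$fitness_trajectory)

  # stationary generator: per-window terns agree across windows
  sim4 <- quick_synth(seed = 23, duration = 4)
  w2 <- run_ga_windowed(sim4$recording, quick_ga_config(seed = 33),
                        window_seconds = 2)
  expect_equal(w2$n_windows, 2L)
  terns <- vapply(w2$window_results, function(r) unclass(r$best_tern),
                  numeric(3))
  expect_lt(max(abs(terns[, 1] - terns[, 2])), 0.05)
  expect_true(is_valid_tern(w2$average_tern))

  expect_error(run_ga_windowed(sim$recording, cfg, window_seconds = 100),
               "parameter error")
})

test_that("grid oracle finds an on-grid planted tern exactly", {
  p <- synth_params(duration = 2, planted_tern = weight_tern(0.25, 0.25, 0.5),
                    noise_sd = 0, baseline_drift_amplitude = 0)
  sim <- generate_recording(p)
  orc <- grid_search_oracle(sim$recording, step = 0.25)
  expect_equal(as.numeric(unclass(orc$tern)), c(0.25, 0.25, 0.5),
               ignore_attr = TRUE)
  expect_lt(orc$aggregate_amplitude, 1e-15)
})

test_that("grid oracle at step 0.5 matches independent hand enumeration", {
  rec <- toy_recording(n = 200L)
  orc <- grid_search_oracle(rec, step = 0.5)

  # independent route: enumerate the coarse lattice, repair by the same rule,
  # and evaluate each candidate with a plain loop
  cand <- list()
  for (i in 0:2) for (j in 0:(2 - i)) {
    v <- c(i * 0.5, j * 0.5, 1 - (i + j) * 0.5)
    v <- pmin(pmax(v, 1e-6), 1 - 2e-6)
    cand[[length(cand) + 1]] <- v / sum(v)
  }
  cand <- unique(cand)
  amps <- vapply(cand, function(v) naive_mean_abs_mwct(rec, v), numeric(1))
  expect_equal(orc$n_candidates, length(cand))
  expect_equal(orc$aggregate_amplitude, min(amps), tolerance = 1e-12)
  expect_equal(as.numeric(unclass(orc$tern)), cand[[which.min(amps)]],
               tolerance = 1e-12, ignore_attr = TRUE)

  expect_error(grid_search_oracle(rec, step = 0.7), "parameter error")
  expect_error(grid_search_oracle(rec, step = 0), "parameter error")
})

test_that("every operator application lands on the open simplex", {
  # property-style closure check across seeds and operators
  set.seed(1234)
  produced <- list()
  pop <- init_population(ga_config(population_size = 50, seed = 77))
  produced <- c(produced, pop)
  for (k in 1:300) {
    i <- sample.int(length(pop), 2L)
    produced <- c(produced,
                  crossover_single_point(pop[[i[1]]], pop[[i[2]]]),
                  list(crossover_averaging(pop[[i[1]]], pop[[i[2]]]),
                       mutate_permutation(pop[[i[1]]], 0.5),
                       repair_tern(rexp(3) - 0.2)))
  }
  expect_true(all(vapply(produced, is_valid_tern, logical(1))))
})
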