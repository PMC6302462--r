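# Shared fixtures, generated in code (no stored data files).

# small deterministic recording with no particular structure
toy_recording <- function(n = 64L, fs = 800, seed = 99L) {
  withr::with_seed(seed, {
    limb_recording(rnorm(n, sd = 1e-3), rnorm(n, sd = 1e-3),
                   rnorm(n, sd = 1e-3), fs, subject_id = "toy")
  })
}

# short synthetic excerpt; defaults keep unit tests fast
quick_synth <- function(seed, duration = 2, ...) {
  generate_recording(synth_params(duration = duration, seed = seed, ...))
}

# small GA config for unit tests (acceptance tests use protocol scale)
quick_ga_config <- function(seed, ...) {
  ga_config(max_generations = 120L, seed = seed, ...)
}

# mean |alpha*L + beta*R + gamma*F| computed by a plain loop, independent of
# the package's matrix evaluation path
naive_mean_abs_mwct <- function(rec, w) {
  s <- 0
  for (i in seq_len(rec$n_samples)) {
    s <- s + abs(w[1L] * rec$phi_L[i] + w[2L] * rec$phi_R[i] +
                   w[3L] * rec$phi_F[i])
  }
  s / rec$n_samples
}
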