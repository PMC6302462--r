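#' Default P-QRS-T wavelet set for the dipole trajectory
#'
#' Each row defines one Gaussian wavelet per beat on one axis of the 3-D
#' equivalent cardiac dipole: a center expressed as a fraction of the beat
#' period, a width in seconds, and an amplitude (V, in dipole-projection
#' units).  The centers are deliberately staggered across the three axes —
#' the dipole traces a rotating loop rather than a fixed direction — which
#' keeps the three axis signals linearly independent over time.  That
#' independence is what makes the planted tern a well-conditioned minimizer:
#' no other point on the simplex can null the dipole contribution.  Values
#' give a lead II with a dominant positive R wave of roughly 2-3 mV
#' peak-to-peak and conventional P/T morphology at 60 bpm.
#'
#' @return A data frame with columns `wave`, `axis` (`"x"`, `"y"` or `"z"`),
#'   `center_frac`, `width_s`, `amp_V`.
#' @export
default_wavelet_set <- function() {
  data.frame(
    wave = rep(c("P", "Q", "R", "S", "T"), times = 3L),
    axis = rep(c("x", "y", "z"), each = 5L),
    center_frac = c(0.180, 0.370, 0.400, 0.435, 0.700,
                    0.190, 0.365, 0.415, 0.450, 0.720,
                    0.170, 0.375, 0.385, 0.425, 0.680),
    width_s = c(0.030, 0.010, 0.014, 0.010, 0.060,
                0.028, 0.010, 0.016, 0.012, 0.055,
                0.032, 0.009, 0.012, 0.011, 0.065),
    amp_V = c(1.0e-4, -1.2e-4, 1.0e-3, -2.5e-4, 3.5e-4,
              6.0e-5, -8.0e-5, 6.0e-4, -2.0e-4, 1.5e-4,
              4.0e-5, 9.0e-5, -4.0e-4, 2.2e-4, -1.0e-4),
    stringsAsFactors = FALSE
  )
}

#' Parameters of the synthetic limb-potential generator
#'
#' The generator emulates the kind of recordings the minimization was designed
#' for: three limb-electrode potentials obtained by projecting a 3-D
#' equivalent cardiac dipole onto per-electrode lead vectors, with
#' per-electrode baseline drift and white noise.  The left-leg lead vector is
#' constructed as \eqn{l_F = -(\alpha^* l_L + \beta^* l_R) / \gamma^*} so that
#' the planted tern \eqn{(\alpha^*, \beta^*, \gamma^*)} exactly nulls the
#' dipole contribution to the weighted mean — a known, recoverable ground
#' truth for the GA.
#'
#' @param heart_rate Beats per minute (> 0; default 60).
#' @param duration Excerpt length in seconds (default 10).
#' @param sample_rate Sampling rate in Hz (default 800, i.e. 8000 samples for
#'   the default excerpt).
#' @param planted_tern The [weight_tern()] that nulls the weighted mean
#'   (default `weight_tern(0.2, 0.2, 0.6)`, left-leg-dominant).
#' @param lead_L,lead_R 3-component dimensionless lead vectors for the left
#'   arm and right arm electrodes.
#' @param wavelet_set Data frame as returned by [default_wavelet_set()].
#' @param baseline_drift_amplitude Per-electrode low-frequency (< 0.5 Hz)
#'   sinusoidal drift amplitude in volts (default 2e-5).
#' @param noise_sd Per-electrode white-noise standard deviation in volts
#'   (default 1e-5).
#' @param seed Integer seed for drift phases/frequencies and noise, or `NULL`.
#' @return An object of class `synth_params`.
#' @export
synth_params <- function(heart_rate = 60,
                         duration = 10,
                         sample_rate = 800,
                         planted_tern = weight_tern(0.2, 0.2, 0.6),
                         lead_L = c(-2.0, 1.5, 0.7),
                         lead_R = c(-0.9, -0.8, 0.2),
                         wavelet_set = default_wavelet_set(),
                         baseline_drift_amplitude = 2e-5,
                         noise_sd = 1e-5,
                         seed = NULL) {
  if (!inherits(planted_tern, "weight_tern")) {
    planted_tern <- weight_tern(planted_tern[1L], planted_tern[2L],
                                planted_tern[3L])
  }
  if (!is.numeric(heart_rate) || heart_rate <= 0) {
    stop("parameter error: heart_rate must be > 0", call. = FALSE)
  }
  if (!is.numeric(duration) || duration <= 0) {
    stop("parameter error: duration must be > 0", call. = FALSE)
  }
  if (!is.numeric(sample_rate) || sample_rate <= 0) {
    stop("parameter error: sample_rate must be > 0", call. = FALSE)
  }
  if (length(lead_L) != 3L || length(lead_R) != 3L ||
      !all(is.finite(c(lead_L, lead_R)))) {
    stop("parameter error: lead vectors must be finite 3-vectors", call. = FALSE)
  }
  stopifnot(is.data.frame(wavelet_set),
            all(c("axis", "center_frac", "width_s", "amp_V")
                %in% names(wavelet_set)),
            all(wavelet_set$axis %in% c("x", "y", "z")))
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    stop("parameter error: noise_sd must be >= 0", call. = FALSE)
  }
  if (!is.numeric(baseline_drift_amplitude) || baseline_drift_amplitude < 0) {
    stop("parameter error: baseline_drift_amplitude must be >= 0", call. = FALSE)
  }
  structure(
    list(heart_rate = heart_rate, duration = duration,
         sample_rate = sample_rate, planted_tern = planted_tern,
         lead_L = as.numeric(lead_L), lead_R = as.numeric(lead_R),
         wavelet_set = wavelet_set,
         baseline_drift_amplitude = baseline_drift_amplitude,
         noise_sd = noise_sd,
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "synth_params"
  )
}

# dipole trajectory: n x 3 matrix, sum of per-beat Gaussian wavelets
dipole_trajectory <- function(t, heart_rate, wavelet_set) {
  period <- 60 / heart_rate
  n_beats <- ceiling(max(t) / period) + 1L
  d <- matrix(0, nrow = length(t), ncol = 3L,
              dimnames = list(NULL, c("x", "y", "z")))
  ax <- match(wavelet_set$axis, c("x", "y", "z"))
  for (k in seq_len(n_beats) - 1L) {
    for (w in seq_len(nrow(wavelet_set))) {
      ctr <- (k + wavelet_set$center_frac[w]) * period
      d[, ax[w]] <- d[, ax[w]] +
        wavelet_set$amp_V[w] * exp(-0.5 * ((t - ctr) / wavelet_set$width_s[w])^2)
    }
  }
  d
}

#' Generate a synthetic limb-potential recording with planted ground truth
#'
#' Builds the dipole trajectory, derives the left-leg lead vector from the
#' planted tern (see [synth_params()]), projects the dipole onto the three
#' lead vectors and adds independent per-electrode baseline drift (a sinusoid
#' with frequency drawn in 0.05-0.45 Hz and random phase) and white noise.
#' The per-electrode drift and noise are what make the weighted mean nonzero
#' at the planted tern — exactly the common-mode-breaking components that make
#' the real WCT nonzero.
#'
#' @param params A [synth_params()].
#' @param subject_id Label stored on the recording.
#' @return An object of class `synthetic_recording`: list with `recording`
#'   (a [limb_recording()]), `planted_tern`, `lead_vectors` (3 x 3 matrix,
#'   rows L/R/F), `r_peak_times` (scheduled R-wave centers in seconds) and
#'   `params`.
#' @examples
#' sim <- generate_recording(synth_params(duration = 2, seed = 42))
#' sim$planted_tern
#' @export
generate_recording <- function(params = synth_params(), subject_id = "synthetic") {
  stopifnot(inherits(params, "synth_params"))
  w <- params$planted_tern
  l_L <- params$lead_L
  l_R <- params$lead_R
  l_F <- -(w[["alpha"]] * l_L + w[["beta"]] * l_R) / w[["gamma"]]
  if (sqrt(sum(l_F^2)) < 1e-9) {
    stop("geometry error: derived left-leg lead vector is null", call. = FALSE)
  }
  if (sqrt(sum((l_F - l_R)^2)) < 1e-9) {
    stop("geometry error: lead II vector is null (l_F equals l_R)",
         call. = FALSE)
  }
  n <- as.integer(round(params$duration * params$sample_rate))
  t <- (seq_len(n) - 1L) / params$sample_rate
  d <- dipole_trajectory(t, params$heart_rate, params$wavelet_set)

  clean <- list(L = as.vector(d %*% l_L),
                R = as.vector(d %*% l_R),
                F = as.vector(d %*% l_F))

  disturb <- with_preserved_seed(params$seed, {
    lapply(1:3, function(i) {
      dr <- if (params$baseline_drift_amplitude > 0) {
        f <- stats::runif(1L, 0.05, 0.45)
        ph <- stats::runif(1L, 0, 2 * pi)
        params$baseline_drift_amplitude * sin(2 * pi * f * t + ph)
      } else {
        rep(0, n)
      }
      nz <- if (params$noise_sd > 0) stats::rnorm(n, 0, params$noise_sd) else rep(0, n)
      dr + nz
    })
  })

  rec <- limb_recording(clean$L + disturb[[1L]],
                        clean$R + disturb[[2L]],
                        clean$F + disturb[[3L]],
                        params$sample_rate, subject_id = subject_id)
  period <- 60 / params$heart_rate
  rrows <- params$wavelet_set[params$wavelet_set$wave == "R", ]
  r_frac <- if (nrow(rrows) > 0L) {
    rrows$center_frac[which.max(abs(rrows$amp_V))]
  } else 0.4
  r_times <- (seq.int(0L, ceiling(params$duration / period)) + r_frac) * period
  r_times <- r_times[r_times < params$duration]

  lv <- rbind(L = l_L, R = l_R, F = l_F)
  structure(
    list(recording = rec, planted_tern = w, lead_vectors = lv,
         r_peak_times = r_times, params = params),
    class = "synthetic_recording"
  )
}

#' @export
print.synthetic_recording <- function(x, ...) {
  cat(sprintf(
    "<synthetic_recording> '%s': %d samples @ %g Hz, planted tern (%.3f, %.3f, %.3f)\n",
    x$recording$subject_id, x$recording$n_samples, x$recording$sample_rate,
    x$planted_tern[["alpha"]], x$planted_tern[["beta"]],
    x$planted_tern[["gamma"]]))
  invisible(x)
}

#' Generate a synthetic cohort with subject-specific planted terns
#'
#' Emulates a cohort of independent subjects: per-subject planted terns are
#' drawn from the open simplex with the left-leg weight biased upward
#' (Dirichlet concentration (1, 1, 2)), consistent with the observation that
#' the left-leg weight is usually the largest; per-subject heart rates are
#' uniform in `heart_rate_range`; drift/noise phases differ per subject.
#' Draws are rejected until the gamma/alpha and gamma/beta ratios fall inside
#' the configurable bands and every component is at least `min_component`
#' (tiny planted weights make the derived left-leg lead vector degenerate).
#'
#' When `noise_frac_lead_ii` is set (default 0.01), each subject's white-noise
#' standard deviation is calibrated to that fraction of the subject's
#' noise-free lead II peak-to-peak amplitude.
#'
#' @param n Number of subjects (>= 1).
#' @param base A [synth_params()] supplying everything not varied per subject.
#' @param seed Integer seed for the cohort draw, or `NULL`.
#' @param gamma_alpha_range Allowed range of gamma/alpha (default
#'   `c(0.78, 5.69)`).
#' @param gamma_beta_range Allowed range of gamma/beta (default
#'   `c(0.62, 5.69)`).
#' @param heart_rate_range Per-subject heart-rate range in bpm (default
#'   `c(50, 100)`).
#' @param noise_frac_lead_ii Noise sd as a fraction of the subject's clean
#'   lead II peak-to-peak, or `NULL` to keep `base$noise_sd` (default 0.01).
#' @param min_component Lower bound on each planted weight (default 0.05).
#' @return A list of `n` `synthetic_recording` objects.
#' @export
generate_cohort <- function(n, base = synth_params(), seed = NULL,
                            gamma_alpha_range = c(0.78, 5.69),
                            gamma_beta_range = c(0.62, 5.69),
                            heart_rate_range = c(50, 100),
                            noise_frac_lead_ii = 0.01,
                            min_component = 0.05) {
  if (!is.numeric(n) || n < 1) {
    stop("parameter error: n must be >= 1", call. = FALSE)
  }
  n <- as.integer(n)
  with_preserved_seed(seed, {
    out <- vector("list", n)
    for (i in seq_len(n)) {
      repeat {
        raw <- c(stats::rexp(1L), stats::rexp(1L),
                 sum(stats::rexp(2L)))          # Dirichlet(1, 1, 2)
        w <- raw / sum(raw)
        ga <- w[3L] / w[1L]
        gb <- w[3L] / w[2L]
        if (all(w >= min_component) &&
            ga >= gamma_alpha_range[1L] && ga <= gamma_alpha_range[2L] &&
            gb >= gamma_beta_range[1L] && gb <= gamma_beta_range[2L]) {
          break
        }
      }
      hr <- stats::runif(1L, heart_rate_range[1L], heart_rate_range[2L])
      sub_seed <- sample.int(.Machine$integer.max - 1L, 1L)
      p <- base
      p$heart_rate <- hr
      p$planted_tern <- weight_tern(w[1L], w[2L], w[3L])
      p$seed <- sub_seed
      if (!is.null(noise_frac_lead_ii)) {
        clean_p <- p
        clean_p$noise_sd <- 0
        clean_p$baseline_drift_amplitude <- 0
        clean <- generate_recording(clean_p)
        p2p <- diff(range(derive_lead_ii(clean$recording)$values))
        p$noise_sd <- noise_frac_lead_ii * p2p
      }
      out[[i]] <- generate_recording(p, subject_id = sprintf("synth-%03d", i))
    }
    out
  })
}
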