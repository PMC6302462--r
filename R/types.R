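#' Limb-electrode potential recording
#'
#' Container for the three synchronized limb-electrode potentials that compose
#' the Wilson Central Terminal: left arm (`phi_L`), right arm (`phi_R`) and
#' left leg (`phi_F`), sampled at a common fixed rate.  All potentials are in
#' volts.
#'
#' @param phi_L Numeric vector, left-arm electrode potential (V).
#' @param phi_R Numeric vector, right-arm electrode potential (V).
#' @param phi_F Numeric vector, left-leg electrode potential (V).
#' @param sample_rate Sampling rate in Hz (> 0).
#' @param subject_id Free-text label for the subject/recording.
#'
#' @return An object of class `limb_recording`: a list with elements `phi_L`,
#'   `phi_R`, `phi_F`, `sample_rate`, `subject_id` and `n_samples`.
#' @examples
#' rec <- limb_recording(sin(1:100), cos(1:100), sin(1:100) / 2, 800)
#' rec
#' @export
limb_recording <- function(phi_L, phi_R, phi_F, sample_rate,
                           subject_id = "unknown") {
  phi_L <- as.numeric(phi_L)
  phi_R <- as.numeric(phi_R)
  phi_F <- as.numeric(phi_F)
  n <- length(phi_L)
  if (length(phi_R) != n || length(phi_F) != n) {
    stop("structural-input error: phi_L, phi_R, phi_F must have identical length",
         call. = FALSE)
  }
  if (n < 2L) {
    stop("structural-input error: traces must have at least 2 samples",
         call. = FALSE)
  }
  if (!all(is.finite(phi_L)) || !all(is.finite(phi_R)) || !all(is.finite(phi_F))) {
    stop("structural-input error: all samples must be finite", call. = FALSE)
  }
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L ||
      !is.finite(sample_rate) || sample_rate <= 0) {
    stop("structural-input error: sample_rate must be a single positive number",
         call. = FALSE)
  }
  structure(
    list(phi_L = phi_L, phi_R = phi_R, phi_F = phi_F,
         sample_rate = as.numeric(sample_rate),
         subject_id = as.character(subject_id)[1L],
         n_samples = n),
    class = "limb_recording"
  )
}

#' @export
print.limb_recording <- function(x, ...) {
  cat(sprintf(
    "<limb_recording> subject '%s': %d samples @ %g Hz (%.3f s)\n",
    x$subject_id, x$n_samples, x$sample_rate, x$n_samples / x$sample_rate))
  invisible(x)
}

#' Duration of a recording or trace in seconds
#' @param x A `limb_recording` or `potential_trace`.
#' @return Duration in seconds.
#' @export
duration <- function(x) {
  UseMethod("duration")
}

#' @export
duration.limb_recording <- function(x) x$n_samples / x$sample_rate

#' @export
duration.potential_trace <- function(x) length(x$values) / x$sample_rate

#' Single potential trace
#'
#' A sampled potential time series in volts, e.g. the WCT, the M-WCT or a
#' derived limb lead.
#'
#' @param values Numeric vector of potentials (V), all finite.
#' @param sample_rate Sampling rate in Hz (> 0).
#' @return An object of class `potential_trace`.
#' @export
potential_trace <- function(values, sample_rate) {
  values <- as.numeric(values)
  if (length(values) < 1L) {
    stop("structural-input error: empty trace", call. = FALSE)
  }
  if (!all(is.finite(values))) {
    stop("structural-input error: trace values must be finite", call. = FALSE)
  }
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L ||
      !is.finite(sample_rate) || sample_rate <= 0) {
    stop("structural-input error: sample_rate must be a single positive number",
         call. = FALSE)
  }
  structure(list(values = values, sample_rate = as.numeric(sample_rate)),
            class = "potential_trace")
}

#' @export
print.potential_trace <- function(x, ...) {
  cat(sprintf("<potential_trace> %d samples @ %g Hz, mean|v| = %.3g V\n",
              length(x$values), x$sample_rate, mean(abs(x$values))))
  invisible(x)
}

# open-interval bounds used by constraint repair; "positive, not null" needs an
# explicit numeric floor
.TERN_LO <- 1e-6
.TERN_HI <- 1 - 2e-6
.TERN_SUM_TOL <- 1e-9

#' Weight tern (GA chromosome)
#'
#' One candidate solution: the weight triple (alpha, beta, gamma) applied to
#' the left-arm, right-arm and left-leg potentials.  Weights must lie strictly
#' inside (0, 1) and sum to one (a point on the open 2-simplex), so the
#' weighted mean is a proper convex combination and every weight maps to a
#' positive physical resistor.
#'
#' @param alpha Weight for `phi_L` (left arm).
#' @param beta Weight for `phi_R` (right arm).
#' @param gamma Weight for `phi_F` (left leg).
#' @return An object of class `weight_tern`: a named numeric vector
#'   `c(alpha, beta, gamma)`.
#' @examples
#' weight_tern(1/3, 1/3, 1/3)   # the WCT chromosome
#' weight_tern(0.2, 0.2, 0.6)
#' @export
weight_tern <- function(alpha, beta, gamma) {
  w <- c(alpha = as.numeric(alpha)[1L], beta = as.numeric(beta)[1L],
         gamma = as.numeric(gamma)[1L])
  if (!all(is.finite(w))) {
    stop("constraint-violation error: weights must be finite", call. = FALSE)
  }
  if (any(w <= 0) || any(w >= 1)) {
    stop("constraint-violation error: weights must lie strictly in (0, 1)",
         call. = FALSE)
  }
  if (abs(sum(w) - 1) > .TERN_SUM_TOL) {
    stop(sprintf(
      "constraint-violation error: weights must sum to 1 (got %.12g)", sum(w)),
      call. = FALSE)
  }
  structure(w, class = "weight_tern")
}

#' The uniform (WCT) tern
#'
#' The chromosome alpha = beta = gamma = 1/3, i.e. the classical Wilson
#' Central Terminal weighting.
#' @return A `weight_tern`.
#' @export
uniform_tern <- function() weight_tern(1 / 3, 1 / 3, 1 / 3)

#' @export
print.weight_tern <- function(x, ...) {
  cat(sprintf("<weight_tern> alpha = %.6f, beta = %.6f, gamma = %.6f\n",
              x[["alpha"]], x[["beta"]], x[["gamma"]]))
  invisible(x)
}

#' Test whether a numeric triple satisfies the simplex constraints
#' @param w Numeric vector of length 3.
#' @return Logical scalar.
#' @export
is_valid_tern <- function(w) {
  length(w) == 3L && all(is.finite(w)) && all(w > 0) && all(w < 1) &&
    abs(sum(w) - 1) <= .TERN_SUM_TOL
}

#' Repair a raw weight triple onto the open simplex
#'
#' Minimal projection used after single-point crossover (whose tail swap breaks
#' the sum constraint) and after random initialization: components are clipped
#' into `[1e-6, 1 - 2e-6]` and the triple is divided by its sum, preserving
#' component ratios.
#'
#' @param w Numeric vector of length 3 (raw, possibly infeasible weights).
#' @return A valid `weight_tern`.
#' @export
repair_tern <- function(w) {
  w <- as.numeric(w)
  if (length(w) != 3L || !all(is.finite(w))) {
    stop("constraint-violation error: repair needs 3 finite components",
         call. = FALSE)
  }
  w <- pmin(pmax(w, .TERN_LO), .TERN_HI)
  w <- w / sum(w)
  # a second clip+renormalize pass is never needed: after division every
  # component lies in (lo/3, 1) and the sum is exactly renormalized
  weight_tern(w[1L], w[2L], w[3L])
}

# Run code under a fixed RNG seed without disturbing the caller's RNG state.
with_preserved_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}
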