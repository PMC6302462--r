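#' Compute the minimized Wilson Central Terminal (M-WCT) trace
#'
#' The M-WCT is the weighted mean of the three limb-electrode potentials,
#' \deqn{M\text{-}WCT(t) = \alpha\,\Phi_L(t) + \beta\,\Phi_R(t) + \gamma\,\Phi_F(t),}
#' with weights constrained to the open 2-simplex
#' (\eqn{0 < \alpha, \beta, \gamma < 1}, \eqn{\alpha+\beta+\gamma = 1}).
#' With the uniform tern this reduces to the classical WCT.
#'
#' @param rec A [limb_recording()].
#' @param w A [weight_tern()] (raw numeric triples are validated first).
#' @return A [potential_trace()] with the same length and sample rate as the
#'   input recording.
#' @seealso [compute_wct()], [wct_fitness()]
#' @examples
#' rec <- limb_recording(sin(1:64), cos(1:64), rep(0.5, 64), 800)
#' mw <- compute_mwct(rec, weight_tern(0.2, 0.3, 0.5))
#' @export
compute_mwct <- function(rec, w) {
  stopifnot(inherits(rec, "limb_recording"))
  if (!inherits(w, "weight_tern")) {
    w <- weight_tern(w[1L], w[2L], w[3L])
  }
  v <- w[["alpha"]] * rec$phi_L + w[["beta"]] * rec$phi_R +
    w[["gamma"]] * rec$phi_F
  potential_trace(v, rec$sample_rate)
}

#' Compute the Wilson Central Terminal (WCT) trace
#'
#' The WCT is the simple average of the left-arm, right-arm and left-leg
#' electrode potentials.  Implemented as [compute_mwct()] with the exact
#' uniform tern so both paths share the identical arithmetic order.
#'
#' @param rec A [limb_recording()].
#' @return A [potential_trace()].
#' @export
compute_wct <- function(rec) {
  compute_mwct(rec, uniform_tern())
}

#' Derive Einthoven lead II from limb potentials
#'
#' Lead II is the bipolar limb lead: left leg minus right arm,
#' \eqn{\Phi_F - \Phi_R}.  It serves as the amplitude reference against which
#' WCT and M-WCT excursions are reported.
#'
#' @param rec A [limb_recording()].
#' @return A [potential_trace()].
#' @export
derive_lead_ii <- function(rec) {
  stopifnot(inherits(rec, "limb_recording"))
  potential_trace(rec$phi_F - rec$phi_R, rec$sample_rate)
}

#' GA fitness of a potential trace
#'
#' The fitness of a candidate M-WCT trace is
#' \deqn{\mathrm{Fitness} = \log_{10^{-5}} a, \qquad
#'   a = \max(\overline{|M\text{-}WCT|},\ \mathrm{floor}),}
#' where \eqn{\overline{|\cdot|}} is the mean absolute value over all samples
#' (one scalar per chromosome) and potentials are in volts, so the base
#' \eqn{10^{-5}} V corresponds to 0.01 mV.  The log is strictly decreasing in
#' the aggregate amplitude: larger fitness means a smaller amplitude, and the
#' GA maximizes it.  Its nonlinearity steepens the reward below 0.1 mV, the
#' amplitude regime considered clinically irrelevant.  The floor guards
#' against a log singularity when the trace is exactly zero (possible on
#' noise-free synthetic data) and preserves the ranking of all candidates
#' above it.
#'
#' @param trace A [potential_trace()] or bare numeric vector (V).
#' @param floor Positive amplitude floor in volts (default `1e-12`).
#' @return A single dimensionless fitness value.
#' @examples
#' wct_fitness(potential_trace(rep(1e-5, 10), 800))   # 1
#' wct_fitness(potential_trace(rep(1, 10), 800))      # 0
#' wct_fitness(potential_trace(rep(1e-10, 10), 800))  # 2
#' @export
wct_fitness <- function(trace, floor = 1e-12) {
  v <- if (inherits(trace, "potential_trace")) trace$values else as.numeric(trace)
  if (length(v) < 1L) {
    stop("structural-input error: empty trace", call. = FALSE)
  }
  if (!all(is.finite(v))) {
    stop("structural-input error: trace values must be finite", call. = FALSE)
  }
  if (!is.numeric(floor) || length(floor) != 1L || !is.finite(floor) ||
      floor <= 0) {
    stop("parameter error: floor must be a single positive number",
         call. = FALSE)
  }
  fitness_from_amplitude(max(mean(abs(v)), floor))
}

# log base 1e-5 of an aggregate amplitude already floored away from zero
fitness_from_amplitude <- function(a) {
  log(a) / log(1e-5)
}
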