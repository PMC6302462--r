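#' Detect beats on a lead II trace
#'
#' Fixture-grade R-peak detector used to anchor the amplitude measurements:
#' band-limited differentiation (first difference smoothed over ~10 ms),
#' squaring, moving-window integration over ~80 ms, and adaptive-threshold
#' peak picking with a refractory period.  Fiducials are refined to the local
#' extremum of the (median-centred) trace within the integration window.  Not
#' a clinical-grade detector; validated on synthetic recordings only.
#'
#' @param lead_ii A [potential_trace()] at least 2 s long.
#' @param refractory_s Minimum fiducial spacing in seconds (default 0.25).
#' @param qrs_half_width_s Half width of the QRS window around each fiducial
#'   in seconds (default 0.06).
#' @param threshold_frac Fraction of the maximum integrated energy used as
#'   detection threshold (default 0.3).
#' @return An object of class `beat_set`: list with `fiducials` (strictly
#'   increasing 1-based sample indices), `qrs_windows` (two-column matrix of
#'   inclusive 1-based start/end indices, non-overlapping, within bounds),
#'   `sample_rate` and `quality` (`"ok"` or `"no_beats"`).  A flat or
#'   peak-free trace returns an empty flagged `beat_set`, not an error.
#' @export
detect_beats <- function(lead_ii, refractory_s = 0.25, qrs_half_width_s = 0.06,
                         threshold_frac = 0.3) {
  stopifnot(inherits(lead_ii, "potential_trace"))
  x <- lead_ii$values
  fs <- lead_ii$sample_rate
  n <- length(x)
  if (n / fs < 2) {
    stop("structural-input error: trace must be at least 2 s long",
         call. = FALSE)
  }

  empty <- structure(
    list(fiducials = integer(0L),
         qrs_windows = matrix(integer(0L), ncol = 2L,
                              dimnames = list(NULL, c("start", "end"))),
         sample_rate = fs, quality = "no_beats"),
    class = "beat_set")

  d <- c(0, diff(x)) * fs                       # V/s
  k_smooth <- max(1L, as.integer(round(0.010 * fs)))
  d <- stats::filter(d, rep(1 / k_smooth, k_smooth), sides = 2L)
  d[is.na(d)] <- 0
  energy <- as.numeric(d)^2
  k_int <- max(1L, as.integer(round(0.080 * fs)))
  integ <- as.numeric(stats::filter(energy, rep(1 / k_int, k_int), sides = 2L))
  integ[is.na(integ)] <- 0

  peak <- max(integ)
  if (peak <= 0) return(empty)
  thr <- threshold_frac * peak

  refr <- max(1L, as.integer(round(refractory_s * fs)))
  half <- max(1L, as.integer(round(qrs_half_width_s * fs)))

  above <- integ >= thr
  fiducials <- integer(0L)
  i <- 1L
  xc <- x - stats::median(x)
  while (i <= n) {
    if (above[i]) {
      j <- i
      while (j < n && above[j + 1L]) j <- j + 1L
      seg <- seq.int(i, j)
      center <- seg[which.max(integ[seg])]
      lo <- max(1L, center - half)
      hi <- min(n, center + half)
      fid <- (lo:hi)[which.max(abs(xc[lo:hi]))]
      if (length(fiducials) == 0L || fid - fiducials[length(fiducials)] >= refr) {
        fiducials <- c(fiducials, fid)
      }
      i <- max(j + 1L, fid + refr)
    } else {
      i <- i + 1L
    }
  }
  if (length(fiducials) == 0L) return(empty)

  win <- cbind(start = pmax(1L, fiducials - half),
               end = pmin(n, fiducials + half))
  structure(
    list(fiducials = fiducials, qrs_windows = win, sample_rate = fs,
         quality = "ok"),
    class = "beat_set")
}

#' @export
print.beat_set <- function(x, ...) {
  cat(sprintf("<beat_set> %d fiducials @ %g Hz (%s)\n",
              length(x$fiducials), x$sample_rate, x$quality))
  invisible(x)
}

#' Beat-averaged amplitude as a percentage of lead II
#'
#' For each of the first `n_beats` consecutive full cardiac cycles (fiducial
#' to next fiducial) the peak-to-peak excursion of `trace` and of `lead_ii`
#' is measured; the statistic is
#' \eqn{100 \times \mathrm{mean}(\Delta_{trace}) / \mathrm{mean}(\Delta_{leadII})}.
#' If fewer than `n_beats` full cycles exist the value is computed on all
#' available cycles and flagged.
#'
#' @param trace A [potential_trace()] (e.g. WCT or M-WCT).
#' @param lead_ii The lead II [potential_trace()] (same sampling).
#' @param beats A `beat_set` from [detect_beats()].
#' @param n_beats Number of consecutive beats to average (protocol default 5).
#' @return A single percentage with attributes `n_beats_used` and `flagged`.
#' @export
amplitude_percent_of_lead_ii <- function(trace, lead_ii, beats, n_beats = 5L) {
  stopifnot(inherits(trace, "potential_trace"),
            inherits(lead_ii, "potential_trace"),
            inherits(beats, "beat_set"))
  if (length(trace$values) != length(lead_ii$values)) {
    stop("structural-input error: trace and lead II must have equal length",
         call. = FALSE)
  }
  fid <- beats$fiducials
  n_cycles <- length(fid) - 1L
  if (n_cycles < 1L) {
    stop("structural-input error: need at least two fiducials for one full cycle",
         call. = FALSE)
  }
  used <- min(n_beats, n_cycles)
  p2p_tr <- numeric(used)
  p2p_ld <- numeric(used)
  for (b in seq_len(used)) {
    idx <- seq.int(fid[b], fid[b + 1L] - 1L)
    p2p_tr[b] <- diff(range(trace$values[idx]))
    p2p_ld[b] <- diff(range(lead_ii$values[idx]))
  }
  ref <- mean(p2p_ld)
  if (ref <= 0) {
    stop("degenerate-reference error: lead II excursion is zero", call. = FALSE)
  }
  structure(100 * mean(p2p_tr) / ref,
            n_beats_used = used, flagged = used < n_beats)
}

#' QRS-orientation polarity of a trace
#'
#' Within each QRS window the maximal positive deflection \eqn{P} and maximal
#' negative deflection \eqn{|N|} are measured from the window baseline (the
#' median of the window's first and last `edge_ms` milliseconds); per-beat
#' deflections are aggregated by the median across beats.  The label is
#' `"positive"` if \eqn{P > r\,|N|}, `"negative"` if \eqn{|N| > r\,P} and
#' `"N"` (unclear: the positive deflection closely matches the negative one)
#' otherwise, with ratio threshold `r` defaulting to 1.2.
#'
#' @param trace A [potential_trace()].
#' @param beats A `beat_set` with at least one QRS window.
#' @param ratio_threshold Dominance ratio `r` (default 1.2).
#' @param edge_ms Baseline edge-segment length in milliseconds (default 10).
#' @return `"positive"`, `"negative"` or `"N"`, with attribute `deflections`
#'   (named vector of the aggregated P and |N|).  An empty beat set returns
#'   `"unclassifiable"`.
#' @export
classify_polarity <- function(trace, beats, ratio_threshold = 1.2,
                              edge_ms = 10) {
  stopifnot(inherits(trace, "potential_trace"), inherits(beats, "beat_set"))
  nw <- nrow(beats$qrs_windows)
  if (nw < 1L) {
    return(structure("unclassifiable",
                     deflections = c(P = NA_real_, N = NA_real_)))
  }
  edge_n <- max(1L, as.integer(round(edge_ms / 1000 * trace$sample_rate)))
  P <- numeric(nw)
  Nn <- numeric(nw)
  for (b in seq_len(nw)) {
    idx <- seq.int(beats$qrs_windows[b, 1L], beats$qrs_windows[b, 2L])
    x <- trace$values[idx]
    m <- length(x)
    k <- min(edge_n, m)
    baseline <- stats::median(c(x[seq_len(k)], x[seq.int(m - k + 1L, m)]))
    P[b] <- max(x) - baseline
    Nn[b] <- baseline - min(x)
  }
  Pm <- stats::median(P)
  Nm <- stats::median(Nn)
  label <- if (Pm > ratio_threshold * Nm) "positive"
           else if (Nm > ratio_threshold * Pm) "negative"
           else "N"
  structure(label, deflections = c(P = Pm, N = Nm))
}

#' Full amplitude report for a recording and a weight tern
#'
#' Runs the complete measurement protocol: derives lead II, detects beats,
#' measures the WCT and M-WCT amplitudes over five consecutive beats as a
#' percentage of lead II, and classifies the QRS polarity of both traces.
#'
#' @param rec A [limb_recording()].
#' @param tern The minimizing [weight_tern()] (e.g. `run_ga(rec, cfg)$best_tern`).
#' @param n_beats Beats to average (default 5).
#' @return An object of class `amplitude_report`: list with
#'   `wct_percent_of_lead_ii`, `mwct_percent_of_lead_ii`, `n_beats_used`,
#'   `quality_flag`, `wct_polarity`, `mwct_polarity`.
#' @export
amplitude_report <- function(rec, tern, n_beats = 5L) {
  stopifnot(inherits(rec, "limb_recording"))
  lead_ii <- derive_lead_ii(rec)
  beats <- detect_beats(lead_ii)
  wct <- compute_wct(rec)
  mwct <- compute_mwct(rec, tern)
  if (beats$quality != "ok" || length(beats$fiducials) < 2L) {
    return(structure(
      list(wct_percent_of_lead_ii = NA_real_,
           mwct_percent_of_lead_ii = NA_real_,
           n_beats_used = 0L, quality_flag = "no_beats",
           wct_polarity = "unclassifiable",
           mwct_polarity = "unclassifiable"),
      class = "amplitude_report"))
  }
  wct_pct <- amplitude_percent_of_lead_ii(wct, lead_ii, beats, n_beats)
  mwct_pct <- amplitude_percent_of_lead_ii(mwct, lead_ii, beats, n_beats)
  structure(
    list(wct_percent_of_lead_ii = as.numeric(wct_pct),
         mwct_percent_of_lead_ii = as.numeric(mwct_pct),
         n_beats_used = attr(wct_pct, "n_beats_used"),
         quality_flag = if (attr(wct_pct, "flagged")) "short_recording" else "ok",
         wct_polarity = as.character(classify_polarity(wct, beats)),
         mwct_polarity = as.character(classify_polarity(mwct, beats))),
    class = "amplitude_report")
}

#' @export
print.amplitude_report <- function(x, ...) {
  cat(sprintf(
    paste0("<amplitude_report> WCT %.2f%% of lead II (%s), ",
           "M-WCT %.2f%% (%s), %d beats [%s]\n"),
    x$wct_percent_of_lead_ii, x$wct_polarity,
    x$mwct_percent_of_lead_ii, x$mwct_polarity,
    x$n_beats_used, x$quality_flag))
  invisible(x)
}
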