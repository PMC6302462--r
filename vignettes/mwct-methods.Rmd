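---
title: "Minimizing the Wilson Central Terminal: model, algorithm and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Minimizing the Wilson Central Terminal: model, algorithm and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mwct)
```

## The problem

The six precordial leads of the 12-lead ECG are measured against the Wilson
Central Terminal (WCT), the simple average of the three limb-electrode
potentials

$$WCT(t) = \tfrac{1}{3}\left(\Phi_L(t) + \Phi_R(t) + \Phi_F(t)\right),$$

where $\Phi_L$, $\Phi_R$, $\Phi_F$ are the raw potentials at the left arm,
right arm and left leg.  The WCT is conventionally assumed to be near zero
and steady over the cardiac cycle, but in practice it is neither: it can carry
a substantial fraction of the amplitude of the bipolar limb leads and its
morphology is highly individual.  Because every subject has different limb
geometry and tissue conductivity, no fixed reweighting works for everyone —
the weights themselves must be fitted per subject.

This package searches for a *minimized* terminal

$$M\text{-}WCT(t) = \alpha\,\Phi_L(t) + \beta\,\Phi_R(t) + \gamma\,\Phi_F(t),
\qquad 0 < \alpha, \beta, \gamma < 1,\quad \alpha + \beta + \gamma = 1,$$

i.e. the point on the open probability 2-simplex whose weighted mean has
minimal amplitude.  The open-interval constraint matters physically: each
weight corresponds to a positive, finite averaging resistor, so boundary
values are rejected, not merely discouraged.

## Fitness

A chromosome is scored by

$$\mathrm{Fitness} = \log_{10^{-5}}\!\big(\max(\overline{|M\text{-}WCT|},\ \mathrm{floor})\big),$$

with $\overline{|\cdot|}$ the mean absolute value over all samples of the
excerpt.  Larger fitness means smaller amplitude and the GA maximizes it.
Three numerical choices deserve a note:

* **Aggregation.** The score needs one scalar per chromosome while the
  objective is a whole trace; we aggregate as the mean absolute amplitude
  before taking the log.  The log is monotone, so the minimizer of the
  aggregate is unchanged by the choice of base.
* **Units.** Potentials are stored in volts throughout (files, fitness,
  reports), and the base $10^{-5}$ is interpreted on the volt scale
  ($10^{-5}\,\mathrm{V} = 0.01\,\mathrm{mV}$).  The base only rescales fitness
  monotonically; fixing a single unit policy keeps reported fitness values
  comparable and keeps the ambiguity out of the data files.
* **Floor.** On noise-free synthetic data the aggregate can be exactly zero,
  which would make the log infinite; the aggregate is floored at
  $10^{-12}$ V (well below any physical signal), which preserves ranking and
  keeps fitness finite.

## The genetic algorithm

Each chromosome is a weight tern $(\alpha, \beta, \gamma)$.  Per generation:

1. **Evaluation** of all chromosomes' fitness (vectorized as one
   matrix product per generation).
2. **Elitism**: the 2 fittest chromosomes are copied unchanged.  The
   protocol says "the elite members" without a count; 2 is the smallest
   plural consistent with that phrasing.
3. **WCT preservation**: the exact uniform tern $(1/3, 1/3, 1/3)$ is
   re-inserted into every generation.  Together with elitism this yields a
   structural guarantee: the best tern can never be worse than the classical
   WCT.
4. **Selection**: tournament of size 2 (each parent is the fitter of two
   uniform draws, ties broken at random).  The selection operator is not
   specified by the protocol; tournaments are invariant under monotone
   rescaling of fitness, which matters because the log-scale fitness is
   routinely negative and would break naive roulette-wheel weighting.
5. **Crossover**, chosen per pair with probability 0.5 each (the protocol
   says "randomly" without a share):
   * *single point*: a cut after gene 1 or 2, tails swapped.  The swap breaks
     the sum constraint, so children are repaired: components clipped into
     $[10^{-6}, 1 - 2\times10^{-6}]$, then divided by their sum — the minimal
     projection that preserves component ratios.  (Whether the original
     protocol repaired or rejected infeasible children is unstated; repair
     wastes no evaluations.)
   * *averaging*: the component-wise midpoint, which stays on the simplex by
     convexity and needs no repair.
6. **Mutation**: with probability 0.1 a chromosome's three weights are
   reordered by a uniformly drawn non-identity permutation.  The probability
   is applied once per chromosome (reading of "a selected chromosome"), not
   per gene.  Permutations preserve both constraints automatically and jump
   between faces of the simplex, which is the operator's anti-local-optimum
   role.

**Stopping.** The protocol reports an iteration count but no stopping rule.
We stop when best fitness improves by less than $10^{-6}$ over 30 consecutive
generations, capped at 500 generations.  This is reproducible and lands in
the same order of magnitude of generations as the published convergence
counts; we report generations and do not treat the published count (whose
definition — generations or evaluations — is unstated) as a target.

**Modes.** The primary mode fits one tern per excerpt: a single tern is the
only result that maps onto fixed replacement resistors, which is the stated
motivation for minimizing the terminal.  A windowed mode
(`run_ga_windowed()`) additionally reproduces the "average of the weighting
parameters across the excerpt" reporting style: the GA runs independently per
non-overlapping window and the component-wise average tern (renormalized) is
reported alongside the per-window results.  Which of the two the original
study used sample-by-sample is ambiguous; both are provided.

**Determinism.** A seed in `ga_config()` makes the entire run bit-for-bit
reproducible; the global RNG state of the caller is saved and restored, so
library calls do not perturb user scripts.

## The grid-search oracle

`grid_search_oracle()` exhaustively evaluates the aggregate amplitude on the
lattice $\{(is, js, 1 - is - js)\}$ and returns the minimizer.  It shares
nothing with the GA except the amplitude definition, so it serves as an
independent check that the GA reaches (or beats, by refinement below the
lattice spacing) the global optimum.  Lattice points on the closed-simplex
boundary are pushed through the same clip-and-renormalize repair as GA
chromosomes: at fine steps this coincides with the open-simplex lattice, and
at coarse steps it keeps the candidate set non-empty.  Ties resolve to the
first candidate in row-major order, making the oracle fully deterministic.

## Measurement protocol

Amplitudes are reported the way the terminal's clinical relevance is judged:
averaged over **five consecutive beats** and expressed as a **percentage of
lead II** (Einthoven convention, $\Phi_F - \Phi_R$; the standard assumption,
since lead II is not defined from raw potentials anywhere in the protocol).

* **Beat detection** (`detect_beats()`) anchors the measurements: smoothed
  differentiation, squaring, 80 ms moving-window integration,
  adaptive-threshold peak picking with a 250 ms refractory period, QRS
  windows of ±60 ms.  These are standard physiological bounds, supplied here
  because the protocol assumes beats are identifiable without giving a
  detector.  It is a fixture-grade component validated on synthetic data
  only — not an arrhythmia-safe clinical detector.
* **"Amplitude"** is undefined in the protocol; we use the peak-to-peak
  excursion within each full beat cycle (fiducial to next fiducial), which is
  how ECG trace amplitudes are conventionally compared and stays well-defined
  for multiphasic WCT shapes.  The reference is beat-matched: trace and lead
  II excursions are measured over the same five cycles (the first five
  complete consecutive cycles — a deterministic choice), then averaged
  separately and divided.
* **Polarity** follows QRS orientation: within each QRS window the maximal
  positive deflection $P$ and maximal negative deflection $|N|$ are measured
  from the window baseline (median of the first and last 10 ms of the window,
  robust to drift), aggregated by median across beats.  The label is
  positive if $P > 1.2\,|N|$, negative if $|N| > 1.2\,P$, otherwise `"N"`
  ("unclear polarity", closely matched deflections).  The 1.2 ratio makes the
  qualitative "closely matched" criterion explicit and is configurable.

## The synthetic-data generator

The recordings the minimization protocol was developed on are not publicly
deposited, so the package ships a first-class generator
(`generate_recording()`, `generate_cohort()`) that emulates their structure
with a *planted ground truth*:

* A 3-D **equivalent cardiac dipole** $d(t)$ is built as a sum of Gaussian
  P-QRS-T wavelets per beat on each axis.  The wavelet centers are staggered
  across the three axes (the dipole traces a rotating loop, as a real heart
  vector does, rather than beating along a fixed direction).  This staggering
  is load-bearing: it keeps the three axis signals linearly independent over
  time, so exactly one point of the simplex nulls the dipole contribution and
  the planted tern is a well-conditioned minimizer.  With collinear axis
  signals the amplitude landscape develops a flat valley and no method — GA
  or exhaustive search — could identify the weights.
* Lead vectors: $l_L$ and $l_R$ are free parameters; the left-leg vector is
  constructed as $l_F = -(\alpha^* l_L + \beta^* l_R)/\gamma^*$, which makes
  the planted tern $(\alpha^*, \beta^*, \gamma^*)$ null the dipole part of
  the weighted mean *exactly*.  Each limb potential is $l_i \cdot d(t)$ plus
  independent per-electrode baseline drift (a sinusoid below 0.5 Hz with
  random frequency and phase) and white noise.  Per-electrode disturbances
  are deliberately independent: common-mode components cancel in every
  weighted mean, and it is precisely the *common-mode-breaking* components
  that make the real WCT nonzero.
* The default lead geometry was chosen once so that (a) lead II has a
  conventional positive-R morphology of a few millivolts peak-to-peak,
  (b) the classical WCT carries tens of percent of lead II on typical
  cohort draws — a sizeable contrast for the GA to reduce, overlapping the
  spread reported for real patients — and (c) all three weights remain
  well-identified (an over-shrunken right-arm vector makes $\beta$ nearly
  unidentifiable).  No claim is made that any synthetic subject matches a
  real one; individual limb-potential morphologies were never published, so
  only these aggregate properties are emulated.
* **Cohorts** draw per-subject terns from a Dirichlet(1, 1, 2) (left-leg
  weight biased upward, consistent with the published observation that
  $\gamma$ is usually largest), rejected until $\gamma/\alpha \in
  [0.78, 5.69]$ and $\gamma/\beta \in [0.62, 5.69]$ — the published
  cohort ranges — and until every component is at least 0.05, because a
  planted $\gamma^*$ near zero blows up the derived $l_F$ (degenerate
  geometry the generator otherwise rejects with an error).  Heart rates are
  uniform in 50–100 bpm.  By default each subject's noise standard deviation
  is calibrated to 1% of that subject's clean lead II peak-to-peak.
* Defaults elsewhere follow the stated recording conditions: 10 s excerpts
  at 800 Hz (8000 samples), 60 bpm for single recordings.

**What a green test does and does not establish.**  Synthetic recordings are
stationary, single-morphology, artifact-free and exactly uniformly sampled;
the planted tern exists by construction.  Green acceptance tests therefore
establish that the optimizer, metrics and I/O behave as specified on signals
with known structure — they do not certify performance on pathological
rhythms, electrode motion artifacts, ectopic beats or any real patient
cohort, and the published per-patient percentages are not reproducible
without the original recordings.

## Worked example

```{r example, eval = FALSE}
sim <- generate_recording(synth_params(seed = 1))
res <- run_ga(sim$recording, ga_config(seed = 1))
amplitude_report(sim$recording, res$best_tern)
```

## Known limitations

* The beat detector is fixture-grade (see above).
* The GA re-fits a full excerpt; no streaming/real-time mode is provided.
* Crossover/mutation schedules are fixed, as in the published protocol.
* File ingestion is limited to the package's CSV dialect; waveform-database
  readers are an extension point, not implemented.
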