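# mwct — genetic-algorithm minimization of the Wilson Central Terminal

The Wilson Central Terminal (WCT) is the artificial "zero" reference used for
the six precordial leads of the 12-lead ECG: the simple average of the three
limb-electrode potentials,

    WCT(t) = (Φ_L(t) + Φ_R(t) + Φ_F(t)) / 3,

with Φ_L, Φ_R, Φ_F the raw potentials at the left arm, right arm and left
leg.  The WCT is assumed to be steady and negligible over the cardiac cycle,
but it is neither — it can carry a large fraction of the amplitude of lead
II, and its shape and polarity differ from person to person.

`mwct` is for biomedical-signal researchers who want to quantify and minimize
that reference.  It searches the open probability 2-simplex for the weight
tern (α, β, γ) whose weighted mean — the minimized terminal

    M-WCT(t) = α Φ_L(t) + β Φ_R(t) + γ Φ_F(t),
    0 < α, β, γ < 1,    α + β + γ = 1

— has minimal amplitude, using a constrained genetic algorithm: population of
80 terns, one initialized at the WCT chromosome (1/3, 1/3, 1/3) and preserved
in every generation, elitism, tournament selection, single-point and
averaging crossover chosen at random, permutation mutation with probability
0.1, and the nonlinear fitness

    Fitness = log_1e-5 ( mean |M-WCT| )      (potentials in volts)

which the GA maximizes (larger fitness = smaller amplitude).  Results are
reported the way the terminal's clinical relevance is judged: amplitude
averaged over five consecutive beats as a percentage of lead II, plus QRS
polarity labels (positive / negative / "N" for closely matched deflections).

The package also ships:

* a synthetic limb-potential generator (equivalent cardiac dipole projected
  onto per-limb lead vectors, with drift and noise) that **plants a known
  ground-truth tern**, standing in for the undeposited clinical recordings;
* a brute-force grid-search oracle for independent verification of the GA;
* a windowed mode reporting across-window averaged weights;
* CSV/JSON/YAML interchange and two CLI entry points.

## Worked example

```r
library(mwct)

sim <- generate_recording(synth_params(seed = 1))   # 10 s @ 800 Hz
sim
#> <synthetic_recording> 'synthetic': 8000 samples @ 800 Hz, planted tern (0.200, 0.200, 0.600)

res <- run_ga(sim$recording, ga_config(seed = 1))
res
#> <ga_result> mode global: best tern (0.1986, 0.2021, 0.5993), fitness 1.0089 (mean|M-WCT| = 9.03e-06 V), 49 generations

amplitude_report(sim$recording, res$best_tern)
#> <amplitude_report> WCT 31.86% of lead II (negative), M-WCT 1.76% (N), 5 beats [ok]
```

Reading the numbers: the recording was synthesized so that the tern
(0.2, 0.2, 0.6) exactly nulls the cardiac-dipole contribution; the GA
recovers it to within ~0.002 from the signal alone.  The classical WCT of
this subject swings through 31.9% of the lead II peak-to-peak amplitude
(averaged over five beats) with a net negative QRS orientation; the minimized
terminal is reduced to 1.8% of lead II — below the mean |M-WCT| of
9×10⁻⁶ V ≈ 0.01 mV, fitness ≈ 1 — with deflections too balanced to call a
polarity ("N").

Command-line equivalents:

```sh
Rscript -e 'mwct::cli_synth()' --n 3 --seed 5 --output-dir data/
Rscript -e 'mwct::cli_minimize()' --input data/recording_001.csv \
    --seed 17 --output result.json
```

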