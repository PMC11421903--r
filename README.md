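# rumblesig

Do elephant rumbles carry group signatures? Female African elephants live
in a nested multi-level society — core groups led by a matriarch, bond
groups of affiliated core groups, populations — and their low-frequency
harmonic rumbles might converge acoustically within social units if
elephants learn call structure from each other. `rumblesig` implements the
complete analysis for that question at four nested levels, together with a
synthetic-data generator that plants known signatures so the whole pipeline
is testable without field recordings.

It is written for bioacousticians and behavioural ecologists who want a
reusable, validated version of this workflow:

1. **Synthetic data** (`generate_dataset()`): nested caller hierarchy,
   per-call harmonic-stack waveforms whose second-harmonic (f1) contour is
   `base + context + population + bond + core + individual + age·slope +
   noise`, a tiered sighting table, and a dyadic relatedness table.
2. **Acoustic features** (`extract_features()`): 94 amplitude-invariant
   mel-spectrogram features plus 9 summary statistics of the traced f1
   contour (dynamic-programming ridge tracking, 14–80 Hz band).
3. **Social tiers** (`infer_tiers()`): simple-ratio association indices
   `x/(x + yA + yB)` (individuals seen < 20 times excluded), Ward
   clustering on `1 − index`, automated knot detection on the
   cumulative-bifurcation curve to cut core groups, repeated on matriarchs
   for bond groups.
4. **Classification experiments** (`run_experiment()`): random forests
   (500 trees, 6 variables/node, 60% of observations/tree, no depth limit)
   with leakage-proof repeated splits — whole callers, whole core groups,
   or whole caller-dates held out — scored against a majority (zero-rate)
   classifier with a one-tailed exact binomial test per iteration and
   medians across iterations.
5. **Call similarity** (`run_similarity()`): 8000-tree full-data forests
   give node-size-adjusted proximity scores
   `score(i,j) = (1/T) Σ_t [leaf_t(i) = leaf_t(j)] / size_t`; same-context,
   different-caller pairs (+ 0.00001 offset) enter gamma log-link mixed
   models with a caller-dyad random intercept, pair-class and
   age-difference fixed effects, Tukey-adjusted post hoc contrasts, and a
   social-vs-genetic variant adding dyad relatedness.

## Worked example

The `analysis/` scripts run the whole workflow at desk scale (two
populations × 12 callers, 8 calls each, 300 iterations per experiment):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_features.R
Rscript analysis/03_social_structure.R
Rscript analysis/04_classification.R
Rscript analysis/05_similarity.R
```

Stage 3 prints, for the simulated sighting data,

```
association matrix over 24 individuals (median index 0.009)
inferred 12 core groups (cut 0.817) in 5 bond groups
recovery vs ground truth: core ARI = 1.000, bond ARI = 0.785
```

i.e. the clustering recovers the planted core groups exactly (adjusted
Rand index 1), while bond groups — inferred from only six matriarchs under
imperfect daily detection — come close but not perfectly at this scale.
Stage 4 prints one block per experiment, e.g.

```
<experiment_result> level=population  n_calls=205  n_iter=300
  median accuracy 0.649 vs baseline 0.438 (median p = 0.008472)
  test fraction 0.16 +/- 0.03
<experiment_result> level=core  n_calls=103  n_iter=300
  median accuracy 0.100 vs baseline 0.140 (median p = 0.8364)
  test fraction 0.50 +/- 0.05
```

read: population identity is classified well above the majority-classifier
baseline (the planted 3 Hz population offset is detected), while core-group
signatures — planted at only 1 Hz s.d. against 2 Hz individual variation —
stay at baseline, the qualitative pattern expected when individual
signatures dominate group signatures. Stage 5 then shows that calls from
the same core group are nonetheless more *similar* than calls from
different bond groups (same-core coefficient 1.17 on the log scale,
pair-class χ² = 53.1, p < 0.0001; post hoc same-core vs different-bond
contrast p < 0.0001, same-bond vs different-bond p = 0.61) and that, with
relatedness decoupled from group membership in the simulation, the social
term (p < 0.0001), not the genetic one (p = 0.72), carries the signal.

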