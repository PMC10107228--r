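# scansync

Group-level behavioural synchrony analysis for scan-sampled animal groups,
including mixed-species groups (MSGs).

## The problem

Ethologists often record group activity by **instantaneous scan sampling**:
at predefined moments, the current behaviour of every visible group member
is noted (one "scan" = one snapshot). Two questions follow naturally:

1. **Within a species** — are group members performing the same behaviour
   at the same time more often than their overall activity budget alone
   would predict?
2. **Between species sharing a group** — do the two species coordinate
   their behaviour, or does the mixed group merely co-occur in space?

Both questions resist classical tests (scan records are not independent),
so `scansync` answers them with randomization tests.

## The statistics

**Within-species synchrony.** Each scan is scored with Simpson's diversity
index over its behaviour counts,

```
BS = Σᵢ nᵢ(nᵢ − 1) / (N(N − 1)),
```

where `nᵢ` is the number of visible individuals engaged in behaviour `i`
(five analysed categories: vigilant, foraging, locomotion, resting,
playing) and `N = Σᵢ nᵢ`. `BS` is exactly the probability that two randomly
chosen visible individuals share a behaviour: 1 = perfect synchrony,
0 = complete asynchrony. The observed mean `BS` is compared against a
**weighted-resampling null**: each scan is regenerated by drawing its `N`
behaviours independently from the species' sampling weights (its marginal
activity budget `pᵢ`), 1000 datasets are generated, and the permutation
p-value is the proportion of null mean scores at least as extreme as the
observed mean. Under this null `E[BS] = Σᵢ pᵢ²`, independent of `N`.

**Between-species synchrony.** For each behaviour, the per-scan frequency
series of the two species are correlated (Pearson r). The null treats the
mixed-species group as *one* group: within every scan both species'
behaviours are pooled, shuffled uniformly, and re-split by the original
species counts (a scan `AAAABBC` split 4/3 might become `BAAA` / `BCA`);
the five same-behaviour correlations are recomputed per shuffled dataset,
1000 times. Observed correlations significantly *below* this null indicate
that the species are less coordinated than a single merged group would be.

A latent-state synthetic generator (`synthetic_config()` /
`generate_scans()`) with tunable within-species coupling `κ_w` and
between-species coupling `κ_b` makes every stage testable end to end; its
closed form `E[BS] = κ² + (1 − κ²)Σpᵢ²` also gives a coupling estimator
(`recover_kappa()`).

## Worked example

```r
library(scansync)

sim    <- generate_scans(synthetic_config(seed = 1))  # 180 scans, 2 groups
report <- run_analysis(sim$scans, n_iterations = 1000, seed = 42)
report
```

```
Behavioural synchrony analysis (180 scans, 5490 records)

  mean BS [capuchin]: 0.388 (s.d. 0.137, 180 scans)
  mean BS [squirrel]: 0.497 (s.d. 0.198, 180 scans)
  mean BS [combined]: 0.387 (s.d. 0.124, 180 scans)

Within-species permutation tests:
  capuchin: observed 0.388 vs null 0.300 [0.280, 0.321], p (greater) = < 1e-04
  squirrel: observed 0.497 vs null 0.414 [0.380, 0.454], p (greater) = < 1e-04

Between-species shuffle-split test (mode = proportion):
  behaviour observed_r null_mean null_sd null_max null_min n_undefined p_value
1 V            0.0541      0.487  0.0399    0.602    0.359           0       0
2 F           -0.00170     0.502  0.0419    0.624    0.346           0       0
3 L           -0.0344      0.467  0.0497    0.635    0.267           0       0
4 R           -0.0414      0.510  0.0473    0.663    0.285           0       0
5 P           -0.0376      0.447  0.0626    0.623    0.193           0       0
```

Reading this: both species are far more synchronous within species than
their activity budgets predict (observed mean 0.388 vs a null grand mean of
0.300 for capuchins; 0.497 vs 0.414 for squirrel monkeys; no null dataset
reached the observed mean, so p < 0.001), while every observed
between-species correlation lies below the pooled-shuffle null — the two
species behave as distinct groups rather than one. `tidy()` and `glance()`
return these tables as tibbles; `autoplot()` draws the null histograms and
the 5×5 correlation heatmap; `write_report()` emits `report.json`,
`table2.csv`, `matrix.csv`, `per_scan_scores.csv` and `null_draws.csv`.

A thin command-line wrapper is installed at
`system.file("scripts", "scansync.R", package = "scansync")` with verbs
`simulate` and `analyze`.

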