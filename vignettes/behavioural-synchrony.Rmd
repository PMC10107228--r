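---
title: "Behavioural synchrony from scan samples: models, nulls and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Behavioural synchrony from scan samples}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scansync)
```

## The data model

`scansync` analyses instantaneous scan samples of a two-group, two-species
system (capuchins and squirrel monkeys housed as mixed-species groups in a
west and an east exhibit): one record per individual per scan, with a
behaviour code from a seven-token vocabulary. Five categories are analysed
— vigilant (V), foraging (F), locomotion (L), resting (R), playing (P).
`OOS` (out-of-sight) and `OTHER` are legal records but contribute to no
statistic anywhere: an unseen animal carries no behavioural information,
and activities outside the five analysed categories are excluded before
weights, synchrony scores and correlations are computed. All scans sharing
an id belong to one group, and `(scan_id, individual_id)` pairs are unique;
violations are rejected at ingest with row-level diagnostics rather than
coerced.

`scan_compositions()` reduces records to per-scan, per-species counts over
the five behaviours. A species that was scanned but has no visible
individual in a scan is kept as an `n_visible = 0` row: different
statistics need different minimum-N rules, so dropping happens
per-statistic, never at ingest.

## Within-species synchrony

Each composition is scored with Simpson's diversity over its counts,
\[
BS = \frac{\sum_i n_i (n_i - 1)}{N (N - 1)},
\]
the probability that two distinct visible individuals drawn at random
share a behaviour. **Minimum-N rule:** with \(N < 2\) the denominator
vanishes and no pair exists, so the score is undefined (`NA`) and the scan
is excluded from means, standard deviations and null generation. A
single-scan series reports s.d. 0 (there is no dispersion to estimate).

The null asks what mean synchrony the species' *marginal activity budget*
alone would produce. The sampling weights \(p_i\) are the proportions of
each behaviour over all of a species' analysed records, pooled over the
west and east groups (one budget per species — per-group budgets differed
only in the third decimal in the data we emulate, and a single vector is
what the reference analysis uses). Each null iteration regenerates every
scan by drawing its \(N\) behaviours independently with probabilities
\(p_i\) (each scan's observed visible total is preserved) and records the
unweighted mean of the per-scan scores; 1000 iterations form the null
distribution of the mean. Under this scheme
\(E[BS] = \sum_i p_i^2\) for every \(N \ge 2\), which
`expected_synchrony()` exposes in closed form and the test suite verifies
by exhaustive multinomial enumeration at \(N = 3\).

Two details worth making explicit:

* `expected_synchrony()` uses a supplied weights vector exactly as given.
  Published budgets are typically rounded and sum to slightly less than 1;
  the literal sum of squares is what such a vector implies. When the same
  rounded vector is used to *simulate* (via `as_sampling_weights()`), it is
  renormalized, shifting the null grand mean by under 0.001 — far inside
  Monte-Carlo error at 1000 iterations.
* The per-iteration summary is the unweighted mean over scans (not an
  N-weighted mean), matching how the observed series is summarised.

**P-values.** `permutation_pvalue()` implements the proportion-as-extreme
rule with ties counted as extreme and no continuity correction: if 90% of
null values lie strictly below the observed statistic, p = 0.10. The
headline within-species direction is `"greater"` (is the group more
synchronized than its budget predicts?); both one-sided values are always
reported. With 1000 iterations the smallest resolvable p is 0.001, so a
reported 0 means "below the null's resolution", printed as p < 1e-04.

**Calibration.** When the null is simulated from the *true* generating
budget, observed and null means are exchangeable under the no-coupling
model and the test holds its nominal level exactly (the acceptance suite
measures the rejection rate at \(\alpha = 0.05\) over 500 replicate
datasets). The default pipeline, like the reference analysis it
implements, *estimates* the weights from the same data. That plug-in step
conditions the null on the observed marginal frequencies and makes the
test conservative — its measured type-I error at the study's scale is far
below 0.05. The suite therefore asserts exact calibration for the
known-weights variant and an upper bound (never anti-conservative) for the
plug-in variant. Users should read non-significant plug-in results as
"no evidence", not as a calibrated 5% test.

## Between-species synchrony

Per behaviour and species, the across-scan frequency series is either the
proportion of visible individuals engaged in the behaviour (default;
comparable across unequal group sizes, here 35 capuchins vs 26 squirrel
monkeys) or the raw count. Proportions are undefined when a species has no
visible individual; such scans are dropped pairwise, never imputed as 0.
Pearson correlations are computed per group over the scans where both
species appear, then aggregated across the two groups by the unweighted
mean of coefficients (`mean_r`, default) or by Fisher-z averaging
(`fisher_z`); reports always name the mode and aggregation because the
choice is not neutral. Cells where either series has zero variance — the
near-absent squirrel-monkey playing category makes this a live concern —
or where a group has fewer than three paired scans are flagged undefined.

The null treats the mixed-species group as one group. For every scan, the
two species' visible behaviours are pooled into one list, shuffled by a
uniform random permutation, and re-split positionally: the first block (of
the original capuchin count) returns to the capuchins, the remainder to
the squirrel monkeys. The pooled multiset and both species' sizes are
conserved exactly. Each of the 1000 iterations shuffles every scan
independently and recomputes the five same-behaviour correlations with the
same per-group aggregation, yielding 5 × 1000 null correlations. The
default test direction is `"less"`: coordination *below* the pooled null
means the species behave as distinct groups.

The production implementation permutes all scans of an iteration in one
vectorized pass (a single within-scan ordering by random keys, with a
precomputed positional species mask); the suite cross-checks its null
means against a literal scan-by-scan `shuffle_split()` re-implementation,
and checks the shuffle itself against an exhaustive enumeration of split
outcomes on a small multiset (chi-squared, including the
shuffle-twice-equals-shuffle-once distributional identity).

## The synthetic generator

`generate_scans()` draws from the simplest latent-state model that gives
independent control of within- and between-species synchrony with a
closed-form mean:

1. per scan, a capuchin latent behaviour is drawn from the capuchin budget;
2. with probability \(\kappa_b\) the squirrel-monkey latent copies it,
   otherwise it is drawn from the squirrel-monkey budget (capuchin-led
   coupling by default — squirrel monkeys are the species described as
   responding to capuchin cues; `symmetric_coupling = TRUE` randomizes the
   leader per scan);
3. each individual adopts its species latent with probability
   \(\kappa_w\), else draws independently from its species budget;
4. each individual is out-of-sight independently with probability
   `p_oos`, emitted as an `OOS` record.

Two individuals of a species match surely if both copied the latent
(\(\kappa_w^2\)) and with probability \(\sum_i p_i^2\) otherwise, so
\[
E[BS] = \kappa_w^2 + (1 - \kappa_w^2)\sum_i p_i^2 ,
\]
which `expected_bs_under_model()` exposes and `recover_kappa()` inverts.
The defaults are fixed once to emulate the study system: group sizes 18/9
(west) and 17/17 (east), 180 scans split equally, the published budgets
(capuchins 0.468, 0.234, 0.118, 0.106, 0.073; squirrel monkeys 0.608,
0.152, 0.126, 0.111, 0.002; renormalized), \(\kappa_w\) = 0.37
(capuchins) and 0.38 (squirrel monkeys) — the values the closed form
implies for the reported observed-vs-null mean synchrony levels of that
system — \(\kappa_b = 0\) (the reference finding is between-species
asynchrony), and `p_oos` = 0.15, a realistic captive-scan
out-of-sight rate (the reference reports none, and visibility matters only
through per-scan totals). A `GenerationTrace` (per-scan latents,
per-individual copy and out-of-sight indicators) fully determines the
emitted dataset, which the suite verifies by reconstruction.

What the generator deliberately does **not** model: circadian or husbandry
rhythms, between-scan autocorrelation, enclosure geometry or spatial
out-of-sight clustering, and age/sex structure. Passing tests therefore
show that the statistics behave correctly under controlled coupling — not
that real scan data meet the generator's independence assumptions. The
permutation framework itself is what licenses inference on real,
serially-dependent data.

## Pipeline, seeding and reports

`run_analysis()` chains validation → frequencies → budgets → synchrony
series (each species and the combined group) → within-species tests →
cross-species test. The "combined" mean synchrony sums the two species'
counts per scan before scoring — the adopted reading of a compiled
mixed-group score, and reports label it as such. Synchrony summaries are
emitted both pooled across groups (the headline numbers) and per group.

One master seed expands deterministically into named per-stage substreams
(`expand_seed()`), so stages can be rerun independently and the whole
report is byte-identical under an identical input, configuration and seed
(no timestamps are written). All RNG use restores the caller's state.
Every excluded quantity — minimum-N scans, missing-species scans,
zero-variance cells — is counted and surfaced in the report rather than
silently absorbed.

## Problem sizes used by the test suite

The suite exercises the pipeline at the emulated study scale (180 scans,
61 individuals) where the claim concerns that scale — null grand means at
1000 iterations, coupling recovery over 100 replicate datasets, type-I
calibration over 500 replicates at 400-iteration nulls (granularity
0.0025), and the qualitative strong-coupling replication at 1000
iterations — and at smaller sizes (16–60 scans, a few hundred shuffle
iterations) for cross-implementation and property checks, with fixed seeds
throughout. These sizes are the package's own precision choices: they keep
Monte-Carlo error well inside each assertion's tolerance.

## Known limitations

* No time-lagged cross-correlation: the scan index is not a time axis here.
* No individual-level or dyadic synchrony indices; all statistics are
  group-level.
* The observed-data reference summaries (mean synchrony 0.395/0.398/0.506
  and the five observed cross-correlations) can only be recomputed from
  the study's own supplementary scan table; `replicate_observed_targets()`
  runs the mode/aggregation search when given such a table and signals a
  typed condition otherwise.
* Fisher-z aggregation clamps |r| = 1 at 1 − 10⁻¹² to avoid the atanh
  pole; with two groups and perfectly correlated series, prefer `mean_r`.
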