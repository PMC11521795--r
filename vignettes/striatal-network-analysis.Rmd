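---
title: "Methods: striatal spike-train analysis on the continuous T-maze"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: striatal spike-train analysis on the continuous T-maze}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
# Chunks are illustrative; some run multi-minute simulations, so the
# vignette is shipped as source and not evaluated at build time.
knitr::opts_chunk$set(eval = FALSE)
```

```{r}
library(striatnet)
```

This vignette documents the statistical models, the conventions behind
every default, and the limits of the synthetic-data generator.

## 1. Behavioral model

The maze is abstracted to four zones: feeders `F1`, `F2` and
intersections `A` (stem base) and `B` (choice point). The input is a
**zone timeline** — strictly increasing entry times — so a zone is
occupied from its entry until the next entry. All downstream frames
derive from this timeline:

- **Elementary paths.** The timeline is segmented at feeder entries and
  each feeder-to-feeder node sequence is matched *exactly* against the
  12-path taxonomy (`path_taxonomy()`): 2 correct alternations
  (`F1 A B F2` and its mirror), same-side returns (`F1 A B F1`), base
  and top crossings (`F1 A F2`, `F1 B F2`), reverse-stem returns
  (`F1 B A F1`) and feeder u-turns (`F1 A F1`). Unmatched segments are
  labeled `unclassified` and excluded everywhere. A traversal *starts*
  when the rat leaves the initial feeder (entry time of the segment's
  second zone) and *ends* at the final feeder entry, so inter-trial
  feeder dwells never belong to a trial.
- **Task events.** Per qualifying passage: intersections contribute the
  central 500 ms of the occupancy; a feeder entry at `t` contributes
  the reward window `[t, t + 0.5)`; a feeder exit at `t` contributes
  the movement-onset window `[t − 0.5, t)`. Occupancies shorter than
  `min_passage = 0.5` s are skipped (the window would exceed the
  passage). Each window carries five contiguous 100 ms bins; both bin
  edges are computed from the window start with the same floating-point
  expression so adjacent bins share edges bitwise.
- **Stem runs** (left/right analysis). The timeline has entries only,
  so a stem run is defined as a consecutive `A`-then-`B` entry pair,
  with the upcoming turn read from the first arm zone entered after
  `B`; runs returning to `A` without entering an arm are dropped. This
  is a declared convention — with exit times one could end runs at the
  `B` exit instead.
- **Learning stages.** Sessions are staged from correct/incorrect
  paths-per-minute with rules applied in precedence order: ratio
  ≤ 1.25 → stage 1; incorrect share ≤ 0.1 → stage 4; both centered
  3-session slopes flat (|slope| < 0.05 paths/min/session) → stage 3;
  correct rising and incorrect falling → stage 2; otherwise stage 1.
  Stages are forced monotone non-decreasing by a running maximum. The
  ratio rule precedes the flatness rule so that chance-level flat
  sessions stay in stage 1.

## 2. Coding-unit detection

Under a constant rate, the spike counts over K conditions are
multinomial with `p_k = d_k / Σ d` (`d_k` the condition durations), and
`Σ (N_k − n p_k)² / (n p_k)` is asymptotically chi-squared with K − 1
degrees of freedom. Three modes: `task_event` (K = 30, five 100 ms bins
× six events, `d_k = 0.1 × passages`), `left_right` (K = 2, stem time
per upcoming turn) and `full_path` (K ≤ 12, time per taken path). The
approximation requires every expected count `n p_k ≥ 5`; the validity
policy is mode-specific: task-event bins are merged into their six
parent events (then discard if still invalid), left/right units are
discarded outright, and full-path conditions are dropped
smallest-expected-first until valid or fewer than two remain. P-values
are pooled across units and Benjamini–Hochberg adjusted at FDR 0.05.

## 3. Population activity

Per unit, `bin_firing_rates()` gives the 30 per-bin rates
`f_t = count / (0.1 × passages)`, z-scored over bins with the sample
standard deviation (`zscore_profile()`; zero-dispersion profiles are
excluded, not NaN-propagated). Population curves average z over units
per group with bands `mean ± q·sd/√n`, with the Bonferroni multiplier
`q = qnorm(1 − α / (2 m))`; the default `m = n_groups × 30` gives the
3.71 multiplier at 8 curves. The **z-score entropy** partitions
[−3.5, 5.5] into 18 bins of width 0.5 and computes
`Σ_{Nz_I>0} (Nz_I/Nz_tot) · log(Nz_I / (0.5 · Nz_tot))` (natural log) —
a plug-in estimate of `∫ p log p` since `Nz_I/(0.5·Nz_tot)` estimates
the within-bin density. Out-of-range z-scores are clipped into the
terminal bins so counts always sum to the total. Two closed forms pin
the convention: all mass in one bin gives `log 2`; equal counts in all
18 bins give `log(1/9)`. Stage contrasts use a unit-block percentile
bootstrap with Bonferroni-corrected CI levels.

## 4. Hawkes network estimation

The conditional intensity of target unit n under condition k is

```
λ_n,k(t) = μ_n,k + Σ_m Σ_{T < t, T ∈ unit m} h_{m→n,k}(t − T)
```

with each kernel piecewise constant on six 10 ms lag bins (60 ms
support), self-edges included: `N + 6N²` parameters per condition.

**Lag-bin convention.** Bin i covers lags `[10(i−1), 10i)` ms,
left-closed, with lag 0 excluded — a spike never predicts itself, and a
spike at `T = 0` makes the bin-2 predictor equal 1 exactly for
`t ∈ [0.010, 0.020)`. Implementation: bin 1 uses a strictly-less count
(`findInterval(..., left.open = TRUE)`), higher bins difference sorted
counts.

**Estimation.** The least-squares contrast
`C(λ) = −2 Σ_{T∈K} λ(T) + ∫_K λ(t)² dt` is evaluated on the union K of
the condition's trials, while predictor *histories* come from the full
session (spikes just before a trial shape the intensity inside it).
Since λ is linear in `θ = (μ, a)`, minimization is the normal system
`Gθ = b`. G is integrated **exactly**: the predictors are piecewise
constant with breakpoints at interval edges and at spike times shifted
by the seven lag-bin edges, so sweeping the sorted breakpoints and
evaluating on segment midpoints is error-free. One Gram matrix per
condition serves all N targets (`b` is computed as a matrix). A
singular system (e.g. silent units) falls back to a logged ridge
(`1e-8 · trace(G)/dim`); an entirely silent target returns an exact
zero fit. Negative coefficients are allowed and read as inhibition
under a rectified-intensity interpretation.

**Two distinct kernel summaries.** The *branching mass*
`∫|h| = 0.01 Σ_i |a_i|` governs stability (spectral radius of the mass
matrix < 1) and stationary rates `r = (I − A^T)^{-1} μ`; the
*interaction strength* `Σ_i |a_i|` (Hz) is what gets thresholded — at
the pooled 70 % type-1 quantile — to binarize graphs.

## 5. Decoding

Sessions enter decoding with ≥ 2 full-path coding units and ≥ 2 paths
each repeated ≥ 3 times. Per retained condition with m trials,
`ceiling(2m/3)` trials train (chronologically first by default, capped
at m − 1), the rest test. A test trial is assigned
`argmin_k Σ_units C(λ̂_n,k; trial)`; Poisson models use the closed form
`−2Nν + ν²D`. Decoding power is compared to `1/NbPaths`. The Hawkes
decoder's advantage on rate-matched, connectivity-differing conditions
is the package's main qualitative result (see the README example).

## 6. Synchrony

Coincidences are unordered cross-unit spike pairs at most 20 ms apart
inside the same 500 ms trial (boundary inclusive, sliding window).
The null re-pairs trial i of unit a with trial π(i) of unit b for
uniform random permutations π; because the per-trial-pair coincidence
matrix is precomputed on trial-relative times, each permutation costs
one vector lookup. P-values use the add-one rule
`(1 + #{perm ≥ obs}) / (n_perm + 1)`, valid but bounded below by
`1/(n_perm+1)` and conservative by at most the largest point mass of
the discrete null — the p-value-uniformity checks therefore use
high-rate (20 Hz) pairs where that mass is < 0.05. Group-level
structure is assessed with one-sided KS tests (uniformity per group;
region vs region per stratum), jointly BH-adjusted.

## 7. Unit classification

Features: log firing rate, peak-to-valley time (global peak to next
local minimum) and width at half height (linear interpolation at the
crossings). After centering/scaling, a Ward-D2 tree cut at k = 2 seeds
a k-means refinement — deterministic, no random starts. The cluster
winning ≥ 2 of (higher log-rate, smaller PV, smaller W) is FSI. A mean
silhouette < 0.2 flags low separation without suppressing labels.
`l_ratio()` scores isolation as
`Σ_noise P(χ²_d ≥ D²_Mahalanobis) / n_cluster`, with a percentile
against 1000 random same-size clusters.

## 8. Synthetic-data generator: scope and limits

`sim_config()` fixes all knobs; a master seed expands into independent
per-stream child seeds so any sub-generator is reproducible in
isolation.

- **Behavior**: paths are drawn feeder-chained from the taxonomy, with
  the correct/incorrect mix set per stage
  (`p_correct_by_stage = c(0.5, 0.7, 0.8, 0.95)`); traversal durations
  are gamma (CV 20 %) around per-path means; zone entries are spread
  evenly along the traversal — so within-traversal kinematics are *not*
  realistic, only the event/label structure is.
- **Spikes**: homogeneous Poisson, event-modulated Poisson
  (multiplicative per-bin gains), or per-condition multivariate Hawkes
  via Ogata thinning with a locally recomputed upper bound (each
  in-window source spike contributes at most `max_i a⁺`); inhibition is
  handled by rectifying the intensity at 0, which is approximate.
  Hawkes history never crosses trials; the enforced inter-trial gap
  (≥ 0.5 s ≫ 60 ms support) makes that exact for nonnegative kernels.
- **Waveform features**: two Gaussian clusters
  (MSN-like: 1.5 Hz, 500 µs PV; FSI-like: 15 Hz, 250 µs PV), > 4 SD
  apart by default. No actual waveforms are simulated — only the
  feature-space geometry the classifier consumes.

## 9. Problem sizes and verified properties

The shipped test suite verifies, among others: exact agreement of the
design system with a 0.1 ms-grid quadrature and a conjugate-gradient
optimizer on a lattice toy (relative 1e-6, residual 1e-8); kernel-mass
recovery within 20 % at T = 2000 s with bias shrinking versus
T = 500 s (10 replicates, 3 units); chi-squared rejection rate within
[0.035, 0.065] over 2000 null units and realized FDR ≤ 0.10 on a 20 %
modulated mixture; permutation p-value uniformity over 500 pairs at
2000 permutations plus p < 0.001 on planted 5 ms co-spiking;
Hawkes > Poisson decoding over 20 seeds on rate-matched ring networks
(paired sign test) with Poisson inside the binomial chance band;
≥ 95 % MSN/FSI accuracy over 20 seeds; and the exact 12/12 taxonomy
round trip. `scripts/acceptance.R` re-runs the same computations at
reduced replication and emits the headline numbers as JSON.

## 10. Limitations

- The thinning simulator's rectification makes inhibitory simulations
  approximate (estimation is unaffected).
- Least-squares Hawkes estimates are unpenalized; with many units and
  short conditions, per-edge estimates are noisy and only pooled
  summaries (quantile-thresholded graphs, decoding contrasts) are
  stable.
- The chi-squared pipeline conditions on behavior; it does not model
  slow nonstationarity within a session, which can inflate rejections
  on real recordings.
- Zone timelines carry entries only; analyses needing exits (true stem
  occupancy, dwell-time kinematics) use the declared conventions above.
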