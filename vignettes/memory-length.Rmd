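---
title: "Memory length of rare events in interval time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Memory length of rare events in interval time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(invmem)
```

## The question and the estimator

Interval series from autonomic physiology — R-R intervals between heartbeats,
inter-breath intervals — fluctuate under a mix of deterministic feedback loops
and cellular-level stochasticity. A useful way to characterise that mix
without perturbing the system is to ask how long a *rare* fluctuation keeps
influencing the process: does a sudden tachycardic beat get "forgotten" within
a beat or two (a Markov-like process), or does it raise the probability of
further rare beats over many cycles?

`invmem` answers this with inverse statistics. For an interval series
$B_1, B_2, \ldots, B_N$ normalised to unit standard deviation, fix a jump
level $\rho$ (in $\sigma$ units) and a direction, and define for every start
$t$ the **exit time**

$$\tau(t) = \min\{\Delta t \ge 1 : B_{t+\Delta t} - B_t \ge \rho\}$$

for decelerating events (interval lengthening: bradycardia, bradypnea), or
with $\le -\rho$ for accelerating events (tachycardia, tachypnea). Starts
whose jump never occurs before the series ends are censored. The empirical
distribution of completed exit times is then compared with the same
distribution computed on **increment-shuffled surrogates**: shuffling is done
in return space ($d_t = B_{t+1} - B_t$, a stationary quantity), and the
permuted increments are re-integrated into a profile. This null preserves
every one-step joint probability of the series and destroys all longer ones.
Consequently the two distributions can differ only over the range of $\tau$
where joint probabilities longer than one step shape the dynamics. The first
$\tau$ from which they coincide for all larger $\tau$ — the merge point — is
the **memory length** $\tau_m$: the scale at which the process becomes
reducible to one-step (Markov) structure for events of size $\rho$.
$\tau_m = 1$ is the Markov case. Unlike Chapman–Kolmogorov-based Markov-length
estimates, which average over all fluctuation levels, $\tau_m(\rho)$ is
level-resolved: it can distinguish short memory around the mean from long
memory around rare excursions, and it works on short clinical records.

The per-subject $\tau_m$ values over a grid of $\rho$ levels form a
groups x levels table, compared across cohorts with a two-way fixed-effects
ANOVA (main effects of group and $\rho$, no interaction) and Bonferroni
post-hoc pairwise t tests.

## A worked run

```{r profile, eval = FALSE}
healthy <- gen_random_walk(n = 5000, n_subjects = 10, seed = 1,
                           group = "healthy")
patient <- gen_clustered_events(event_rate = 0.02, event_length = 8,
                                event_shift = -1.5, n = 5000,
                                n_subjects = 10, seed = 2, group = "patient")
prof <- memory_profile(c(healthy, patient), rho_grid = c(0.25, 0.5, 0.75, 1),
                       direction = "accelerating", M = 100, seed = 3)
summary(prof)   # group means +/- SEM, ANOVA, post-hoc table
plot(prof)      # mean tau_m against rho, one line per group
```

## Tunable parameters

* `rho_grid` ($\sigma$ units, dimensionless after normalisation). Defaults to
  the respiratory grid $\{0.25, 0.5, 0.75, 1\}$; cardiac analyses
  conventionally use $\{0.5, 1, 1.5, 2\}$. Larger $\rho$ selects rarer
  events.
* `direction`. Accelerating ($\Delta B \le -\rho$) or decelerating
  ($\Delta B \ge \rho$); pathologies need not be symmetric between the two.
* `M` (surrogates per subject, default 100). A single shuffle would make
  $\tau_m$ hostage to one permutation; the ensemble realises the same null
  with a quantified per-$\tau$ spread that the merge test uses as its noise
  scale. The identity permutation is not excluded (its probability is
  negligible and excluding it would bias the null).
* `tau_max` (default: automatic). The merge test runs over
  $\tau = 1..\tau_{max}$, by default the smallest $\tau$ covering 99% of the
  original's completed exits, capped at 100 steps — tail bins holding a
  handful of counts would otherwise dominate the test with noise.
* Merge tolerance `k_tol`, `eps_floor`, `count_floor`, discussed next.

## Calibration of the merge test

Empirical PMFs never coincide exactly, so "merged" means the absolute
difference stays within a per-$\tau$ tolerance

$$\varepsilon(\tau) = \max\bigl(k_{tol}\cdot s(\tau),\;
  \varepsilon_{floor},\; c_{floor}/n_{exits}\bigr),$$

where $s(\tau)$ is the surrogate-ensemble standard deviation at $\tau$. Two
calibration points matter, and both were set on the memoryless null (a
random-walk profile, which is statistically exchangeable with its own
increment shuffle) *before* any cohort comparisons were run:

* **Family-wise `k_tol`.** The merge test inspects up to ~100 bins jointly,
  and $\tau_m$ is one plus the *last* offending bin, so a per-bin band has to
  be calibrated family-wise: with a conventional 2-SD band a memoryless
  series has a ~5% exceedance per bin, hence almost surely some late noise
  bin, and $\tau_m$ inflates to wherever the last false alarm lands. The
  default $k_{tol} = 3.5$ is the
  two-sided normal quantile for a 5% family-wise rate over 100 bins
  (Bonferroni); with it the memoryless null merges at $\tau_m = 1$ in the
  large majority of cells, while genuine low-$\tau$ structure — far larger
  than the null scale — is still detected.
* **Resolution floor.** A PMF built from $n_{exits}$ completed exits cannot
  resolve differences below a few counts; without a count-aware floor a
  single original count in a bin where the ensemble happens to have none
  (spread 0) is a spurious exceedance. The default is 2.5 counts,
  i.e. $2.5/n_{exits}$, alongside the absolute floor $10^{-3}$.

PMFs are normalised over completed exits only, for original and surrogates
alike, so censoring biases cancel to first order. $\tau_m$ is estimated per
subject and only then averaged (mean ± SEM) within groups; cells that never
merge within $\tau_{max}$ are flagged and excluded from group statistics with
a warning, and cells with zero completed exits are reported as missing, never
silently dropped.

## What the synthetic generators emulate — and what they do not

All three generators draw an increment process and integrate it, then pass
through the same $\sigma$-normalisation as real data.

* `gen_random_walk()` — i.i.d. standard-normal increments; the memoryless
  reference, indistinguishable from its own shuffle.
* `gen_ar_increments()` — increments from an order-$p$ autoregression with
  unit-variance innovations (stationarity is enforced via the characteristic
  roots; burn-in $10p$ discarded). Exactly $p$ previous increments enter the
  recursion, so recovering an elevated $\tau_m$ for $p = 5$ versus $p = 0$
  exercises the estimator's core claim. Note that the *correlation* range of
  a stationary AR process exceeds its order, so $\tau_m$ is expected to
  exceed $p$ — the qualitative ordering, not $\tau_m = p$, is the target.
* `gen_clustered_events()` — a two-regime increment process: baseline
  standard normal, with per-step probability `event_rate` of (re)triggering
  an event regime of `event_length` steps whose increment mean is shifted by
  `event_shift` (retriggering resets the remaining length). This emulates the
  pathological signature in which one rare event tends to be followed by
  further similar ones.

One structural difference from clinical recordings matters when choosing
experiment scales. Physiological interval series are approximately
stationary: their overall $\sigma$ is a small multiple of the typical
beat-to-beat increment, so the clinical $\rho = 0.5\sigma$ sits at the scale
of a single large increment. An integrated synthetic profile instead has
$\sigma$ growing with record length (diffusion plus the event-induced
drift), so the same $\rho$-in-$\sigma$ prescription maps to ever larger
absolute jumps as records lengthen. The validation experiments therefore fix
their record lengths so that the jump levels probed sit at the intended
increment scale:

* *Level dependency* (mean $\tau_m$ rising with $\rho$ over
  $\{0.25, 0.5, 0.75, 1\}\sigma$): records of $n = 120$ put $0.25\sigma$ near
  the noise scale (~1.5 increment $\sigma$, short memory) and $1\sigma$ near
  a full event run (long memory). At much larger $n$ every grid level is far
  above the event scale and the dependency flattens or reverses — a property
  of integrated profiles, not of the estimator.
* *Deviation signature* (original PMF below the surrogate PMF at small
  $\tau$): clustering big negative increments into bursts raises the void
  probability — windows with no rare increment at all — relative to the
  uniformly spread shuffle, which is exactly the "less likely to observe an
  event at any given exit time" signature seen in patients. The effect lives
  where a *single* pathological increment can cross $\rho$; the experiment
  uses $n = 400$ and a jump of 1.5 increment $\sigma$ (= the event shift).
  At jump levels requiring several accumulated event increments the sign
  reverses (bursts then *create* early exits); passing this check therefore
  shows the estimator reproduces the clinical signature in the matched
  regime, not that every synthetic regime mimics patients.

Other fixed study conditions: memoryless-recovery and order-5-memory
experiments use 10-subject cohorts, $n = 5000$, $\rho = 0.5\sigma$,
$M = 100$; the AR(5) coefficients are $(0.15, 0.08, 0.05, 0.04, 0.03)$ —
stationary, mild, with memory long but mostly estimable inside the
$\tau_{max}$ cap; ANOVA null calibration uses two 10-subject random-walk
cohorts at $n = 400$, $\rho \in \{0.25, 1\}$ (levels far enough apart that a
subject's two $\tau_m$ values are effectively uncorrelated under the null,
keeping the no-repeated-measures ANOVA honest), 200 replicates.

## Numerical and design choices

* **Normalisation** divides by the sample standard deviation (denominator
  $n-1$) without mean removal: exit times depend only on differences, so
  centering is irrelevant, and pure division keeps exit times exactly
  equivariant between raw and normalised series.
* **Crossing rule** is "at or beyond" ($\ge \rho$ / $\le -\rho$): with
  continuous data an exact hit has probability zero.
* **Starts** slide over every index (overlapping). The induced correlation
  between successive exit times affects original and surrogates identically,
  and it makes the one-step exit count a permutation invariant shared exactly
  with every surrogate — a useful internal consistency check.
* **Merge convention**: $\tau_m$ is the first $\tau$ from which the
  distributions coincide for all larger $\tau$ (last non-overlapping point
  plus one), so $\tau_m = 1$ means Markov. The literature's verbal
  definitions oscillate between this and the last non-overlapping point
  itself; the off-by-one is a convention and is stated here once.
* **Exit-time scan** is implemented in C++ as a right-to-left monotone
  staircase with binary search ($O(n\log n)$), exact against a naive
  double-loop oracle in the tests.
* **Surrogate construction** pins the final value to the parent's endpoint
  (the permuted increments sum to the original total mathematically; pinning
  removes the accumulated float rounding) and stores the permuted increment
  vectors as the defining construction, so conservation laws hold exactly.
* **Degenerate inputs**: constant series are rejected at normalisation
  ($\sigma = 0$); cells with zero completed exits are reported as missing; a
  surrogate with zero completed exits contributes an all-zero PMF to the
  ensemble.
* **ANOVA** uses Type II sums of squares via model comparison (`lm` fits),
  which reduces to the classical decomposition for balanced designs; the
  repeated-measures structure over $\rho$ within subject is deliberately
  ignored for comparability with how such tables are conventionally analysed,
  and the post-hoc tests are pooled-variance t tests with Bonferroni
  correction ($p_{adj} = \min(1, m\,p)$ over all $m$ comparisons performed).

## Limitations

* $\tau_m$ is resolution-limited by $n_{exits}$ and $\tau_{max}$: on short
  records with few completed exits the merge test is conservative (it will
  call "merged" early), and memory extending beyond $\tau_{max}$ is reported
  only as an unmerged flag.
* The tolerance is calibrated against the increment-shuffle null; it is not
  a goodness-of-fit band for arbitrary alternative nulls (e.g. phase
  randomisation), which this package deliberately does not implement.
* The synthetic generators validate the estimator; they are not physiological
  models (no respiratory sinus arrhythmia, no baroreflex), and their
  integrated profiles are non-stationary where clinical records are
  approximately stationary — the scale correspondence above is the bridge,
  and results on them transfer to real data only in that matched regime.
* Raw-signal processing (R-peak detection, plethysmography calibration,
  artifact editing) is assumed done upstream.
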