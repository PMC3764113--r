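# invmem — memory length of rare events in physiological interval time series

Cardio-respiratory interval series (R-R intervals between heartbeats,
inter-breath intervals) are shaped by deterministic feedback loops and
cellular-level stochasticity. A clinically meaningful way to summarise that
mix is to ask how long a *rare* fluctuation — a sudden tachycardic beat, a
burst of rapid breathing — keeps influencing the process. In healthy subjects
such events are "forgotten" within a beat or two; in conditions like
uncontrolled asthma or decompensated cirrhosis their influence persists, so
rare events tend to be followed by further rare events.

`invmem` quantifies this with inverse statistics. For a series
B<sub>1</sub>, …, B<sub>N</sub> normalised to σ = 1 and a jump level ρ (in σ
units), the **exit time** from start *t* is

&nbsp;&nbsp;&nbsp;&nbsp;τ(t) = min{ Δt ≥ 1 : B<sub>t+Δt</sub> − B<sub>t</sub> ≥ ρ }

for decelerating events (interval lengthening), or with ≤ −ρ for accelerating
events. The distribution of exit times is compared with the same distribution
on **increment-shuffled surrogates** (shuffle the returns
d<sub>t</sub> = B<sub>t+1</sub> − B<sub>t</sub>, re-integrate), a null that
keeps all one-step statistics and destroys every longer joint probability.
The first τ from which the two distributions coincide for all larger τ is the
**memory length τ<sub>m</sub>** at level ρ: τ<sub>m</sub> = 1 is the Markov
case, and larger values mean rare events of size ρ are remembered over
τ<sub>m</sub> beats/breaths. Per-subject τ<sub>m</sub> over a ρ grid feeds a
two-way ANOVA (group + ρ) with Bonferroni post-hoc comparisons.

The package provides the estimator (`compute_exit_times`, `shuffle_returns`,
`estimate_exit_distribution`, `estimate_memory_length`, and the cohort-level
`memory_profile` with `print`/`summary`/`coef`/`plot` methods), synthetic
generators with known memory structure (`gen_random_walk`,
`gen_ar_increments`, `gen_clustered_events`), group statistics
(`two_way_anova`, `bonferroni_posthoc`), an end-to-end pipeline
(`run_config`/`run_pipeline`/`run_demo`) and a thin command-line wrapper
(`inst/cli/invmem.R`). See the methods vignette
(`vignettes/memory-length.Rmd`) for the model, calibration and design
choices.

## Worked example

A synthetic two-cohort study: 10 "healthy" subjects (memoryless increment
profiles) versus 10 "patients" whose accelerating rare events cluster in
time (event regimes of 8 steps with increment mean shifted by −1.5σ,
triggered at rate 0.02/step), 150 intervals each:

```r
library(invmem)
res <- run_demo(seed = 1, out_dir = "demo")
print(res$profile)
print(res$anova)
```

```
Memory-length profile: 20 subject(s) x 2 rho level(s), accelerating events
  M = 100 surrogates/subject, k_tol = 3.5, eps_floor = 0.001, seed = 1

    group  rho  n mean_tau_m sem_tau_m n_unmerged n_missing
1 healthy 0.25 10       3.00     1.892          0         0
2 healthy 0.50 10       6.50     5.500          0         0
3 patient 0.25  9      15.56     6.902          1         0
4 patient 0.50 10      26.80     8.606          0         0
Two-way ANOVA of tau_m (group + rho, no interaction)
  F_group = 7.211 on (1, 36) df, p = 0.01089
  F_rho   = 1.393 on (1, 36) df, p = 0.2456
  39 observations, groups: healthy, patient; rho levels: 0.25, 0.5
```

Healthy subjects forget accelerating events within a few breaths
(τ<sub>m</sub> ≈ 3–6, mean ± SEM over subjects), while in the patient cohort
the same events stay "in memory" an order of magnitude longer
(τ<sub>m</sub> ≈ 16–27), and the group difference is significant
(F<sub>group</sub> = 7.2, p = 0.011). One patient cell never merged within
the τ window and is excluded from the group statistics (`n_unmerged`). The
run also writes `exits.tsv`, `memory.tsv`, `anova.json` and `manifest.json`
into the output directory; identical configuration and inputs reproduce them
byte for byte.

Real recordings enter the same way via `read_intervals()` (plain text, one
interval per line, or CSV with `interval_s`/`subject_id`/`group` columns)
followed by `memory_profile()`.

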