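# comorbnet

Temporal bipartite patient–diagnosis networks for studying multimorbidity
trajectories around a first diagnosis of severe mental illness (SMI;
schizophrenia F20 or bipolar disorder F31).

Patients with SMI carry a heavy burden of physical comorbidity, and most of
their conditions are first recorded *after* the index psychiatric diagnosis.
`comorbnet` represents hospital admission episodes as a two-mode network — a
patient set *U*, a disease set *V* of 3-character ICD-10 categories, and
edges (u, v) weighted by diagnosis frequency — and asks how that network
changes through time around the index date, and *why* it becomes more
clustered: disease progression (a patient's existing conditions beget new
ones) or selection (patients with similar attributes acquire the same
conditions). It is written for epidemiologists and network scientists who
have episode-level diagnosis data in the simple two-table schema below, or
who want a fully synthetic, mechanism-controlled cohort to develop against.

## What it computes

- **Event stream ETL** — ICD-10 codes rounded to 3 characters, non-disease
  chapters XV–XXII excluded, earliest-SMI resolution across sources,
  optional mental-health exclusion and ±w-year windows.
- **Condition split per patient** — pre-SMI set N1, post-SMI set N2, and the
  new-condition ratio |N2 ∖ N1| / |N1 ∪ N2| ∈ [0, 1], plus
  new-conditions-per-year normalised by follow-up.
- **Aggregated bipartite networks and snapshots** — pre/post networks,
  sliding windows [t, t+Δt) and cumulative windows, with Table-1-style
  summaries (degrees, density = |E| / (|U|·|V|), components).
- **Structure metrics** — degree profiles by chapter/age with 95% CIs,
  degree mixing ⟨knn⟩(k) with Kendall τ-b, second-order neighbourhoods
  N(N(v)), peer-attribute correlations, one-mode projection modularity,
  chapter lift P(A,B)/(P(A)P(B)), and average efficiency
  E = 1/(N(N−1)) Σ_{i≠j} 1/d_ij with unreachable pairs contributing 0.
- **Degree-preserving null model** — bipartite double-edge swaps
  (A–X, B–Y → A–Y, B–X), z = (φ_o − ⟨φ_r⟩)/σ(φ_r), two-tailed normal p.
- **Temporal graphlets** — the 7 static bipartite graphlet classes (n ≤ 4),
  the temporal catalogue (m ≤ 3 ordered edges), and fast Δt-window counting
  of the three 2-edge classes: D1 (repeated pair), D2 (patient-centred
  wedge: progression-type), D3 (disease-centred wedge: selection-type),
  with an all-pairs brute-force oracle.
- **Synthetic cohort generator** — seed-reproducible patients + episodes
  with switchable selection / progression / recurrence mechanisms and a
  JSON-dumped planted ground truth for recovery tests.

## Worked example

```r
library(comorbnet)

cfg      <- cohort_config(n_patients = 500, seed = 1)
patients <- generate_cohort(cfg)
episodes <- generate_episodes(patients, cfg)
events   <- build_event_stream(episodes, patients)

nets <- build_pre_post(events, patients)
rbind(summary(nets$pre), summary(nets$post))
#>   window n_nodes n_patients n_diseases n_edges mean_degree mean_patient_degree
#> 1    PRE     650        500        150    6288    19.34769            12.57600
#> 2   POST     620        470        150    5647    18.21613            12.01489
#>   mean_disease_degree    density n_components gcr
#> 1            41.92000 0.08384000            1 100
#> 2            37.64667 0.08009929            1 100

splits <- condition_splits(events, patients)
mean(splits$new_ratio, na.rm = TRUE)   # fraction of conditions that are new post-SMI
#> [1] 0.311

count_graphlets(events, delta_t = 5)
#> 2-edge temporal graphlets (ALL scope, delta_t = 5 y): total 6.31426e+06
#>   D1: 18706 (0.3%)
#>   D2: 256648 (4.1%)
#>   D3: 6.03891e+06 (95.6%)

null_test(build_network(events, patients, label = "ALL"),
          function(n) mixing_profile(n, "patients")$tau,
          n_replicates = 100, seed = 1)
#> Null test of ...: observed -0.5325, null -0.6266 +/- 0.01454 (n=100)
#>   z = 6.478, two-tailed p = 9.32e-11
```

Reading the output: in this synthetic world a patient carries ~12 distinct
conditions either side of the index date; a third of each patient's
conditions appear only after it; the disease-centred wedge D3 dominates the
2-edge temporal graphlets (many patients re-hitting the same prevalent
codes); and the patient-side degree mixing is strongly disassortative
(τ = −0.53), though a heavy-tailed degree sequence alone already forces much
of that (null mean −0.63) — the null comparison is what separates structure
from bookkeeping.

The full pipeline (ETL → networks → metrics → nulls → graphlets, CSV report
bundle) runs from one config:

```r
cfg <- pipeline_config(generator = list(n_patients = 300), seed = 1)
run_pipeline(cfg, "report/")
```

or from a YAML file via `validate_config("config.yaml")`.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

runs the full pipeline end-to-end on a synthetic cohort generated from the
given seed (all stages: generation, ETL, pre/post and snapshot networks,
structure metrics, null tests, efficiency series, graphlet fractions) and
writes the target report to `--out`.

## Vignette

`vignettes/multimorbidity-networks.Rmd` documents the model definitions, the
generator's mechanisms and their calibration, every boundary/tie convention,
and the known limitations of what a synthetic-world test can establish.
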