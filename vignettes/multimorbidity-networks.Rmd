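---
title: "Temporal bipartite networks for multimorbidity around a first SMI diagnosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal bipartite networks for multimorbidity around a first SMI diagnosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`comorbnet` analyses episode-level hospital diagnosis data for a cohort of
patients whose index condition is a severe mental illness (SMI): ICD-10 F20
(schizophrenia) or F31 (bipolar disorder). The data model is two tables —
patients (demographics, index code, index date) and admission episodes
(admission/discharge dates, up to 20 ICD-10 codes) — which the ETL turns
into a *diagnosis event stream*: one event per (episode, retained
3-character code), timestamped by admission date and carrying the signed
offset in years from the patient's index date.

From the stream, three representations are built:

1. **Aggregated bipartite networks.** Patients *U* and diseases *V* as node
   sets, an undirected edge (u, v) when u was diagnosed with v inside the
   window, weighted by diagnosis frequency. Patient nodes carry gender,
   ethnicity, index code and age at index; edges carry the patient's age at
   first diagnosis of that pair. Each patient's own index code is excluded
   from network construction (it is a node attribute instead), so a patient
   with no other diagnoses has no node.
2. **Snapshot sequences.** Sliding windows of length Δt (default 5 years)
   stepped yearly across the years-to-index axis, or cumulative windows
   (−∞, t]. Efficiency trends over these windows, compared against
   degree-preserving nulls, describe when and how strongly nodes cluster.
3. **The temporal event stream itself**, for graphlet counting, where —
   unlike in the network representations — index SMI diagnoses are kept, so
   diagnosis sequences are complete.

Key statistics: the per-patient new-condition ratio
$|N_2 \setminus N_1| / |N_1 \cup N_2|$ (with $N_1$, $N_2$ the pre/post
condition sets); average efficiency
$E = \frac{1}{N(N-1)} \sum_{i \ne j} 1/d_{ij}$ with unreachable pairs
contributing zero; nearest-neighbour degree mixing $\langle k_{nn}\rangle(k)$
summarised by Kendall's τ-b; second-order (distance-2, same-parity)
neighbourhood sizes and peer-attribute means; chapter-level lift
$P(A,B)/(P(A)P(B))$; and the three 2-edge Δt-temporal graphlet classes —
D1 a repeated (patient, disease) pair, D2 a patient-centred wedge (one
patient, two diseases, in temporal order), D3 a disease-centred wedge (one
disease, two patients). D2 abundance is the progression-type signal, D3 the
selection-type signal.

## Null model and significance

Structure is judged against a configuration-type null: repeated double-edge
swaps A–X, B–Y → A–Y, B–X that preserve both unweighted degree sequences
exactly, rejecting swaps that would duplicate an edge or touch a shared
endpoint. Defaults: 10·|E| accepted swaps per replicate (a standard MCMC
mixing heuristic; the swap chain is uniform on the set of bipartite simple
graphs with the given degrees), 1000 replicates where runtime allows.
Significance is the z-score $z = (\phi_o - \langle\phi_r\rangle)/\sigma(\phi_r)$
with a two-tailed normal p-value; the empirical percentile is also reported
as a diagnostic since the normal approximation can be poor in small
ensembles. Nulls reset edge weights to 1, so only weight-free statistics are
meaningful against them. A statistic with zero null variance (e.g. edge
count) yields an `NA` z rather than a misleading number.

## The synthetic cohort generator

The linked clinical data the analysis was designed for are not publicly
deposited, so the package ships a generator whose *defaults are the stated
world*: a 60/40 F20/F31 split; age at index Normal(39.5, 16.5) truncated to
[0, 100]; index dates uniform over a 2008–2018 identification window with
administrative censoring at 2018-03-31; a disease vocabulary of 150
3-character codes from the disease chapters I–XIV with Zipf prevalence
rank^(−1.2); pre/post episode rates 0.8 and 1.5 per year over 12/8
observation years; ~2 fresh codes per episode. Values not pinned by the
cohort description (rates, spans, vocabulary size, codes per episode) were
chosen once as plausible for a secondary-care SMI cohort and are not tuned.

Three mechanisms, all off/neutral by default, shape how diagnoses attach:

- **Selection** (age homophily): each disease has a latent age centre;
  per-draw weight is multiplied by exp(−s·|patient age − centre|/10).
- **Progression**: each disease has latent partner diseases; a disease
  already in the patient's history multiplies its partners' weights by
  (1 + p · partner count).
- **Recurrence**: chronic conditions in the history re-appear in each later
  episode with fixed probability (default 0.25) — this inflates edge
  weights and D1 counts but not unweighted structure.

The index diagnosis is materialised as its own episode on the index date and
F20/F31 are excluded from the vocabulary, so every patient has exactly one
index event. A `ground_truth.json` dump of the latent model supports
recovery tests.

Two details exist purely to keep the stated world self-consistent. The age
truncation bound is 0 rather than a clinically tighter value because
truncating a Normal(39.5, 16.5) at, say, age 5 shifts its mean by +0.75
years — enough to break the stated default behaviour (sample mean within
39.5 ± 1) — while the bound's purpose is only to exclude impossible values.
And "years" are day differences divided by 365.25 throughout.

### What the generator does and does not emulate

It reproduces: heavy-tailed prevalence, multi-year episode streams either
side of the index date, attribute-dependent diagnosis (when switched on),
history-dependent progression, chronic recurrence, and seed-exact
reproducibility. It does **not** emulate: real ICD-10 semantics beyond the
chapter structure, mortality, age-dependent episode rates, coding practice
drift, or any correlation between patient degree and attributes. A green
recovery test therefore establishes that the *pipeline measures what it
claims to measure on a world with known mechanisms* — not that the real
cohort behaves this way.

### Mechanism-recovery worlds

Parameter-recovery experiments use `mechanism_config()`, frozen once at
design time from three pilot seeds:

- base: 500 patients, 1000 diseases, prevalence exponent 0.2 (near-flat).
  With a strong Zipf tail, cross-patient collisions on top-ranked codes
  swamp the D2/D3 contrast regardless of mechanism; flattening the marginal
  makes collisions informative about the mechanism.
- `"selection"`: selection strength 8 (e-folding ≈ 1.25 years of age
  distance). Yields fraction(D3) > fraction(D2).
- `"progression"`: progression strength 30 (a partner disease is ~30× more
  likely per history hit). Each patient walks its own partner chain, so
  within-patient wedges dominate: fraction(D2) > fraction(D3).
- `"disassortativity"`: selection with the heavy tail retained (exponent
  1.0). Homophily plus a heavy-tailed disease-degree sequence produces
  degree mixing significantly *below* the degree-preserving null
  (τ ≈ −0.3, z ≈ −5 to −8).

With all mechanisms off the generator is product-form: conditional on its
degree sequences it is statistically indistinguishable from its own
rewiring, which is exactly why the mechanism-off arms of the recovery tests
expect |z| < 3.

## Numerical and boundary conventions

- **Pre/post boundary**: events dated exactly on the index date are
  post-SMI (the index event itself occurs that day); "pre" is strictly
  earlier. Sensitivity windows are closed on the SMI side.
- **Snapshot windows** are closed-left, open-right [t, t+Δt), with the final
  window closed, so sliding windows partition events without double
  counting. Window midpoints t+Δt/2 are recorded for plotting.
- **Within-episode duplicates** of a code collapse to one event at the
  smallest rank; repeats across episodes are kept (they drive edge weights
  and D1).
- **Simultaneous events never pair** in graphlet counting: the temporal
  order must be strict, and all codes in one episode share the admission
  date, so within-episode pairs are excluded. This is the single largest
  unstated convention in the counting definition; the brute-force oracle
  implements it identically.
- **Graphlet scopes**: pre/post membership is per event; a pair straddling
  the boundary is counted in neither restricted scope. Δt is converted to
  days via 365.25.
- **Kendall τ** is the tie-corrected τ-b (ties are ubiquitous in integer
  degrees) and is `NA` when either variable is constant.
- **Efficiency on node subsets** restricts the *pair set*, not the graph:
  distances are always measured through the full bipartite network, so
  patient-side efficiency counts patient–disease–patient paths.
- **Invalid codes** are rejected (not repaired) when rounding to 3
  characters; rejection is a value, not an error.
- **First-SMI tie-break** across sources: earliest date, then mental-health
  source over hospital source, then code order.
- The null-model worked description in the counting literature sometimes
  writes the swap result inconsistently; only A–Y, B–X preserves degrees,
  and that is what is implemented.

## Known limitations

- **Patient-side efficiency cannot beat its null in this world.** For any
  generator in this family — per-draw disease weights that factor into a
  prevalence term times a patient-level kernel — the expected number of
  distance-2 patient pairs cannot exceed its expectation under the exact
  degree-preserving null: redistributing co-occurrence mass holds mean pair
  overlap fixed while the probability of sharing ≥1 neighbour is concave in
  overlap (Jensen), and longer-range pair terms lose alongside. Measured
  patient-efficiency z-scores under planted selection are −90 to −212. The
  corresponding recovery check is therefore expected to fail and is kept
  failing rather than weakened: a positive empirical signal of this kind in
  real data reflects structure (e.g. attribute-neutral hub conditions
  coexisting with attribute-specific ones, degree–attribute coupling) that
  this synthetic world deliberately does not contain.
- The configuration null itself is mildly disassortative for heavy-tailed
  degrees; raw τ(k, knn) < 0 is partly bookkeeping, and only the gap to the
  null is evidence.
- 3-edge temporal graphlets are catalogued but not counted at scale; 4-node
  temporal counting is out of scope.
- The modularity analysis takes partitions from node attributes; no
  community detection is performed.

## Reproducibility

Every stage draws from a seed derived deterministically from the config
seed, so `run_pipeline()` output is byte-identical across reruns, and
stages can be re-run in isolation. All report artefacts are plain CSV plus
one JSON ground-truth dump.
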