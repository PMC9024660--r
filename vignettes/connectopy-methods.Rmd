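---
title: "Methods: modular connectome topology and trait associations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modular connectome topology and trait associations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connectopy)
```

`connectopy` estimates associations between the modular topology of
resting-state functional brain networks and two psychometric empathy traits.
This vignette documents the models, the tunable parameters, the
synthetic-data generator, and every numerical choice a user (or reviewer)
might want to interrogate. No empirical claim is made here beyond what the
package's tests and acceptance script compute.

## 1. From time series to binary graphs

`fisherZConnectome()` correlates every pair of nodal time series and applies
the Fisher z transform, `z = atanh(r)`. Correlations with `|r| >= 1 - 1e-7`
(numerically degenerate, e.g. duplicated series) are capped at
`atanh(1 - 1e-7)` with a warning rather than propagating infinities; the
diagonal is forced to zero.

`proportionalThreshold()` binarizes a weighted connectome by keeping the
strongest `floor(d * n(n-1)/2)` upper-triangle entries at density `d`
(default 0.10) and mirroring. Three choices deserve comment:

- **Ranking is by signed z by default** — the strongest *positive*
  couplings. Ranking by `|z|` is available via `rank = "absolute"`, but mixed
  positive/negative edges change the meaning of binary modularity, so signed
  ranking is the default for resting-state graphs.
- **Ties at the cutoff** are broken in lexicographic (row, column) order, so
  the retained edge *count* is exact and runs are reproducible even on
  degenerate inputs.
- **Connectedness is not enforced.** Disconnected graphs are legal
  throughout: closeness uses a composite that handles unreachable nodes (see
  below), betweenness treats unreachable pairs as contributing zero, and
  modularity is defined per component implicitly.

The exact edge count `floor(d * n(n-1)/2)` depends only on `n` and `d`, so
every subject of a cohort has the same number of edges — this is what makes
nodal metrics comparable across individuals without density covariates.

`makeNodeRegistry()` assembles the 418-parcel bookkeeping table (346
cortical, 40 subcortical, 32 cerebellar nodes). Its MNI coordinates are
*synthetic placeholders* drawn inside component-specific bounding boxes; use
`readNodeRegistry()` with a real atlas table for anatomical work.

## 2. Modularity, Louvain, and the fine-tuning loop

Modularity at structural resolution γ is

$$Q(\gamma) = \frac{1}{2m}\sum_{ij}\Big[A_{ij} - \gamma\frac{k_i k_j}{2m}\Big]\delta(c_i, c_j).$$

γ weights the configuration-model null: γ < 1 favors few large modules,
γ > 1 many small ones. `louvainFinetune()` maximizes Q with the Louvain
heuristic — greedy single-node moves over a randomized node order, then
aggregation of modules into super-nodes, recursively — wrapped in an
iterated fine-tuning loop: each cycle restarts the local-move phase from the
previous cycle's optimum (the first cycle starts from singletons) and the
loop stops when a cycle improves Q by less than `tol = 1e-10`. Q is
non-decreasing across cycles by construction because moves are only accepted
at positive gain. All randomness is governed by an explicit seed; two calls
with the same seed return identical partitions.

The implementation operates on (possibly weighted) dense matrices, which is
the right regime for connectomes of a few hundred nodes. The per-move gain
for node *i* joining module *c* is
`k_{i,c} - γ s_i Σ_tot(c \ i) / 2m`, with strengths `s` and module strength
totals maintained incrementally. `modularityQ()` is tested against the
independent `igraph::modularity(..., resolution = γ)` implementation, and
returned partitions are verified to be single-move locally optimal by
exhaustive enumeration in the tests.

`gammaSweep()` runs the optimizer over γ ∈ {0.3, 0.4, ..., 5.0} (48 values —
the default grid) with per-γ child seeds. Empirically, mean optimized Q
decreases and module count increases with γ; the test suite asserts these
trends on synthetic cohorts, allowing local module-count jitter of at most
one module between adjacent γ (the optimizer is a heuristic; tiny local
non-monotonicities in the count are expected and observed).

## 3. Group-level consensus and the module screen

`agreementMatrix()` counts, for every node pair, how many subjects placed
the pair in the same module. `consensusPartition()` then applies iterative
consensus clustering: normalize counts to proportions; zero all entries at
or below the *analytic null rate* (the expected co-assignment of a random
pair if each subject's module labels were permuted over nodes, computable
from the module-size profiles stored in the `AgreementMatrix`); re-cluster
the thresholded matrix with `reps` seeded Louvain restarts; and iterate on
the restarts' own agreement matrix until all restarts return the identical
partition. The returned partition carries the modularity of that final
partition on the consensus matrix. The pipeline default is `reps = 1000`;
the tests and acceptance script use 20–100 restarts, which is ample at the
graph sizes they run (the procedure converges in one or two iterations on
all benchmarks).

Degenerate agreement (no pair above the null rate) or non-convergence within
`maxIter = 50` iterations raises an error with diagnostics rather than
returning a silently arbitrary partition. When two partitions are tied (e.g.
two conflicting bipartitions contributed equally), the seeded restart makes
the choice deterministic.

`moduleSignificance()` screens consensus modules: the observed statistic is
a module's mean within-module agreement proportion, and the null rebuilds
the agreement matrix after permuting each subject partition's node labels
(`nNull = 100` by default); modules above the 95th null percentile are kept.
This permutation operationalization is a documented design choice — the
screen's classical description is cited in the connectomics literature
without a formula — and its calibration (~5% of random modules kept) is
verified by simulation in the tests. A single-module consensus is kept
vacuously with a warning.

`adjustedModularity()` (optional, off the main path) z-scores a graph's
optimized Q against degree-preserving rewired nulls, each re-optimized at
the same γ. It is provided as a diagnostic for comparing Q across degree
structures and feeds nothing downstream.

## 4. Nodal metrics

All five metrics operate on binary undirected graphs and are oracle-tested
against exhaustive brute-force implementations on all random graphs up to 8
nodes (200 instances in the acceptance suite):

- **Degree**: row sums.
- **Betweenness**: unnormalized shortest-path fraction sums
  (`σ_st(v)/σ_st` over unordered pairs, unit edge lengths, unreachable pairs
  contribute 0). Unnormalized values are the default because module-level
  regression slopes are then in interpretable path-count units; a
  `normalized` flag divides by `(n-1)(n-2)/2`.
- **Closeness**: the Wasserman–Faust composite
  `(r_v/(n-1)) · (r_v / Σ d(v,u))` over the `r_v` reachable nodes, which
  handles disconnected graphs deterministically (isolated nodes score 0) and
  reduces to classical closeness on connected graphs.
- **Participation coefficient**: `1 - Σ_s (k_vs/k_v)²`; disconnected nodes
  are assigned 0.
- **Within-module degree**: within-module link counts z-scored inside each
  module using the *population* SD (the module is the full population of its
  nodes, not a sample); modules with zero SD (e.g. cliques) get z = 0
  throughout. The raw counts are available via `zscore = FALSE`. Whether the
  z-scored or raw variant is used upstream in the literature is ambiguous;
  the z-scored form is the standard companion of the participation
  coefficient and is the default.

## 5. Behavioral scoring

`scoreEES()` scores the 30-item instrument: VE = sum of the 15 odd items,
IU = sum of the 15 even items (1-based numbering, no reverse-coding), each
in [15, 75]. `boxcoxTransform()` fits the Box–Cox power parameter by profile
maximum likelihood — a coarse grid over [-3, 3] brackets the optimum and
`stats::optimize()` (golden-section with parabolic refinement) polishes it
to 1e-4; the estimate is cross-checked against the `MASS::boxcox` profile in
the tests. `scoreCohort()` standardizes the transformed scores (mean 0,
SD 1) by default so regression slopes are per-SD of trait; the raw scale is
available. λ values are stored as attributes.

Sex contrasts use the pooled-variance two-sample t (df = n − 2): with
unequal group sizes a paired test is impossible, and the pooled form is the
one whose degrees of freedom match a 116-subject cohort reported with
t(114). Subscale correlations get Fisher-z confidence intervals; Cronbach's
alpha uses the classical closed form and is reported as missing for
zero-variance scores.

## 6. The association model

For one (γ, module, metric, trait) combination, `buildLongTable()` assembles
one row per (subject, node-in-module) and `fitModuleModel()` fits, by REML:

```
value ~ trait * sex + age + (1 | subject) + (0 + trait | node) + (1 | scan_group)
```

- **Orientation**: the nodal metric is the outcome and the trait the
  predictor. This is the only orientation in which "the module's nodes as
  random groupings" and node-level random *slopes* are coherent: the fixed
  trait effect is the module-level association and the node random slopes
  are the individual-node deviations, extracted as BLUPs.
- **Sex coding** is female = −0.5, male = +0.5, so the trait main effect is
  the sex-averaged slope and partial per-sex slopes follow exactly from
  `slope(level) = β_trait + code(level) · β_interaction` (an identity the
  tests verify). Age is centered.
- **Inference**: Satterthwaite degrees of freedom (via lmerTest) with Wald
  confidence intervals. Under the simulator's null the trait effect's
  type-I error at α = 0.05 is calibrated (verified at 200 replicates), and
  with a planted slope of 3.2 the estimator is unbiased within Monte-Carlo
  error with ≥ 85% CI coverage (50 replicates); both checks run at 30
  subjects × 40 nodes, sizes chosen to exercise the model at desk scale.
- **Singular fits** are refitted after dropping the γ-level random intercept
  first, then the scanning-group intercept — never the node random slope,
  which carries the scientific content; the result records what was dropped.
  Fewer than 2 scanning groups drops the group term with a warning; fewer
  than 10 subjects warns.

`residualScreen()` is the "robust" second step: per-node Anderson–Darling
normality tests on the residuals of an initial fit, exclusion of nodes with
p < 0.05, and a refit; both fits are returned. `alpha_ad = 0` disables
exclusions exactly. Nodes with fewer than 8 residuals are retained untested
(the statistic is undefined there). No M-estimation is used: robustness here
*is* the screen-and-refit step.

`fdrCorrect()` is Benjamini–Hochberg. The family is all (module × metric)
models within one (γ, trait) pair — the unit at which discoveries are
reported per resolution. Other plausible families (pooling γ) would be more
conservative; the chosen family matches reporting significance separately at
every γ. Empirical FDR under the simulator's complete null is ≤ nominal
(verified over 500 replicates at q = 0.05).

`crossGammaModel()` stacks the per-γ tables for a module detected at several
resolutions and adds a random intercept per γ with node slopes nested within
γ (`(0 + trait | γ:node)`); γ thus enters as a repeated measure and the
fixed trait effect is the cross-resolution headline estimate. With one γ the
function falls back to the per-γ model with a warning. `iceCurves()`
evaluates each subject's predicted outcome over a trait grid at their
observed covariates (including their random intercept); every curve is a
line with slope `β_trait + code(sex) · β_interaction`.

## 7. The synthetic-data generator

The generator exists so that every downstream stage has a ground truth. Its
defaults describe the cohort the pipeline is designed around: 116 subjects,
62 female, four scanning groups in proportions 38/28/22/28, age ~ N(23, 3²)
truncated to [18, 35], subscale consistencies 0.92/0.95, raw-score
correlation 0.315, and a standardized female−male VE difference of 0.90
(the d implied by a pooled t of 4.85 at those group sizes).

**Items.** Responses are thresholded latent normals: item latent
`x = λ f + √(1−λ²) ε` with 5 equal-width category cuts at
(−1.5, −0.5, 0.5, 1.5); odd items load on factor 1 (VE), even on factor 2
(IU). Discretizing to 5 categories attenuates correlations, so the latent
parameters are *calibrated*, not copied from the targets: the moments of the
discretized bivariate normal (category means, variances, cross-moments) are
computed by 1-D numerical integration, and the loadings λ, the latent sex
shift δ, and the factor correlation ρ are solved (by `uniroot`, iterating
the coupled λ/δ system to convergence) so that the *observed* pooled alpha,
Cohen's d, and sum-score correlation hit the configured targets. The tests
verify convergence at n = 2000 to within ±0.02 on all four calibrated
quantities (averaged over 20 cohorts); a residual bias of about +0.01 on the
trait correlation remains from higher-order mixture effects and is accepted.
This factor model is a *stand-in*: the real instrument's generative process
is unknown, and nothing downstream depends on its specifics beyond the
calibrated marginals.

**Connectomes.** Mode A draws planted-partition binary graphs directly
(within-module edge probability `p_in = 0.4`, between `p_out = 0.05` by
default, nodes split into equal blocks with the remainder in the last);
mode B draws nodal time series from a block-structured correlation matrix
(0.8 within / 0.0 between by default) and pushes them through the real
`fisherZConnectome()` → `proportionalThreshold()` chain, exercising the full
pipeline. Both are deterministic given the configuration seed and subject
index; p_in ≤ p_out is allowed but warned about at configuration time.

**Planted effects.** `plantEffect()` writes the association model's
generative counterpart into a metric table: target-module rows of the target
metric gain `(β + b_node + β_sex · sex_code) · trait` with
`b_node ~ N(0, node_slope_sd²)`, and all rows of that metric gain subject
intercepts, scanning-group intercepts, and residual noise. The default
variance components (subject 3, node slope 2, group 1, residual 5, on the
degree scale) were chosen once so that, at the default cohort size, the
planted degree effect of 3.2 per trait SD is estimated with a standard error
near 1 and node BLUPs span a few units around the fixed effect — the regime
in which the two-step framework is intended to operate. They were not tuned
to any test outcome.

**What the generator does not emulate:** hemodynamics, motion, spatial
autocorrelation of parcels, non-modular network features (hubs spanning
modules, rich clubs), missing item responses, or floor/ceiling effects in
the questionnaire. Passing tests therefore demonstrate the *statistical
machinery* — recovery, calibration, error control — under the stated
generative assumptions, not performance on real fMRI.

## 8. Problem sizes and runtime

The tests and the acceptance script run at deliberately reduced sizes chosen
as the smallest at which each property is meaningfully testable: oracle
checks on ≤ 8-node graphs (where exhaustive path enumeration is exact),
community benchmarks on 40–60 nodes, mixed-model calibration at 30 subjects
× 40 nodes (200 null + 50 recovery replicates), FDR calibration at 10
subjects × 20 nodes × 8-model families (500 replicates), and γ sweeps over
the full 48-point grid on 10-subject cohorts. The full pipeline on a
418-node, 116-subject cohort with 1000 consensus repetitions is the intended
production configuration and runs unchanged, only longer.

## 9. Known limitations

- Binary undirected graphs only; no weighted or signed modularity.
- One connectome per subject: concatenate runs before correlation
  (averaging per-run connectomes is deliberately not offered).
- The consensus procedure and the module screen are documented
  operationalizations of methods the connectomics literature cites without
  formulas; both are flagged as such above and validated by calibration
  simulations rather than against a reference implementation.
- The Louvain heuristic does not guarantee the global optimum; the tests
  assert local optimality and benchmark recovery, not global optimality on
  arbitrary graphs.
- BLUP–truth correlations degrade gracefully with noise; at the default
  variance components and 80 subjects they exceed 0.5, which is the
  realistic shrinkage regime, not a deficiency.
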