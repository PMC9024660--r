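# connectopy

Linking the modular topology of resting-state functional brain networks to
psychometric traits.

## The problem

Resting-state fMRI yields, for every participant, a functional connectome: a
node-by-node matrix of Fisher-z transformed Pearson correlations between the
time series of brain parcels. A recurring question in network neuroscience is
whether stable behavioral traits — here the two subscales of a 30-item
empathy questionnaire, *vicarious experience* (VE) and *intuitive
understanding* (IU) — are encoded in the topology of these networks: in how
central individual nodes are, and in how nodes distribute their connections
within and between the brain's intrinsic modules.

`connectopy` implements that analysis end to end for researchers who have
per-subject node time series (or precomputed connectomes) and questionnaire
responses:

1. **Connectome construction** — Fisher-z correlation matrices, binarized by
   proportional thresholding so every subject keeps exactly the strongest
   `floor(d · n(n−1)/2)` connections (default density d = 0.10), holding
   network density fixed across individuals.
2. **Modular architecture** — per-subject modularity maximization

   Q = (1/2m) Σᵢⱼ [Aᵢⱼ − γ kᵢkⱼ/(2m)] δ(cᵢ, cⱼ)

   via a seeded Louvain algorithm with an iterated fine-tuning wrapper
   (restart from the previous optimum until Q stops increasing), swept over
   the structural resolution γ ∈ {0.3, 0.4, …, 5.0}. Group-level modules
   come from consensus clustering of the cross-subject agreement matrix,
   followed by a permutation screen for significant modules.
3. **Nodal topology** — degree, betweenness and closeness centrality,
   participation coefficient Pᵥ = 1 − Σₛ (k_vs/k_v)², and within-module
   degree z, all validated against brute-force oracles.
4. **Behavior** — questionnaire scoring (VE = Σ odd items, IU = Σ even
   items, range 15–75), Cronbach's alpha, subscale correlations, sex
   contrasts, and Box–Cox transformation with profile-ML λ.
5. **Brain–behavior association** — a two-step robust linear mixed-effects
   framework per (γ, module, metric, trait):

   metric ~ trait × sex + age + (1 | subject) + (0 + trait | node) + (1 | scanning group)

   with REML estimation, Satterthwaite inference, per-node random-slope
   BLUPs, Anderson–Darling residual screening with refit,
   Benjamini–Hochberg FDR within each (γ, trait) family, individual
   conditional expectation (ICE) curves, and a cross-γ multivariate model
   with γ as repeated measures.
6. **Synthetic cohorts** — a first-class generator of planted-partition
   connectomes, calibrated ordinal questionnaire responses (target alphas,
   trait correlation, sex effect) and planted trait→topology effects, so the
   whole chain is testable without any data download.

## Worked example

```r
library(connectopy)

cfg <- cohortConfig(n_subjects = 25, n_nodes = 60, n_modules_planted = 4,
                    p_in = 0.4, p_out = 0.05, planted_beta = 3.2, seed = 1)
run <- runPipeline(runConfig(simConfig = cfg, gammas = c(0.8, 1.0, 1.2),
                             consensusReps = 100, metrics = "degree",
                             traits = "ve_t", seed = 1), verbose = FALSE)

run$consensus[["1"]]
#> ModularPartition: 60 nodes, 4 modules, gamma = 1.00, Q = 0.7500

subset(run$scan$table, q < 0.05,
       select = c(gamma, module, metric, estimate, se, p, q))
#>   gamma module metric estimate        se           p          q
#> 1   0.8      1 degree 3.205896 1.0251116 0.005319856 0.02127943
#> 5   1.0      1 degree 3.165260 0.9776189 0.003778876 0.01511550
#> 9   1.2      1 degree 3.022662 1.0720140 0.009630555 0.03852222
```

The consensus partition recovers the four planted modules exactly (its Q
slot, 0.75, is the modularity of the partition on the thresholded consensus
matrix). The association scan finds exactly one FDR-significant family
member per γ: the planted module-1 degree–VE effect, whose estimates
(3.0–3.2 per SD of the transformed trait) match the planted slope 3.2 within
their standard errors; all other (module, metric) combinations stay null. `run$cohort` holds
the scored subject table, `run$qTable` per-subject modularity across γ, and
`iceCurves()` turns any fitted result into per-subject prediction curves.

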