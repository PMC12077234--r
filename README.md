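# vocnet

Social-network drivers of individual vocal complexity in colonial
parrots: multilayer networks from field observations, dynamic-time-warping
acoustic distances, hierarchical Bayesian decomposition of call similarity
and diversity, measurement-error effect models guided by causal diagrams,
and a Dirichlet-multinomial model of repertoire composition — with a
synthetic-data generator that records its ground truth so every stage can
be tested against known parameters.

## What it computes

**Networks.** Five layers over marked individuals — foraging association
by the simple ratio index under the gambit of the group
(`SRI = x / (x + y_AB + y_A + y_B)`), binary mate / affiliative /
aggression layers, a normalized nest-distance layer — plus a four-layer
multiplex. Node metrics: degree, betweenness, eigenvector centrality,
degree versatility (degree summed across layers), chamber and tree group
sizes.

**Acoustics.** Pairwise call distances by dynamic time warping on
fundamental-frequency contours (absolute-difference cost, path-length
normalized); amplitude-modulation peak counts (prominence ≥ 30) as an
information-content proxy.

**Stage-1 models.** Between-individual distances decompose as
`y ~ normal(α_dyad + α_rec[i] + α_rec[j], σ)` with
`ᾱ ~ normal(0, 0.5)` and `σ, σ_dyad, σ_rec ~ exponential(2)`;
within-individual distances as
`μ = α_ind + α_same_rec + α_rec_pair + α_call_i + α_call_j` with
`ᾱ ~ normal(0, 0.25)`, `σ ~ exponential(5)`, group SDs `exponential(3)`.
`α_dyad` (similarity) and `α_ind` (diversity) are exported with posterior
mean and SD.

**Stage-2 models.** Latent-truth regressions
`m_i ~ normal(ℓ_i, s_i)`, `ℓ_i ~ normal(a + X b, σ)` propagate that
uncertainty; dyadic outcomes get multi-membership varying intercepts for
both members. Total vs direct effects use back-door adjustment sets from
shipped causal diagrams (total: the exposure's parents; direct: plus the
mediators).

**Repertoire.** Shannon entropy (≥ 30 calls per individual) and the
composition model
`x_i ~ multinomial(p_i)`, `p_i ~ dirichlet(π_i θ)`,
`s_i = exp(log α + β A_i + δ F_i)`, with
`θ ~ exponential(0.2)`, `α ~ dirichlet(5, 0.5 × 8)`,
`β, δ ~ normal(0, 0.5)`, fitted on the analytically marginalised
Dirichlet-multinomial likelihood; per-type female−male contrasts on the
proportion scale.

## Worked example

```r
library(vocnet)

pop <- simulate_population(population_config(n_individuals = 60,
                                             n_trees = 12), seed = 7)
obs <- simulate_social_observations(pop$individuals,
                                    observation_config(), seed = 7)
f <- foraging_layer(obs$sightings)
f
#> <network_layer 'foraging': 60 nodes, 1046 edges>
head(centralities(f), 3)
#>       id degree betweenness eigenvector
#> 1 ind001     45    21.24429   0.9606811
#> 2 ind002     35    11.44093   0.7604161
#> 3 ind003     40    16.56903   0.8579231

sim <- simulate_dyadic_distances(n_dyads = 150, obs_per_dyad = 8, seed = 11)
fit <- fit_dyadic_model(sim$observations,
                        sampler_config(chains = 2, warmup = 500,
                                       samples = 400, seed = 5))
fit
#> <dyadic_fit: 150 dyads, 1200 obs | Rhat 0.998-1.049>
#>      unit_id    mean      sd pi89_low pi89_high  rhat
#> 1       abar 0.00768 0.03991  -0.0568     0.070 1.032
#> 2      sigma 0.19687 0.00450   0.1899     0.204 0.998
#> 3 sigma_dyad 0.37916 0.02132   0.3459     0.414 1.001
#> 4  sigma_rec 0.09115 0.00932   0.0770     0.107 0.999
```

The generator drew dyad offsets with SD 0.4, recording offsets with SD
0.1 and residual SD 0.2; the posterior recovers all three (`sigma_dyad`
0.38 with 89% interval 0.35–0.41, covering the realized spread of the 150
drawn offsets), and the per-dyad estimates rank-correlate with the true
offsets at 0.98.

`repertoire_entropy(c(5, 3, 2))` returns 1.0297 — the Shannon entropy (in
nats) of a repertoire split 50/30/20 across three call types.

## Analysis workflow

`analysis/01_simulate.R` … `analysis/06_repertoire.R` run the whole study
on synthetic data with one master seed: simulate the colony, build the
network layers, compute DTW distances and peak counts, fit the two
stage-1 models, fit the stage-2 effect models (similarity ~ tolerance
edge; diversity ~ chamber size, age, sex; entropy ~ tree size;
information ~ degree) and the composition model with its sex contrast.
Each script prints what it found and writes its tables under `results/`.
`run_pipeline()` performs the same sequence as one call.

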