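---
title: "Models and methods: social networks and vocal complexity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: social networks and vocal complexity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(vocnet)
```

## The scientific problem

The social complexity hypothesis predicts that individuals navigating
richer social environments express richer communication. Testing it
*within* a species needs three ingredients this package provides: a
fine-grained description of each individual's social environment
(multilayer social networks built from field observations), individual-level
measures of vocal output (contact-call diversity, call similarity between
individuals, repertoire diversity and information content), and a
statistical bridge between the two that respects how uncertain the vocal
measures are. The motivating system is a colonial-nesting parrot
(the monk parakeet, *Myiopsitta monachus*): individually marked birds
nesting in chambered stick nests grouped in trees, foraging in
fission–fusion flocks, with a repertoire of eleven call types dominated by
a highly variable contact call.

Because the interesting quantities (a dyad's average acoustic distance, an
individual's average within-repertoire distance) are themselves model
estimates, the pipeline is two-staged: stage 1 decomposes raw pairwise
acoustic distances with hierarchical Bayesian models and exports each
unit's posterior mean *and* standard deviation; stage 2 regresses these
measured outcomes on social predictors with a measurement-error
likelihood, so that units measured imprecisely carry less weight.

## Social networks

Five layers are built over the marked population:

* **foraging** — gambit of the group over survey sessions: all members of
  an observed foraging group are taken to associate pairwise. Edges are
  weighted by the simple ratio index
  $\mathrm{SRI} = x / (x + y_{AB} + y_A + y_B)$, where $x$ counts sessions
  with the two birds in one group, $y_{AB}$ sessions with both seen but
  apart, and $y_A, y_B$ sessions with only one seen. Co-sighting is
  deduplicated at the session level, so a session contributes at most one
  joint sighting per dyad. A dyad with no observations at all has an
  *undefined* index (`NA`), never 0.
* **mate** — binary: sharing a nest entry (chamber), or at least one
  allopreening event (allopreening is almost exclusively between mates).
* **affiliative** — binary: at least one close-tolerance or allopreening
  event.
* **aggression** — binary and undirected: at least one displacement or
  fight.
* **nest distance** — planar Euclidean distance between the trees holding
  the birds' assigned nest entries, divided by the maximum observed
  distance so values span [0, 1]; two entries in one tree score 0.

The **multiplex** bundles the first four layers (the nest layer largely
duplicates the mate layer). Node metrics: unweighted degree, betweenness
(number of shortest paths through the focal node, fractional under ties)
and eigenvector centrality on the binarised foraging layer, **degree
versatility** (degree summed across the multiplex layers), and chamber and
tree group sizes counting the focal bird. Centralities are computed with
igraph; eigenvector centrality is evaluated per connected component and
max-normalised, a choice made because the layers are routinely
disconnected and raw scores are not comparable across components.

## Acoustic distance

Call similarity is measured by dynamic time warping on the smoothed
fundamental-frequency (F0) contour of each call: absolute-difference local
cost, symmetric steps, total cost divided by the warping-path length, with
each trace mean-centred first so the distance reflects contour shape
rather than absolute pitch. Among equal-cost warping paths the shortest is
used for normalisation, which makes the value a deterministic function of
its inputs; the kernel is exact dynamic programming (verified against
exhaustive path enumeration in the test suite). Window constraints and
alternative step patterns are deliberately not defaulted in — the exposed
arguments (`normalize`, `center`) cover the choices this analysis needs.

Information content of a call is proxied by the number of prominent
amplitude-modulation peaks in its smoothed trace: a local maximum counts
when its height above the higher of its two flanking troughs reaches
`min_height = 30` (trace units). Endpoints are never peaks and the count
is invariant to constant offsets.

## Stage 1: hierarchical distance models

**Dyadic (between-individual) model.** For distances $y$ between contact
calls of different individuals:

$$y \sim \mathrm{normal}(\mu, \sigma), \qquad
\mu = \alpha_{dyad} + \alpha_{rec[i]} + \alpha_{rec[j]}$$

with $\alpha_{dyad} \sim \mathrm{normal}(\bar\alpha, \sigma_{dyad})$,
$\bar\alpha \sim \mathrm{normal}(0, 0.5)$,
$\alpha_{rec} \sim \mathrm{normal}(0, \sigma_{rec})$ and
$\sigma, \sigma_{dyad}, \sigma_{rec} \sim \mathrm{exponential}(2)$.
$\alpha_{dyad}$ is the dyad's average acoustic distance — the similarity
measure carried forward. The recording offset $\alpha_{rec}$ controls for
repeated comparisons of the same recordings; both recordings of a pair
enter additively, which is this package's resolution of an
under-determined notational point (a single per-pair term is the
alternative reading; the additive form nests it).

**Within-individual model.** For distances between calls of one bird:

$$\mu = \alpha_{ind} + \alpha_{same\,rec} + \alpha_{rec\,pair}
      + \alpha_{call_i} + \alpha_{call_j}$$

with $\bar\alpha \sim \mathrm{normal}(0, 0.25)$,
$\sigma \sim \mathrm{exponential}(5)$, group SDs
$\sim \mathrm{exponential}(3)$, and $\alpha_{same\,rec}$ a single scalar
offset (prior normal(0, 0.5)) applied when both calls come from one
recording. $\alpha_{ind}$ — the bird's average distance between its own
calls — is the contact-call diversity measure.

Distances are z-scored before fitting so these priors are weakly
informative regardless of the DTW scale; the transform is inverted on
export and all reported estimates are on the input scale. Models are
fitted by Gibbs/slice MCMC (rjags). Convergence is monitored with
split-Rhat; any hyperparameter above 1.01 raises a warning rather than
silently passing. Equal-tailed 89% posterior intervals are reported
throughout. The exponential scale priors carry a truncation floor at
0.001 (≈0.05–0.2% of prior mass) purely as a numerical guard: without it,
degenerate inputs (e.g. exactly constant distances) drive a precision to
infinity and abort the sampler.

## Stage 2: effect models with error propagation

Exported unit summaries (posterior mean $m_i$, SD $s_i$) enter a
latent-truth regression:

$$m_i \sim \mathrm{normal}(\ell_i, s_i), \qquad
\ell_i \sim \mathrm{normal}(a + X_i b, \sigma)$$

with slopes $b \sim \mathrm{normal}(0, 0.5)$, intercept prior
configurable (repertoire-entropy models use normal(1, 1), matching the
entropy scale), and $\sigma \sim \mathrm{exponential}(2)$. Dyadic
outcomes additionally get multi-membership varying intercepts
$u_{id_i} + u_{id_j}$, absorbing the non-independence of dyads sharing a
member. Continuous predictors are z-scored; binary predictors are left
as 0/1. The outcome is z-scored internally for sampling (the printed
priors assume a standardised scale) and every reported parameter is
back-transformed. Setting $s_i \to 0$ recovers an ordinary hierarchical
regression, which the test suite uses as a limiting-case cross-check
against `lm()`.

Information-content models default to a normal likelihood on square-root
counts (variance-stabilising at these low counts, and robust to the mild
overdispersion the generator produces); a Poisson log-link variant is
available and satisfies the usual invariance (doubling all counts shifts
the intercept by $\log 2$ and leaves slopes unchanged).

**Total vs direct effects.** Covariate sets come from explicit causal
diagrams shipped as JSON (`inst/extdata/dags.json`). For a total effect
the adjustment set is the exposure's parents — with all confounders
observed, as in these diagrams, this closes every back-door path; for a
direct effect the mediators (nodes on directed exposure→outcome paths)
are added. The shipped model registry
(`inst/extdata/model_registry.json`) records, for every planned model,
the outcome, exposure, effect kind and adjustment set, plus a note where
the source material's single-letter abbreviations are ambiguous (`S` is
both "similarity" and "sex"; "N" both "nesting network" and "network
position"). The diagrams are inputs, not estimates: no causal discovery
is attempted.

## Repertoire diversity

Per-individual Shannon entropy $-\sum_i p_i \log p_i$ over call-type
proportions, natural log (the base is exposed as an argument; the choice
is conventional and affects only the scale). Only individuals with at
least 30 vocalizations are included — below that, entropy is dominated by
sampling noise. Zero-count types contribute zero (the $p\log p \to 0$
limit).

Composition is modelled Dirichlet-multinomially:

$$x_i \sim \mathrm{multinomial}(p_i), \quad
p_i \sim \mathrm{dirichlet}(\pi_i \theta), \quad
\pi_{ik} = \frac{s_{ik}}{\sum_k s_{ik}}, \quad
s_{ik} = \exp(\log\alpha_k + \beta_k A_i + \delta_k F_i)$$

with $\theta \sim \mathrm{exponential}(0.2)$ (how far individuals stray
from their expected proportions),
$\alpha \sim \mathrm{dirichlet}(5, 0.5, \ldots, 0.5)$ (the first — contact
— type dominates real repertoires) and per-type covariate effects
$\beta, \delta \sim \mathrm{normal}(0, 0.5)$. Sex enters as a type-specific
additive term $\delta_k$ on the log-abundance scale; the female–male
contrast is reported per type on the *proportion* scale
($\mathrm{softmax}(\log\alpha + \delta) - \alpha$), where the contrasts
necessarily sum to zero. The two rarest types (`frill`, `other_tonal`)
are excluded from the composition model; the ≥30-call filter is applied
on the full total *before* the exclusion.

Two identifiability facts shape the implementation. First, adding a
constant to all per-type log-effects leaves the softmax unchanged, so
$\beta$ and $\delta$ are identified only up to an additive constant; the
fit therefore reports both raw and sum-to-zero-centred versions, and the
centred ones are the quantities to interpret (the synthetic generator
draws sum-to-zero effect vectors for the same reason). Second, the
per-individual Dirichlet draw can be integrated out analytically, giving
the Dirichlet-multinomial likelihood

$$\log P(x_i) = \log\Gamma(\theta) - \log\Gamma(n_i + \theta)
 + \sum_k \left[\log\Gamma(x_{ik} + \theta\pi_{ik})
 - \log\Gamma(\theta\pi_{ik})\right] + \text{const}.$$

The package samples this marginalised posterior directly with a
component-wise adaptive random-walk Metropolis sampler:
$\alpha$ through its exact gamma representation
($g_k \sim \Gamma(a_{0k}, 1)$ on the log scale, $\alpha = g/\sum g$,
which *is* the stated Dirichlet prior), $\theta$ on the log scale, and
$\beta, \delta$ directly. Proposal scales adapt towards 44% acceptance
during warmup and are frozen for the retained draws, preserving detailed
balance. Sampling the per-individual simplexes explicitly is avoided on
purpose: their conditional density is unbounded at the simplex boundary
whenever a concentration drops below one, which general-purpose slice
samplers handle badly; the marginal form has no such boundary.

## The synthetic-data generator

The generator is first-class code: every analysis stage can be exercised
against data whose truth is recorded (`ground_truth` objects). It
emulates:

* a colony of individuals packed into nest chambers of 1–4 birds and
  trees of at most 20, uniformly placed in a 1 km square — the chamber
  and tree ranges match what a field survey of an established colony
  records; ages log-normal (median ≈ 900 days, roughly the mixed-age
  structure of an urban population), sexes balanced with a small unsexed
  fraction;
* session-structured foraging sightings (gambit of the group) and typed
  interactions, with allopreening concentrated within nest entries
  (default 95% fidelity) — this is what makes the synthetic mate layer
  meaningful;
* a relatedness matrix with small baseline values and designated kin
  pairs near 0.5 — relatedness estimation itself is out of scope, so the
  matrix is an input, not an inference;
* calls whose type counts follow *exactly* the Dirichlet-multinomial
  model above (so the composition fit is tested against its own
  generative model), and whose F0 contours are smooth sums of sinusoids
  parameterised by a 3-D latent embedding per call: each individual has a
  centroid, calls scatter around it, and DTW distance between contours
  grows with embedding distance. Optional hooks tie the embedding to the
  social structure: a `dyad_effect` pushes the centroids of connected
  dyads apart (or together) along a network's edges, and
  `within_sd_slope` ties within-individual spread to a covariate. The
  distributional form of within-individual variation is not prescribed by
  the field data; an isotropic Gaussian scatter in embedding space is the
  documented choice, and any smooth unimodal alternative would serve.

What the generator does **not** emulate — and hence what green tests do
not certify about real data: audio, spectral structure and F0-extraction
error; observation biases in who gets sighted; temporal drift across a
field season; non-Gaussian heavy tails in acoustic variation; and
misclassified call types.

Direct model-scale generators (`simulate_dyadic_distances`,
`simulate_within_distances`, `simulate_measured_outcomes`,
`simulate_dyadic_outcomes`, `simulate_peak_counts`) draw from the exact
likelihoods the fits assume, for parameter-recovery and calibration
testing uncontaminated by the acoustic layer.

## Numerical and design choices

* **Sampler defaults** are 4 chains × (1000 warmup + 1000 draws), with
  per-chain deterministic seeds derived from one config seed; every fit
  in the package is exactly reproducible. The pipeline default and the
  test/calibration suites use 2 chains × a few hundred iterations: these
  conditionally conjugate models mix quickly (split-Rhat is checked every
  fit), and the suites were sized so a complete run stays in the minutes
  range — the calibration suites use 150 dyads × 8 observations, 60
  individuals × 15 calls, n = 80 stage-2 units and n = 60 repertoires,
  scales at which every parameter of interest is comfortably identified.
* **Fixed-truth interval coverage** in those suites behaves as theory
  predicts: the posterior for a group-level SD concentrates around the
  *realized* spread of the drawn effects, which itself fluctuates around
  the generating value (for 150 dyads, SD ≈ $0.4/\sqrt{2 \cdot 149}$),
  so ~85–90% of 89% intervals cover the generating value.
* **Ties and determinism**: DTW tie-breaks by shortest optimal path;
  pipeline stage seeds are `seed * 1000 + stage`; subsampling of call
  pairs is seeded; two runs with one config are byte-identical.
* **Degenerate inputs**: constant distances are handled (no z-scoring,
  scale-prior floors); all-equal counts yield a near-zero
  between-individual SD; an individual with a single call contributes no
  within-individual pairs; unassigned individuals propagate `NA` group
  sizes rather than zeros.
* **Complete-case analysis** per model: each stage-2 model uses the units
  with complete data for *its* variables, so different models have
  different n — reported in the effect table.

## Known limitations

* The DAGs are assumptions; total/direct adjustment is only as good as
  the diagrams, and parents-of-exposure is a valid back-door set only
  because the diagrams contain no unobserved confounders.
* The slope prior normal(0, 0.5) meaningfully shrinks standardised
  effects approaching one outcome-SD; for the small effects this analysis
  targets that is the intended regularisation, but recovery tests of
  large planted effects check sign and detection rather than unshrunk
  magnitude.
* Raw $\alpha$ components of the composition model mix more slowly than
  their contrasts (a softmax ridge shared with any sampler of this
  model); inferences are drawn from contrasts and centred effects, which
  mix well.
* The repertoire-entropy regression treats entropy as exactly measured
  (its sampling error at ≥30 calls is small but not zero); the
  composition model, which does account for count noise, is the primary
  analysis of repertoire structure.
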