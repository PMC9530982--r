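---
title: "Confidant networks and depressive-symptom homophily: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Confidant networks and depressive-symptom homophily: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(confnet)
```

## The scientific problem

Depression in later life tends to go untreated, and whether older adults
befriend others with a similar symptom burden ("homophily") matters for
how support and intervention propagate through a community. confnet
implements the full analysis pipeline for one study design: a postal
survey of community-dwelling adults aged 65+ that collects household
listings, name-only nominations of community confidants, the 15-item
Geriatric Depression Scale (GDS-15), and functional covariates. The
pipeline turns those records into a directed network ("i regards j as a
confidant"), summarises it, and estimates symptom homophily with an
exponential random graph model (ERGM).

## Tie identification

Ties are identified in two steps.

**Household step.** Every co-residing participant is a confidant of the
respondent, with one exception: a respondent who reports poor marital
satisfaction (by default a score above 6 on the 10-point scale) *and*
reports having no confidants does not get ties to opposite-sex
co-residents within 15 years of age (the likely spouse). The
parenthetical "more than six points" that motivates the default is
ambiguous about the direction of the satisfaction scale; we orient the
scale so higher means more dissatisfied and expose both the threshold
and the orientation in `tie_rules()`. The exception clause itself is
convoluted in the source instrument; `confnet` implements the literal
reading (suppress likely-spouse ties for dissatisfied respondents
reporting no confidants) and keeps it configurable rather than
asserting it as the only possible intent.

**Community step.** A written nomination (family and given name)
resolves to a roster member only if all five criteria hold: (1) exact
name equality in either the kanji or the kana rendering, after Unicode
NFC normalisation and whitespace trimming — "spelled the same" is
exact-match language, so no fuzzy matching is attempted; (2) same sex
as the nominator; (3) at most 3 years of age difference from the
nominator; (4) same district but different address; (5) a unique
candidate after (1)–(4). Criteria (2)–(4) compare the candidate to the
*nominator* because a nomination carries nothing but a name; this is
the only reading under which they are computable. Every nomination
receives an audit outcome (`matched`, `no_candidate`,
`excluded_by_criterion`, `ambiguous`), so match loss is observable
rather than silent.

## Scales and covariates

GDS-15 items are dichotomous; each contributes a point when answered in
the symptomatic direction under the standard published keying
(positively worded items — "full of energy", "happy most of the time",
"wonderful to be alive", and so on — score on "no"). The key is an
explicit table (`gds_item_key()`) so an alternative keying can be
swapped in. The apathy subscale (3 items, 0–3) and suicidal-ideation
subscale (5 items, 0–5) are disjoint subsets of the 15 items. Missing
items never zero-fill: any missing response blanks all three scores and
excludes the participant from the analysis set.

Covariates follow the reference codings of the reporting tables:
female vs male; age 75+ vs under 75 (the boundary age 75 codes 1, the
literal reading of "ref: <75 years-old"); household of two or more vs
living alone; disability as a TMIG-IC score below the full 13;
education dummies for 10–12 and 13+ years against a reference of 9
years or less. The "other/unknown" education band is excluded listwise
by default (a `code_covariates()` switch turns it into its own
indicator instead). The subjective-memory-complaint scale is scored as
four frequency items of 1–7 points summing to 4–28 — only the range
and direction are fixed by the instrument description, and four 1–7
items is the natural decomposition; the severe-problem item is carried
as metadata. SMC is computed and reported but not included in the
default model term sets, which mirror the reporting tables (term lists
are fully configurable).

## The model

For each ordered pair the outcome is $Y_{ij} \in \{0,1\}$. The ERGM
places $P(Y = y) \propto \exp(\theta^\top s(y))$ over directed graphs,
with statistics

* `edges` — the directed tie count (intercept);
* `mutual` — the number of reciprocated dyads (the "reciprocity" term);
* `nodal:x` — $\sum_{ij} y_{ij}(x_i + x_j)$, a nodal main effect
  (sender+receiver sum convention, matching a single reported row per
  attribute; directional sender-only/receiver-only variants are outside
  the dyad-symmetric family this engine exploits and are not provided);
* `absdiff:x` — $\sum_{ij} y_{ij} |x_i - x_j|$, the similarity term. A
  negative coefficient is homophily: each additional point of score
  difference multiplies the tie odds by $e^\theta$.

Every one of these statistics decomposes over unordered dyads, each of
which occupies one of four states (null, $i{\to}j$, $j{\to}i$, mutual).
The likelihood therefore factorises into independent four-state
multinomials, and

$$\ell(\theta) = \theta^\top s(y^{obs}) - \sum_{d} \log
  \left(1 + 2e^{\eta_d} + e^{2\eta_d + \theta_{mut}}\right),$$

with $\eta_d$ the one-tie linear predictor of dyad $d$, can be
maximised *exactly* by Newton–Raphson (`fit_exact()`), with standard
errors from the inverse observed information. No MCMC approximation is
needed for this term family; that is the package's central
computational observation, and it gives every stochastic estimator an
exact oracle.

Three other estimation routes are provided for fidelity to common
practice and for future non-separable terms:

* `fit_mple()` — maximum pseudolikelihood, the logistic regression of
  every $Y_{ij}$ on its change statistic. For models without `mutual`
  the model is dyad-independent and MPLE *equals* the exact MLE (a
  property the tests assert); with `mutual` its standard errors ignore
  dyad dependence and should be treated as approximate.
* `simulate_ergm()` — Metropolis–Hastings over uniform single-tie
  toggles, with the acceptance ratio $\exp(\theta^\top\delta_{ij})$.
  Defaults: burn-in $10\,n(n-1)$ proposals and thinning $n(n-1)$,
  i.e. ten sweeps before the first draw and one sweep between draws;
  both configurable. A tie/no-tie proposal mixture was considered and
  not implemented: at the densities this pipeline targets the uniform
  sampler mixes adequately within those defaults, which the
  dyad-state goodness-of-fit test verifies against the exact
  distribution. The sampler is written in C++ and tracks sufficient
  statistics incrementally; it uses R's RNG, so runs are reproducible
  under `set.seed()`.
* `fit_mcmle()` — Monte-Carlo MLE: start at the MPLE, repeatedly
  simulate at the current estimate and maximise the importance-sampled
  likelihood ratio inside a trust region (coefficient steps capped at
  0.5 by default, since importance weights degrade with distance),
  stopping when simulated mean statistics match the observed
  statistics within 0.15 simulated standard deviations per term.
  Standard errors use the covariance of simulated statistics at the
  final estimate — the Fisher information of an exponential family.
  Non-convergence is flagged on the returned fit and warned about,
  never silent.

Reported odds ratios are $e^{\hat\theta}$ with 95% Wald bounds
$e^{\hat\theta \pm z_{0.975}\hat{se}}$; $z_{0.975}$ is fixed at
1.959964 internally and rounding to two decimals happens only in
`format_fit_table()`, which reproduces the published reporting
convention (structural terms show no OR). Two-sided normal p-values
are attached; significance language is left to the analyst.

Nodes missing any model attribute are dropped listwise before fitting,
with the dropped count recorded on the fit. Degenerate inputs fail
loudly: separation (an observed statistic on the boundary, e.g. a
complete or empty graph) raises an error naming the offending terms, as
does a collinear design.

## Network descriptives

Density follows the duplicate-collapsing convention: two participants
are "tied" if at least one of them named the other, and the collapsed
tie count is divided by $n(n-1)/2$ (for $n = 660$: 217,470 potential
ties). Components and geodesic distances are computed on the undirected
collapse with isolates excluded, via igraph; the mean geodesic averages
shortest paths over pairs within the same component. Whether geodesics
should respect tie direction is genuinely open for this design; the
undirected choice matches how "number of social networks" treats
relations symmetrically, and is documented rather than hidden. Density
is reported to 3 decimals and the mean geodesic to 1, with full
precision retained in the returned objects.

## The synthetic-community generator

Because survey data of this kind cannot be redistributed, the generator
is a first-class module: every pipeline stage is tested against
communities whose ground truth is known. Its defaults emulate the
target study population — about 660 adults 65+, mean age 76.2 (SD 7.3),
53.2% female, 85.1% living with family, GDS-15 mean 5.0 with SD near
3.8 (apathy 1.4, suicidal ideation 1.3), SMC 10.5 (SD 4.9), disability
prevalence 0.545 on the non-missing scale — and a sparse directed
network with collapsed density near 0.001, strong reciprocity and
negative similarity coefficients.

Choices worth knowing about:

* **GDS items** are conditionally independent Bernoullis given a
  per-person latent propensity on the logit scale. Item intercepts are
  recalibrated by quadrature so the *marginal* item means stay on
  target whatever the latent SD; the default SD of 1.4 was chosen once
  to put the total-score SD near 3.8. An optional household-shared
  component of the latent exists (`gds_household_cor`, default 0). The
  exact distributional shape of the real scale is explicitly a
  non-goal.
* **Households**: a configurable share of participants (default 20%)
  live as opposite-sex participant couples sharing surname, household
  and address; younger non-participant co-residents are added until
  the living-with-family share reaches its target. The education band
  "9 years or less" is split as 5% under 6 years and 27.6% at 6–9
  years — only the combined share is constrained by the emulated
  population.
* **Names** come from finite Japanese surname/given pools with both
  kanji and kana renderings. In noiseless mode full names are unique in
  both renderings, which makes criterion (1) decisive and the survey
  exactly re-identifiable; the collision rate is the identifiability
  dial in noisy mode, and an out-of-roster rate appends nominations
  that match nobody.
* **Ground-truth network**: out-of-household ties are drawn from the
  configured ERGM *restricted to the identifiable dyad support* (same
  sex, ≤3-year gap, same district, different address), so every
  emitted nomination can be re-matched. Household ties are then added
  deterministically by the household identification rule itself
  (mutual ties, minus the marital-dissatisfaction suppression) rather
  than sampled: the tie builder will deterministically identify all
  co-residents, so sampling household dyads would make the noiseless
  round-trip — the module's central invariant — unattainable. The
  confidant-presence flag is filled after sampling (everyone with an
  outgoing community tie reports a confidant, topped up to the
  configured 58.3% share) so the emitted survey is internally
  consistent with the suppression rule.
* **The default coefficient preset** (edges −3.8, reciprocity 2.9,
  GDS similarity −0.05 on the constrained support) targets the
  descriptive regime above — roughly 300 directed ties at $n = 660$,
  about 60% of them reciprocated once household ties are included. It
  is a documented emulation choice, not an estimate of any real
  community's parameters.

Because the constrained support is part of the generating model,
recovery experiments condition on it: `fit_exact(..., allowed = )`
restricts the likelihood to the same dyad set, making
generate → emit → rebuild → fit an exact self-consistency loop.

## Validation strategy and problem sizes

The test suite pins each layer to an independent oracle:

* exact likelihood vs brute-force enumeration of all $2^{n(n-1)}$
  directed graphs at $n = 3, 4$ (tolerance 1e-10);
* change statistics vs recomputed global statistics under exhaustive
  single-tie toggles;
* MPLE vs exact MLE on dyad-independent models;
* sampler dyad-state frequencies vs the exact four-state law at
  $n = 3$ (chi-square, $\alpha = 0.01$);
* MCMC-MLE vs exact MLE on simulated networks;
* parameter recovery across 100 simulated communities of $n = 100$ at
  a fixed preset (edges −4.5, mutual 3.0, similarity −0.10, sized so
  each community carries enough ties and mutual dyads for the MLE to
  exist): mean estimates within 3 Monte-Carlo standard errors and 95%
  CI coverage inside [0.85, 0.99];
* noiseless round-trip equality of edge sets, plus one perturbation
  fixture per matching criterion flipping exactly its target
  nomination.

These sizes were chosen so the whole suite runs in minutes on one CPU
while keeping every check statistically meaningful.

What passing tests do *not* show: the generator makes no attempt to
reproduce real name-frequency distributions, non-response, reporting
error in ages, or geographic structure beyond uniform districts, so
matching performance on real survey records (where ambiguity and
misspelling are endemic) will be worse than the noiseless round-trip
suggests; the noisy mode exists to probe exactly that degradation.

## Known limitations

* Only dyad-separable terms (edges, mutual, nodal sums,
  absolute-difference) are supported; triangles, degree terms, GWESP
  and other Markov terms are out of scope, as are curved ERGMs,
  Bayesian estimation and valued ties.
* Pseudolikelihood standard errors with a `mutual` term are known to
  be optimistic; use `fit_exact()` (default) or `fit_mcmle()`.
* The analysis is cross-sectional by design: nothing here separates
  selection (similar people befriend) from influence (friends become
  similar).
* Dyads involving non-respondents are excluded from the network by
  construction, which depresses density relative to the full
  community.

## A worked example

```{r, eval = FALSE}
cfg <- community_config(seed = 1)          # 660-person default community
sim <- simulate_community(cfg)
built <- build_network(sim$survey$participants,
                       sim$survey$household_members,
                       sim$survey$nominations)
describe_network(built$network)
fit_exact(built$network, default_model_terms("gds_total"))
```

The same flow is available as files-on-disk commands
(`cmd_simulate()`, `cmd_build()`, `cmd_describe()`, `cmd_fit()`), each
writing a JSON manifest so any artifact is traceable to its seed and
configuration.
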