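# confnet

Confidant-network construction and depressive-symptom homophily
analysis for community surveys of older adults.

## The problem

Postal surveys of community-dwelling adults aged 65+ can measure who
confides in whom: respondents list their household members and write
the names of the non-coresiding people in the community to whom they
disclose their worries. Turning those records into a directed network
and asking whether people with similar depressive-symptom burdens are
more likely to be tied ("homophily") takes four nontrivial steps, all
implemented here:

1. **Scoring** (`score_gds`, `score_smc`, `code_disability`,
   `code_covariates`) — the 15-item Geriatric Depression Scale with its
   3-item apathy and 5-item suicidal-ideation subscales, subjective
   memory complaints (4–28), TMIG-IC disability (< 13 of 13), and the
   reference-coded demographic covariates.
2. **Tie identification** (`identify_household_ties`,
   `match_nomination`, `build_network`) — co-residing participants
   become confidants (with a marital-dissatisfaction exception), and a
   written nomination resolves only when five criteria hold: exact
   name equality in kanji or kana, same sex as the nominator, at most
   3 years of age difference, same district but different address, and
   uniqueness of the candidate. Every nomination gets an audit outcome.
3. **Descriptives** (`describe_network`) — directed/one-way/reciprocal
   tie counts, duplicate-collapsed density
   (ties ÷ *n*(*n*−1)/2), components and mean geodesic distance.
4. **Modelling** (`fit_exact`, `fit_mple`, `simulate_ergm`,
   `fit_mcmle`) — a directed exponential random graph model
   P(Y = y) ∝ exp(θᵀs(y)) with statistics `edges`, `mutual`
   (reciprocity), nodal main effects Σ y_ij (x_i + x_j) and the
   homophily term Σ y_ij |x_i − x_j|. All of these decompose over
   dyads, so the likelihood factorises into per-dyad four-state
   multinomials and is maximised **exactly** by Newton–Raphson —
   MPLE, Metropolis–Hastings simulation (C++), and Monte-Carlo MLE are
   provided alongside, each testable against the exact estimator.
   Results are reported as odds ratios with 95% Wald intervals,
   exp(θ̂ ± 1.959964·SE): a similarity OR below 1 means each extra
   point of score difference multiplies the tie odds by that factor.

Because real survey rosters of this kind cannot be shared, a
**synthetic-community generator** (`community_config`,
`simulate_community`) is a first-class module: it emits survey tables
with a known ground-truth network (re-identifiable by construction in
noiseless mode), which is how the whole pipeline is validated.

## Worked example

```r
library(confnet)

cfg   <- community_config(seed = 7)       # 660-person default community
sim   <- simulate_community(cfg)
built <- build_network(sim$survey$participants,
                       sim$survey$household_members,
                       sim$survey$nominations)
describe_network(built$network)
#> Confidant network descriptives
#>   participants (n)             660
#>   density                      0.001
#>   vertices with >=1 tie        320
#>   total directed ties          293
#>     inside the household       127
#>     outside the household      166
#>     one-way                    139
#>     reciprocal (two-way)       154
#>   social networks (size range) 105 (2-18)
#>   mean geodesic distance       2.8

fit_exact(built$network, default_model_terms("gds_total"))
#> Dyad-separable directed ERGM (exact_dyad)
#>   653 nodes, 212878 dyads in support; 7 node(s) dropped for missing attributes
#>                     term coefficient    se p_value           or_95ci
#>                    edges       -8.82 0.300   0.000
#>                   mutual        8.10 0.210   0.000
#>        absdiff.gds_total       -0.02 0.016   0.317 0.98 (0.95, 1.02)
#>             nodal.female        0.00 0.068   0.957 1.00 (0.88, 1.15)
#>           nodal.age_ge75        0.05 0.069   0.426 1.06 (0.92, 1.21)
#>  nodal.lives_with_family        0.36 0.120   0.004 1.43 (1.12, 1.82)
#>         nodal.disability        0.01 0.068   0.895 1.01 (0.88, 1.15)
#>          nodal.edu_10_12        0.10 0.078   0.189 1.11 (0.95, 1.29)
#>         nodal.edu_13plus        0.01 0.100   0.901 1.01 (0.83, 1.23)
#>          nodal.gds_total        0.00 0.009   0.659 1.00 (0.99, 1.02)
```

Reading the output: the community is sparse (collapsed density 0.001 —
about one tie per thousand potential pairs), reciprocity is strong
(coefficient 8.10: a tie is enormously more likely if its reverse
exists), and the similarity row says each extra point of GDS-15
difference multiplies the tie odds by 0.98 (95% CI 0.95–1.02) — mild
homophily, consistent with the generator's preset of −0.05 given one
draw's sampling noise. The 7 dropped nodes are the participants whose
education band is "other/unknown" under the default listwise handling.

The same stages run as file-based commands (`cmd_simulate`,
`cmd_build`, `cmd_describe`, `cmd_fit`), each writing a JSON run
manifest; a thin CLI wrapper lives at
`inst/scripts/confnet-cli.R` (`simulate | build | describe | fit`).

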