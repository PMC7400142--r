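# fcmpanel

Consensus fuzzy cognitive maps from multi-expert rating panels.

Semi-quantitative system modelling with fuzzy cognitive maps (FCMs) is a
standard way to capture how a group of domain experts believes the factors
of a complex problem influence one another — for example, how
post-migration risk factors (housing, language skills, residence security,
access to care) jointly shape the mental health of unaccompanied minor
refugees. `fcmpanel` implements the full elicitation-to-model pipeline for
this kind of study:

1. **Factor consolidation.** Raw factors elicited independently by several
   workshop panels are reduced to a shared main-factor set with
   keep / merge / split / exclude actions
   (`apply_consolidation()`, `validate_mapping()`).
2. **Consensus aggregation.** Each expert rates every ordered factor pair
   on a 0–10 scale. A directed influence *s → t* enters the model only if

   * at least ⌈q·K⌉ of the K experts rate it strictly above 0
     (quorum, default q = 2/3 — "at least four of six"), and
   * the group mean rating exceeds the threshold μ (default 5.0);

   the retained edge weight is that mean (`fcm_consensus()`,
   `consensus_weight()`). Edges with weight below the display threshold
   (default 5.0) are retained but flagged, mirroring the convention of
   drawing only the stronger relations in a published final model.
3. **Network metrics.** Absolute and weighted in/out degree (per cent of
   total edge weight), influence categories (medium 5.0–5.9,
   strong 6.0–6.9, powerful ≥ 7.0), reciprocal dyads, self-reinforcing
   triads and indirect influence paths (`degree_table()`,
   `motif_census()`, `influence_paths()`, `summary()`).
4. **Scenario dynamics.** Standard FCM inference
   `a′ = σ(λ(Σⱼ sign·(wⱼᵢ/10)·aⱼ + m·(2aᵢ−1)))` with logistic squashing σ,
   clamped interventions and convergence / limit-cycle detection
   (`run_scenario()`, `predict()`, `compare_scenarios()`).
5. **Synthetic panels.** A seeded generator draws ground-truth models and
   noisy expert panels (rating noise, edge-detection dropout, false
   positives) so the consensus rule can be benchmarked by its edge
   recovery — sensitivity, specificity, F1, weight RMSE
   (`generate_truth()`, `simulate_panel()`, `recovery_metrics()`,
   `recovery_sweep()`).

Models are plain S3 objects with `print`, `summary`, `coef` (signed
weight matrix), `plot`, `simulate` (draw panels from a truth) and
`predict` (steady state under clamps) methods, and can be exchanged as
GraphML or DOT (`write_model()` / `read_model()`).

## Worked example

The package ships the published final system model of post-migration risk
factors for unaccompanied minor refugees (11 factors; text-attested edges;
group-mean impact scores on a 0–1 scale) as plain-text fixtures:

```r
library(fcmpanel)
m <- umr_final_model()
summary(m)
#> Consensus system model: 11 factors, 24 edges (24 at display threshold)
#>
#>                          name impact in in_w% out out_w%
#>               Social contacts   0.78  6    25   3     13
#>                   Health care   0.77  1     4   0      0
#>                       Housing   0.77  2     8   0      0
#>                   Social care   0.75  1     4   1      4
#>              Daily activities   0.72  3    12   1      4
#>            Residence security   0.70  1     4   3     12
#>           Access to education   0.67  2     8   4     17
#>               Income security   0.65  3    13   3     12
#>      Sociocultural adaptation   0.58  2     8   2      9
#>  Political and social climate   0.53  0     0   3     13
#>        German language skills   0.52  3    14   4     17
#>
#> Motif census:
#>   reciprocal pairs:         5
#>   directed 3-cycles:        3
#>   fully reciprocal triads:  1
#>     { german_language, social_contacts, sociocultural_adaptation }
#>
#> Influence categories: medium [5.0, 6.0), strong [6.0, 7.0), powerful [7.0, 10]
```

Social contacts is the most impactful factor (0.78, "powerful") and also
the most influenced one: six incoming ties carrying 25 % of the model's
edge weight. The political and social climate influences others but is
influenced by nothing — an upstream lever. The single fully reciprocal
triad (sociocultural adaptation ↔ German language skills ↔ social
contacts) is the model's self-reinforcing core: any change there feeds
back on itself.

What-if scenarios propagate a clamped intervention through the map. Here,
a deteriorating societal climate (activation clamped from 0.9 down to
0.2):

```r
compare_scenarios(m,
  baseline     = list(clamp = c(political_climate = 0.9)),
  intervention = list(clamp = c(political_climate = 0.2)))
#>                    factor baseline intervention   delta
#>          access_education   0.7093       0.6969 -0.0123
#>          daily_activities   0.8127       0.8071 -0.0056
#>           german_language   0.8374       0.8327 -0.0048
#>               health_care   0.6167       0.6148 -0.0018
#>                   housing   0.6948       0.6812 -0.0137
#>           income_security   0.7923       0.7794 -0.0129
#>         political_climate   0.9000       0.2000 -0.7000
#>        residence_security   0.6318       0.5300 -0.1018
#>               social_care   0.6318       0.5300 -0.1018
#>           social_contacts   0.9444       0.9089 -0.0355
#>  sociocultural_adaptation   0.7523       0.7477 -0.0046
#> Impact-weighted composite delta: -0.5841
```

Every factor moves down (all influences in this model are positive), the
directly fed factors (residence security, social care) most, and the
impact-weighted composite summarises the total load on the modeled
outcome. The dynamics are a documented extension of the elicitation
study design: the update rule is the canonical FCM inference, not an
elicited quantity — see the vignette (`vignettes/consensus-cognitive-maps.Rmd`).

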