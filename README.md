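# exoNiche

Infer directional pairwise interactions among bacterial isolates from
exometabolomic profiling of spent culture media.

When a panel of isolates is grown individually in a chemically defined
medium (tens of metabolites at equimolar concentration), LC-MS profiling
of the spent media reveals which substrates each isolate depletes and
which metabolites it secretes. `exoNiche` turns those peak-height tables,
together with growth curves from sequential spent-medium re-culture
experiments, into a quantitative interaction analysis:

1. **Gated fold changes.** For each (metabolite, isolate) the relative
   fold change `FC = mean(spent)/mean(control) − 1` against the matched
   uninoculated medium control, computed only when a one-way ANOVA with a
   Dunnett-style many-to-one post hoc test finds the difference
   significant (otherwise FC is exactly 0). Negative FC is depletion,
   positive is production.
2. **Utilization metrics.** Per isolate: richness (number of substrates
   depleted), abundance (sum of the percentages of depletion) and
   diversity (inverse Simpson index over the depletion fractions).
3. **Predicted interaction strengths.** Directional niche overlap of
   recipient *r* and influencer *i* over depletion fractions
   *p*<sub>m</sub>:

   PIS<sub>ri</sub> = −Σ<sub>m</sub> p<sub>m,r</sub> p<sub>m,i</sub> / Σ<sub>m</sub> p<sub>m,r</sub>²

   (0 for disjoint substrate use, −1 for identical profiles), and the
   competitive rank R<sub>r</sub> = Σ<sub>i</sub> (PIS<sub>ri</sub> −
   PIS<sub>ir</sub>).
4. **Measured interaction strengths.** From sequential growth of each
   recipient in each influencer's spent medium,
   MIS<sub>ri</sub> = Growth<sub>r,i</sub>/Growth<sub>r,SDM</sub> − 1
   (bounded below by −1), for two growth metrics — blank-corrected final
   OD600 and MicroResp cumulative CO₂ respiration (ΔA570) — with
   per-recipient Dunnett significance against the fresh-medium reference.
5. **Cross-feeding classification.** Untargeted features filtered
   against extraction blanks, then classified across the
   SDM → spent → double-spent trajectory: `cross_fed` (up then down),
   `sequentially_depleted` (down then down), `produced_not_consumed`,
   `recipient_produced`, `unchanged`.
6. **Reporting.** Pearson comparison of predicted vs. measured
   strengths, Cytoscape-ready GraphML/SIF network export, and a
   one-call `runPipeline()` driver.

A seeded synthetic-community generator (`simulateTruth()`,
`simulateMonocultures()`, `simulateSequential()`) produces complete
experiments with known consumption/secretion ground truth, so every
stage has an end-to-end recovery test without any external data.

## Worked example

```r
library(exoNiche)

## a standard 8-isolate, 60-metabolite pure-competition community
fx  <- fixtureCommunity(cv = 0.1, crossFeeding = FALSE)

fc  <- gatedFoldChanges(fx$mono$peaks)
#> FoldChangeMatrix: 60 metabolites x 8 isolates (alpha = 0.05)
#>   depleted cells: 182, produced: 4, gated to 0: 294, undefined: 0

P   <- utilizationProfiles(fc)
head(substrateMetrics(P), 4)
#>   isolate richness abundance diversity
#> 1    iso1       38 1967.1855 32.871753
#> 2    iso2        8  513.2816  7.053772
#> 3    iso3       34 1802.1854 28.661391
#> 4    iso4       12  576.1882  9.953429

pis <- predictedInteractions(P)
head(competitiveRank(pis)[order(competitiveRank(pis)$rank), ], 3)
#>   isolate    score rank
#> 1    iso1 1.648269    1
#> 3    iso3 1.596971    2
#> 5    iso5 1.541457    3

mis <- misMatrix(finalGrowth(fx$sequential$growth), metric = "final_od")
#> InteractionMatrix [MIS, final_od]: 8 x 8 isolates
#>   defined pairs: 56 (negative: 54, positive: 2)
#>   significant at alpha = 0.05: 32

cmp <- correlatePredictedMeasured(pis, mis)
sprintf("Pearson R = %.2f (p = %.2g, n = %d)", cmp$r, cmp$p, cmp$n)
#> "Pearson R = 0.74 (p = 1.1e-06, n = 32)"
```

Reading the numbers: the generalist iso1 depletes 38 of 60 substrates
(richness) with high evenness (inverse Simpson 32.9 close to its
richness), which earns it the top competitive rank. Almost all
significant measured interactions in this pure-competition community
are negative, and the measured strengths correlate positively with the
niche-overlap predictions — competition for shared substrates explains
most of the growth suppression.

`runPipeline(list(simulate = list(seed = 42)), "out/")` runs every
stage and writes all result tables (fold changes, metrics, PIS/ranks,
MIS matrices, cross-feeding calls, networks) into `out/`.

## Documentation

The methods vignette (`vignettes/exoNiche-methods.Rmd`) describes the
statistical model, the synthetic generator's assumptions, numerical
choices and known limitations.
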